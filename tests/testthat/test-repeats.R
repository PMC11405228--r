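test_that("minimum-count thresholds gate perfect SSR calls", {
  hits <- find_ssrs("GGCAAAAAAAACC")       # 8xA: at the monomer minimum
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$motif, "A")
  expect_identical(hits$repeat_count, 8L)
  expect_identical(hits$end - hits$start + 1L, 8L)
  expect_identical(nrow(find_ssrs("GGCAAAAAAACC")), 0L)   # 7xA: below
})

test_that("a planted hexamer is found amid random background", {
  set.seed(61)
  bg <- random_dna_str(2000)
  s <- paste0(substr(bg, 1, 1000), "G", strrep("CTATCC", 3), "A",
              substr(bg, 1002, 2000))
  hits <- find_ssrs(s)
  hex <- hits[hits$kind == "perfect" & hits$unit_len == 6, ]
  expect_true("CTATCC" %in% hex$motif)
  expect_true(any(hex$start == 1002 & hex$repeat_count >= 3))
})

test_that("sub-periodic runs resolve to the smallest period", {
  s <- paste0("GC", strrep("AT", 5), "GG")
  hits <- find_ssrs(s, minima = c(8, 4, 4, 2, 2, 2))
  expect_identical(hits$motif, "AT")      # no ATAT tetramer record
  # a poly-A run never surfaces as an AA dimer
  s2 <- paste0("GC", strrep("A", 9), "TT")
  h2 <- find_ssrs(s2, minima = c(8, 2, 2, 2, 2, 2))
  expect_identical(h2$motif, "A")
})

test_that("N never matches anything, including another N", {
  expect_identical(nrow(find_ssrs("CCANNNNNNNNNNGG",
                                  minima = c(8, 4, 4, 3, 3, 3))), 0L)
  expect_error(find_ssrs("ACGTX"), "position 5")
})

test_that("nearby runs merge into compound records within the spacing limit", {
  run1 <- strrep("A", 9)
  run2 <- strrep("TC", 5)
  sp50 <- "TATCCAGCCCTCTATTGTACTCCTATCTCAGCGCCTATGCCACTTCGACT"
  sp101 <- paste0("GAATTAAACCGTCCCTTACTCTGGGCTTGAATCCTACGTTAGTAGCCTTC",
                  "CCTCGCGTCCTTCGCGCTCTAGCATAGACCTGGCGACTGAGTATTCCTGTT")
  near <- paste0("GG", run1, sp50, run2, "AA")
  h <- find_ssrs(near)
  cmp <- h[h$kind == "compound", ]
  expect_identical(nrow(cmp), 1L)
  expect_identical(cmp$n_components, 2L)
  expect_identical(cmp$motif, "(A)9-(TC)5")
  far <- paste0("GG", run1, sp101, run2, "AA")
  h2 <- find_ssrs(far)
  expect_identical(nrow(h2[h2$kind == "compound", ]), 0L)
})

test_that("perfect SSR calls equal the per-start extension oracle", {
  set.seed(62)
  minima <- c(6L, 3L, 3L, 3L, 3L, 3L)   # denser calls on short sequences
  for (rep in 1:15) {
    s <- random_dna_str(800)
    got <- find_ssrs(s, minima = minima)
    got <- got[got$kind == "perfect",
               c("motif", "unit_len", "repeat_count", "start", "end")]
    exp <- oracle_ssrs(s, minima)
    if (is.null(exp)) {
      expect_identical(nrow(got), 0L)
    } else {
      rownames(got) <- rownames(exp) <- NULL
      expect_identical(got, exp)
    }
  }
})

test_that("every reported perfect SSR re-verifies on the input sequence", {
  set.seed(63)
  s <- paste0(random_dna_str(500), strrep("TTCT", 5), random_dna_str(500))
  h <- find_ssrs(s, minima = c(6, 3, 3, 3, 3, 3))
  h <- h[h$kind == "perfect", ]
  expect_gt(nrow(h), 0)
  for (i in seq_len(nrow(h))) {
    expect_identical(substr(s, h$start[i], h$end[i]),
                     strrep(h$motif[i], h$repeat_count[i]))
  }
})

test_that("circular scanning finds runs across the origin once", {
  s <- paste0("AAAA", random_dna_str(200), "CAAAA")  # 8xA across the origin
  lin <- find_ssrs(s)
  expect_identical(nrow(lin), 0L)
  circ <- find_ssrs(s, circular = TRUE)
  expect_identical(nrow(circ), 1L)
  expect_identical(circ$motif, "A")
  expect_identical(circ$start, nchar(s) - 3L)
  expect_identical(circ$repeat_count, 8L)
})

test_that("planted duplications and palindromes are detected with zero mismatches", {
  set.seed(64)
  s <- random_dna_str(700)
  s2 <- plant_pair(s, src = 101, dst = 501, len = 60)
  d <- find_dispersed_repeats(s2, min_len = 50)
  fwd <- d[d$kind == "forward" & d$start2 - d$start1 == 400, ]
  expect_true(any(fwd$start1 <= 101 & fwd$start1 + fwd$length >= 161))
  s3 <- plant_pair(s, src = 101, dst = 501, len = 60, palindromic = TRUE)
  d3 <- find_dispersed_repeats(s3, min_len = 50)
  pal <- d3[d3$kind == "palindromic" &
              d3$start1 + d3$start2 + d3$length == 101 + 501 + 60, ]
  expect_true(any(pal$start1 <= 101 & pal$start1 + pal$length >= 161))
  expect_error(find_dispersed_repeats(s, min_len = 6), "min_len")
})

test_that("dispersed repeats equal the greedy-window oracle on random sequences", {
  set.seed(65)
  for (rep in 1:8) {
    n <- sample(150:280, 1)
    s <- random_dna_str(n)
    if (rep %% 2 == 0) {   # plant one pair so long hits exist
      len <- sample(30:45, 1)
      s <- plant_pair(s, src = 5, dst = n - len - 4L, len = len,
                      mm = sample(0:3, 1), palindromic = rep %% 4 == 0)
    }
    for (kind in c("forward", "palindromic")) {
      got <- find_dispersed_repeats(s, min_len = 20, max_mismatch = 4,
                                    kinds = kind)
      exp <- oracle_dispersed(s, min_len = 20, max_mm = 4, kind = kind)
      cols <- c("kind", "start1", "start2", "length", "mismatches")
      if (is.null(exp)) {
        expect_identical(nrow(got), 0L)
      } else {
        got <- got[order(got$start1, got$start2, got$length), cols]
        rownames(got) <- rownames(exp) <- NULL
        expect_identical(got, exp[cols])
      }
    }
  }
})

test_that("palindromic pairs map onto themselves under reverse complement", {
  set.seed(66)
  s <- plant_pair(random_dna_str(400), src = 21, dst = 301, len = 50,
                  palindromic = TRUE)
  d <- find_dispersed_repeats(s, min_len = 40, kinds = "palindromic")
  expect_gt(nrow(d), 0)
  n <- nchar(s)
  src <- find_dispersed_repeats(revcomp_str(s), min_len = 40,
                                kinds = "palindromic")
  # transform: a copy at [a, a+len-1] maps to [n-(a+len-1)+1, n-a+1]
  mapped <- data.frame(
    start1 = n - (src$start2 + src$length - 1L) + 1L,
    start2 = n - (src$start1 + src$length - 1L) + 1L,
    length = src$length, mismatches = src$mismatches)
  o1 <- d[order(d$start1, d$start2), c("start1", "start2", "length",
                                       "mismatches")]
  o2 <- mapped[order(mapped$start1, mapped$start2), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_identical(o1, o2)
})

test_that("repeat detection is deterministic", {
  set.seed(67)
  s <- random_dna_str(1500)
  expect_identical(find_dispersed_repeats(s, min_len = 20, max_mismatch = 4),
                   find_dispersed_repeats(s, min_len = 20, max_mismatch = 4))
  expect_identical(find_ssrs(s), find_ssrs(s))
})

test_that("summary percentages are computed over the perfect-record total", {
  set.seed(68)
  recs <- data.frame(
    kind = "perfect",
    motif = sample(c("A", "T", "AG", "TTC"), 40, TRUE),
    repeat_count = sample(3:9, 40, TRUE), start = 1L, end = 1L)
  recs$unit_len <- nchar(recs$motif)
  sm <- ssr_summary(recs)
  expect_equal(sum(sm$by_unit$pct), 100)
  expect_identical(sum(sm$by_motif$n), 40L)
  expect_identical(sm$total, 40L)
  # empty input gives a zero table
  sm0 <- ssr_summary(recs[0, ])
  expect_identical(sm0$total, 0L)
  expect_identical(sum(sm0$by_unit$n), 0L)
})

test_that("motif canonicalization groups rotations and complements", {
  expect_identical(canonicalize_motif(c("TA", "AT", "GA", "TC")),
                   c("AT", "AT", "AG", "AG"))
})
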