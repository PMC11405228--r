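test_that("tRNAs are invisible to adjacency; constructed pairs come out right", {
  g <- make_ann(c("nad4", "trnm-cau", "nad5", "trnd-guc", "cob"),
                starts = c(100, 220, 250, 400, 500),
                ends = c(200, 240, 350, 430, 600),
                strands = c("+", "+", "+", "-", "-"),
                classes = c("cds", "trna", "cds", "trna", "cds"),
                L = 1000)
  ring <- adjacency_ring(g)
  expect_identical(nrow(ring), 3L)
  p <- find_tandem_pairs(g)
  expect_identical(nrow(p), 3L)
  r1 <- p[p$family_a == "nad4" & p$family_b == "nad5", ]
  expect_identical(r1$orientation, "same_strand_plus")
  expect_identical(r1$gap_bp, 49L)   # 250 - 200 - 1, tRNA in between ignored
  r2 <- p[p$family_a == "cob" & p$family_b == "nad5", ]
  expect_identical(r2$orientation, "opposite")
})

test_that("the wrap edge across the origin is included with a circular gap", {
  L <- 10000L
  g <- make_ann(c("genex", "geney"), starts = c(L - 500L, 50L),
                ends = c(L - 100L, 300L), L = L)
  p <- find_tandem_pairs(g)
  expect_identical(nrow(p), 2L)
  wrapp <- p[p$upstream == "genex", ]
  expect_identical(wrapp$gap_bp, 149L)   # (L - end) + start - 1
})

test_that("single-gene rings yield no pairs; self pairs obey allow_self", {
  g1 <- make_ann("nad1", 100, 500, L = 1000)
  expect_identical(nrow(find_tandem_pairs(g1)), 0L)
  g2 <- make_ann(c("atp9", "atp9"), c(100, 600), c(300, 800), L = 1000)
  expect_identical(nrow(find_tandem_pairs(g2)), 0L)
  expect_identical(nrow(find_tandem_pairs(g2, allow_self = TRUE)), 2L)
})

test_that("pair sets match the brute-force successor oracle on random annotations", {
  set.seed(31)
  for (rep in 1:40) {
    g <- random_annotation(sample(3:50, 1))
    got <- find_tandem_pairs(g, allow_self = TRUE)
    got <- got[order(got$upstream, got$family_a, got$family_b, got$gap_bp), ,
               drop = FALSE]
    exp <- oracle_tandem_pairs(g, allow_self = TRUE)
    n_ring <- nrow(adjacency_ring(g))
    if (n_ring >= 2L) {
      expect_identical(nrow(got), n_ring)  # ring edge-count invariant
    }
    if (is.null(exp)) {
      expect_identical(nrow(got), 0L)
    } else {
      rownames(got) <- rownames(exp) <- NULL
      cols <- c("family_a", "family_b", "upstream", "orientation", "gap_bp")
      expect_identical(got[cols], exp[cols])
    }
  }
})

test_that("tandem pairs are invariant under origin rotation", {
  set.seed(32)
  for (rep in 1:10) {
    g <- random_annotation(20)
    p0 <- find_tandem_pairs(g)
    g2 <- rotate_annotation(g, sample.int(g$genome_length, 1))
    p1 <- find_tandem_pairs(g2)
    cols <- c("family_a", "family_b", "upstream", "orientation", "gap_bp")
    s0 <- p0[do.call(order, p0[cols]), cols]
    s1 <- p1[do.call(order, p1[cols]), cols]
    rownames(s0) <- rownames(s1) <- NULL
    expect_identical(s0, s1)
  }
})

test_that("identical and fully inverted rings give the expected single block", {
  g1 <- make_ann(c("a", "b", "c", "z"), c(100, 300, 500, 700),
                 c(200, 400, 600, 800), strands = c("+", "+", "+", "-"),
                 L = 1000)
  g2 <- make_ann(c("a", "b", "c", "q"), c(50, 250, 450, 650),
                 c(150, 350, 550, 750), strands = c("+", "+", "+", "+"),
                 L = 1000, species = "T2")
  b <- find_shared_blocks(g1, g2)
  expect_identical(b$relation, "colinear")
  expect_identical(b$families, "a,b,c")
  # same genes in reversed order with flipped strands: inverted block
  g3 <- make_ann(c("c", "b", "a", "q"), c(50, 250, 450, 650),
                 c(150, 350, 550, 750), strands = c("-", "-", "-", "+"),
                 L = 1000, species = "T3")
  b2 <- find_shared_blocks(g1, g3)
  expect_identical(b2$relation, "inverted")
  expect_identical(b2$families, "a,b,c")
})

test_that("shared blocks match the exhaustive window oracle and are symmetric", {
  set.seed(33)
  pool <- sprintf("f%02d", 1:15)
  for (rep in 1:25) {
    g1 <- random_annotation(sample(5:12, 1), fam_pool = pool,
                            classes = "cds", species = "A")
    g2 <- random_annotation(sample(5:12, 1), fam_pool = pool,
                            classes = "cds", species = "B")
    got <- find_shared_blocks(g1, g2)
    exp <- oracle_blocks(g1, g2)
    cols <- c("relation", "n_families", "families", "g1_start", "g2_start")
    if (is.null(exp)) {
      expect_identical(nrow(got), 0L)
    } else {
      got2 <- got[order(got$relation, got$g1_start, got$g2_start), cols]
      rownames(got2) <- rownames(exp) <- NULL
      expect_identical(got2, exp[cols])
    }
    # symmetry: swapping the genomes swaps the roles, block for block
    rev <- find_shared_blocks(g2, g1)
    expect_identical(nrow(rev), nrow(got))
    expect_setequal(rev$relation, got$relation)
    expect_identical(sort(rev$n_families), sort(got$n_families))
  }
})

test_that("reverse-complementing one genome swaps colinear and inverted blocks", {
  set.seed(34)
  for (rep in 1:10) {
    g1 <- random_annotation(8, fam_pool = sprintf("f%02d", 1:10),
                            classes = "cds", species = "A")
    g2 <- random_annotation(8, fam_pool = sprintf("f%02d", 1:10),
                            classes = "cds", species = "B")
    b <- find_shared_blocks(g1, g2)
    brc <- find_shared_blocks(g1, reverse_complement_annotation(g2))
    swap <- c(colinear = "inverted", inverted = "colinear")
    expect_identical(sort(paste(unname(swap[b$relation]), b$families)),
                     sort(paste(brc$relation, brc$families)))
  }
})

test_that("blocks are invariant under origin rotation", {
  set.seed(35)
  g1 <- random_annotation(10, fam_pool = sprintf("f%02d", 1:12),
                          classes = "cds", species = "A")
  g2 <- random_annotation(10, fam_pool = sprintf("f%02d", 1:12),
                          classes = "cds", species = "B")
  b0 <- find_shared_blocks(g1, g2)
  b1 <- find_shared_blocks(rotate_annotation(g1, 4321), g2)
  expect_identical(sort(paste(b0$relation, b0$families)),
                   sort(paste(b1$relation, b1$families)))
})
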