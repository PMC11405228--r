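panel_of <- function(...) {
  gs <- list(...)
  names(gs) <- vapply(gs, `[[`, character(1), "species_id")
  gs
}

test_that("conserved families follow the presence-fraction rule", {
  g1 <- make_ann(c("atp1", "cob", "nad5"), c(100, 400, 700),
                 c(200, 500, 800), L = 1000, species = "A")
  g2 <- make_ann(c("atp1", "cob", "nad5"), c(50, 350, 650),
                 c(150, 450, 750), L = 1000, species = "B")
  g3 <- make_ann(c("atp1", "cob"), c(50, 350), c(150, 450), L = 1000,
                 species = "C")
  expect_identical(conserved_families(panel_of(g1, g2)),
                   c("atp1", "cob", "nad5"))
  # present in 2 of 3: excluded at 1.0, included at 2/3
  expect_identical(conserved_families(panel_of(g1, g2, g3)),
                   c("atp1", "cob"))
  expect_identical(conserved_families(panel_of(g1, g2, g3),
                                      min_presence = 0.66),
                   c("atp1", "cob", "nad5"))
  expect_error(conserved_families(list()), "empty")
})

test_that("conserved families equal the brute-force intersection on random panels", {
  set.seed(41)
  for (rep in 1:10) {
    panel <- lapply(1:8, function(i) {
      random_annotation(sample(5:15, 1), fam_pool = sprintf("f%02d", 1:12),
                        species = sprintf("S%d", i))
    })
    got <- conserved_families(panel)
    exp <- sort(Reduce(intersect,
                       lapply(panel, function(g) unique(g$features$family))))
    expect_identical(got, exp)
    # anti-monotonicity: adding a genome never enlarges the strict core
    extra <- random_annotation(6, fam_pool = sprintf("f%02d", 1:12),
                               species = "S9")
    expect_true(all(conserved_families(c(panel, list(extra))) %in% got))
  }
})

test_that("conserved pair fractions count only genomes containing both members", {
  # tandem in 3 genomes, present-not-tandem in 1, both members missing in 1
  gt <- function(id) make_ann(c("nad3", "rps12", "cob"), c(100, 300, 600),
                              c(250, 450, 700), L = 1000, species = id)
  gn <- make_ann(c("nad3", "cob", "rps12", "atp1"), c(100, 400, 700, 900),
                 c(200, 500, 800, 950), L = 1000, species = "N")
  gm <- make_ann(c("atp1", "cob"), c(100, 400), c(200, 500), L = 1000,
                 species = "M")
  panel <- panel_of(gt("A"), gt("B"), gt("C"), gn, gm)
  cp <- conserved_pairs(panel, min_tandem_fraction = 0.75)
  row <- cp[cp$family_a == "nad3" & cp$family_b == "rps12", ]
  expect_identical(row$n_both_present, 4L)
  expect_identical(row$n_tandem, 3L)
  expect_true(row$conserved)
  cp2 <- conserved_pairs(panel, min_tandem_fraction = 0.8)
  expect_false(cp2[cp2$family_a == "nad3" & cp2$family_b == "rps12",
                   "conserved"])
})

test_that("profiles report tandem orientation, via-intermediate and missing states", {
  # nad3-rps12 adjacent on plus strand -> tandem_sense
  ga <- make_ann(c("nad3", "rps12", "rpl5", "rps14", "cob", "rrns"),
                 starts = c(100, 300, 600, 800, 1000, 1300),
                 ends = c(250, 450, 700, 900, 1200, 1500),
                 strands = c("+", "+", "-", "-", "-", "+"),
                 L = 2000, species = "A")
  pairs <- conserved_pair_defaults()
  prof <- suppressWarnings(build_profiles(panel_of(ga), pairs))
  expect_identical(prof[["nad3-rps12"]], "tandem_sense")
  # rpl5-cob satisfied through rps14, on the minus strand
  expect_identical(prof[["rpl5-cob"]], "tandem_antisense")
  # rrn5 absent entirely -> one_missing
  expect_identical(prof[["rrnS-rrn5"]], "one_missing")
  # both members absent -> both_missing
  expect_identical(prof[["rps3-rpl16"]], "both_missing")
  # an empty genome is all both_missing
  ge <- make_ann("orf1", 10, 100, classes = "orf", L = 500, species = "E")
  pe <- suppressWarnings(build_profiles(panel_of(ge), pairs))
  expect_true(all(unlist(pe[1, -1]) == "both_missing"))
})

test_that("opposite-strand adjacency is not tandem unless allowed", {
  g <- make_ann(c("nad1", "matr"), c(100, 400), c(300, 700),
                strands = c("+", "-"), L = 1000, species = "O")
  pairs <- conserved_pair_defaults()[5, ]
  p0 <- suppressWarnings(build_profiles(panel_of(g), pairs))
  expect_identical(p0[["nad1-matR"]], "present_not_tandem")
  p1 <- suppressWarnings(build_profiles(panel_of(g), pairs,
                                        allow_opposite = TRUE))
  expect_identical(p1[["nad1-matR"]], "tandem_sense")
})

test_that("grouping is an exact partition, order-invariant up to relabelling", {
  prof <- data.frame(
    species_id = c("Bna", "Ath", "Cpa", "Gba", "Vvi", "Mdo", "Gma"),
    p1 = c("tandem_sense", "tandem_sense", "tandem_sense", "tandem_sense",
           "tandem_antisense", "tandem_antisense", "tandem_antisense"),
    p2 = "tandem_sense", stringsAsFactors = FALSE)
  gr <- group_species(prof)
  expect_identical(split(gr$species_id, gr$group_id),
                   list(`1` = c("Bna", "Ath", "Cpa", "Gba"),
                        `2` = c("Vvi", "Mdo", "Gma")))
  # identical profiles give one group
  prof2 <- prof; prof2$p1 <- "tandem_sense"
  expect_identical(unique(group_species(prof2)$group_id), 1L)
  # permuting rows relabels but does not change the partition
  set.seed(42)
  for (rep in 1:10) {
    prof3 <- prof[sample(nrow(prof)), ]
    gr3 <- group_species(prof3)
    part <- function(g) unname(lapply(split(g$species_id, g$group_id), sort))
    expect_setequal(vapply(part(gr3), paste, "", collapse = ","),
                    vapply(part(gr), paste, "", collapse = ","))
  }
})

test_that("random profiles partition exactly as brute-force equality classes", {
  set.seed(43)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    prof <- data.frame(species_id = sprintf("s%02d", 1:n),
                       a = sample(c("x", "y"), n, TRUE),
                       b = sample(c("x", "y", "z"), n, TRUE),
                       stringsAsFactors = FALSE)
    gr <- group_species(prof)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        same <- prof$a[i] == prof$a[j] && prof$b[i] == prof$b[j]
        expect_identical(gr$group_id[i] == gr$group_id[j], same)
      }
    }
  }
})

test_that("tree concordance flags non-monophyletic groups and counts clades", {
  tree <- "(((A,B),C),((D,E),F));"
  gr <- data.frame(species_id = c("A", "B", "C", "D", "E", "F"),
                   group_id = c(1L, 1L, 2L, 3L, 3L, 3L))
  tc <- tree_concordance(gr, tree)
  expect_identical(tc$concordance, 1.0)
  # {D,F} straddles the (D,E) cherry: flagged, smallest containing clade of 3
  gr2 <- data.frame(species_id = c("A", "B", "C", "D", "E", "F"),
                    group_id = c(1L, 1L, 2L, 3L, 4L, 3L))
  tc2 <- tree_concordance(gr2, tree)
  expect_identical(tc2$per_group$is_clade, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(tc2$concordance, 3 / 4)
  expect_identical(tc2$per_group$smallest_clade_size[3], 3L)
  expect_error(tree_concordance(
    data.frame(species_id = "Zzz", group_id = 1L), tree), "missing")
})

test_that("neighbor joining recovers four-taxon additive distances", {
  # distances generated on the tree ((A:1,B:2):1,(C:3,D:1):1)
  lab <- c("A", "B", "C", "D")
  d <- matrix(c(0, 3, 5, 3,
                3, 0, 6, 4,
                5, 6, 0, 4,
                3, 4, 4, 0), 4, 4, dimnames = list(lab, lab))
  tr <- nj_tree(d)
  expect_s3_class(tr, "phylo")
  ref <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:1);")
  expect_identical(ape::dist.topo(ape::unroot(tr), ape::unroot(ref))[1], 0)
  # three taxa give the unique unrooted topology
  expect_identical(ape::Ntip(nj_tree(d[1:3, 1:3])), 3L)
  bad <- d; bad[1, 2] <- 99
  expect_error(nj_tree(bad), "symmetric")
  nf <- d; nf[1, 2] <- nf[2, 1] <- Inf
  expect_error(nj_tree(nf), "finite")
})

test_that("p-distance feeds NJ and groups identical sequences together", {
  set.seed(44)
  base <- random_dna_str(300)
  mut <- function(s, k) {
    sv <- strsplit(s, "")[[1]]
    at <- sample(length(sv), k)
    for (i in at) sv[i] <- sample(setdiff(c("A", "C", "G", "T"), sv[i]), 1)
    paste(sv, collapse = "")
  }
  seqs <- c(a1 = mut(base, 2), a2 = mut(base, 3),
            b1 = mut(base, 60), b2 = mut(base, 61))
  d <- p_distance_matrix(seqs)
  expect_true(d["a1", "a2"] < d["a1", "b1"])
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_error(p_distance_matrix(c(x = "ACGT", y = "ACG")), "aligned")
})
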