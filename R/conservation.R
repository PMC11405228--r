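# Panel-level conservation: conserved families, conserved tandem pairs,
# arrangement profiles, species grouping, and tree concordance.

panel_check <- function(panel) {
  if (!length(panel)) stop("panel is empty")
  ok <- vapply(panel, inherits, logical(1), "GenomeAnnotation")
  if (!all(ok)) stop("panel must be a list of GenomeAnnotation objects")
  ids <- vapply(panel, `[[`, character(1), "species_id")
  if (anyDuplicated(ids)) stop("duplicate species_id in panel: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  ids
}

#' Gene families conserved across a panel
#'
#' A family counts as present in a genome when at least one copy is annotated
#' (copies are not counted).  With the default `min_presence = 1` the result
#' is the strict intersection of the panel's family sets.
#'
#' @param panel List of [genome_annotation()] objects.
#' @param min_presence Minimum fraction of genomes a family must occur in.
#' @param keep_classes Feature classes considered; default all classes.
#' @return Sorted character vector of conserved family names.
#' @export
conserved_families <- function(panel, min_presence = 1.0,
                               keep_classes = FEAT_CLASSES) {
  panel_check(panel)
  stopifnot(min_presence >= 0, min_presence <= 1)
  fams <- lapply(panel, function(g) {
    unique(g$features$family[g$features$feat_class %in% keep_classes])
  })
  tab <- table(unlist(fams))
  sort(names(tab)[tab / length(panel) >= min_presence])
}

#' Reference pairs used for arrangement profiles
#'
#' The five gene pairs whose adjacency persists across the study panel:
#' rps3–rpl16, rrnS–rrn5, rpl5–cob, nad3–rps12 and nad1–matR.  rpl5–cob is
#' satisfied either by direct adjacency or by the rpl5–rps14–cob arrangement
#' (adjacency through rps14 only); no other intervening family qualifies.
#'
#' @return `data.frame` with columns `family_a`, `family_b` (lexicographic),
#'   `via` (allowed single intervening family or `NA`) and `label`.
#' @export
conserved_pair_defaults <- function() {
  data.frame(
    family_a = c("rpl16", "rrn5", "cob", "nad3", "matr"),
    family_b = c("rps3", "rrns", "rpl5", "rps12", "nad1"),
    via = c(NA, NA, "rps14", NA, NA),
    label = c("rps3-rpl16", "rrnS-rrn5", "rpl5-cob", "nad3-rps12",
              "nad1-matR"),
    stringsAsFactors = FALSE)
}

# Arrangement state of one family pair on one genome.  State precedence:
# both_missing > one_missing > present_not_tandem > tandem_{sense,antisense}.
# Orientation refers to the shared strand of both members; opposite-strand
# adjacency maps to present_not_tandem unless allow_opposite.
pair_status <- function(g, fam_a, fam_b, via = NA,
                        keep_classes = DEFAULT_RING_CLASSES,
                        allow_opposite = FALSE, pairs = NULL) {
  ring <- adjacency_ring(g, keep_classes)
  fams <- unique(ring$family)
  n_missing <- sum(!c(fam_a, fam_b) %in% fams)
  if (n_missing == 2L) return("both_missing")
  if (n_missing == 1L) return("one_missing")
  if (is.null(pairs)) pairs <- find_tandem_pairs(g, keep_classes)
  key <- sort(c(fam_a, fam_b))
  hit <- pairs[pairs$family_a == key[1] & pairs$family_b == key[2], ,
               drop = FALSE]
  strands <- character(0)
  if (nrow(hit)) {
    strands <- hit$orientation
  } else if (!is.na(via) && via %in% fams) {
    # adjacency through the single allowed intervening family
    n <- nrow(ring)
    for (k in seq_len(n)) {
      if (ring$family[k] != via) next
      prevf <- ring[((k - 2L) %% n) + 1L, ]
      nextf <- ring[(k %% n) + 1L, ]
      if (setequal(c(prevf$family, nextf$family), c(fam_a, fam_b))) {
        strands <- c(strands, if (prevf$strand == nextf$strand) {
          if (prevf$strand == "+") "same_strand_plus" else "same_strand_minus"
        } else "opposite")
      }
    }
  }
  if (!length(strands)) return("present_not_tandem")
  if ("same_strand_plus" %in% strands) return("tandem_sense")
  if ("same_strand_minus" %in% strands) return("tandem_antisense")
  if (allow_opposite) return("tandem_sense")
  "present_not_tandem"
}

#' Conserved tandem pairs across a panel
#'
#' Candidate pairs are the union of family-level tandem pairs observed in any
#' panel genome (plus any pairs listed in `extra_pairs`, e.g. the rpl5–cob
#' pair with its allowed rps14 intermediate).  A pair is conserved when it is
#' tandem (sense or antisense) in at least `min_tandem_fraction` of the
#' genomes that contain both members — genomes missing a member are excluded
#' from the denominator, so a pair survives the loss of a gene in individual
#' species.
#'
#' @inheritParams conserved_families
#' @param min_tandem_fraction Required tandem fraction among genomes
#'   containing both members.
#' @param keep_classes Feature classes visible to adjacency.
#' @param extra_pairs Optional `data.frame` like [conserved_pair_defaults()]
#'   whose `via` column allows a single intervening family.
#' @return `data.frame`: `family_a`, `family_b`, `via`, `n_both_present`,
#'   `n_tandem`, `fraction`, `conserved`; per-genome states are attached as
#'   the `"status"` attribute (species x pair character matrix).
#' @export
conserved_pairs <- function(panel, min_tandem_fraction = 1.0,
                            keep_classes = DEFAULT_RING_CLASSES,
                            extra_pairs = NULL) {
  ids <- panel_check(panel)
  stopifnot(min_tandem_fraction >= 0, min_tandem_fraction <= 1)
  per_genome <- lapply(panel, find_tandem_pairs, keep_classes = keep_classes)
  cand <- unique(do.call(rbind, c(
    lapply(per_genome, function(p) p[, c("family_a", "family_b")]),
    list(data.frame(family_a = character(), family_b = character())))))
  cand$via <- NA_character_
  if (!is.null(extra_pairs) && nrow(extra_pairs)) {
    ep <- data.frame(
      family_a = pmin(extra_pairs$family_a, extra_pairs$family_b),
      family_b = pmax(extra_pairs$family_a, extra_pairs$family_b),
      via = extra_pairs$via, stringsAsFactors = FALSE)
    key <- paste(cand$family_a, cand$family_b)
    for (r in seq_len(nrow(ep))) {
      i <- match(paste(ep$family_a[r], ep$family_b[r]), key)
      if (is.na(i)) {
        cand <- rbind(cand, ep[r, ])
        key <- c(key, paste(ep$family_a[r], ep$family_b[r]))
      } else if (!is.na(ep$via[r])) {
        cand$via[i] <- ep$via[r]
      }
    }
  }
  if (!nrow(cand)) {
    out <- data.frame(family_a = character(), family_b = character(),
                      via = character(), n_both_present = integer(),
                      n_tandem = integer(), fraction = numeric(),
                      conserved = logical(), stringsAsFactors = FALSE)
    attr(out, "status") <- matrix(character(), 0, 0)
    return(out)
  }
  status <- matrix(NA_character_, nrow = length(panel), ncol = nrow(cand),
                   dimnames = list(ids,
                                   paste(cand$family_a, cand$family_b,
                                         sep = "|")))
  for (gi in seq_along(panel)) {
    for (ci in seq_len(nrow(cand))) {
      status[gi, ci] <- pair_status(panel[[gi]], cand$family_a[ci],
                                    cand$family_b[ci], via = cand$via[ci],
                                    keep_classes = keep_classes,
                                    pairs = per_genome[[gi]])
    }
  }
  tandem <- status %in% c("tandem_sense", "tandem_antisense")
  dim(tandem) <- dim(status)
  both <- !(status %in% c("one_missing", "both_missing"))
  dim(both) <- dim(status)
  n_both <- as.integer(colSums(both))
  n_tand <- as.integer(colSums(tandem))
  frac <- ifelse(n_both > 0, n_tand / n_both, 0)
  out <- cbind(cand,
               data.frame(n_both_present = n_both, n_tandem = n_tand,
                          fraction = frac,
                          conserved = n_both > 0 & frac >= min_tandem_fraction))
  ord <- order(-out$conserved, -out$fraction, out$family_a, out$family_b)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "status") <- status
  out
}

#' Arrangement profiles over a reference pair set
#'
#' One profile per genome: for every reference pair, one of `tandem_sense`,
#' `tandem_antisense`, `present_not_tandem`, `one_missing`, `both_missing`.
#' Reference pairs naming families absent from the whole panel trigger a
#' warning and simply evaluate to missing states.
#'
#' @inheritParams conserved_pairs
#' @param reference_pairs `data.frame` like [conserved_pair_defaults()].
#' @param allow_opposite Count opposite-strand adjacency as tandem?
#' @return `data.frame` with `species_id` and one state column per pair
#'   (named by `label`); the reference pairs are attached as attribute
#'   `"pairs"`.
#' @export
build_profiles <- function(panel, reference_pairs = conserved_pair_defaults(),
                           keep_classes = DEFAULT_RING_CLASSES,
                           allow_opposite = FALSE) {
  ids <- panel_check(panel)
  stopifnot(is.data.frame(reference_pairs), nrow(reference_pairs) >= 1)
  if (is.null(reference_pairs$via)) reference_pairs$via <- NA_character_
  if (is.null(reference_pairs$label)) {
    reference_pairs$label <- paste(reference_pairs$family_a,
                                   reference_pairs$family_b, sep = "-")
  }
  all_fams <- unique(unlist(lapply(panel, function(g) g$features$family)))
  unknown <- setdiff(unique(c(reference_pairs$family_a,
                              reference_pairs$family_b)), all_fams)
  if (length(unknown)) {
    warning("reference pair family not seen in panel: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  states <- vapply(panel, function(g) {
    pairs <- find_tandem_pairs(g, keep_classes)
    vapply(seq_len(nrow(reference_pairs)), function(ci) {
      pair_status(g, reference_pairs$family_a[ci], reference_pairs$family_b[ci],
                  via = reference_pairs$via[ci], keep_classes = keep_classes,
                  allow_opposite = allow_opposite, pairs = pairs)
    }, character(1))
  }, character(nrow(reference_pairs)))
  states <- matrix(states, nrow = nrow(reference_pairs))
  out <- data.frame(species_id = ids, t(states), stringsAsFactors = FALSE)
  names(out) <- c("species_id", reference_pairs$label)
  attr(out, "pairs") <- reference_pairs
  out
}

#' Group species by identical arrangement profiles
#'
#' Exact-match partition on the state vectors: two species fall in the same
#' group iff their profiles agree on every reference pair.  Group ids are
#' assigned in order of first member appearance, so the partition is
#' deterministic and invariant to input order up to relabelling.
#'
#' @param profiles Output of [build_profiles()].
#' @return `data.frame` with `species_id` and integer `group_id`.
#' @export
group_species <- function(profiles) {
  stopifnot(is.data.frame(profiles), "species_id" %in% names(profiles))
  statecols <- setdiff(names(profiles), "species_id")
  key <- do.call(paste, c(profiles[statecols], sep = "\r"))
  gid <- match(key, unique(key))
  data.frame(species_id = profiles$species_id, group_id = gid,
             stringsAsFactors = FALSE)
}

#' Concordance of species groups with a phylogeny
#'
#' After restricting the tree to the grouped species, each group of two or
#' more members is tested for monophyly; for non-monophyletic groups the size
#' of the smallest clade containing all members is reported.  Singleton
#' groups are trivially clades.  Overall concordance is the fraction of
#' groups that are clades.
#'
#' @param groups Output of [group_species()].
#' @param tree An [ape::read.tree()] `phylo` object, a newick string, or a
#'   path to a newick file.  Leaf labels must cover all grouped species.
#' @return List with `per_group` (`data.frame`: `group_id`, `n_members`,
#'   `is_clade`, `smallest_clade_size`) and `concordance` (numeric).
#' @export
tree_concordance <- function(groups, tree) {
  stopifnot(is.data.frame(groups),
            all(c("species_id", "group_id") %in% names(groups)))
  phy <- as_phylo(tree)
  missing <- setdiff(groups$species_id, phy$tip.label)
  if (length(missing)) {
    stop("species missing from tree: ", paste(missing, collapse = ", "))
  }
  phy <- ape::keep.tip(phy, groups$species_id)
  members <- split(groups$species_id, groups$group_id)
  per <- lapply(names(members), function(gid) {
    m <- members[[gid]]
    if (length(m) == 1L) {
      return(data.frame(group_id = as.integer(gid), n_members = 1L,
                        is_clade = TRUE, smallest_clade_size = 1L))
    }
    mono <- ape::is.monophyletic(phy, m)
    node <- ape::getMRCA(phy, m)
    csize <- length(ape::extract.clade(phy, node)$tip.label)
    data.frame(group_id = as.integer(gid), n_members = length(m),
               is_clade = mono, smallest_clade_size = csize)
  })
  per <- do.call(rbind, per)
  per <- per[order(per$group_id), , drop = FALSE]
  rownames(per) <- NULL
  list(per_group = per, concordance = mean(per$is_clade))
}

as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1L) {
    if (grepl("\\(", tree)) return(ape::read.tree(text = tree))
    return(ape::read.tree(tree))
  }
  stop("tree must be a phylo object, newick string or newick file path")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Thin deterministic wrapper around the standard neighbor-joining
#' agglomeration: the matrix is validated (symmetric, zero diagonal, finite)
#' and its rows are put in lexicographic label order before joining so that
#' ties resolve identically on every run.
#'
#' @param distances Symmetric numeric matrix (or `dist`) with labels.
#' @return An unrooted `phylo` tree with branch lengths.
#' @export
nj_tree <- function(distances) {
  d <- as.matrix(distances)
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric")
  }
  if (any(!is.finite(d))) stop("distance matrix must be finite")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  ord <- order(rownames(d))
  ape::nj(stats::as.dist(d[ord, ord]))
}

#' Pairwise p-distance matrix
#'
#' Proportion of differing sites between every pair of equal-length
#' sequences (aligned input expected; positions with N in either sequence are
#' excluded pairwise).  Feeds [nj_tree()] when no externally inferred
#' phylogeny is supplied.
#'
#' @param seqs Named character vector or [Biostrings::DNAStringSet] of
#'   equal-length sequences.
#' @return Symmetric numeric matrix of p-distances.
#' @export
p_distance_matrix <- function(seqs) {
  if (methods::is(seqs, "DNAStringSet")) {
    seqs <- setNames(as.character(seqs), names(seqs))
  }
  stopifnot(is.character(seqs), length(seqs) >= 2, !is.null(names(seqs)))
  if (length(unique(nchar(seqs))) != 1L) {
    stop("sequences must be aligned (equal length); align before calling")
  }
  mat <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  rownames(mat) <- names(seqs)
  bin <- ape::as.DNAbin(mat)
  as.matrix(ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE))
}
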