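# Tandem (ring-adjacent) gene pairs and shared gene-order blocks.
#
# "Tandem" is defined as adjacency on the circular gene ring after class
# filtering (tRNAs are invisible to adjacency by default; ORFs are kept).
# Adjacency, not a distance cutoff, is the criterion: max_gap defaults to
# unlimited and is exposed only for sensitivity analysis.

#' Default feature classes retained on the adjacency ring
#' @export
DEFAULT_RING_CLASSES <- c("cds", "rrna", "orf")

#' Circular adjacency ring of a genome
#'
#' Drops features outside `keep_classes` and returns the remaining features
#' in circular order (the last row is adjacent to the first across the
#' origin).
#'
#' @param g A [genome_annotation()].
#' @param keep_classes Feature classes visible to adjacency.
#' @return The ordered feature `data.frame` with attributes `genome_length`,
#'   `species_id` and `circular`.  Zero rows signal an empty ring.
#' @export
adjacency_ring <- function(g, keep_classes = DEFAULT_RING_CLASSES) {
  stopifnot(inherits(g, "GenomeAnnotation"))
  f <- g$features[g$features$feat_class %in% keep_classes, , drop = FALSE]
  rownames(f) <- NULL
  attr(f, "genome_length") <- g$genome_length
  attr(f, "species_id") <- g$species_id
  attr(f, "circular") <- g$circular
  f
}

# circular gap in bp between consecutive ring features a (upstream) and b
ring_gap <- function(a_end, a_wraps, b_start, wrap_edge, L) {
  raw <- if (!wrap_edge || a_wraps) {
    b_start - a_end - 1L
  } else {
    (L - a_end) + (b_start - 1L)
  }
  max(0L, raw)
}

#' Tandem gene pairs of one genome
#'
#' One record per adjacency edge of the circular ring whose intergenic gap is
#' at most `max_gap`.  The wrap edge (last feature to first feature across
#' the origin) is included on circular genomes.  The pair identity is
#' symmetric: `family_a`/`family_b` are reported in lexicographic order and
#' `upstream` records which family comes first on the plus reading of the
#' circle.  Overlapping genes get `gap_bp = 0`.
#'
#' @inheritParams adjacency_ring
#' @param max_gap Maximum intergenic distance in bp (`Inf` = adjacency only).
#' @param allow_self Report edges between two copies of the same family?
#' @return `data.frame`: `genome`, `family_a`, `family_b`, `upstream`,
#'   `orientation` (`same_strand_plus`, `same_strand_minus`, `opposite`),
#'   `gap_bp`, `upstream_start`, `downstream_start`.
#' @export
find_tandem_pairs <- function(g, keep_classes = DEFAULT_RING_CLASSES,
                              max_gap = Inf, allow_self = FALSE) {
  ring <- adjacency_ring(g, keep_classes)
  n <- nrow(ring)
  L <- g$genome_length
  empty <- data.frame(genome = character(), family_a = character(),
                      family_b = character(), upstream = character(),
                      orientation = character(), gap_bp = integer(),
                      upstream_start = integer(), downstream_start = integer(),
                      stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  last_edge <- if (g$circular) n else n - 1L
  rows <- vector("list", last_edge)
  for (i in seq_len(last_edge)) {
    j <- if (i == n) 1L else i + 1L
    a <- ring[i, ]; b <- ring[j, ]
    if (!allow_self && a$family == b$family) next
    ori <- if (a$strand == b$strand) {
      if (a$strand == "+") "same_strand_plus" else "same_strand_minus"
    } else "opposite"
    gap <- ring_gap(a$end, a$wraps, b$start, wrap_edge = (i == n), L = L)
    if (gap > max_gap) next
    fams <- sort(c(a$family, b$family))
    rows[[i]] <- data.frame(genome = g$species_id,
                            family_a = fams[1], family_b = fams[2],
                            upstream = a$family, orientation = ori,
                            gap_bp = gap, upstream_start = a$start,
                            downstream_start = b$start,
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- shared blocks ----------------------------------------------------------

#' Shared gene-order blocks between two genomes
#'
#' Maximal runs of at least two gene families (one representative per family
#' per run) that are consecutive on the rings of both genomes, either in the
#' same order with identical strands (`colinear`) or in reversed order with
#' complemented strands (`inverted`).  Maximality: no extension in either
#' direction preserves the relation (extensions that would repeat a family in
#' the run are blocked).
#'
#' @param g1,g2 Two [genome_annotation()] objects.
#' @inheritParams adjacency_ring
#' @return `data.frame`: `genome1`, `genome2`, `relation`, `n_families`,
#'   `families` (comma-joined in genome1 ring order), and the coordinates of
#'   the run in both genomes (`g1_start`, `g1_end`, `g2_start`, `g2_end`,
#'   start of first / end of last member feature).
#' @export
find_shared_blocks <- function(g1, g2, keep_classes = DEFAULT_RING_CLASSES) {
  r1 <- adjacency_ring(g1, keep_classes)
  r2 <- adjacency_ring(g2, keep_classes)
  empty <- data.frame(genome1 = character(), genome2 = character(),
                      relation = character(), n_families = integer(),
                      families = character(), g1_start = integer(),
                      g1_end = integer(), g2_start = integer(),
                      g2_end = integer(), stringsAsFactors = FALSE)
  n1 <- nrow(r1); n2 <- nrow(r2)
  if (n1 < 2L || n2 < 2L) return(empty)
  f1 <- r1$family; s1 <- r1$strand
  f2 <- r2$family; s2 <- r2$strand
  w1 <- function(i) ((i - 1L) %% n1) + 1L
  w2 <- function(j) ((j - 1L) %% n2) + 1L
  cap <- min(n1, n2)

  match_at <- function(i, j, dir, k) {
    p <- w1(i + k); q <- w2(j + dir * k)
    if (dir == 1L) f1[p] == f2[q] && s1[p] == s2[q]
    else f1[p] == f2[q] && s1[p] != s2[q]
  }
  run_len <- function(i, j, dir) {
    len <- 0L
    seen <- character(0)
    while (len < cap) {
      p <- w1(i + len)
      if (f1[p] %in% seen) break
      if (!match_at(i, j, dir, len)) break
      seen <- c(seen, f1[p])
      len <- len + 1L
    }
    len
  }

  res <- list()
  keys <- character(0)
  for (dir in c(1L, -1L)) {
    for (i in seq_len(n1)) {
      for (j in seq_len(n2)) {
        len <- run_len(i, j, dir)
        if (len < 2L) next
        # maximal-left: extending to (i-1, j-dir) must fail, either on the
        # match relation or on family uniqueness within the extended run
        prev_fam <- f1[w1(i - 1L)]
        fams <- f1[w1(i + seq_len(len) - 1L)]
        left_ok <- len < cap && !(prev_fam %in% fams) &&
          match_at(i - 1L, j - dir, dir, 0L)
        if (left_ok) next
        idx1 <- w1(i + seq_len(len) - 1L)
        idx2 <- w2(j + dir * (seq_len(len) - 1L))
        key <- paste(dir, paste(sort(idx1), collapse = ","),
                     paste(sort(idx2), collapse = ","), sep = "|")
        if (key %in% keys) next
        keys <- c(keys, key)
        res[[length(res) + 1L]] <- data.frame(
          genome1 = g1$species_id, genome2 = g2$species_id,
          relation = if (dir == 1L) "colinear" else "inverted",
          n_families = len,
          families = paste(fams, collapse = ","),
          g1_start = r1$start[idx1[1]], g1_end = r1$end[idx1[len]],
          g2_start = r2$start[idx2[1]], g2_end = r2$end[idx2[len]],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(out$relation, out$g1_start, out$g2_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
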