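# Summaries of externally predicted C-to-U RNA-editing sites.  Prediction
# itself is out of scope: this module consumes a site table so that published
# spectra can be reproduced from their own counts and so the synthetic
# generator can supply sites with known structure.

#' Read an RNA-editing site table
#'
#' TSV with columns `gene`, `cds_position`, `codon_position` (1, 2 or `1&2`),
#' `aa_from`, `aa_to` (one-letter codes, `X` for a created stop) and `score`.
#'
#' @param path TSV path.
#' @return `data.frame` of editing sites.
#' @export
read_editing_sites <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "cds_position", "codon_position", "aa_from", "aa_to")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("site table missing column(s): ",
                         paste(miss, collapse = ", "))
  d$codon_position <- as.character(d$codon_position)
  d
}

#' Amino-acid conversion spectrum of editing sites
#'
#' Counts and percentages per (from, to) amino-acid class and per codon
#' position.  All edits are C-to-U by construction, so a site with
#' `aa_from == aa_to` (a synonymous edit) is a validation error.  The `1&2`
#' codon-position class (conversions hit at either the first or the second
#' base, e.g. proline to phenylalanine) is tallied as its own category.
#'
#' @param sites Editing-site `data.frame`, see [read_editing_sites()].
#' @return List: `conversions` (`aa_from`, `aa_to`, `n`, `pct`),
#'   `codon_positions` (`codon_position`, `n`, `pct`), `total`.
#' @export
editing_spectrum <- function(sites) {
  stopifnot(is.data.frame(sites))
  if (!nrow(sites)) stop("site table is empty")
  if (any(sites$aa_from == sites$aa_to)) {
    bad <- which(sites$aa_from == sites$aa_to)
    stop("synonymous edit (aa_from == aa_to) at row ",
         paste(bad, collapse = ", "))
  }
  total <- nrow(sites)
  conv <- aggregate(list(n = sites$aa_from),
                    by = list(aa_from = sites$aa_from, aa_to = sites$aa_to),
                    FUN = length)
  conv <- conv[order(conv$aa_from, conv$aa_to), , drop = FALSE]
  conv$pct <- 100 * conv$n / total
  rownames(conv) <- NULL
  cp <- as.character(sites$codon_position)
  cpt <- aggregate(list(n = cp), by = list(codon_position = cp), FUN = length)
  cpt$pct <- 100 * cpt$n / total
  rownames(cpt) <- NULL
  list(conversions = conv, codon_positions = cpt, total = total)
}

#' Per-gene editing density
#'
#' Site count, gene length and sites per kb for every edited gene, plus the
#' Spearman rank correlation between coding length and site count as a
#' diagnostic: longer genes tend to carry more sites, but the relationship is
#' not strictly linear.
#'
#' @param sites Editing-site `data.frame`.
#' @param gene_lengths Named numeric vector mapping gene family to coding
#'   length in bp; every edited gene must have an entry.
#' @return List: `table` (`gene`, `n_sites`, `length_bp`, `sites_per_kb`,
#'   sorted by descending count) and `spearman` (`NA` with fewer than two
#'   genes).
#' @export
gene_editing_density <- function(sites, gene_lengths) {
  stopifnot(is.data.frame(sites), !is.null(names(gene_lengths)))
  genes <- unique(sites$gene)
  miss <- setdiff(genes, names(gene_lengths))
  if (length(miss)) stop("no length entry for gene(s): ",
                         paste(miss, collapse = ", "))
  n <- table(sites$gene)
  tab <- data.frame(gene = names(n), n_sites = as.integer(n),
                    length_bp = as.numeric(gene_lengths[names(n)]),
                    stringsAsFactors = FALSE)
  tab$sites_per_kb <- 1000 * tab$n_sites / tab$length_bp
  tab <- tab[order(-tab$n_sites, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  rho <- if (nrow(tab) >= 2L) {
    suppressWarnings(cor(tab$length_bp, tab$n_sites, method = "spearman"))
  } else NA_real_
  list(table = tab, spearman = rho)
}
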