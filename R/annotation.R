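#' @rdname genome_annotation
#' @export
FEAT_CLASSES <- c("cds", "trna", "rrna", "orf")

#' Construct a GenomeAnnotation
#'
#' The internal model of one annotated (usually circular) mitochondrial
#' genome: a short species label, the genome length, and an ordered feature
#' table.  Coordinates are 1-based inclusive throughout (GenBank/GFF3
#' convention).  Features that span the origin of a circular molecule are
#' stored once with their annotated start and end and `wraps = TRUE`; their
#' length is `(genome_length - start + 1) + end`.
#'
#' @param species_id Short species label (e.g. `"Col"`, `"YK10"`).
#' @param genome_length Genome length in bp.
#' @param features `data.frame` with columns `raw_name`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`), `feat_class` (one of `FEAT_CLASSES`); optional
#'   columns `family`, `wraps`, `coverage`, `match`.
#' @param circular Is the molecule circular?  Origin-spanning features are
#'   only legal on circular molecules.
#' @param sequence Optional nucleotide sequence (character or
#'   [Biostrings::DNAString]) of length `genome_length`.
#' @param name_map Alias table used to derive `family` from `raw_name` when
#'   no `family` column is supplied.
#' @return Object of class `GenomeAnnotation`: a list with elements
#'   `species_id`, `genome_length`, `circular`, `features` (sorted by start,
#'   ties broken by end then family; `copy_index` numbers copies within a
#'   family) and `sequence` (character or `NULL`).
#' @export
genome_annotation <- function(species_id, genome_length, features,
                              circular = TRUE, sequence = NULL,
                              name_map = default_name_map()) {
  stopifnot(is.character(species_id), length(species_id) == 1L,
            is.numeric(genome_length), length(genome_length) == 1L,
            genome_length >= 1, is.data.frame(features))
  genome_length <- as.integer(genome_length)
  need <- c("raw_name", "start", "end", "strand", "feat_class")
  miss <- setdiff(need, names(features))
  if (length(miss)) {
    stop("features is missing column(s): ", paste(miss, collapse = ", "))
  }
  f <- features
  f$start <- as.integer(f$start)
  f$end <- as.integer(f$end)
  f$strand <- as.character(f$strand)
  f$feat_class <- as.character(f$feat_class)
  if (!all(f$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!all(f$feat_class %in% FEAT_CLASSES)) {
    stop("feat_class must be one of: ", paste(FEAT_CLASSES, collapse = ", "))
  }
  if (any(f$start < 1L | f$start > genome_length) ||
      any(f$end < 1L | f$end > genome_length)) {
    bad <- which(f$start < 1L | f$start > genome_length |
                   f$end < 1L | f$end > genome_length)
    stop("feature(s) outside [1, genome_length]: row ",
         paste(bad, collapse = ", "))
  }
  if (is.null(f$wraps)) f$wraps <- f$end < f$start
  f$wraps <- as.logical(f$wraps)
  if (any(f$wraps) && !circular) {
    stop("origin-spanning feature on a non-circular record (row ",
         paste(which(f$wraps), collapse = ", "), ")")
  }
  if (any(!f$wraps & f$end < f$start)) {
    stop("end < start on non-wrapping feature")
  }
  if (is.null(f$family)) f$family <- normalize_family(f$raw_name, name_map)
  f$length_bp <- ifelse(f$wraps,
                        genome_length - f$start + 1L + f$end,
                        f$end - f$start + 1L)
  ord <- order(f$start, f$end, f$family, method = "radix")
  f <- f[ord, , drop = FALSE]
  f$copy_index <- as.integer(stats::ave(seq_len(nrow(f)), f$family,
                                        FUN = seq_along))
  keep <- c("raw_name", "family", "start", "end", "strand", "feat_class",
            "copy_index", "length_bp", "wraps",
            intersect(c("coverage", "match"), names(f)))
  f <- f[, keep, drop = FALSE]
  rownames(f) <- NULL
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (nchar(sequence) != genome_length) {
      stop("sequence length (", nchar(sequence),
           ") != genome_length (", genome_length, ")")
    }
  }
  structure(list(species_id = species_id,
                 genome_length = genome_length,
                 circular = isTRUE(circular),
                 features = f,
                 sequence = sequence),
            class = "GenomeAnnotation")
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat("GenomeAnnotation <", x$species_id, ">: ", x$genome_length, " bp, ",
      if (x$circular) "circular" else "linear", ", ",
      nrow(x$features), " features (",
      paste(names(table(x$features$feat_class)),
            table(x$features$feat_class), sep = ":", collapse = " "),
      ")", if (!is.null(x$sequence)) ", with sequence", "\n", sep = "")
  invisible(x)
}

#' @export
#' @method as.data.frame GenomeAnnotation
as.data.frame.GenomeAnnotation <- function(x, ...) {
  cbind(species_id = x$species_id, x$features)
}

#' Rotate the origin of a circular annotation
#'
#' Moves the coordinate origin forward by `offset` bp; feature content,
#' adjacency and strand are unchanged, only coordinates move.  Used to check
#' that tandem pairs and shared blocks are rotation-invariant.
#'
#' @param g A `GenomeAnnotation` (must be circular).
#' @param offset Number of bp the origin moves forward (0 to length-1).
#' @return A rotated `GenomeAnnotation`.
#' @export
rotate_annotation <- function(g, offset) {
  stopifnot(inherits(g, "GenomeAnnotation"), g$circular)
  L <- g$genome_length
  offset <- as.integer(offset %% L)
  if (offset == 0L) return(g)
  shift <- function(p) ((p - 1L - offset) %% L) + 1L
  f <- g$features
  f$start <- shift(f$start)
  f$end <- shift(f$end)
  f$wraps <- NULL # re-derived from end < start
  s <- g$sequence
  if (!is.null(s)) {
    s <- paste0(substr(s, offset + 1L, L), substr(s, 1L, offset))
  }
  genome_annotation(g$species_id, L, f, circular = TRUE, sequence = s)
}

#' Reverse-complement an annotation
#'
#' Maps every feature onto the opposite strand of the reversed coordinate
#' system.  Turns every colinear shared block into an inverted one and vice
#' versa, which is used as a property check.
#'
#' @param g A `GenomeAnnotation`.
#' @return The reverse-complemented `GenomeAnnotation`.
#' @export
reverse_complement_annotation <- function(g) {
  stopifnot(inherits(g, "GenomeAnnotation"))
  L <- g$genome_length
  f <- g$features
  new_start <- L - f$end + 1L
  new_end <- L - f$start + 1L
  f$start <- new_start
  f$end <- new_end
  f$strand <- flip_strand(f$strand)
  f$wraps <- NULL
  s <- g$sequence
  if (!is.null(s)) s <- revcomp_chr(s)
  genome_annotation(g$species_id, L, f, circular = g$circular, sequence = s)
}

#' Write / read the canonical annotation TSV
#'
#' Serializes one genome (or a panel) to the canonical flat table:
#' `species_id, family, raw_name, start, end, strand, feat_class, copy_index`
#' plus `genome_length`, `circular` and `wraps` so the round trip is exact.
#'
#' @param g A `GenomeAnnotation` or list of them.
#' @param path Output TSV path.
#' @return `write_annotation_tsv`: the path, invisibly.
#' @export
write_annotation_tsv <- function(g, path) {
  if (inherits(g, "GenomeAnnotation")) g <- list(g)
  rows <- do.call(rbind, lapply(g, function(x) {
    cbind(species_id = x$species_id,
          x$features[, c("family", "raw_name", "start", "end", "strand",
                         "feat_class", "copy_index", "wraps")],
          genome_length = x$genome_length, circular = x$circular)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_tsv
#' @return `read_annotation_tsv`: a named list of `GenomeAnnotation`.
#' @export
read_annotation_tsv <- function(path) {
  tb <- read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(split(tb, tb$species_id), function(d) {
    genome_annotation(d$species_id[1], d$genome_length[1],
                      d[, c("raw_name", "family", "start", "end", "strand",
                            "feat_class", "wraps")],
                      circular = d$circular[1])
  })
  out[unique(tb$species_id)]
}
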