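# Repeat layer: perfect/compound microsatellites (SSRs) and dispersed
# forward/palindromic repeats.
#
# SSR semantics follow the usual microsatellite-survey conventions: a perfect
# SSR is a maximal tandem run of a primitive 1-6 nt motif meeting a per-unit
# minimum repeat count; runs separated by short interruptions merge into
# compound records.  Motifs are reported exactly as observed on the given
# strand — rotations and complements are NOT grouped by default, because the
# downstream category tables list AT and TA (etc.) separately; a
# canonicalization flag exists for interoperability with tools that do group.
#
# Dispersed repeats use a fixed-pair Hamming model (no indels): a reported
# pair is a maximal run of positions, along one offset (forward) or one
# antidiagonal (palindromic), containing at most `max_mismatch` mismatches
# and not extendable in either direction without exceeding the budget or
# leaving the sequence.  Palindromic copies may not overlap.  N never matches
# anything, including another N.

DEFAULT_SSR_MINIMA <- c(8L, 4L, 4L, 3L, 3L, 3L)

validate_seq <- function(seq) {
  if (methods::is(seq, "DNAString") || methods::is(seq, "DNAStringSet")) {
    seq <- as.character(if (methods::is(seq, "DNAStringSet")) seq[[1]] else seq)
  }
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  bad <- regexpr("[^ACGTN]", s)
  if (bad > 0) {
    stop("non-IUPAC character '", substr(s, bad, bad), "' at position ", bad)
  }
  s
}

motif_is_primitive <- function(motif) {
  p <- nchar(motif)
  if (p == 1L) return(TRUE)
  for (d in seq_len(p - 1L)) {
    if (p %% d == 0L &&
        motif == strrep(substr(motif, 1L, d), p / d)) return(FALSE)
  }
  TRUE
}

#' Detect microsatellites (SSRs)
#'
#' Finds every maximal perfect tandem run of a primitive 1–6 nt motif whose
#' repeat count meets the per-unit-length minimum (defaults 8, 4, 4, 3, 3, 3
#' for monomers through hexamers), then merges perfect runs separated by at
#' most `max_interruption` bp into additional compound records.  Runs whose
#' motif is itself periodic (e.g. an `AA` dimer inside a poly-A run) are
#' resolved to the smallest period and not reported again at larger periods.
#'
#' @param seq Nucleotide string (or `DNAString`) over A, C, G, T, N.
#' @param minima Integer vector of six minimum repeat counts (unit lengths
#'   1–6).
#' @param max_interruption Maximum spacing in bp between member runs of a
#'   compound SSR (default 100).
#' @param circular Scan across the origin of a circular sequence?  Wrapping
#'   records keep `start <= length` and report an unwrapped `end` that may
#'   exceed the sequence length.
#' @return `data.frame` with columns `kind` (`perfect`/`compound`), `motif`
#'   (for compounds, the composed `(motif)count` notation), `unit_len`,
#'   `repeat_count`, `start`, `end`, `n_components`; attribute
#'   `"components"` holds, for each compound row, the indices of its member
#'   perfect records.
#' @export
find_ssrs <- function(seq, minima = DEFAULT_SSR_MINIMA,
                      max_interruption = 100, circular = FALSE) {
  s <- validate_seq(seq)
  stopifnot(length(minima) == 6L, all(minima >= 1))
  n <- nchar(s)
  scan <- if (circular && n > 1L) paste0(s, substr(s, 1L, n - 1L)) else s
  sv <- strsplit(scan, "", fixed = TRUE)[[1]]
  m <- length(sv)
  recs <- list()
  for (p in 1:6) {
    if (m <= p) next
    eq <- sv[seq_len(m - p)] == sv[(p + 1L):m] &
      sv[seq_len(m - p)] != "N" & sv[(p + 1L):m] != "N"
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values)
    for (h in hit) {
      t0 <- starts[h]
      stretch <- r$lengths[h] + p         # bases in the maximal periodic run
      count <- stretch %/% p
      if (count < minima[p]) next
      motif <- substr(scan, t0, t0 + p - 1L)
      if (grepl("N", motif, fixed = TRUE)) next
      if (!motif_is_primitive(motif)) next
      recs[[length(recs) + 1L]] <- data.frame(
        kind = "perfect", motif = motif, unit_len = p,
        repeat_count = count, start = t0, end = t0 + p * count - 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(recs)) {
    out <- data.frame(kind = character(), motif = character(),
                      unit_len = integer(), repeat_count = integer(),
                      start = integer(), end = integer(),
                      n_components = integer(), stringsAsFactors = FALSE)
    attr(out, "components") <- list()
    return(out)
  }
  pf <- do.call(rbind, recs)
  if (circular && n > 1L) {
    pf <- pf[pf$start <= n, , drop = FALSE]
    # drop runs that are circular sub-intervals of a wrapped run
    span <- pf$end - pf$start
    ord <- order(-span)
    keep <- rep(TRUE, nrow(pf))
    for (a in seq_along(ord)) {
      i <- ord[a]
      if (!keep[i]) next
      for (b in seq_along(ord)) {
        j <- ord[b]
        if (i == j || !keep[j] || pf$unit_len[j] != pf$unit_len[i]) next
        contained <- (pf$start[j] >= pf$start[i] && pf$end[j] <= pf$end[i]) ||
          (pf$start[j] + n >= pf$start[i] && pf$end[j] + n <= pf$end[i])
        if (contained) keep[j] <- FALSE
      }
    }
    pf <- pf[keep, , drop = FALSE]
  }
  pf <- pf[order(pf$start, pf$unit_len), , drop = FALSE]
  rownames(pf) <- NULL
  pf$n_components <- 1L

  # compound merging
  comps <- list()
  if (nrow(pf) >= 2L) {
    gap_next <- pf$start[-1L] - pf$end[-nrow(pf)] - 1L
    chain_id <- cumsum(c(1L, as.integer(gap_next > max_interruption)))
    for (ch in split(seq_len(nrow(pf)), chain_id)) {
      if (length(ch) < 2L) next
      comps[[length(comps) + 1L]] <- ch
    }
  }
  if (length(comps)) {
    crows <- do.call(rbind, lapply(comps, function(ch) {
      data.frame(
        kind = "compound",
        motif = paste(sprintf("(%s)%d", pf$motif[ch], pf$repeat_count[ch]),
                      collapse = "-"),
        unit_len = NA_integer_, repeat_count = NA_integer_,
        start = pf$start[ch[1]], end = pf$end[ch[length(ch)]],
        n_components = length(ch), stringsAsFactors = FALSE)
    }))
    out <- rbind(pf, crows)
  } else {
    out <- pf
  }
  out <- out[order(out$start, !is.na(out$unit_len), out$unit_len), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "components") <- comps
  out
}

#' Canonicalize SSR motifs
#'
#' Optional interoperability helper: maps each motif to the lexicographically
#' smallest string among its rotations and their reverse complements (the
#' grouping some microsatellite tools apply).  Detection never applies this.
#'
#' @param motifs Character vector of motifs.
#' @return Character vector of canonical motifs.
#' @export
canonicalize_motif <- function(motifs) {
  vapply(motifs, function(mo) {
    p <- nchar(mo)
    rot <- vapply(seq_len(p) - 1L, function(k) {
      paste0(substr(mo, k + 1L, p), substr(mo, 1L, k))
    }, character(1))
    min(c(rot, revcomp_chr(rot)))
  }, character(1), USE.NAMES = FALSE)
}

#' Summarize SSR records
#'
#' Counts and percentages of perfect SSRs by unit length and the per-motif
#' repeat-count histogram, in the layout of a standard microsatellite survey
#' table.
#'
#' @param records Output of [find_ssrs()] (only `kind == "perfect"` rows are
#'   tallied) or any `data.frame` with `motif`, `unit_len`, `repeat_count`.
#' @return List: `by_unit` (`unit_len`, `n`, `pct` over unit lengths 1–6),
#'   `by_motif` (`motif`, `unit_len`, `repeat_count`, `n`), `total`.
#' @export
ssr_summary <- function(records) {
  stopifnot(is.data.frame(records))
  if (!is.null(records$kind)) {
    records <- records[records$kind == "perfect", , drop = FALSE]
  }
  total <- nrow(records)
  by_unit <- data.frame(unit_len = 1:6, n = 0L, pct = 0)
  if (total) {
    tab <- table(factor(records$unit_len, levels = 1:6))
    by_unit$n <- as.integer(tab)
    by_unit$pct <- 100 * by_unit$n / total
  }
  by_motif <- if (total) {
    agg <- aggregate(list(n = records$motif),
                     by = list(motif = records$motif,
                               unit_len = records$unit_len,
                               repeat_count = records$repeat_count),
                     FUN = length)
    agg[order(agg$unit_len, agg$motif, agg$repeat_count), , drop = FALSE]
  } else {
    data.frame(motif = character(), unit_len = integer(),
               repeat_count = integer(), n = integer())
  }
  rownames(by_motif) <- NULL
  list(by_unit = by_unit, by_motif = by_motif, total = total)
}

#' Detect dispersed forward and palindromic repeats
#'
#' Reports every maximal repeat pair of length at least `min_len` under the
#' fixed-pair Hamming model: for `forward` pairs the two copies match at the
#' same orientation and offset; for `palindromic` pairs the second copy
#' matches the reverse complement of the first and the copies do not overlap.
#' Maximality means the pair cannot be extended at either end without
#' exceeding `max_mismatch` mismatches or leaving the sequence, so any pair
#' wholly contained in a longer pair at the same offset is never reported.
#'
#' @inheritParams find_ssrs
#' @param min_len Minimum repeat length in bp (default 50; values below 8 are
#'   rejected — the detection model degenerates).
#' @param max_mismatch Mismatch budget per pair (default 8).
#' @param kinds Which repeat classes to report.
#' @param circular Scan across the origin (hits are reported with
#'   `start1 <= length`; coordinates of the second copy may exceed the
#'   length when the pair wraps)?
#' @return `data.frame`: `kind`, `start1`, `start2`, `length`, `mismatches`,
#'   with `start1 < start2`.
#' @export
find_dispersed_repeats <- function(seq, min_len = 50, max_mismatch = 8,
                                   kinds = c("forward", "palindromic"),
                                   circular = FALSE) {
  s <- validate_seq(seq)
  kinds <- match.arg(kinds, several.ok = TRUE)
  if (min_len < 8) stop("min_len below 8 is not supported")
  stopifnot(max_mismatch >= 0)
  n <- nchar(s)
  scan <- if (circular && n > 1L) paste0(s, substr(s, 1L, n - 1L)) else s
  code <- match(strsplit(scan, "", fixed = TRUE)[[1]],
                c("A", "C", "G", "T")) - 1L
  code[is.na(code)] <- -1L
  out <- list()
  for (k in kinds) {
    m <- scan_repeat_pairs(code, as.integer(min_len),
                           as.integer(max_mismatch), k == "palindromic")
    if (nrow(m)) {
      out[[k]] <- data.frame(kind = k, start1 = m[, 1], start2 = m[, 2],
                             length = m[, 3], mismatches = m[, 4],
                             stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(kind = character(), start1 = integer(),
                      start2 = integer(), length = integer(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  if (circular && n > 1L) {
    res <- res[res$start1 <= n, , drop = FALSE]
    key <- paste(res$kind, res$start1, ((res$start2 - 1L) %% n) + 1L,
                 res$length)
    res <- res[!duplicated(key), , drop = FALSE]
  }
  res <- res[order(res$kind, res$start1, res$start2), , drop = FALSE]
  rownames(res) <- NULL
  res
}
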