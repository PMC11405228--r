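# Fixture builders used across the suite.  Everything is generated in code;
# tests seed the RNG themselves.

# quick annotation from parallel vectors
make_ann <- function(families, starts, ends, strands = "+", classes = "cds",
                     L = max(ends, starts) + 100L, species = "T1",
                     circular = TRUE, sequence = NULL) {
  n <- length(families)
  genome_annotation(
    species, L,
    data.frame(raw_name = families, family = tolower(families),
               start = starts, end = ends,
               strand = rep_len(strands, n),
               feat_class = rep_len(classes, n), stringsAsFactors = FALSE),
    circular = circular, sequence = sequence)
}

# random non-overlapping circular annotation; rotating by a random offset
# afterwards produces origin-wrapping features
random_annotation <- function(n_genes, L = 10000L, species = "R1",
                              fam_pool = NULL, classes = c("cds", "trna",
                                                           "rrna", "orf"),
                              rotate = TRUE) {
  if (is.null(fam_pool)) fam_pool <- sprintf("gene%02d", seq_len(n_genes + 5))
  bounds <- sort(sample.int(L, n_genes))
  gaps <- diff(c(bounds, bounds[1] + L))
  lens <- pmax(1L, floor(gaps * 0.5))
  ends <- bounds + pmax(0L, pmin(lens - 1L, gaps - 2L))
  ends <- ifelse(ends > L, ends - L, ends)  # last gene may wrap the origin
  g <- make_ann(sample(fam_pool, n_genes, replace = TRUE),
                starts = bounds,
                ends = ends,
                strands = sample(c("+", "-"), n_genes, replace = TRUE),
                classes = sample(classes, n_genes, replace = TRUE,
                                 prob = c(0.6, 0.15, 0.1, 0.15)[seq_along(classes)]),
                L = L, species = species)
  if (rotate) g <- rotate_annotation(g, sample.int(L, 1) - 1L)
  g
}

revcomp_str <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

random_dna_str <- function(n, gc = 0.45) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# plant a forward or palindromic copy of s[src..src+len-1] at dst with mm
# mismatches; returns the modified sequence
plant_pair <- function(s, src, dst, len, mm = 0L, palindromic = FALSE) {
  sv <- strsplit(s, "", fixed = TRUE)[[1]]
  copy <- sv[src:(src + len - 1L)]
  if (palindromic) copy <- rev(chartr("ACGT", "TGCA", copy))
  if (mm > 0L) {
    at <- sample.int(len, mm)
    for (i in at) copy[i] <- sample(setdiff(c("A", "C", "G", "T"), copy[i]), 1)
  }
  sv[dst:(dst + len - 1L)] <- copy
  paste(sv, collapse = "")
}
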