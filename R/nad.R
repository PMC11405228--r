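# Tandem structure of the nad (respiratory complex I) gene family.

#' nad subfamily whitelist
#'
#' The mitochondrially encoded complex I subunits: nad1–nad7, nad9 and
#' nad4L.  orf-fused or exon-split annotations count through their normalized
#' family name.
#' @export
NAD_FAMILIES <- c("nad1", "nad2", "nad3", "nad4", "nad4l", "nad5", "nad6",
                  "nad7", "nad9")

#' nad–nad tandem pairs of one genome
#'
#' The subset of [find_tandem_pairs()] where both members are nad
#' subfamilies.
#'
#' @inheritParams find_tandem_pairs
#' @return `data.frame` in the [find_tandem_pairs()] layout.
#' @export
nad_pairs <- function(g, keep_classes = DEFAULT_RING_CLASSES, max_gap = Inf) {
  p <- find_tandem_pairs(g, keep_classes = keep_classes, max_gap = max_gap)
  p[p$family_a %in% NAD_FAMILIES & p$family_b %in% NAD_FAMILIES, ,
    drop = FALSE]
}

#' nad subfamilies with a tandem partner, per group
#'
#' For a grouped panel, the union over member genomes of nad subfamilies that
#' participate in any nad–nad tandem pair.
#'
#' @inheritParams conserved_pairs
#' @param groups Output of [group_species()]; when `NULL` the whole panel is
#'   treated as one group.
#' @return `data.frame`: `group_id`, `subfamilies` (comma-joined).
#' @export
nad_tandem_by_group <- function(panel, groups = NULL,
                                keep_classes = DEFAULT_RING_CLASSES) {
  ids <- panel_check(panel)
  if (is.null(groups)) {
    groups <- data.frame(species_id = ids, group_id = 1L)
  }
  per_genome <- lapply(panel, nad_pairs, keep_classes = keep_classes)
  names(per_genome) <- ids
  out <- lapply(sort(unique(groups$group_id)), function(gid) {
    mem <- groups$species_id[groups$group_id == gid]
    fams <- sort(unique(unlist(lapply(per_genome[mem], function(p) {
      c(p$family_a, p$family_b)
    }))))
    data.frame(group_id = gid, subfamilies = paste(fams, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' The nad5 tandem rule across a panel
#'
#' Per genome: `TRUE` iff nad5 is present and at least one nad–nad tandem
#' pair involves nad5 (when a genome carries several nad5 copies, any one
#' copy with a nad partner satisfies the rule; the per-copy detail is
#' recoverable from [nad_pairs()]).  The panel verdict is `TRUE` iff every
#' genome satisfies the rule; genomes lacking nad5 are reported separately.
#'
#' @inheritParams conserved_pairs
#' @return List: `per_genome` (`data.frame`: `species_id`, `has_nad5`,
#'   `nad5_tandem`, `satisfied`), `verdict` (logical), `missing_nad5`
#'   (character vector of species without nad5).
#' @export
nad5_rule <- function(panel, keep_classes = DEFAULT_RING_CLASSES) {
  ids <- panel_check(panel)
  per <- lapply(seq_along(panel), function(i) {
    g <- panel[[i]]
    has <- "nad5" %in% g$features$family[g$features$feat_class %in%
                                           keep_classes]
    np <- nad_pairs(g, keep_classes)
    tand <- has && any(np$family_a == "nad5" | np$family_b == "nad5")
    data.frame(species_id = ids[i], has_nad5 = has, nad5_tandem = tand,
               satisfied = has && tand, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  list(per_genome = per,
       verdict = all(per$satisfied),
       missing_nad5 = per$species_id[!per$has_nad5])
}

#' Collect nad gene sequences from a panel
#'
#' Extracts every nad-family gene sequence (strand-corrected to coding
#' orientation, origin-spanning genes re-joined) of length at least
#' `min_len`; short fragments are removed before tree building because they
#' carry mostly alignment noise.
#'
#' @inheritParams conserved_pairs
#' @param min_len Minimum gene length in bp (default 200).
#' @return [Biostrings::DNAStringSet] named `species_family_copy`.
#' @export
collect_nad_sequences <- function(panel, min_len = 200) {
  ids <- panel_check(panel)
  out <- character(0)
  for (g in panel) {
    if (is.null(g$sequence)) {
      stop("genome '", g$species_id, "' has no sequence backing")
    }
    f <- g$features[g$features$family %in% NAD_FAMILIES &
                      g$features$length_bp >= min_len, , drop = FALSE]
    if (!nrow(f)) next
    L <- g$genome_length
    for (i in seq_len(nrow(f))) {
      s <- if (f$wraps[i]) {
        paste0(substr(g$sequence, f$start[i], L),
               substr(g$sequence, 1L, f$end[i]))
      } else {
        substr(g$sequence, f$start[i], f$end[i])
      }
      if (f$strand[i] == "-") s <- revcomp_chr(s)
      out[paste(g$species_id, f$family[i], f$copy_index[i], sep = "_")] <- s
    }
  }
  Biostrings::DNAStringSet(out)
}
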