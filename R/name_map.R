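#' Default gene-name alias table
#'
#' Published plant mitochondrial annotations mix vocabularies: the small and
#' large ribosomal RNAs appear as `rrn18`/`rrnS` and `rrn26`/`rrnL`, the rps3
#' partner as `rpl6` or `rpl16`, maturase as `matR`/`mat-r`, and so on.  The
#' name map sends every annotated alias to one lowercase canonical family so
#' that presence, adjacency and copy counting compare like with like across a
#' panel.  `rpl16` is used as the canonical name for the rps3 partner.
#'
#' @return Named character vector mapping lowercase aliases to canonical
#'   lowercase family names.  Every value is itself a key (the map is
#'   idempotent).
#' @export
#' @examples
#' default_name_map()[["rrn18"]]
default_name_map <- function() {
  m <- c(
    rrn18 = "rrns", rrn16 = "rrns", rrns = "rrns", "rrn-s" = "rrns",
    rrn26 = "rrnl", rrnl = "rrnl", "rrn-l" = "rrnl",
    rrn5  = "rrn5",
    rpl6  = "rpl16", rpl16 = "rpl16",
    "mat-r" = "matr", matr = "matr",
    nad4l = "nad4l",
    ccmfn = "ccmfn", ccmfc = "ccmfc",
    mttb  = "mttb", cob = "cob"
  )
  # make idempotent: every canonical value maps to itself
  vals <- unique(unname(m))
  extra <- setNames(vals, vals)
  c(m, extra[!names(extra) %in% names(m)])
}

# prefixes of gene names we recognise as mitochondrial vocabulary; unknown
# names outside this set trigger a pass-through warning
.known_prefix_re <- "^(nad|sdh|cob|cox|atp|ccm|rps|rpl|rrn|trn|mat|mtt|orf)"

#' Normalize annotated gene names to canonical families
#'
#' Lowercases names, strips copy-number decorations (`nad4-2`, `atp9_1`,
#' `rps4-copy2`) when the remaining stem is recognisable mitochondrial
#' vocabulary, and applies the alias table.  tRNA genes keep their anticodon
#' suffix (`trnM-CAU` becomes `trnm-cau`) because copy counting distinguishes
#' isoacceptors.  Unknown names pass through lowercased with a warning rather
#' than being dropped: published panels mix annotation vocabularies and a
#' silent drop would bias presence/absence calls.
#'
#' @param x Character vector of annotated gene names.
#' @param map Alias table, see [default_name_map()].
#' @return Character vector of canonical lowercase family names.
#' @export
#' @examples
#' normalize_family(c("NAD5", "rrn18", "trnM-CAU", "atp9-2"))
normalize_family <- function(x, map = default_name_map()) {
  low <- tolower(trimws(as.character(x)))
  # strip a trailing copy decoration if the stem still looks like a gene name
  stem <- sub("[_-](copy)?[0-9]+$", "", low)
  strip_ok <- stem != low & grepl(.known_prefix_re, stem) &
    # never strip the only digits a name has (e.g. "rrn5" written "rrn-5")
    (grepl("[0-9]", stem) | stem %in% names(map) | grepl("^trn", stem))
  low[strip_ok] <- stem[strip_ok]
  mapped <- ifelse(low %in% names(map), unname(map[low]), low)
  unknown <- unique(low[!low %in% names(map) & !grepl(.known_prefix_re, low)])
  if (length(unknown)) {
    warning("unrecognised gene name(s) passed through lowercased: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  mapped
}
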