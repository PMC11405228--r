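# Reading annotated genomes into the internal model.
#
# GFF3+FASTA goes through rtracklayer/Biostrings.  GenBank flat files are
# parsed by a small purpose-built reader below (LOCUS, FEATURES with
# complement()/join() locations including origin-spanning joins, ORIGIN):
# only the fields the comparative analysis consumes are extracted.

#' Read an annotated genome
#'
#' Reads a GenBank flat file or a GFF3 (+ optional FASTA) pair into a
#' [genome_annotation()].  Gene names are normalized through the alias table;
#' features are sorted by start with deterministic tie-breaks.  Features that
#' span the origin of a circular record keep their annotated start/end and
#' are flagged `wraps`.
#'
#' @param path Path to the GenBank (`.gb`, `.gbk`) or GFF3 (`.gff`, `.gff3`)
#'   file.
#' @param format `"auto"` (by extension), `"genbank"` or `"gff3"`.
#' @param fasta Optional FASTA path giving the sequence (GFF3 input only).
#' @param species_id Species label; defaults to the record name (GenBank) or
#'   the file stem (GFF3).
#' @param name_map Alias table, see [default_name_map()].
#' @param circular For GFF3 input, whether the molecule is circular
#'   (GenBank records carry this on the LOCUS line). Default `TRUE`.
#' @return A `GenomeAnnotation`.
#' @export
read_genome <- function(path, format = c("auto", "genbank", "gff3"),
                        fasta = NULL, species_id = NULL,
                        name_map = default_name_map(), circular = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gb|gbk|gbff|genbank)$", path, ignore.case = TRUE))
      "genbank" else "gff3"
  }
  if (format == "genbank") {
    rec <- parse_genbank(path)
    genome_annotation(species_id %||% rec$name, rec$length, rec$features,
                      circular = rec$circular, sequence = rec$sequence,
                      name_map = name_map)
  } else {
    read_gff3_genome(path, fasta, species_id, name_map, circular)
  }
}

feature_class_from_name <- function(key, name) {
  cls <- rep("cds", length(key))
  cls[key %in% c("tRNA", "trna")] <- "trna"
  cls[key %in% c("rRNA", "rrna")] <- "rrna"
  nm <- tolower(name)
  cls[cls == "cds" & grepl("^trn", nm)] <- "trna"
  cls[cls == "cds" & grepl("^rrn", nm)] <- "rrna"
  cls[cls == "cds" & grepl("^orf", nm)] <- "orf"
  cls
}

read_gff3_genome <- function(path, fasta, species_id, name_map, circular) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("cannot parse GFF3 '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  d <- as.data.frame(gr, stringsAsFactors = FALSE)
  seq <- NULL
  glen <- NA_integer_
  if (!is.null(fasta)) {
    ss <- Biostrings::readDNAStringSet(fasta)
    seq <- as.character(ss[[1]])
    glen <- Biostrings::width(ss)[1]
  } else {
    sl <- GenomeInfoDb_seqlengths(gr)
    if (length(sl) && !is.na(sl[1])) glen <- as.integer(sl[1])
    if (is.na(glen)) glen <- max(d$end)
  }
  types <- as.character(d$type)
  use <- if (any(types == "gene")) types == "gene" else
    types %in% c("CDS", "tRNA", "rRNA")
  d <- d[use, , drop = FALSE]
  types <- types[use]
  nm <- rep(NA_character_, nrow(d))
  for (col in c("Name", "gene", "ID")) {
    if (col %in% names(d)) {
      v <- as.character(d[[col]])
      nm <- ifelse(is.na(nm) & !is.na(v), v, nm)
    }
  }
  if (anyNA(nm)) stop("GFF3 feature without Name/gene/ID attribute in ", path)
  f <- data.frame(raw_name = nm, start = d$start, end = d$end,
                  strand = ifelse(as.character(d$strand) == "-", "-", "+"),
                  feat_class = feature_class_from_name(types, nm),
                  stringsAsFactors = FALSE)
  for (col in c("coverage", "match")) {
    if (col %in% names(d)) f[[col]] <- suppressWarnings(as.numeric(d[[col]]))
  }
  # merge origin-spanning feature split over two rows sharing an ID
  if ("ID" %in% names(d)) {
    ids <- as.character(d$ID)
    dup <- ids[duplicated(ids) & !is.na(ids)]
    for (id in unique(dup)) {
      i <- which(ids == id)
      if (length(i) == 2L) {
        hi <- i[which.max(f$start[i])]; lo <- setdiff(i, hi)
        if (f$end[hi] == glen && f$start[lo] == 1L) {
          f$end[hi] <- f$end[lo]   # wraps: end < start
          f <- f[-lo, , drop = FALSE]
          ids <- ids[-lo]
        }
      }
    }
  }
  if (is.null(species_id)) {
    species_id <- sub("\\.(gff3?|gff)$", "", basename(path),
                      ignore.case = TRUE)
  }
  genome_annotation(species_id, glen, f, circular = circular,
                    sequence = seq, name_map = name_map)
}

GenomeInfoDb_seqlengths <- function(gr) {
  tryCatch(GenomeInfoDb::seqlengths(gr), error = function(e) integer())
}

# ---- GenBank flat-file parsing ---------------------------------------------

parse_gb_location <- function(loc, glen, line_no) {
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  rng <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^([0-9]+)(\\.\\.([0-9]+))?$", p))[[1]]
    if (!length(m)) stop("unparseable location '", p, "' (GenBank line ",
                         line_no, ")", call. = FALSE)
    a <- as.integer(m[2])
    b <- if (m[4] == "") a else as.integer(m[4])
    c(a, b)
  })
  starts <- vapply(rng, `[`, integer(1), 1L)
  ends <- vapply(rng, `[`, integer(1), 2L)
  wraps <- length(parts) > 1L && ends[1] == glen && starts[length(starts)] == 1L
  if (wraps) {
    c(start = starts[1], end = ends[length(ends)], minus = strand == "-")
  } else {
    c(start = min(starts), end = max(ends), minus = strand == "-")
  }
}

parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("no LOCUS line in '", path, "'", call. = FALSE)
  name <- strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]][1]
  glen <- as.integer(sub(".*?([0-9]+)\\s+bp.*", "\\1", locus[1]))
  if (is.na(glen)) stop("cannot recover genome length from LOCUS line of '",
                        path, "'", call. = FALSE)
  circular <- grepl("circular", locus[1], ignore.case = TRUE)

  fstart <- grep("^FEATURES", lines)
  fend <- grep("^(ORIGIN|CONTIG|//)", lines)
  fend <- if (length(fend)) min(fend[fend > fstart[1]]) else length(lines) + 1L
  if (!length(fstart)) stop("no FEATURES table in '", path, "'", call. = FALSE)
  block <- lines[(fstart[1] + 1L):(fend - 1L)]
  block_no <- (fstart[1] + 1L):(fend - 1L)

  is_key <- grepl("^ {5}\\S", block)
  idx <- which(is_key)
  feats <- list()
  for (k in seq_along(idx)) {
    i <- idx[k]
    j <- if (k < length(idx)) idx[k + 1] - 1L else length(block)
    key <- trimws(substr(block[i], 6, 20))
    if (!key %in% c("gene", "CDS", "tRNA", "rRNA")) next
    body <- block[i:j]
    # location may continue over lines until the first qualifier
    qual_at <- grep("^ {21}/", body)
    loc_end <- if (length(qual_at)) qual_at[1] - 1L else length(body)
    loc <- paste0(trimws(substr(body[1], 21, nchar(body[1]))),
                  paste(trimws(body[seq_len(loc_end)][-1]), collapse = ""))
    quals <- body[grepl("^ {21}/", body)]
    getq <- function(q) {
      hit <- grep(paste0("^\\s*/", q, "="), quals, value = TRUE)
      if (!length(hit)) return(NA_character_)
      gsub("\"", "", sub(paste0("^\\s*/", q, "="), "", trimws(hit[1])))
    }
    nmv <- getq("gene")
    if (is.na(nmv)) nmv <- getq("label")
    if (is.na(nmv)) nmv <- getq("product")
    if (is.na(nmv)) next
    pos <- parse_gb_location(loc, glen, block_no[i])
    feats[[length(feats) + 1L]] <- data.frame(
      key = key, raw_name = nmv, start = pos[["start"]], end = pos[["end"]],
      strand = if (pos[["minus"]] == 1) "-" else "+",
      stringsAsFactors = FALSE)
  }
  if (!length(feats)) stop("no gene/CDS/tRNA/rRNA features in '", path, "'",
                           call. = FALSE)
  f <- do.call(rbind, feats)
  # NCBI records usually carry both a gene row and a CDS/tRNA/rRNA row for
  # the same locus; keep gene rows plus any typed row not covered by one
  if (any(f$key == "gene")) {
    gk <- paste(tolower(f$raw_name), f$start)[f$key == "gene"]
    f <- f[f$key == "gene" | !paste(tolower(f$raw_name), f$start) %in% gk, ,
           drop = FALSE]
  }
  f$feat_class <- feature_class_from_name(f$key, f$raw_name)
  f$key <- NULL

  seq <- NULL
  ostart <- grep("^ORIGIN", lines)
  if (length(ostart)) {
    oend <- grep("^//", lines)
    oend <- if (length(oend)) min(oend[oend > ostart[1]]) else length(lines) + 1L
    sl <- lines[(ostart[1] + 1L):(oend - 1L)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(sl, collapse = "")))
    if (!nchar(seq)) seq <- NULL
  }
  list(name = name, length = glen, circular = circular, features = f,
       sequence = seq)
}

# ---- annotation-quality filter ---------------------------------------------

#' Filter features on annotation coverage and match
#'
#' Annotation transfer tools report per-feature "coverage" and "match"
#' fractions; weakly supported transfers are removed before comparative
#' analysis.  A feature is kept when both attributes are at or above their
#' thresholds; features lacking the attributes are kept.  The default
#' threshold of 0.60 reflects the usual manual-curation cut; lowering it to
#' 0.40 retains borderline multi-copy calls (the nad family is the classic
#' case where the two settings disagree).
#'
#' @param g A `GenomeAnnotation`.
#' @param min_coverage,min_match Thresholds in \[0, 1\].
#' @param attrs Optional `data.frame` with one row per feature (in `g`'s
#'   sorted order) and columns `coverage` and/or `match`; when `NULL`, the
#'   feature table's own `coverage`/`match` columns are used if present.
#' @return The filtered `GenomeAnnotation` (copy indices recomputed).
#' @export
filter_features <- function(g, min_coverage = 0.6, min_match = 0.6,
                            attrs = NULL) {
  stopifnot(inherits(g, "GenomeAnnotation"))
  if (min_coverage < 0 || min_coverage > 1 || min_match < 0 || min_match > 1) {
    stop("thresholds must be in [0, 1]")
  }
  f <- g$features
  cov <- mtch <- rep(NA_real_, nrow(f))
  if (!is.null(attrs)) {
    if (nrow(attrs) != nrow(f)) {
      stop("attrs must have one row per feature (", nrow(f), ")")
    }
    if (!is.null(attrs$coverage)) cov <- as.numeric(attrs$coverage)
    if (!is.null(attrs$match)) mtch <- as.numeric(attrs$match)
  } else {
    if (!is.null(f$coverage)) cov <- f$coverage
    if (!is.null(f$match)) mtch <- f$match
  }
  keep <- (is.na(cov) | cov >= min_coverage) & (is.na(mtch) | mtch >= min_match)
  genome_annotation(g$species_id, g$genome_length,
                    f[keep, , drop = FALSE],
                    circular = g$circular, sequence = g$sequence)
}
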