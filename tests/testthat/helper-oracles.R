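# Independent brute-force oracles.  These re-derive expected results straight
# from the definitions (successor-by-circular-distance adjacency, per-start
# greedy repeat windows, exhaustive block windows) and stay independent of the
# package's algorithms.

# adjacency edges as successor-by-smallest-circular-distance between starts
oracle_tandem_pairs <- function(g, keep_classes = DEFAULT_RING_CLASSES,
                                max_gap = Inf, allow_self = FALSE) {
  f <- g$features[g$features$feat_class %in% keep_classes, , drop = FALSE]
  n <- nrow(f)
  L <- g$genome_length
  out <- list()
  if (n >= 2L) {
    for (i in seq_len(n)) {
      dist <- (f$start - f$start[i]) %% L
      dist[i] <- NA
      j <- which.min(ifelse(dist == 0, L, dist)) # ties: first by sort order
      a <- f[i, ]; b <- f[j, ]
      if (!g$circular && b$start < a$start) next # no wrap edge on linear
      if (!allow_self && a$family == b$family) next
      a_end_circ <- if (a$wraps) a$end else a$end
      raw <- if (b$start > a$end || a$wraps) b$start - a$end - 1L
        else (L - a$end) + b$start - 1L
      gap <- max(0L, raw)
      if (gap > max_gap) next
      ori <- if (a$strand == b$strand) {
        if (a$strand == "+") "same_strand_plus" else "same_strand_minus"
      } else "opposite"
      fams <- sort(c(a$family, b$family))
      out[[length(out) + 1L]] <- data.frame(
        genome = g$species_id, family_a = fams[1], family_b = fams[2],
        upstream = a$family, orientation = ori, gap_bp = gap,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  d <- do.call(rbind, out)
  d[order(d$upstream, d$family_a, d$family_b, d$gap_bp), , drop = FALSE]
}

# maximal perfect SSR runs by direct per-start extension
oracle_ssrs <- function(s, minima = c(8L, 4L, 4L, 3L, 3L, 3L)) {
  sv <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  n <- length(sv)
  prim <- function(mo) {
    p <- nchar(mo)
    if (p == 1L) return(TRUE)
    for (d in seq_len(p - 1L)) {
      if (p %% d == 0L && mo == strrep(substr(mo, 1, d), p / d)) return(FALSE)
    }
    TRUE
  }
  eq <- function(t, p) {
    t >= 1L && t + p <= n && sv[t] != "N" && sv[t + p] != "N" &&
      sv[t] == sv[t + p]
  }
  out <- list()
  for (p in 1:6) {
    t <- 1L
    while (t + p <= n) {
      if (eq(t, p) && !eq(t - 1L, p)) {
        len <- 0L
        while (eq(t + len, p)) len <- len + 1L
        stretch <- len + p
        count <- stretch %/% p
        motif <- paste(sv[t:(t + p - 1L)], collapse = "")
        if (count >= minima[p] && !grepl("N", motif) && prim(motif)) {
          out[[length(out) + 1L]] <- data.frame(
            motif = motif, unit_len = p, repeat_count = count, start = t,
            end = t + p * count - 1L, stringsAsFactors = FALSE)
        }
        t <- t + len
      } else {
        t <- t + 1L
      }
    }
  }
  if (!length(out)) return(NULL)
  d <- do.call(rbind, out)
  d[order(d$start, d$unit_len), , drop = FALSE]
}

# maximal repeat-pair windows by per-start greedy extension and an explicit
# left-maximality check
oracle_dispersed <- function(s, min_len, max_mm, kind) {
  code <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]],
                c("A", "C", "G", "T"))
  n <- length(code)
  rows <- list()
  scan_domain <- function(mis, dom_off, pair_c, d) {
    Ld <- length(mis)
    if (Ld < min_len) return()
    cs <- c(0L, cumsum(mis))
    zpos <- which(mis)
    K <- length(zpos)
    for (p0 in seq_len(Ld)) {
      idx <- cs[p0]                       # mismatches strictly before p0
      target <- idx + max_mm + 1L
      pend <- if (target <= K) zpos[target] - 1L else Ld
      mm_w <- cs[pend + 1L] - cs[p0]
      maximal_left <- p0 == 1L || (mis[p0 - 1L] && mm_w + 1L > max_mm)
      len <- pend - p0 + 1L
      if (maximal_left && len >= min_len) {
        p1 <- dom_off + p0 - 1L
        pb <- dom_off + pend - 1L
        p2 <- if (is.na(pair_c)) p1 + d else pair_c - pb
        rows[[length(rows) + 1L]] <<- data.frame(
          kind = kind, start1 = p1, start2 = p2, length = len,
          mismatches = mm_w, stringsAsFactors = FALSE)
      }
    }
  }
  if (kind == "forward") {
    for (d in seq_len(n - 1L)) {
      Ld <- n - d
      if (Ld < min_len) break
      a <- code[seq_len(Ld)]
      b <- code[(1L + d):n]
      scan_domain(is.na(a) | is.na(b) | a != b, 1L, NA, d)
    }
  } else {
    for (cc in 3L:(2L * n - 1L)) {
      pmin_ <- max(1L, cc - n)
      pmax_ <- (cc - 1L) %/% 2L
      if (pmax_ < pmin_) next
      p <- pmin_:pmax_
      a <- code[p]
      b <- code[cc - p]
      scan_domain(is.na(a) | is.na(b) | a + b != 5L, pmin_, cc, NA)
    }
  }
  if (!length(rows)) return(NULL)
  d <- do.call(rbind, rows)
  d[order(d$start1, d$start2, d$length), , drop = FALSE]
}

# exhaustive shared-block enumeration over all circular windows of both rings
oracle_blocks <- function(g1, g2, keep_classes = DEFAULT_RING_CLASSES) {
  r1 <- adjacency_ring(g1, keep_classes)
  r2 <- adjacency_ring(g2, keep_classes)
  n1 <- nrow(r1); n2 <- nrow(r2)
  if (n1 < 2L || n2 < 2L) return(NULL)
  w1 <- function(i) ((i - 1L) %% n1) + 1L
  w2 <- function(j) ((j - 1L) %% n2) + 1L
  cand <- list()
  for (len in 2L:min(n1, n2)) {
    for (i in seq_len(n1)) {
      idx1 <- w1(i + 0:(len - 1L))
      fam <- r1$family[idx1]
      if (anyDuplicated(fam)) next
      str <- r1$strand[idx1]
      for (j in seq_len(n2)) {
        idx2f <- w2(j + 0:(len - 1L))
        if (identical(r2$family[idx2f], fam) &&
            identical(r2$strand[idx2f], str)) {
          cand[[length(cand) + 1L]] <- list(i = i, j = j, dir = 1L, len = len)
        }
        idx2r <- w2(j - 0:(len - 1L))
        if (identical(r2$family[idx2r], fam) &&
            identical(r2$strand[idx2r],
                      ifelse(str == "+", "-", "+"))) {
          cand[[length(cand) + 1L]] <- list(i = i, j = j, dir = -1L,
                                            len = len)
        }
      }
    }
  }
  if (!length(cand)) return(NULL)
  contained <- function(bsm, bbig) {
    if (bsm$dir != bbig$dir || bsm$len > bbig$len) return(FALSE)
    for (s in 0:(bbig$len - bsm$len)) {
      if (w1(bbig$i + s) == bsm$i &&
          w2(bbig$j + bbig$dir * s) == bsm$j) return(TRUE)
    }
    FALSE
  }
  keep <- rep(TRUE, length(cand))
  for (a in seq_along(cand)) {
    for (b in seq_along(cand)) {
      if (a == b || !keep[a]) next
      if (cand[[a]]$len < cand[[b]]$len && contained(cand[[a]], cand[[b]])) {
        keep[a] <- FALSE
        break
      }
    }
  }
  cand <- cand[keep]
  rows <- lapply(cand, function(x) {
    idx1 <- w1(x$i + 0:(x$len - 1L))
    idx2 <- w2(x$j + x$dir * (0:(x$len - 1L)))
    data.frame(relation = if (x$dir == 1L) "colinear" else "inverted",
               n_families = x$len,
               families = paste(r1$family[idx1], collapse = ","),
               g1_start = r1$start[idx1[1]], g2_start = r2$start[idx2[1]],
               key = paste(x$dir, paste(sort(idx1), collapse = ","),
                           paste(sort(idx2), collapse = ",")),
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  d <- d[!duplicated(d$key), setdiff(names(d), "key"), drop = FALSE]
  d[order(d$relation, d$g1_start, d$g2_start), , drop = FALSE]
}
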