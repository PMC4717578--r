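## Exact k-mer seeding with diagonal chaining and X-drop extension.
## Substitution-dominated homology is the regime this package targets
## (miniature LTR elements diverge mostly by point substitution), so
## chains and extensions are gapless: a hit lives on one alignment
## diagonal. Gapped refinement, where needed (clustering, gene capture),
## goes through Biostrings::pairwiseAlignment instead.

# X-drop extension along a match vector (logical). From anchor [a, b]
# (1-based on m), extend outward scoring +1 match / `mis` mismatch,
# dropping out when the running score falls more than `x` below its
# maximum. Returns c(start, end) of the score-maximal extension.
.xdrop_extend <- function(m, a, b, x = 12, mis = -3) {
  n <- length(m)
  step <- ifelse(m, 1, mis)
  # right
  e <- b
  if (b < n) {
    s <- cumsum(step[(b + 1L):n])
    peak <- cummax(s)
    stopi <- which(peak - s > x)
    lim <- if (length(stopi)) stopi[1L] - 1L else length(s)
    if (lim > 0) {
      best <- which.max(s[seq_len(lim)])
      if (s[best] > 0) e <- b + best
    }
  }
  # left
  s0 <- a
  if (a > 1L) {
    s <- cumsum(rev(step[1L:(a - 1L)]))
    peak <- cummax(s)
    stopi <- which(peak - s > x)
    lim <- if (length(stopi)) stopi[1L] - 1L else length(s)
    if (lim > 0) {
      best <- which.max(s[seq_len(lim)])
      if (s[best] > 0) s0 <- a - best
    }
  }
  c(s0, e)
}

# Clean-terminus trim: shrink [a, b] on match vector m until the
# outermost `w` columns at each end are all matches. Keeps exact-repeat
# boundaries exact and prevents chance-match overrun into flanking
# sequence. Returns c(a, b) or NULL if no clean window survives.
.clean_trim <- function(m, a, b, w = 6L) {
  if (b - a + 1L < w) return(NULL)
  cs <- cumsum(m)
  # positions j in [a+w-1, b] where m[j-w+1 .. j] are all matches
  j <- (a + w - 1L):b
  full <- (cs[j] - c(0, cs)[j - w + 1L]) == w
  if (!any(full)) return(NULL)
  b2 <- j[max(which(full))]
  a2 <- j[min(which(full))] - w + 1L
  if (a2 > b2) NULL else c(a2, b2)
}

# Collapse sorted positions into chains with gaps <= gap; returns an
# integer chain id per position.
.chain_ids <- function(pos, gap) {
  if (length(pos) == 0) return(integer(0))
  cumsum(c(1L, diff(pos) > gap))
}

# Seed pairs within one sequence: positions i < j carrying identical
# k-mers with start-to-start distance in [dmin, dmax]. Returns a
# data.table(p1, p2, d). Codes with more than max_occ occurrences are
# skipped (tandem-repeat guard).
.self_seed_pairs <- function(codes, dmin, dmax, max_occ = 400L) {
  ok <- which(!is.na(codes))
  if (length(ok) < 2)
    return(data.table::data.table(p1 = integer(0), p2 = integer(0),
                                  d = integer(0)))
  dt <- data.table::data.table(code = codes[ok], pos = ok)
  data.table::setkey(dt, code, pos)
  dt[, n := .N, by = code]
  dt <- dt[n >= 2L & n <= max_occ]
  if (nrow(dt) == 0)
    return(data.table::data.table(p1 = integer(0), p2 = integer(0),
                                  d = integer(0)))
  out <- dt[, {
    p <- pos
    res_p1 <- integer(0); res_p2 <- integer(0)
    for (lag in seq_len(length(p) - 1L)) {
      dd <- p[-seq_len(lag)] - p[seq_len(length(p) - lag)]
      keep <- dd >= dmin & dd <= dmax
      if (!any(keep)) { if (all(dd > dmax)) break else next }
      res_p1 <- c(res_p1, p[seq_len(length(p) - lag)][keep])
      res_p2 <- c(res_p2, p[-seq_len(lag)][keep])
    }
    list(p1 = res_p1, p2 = res_p2)
  }, by = code][, .(p1, p2, d = p2 - p1)]
  out
}

# Gapless local hits of query in subject via shared k-mers on common
# diagonals. Returns a data.frame of hits with subject/query coordinates,
# match counts and scores (match +1 / mismatch -1, scaled by
# score_scale). Coordinates 1-based inclusive.
.seed_hits <- function(query, subject, k = 12L, chain_gap = 40L,
                       xdrop = 15, mis = -3, min_len = 20L,
                       score_scale = 10, max_occ = 2000L) {
  qv <- .dna_codes(query); sv <- .dna_codes(subject)
  qc <- .kmer_codes(qv, k); sc <- .kmer_codes(sv, k)
  empty <- data.frame(sstart = integer(0), send = integer(0),
                      qstart = integer(0), qend = integer(0),
                      matches = integer(0), length = integer(0),
                      identity = numeric(0), score = numeric(0))
  if (length(qc) == 0 || length(sc) == 0) return(empty)
  qdt <- data.table::data.table(code = qc, qpos = seq_along(qc))
  qdt <- qdt[!is.na(code)]
  sdt <- data.table::data.table(code = sc, spos = seq_along(sc))
  sdt <- sdt[!is.na(code)]
  sdt[, n := .N, by = code]
  sdt <- sdt[n <= max_occ]
  if (nrow(qdt) == 0 || nrow(sdt) == 0) return(empty)
  hits <- merge(qdt, sdt, by = "code", allow.cartesian = TRUE)
  if (nrow(hits) == 0) return(empty)
  hits[, diag := spos - qpos]
  data.table::setorder(hits, diag, spos)
  hits[, chain := paste0(diag, "_", .chain_ids(spos, chain_gap)), by = diag]
  anchors <- hits[, .(diag = diag[1L], s1 = min(spos), s2 = max(spos) + k - 1L),
                  by = chain]

  nq <- length(qv); ns <- length(sv)
  out <- vector("list", nrow(anchors))
  for (i in seq_len(nrow(anchors))) {
    dg <- anchors$diag[i]
    # overlap of subject positions for this diagonal
    lo <- max(1L, 1L + dg); hi <- min(ns, nq + dg)
    if (hi - lo + 1L < min_len) next
    m <- !is.na(sv[lo:hi]) & !is.na(qv[(lo - dg):(hi - dg)]) &
      sv[lo:hi] == qv[(lo - dg):(hi - dg)]
    a <- anchors$s1[i] - lo + 1L
    b <- anchors$s2[i] - lo + 1L
    ext <- .xdrop_extend(m, a, b, x = xdrop, mis = mis)
    tr <- .clean_trim(m, ext[1L], ext[2L])
    if (is.null(tr)) next
    len <- tr[2L] - tr[1L] + 1L
    if (len < min_len) next
    nm <- sum(m[tr[1L]:tr[2L]])
    out[[i]] <- data.frame(
      sstart = lo + tr[1L] - 1L, send = lo + tr[2L] - 1L,
      qstart = lo + tr[1L] - 1L - dg, qend = lo + tr[2L] - 1L - dg,
      matches = nm, length = len, identity = nm / len,
      score = score_scale * (nm - (len - nm)))
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) return(empty)
  # de-duplicate identical extensions arising from split chains
  res <- res[!duplicated(res[, c("sstart", "send", "qstart")]), , drop = FALSE]
  res[order(res$sstart, res$send), , drop = FALSE]
}

# Best placement(s) of a query in a subject; returns top hits sorted by
# score desc. Used for flank mapping in polymorphism calling.
.best_hits <- function(query, subject, k = 12L, ...) {
  h <- .seed_hits(query, subject, k = k, ...)
  h[order(-h$score, h$sstart), , drop = FALSE]
}
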