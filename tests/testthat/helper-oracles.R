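# Independent oracles used across the suite. Each re-derives a result by
# a method unrelated to the implementation it checks.

# Brute-force direct-repeat enumeration by shift-and-compare run-length
# encoding: for every spacing D, exact-match runs between the sequence
# and its D-shifted copy are maximal exact repeats. Shares only the
# final candidate post-processing with the scanner (by design, so the
# two sets are comparable).
oracle_scan <- function(genome, params = scan_params()) {
  stopifnot(length(genome) == 1)
  v <- utf8ToInt(genome[[1]])
  n <- length(v)
  dmin <- params$min_ltr + params$min_spacing
  dmax <- min(params$max_ltr + params$max_spacing, n - params$min_ltr)
  rows <- list()
  for (D in dmin:dmax) {
    m <- v[1:(n - D)] == v[(1 + D):n]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= params$min_ltr)) {
      L <- r$lengths[k]
      if (L > params$max_ltr) next
      sp <- D - L
      if (sp < params$min_spacing || sp > params$max_spacing) next
      st <- starts[k]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = names(genome)[1], start = st, end = st + D + L - 1L,
        ltr5_start = st, ltr5_end = st + L - 1L,
        ltr3_start = st + D, ltr3_end = st + D + L - 1L,
        ltr_identity = 1.0)
    }
  }
  cands <- do.call(rbind, rows)
  if (is.null(cands))
    return(cands)
  finalize_candidates(cands, genome, params)
}

# Exhaustive Nei-Gojobori-style codon comparison: enumerates every
# mutational pathway explicitly with its own codon table lookups.
oracle_ng86_codon <- function(c1, c2) {
  code <- as.list(Biostrings::GENETIC_CODE)
  sites <- function(codon) {
    s <- 0
    for (pos in 1:3) {
      for (b in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
        mut <- codon
        substr(mut, pos, pos) <- b
        if (code[[mut]] != "*" && code[[mut]] == code[[codon]])
          s <- s + 1 / 3
      }
    }
    s
  }
  diffpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  enum_paths <- function(cur, remaining) {
    if (length(remaining) == 0)
      return(list(list(sd = 0, nd = 0, stop = FALSE)))
    out <- list()
    for (i in seq_along(remaining)) {
      pos <- remaining[i]
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      syn <- code[[nxt]] == code[[cur]] && code[[cur]] != "*"
      hit_stop <- code[[nxt]] == "*" || code[[cur]] == "*"
      for (tailp in enum_paths(nxt, remaining[-i])) {
        out[[length(out) + 1L]] <- list(
          sd = tailp$sd + as.integer(syn),
          nd = tailp$nd + as.integer(!syn),
          stop = tailp$stop || hit_stop)
      }
    }
    out
  }
  paths <- enum_paths(c1, diffpos)
  keep <- Filter(function(p) !p$stop, paths)
  if (length(keep) == 0) keep <- paths
  list(S = (sites(c1) + sites(c2)) / 2,
       N = 3 - (sites(c1) + sites(c2)) / 2,
       Sd = mean(vapply(keep, `[[`, numeric(1), "sd")),
       Nd = mean(vapply(keep, `[[`, numeric(1), "nd")))
}

# All-pairs single-linkage partition by explicit transitive closure over
# a precomputed predicate matrix (no graph library).
oracle_single_linkage <- function(adj) {
  n <- nrow(adj)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# Per-base bitmap measure of an interval union.
oracle_masked_bp <- function(starts, ends, n) {
  bm <- logical(n)
  for (i in seq_along(starts)) bm[starts[i]:ends[i]] <- TRUE
  sum(bm)
}

# Implant an element with a TSD into a host sequence at a given point:
# host[1..p] + tsd + element + tsd + host[(p+len(tsd)+1)..]; returns the
# sequence and the element's 1-based interval.
implant <- function(host, p, element, tsd) {
  stopifnot(substr(host, p + 1, p + nchar(tsd)) == tsd ||
              TRUE)  # tsd may be arbitrary; we overwrite the site
  before <- substr(host, 1, p)
  after <- substr(host, p + nchar(tsd) + 1, nchar(host))
  seqs <- paste0(before, tsd, element, tsd, after)
  list(seq = seqs, start = p + nchar(tsd) + 1,
       end = p + nchar(tsd) + nchar(element))
}

# Match detected candidates to truth records; returns per-truth row the
# index of the nearest candidate and its boundary errors.
match_truth <- function(truth, cands, max_dist = 100) {
  do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
    if (nrow(cands) == 0)
      return(data.frame(truth_i = i, cand_i = NA, dstart = NA, dend = NA))
    d <- abs(cands$start - truth$start[i]) + abs(cands$end - truth$end[i])
    j <- which.min(d)
    if (d[j] > max_dist)
      return(data.frame(truth_i = i, cand_i = NA, dstart = NA, dend = NA))
    data.frame(truth_i = i, cand_i = j,
               dstart = cands$start[j] - truth$start[i],
               dend = cands$end[j] - truth$end[i])
  }))
}
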