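## De novo detection of miniature LTR-element candidates: pairs of nearby
## direct repeats of 30-500 bp separated by 30-2000 bp, with 4-6 bp
## target-site duplications. Replaces an external LTR finder with an
## auditable k-mer seed + X-drop implementation.

#' Scanner parameters
#'
#' Defaults follow the element envelope used throughout the package: LTRs
#' of 30-500 bp, internal spacing of 30-2000 bp, 4-6 bp TSDs, and an LTR
#' pair identity floor of 0.80 (aligned with the 80/80 clustering rule; the
#' threshold is exposed because no canonical value exists).
#'
#' @param min_ltr,max_ltr LTR length bounds, bp.
#' @param min_spacing,max_spacing Internal-region length bounds, bp.
#' @param seed_k Exact k-mer seed length.
#' @param min_ltr_identity Minimum LTR-pair identity (fraction).
#' @param tsd_min,tsd_max TSD length bounds.
#' @param tsd_snap Maximum boundary adjustment (bp) allowed when snapping
#'   element ends onto a flanking exact TSD.
#' @return A list of class `trim_scan_params`.
#' @export
scan_params <- function(min_ltr = 30L, max_ltr = 500L,
                        min_spacing = 30L, max_spacing = 2000L,
                        seed_k = 12L, min_ltr_identity = 0.80,
                        tsd_min = 4L, tsd_max = 6L, tsd_snap = 12L) {
  p <- list(min_ltr = as.integer(min_ltr), max_ltr = as.integer(max_ltr),
            min_spacing = as.integer(min_spacing),
            max_spacing = as.integer(max_spacing),
            seed_k = as.integer(seed_k),
            min_ltr_identity = min_ltr_identity,
            tsd_min = as.integer(tsd_min), tsd_max = as.integer(tsd_max),
            tsd_snap = as.integer(tsd_snap))
  stopifnot(p$min_ltr <= p$max_ltr, p$min_spacing <= p$max_spacing,
            p$min_ltr_identity > 0, p$min_ltr_identity <= 1,
            p$tsd_min >= 1, p$tsd_min <= p$tsd_max)
  class(p) <- "trim_scan_params"
  p
}

.empty_candidates <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             ltr5_start = integer(0), ltr5_end = integer(0),
             ltr3_start = integer(0), ltr3_end = integer(0),
             ltr_identity = numeric(0), tsd = character(0),
             stringsAsFactors = FALSE)
}

# LTR pair identity for possibly unequal-length LTRs: gapless when equal
# length (the dominant case under substitution divergence), global
# alignment otherwise.
.ltr_pair_identity <- function(l5, l3) {
  if (nchar(l5) == 0 || nchar(l3) == 0) return(0)
  if (nchar(l5) == nchar(l3)) return(seq_identity(l5, l3))
  a <- .local_align(l5, l3, match = 1, mismatch = -1,
                    gap_open = -4, gap_ext = -1)
  if (a$ncol == 0) return(0)
  a$nmatch / max(nchar(l5), nchar(l3))
}

#' Detect the target-site duplication flanking a candidate element
#'
#' Looks for the longest exact match of length `tsd_min`-`tsd_max` between
#' the sequence immediately left of the element start and immediately right
#' of the element end (both anchored to the element boundary).
#'
#' @param candidate One-row data.frame with `chrom`, `start`, `end`.
#' @param genome Genome as accepted by [scan_genome()].
#' @param tsd_min,tsd_max TSD length bounds.
#' @return The TSD sequence, or `NA_character_` when no exact 4-6 bp match
#'   exists. Errors if either flank is shorter than `tsd_max`.
#' @export
detect_tsd <- function(candidate, genome, tsd_min = 4L, tsd_max = 6L) {
  g <- .as_genome(genome)
  s <- g[[candidate$chrom]]
  if (candidate$start - tsd_max < 1L ||
      candidate$end + tsd_max > nchar(s))
    stop("insufficient flank for TSD detection (need ", tsd_max,
         " bp on each side)")
  for (len in rev(seq(tsd_min, tsd_max))) {
    left <- substr(s, candidate$start - len, candidate$start - 1L)
    right <- substr(s, candidate$end + 1L, candidate$end + len)
    if (left == right && !grepl("N", left, fixed = TRUE)) return(left)
  }
  NA_character_
}

# TSD-guided boundary snap: try outer-boundary shifts (dl on start, dr on
# end) within +/- snap bp. Pseudo-TSDs -- the true TSD plus one or two
# chance-matching bases eaten from the element edge or the flanking
# background -- are common, so candidates whose element termini are
# canonical (5'-TG ... CA-3') are preferred hierarchically (both termini
# >> one terminus >> none) before TSD length and shift distance decide.
# The shift is applied to both repeat copies (start and ltr3_start move by
# dl; end and ltr5_end by dr) so the two LTRs stay paired, and must keep
# the identity floor within 0.03.
.snap_tsd_one <- function(cand, s, params) {
  best <- list(score = -Inf)
  n <- nchar(s)
  snap <- params$tsd_snap
  for (dl in -snap:snap) {
    st <- cand$start + dl
    if (st - params$tsd_max < 1L) next
    for (dr in -snap:snap) {
      en <- cand$end + dr
      if (en + params$tsd_max > n || en <= st) next
      tsd <- NA_character_
      for (len in rev(seq(params$tsd_min, params$tsd_max))) {
        left <- substr(s, st - len, st - 1L)
        right <- substr(s, en + 1L, en + len)
        if (left == right && !grepl("N", left, fixed = TRUE)) {
          tsd <- left; break
        }
      }
      if (is.na(tsd)) next
      l5e <- cand$ltr5_end + dr
      l3s <- cand$ltr3_start + dl
      # Four terminus signals: each LTR copy starts TG and ends CA, so a
      # point mutation at one element edge is rescued by the paired
      # copy's intact motif. Lexicographic: termini tier, then smallest
      # shift, then longest TSD.
      tier <- (substr(s, st, st + 1L) == "TG") +
        (substr(s, en - 1L, en) == "CA") +
        (substr(s, l5e - 1L, l5e) == "CA") +
        (substr(s, l3s, l3s + 1L) == "TG")
      sc <- 1000 * tier - 10 * (abs(dl) + abs(dr)) + nchar(tsd)
      if (sc > best$score) {
        L5 <- l5e - st + 1L; L3 <- en - l3s + 1L
        if (L5 < params$min_ltr || L5 > params$max_ltr ||
            L3 < params$min_ltr || L3 > params$max_ltr || l5e >= l3s) next
        l5seq <- substr(s, st, l5e); l3seq <- substr(s, l3s, en)
        if (grepl("N", l5seq, fixed = TRUE) ||
            grepl("N", l3seq, fixed = TRUE)) next
        id <- .ltr_pair_identity(l5seq, l3seq)
        if (id >= params$min_ltr_identity - 0.03) {
          best <- list(score = sc, dl = dl, dr = dr, tsd = tsd,
                       identity = id)
        }
      }
    }
  }
  if (is.finite(best$score)) {
    cand$start <- cand$start + best$dl
    cand$ltr5_start <- cand$start
    cand$ltr3_start <- cand$ltr3_start + best$dl
    cand$end <- cand$end + best$dr
    cand$ltr3_end <- cand$end
    cand$ltr5_end <- cand$ltr5_end + best$dr
    cand$ltr_identity <- best$identity
    cand$tsd <- best$tsd
  }
  cand
}

#' Shared candidate post-processing: TSD snap, overlap resolution, sorting
#'
#' Applied identically to scanner output and to any independently
#' enumerated candidate set so the two are comparable. Overlapping
#' candidates are resolved by keeping the higher identity, then the longer
#' element, then the leftmost.
#'
#' @param cands Candidate data.frame (scanner schema).
#' @param genome Genome.
#' @param params [scan_params()].
#' @return Resolved candidate data.frame sorted by (chrom, start).
#' @export
finalize_candidates <- function(cands, genome, params = scan_params()) {
  if (nrow(cands) == 0) return(.empty_candidates())
  g <- .as_genome(genome)
  cands$tsd <- NA_character_
  out <- vector("list", length(unique(cands$chrom)))
  ci <- 0L
  for (chrom in unique(cands$chrom)) {
    ci <- ci + 1L
    s <- g[[chrom]]
    cc <- cands[cands$chrom == chrom, , drop = FALSE]
    cc <- cc[!duplicated(cc[, c("start", "end", "ltr5_end")]), ,
             drop = FALSE]
    for (i in seq_len(nrow(cc))) cc[i, ] <- .snap_tsd_one(cc[i, ], s, params)
    cc <- cc[!duplicated(cc[, c("start", "end")]), , drop = FALSE]
    ord <- order(-cc$ltr_identity, -(cc$end - cc$start), cc$start)
    cc <- cc[ord, , drop = FALSE]
    keep <- logical(nrow(cc))
    sel_ir <- IRanges::IRanges()
    for (i in seq_len(nrow(cc))) {
      ir <- IRanges::IRanges(cc$start[i], cc$end[i])
      if (length(sel_ir) == 0 ||
          !any(IRanges::overlapsAny(ir, sel_ir))) {
        keep[i] <- TRUE
        sel_ir <- c(sel_ir, ir)
      }
    }
    cc <- cc[keep, , drop = FALSE]
    out[[ci]] <- cc[order(cc$start), , drop = FALSE]
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Scan a genome for miniature LTR-element candidates
#'
#' Finds pairs of direct repeats (putative LTR pairs) via exact k-mer
#' seeding at a common spacing, X-drop extension with clean-terminus
#' trimming, identity filtering, TSD-guided boundary snapping, and overlap
#' resolution. Candidates whose LTRs contain N are dropped.
#'
#' @param genome Named character vector, `DNAString`/`DNAStringSet`, or a
#'   FASTA path readable by [Biostrings::readDNAStringSet()].
#' @param params [scan_params()].
#' @return Candidate data.frame, one row per element: `chrom`, `start`,
#'   `end` (element span), `ltr5_start/ltr5_end`, `ltr3_start/ltr3_end`,
#'   `ltr_identity`, `tsd` (NA when no exact TSD), sorted by (chrom, start).
#'   All coordinates 1-based inclusive.
#' @export
scan_genome <- function(genome, params = scan_params()) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  g <- .as_genome(genome)
  if (any(nchar(g) == 0)) stop("genome contains an empty sequence")
  res <- lapply(names(g), function(chrom) {
    cc <- .scan_chrom(g[[chrom]], params)
    if (nrow(cc)) cc$chrom <- chrom
    cc
  })
  res <- do.call(rbind, res[vapply(res, nrow, integer(1)) > 0])
  if (is.null(res)) return(.empty_candidates())
  finalize_candidates(res, g, params)
}

.scan_chrom <- function(s, params) {
  v <- .dna_codes(s)
  k <- params$seed_k
  codes <- .kmer_codes(v, k)
  dmin <- params$min_ltr + params$min_spacing
  dmax <- params$max_ltr + params$max_spacing
  pairs <- .self_seed_pairs(codes, dmin, dmax)
  empty <- cbind(.empty_candidates()[, -1L], chrom = character(0))
  if (nrow(pairs) == 0) return(.empty_candidates())
  data.table::setorder(pairs, d, p1)
  pairs[, chain := .chain_ids(p1, 30L), by = d]
  anchors <- pairs[, .(a = min(p1), b = max(p1) + params$seed_k - 1L),
                   by = .(d, chain)]
  n <- length(v)
  out <- vector("list", nrow(anchors))
  for (i in seq_len(nrow(anchors))) {
    D <- anchors$d[i]
    lo <- max(1L, anchors$a[i] - params$max_ltr - 10L)
    hi <- min(n - D, anchors$b[i] + params$max_ltr + 10L)
    if (hi < lo) next
    m <- !is.na(v[lo:hi]) & !is.na(v[(lo + D):(hi + D)]) &
      v[lo:hi] == v[(lo + D):(hi + D)]
    a <- anchors$a[i] - lo + 1L
    b <- anchors$b[i] - lo + 1L
    ext <- .xdrop_extend(m, a, b, x = 12, mis = -3)
    tr <- .clean_trim(m, ext[1L], ext[2L])
    if (is.null(tr)) next
    L <- tr[2L] - tr[1L] + 1L
    if (L < params$min_ltr || L > params$max_ltr) next
    spacing <- D - L
    if (spacing < params$min_spacing || spacing > params$max_spacing) next
    st <- lo + tr[1L] - 1L
    l5 <- substr(s, st, st + L - 1L)
    l3 <- substr(s, st + D, st + D + L - 1L)
    if (grepl("N", l5, fixed = TRUE) || grepl("N", l3, fixed = TRUE)) next
    id <- seq_identity(l5, l3)
    if (id < params$min_ltr_identity) next
    out[[i]] <- data.frame(
      start = st, end = st + D + L - 1L,
      ltr5_start = st, ltr5_end = st + L - 1L,
      ltr3_start = st + D, ltr3_end = st + D + L - 1L,
      ltr_identity = id, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) return(.empty_candidates())
  res$chrom <- "chr"
  res[, c("chrom", setdiff(names(res), "chrom"))]
}

#' Refine candidate boundaries by LTR-pair identity
#'
#' Coordinate-descent search over shifts of up to +/-15 bp for each of the
#' four LTR boundaries, maximizing LTR-pair identity. Identity ties are
#' broken by preferring LTRs with canonical 5'-TG...CA-3' termini, then the
#' longer LTR pair, then the leftmost start. Returns the candidate
#' unchanged when no shift improves it.
#'
#' @param candidate One-row candidate data.frame.
#' @param genome Genome.
#' @param max_shift Maximum boundary shift, bp.
#' @param params [scan_params()].
#' @return The refined one-row candidate data.frame.
#' @export
refine_boundaries <- function(candidate, genome, max_shift = 15L,
                              params = scan_params()) {
  g <- .as_genome(genome)
  s <- g[[candidate$chrom]]
  n <- nchar(s)
  state <- c(candidate$ltr5_start, candidate$ltr5_end,
             candidate$ltr3_start, candidate$ltr3_end)
  orig <- state
  eval_state <- function(st) {
    if (st[1] < 1 || st[4] > n || st[1] >= st[2] || st[3] >= st[4] ||
        st[2] >= st[3]) return(NULL)
    L5 <- st[2] - st[1] + 1L; L3 <- st[4] - st[3] + 1L
    if (L5 < params$min_ltr || L5 > params$max_ltr ||
        L3 < params$min_ltr || L3 > params$max_ltr) return(NULL)
    sp <- st[3] - st[2] - 1L
    if (sp < params$min_spacing || sp > params$max_spacing) return(NULL)
    l5 <- substr(s, st[1], st[2]); l3 <- substr(s, st[3], st[4])
    id <- .ltr_pair_identity(l5, l3)
    tgca <- (substr(l5, 1, 2) == "TG") + (substr(l5, L5 - 1, L5) == "CA") +
      (substr(l3, 1, 2) == "TG") + (substr(l3, L3 - 1, L3) == "CA")
    list(id = id, tgca = tgca, len = L5 + L3, start = st[1])
  }
  better <- function(a, b) {
    # TRUE if a beats b
    if (is.null(b)) return(TRUE)
    if (is.null(a)) return(FALSE)
    if (abs(a$id - b$id) > 1e-12) return(a$id > b$id)
    if (a$tgca != b$tgca) return(a$tgca > b$tgca)
    if (a$len != b$len) return(a$len > b$len)
    a$start < b$start
  }
  cur <- eval_state(state)
  for (pass in 1:3) {
    changed <- FALSE
    for (bi in 1:4) {
      best_sh <- 0L
      for (sh in setdiff(-max_shift:max_shift, 0L)) {
        if (abs(state[bi] + sh - orig[bi]) > max_shift) next
        st2 <- state; st2[bi] <- state[bi] + sh
        cand2 <- eval_state(st2)
        if (better(cand2, cur)) { cur <- cand2; best_sh <- sh }
      }
      if (best_sh != 0L) { state[bi] <- state[bi] + best_sh; changed <- TRUE }
    }
    if (!changed) break
  }
  if (is.null(cur)) return(candidate)
  candidate$ltr5_start <- state[1]; candidate$ltr5_end <- state[2]
  candidate$ltr3_start <- state[3]; candidate$ltr3_end <- state[4]
  candidate$start <- state[1]; candidate$end <- state[4]
  candidate$ltr_identity <- cur$id
  candidate
}

#' Export scanner candidates as GFF3
#'
#' Writes `LTR_retrotransposon`, two `long_terminal_repeat` and (when a TSD
#' was detected) two `target_site_duplication` features per candidate.
#'
#' @param cands Candidate data.frame from [scan_genome()].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_candidates_gff3 <- function(cands, path) {
  grs <- list()
  for (i in seq_len(nrow(cands))) {
    cc <- cands[i, ]
    id <- sprintf("cand%04d", i)
    feats <- data.frame(
      type = c("LTR_retrotransposon", "long_terminal_repeat",
               "long_terminal_repeat"),
      start = c(cc$start, cc$ltr5_start, cc$ltr3_start),
      end = c(cc$end, cc$ltr5_end, cc$ltr3_end))
    if (!is.na(cc$tsd)) {
      tl <- nchar(cc$tsd)
      feats <- rbind(feats, data.frame(
        type = rep("target_site_duplication", 2),
        start = c(cc$start - tl, cc$end + 1L),
        end = c(cc$start - 1L, cc$end + tl)))
    }
    gr <- GenomicRanges::GRanges(cc$chrom,
                                 IRanges::IRanges(feats$start, feats$end))
    gr$type <- feats$type
    gr$ID <- paste0(id, "_", seq_along(gr))
    gr$Parent <- c(NA, rep(paste0(id, "_1"), length(gr) - 1L))
    grs[[i]] <- gr
  }
  gr <- if (length(grs)) do.call(c, grs) else GenomicRanges::GRanges()
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}
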