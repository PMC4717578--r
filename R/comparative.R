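## Comparative analyses: larger autonomous "partner" retroelements of
## miniature elements, internal-deletion breakpoints with duplicated
## internal sequences, coding autonomy, and insertion polymorphisms
## between two assemblies.

#' Find larger partner retroelements of a miniature element
#'
#' Searches a genome for LTR pairs matching the element's LTR at >=
#' `min_ltr_identity` whose span is >= `min_partner_len`, requiring that
#' the putative partner's internal region also shares at least one
#' aligned segment >= 100 bp with the element's internal region.
#'
#' @param trim_consensus Element consensus (character scalar).
#' @param ltr_length LTR length on the consensus.
#' @param genome Genome.
#' @param min_ltr_identity LTR identity floor (default 0.79, the lower
#'   end of observed partner-element LTR identity).
#' @param min_partner_len Minimum partner span, bp (default 3000).
#' @param max_partner_len Maximum partner span, bp (default 20000).
#' @return data.frame: chrom, start, end, ltr5_start/end, ltr3_start/end,
#'   ltr_identity_to_trim, internal_shared_bp.
#' @export
find_partners <- function(trim_consensus, ltr_length, genome,
                          min_ltr_identity = 0.79,
                          min_partner_len = 3000L,
                          max_partner_len = 20000L) {
  stopifnot(ltr_length >= 30, 2 * ltr_length < nchar(trim_consensus))
  ltr <- substr(trim_consensus, 1L, ltr_length)
  internal <- substr(trim_consensus, ltr_length + 1L,
                     nchar(trim_consensus) - ltr_length)
  g <- .as_genome(genome)
  out <- list()
  for (chrom in names(g)) {
    s <- g[[chrom]]
    h <- .seed_hits(ltr, s, min_len = 25L)
    h <- h[h$identity >= min_ltr_identity &
             h$length >= 0.7 * ltr_length, , drop = FALSE]
    if (nrow(h) < 2) next
    h <- h[order(h$sstart), , drop = FALSE]
    for (i in seq_len(nrow(h) - 1)) {
      for (j in (i + 1):nrow(h)) {
        span <- h$send[j] - h$sstart[i] + 1L
        if (span > max_partner_len) break
        if (span < min_partner_len) next
        inner <- substr(s, h$send[i] + 1L, h$sstart[j] - 1L)
        if (nchar(inner) < 100) next
        ih <- .seed_hits(internal, inner, min_len = 50L)
        ih <- ih[ih$length >= 100 & ih$identity >= 0.75, , drop = FALSE]
        if (nrow(ih) == 0) next
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = h$sstart[i], end = h$send[j],
          ltr5_start = h$sstart[i], ltr5_end = h$send[i],
          ltr3_start = h$sstart[j], ltr3_end = h$send[j],
          ltr_identity_to_trim = (h$identity[i] + h$identity[j]) / 2,
          internal_shared_bp = max(ih$length))
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), ltr5_start = integer(0),
                      ltr5_end = integer(0), ltr3_start = integer(0),
                      ltr3_end = integer(0),
                      ltr_identity_to_trim = numeric(0),
                      internal_shared_bp = integer(0)))
  # Nested or chained pairings (e.g. a partner's 5' LTR paired with a
  # nearby related element's 3' LTR) span more than the element itself:
  # prefer the tightest valid pairing, then the better internal support.
  res <- res[order(res$end - res$start, -res$internal_shared_bp), ,
             drop = FALSE]
  keep <- logical(nrow(res))
  sel <- GenomicRanges::GRanges()
  for (i in seq_len(nrow(res))) {
    gr <- GenomicRanges::GRanges(res$chrom[i],
                                 IRanges::IRanges(res$start[i], res$end[i]))
    if (length(sel) == 0 || !any(GenomicRanges::countOverlaps(gr, sel))) {
      keep[i] <- TRUE; sel <- c(sel, gr)
    }
  }
  res <- res[keep, , drop = FALSE]
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Locate the deletion breakpoint relating a miniature element to its
#' partner
#'
#' Decomposes the element into a 5' block aligning to the partner's 5'
#' region and a 3' block aligning to its 3' region (each at >= 85\%
#' identity); the junction is the breakpoint. A duplicated internal
#' sequence is reported when near-identical copies (>= 90\% identity,
#' >= 8 bp) flank the deleted partner segment.
#'
#' @param trim Element sequence (character scalar).
#' @param partner Partner sequence (character scalar).
#' @param min_block_identity Per-block identity floor (default 0.85).
#' @param dup_min_len,dup_max_len Duplicated-sequence length bounds
#'   (defaults 8, 60).
#' @param dup_min_identity Identity floor between the two copies
#'   (default 0.90).
#' @return List: `found` (logical), and when TRUE: `breakpoint` (bp on
#'   the partner, end of the 5' block), `trim_breakpoint`, `deleted`
#'   (partner interval c(from,to)), `dup_seq`, `dup_len`,
#'   `dup_identity`, `dup_copy_5p`, `dup_copy_3p` (partner intervals).
#'   `found = FALSE` with `reason` otherwise (e.g. no internal deletion).
#' @export
locate_breakpoint <- function(trim, partner, min_block_identity = 0.85,
                              dup_min_len = 8L, dup_max_len = 60L,
                              dup_min_identity = 0.90) {
  h <- .seed_hits(trim, partner, min_len = 25L)
  if (nrow(h) == 0) return(list(found = FALSE, reason = "no homology"))
  h <- h[h$identity >= min_block_identity, , drop = FALSE]
  if (nrow(h) == 0) return(list(found = FALSE, reason = "no homology"))
  # 5' block: hit containing the trim start; 3' block: hit containing
  # the trim end, on a larger partner offset. The diagonal difference is
  # the deletion length, exact under a substitution-only divergence
  # model even when the block ends are fuzzy.
  h$diag <- h$sstart - h$qstart
  h5 <- h[h$qstart <= 30, , drop = FALSE]
  h3 <- h[h$qend >= nchar(trim) - 30, , drop = FALSE]
  if (nrow(h5) == 0 || nrow(h3) == 0)
    return(list(found = FALSE, reason = "no two-block decomposition"))
  h5 <- h5[which.max(h5$length), ]
  h3 <- h3[which.max(h3$length), ]
  delta <- h3$diag - h5$diag
  if (delta < 1)
    return(list(found = FALSE, reason = "no internal deletion"))
  # Split-point scan: t maximizing matches(trim[1..t], partner[1..t]) +
  # matches(trim[t+1..], partner[t+1+delta..]). Within the duplicated
  # internal sequence both sides match, so the objective plateaus across
  # it; the rightmost maximum is the breakpoint (the copy sits
  # immediately 5' of it, matching the published convention).
  Tn <- nchar(trim)
  off5 <- h5$diag
  vt <- .dna_codes(trim); vp <- .dna_codes(partner)
  idx5 <- seq_len(Tn) + off5
  ok5 <- idx5 >= 1 & idx5 <= length(vp)
  v5 <- ok5 & !is.na(vt) & vt == vp[pmax(1L, pmin(length(vp), idx5))]
  idx3 <- seq_len(Tn) + off5 + delta
  ok3 <- idx3 >= 1 & idx3 <= length(vp)
  v3 <- ok3 & !is.na(vt) & vt == vp[pmax(1L, pmin(length(vp), idx3))]
  C5 <- c(0, cumsum(v5)); C3 <- c(0, cumsum(v3))
  tot <- C5[seq_len(Tn + 1)] + (C3[Tn + 1] - C3[seq_len(Tn + 1)])
  t_star <- max(which(tot == max(tot))) - 1L   # trim coordinate
  id5 <- if (t_star > 0) C5[t_star + 1] / t_star else 1
  id3 <- if (t_star < Tn) (C3[Tn + 1] - C3[t_star + 1]) / (Tn - t_star)
         else 1
  if (id5 < min_block_identity || id3 < min_block_identity)
    return(list(found = FALSE, reason = "no two-block decomposition"))
  p2 <- t_star + off5            # breakpoint on partner
  p3 <- t_star + off5 + delta + 1L  # start of 3' block on partner
  # Duplicated internal sequence: both copies are right-anchored at the
  # junctions (one ends at the breakpoint p2, the other just 5' of the
  # 3' block at p3 - 1). Among lengths meeting the identity floor the
  # alignment score matches - 3*mismatches decides (ties to the longer
  # copy): extending past the duplication adds unrelated columns that
  # the penalty rejects, while interior divergence between the copies
  # does not truncate them.
  best <- NULL
  for (L in seq(dup_max_len, dup_min_len)) {
    if (p2 - L + 1L < 1L || p3 - L < 1L) next
    copy5 <- substr(partner, p2 - L + 1L, p2)
    copy3 <- substr(partner, p3 - L, p3 - 1L)
    id <- seq_identity(copy5, copy3)
    if (!is.na(id) && id >= dup_min_identity) {
      sc <- id * L - 3 * (1 - id) * L
      if (is.null(best) || sc > best$sc) best <- list(L = L, id = id,
                                                      sc = sc)
    }
  }
  out <- list(found = TRUE, breakpoint = p2,
              trim_breakpoint = t_star,
              deleted = c(p2 + 1L, p3 - 1L),
              dup_seq = NULL, dup_len = 0L, dup_identity = NA_real_)
  if (!is.null(best)) {
    out$dup_seq <- substr(partner, p2 - best$L + 1L, p2)
    out$dup_len <- best$L
    out$dup_identity <- best$id
    out$dup_copy_5p <- c(p2 - best$L + 1L, p2)
    out$dup_copy_3p <- c(p3 - best$L, p3 - 1L)
  }
  out
}

#' Classify coding autonomy of a partner element
#'
#' Six-frame ORF scan (stop-free stretches); `putative_autonomous` iff
#' the longest ORF is >= `min_orf_aa` amino acids *and* the element has
#' retrotransposase coding capacity against the supplied protein set.
#' The 900-aa floor separates full-length retrotransposases (roughly
#' 1,200-1,600 aa) from truncated ones (roughly 400 aa).
#'
#' @param partner_seq Partner DNA sequence.
#' @param proteins Retroelement protein set.
#' @param min_orf_aa ORF floor in amino acids (default 900).
#' @return List: `autonomy` ("putative_autonomous"/"non_autonomous"),
#'   `longest_orf_aa`, `coding`.
#' @export
classify_autonomy <- function(partner_seq, proteins,
                              min_orf_aa = 900L) {
  orfs <- .six_frame_orfs(partner_seq, min_aa = 50L)
  longest <- if (length(orfs)) max(nchar(orfs)) else 0L
  coding <- coding_capacity(partner_seq, proteins)$coding
  list(autonomy = if (longest >= min_orf_aa && coding)
    "putative_autonomous" else "non_autonomous",
    longest_orf_aa = as.integer(longest), coding = coding)
}

#' Call insertion polymorphisms between two assemblies
#'
#' For each annotated element in genome A, maps its two `flank`-bp flanks
#' onto genome B. The element is polymorphic iff both flanks align
#' (>= `min_identity` over >= 60\% of the flank) contiguously -- inner
#' ends separated by at most `tsd_max` bp of overlap (the single
#' target-site copy at the empty site) or a gap of at most 2 bp -- with
#' no element between them. Flanks mapping to multiple near-best loci
#' are skipped as ambiguous.
#'
#' @param genome_a,genome_b The two assemblies.
#' @param annotations Element table on genome A (chrom/start/end, plus
#'   optional element_id).
#' @param flank Flank width, bp (default 500).
#' @param min_identity Flank alignment identity floor (default 0.90).
#' @param tsd_max Maximum empty-site target-site length (default 6).
#' @return data.frame: element_id, chrom, start, end, status
#'   ("polymorphic", "shared", "ambiguous", "unmapped"), tsd (empty-site
#'   copy for polymorphic calls), b_chrom, b_pos.
#' @export
call_polymorphic_insertions <- function(genome_a, genome_b, annotations,
                                        flank = 500L, min_identity = 0.90,
                                        tsd_max = 6L) {
  ga <- .as_genome(genome_a)
  gb <- .as_genome(genome_b)
  if (!"element_id" %in% names(annotations) && nrow(annotations) > 0)
    annotations$element_id <- sprintf("el%04d",
                                      seq_len(nrow(annotations)))
  map_flank <- function(fseq) {
    best <- NULL
    for (chrom in names(gb)) {
      h <- .best_hits(fseq, gb[[chrom]])
      h <- h[h$identity >= min_identity &
               h$length >= 0.6 * nchar(fseq), , drop = FALSE]
      if (nrow(h) == 0) next
      h$chrom <- chrom
      best <- rbind(best, utils::head(h, 2))
    }
    if (is.null(best) || nrow(best) == 0) return(NULL)
    best <- best[order(-best$score), , drop = FALSE]
    if (nrow(best) >= 2 && best$score[2] >= 0.9 * best$score[1])
      return("ambiguous")
    best[1, ]
  }
  out <- lapply(seq_len(nrow(annotations)), function(i) {
    a <- annotations[i, ]
    res <- data.frame(element_id = a$element_id, chrom = a$chrom,
                      start = a$start, end = a$end, status = "unmapped",
                      tsd = NA_character_, b_chrom = NA_character_,
                      b_pos = NA_integer_)
    s <- ga[[a$chrom]]
    if (a$start - flank < 1L || a$end + flank > nchar(s)) return(res)
    left <- substr(s, a$start - flank, a$start - 1L)
    right <- substr(s, a$end + 1L, a$end + flank)
    hl <- map_flank(left); hr <- map_flank(right)
    if (is.null(hl) || is.null(hr)) return(res)
    if (identical(hl, "ambiguous") || identical(hr, "ambiguous")) {
      res$status <- "ambiguous"; return(res)
    }
    if (hl$chrom != hr$chrom) return(res)
    # project flank inner edges onto B (gapless hits: constant offset)
    left_inner <- hl$send + (nchar(left) - hl$qend)
    right_inner <- hr$sstart - (hr$qstart - 1L)
    gap <- right_inner - left_inner - 1L
    res$b_chrom <- hl$chrom
    res$b_pos <- left_inner
    if (gap >= -tsd_max && gap <= 2L) {
      res$status <- "polymorphic"
      if (gap < 0) {
        # overlap = single target-site copy retained at the empty site
        res$tsd <- substr(gb[[hl$chrom]], right_inner, left_inner)
      }
    } else if (gap > (a$end - a$start + 1L) * 0.5) {
      res$status <- "shared"
    }
    res
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
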