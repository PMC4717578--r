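## Library-based genome annotation: local alignments of subfamily
## consensuses against both strands, score-filtered in the masking-score
## convention (match +1 / mismatch -1, gap open -5 / extend -1, scaled
## x10; the engine is gapless so gap penalties never fire on
## substitution-divergent copies), completeness classification and
## Table-1-style summaries.

#' Annotate a genome with a consensus library
#'
#' Finds local alignments of each library consensus on both strands,
#' keeps hits with score >= `min_score` and length >= `min_len`, resolves
#' overlapping hits from different subfamilies by higher score, then
#' longer, then leftmost, and classifies each hit's completeness.
#'
#' @param genome Genome (see [scan_genome()]).
#' @param library data.frame with `subfamily_id`, `consensus` and
#'   optionally `ltr_length` (used for completeness calls).
#' @param min_score Score cutoff (default 250, i.e. 25 net matches at the
#'   x10 scale).
#' @param min_len Minimum hit length, bp (default 50).
#' @return data.frame of hits: chrom, start, end, strand, subfamily_id,
#'   score, qstart, qend (consensus coords, + orientation), identity,
#'   completeness in complete/fragmented/solo_ltr.
#' @export
mask_genome <- function(genome, library, min_score = 250, min_len = 50L) {
  if (is.null(library) || nrow(library) == 0)
    stop("empty consensus library")
  g <- .as_genome(genome)
  out <- list()
  for (chrom in names(g)) {
    s <- g[[chrom]]
    for (li in seq_len(nrow(library))) {
      cons <- library$consensus[li]
      for (strand in c("+", "-")) {
        q <- if (strand == "+") cons else revcomp(cons)
        h <- .seed_hits(q, s, min_len = min_len)
        if (nrow(h) == 0) next
        h <- h[h$score >= min_score & h$length >= min_len, , drop = FALSE]
        if (nrow(h) == 0) next
        qs <- h$qstart; qe <- h$qend
        if (strand == "-") {
          qs <- nchar(cons) - h$qend + 1L
          qe <- nchar(cons) - h$qstart + 1L
        }
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = h$sstart, end = h$send, strand = strand,
          subfamily_id = library$subfamily_id[li], score = h$score,
          qstart = qs, qend = qe, identity = h$identity)
      }
    }
  }
  hits <- do.call(rbind, out)
  if (is.null(hits))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      subfamily_id = character(0), score = numeric(0),
                      qstart = integer(0), qend = integer(0),
                      identity = numeric(0), completeness = character(0)))
  hits <- .resolve_hits(hits)
  hits$completeness <- vapply(seq_len(nrow(hits)), function(i) {
    li <- match(hits$subfamily_id[i], library$subfamily_id)
    classify_completeness(hits[i, ], library$consensus[li],
                          library$ltr_length[li])
  }, character(1))
  rownames(hits) <- NULL
  hits
}

# Greedy overlap resolution across subfamilies: score desc, length desc,
# leftmost. Same-subfamily overlaps collapse too (tilings over tandem
# arrays are recovered separately by annotate_segments()).
.resolve_hits <- function(hits) {
  hits <- hits[order(hits$chrom, -hits$score,
                     -(hits$end - hits$start), hits$start), , drop = FALSE]
  keep <- logical(nrow(hits))
  for (chrom in unique(hits$chrom)) {
    idx <- which(hits$chrom == chrom)
    sel <- IRanges::IRanges()
    for (i in idx) {
      ir <- IRanges::IRanges(hits$start[i], hits$end[i])
      if (length(sel) == 0 || !any(IRanges::overlapsAny(ir, sel))) {
        keep[i] <- TRUE
        sel <- c(sel, ir)
      }
    }
  }
  hits <- hits[keep, , drop = FALSE]
  hits[order(hits$chrom, hits$start), , drop = FALSE]
}

#' Classify a hit as complete, fragmented or solo LTR
#'
#' `complete` iff the alignment covers >= `min_cov` of the consensus and
#' includes both terminal 20-bp consensus ends; `solo_ltr` iff the
#' alignment is confined to one LTR interval of the consensus and covers
#' >= 80\% of that LTR; otherwise `fragmented`. The >=80\%-plus-both-ends
#' rule is this package's operational definition (exposed as parameters).
#'
#' @param hit One hit row (needs qstart/qend).
#' @param consensus Consensus sequence the hit was aligned to.
#' @param ltr_length LTR length on the consensus (NA disables the
#'   solo-LTR call).
#' @param min_cov Consensus coverage required for `complete`
#'   (default 0.8).
#' @return One of "complete", "fragmented", "solo_ltr".
#' @export
classify_completeness <- function(hit, consensus, ltr_length = NA,
                                  min_cov = 0.8) {
  L <- nchar(consensus)
  span <- hit$qend - hit$qstart + 1
  if (span >= min_cov * L && hit$qstart <= 20 && hit$qend >= L - 19)
    return("complete")
  if (!is.na(ltr_length) && ltr_length > 0) {
    in5 <- hit$qend <= ltr_length
    in3 <- hit$qstart >= L - ltr_length + 1
    if ((in5 || in3) && span >= 0.8 * ltr_length) return("solo_ltr")
  }
  "fragmented"
}

#' Summarize masking results per subfamily and in total
#'
#' Copy numbers by completeness and masked bp computed on the union of
#' hit intervals (overlap counted once), with the masked genome fraction
#' as a percentage.
#'
#' @param hits Hit data.frame from [mask_genome()].
#' @param genome_bp Genome length in bp.
#' @return data.frame with one row per subfamily plus a `total` row:
#'   subfamily_id, copy_number_total, copy_number_complete,
#'   copy_number_solo, masked_bp, fraction_percent.
#' @export
summarize_masking <- function(hits, genome_bp) {
  one <- function(h, id) {
    masked <- if (nrow(h) == 0) 0L else
      sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(h$start, h$end))))
    data.frame(subfamily_id = id,
               copy_number_total = nrow(h),
               copy_number_complete = sum(h$completeness == "complete"),
               copy_number_solo = sum(h$completeness == "solo_ltr"),
               masked_bp = masked,
               fraction_percent = 100 * masked / genome_bp)
  }
  per <- do.call(rbind, lapply(split(hits, hits$subfamily_id),
                               function(h) one(h, h$subfamily_id[1])))
  rbind(per, one(hits, "total"))
}

#' Segment-level (LTR vs internal) annotation for tandem-array analysis
#'
#' Masks the genome separately with a subfamily's LTR consensus and
#' internal consensus so that tandem arrays appear as runs of alternating
#' L and I segments (overlaps are resolved within each segment kind only).
#'
#' @param genome Genome.
#' @param consensus Full element consensus.
#' @param ltr_length LTR length on the consensus.
#' @param min_score Score cutoff per segment (default 150; segments are
#'   shorter than whole elements).
#' @param min_len Minimum segment hit length (default 25).
#' @return data.frame: chrom, start, end, strand, kind ("L"/"I"), score,
#'   identity, sorted by position.
#' @export
annotate_segments <- function(genome, consensus, ltr_length,
                              min_score = 150, min_len = 25L) {
  stopifnot(ltr_length > 0, 2 * ltr_length < nchar(consensus))
  ltr <- substr(consensus, 1L, ltr_length)
  internal <- substr(consensus, ltr_length + 1L,
                     nchar(consensus) - ltr_length)
  g <- .as_genome(genome)
  out <- list()
  for (chrom in names(g)) {
    s <- g[[chrom]]
    for (kind in c("L", "I")) {
      q0 <- if (kind == "L") ltr else internal
      for (strand in c("+", "-")) {
        q <- if (strand == "+") q0 else revcomp(q0)
        h <- .seed_hits(q, s, min_len = min_len)
        h <- h[h$score >= min_score & h$length >= 0.6 * nchar(q0), ,
               drop = FALSE]
        if (nrow(h) == 0) next
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = h$sstart, end = h$send, strand = strand,
          kind = kind, score = h$score, identity = h$identity)
      }
    }
  }
  segs <- do.call(rbind, out)
  if (is.null(segs))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      kind = character(0), score = numeric(0),
                      identity = numeric(0)))
  # resolve overlaps within each kind
  segs <- do.call(rbind, lapply(split(segs, segs$kind), .resolve_hits))
  segs <- segs[order(segs$chrom, segs$start), , drop = FALSE]
  rownames(segs) <- NULL
  segs
}

#' Write masking hits as GFF3
#' @param hits Hits from [mask_genome()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_hits_gff3 <- function(hits, path) {
  gr <- GenomicRanges::GRanges(
    hits$chrom, IRanges::IRanges(hits$start, hits$end),
    strand = hits$strand)
  gr$type <- "repeat_region"
  gr$ID <- sprintf("hit%04d", seq_len(nrow(hits)))
  gr$Name <- hits$subfamily_id
  gr$completeness <- hits$completeness
  gr$score <- hits$score
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}
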