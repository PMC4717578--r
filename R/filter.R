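## The three TRIM-defining criteria applied to scanner candidates:
## (1) element < 1,500 bp and gap-free (no N);
## (2) at least two complete copies flanked by different TSDs, or one
##     complete copy plus one solo LTR, within the genome;
## (3) no retrotransposase coding capacity.

.cand_seq <- function(cand, g) {
  substr(g[[cand$chrom]], cand$start, cand$end)
}

#' Find solo LTRs of a consensus LTR in a genome
#'
#' Reports genomic matches to the LTR alone (identity >= `min_identity`
#' over >= 80\% of the consensus length) that are not part of any candidate
#' element's LTR pair. Each hit carries its own flanking TSD when one
#' exists.
#'
#' @param genome Genome (see [scan_genome()]).
#' @param ltr_consensus LTR sequence (character scalar), 30-500 bp.
#' @param min_identity Identity floor (default 0.80, by analogy with the
#'   subfamily clustering rule).
#' @param candidates Optional candidate data.frame whose LTR intervals are
#'   excluded.
#' @return data.frame: chrom, start, end, identity, tsd (NA if none).
#' @export
find_solo_ltrs <- function(genome, ltr_consensus, min_identity = 0.80,
                           candidates = NULL) {
  stopifnot(nchar(ltr_consensus) >= 30, nchar(ltr_consensus) <= 500)
  g <- .as_genome(genome)
  L <- nchar(ltr_consensus)
  out <- list()
  for (chrom in names(g)) {
    h <- .seed_hits(ltr_consensus, g[[chrom]], min_len = 25L)
    if (nrow(h) == 0) next
    h <- h[h$identity >= min_identity & h$length >= 0.8 * L, , drop = FALSE]
    if (nrow(h) == 0) next
    # collapse overlapping hits, best first
    h <- h[order(-h$score), , drop = FALSE]
    keep <- !logical(nrow(h))
    ir <- IRanges::IRanges(h$sstart, h$send)
    ov <- IRanges::findOverlaps(ir, ir)
    ov <- ov[S4Vectors::queryHits(ov) < S4Vectors::subjectHits(ov)]
    for (i in seq_along(ov))
      keep[max(S4Vectors::queryHits(ov)[i],
               S4Vectors::subjectHits(ov)[i])] <- FALSE
    h <- h[keep, , drop = FALSE]
    if (!is.null(candidates)) {
      cc <- candidates[candidates$chrom == chrom, , drop = FALSE]
      if (nrow(cc)) {
        ltr_ir <- c(IRanges::IRanges(cc$ltr5_start, cc$ltr5_end),
                    IRanges::IRanges(cc$ltr3_start, cc$ltr3_end))
        h <- h[!IRanges::overlapsAny(IRanges::IRanges(h$sstart, h$send),
                                     ltr_ir), , drop = FALSE]
      }
    }
    if (nrow(h) == 0) next
    tsd <- vapply(seq_len(nrow(h)), function(i) {
      cand <- data.frame(chrom = chrom, start = h$sstart[i], end = h$send[i])
      if (h$sstart[i] <= 6L || h$send[i] + 6L > nchar(g[[chrom]]))
        return(NA_character_)
      detect_tsd(cand, g)
    }, character(1))
    out[[chrom]] <- data.frame(chrom = chrom, start = h$sstart,
                               end = h$send, identity = h$identity,
                               tsd = tsd)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), identity = numeric(0),
                      tsd = character(0))
  rownames(res) <- NULL
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Test an element for retrotransposase coding capacity
#'
#' True iff any six-frame translation segment of >= 100 aa (stop-free)
#' aligns locally to a retroelement protein at >= `min_identity` over
#' >= `min_aa` aligned residues.
#'
#' @param element_seq Element DNA (character scalar).
#' @param proteins Character vector of protein sequences (the
#'   retrotransposase set); may be empty.
#' @param min_identity Identity floor over the aligned block (default 0.5).
#' @param min_aa Minimum aligned residues (default 80).
#' @return List: `coding` (logical), `best` (best-hit data.frame or NULL).
#' @export
coding_capacity <- function(element_seq, proteins, min_identity = 0.50,
                            min_aa = 80L) {
  if (length(proteins) == 0 || nchar(element_seq) < 300)
    return(list(coding = FALSE, best = NULL))
  orfs <- .six_frame_orfs(element_seq, min_aa = 100L)
  if (length(orfs) == 0) return(list(coding = FALSE, best = NULL))
  best <- NULL
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  for (orf in orfs) {
    for (pi in seq_along(proteins)) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(orf), Biostrings::AAString(proteins[pi]),
        type = "local", substitutionMatrix = B62,
        gapOpening = 10, gapExtension = 1)
      ncol <- nchar(as.character(Biostrings::alignedPattern(aln)))
      if (ncol >= min_aa &&
          Biostrings::nmatch(aln) / ncol >= min_identity) {
        hit <- data.frame(protein = pi, aligned_aa = ncol,
                          identity = Biostrings::nmatch(aln) / ncol,
                          score = Biostrings::score(aln))
        if (is.null(best) || hit$score > best$score) best <- hit
      }
    }
  }
  list(coding = !is.null(best), best = best)
}

# Stop-free translation segments >= min_aa from all six frames.
.six_frame_orfs <- function(s, min_aa = 100L) {
  dna <- Biostrings::DNAString(gsub("N", "A", s))
  orfs <- character(0)
  for (sq in list(dna, Biostrings::reverseComplement(dna))) {
    for (off in 0:2) {
      len <- floor((length(sq) - off) / 3) * 3
      if (len < 3 * min_aa) next
      aa <- suppressWarnings(as.character(
        Biostrings::translate(Biostrings::subseq(sq, off + 1L, off + len),
                              if.fuzzy.codon = "X")))
      segs <- strsplit(aa, "*", fixed = TRUE)[[1]]
      orfs <- c(orfs, segs[nchar(segs) >= min_aa])
    }
  }
  orfs
}

# Provisional 80/80 single-linkage clusters over candidate sequences;
# returns an integer cluster id per candidate.
.provisional_clusters <- function(seqs) {
  n <- length(seqs)
  if (n == 0) return(integer(0))
  if (n == 1) return(1L)
  edges <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ci <- pairwise_coverage_identity(seqs[i], seqs[j])
      if (!is.na(ci$identity) && ci$identity >= 0.80 &&
          ci$coverage >= 0.80)
        edges[[length(edges) + 1L]] <- c(i, j)
    }
  }
  gr <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges))
    gr <- igraph::add_edges(gr, unlist(edges))
  as.integer(igraph::components(gr)$membership)
}

#' Apply the three TRIM-defining criteria
#'
#' Retains a candidate iff (1) its span is under `max_len` bp with no N;
#' (2) its provisional subfamily has at least two complete copies flanked
#' by *different* TSD sequences, or at least one complete copy plus one
#' solo LTR of the subfamily's LTR; and (3) it shows no retrotransposase
#' coding capacity. Copies with identical TSDs are conservatively counted
#' as one (guards against segmental duplications).
#'
#' @param candidates Candidate data.frame from [scan_genome()].
#' @param genome Genome.
#' @param proteins Retroelement protein set (character vector, possibly
#'   empty).
#' @param max_len Maximum element length, exclusive (default 1500).
#' @return List: `elements` (retained rows + `subfamily_id`,
#'   `copy_support`), `rejected` (rows + `reason`), such that the two
#'   partition the input.
#' @export
apply_trim_criteria <- function(candidates, genome, proteins = character(0),
                                max_len = 1500L) {
  g <- .as_genome(genome)
  n <- nrow(candidates)
  if (n == 0)
    return(list(elements = cbind(candidates,
                                 data.frame(subfamily_id = character(0),
                                            copy_support = character(0))),
                rejected = cbind(candidates,
                                 data.frame(reason = character(0)))))
  seqs <- vapply(seq_len(n), function(i) .cand_seq(candidates[i, ], g),
                 character(1))
  reason <- rep(NA_character_, n)

  len_ok <- (nchar(seqs) < max_len)
  has_n <- grepl("N", seqs, fixed = TRUE)
  reason[!len_ok] <- "size_ge_1500"
  reason[is.na(reason) & has_n] <- "contains_gap"
  reason[is.na(reason) & is.na(candidates$tsd)] <- "no_tsd"

  cl <- .provisional_clusters(seqs)
  candidates$subfamily_id <- sprintf("PC%02d", cl)
  copy_support <- rep(NA_character_, n)
  for (k in unique(cl)) {
    idx <- which(cl == k & is.na(reason))
    if (length(idx) == 0) next
    tsds <- candidates$tsd[idx]
    multi <- length(unique(tsds[!is.na(tsds)])) >= 2
    if (multi) {
      copy_support[idx] <- "multi_complete"
    } else {
      # one complete copy + a solo LTR of this subfamily's LTR?
      rep_i <- idx[1L]
      ltr <- substr(seqs[rep_i], 1L,
                    candidates$ltr5_end[rep_i] -
                      candidates$ltr5_start[rep_i] + 1L)
      solos <- find_solo_ltrs(g, ltr, candidates = candidates)
      if (nrow(solos) > 0) {
        copy_support[idx] <- "complete_plus_solo"
      } else {
        reason[idx] <- "single_copy"
      }
    }
  }
  for (i in which(is.na(reason))) {
    if (coding_capacity(seqs[i], proteins)$coding)
      reason[i] <- "retrotransposase"
  }
  keep <- is.na(reason)
  elements <- candidates[keep, , drop = FALSE]
  elements$copy_support <- copy_support[keep]
  rejected <- candidates[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  rownames(elements) <- NULL; rownames(rejected) <- NULL
  list(elements = elements, rejected = rejected)
}
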