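## Bisulfite methylation and small-RNA profiling of elements: binomial
## methylation calls, weighted levels, metaprofiles, 21/24-nt abundance,
## family Type I/II/III classification and gene-body methylation classes.

#' Cytosine positions and contexts of a genome
#'
#' Lists every cytosine on both strands with its context (CG, CHG, CHH;
#' H = A, C or T). Positions too close to a sequence end for context
#' resolution are dropped.
#'
#' @param genome Genome.
#' @return data.frame: chrom, pos (1-based), strand, context.
#' @export
cytosine_contexts <- function(genome) {
  g <- .as_genome(genome)
  out <- list()
  for (chrom in names(g)) {
    v <- strsplit(g[[chrom]], "")[[1]]
    n <- length(v)
    if (n < 3) next
    # plus strand: C at i, context from i+1, i+2
    ip <- which(v == "C")
    ip <- ip[ip <= n - 2L]
    ctx_p <- ifelse(v[ip + 1L] == "G", "CG",
                    ifelse(v[ip + 2L] == "G", "CHG", "CHH"))
    # minus strand: G at i, context from i-1, i-2 (complemented)
    im <- which(v == "G")
    im <- im[im >= 3L]
    ctx_m <- ifelse(v[im - 1L] == "C", "CG",
                    ifelse(v[im - 2L] == "C", "CHG", "CHH"))
    out[[chrom]] <- data.frame(
      chrom = chrom, pos = c(ip, im),
      strand = rep(c("+", "-"), c(length(ip), length(im))),
      context = c(ctx_p, ctx_m))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Simulate a per-cytosine bisulfite count table
#'
#' Draws Poisson coverage and binomial methylated counts at every
#' cytosine. Rates depend on element bodies and flanks according to each
#' subfamily's epigenetic type: Type I has high methylation in all three
#' contexts in the body with low flanks (sharp borders); Type II has high
#' CG+CHG in body *and* flanks (no borders, CHH low); Type III has high
#' CG only. Background (and all other contexts) sits at `low`.
#'
#' @param genome Genome.
#' @param elements data.frame with chrom/start/end/subfamily_id.
#' @param type_labels Named character vector mapping subfamily_id to
#'   "I", "II" or "III".
#' @param coverage_mean Mean read depth (Poisson; default 20). Positions
#'   drawing 0 coverage are dropped, so a mean of 0 gives an empty table.
#' @param high,low High and low methylation rates (defaults 0.85, 0.05).
#' @param flank Flank width in bp for the Type II flank signal
#'   (default 2000).
#' @param seed Integer seed.
#' @return data.frame: chrom, pos, strand, context, mC, total.
#' @export
emit_methylome <- function(genome, elements, type_labels,
                           coverage_mean = 20, high = 0.85, low = 0.05,
                           flank = 2000L, seed = 1L) {
  stopifnot(all(type_labels %in% c("I", "II", "III")))
  if (nrow(elements) > 0) {
    missing_t <- setdiff(unique(elements$subfamily_id), names(type_labels))
    if (length(missing_t))
      stop("no type label for subfamily: ",
           paste(missing_t, collapse = ", "))
  }
  set.seed(seed)
  cyt <- cytosine_contexts(genome)
  rate <- rep(low, nrow(cyt))
  cgr <- GenomicRanges::GRanges(cyt$chrom, IRanges::IRanges(cyt$pos,
                                                            cyt$pos))
  if (nrow(elements) > 0) {
    for (i in seq_len(nrow(elements))) {
      ty <- type_labels[[elements$subfamily_id[i]]]
      body <- GenomicRanges::GRanges(
        elements$chrom[i],
        IRanges::IRanges(elements$start[i], elements$end[i]))
      inb <- IRanges::overlapsAny(cgr, body)
      if (ty == "I") {
        rate[inb] <- high
      } else if (ty == "II") {
        fl <- GenomicRanges::GRanges(
          elements$chrom[i],
          IRanges::IRanges(max(1L, elements$start[i] - flank),
                           elements$end[i] + flank))
        infl <- IRanges::overlapsAny(cgr, fl)
        sel <- infl & cyt$context %in% c("CG", "CHG")
        rate[sel] <- high
      } else {
        sel <- inb & cyt$context == "CG"
        rate[sel] <- high
      }
    }
  }
  total <- stats::rpois(nrow(cyt), coverage_mean)
  keep <- total > 0
  mC <- stats::rbinom(sum(keep), total[keep], rate[keep])
  out <- cyt[keep, , drop = FALSE]
  out$mC <- mC
  out$total <- total[keep]
  rownames(out) <- NULL
  out
}

#' Simulate small-RNA alignments over a genome
#'
#' Type I element bodies are tiled with 24-nt reads at `typeI_density`
#' reads/bp; background reads (21 and 24 nt) land outside element bodies.
#' Stray background reads on a small element body would dominate its TPM
#' at simulated sequencing depths, so the background avoids bodies; the
#' methods vignette discusses this simplification.
#'
#' @param genome Genome.
#' @param elements data.frame with chrom/start/end/subfamily_id.
#' @param type_labels Named vector as in [emit_methylome()].
#' @param typeI_density 24-nt reads per bp of Type I body (default 0.4).
#' @param n_background Background read count (default 20000).
#' @param seed Integer seed.
#' @return data.frame (BED-like, 1-based): chrom, start, end, read_id,
#'   length, strand, n_loci.
#' @export
emit_srna <- function(genome, elements, type_labels,
                      typeI_density = 0.4, n_background = 20000L,
                      seed = 1L) {
  set.seed(seed)
  g <- .as_genome(genome)
  out <- list()
  body_ir <- list()
  for (chrom in names(g)) {
    ee <- elements[elements$chrom == chrom, , drop = FALSE]
    body_ir[[chrom]] <- IRanges::IRanges(ee$start, ee$end)
  }
  if (nrow(elements) > 0) {
    for (i in seq_len(nrow(elements))) {
      if (type_labels[[elements$subfamily_id[i]]] != "I") next
      blen <- elements$end[i] - elements$start[i] + 1L
      nr <- round(typeI_density * blen)
      if (nr == 0) next
      st <- elements$start[i] +
        sample.int(max(1L, blen - 24L), nr, replace = TRUE) - 1L
      out[[length(out) + 1L]] <- data.frame(
        chrom = elements$chrom[i], start = st, end = st + 23L,
        length = 24L, strand = sample(c("+", "-"), nr, replace = TRUE))
    }
  }
  # background outside bodies
  chroms <- sample(names(g), n_background, replace = TRUE,
                   prob = nchar(g) / sum(nchar(g)))
  for (chrom in unique(chroms)) {
    nb <- sum(chroms == chrom)
    lens <- sample(c(21L, 24L), nb, replace = TRUE)
    st <- sample.int(nchar(g[[chrom]]) - 24L, nb, replace = TRUE)
    ok <- !IRanges::overlapsAny(IRanges::IRanges(st, st + lens - 1L),
                                body_ir[[chrom]])
    out[[length(out) + 1L]] <- data.frame(
      chrom = chrom, start = st[ok], end = (st + lens - 1L)[ok],
      length = lens[ok],
      strand = sample(c("+", "-"), sum(ok), replace = TRUE))
  }
  reads <- do.call(rbind, out)
  reads <- reads[order(reads$chrom, reads$start), , drop = FALSE]
  reads$read_id <- sprintf("r%06d", seq_len(nrow(reads)))
  reads$n_loci <- 1L
  rownames(reads) <- NULL
  reads[, c("chrom", "start", "end", "read_id", "length", "strand",
            "n_loci")]
}

#' Binomial methylation calls per cytosine
#'
#' A position is called methylated iff the one-sided binomial tail
#' P(X >= mC | total, nonconversion_rate) stays below `alpha` after
#' Benjamini-Hochberg correction across all covered positions.
#'
#' @param counts data.frame with mC and total columns.
#' @param nonconversion_rate Bisulfite non-conversion rate in [0, 1).
#' @param alpha FDR level (default 0.01).
#' @return Logical vector (NA where total is 0).
#' @export
call_methylated_cytosines <- function(counts, nonconversion_rate,
                                      alpha = 0.01) {
  stopifnot(nonconversion_rate >= 0, nonconversion_rate < 1)
  p <- rep(NA_real_, nrow(counts))
  ok <- counts$total > 0
  p[ok] <- stats::pbinom(counts$mC[ok] - 1, counts$total[ok],
                         nonconversion_rate, lower.tail = FALSE)
  out <- rep(NA, nrow(counts))
  out[ok] <- stats::p.adjust(p[ok], method = "BH") < alpha
  out
}

#' Weighted methylation level of a region
#'
#' Sum of methylated counts over sum of total counts across the
#' positions of one context inside the region; NA when no coverage.
#'
#' @param region List/one-row data.frame with chrom, start, end.
#' @param counts Methylation count table (see [emit_methylome()]).
#' @param context One of "CG", "CHG", "CHH" (or NULL for all).
#' @return Fraction, or NA.
#' @export
weighted_level <- function(region, counts, context = NULL) {
  sel <- counts$chrom == region$chrom & counts$pos >= region$start &
    counts$pos <= region$end
  if (!is.null(context)) sel <- sel & counts$context == context
  tot <- sum(counts$total[sel])
  if (tot == 0) return(NA_real_)
  sum(counts$mC[sel]) / tot
}

#' Methylation metaprofile over elements
#'
#' Element bodies are rescaled to `bins` bins; flanks are binned at fixed
#' width `flank / bins`. Each cell pools counts over all elements first
#' (weighted level of the pool), per context.
#'
#' @param elements data.frame with chrom/start/end.
#' @param counts Methylation count table.
#' @param bins Body bin count (default 20).
#' @param flank Flank width, bp (default 2000).
#' @return List of matrices (one per context CG/CHG/CHH), each with
#'   `3 * bins` columns: upstream flank, body, downstream flank.
#' @export
metaprofile <- function(elements, counts, bins = 20L, flank = 2000L) {
  stopifnot(nrow(elements) > 0)
  ctxs <- c("CG", "CHG", "CHH")
  mc <- array(0, dim = c(3, 3 * bins), dimnames = list(ctxs, NULL))
  tot <- array(0, dim = c(3, 3 * bins), dimnames = list(ctxs, NULL))
  fw <- flank / bins
  for (i in seq_len(nrow(elements))) {
    e <- elements[i, ]
    cc <- counts[counts$chrom == e$chrom &
                   counts$pos >= e$start - flank &
                   counts$pos <= e$end + flank, , drop = FALSE]
    if (nrow(cc) == 0) next
    rel <- ifelse(cc$pos < e$start,
                  floor((cc$pos - (e$start - flank)) / fw),
                  ifelse(cc$pos > e$end,
                         2L * bins + floor((cc$pos - e$end - 1L) / fw),
                         bins + floor((cc$pos - e$start) /
                                        (e$end - e$start + 1) * bins)))
    rel <- pmax(0L, pmin(3L * bins - 1L, rel)) + 1L
    for (ctx in ctxs) {
      sel <- cc$context == ctx
      if (!any(sel)) next
      mc[ctx, ] <- mc[ctx, ] +
        tapply_sum(cc$mC[sel], rel[sel], 3L * bins)
      tot[ctx, ] <- tot[ctx, ] +
        tapply_sum(cc$total[sel], rel[sel], 3L * bins)
    }
  }
  lapply(stats::setNames(ctxs, ctxs), function(ctx) {
    lev <- mc[ctx, ] / ifelse(tot[ctx, ] == 0, NA, tot[ctx, ])
    matrix(lev, nrow = 1,
           dimnames = list(ctx, c(paste0("up", seq_len(bins)),
                                  paste0("body", seq_len(bins)),
                                  paste0("down", seq_len(bins)))))
  })
}

tapply_sum <- function(x, idx, n) {
  out <- numeric(n)
  s <- tapply(x, idx, sum)
  out[as.integer(names(s))] <- s
  out
}

#' Small-RNA abundance over elements in TPM
#'
#' Counts reads overlapping each element by read length (21 and 24 nt),
#' weighting a read placed at k loci by 1/k, and normalizes to
#' transcripts per million using the total (weight-summed) reads in the
#' input.
#'
#' @param elements data.frame with chrom/start/end (and optionally
#'   element_id).
#' @param reads sRNA alignment table (see [emit_srna()]).
#' @return data.frame: element_id, tpm21, tpm24.
#' @export
srna_abundance <- function(elements, reads) {
  if (!"element_id" %in% names(elements) && nrow(elements) > 0)
    elements$element_id <- sprintf("el%04d", seq_len(nrow(elements)))
  w <- 1 / reads$n_loci
  total <- sum(w)
  egr <- GenomicRanges::GRanges(elements$chrom,
                                IRanges::IRanges(elements$start,
                                                 elements$end))
  rgr <- GenomicRanges::GRanges(reads$chrom,
                                IRanges::IRanges(reads$start, reads$end))
  ov <- GenomicRanges::findOverlaps(rgr, egr, ignore.strand = TRUE)
  out <- data.frame(element_id = elements$element_id,
                    tpm21 = 0, tpm24 = 0)
  if (length(ov) > 0 && total > 0) {
    for (len in c(21L, 24L)) {
      sel <- reads$length[S4Vectors::queryHits(ov)] == len
      cnt <- tapply(w[S4Vectors::queryHits(ov)[sel]],
                    S4Vectors::subjectHits(ov)[sel], sum)
      col <- if (len == 21L) "tpm21" else "tpm24"
      out[[col]][as.integer(names(cnt))] <- cnt * 1e6 / total
    }
  }
  out
}

#' Classify a family's epigenetic type (I / II / III)
#'
#' Rule set over body/flank weighted levels and 24-nt body abundance:
#' Type I iff srna24 >= `t_srna` and CHH(body) >= `t_chh` and the summed
#' body-minus-flank contrast >= `t_border`; Type III iff srna24 <
#' `t_srna`, CG(body) >= `t_cg`, CHG(body) < `t_chg` and CHH(body) <
#' `t_chh`; otherwise Type II. NA levels give "unclassified". The
#' numeric thresholds are this package's calibration of the qualitative
#' class definitions; all are exposed.
#'
#' @param body Named levels `c(CG=, CHG=, CHH=)` for the body.
#' @param flank Same for the flanks.
#' @param srna24_body 24-nt abundance over the body, TPM.
#' @param t_srna,t_chh,t_cg,t_chg,t_border Thresholds (defaults 5 TPM,
#'   0.10, 0.40, 0.10, 0.10).
#' @return One of "I", "II", "III", "unclassified".
#' @export
classify_family_type <- function(body, flank, srna24_body,
                                 t_srna = 5, t_chh = 0.10, t_cg = 0.40,
                                 t_chg = 0.10, t_border = 0.10) {
  if (any(is.na(body)) || any(is.na(flank)) || is.na(srna24_body))
    return("unclassified")
  if (srna24_body >= t_srna && body["CHH"] >= t_chh &&
      (sum(body) - sum(flank)) >= t_border) return("I")
  if (srna24_body < t_srna && body["CG"] >= t_cg &&
      body["CHG"] < t_chg && body["CHH"] < t_chh) return("III")
  "II"
}

#' Compute body/flank levels and sRNA abundance per family, then type
#'
#' Convenience wrapper: pools each family's elements, computes weighted
#' body and flank levels per context and the 24-nt body TPM, and applies
#' [classify_family_type()].
#'
#' @param elements data.frame with chrom/start/end/subfamily_id.
#' @param counts Methylation counts.
#' @param reads sRNA reads.
#' @param flank Flank width, bp (default 2000).
#' @param ... Thresholds passed to [classify_family_type()].
#' @return data.frame: subfamily_id, CG/CHG/CHH body and flank levels,
#'   srna24_body, type.
#' @export
family_epitypes <- function(elements, counts, reads, flank = 2000L, ...) {
  fams <- unique(elements$subfamily_id)
  out <- lapply(fams, function(f) {
    ee <- elements[elements$subfamily_id == f, , drop = FALSE]
    lev <- function(regions, ctx) {
      mC <- 0; tot <- 0
      for (i in seq_len(nrow(regions))) {
        sel <- counts$chrom == regions$chrom[i] &
          counts$pos >= regions$start[i] &
          counts$pos <= regions$end[i] & counts$context == ctx
        mC <- mC + sum(counts$mC[sel]); tot <- tot + sum(counts$total[sel])
      }
      if (tot == 0) NA_real_ else mC / tot
    }
    fl <- data.frame(chrom = rep(ee$chrom, 2),
                     start = c(pmax(1L, ee$start - flank), ee$end + 1L),
                     end = c(ee$start - 1L, ee$end + flank))
    body <- vapply(c(CG = "CG", CHG = "CHG", CHH = "CHH"),
                   function(cx) lev(ee, cx), numeric(1))
    flv <- vapply(c(CG = "CG", CHG = "CHG", CHH = "CHH"),
                  function(cx) lev(fl, cx), numeric(1))
    ab <- srna_abundance(ee, reads)
    srna24 <- sum(ab$tpm24)
    data.frame(subfamily_id = f, cg_body = body["CG"],
               chg_body = body["CHG"], chh_body = body["CHH"],
               cg_flank = flv["CG"], chg_flank = flv["CHG"],
               chh_flank = flv["CHH"], srna24_body = srna24,
               type = classify_family_type(body, flv, srna24, ...))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify gene-body methylation
#'
#' `C_methylated` iff the CHG or CHH body level is >= `t_nonCG` *and*
#' binomially enriched over the `background` rate (one-sided test on the
#' pooled counts at level `alpha`); `CG_body_methylated` iff not
#' C-methylated and the CG level is >= `t_cg` with the same enrichment
#' test; otherwise `unmethylated`. Genes with fewer than `min_reads`
#' total reads in every context return `uncallable`.
#'
#' @param gene One-row data.frame with chrom/start/end.
#' @param counts Methylation counts.
#' @param t_nonCG Non-CG level threshold (default 0.05).
#' @param t_cg CG level threshold (default 0.20).
#' @param background Background (incidental) methylation rate the pooled
#'   counts must exceed (default 0.05).
#' @param alpha Significance level for the enrichment test
#'   (default 0.01).
#' @param min_reads Minimum reads per context (default 5).
#' @return One of "CG_body_methylated", "C_methylated", "unmethylated",
#'   "uncallable".
#' @export
classify_gene_methylation <- function(gene, counts, t_nonCG = 0.05,
                                      t_cg = 0.20, background = 0.05,
                                      alpha = 0.01, min_reads = 5L) {
  stat <- lapply(c(CG = "CG", CHG = "CHG", CHH = "CHH"), function(cx) {
    sel <- counts$chrom == gene$chrom & counts$pos >= gene$start &
      counts$pos <= gene$end & counts$context == cx
    tot <- sum(counts$total[sel])
    if (tot < min_reads)
      return(list(level = NA_real_, enriched = FALSE))
    mC <- sum(counts$mC[sel])
    list(level = mC / tot,
         enriched = stats::pbinom(mC - 1, tot, background,
                                  lower.tail = FALSE) < alpha)
  })
  if (all(vapply(stat, function(s) is.na(s$level), logical(1))))
    return("uncallable")
  nonCG_hit <- vapply(stat[c("CHG", "CHH")], function(s)
    !is.na(s$level) && s$level >= t_nonCG && s$enriched, logical(1))
  if (any(nonCG_hit)) return("C_methylated")
  cg <- stat$CG
  if (!is.na(cg$level) && cg$level >= t_cg && cg$enriched)
    return("CG_body_methylated")
  "unmethylated"
}
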