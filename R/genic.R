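## Genic context of element insertions: positional classes with the
## single-category dedup rule, TRIM-related-gene statistics, size-class
## densities, gene-capture detection, and a Nei-Gojobori (1986) Ka/Ks
## estimator.

.genes_granges <- function(genes) {
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(genes$start, genes$end),
                         strand = genes$strand, gene_id = genes$gene_id)
}

.exons_granges <- function(genes) {
  do.call(c, lapply(seq_len(nrow(genes)), function(i) {
    GenomicRanges::GRanges(genes$chrom[i],
                           IRanges::IRanges(genes$exon_start[[i]],
                                            genes$exon_end[[i]]),
                           strand = genes$strand[i],
                           gene_id = genes$gene_id[i])
  }))
}

#' Classify element insertions relative to gene models
#'
#' Each hit gets exactly one category with precedence exon > intron >
#' upstream_1500 > intergenic, so a hit spanning an exon/intron or
#' upstream/exon boundary counts once as exon. `upstream_1500` means
#' within 1,500 bp 5' of the transcription start (strand-aware) and not
#' inside any gene; downstream proximity is intergenic. A hit inside two
#' genes goes to the gene whose exon it touches, else the longer gene.
#'
#' @param hits data.frame with chrom/start/end (and optionally an id
#'   column `hit_id`).
#' @param genes Gene table from [simulate_genome()] (`gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `exon_start`/`exon_end` list columns).
#' @param upstream Upstream window, bp (default 1500).
#' @return data.frame: hit_id, chrom, start, end, category, gene_id (NA
#'   for intergenic).
#' @export
classify_insertions <- function(hits, genes, upstream = 1500L) {
  if (nrow(hits) == 0)
    return(data.frame(hit_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      category = character(0), gene_id = character(0)))
  if (!"hit_id" %in% names(hits))
    hits$hit_id <- sprintf("hit%04d", seq_len(nrow(hits)))
  out <- data.frame(hit_id = hits$hit_id, chrom = hits$chrom,
                    start = hits$start, end = hits$end,
                    category = rep("intergenic", nrow(hits)),
                    gene_id = NA_character_)
  if (nrow(hits) == 0 || is.null(genes) || nrow(genes) == 0) return(out)
  if (!all(vapply(genes$exon_start, length, integer(1)) > 0))
    stop("gene annotation without exon features")
  hgr <- GenomicRanges::GRanges(hits$chrom,
                                IRanges::IRanges(hits$start, hits$end))
  ggr <- .genes_granges(genes)
  egr <- .exons_granges(genes)
  up <- GenomicRanges::flank(ggr, upstream, start = TRUE)
  up$gene_id <- ggr$gene_id

  ov_exon <- GenomicRanges::findOverlaps(hgr, egr, ignore.strand = TRUE)
  ov_gene <- GenomicRanges::findOverlaps(hgr, ggr, ignore.strand = TRUE)
  ov_up <- GenomicRanges::findOverlaps(hgr, up, ignore.strand = TRUE)
  glen <- genes$end - genes$start + 1L

  for (i in seq_len(nrow(hits))) {
    ex_g <- unique(egr$gene_id[S4Vectors::subjectHits(ov_exon)[
      S4Vectors::queryHits(ov_exon) == i]])
    in_g <- unique(ggr$gene_id[S4Vectors::subjectHits(ov_gene)[
      S4Vectors::queryHits(ov_gene) == i]])
    up_g <- unique(up$gene_id[S4Vectors::subjectHits(ov_up)[
      S4Vectors::queryHits(ov_up) == i]])
    if (length(ex_g)) {
      pick <- ex_g[which.max(glen[match(ex_g, genes$gene_id)])]
      out$category[i] <- "exon"; out$gene_id[i] <- pick
    } else if (length(in_g)) {
      pick <- in_g[which.max(glen[match(in_g, genes$gene_id)])]
      out$category[i] <- "intron"; out$gene_id[i] <- pick
    } else if (length(up_g)) {
      pick <- up_g[which.max(glen[match(up_g, genes$gene_id)])]
      out$category[i] <- "upstream_1500"; out$gene_id[i] <- pick
    }
  }
  out
}

#' Per-gene structural statistics and TRIM-related-gene comparison
#'
#' A gene is a TRG when it carries at least one element hit in an exon or
#' intron. Compares exon counts, exon sizes and intron sizes between TRGs
#' and non-TRGs with two-sample t-tests on log-transformed values.
#'
#' @param contexts Output of [classify_insertions()].
#' @param genes Gene table.
#' @return List: `genes` (per-gene stats + class), `tests` (data.frame of
#'   t-test p-values, NA with a warning when a class has < 2 genes).
#' @export
trg_stats <- function(contexts, genes) {
  ex_n <- vapply(genes$exon_start, length, integer(1))
  ex_len <- vapply(seq_len(nrow(genes)), function(i)
    mean(genes$exon_end[[i]] - genes$exon_start[[i]] + 1), numeric(1))
  in_len <- vapply(seq_len(nrow(genes)), function(i) {
    es <- genes$exon_start[[i]]; ee <- genes$exon_end[[i]]
    if (length(es) < 2) return(NA_real_)
    mean(es[-1] - ee[-length(ee)] - 1)
  }, numeric(1))
  trg_ids <- unique(contexts$gene_id[contexts$category %in%
                                       c("exon", "intron")])
  gstats <- data.frame(gene_id = genes$gene_id,
                       gene_length = genes$end - genes$start + 1L,
                       exon_count = ex_n,
                       mean_exon_length = ex_len,
                       mean_intron_length = in_len,
                       class = ifelse(genes$gene_id %in% trg_ids,
                                      "TRG", "NTRG"))
  tests <- data.frame(metric = c("exon_count", "mean_exon_length",
                                 "mean_intron_length",
                                 "gene_length"),
                      p_value = NA_real_, trg_mean = NA_real_,
                      ntrg_mean = NA_real_)
  if (sum(gstats$class == "TRG") < 2 || sum(gstats$class == "NTRG") < 2) {
    warning("fewer than 2 genes in a class; tests skipped")
    return(list(genes = gstats, tests = tests))
  }
  for (r in seq_len(nrow(tests))) {
    v <- gstats[[tests$metric[r]]]
    ok <- !is.na(v) & v > 0
    a <- log(v[ok & gstats$class == "TRG"])
    b <- log(v[ok & gstats$class == "NTRG"])
    tests$trg_mean[r] <- mean(exp(a)); tests$ntrg_mean[r] <- mean(exp(b))
    if (length(a) >= 2 && length(b) >= 2)
      tests$p_value[r] <- stats::t.test(a, b)$p.value
  }
  list(genes = gstats, tests = tests)
}

#' Element density in small, mid and large genes
#'
#' Ranks genes by length; the bottom and top 20\% are the small and large
#' classes. Reports per class the gene count, cumulative kb, insertion
#' count (exon or intron hits), insertions per gene and per kb, plus
#' large:small ratios.
#'
#' @param contexts Output of [classify_insertions()].
#' @param genes Gene table (>= 5 genes).
#' @return List: `table` (per-class densities), `ratios` (large vs small,
#'   per gene and per kb; NA when the small-class density is 0).
#' @export
size_class_density <- function(contexts, genes) {
  stopifnot(nrow(genes) >= 5)
  glen <- genes$end - genes$start + 1L
  n20 <- max(1L, round(0.2 * nrow(genes)))
  ord <- order(glen)
  cls <- rep("mid", nrow(genes))
  cls[ord[seq_len(n20)]] <- "small"
  cls[ord[seq(nrow(genes) - n20 + 1L, nrow(genes))]] <- "large"
  genic <- contexts[contexts$category %in% c("exon", "intron"), ,
                    drop = FALSE]
  ins <- table(factor(cls[match(genic$gene_id, genes$gene_id)],
                      levels = c("small", "mid", "large")))
  tab <- do.call(rbind, lapply(c("small", "mid", "large"), function(k) {
    idx <- cls == k
    density_from_counts(sum(idx), sum(glen[idx]) / 1000,
                        as.integer(ins[k]), class = k)
  }))
  ratios <- data.frame(
    per_gene = if (tab$insertions_per_gene[tab$class == "small"] > 0)
      tab$insertions_per_gene[tab$class == "large"] /
      tab$insertions_per_gene[tab$class == "small"] else NA_real_,
    per_kb = if (tab$insertions_per_kb[tab$class == "small"] > 0)
      tab$insertions_per_kb[tab$class == "large"] /
      tab$insertions_per_kb[tab$class == "small"] else NA_real_)
  list(table = tab, ratios = ratios)
}

#' Density arithmetic for one gene size class
#'
#' The reporting core behind [size_class_density()], usable directly on
#' published per-class counts: insertions per gene (2 decimals) and per
#' kb (4 decimals).
#'
#' @param n_genes Gene count in the class.
#' @param kb Cumulative gene length in kb.
#' @param insertions Insertion count in the class.
#' @param class Optional class label.
#' @return One-row data.frame: class, n_genes, kb, insertions,
#'   insertions_per_gene, insertions_per_kb.
#' @export
density_from_counts <- function(n_genes, kb, insertions, class = NA) {
  data.frame(class = class, n_genes = n_genes, kb = kb,
             insertions = insertions,
             insertions_per_gene = round(insertions / n_genes, 2),
             insertions_per_kb = round(insertions / kb, 4))
}

#' Detect host-gene fragments captured in element internal regions
#'
#' Aligns each internal sequence to spliced transcripts; reports local
#' alignments at >= `min_identity` over >= `min_bp`. `exon_only` is TRUE
#' iff the captured fragment contains no intronic sequence, decided by
#' re-aligning to the unspliced gene: a capture that crosses an exon
#' junction on the transcript but aligns only in broken pieces on the
#' unspliced gene carried spliced exons only.
#'
#' @param internals data.frame: element_id, seq (internal sequences).
#' @param genes Gene table.
#' @param genome Genome (to extract transcript/gene sequences).
#' @param min_identity Identity floor (default 0.70).
#' @param min_bp Minimum aligned span (default 50).
#' @return data.frame: element_id, gene_id, aligned_bp, identity,
#'   exon_only.
#' @export
detect_gene_capture <- function(internals, genes, genome,
                                min_identity = 0.70, min_bp = 50L) {
  empty <- data.frame(element_id = character(0), gene_id = character(0),
                      aligned_bp = integer(0), identity = numeric(0),
                      exon_only = logical(0))
  if (nrow(internals) == 0 || is.null(genes) || nrow(genes) == 0)
    return(empty)
  g <- .as_genome(genome)
  out <- list()
  for (gi in seq_len(nrow(genes))) {
    s <- g[[genes$chrom[gi]]]
    exons <- vapply(seq_along(genes$exon_start[[gi]]), function(k)
      substr(s, genes$exon_start[[gi]][k], genes$exon_end[[gi]][k]),
      character(1))
    transcript <- paste(exons, collapse = "")
    unspliced <- substr(s, genes$start[gi], genes$end[gi])
    if (genes$strand[gi] == "-") {
      transcript <- revcomp(transcript)
      unspliced <- revcomp(unspliced)
    }
    for (ii in seq_len(nrow(internals))) {
      aln <- .local_align(internals$seq[ii], transcript,
                          match = 2, mismatch = -4,
                          gap_open = -8, gap_ext = -4)
      if (aln$ncol == 0) next
      span <- aln$qend - aln$qstart + 1
      id <- aln$nmatch / aln$ncol
      if (span < min_bp || id < min_identity) next
      aln_g <- .local_align(internals$seq[ii], unspliced,
                            match = 2, mismatch = -4,
                            gap_open = -8, gap_ext = -4)
      g_span <- if (aln_g$ncol == 0) 0 else aln_g$qend - aln_g$qstart + 1
      # A fragment that carries intronic sequence aligns further along
      # the unspliced gene than along the transcript; a spliced capture
      # (or one inside a single exon) does not.
      exon_only <- g_span <= span + 10
      out[[length(out) + 1L]] <- data.frame(
        element_id = internals$element_id[ii],
        gene_id = genes$gene_id[gi],
        aligned_bp = as.integer(span), identity = id,
        exon_only = exon_only)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) empty else res
}


## ---- Nei-Gojobori (1986) Ka/Ks -------------------------------------

# Synonymous fraction per codon position: share of the three possible
# point mutations at each position that preserve the amino acid.
# Mutations to stop codons count as nonsynonymous.
.ng86_sites <- function(codon, code) {
  aa <- code[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"),
                      substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (!is.na(code[[mut]]) && code[[mut]] != "*" &&
          code[[mut]] == aa)
        s <- s + 1 / 3
    }
  }
  s
}

# Average synonymous/nonsynonymous differences between two codons over
# all mutational pathways; pathways through stop codons are excluded
# (all pathways used if every one passes through a stop).
.ng86_diffs <- function(c1, c2, code) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(pos)
  if (nd == 0) return(c(sd = 0, nd = 0))
  perms <- .permutations(pos)
  path_sd <- numeric(0); path_nd <- numeric(0)
  path_sd_all <- numeric(0); path_nd_all <- numeric(0)
  for (p in seq_len(nrow(perms))) {
    cur <- c1
    sd <- 0; ndf <- 0; hits_stop <- FALSE
    for (step in perms[p, ]) {
      nxt <- cur
      substr(nxt, step, step) <- substr(c2, step, step)
      if (code[[nxt]] == "*" || code[[cur]] == "*") hits_stop <- TRUE
      if (code[[nxt]] == code[[cur]] && code[[cur]] != "*")
        sd <- sd + 1 else ndf <- ndf + 1
      cur <- nxt
    }
    path_sd_all <- c(path_sd_all, sd); path_nd_all <- c(path_nd_all, ndf)
    if (!hits_stop) {
      path_sd <- c(path_sd, sd); path_nd <- c(path_nd, ndf)
    }
  }
  if (length(path_sd) == 0) { path_sd <- path_sd_all; path_nd <- path_nd_all }
  c(sd = mean(path_sd), nd = mean(path_nd))
}

.permutations <- function(x) {
  if (length(x) == 1) return(matrix(x, 1))
  out <- NULL
  for (i in seq_along(x))
    out <- rbind(out, cbind(x[i], .permutations(x[-i])))
  out
}

#' Nei-Gojobori (1986) Ka/Ks between two aligned coding sequences
#'
#' Pathway-averaged synonymous/nonsynonymous site and difference counts
#' with the Jukes-Cantor correction. Sequences must be the same length, a
#' multiple of 3, and free of internal stop codons.
#'
#' @param cds_a,cds_b Aligned coding sequences (character scalars).
#' @return List of class `ng86`: `Ka`, `Ks`, `ratio` (NA when Ks is 0),
#'   `S`, `N` (site counts), `Sd`, `Nd` (difference counts).
#' @export
ka_ks_ng86 <- function(cds_a, cds_b) {
  if (nchar(cds_a) != nchar(cds_b))
    stop("coding sequences differ in length")
  if (nchar(cds_a) %% 3 != 0)
    stop("sequence length is not a multiple of 3")
  code <- as.list(Biostrings::GENETIC_CODE)
  cod_a <- substring(cds_a, seq(1, nchar(cds_a), 3),
                     seq(3, nchar(cds_a), 3))
  cod_b <- substring(cds_b, seq(1, nchar(cds_b), 3),
                     seq(3, nchar(cds_b), 3))
  if (any(unlist(code[cod_a]) == "*") || any(unlist(code[cod_b]) == "*"))
    stop("internal stop codon")
  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  for (i in seq_along(cod_a)) {
    s_a <- .ng86_sites(cod_a[i], code)
    s_b <- .ng86_sites(cod_b[i], code)
    S <- S + (s_a + s_b) / 2
    N <- N + 3 - (s_a + s_b) / 2
    d <- .ng86_diffs(cod_a[i], cod_b[i], code)
    Sd <- Sd + d["sd"]; Nd <- Nd + d["nd"]
  }
  jc <- function(p) {
    if (!is.finite(p)) return(NA_real_)   # no sites of this kind
    if (p <= 0) return(0)
    if (p >= 0.75) return(NA_real_)       # Jukes-Cantor saturation
    -0.75 * log(1 - 4 * p / 3)
  }
  Ks <- jc(Sd / S); Ka <- jc(Nd / N)
  structure(list(Ka = Ka, Ks = Ks,
                 ratio = if (!is.na(Ks) && Ks > 0) Ka / Ks else NA_real_,
                 S = S, N = N, Sd = unname(Sd), Nd = unname(Nd)),
            class = "ng86")
}
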