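## Readers and writers for the external formats: FASTA, GFF3 gene models,
## truth/annotation TSVs, bedGraph-like methylation tables and BED-like
## sRNA alignments. All exported TSVs are 1-based inclusive and say so in
## their headers.

#' Write a genome to FASTA
#' @param genome Named character vector or DNAStringSet.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_genome_fasta <- function(genome, path) {
  g <- .as_genome(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(g), path)
  invisible(path)
}

#' Read a genome from FASTA
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  .as_genome(Biostrings::readDNAStringSet(path))
}

#' Write gene models as GFF3 (gene / mRNA / exon)
#' @param genes Gene table from [simulate_genome()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_genes_gff3 <- function(genes, path) {
  grs <- lapply(seq_len(nrow(genes)), function(i) {
    gid <- genes$gene_id[i]
    es <- genes$exon_start[[i]]; ee <- genes$exon_end[[i]]
    gr <- GenomicRanges::GRanges(
      genes$chrom[i],
      IRanges::IRanges(c(genes$start[i], genes$start[i], es),
                       c(genes$end[i], genes$end[i], ee)),
      strand = genes$strand[i])
    gr$type <- c("gene", "mRNA", rep("exon", length(es)))
    gr$ID <- c(gid, paste0(gid, ".1"),
               paste0(gid, ".1.exon", seq_along(es)))
    gr$Parent <- c(NA, gid, rep(paste0(gid, ".1"), length(es)))
    gr
  })
  rtracklayer::export.gff3(do.call(c, grs), path)
  invisible(path)
}

#' Read gene models from GFF3 into the package's gene table
#'
#' Expects gene/mRNA/exon features with ID/Parent attributes; uses the
#' longest mRNA per gene.
#'
#' @param path GFF3 path.
#' @return Gene table (gene_id, chrom, start, end, strand,
#'   exon_start/exon_end list columns).
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  genes <- gr[gr$type == "gene"]
  mrnas <- gr[gr$type == "mRNA"]
  exons <- gr[gr$type == "exon"]
  out <- lapply(seq_along(genes), function(i) {
    gid <- genes$ID[i]
    mr <- mrnas[vapply(mrnas$Parent, function(p) gid %in% p, logical(1))]
    if (length(mr) == 0) return(NULL)
    mr <- mr[which.max(GenomicRanges::width(mr))]
    ex <- exons[vapply(exons$Parent, function(p) mr$ID %in% p,
                       logical(1))]
    ex <- ex[order(GenomicRanges::start(ex))]
    data.frame(gene_id = gid,
               start = GenomicRanges::start(genes[i]),
               end = GenomicRanges::end(genes[i]),
               strand = as.character(GenomicRanges::strand(genes[i])),
               exon_start = I(list(GenomicRanges::start(ex))),
               exon_end = I(list(GenomicRanges::end(ex))),
               chrom = as.character(GenomicRanges::seqnames(genes[i])))
  })
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}

#' Write the simulation truth table as TSV
#' @param truth Truth data.frame from [simulate_genome()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read a per-cytosine methylation table
#'
#' Tab-separated: chrom, pos (1-based), strand, context, mC, total.
#'
#' @param counts Methylation table (see [emit_methylome()]).
#' @param path File path.
#' @return Invisibly the path, or the table.
#' @export
write_methylation_tsv <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_methylation_tsv
#' @export
read_methylation_tsv <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  bad <- setdiff(c("CG", "CHG", "CHH"), unique(out$context))
  unknown <- setdiff(unique(out$context), c("CG", "CHG", "CHH"))
  if (length(unknown))
    stop("unknown methylation context symbol: ",
         paste(unknown, collapse = ", "))
  out
}

#' Write / read sRNA alignments (BED-like, 1-based, with read length)
#' @param reads sRNA table (see [emit_srna()]).
#' @param path File path.
#' @return Invisibly the path, or the table.
#' @export
write_srna_bed <- function(reads, path) {
  utils::write.table(reads, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_srna_bed
#' @export
read_srna_bed <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write all outputs of a simulation to a directory
#'
#' FASTA genome, GFF3 genes (when present), truth TSV, and GFF3 of the
#' implanted elements.
#'
#' @param sim Result of [simulate_genome()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_truth_tsv(sim$truth, file.path(dir, "truth.tsv"))
  if (!is.null(sim$genes))
    write_genes_gff3(sim$genes, file.path(dir, "genes.gff3"))
  if (nrow(sim$truth) > 0) {
    gr <- GenomicRanges::GRanges(
      sim$truth$chrom,
      IRanges::IRanges(sim$truth$start, sim$truth$end))
    gr$type <- "mobile_genetic_element"
    gr$ID <- sim$truth$element_id
    gr$kind <- sim$truth$kind
    gr$subfamily <- sim$truth$subfamily_id
    rtracklayer::export.gff3(gr, file.path(dir, "elements.gff3"))
  }
  invisible(dir)
}
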