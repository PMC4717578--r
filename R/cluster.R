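## Subfamily clustering (within a genome, the 80/80 rule) and family
## grouping (across genomes), with conservation labels.

#' Identity and coverage of the best local alignment of two sequences
#'
#' Identity is matches / alignment columns of the best local alignment;
#' coverage is the aligned span divided by the length of the shorter
#' sequence. Symmetric: arguments are ordered canonically (shorter as
#' query) before aligning.
#'
#' @param a,b DNA sequences (character scalars), non-empty.
#' @return List with `identity` and `coverage` (fractions).
#' @export
pairwise_coverage_identity <- function(a, b) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  if (identical(a, b)) return(list(identity = 1.0, coverage = 1.0))
  aln <- .local_align(a, b, match = 2, mismatch = -2,
                      gap_open = -6, gap_ext = -2)
  if (aln$ncol == 0) return(list(identity = 0, coverage = 0))
  list(identity = aln$nmatch / aln$ncol,
       coverage = (aln$qend - aln$qstart + 1) / nchar(a))
}

# Single-linkage clusters from an edge predicate over n items.
.single_linkage <- function(n, pred) {
  gr <- igraph::make_empty_graph(n, directed = FALSE)
  if (n >= 2) {
    edges <- integer(0)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) if (pred(i, j)) edges <- c(edges, i, j)
    }
    if (length(edges)) gr <- igraph::add_edges(gr, edges)
  }
  as.integer(igraph::components(gr)$membership)
}

# Majority-vote consensus via a star alignment of all members onto a
# reference member. The reference is the member of modal length (ties:
# the longest), not simply the longest: a tandem array clustered into its
# parent subfamily would otherwise become the reference and inflate the
# consensus past the unit element. Substitution-dominated inputs make
# this a near-trivial column vote; gapped members still project through
# the pairwise alignment. Ties resolve in A<C<G<T order for determinism.
.star_consensus <- function(seqs) {
  lens <- nchar(seqs)
  tab <- table(lens)
  modal <- as.integer(names(tab)[tab == max(tab)])
  ref_i <- which(lens == max(modal))[1L]
  ref <- seqs[ref_i]
  L <- nchar(ref)
  votes <- matrix(0L, nrow = 4, ncol = L,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
  add_votes <- function(sq) {
    if (identical(sq, ref)) {
      v <- .dna_codes(sq) + 1L
      ok <- !is.na(v)
      votes[cbind(v[ok], which(ok))] <<- votes[cbind(v[ok], which(ok))] + 1L
      return(invisible())
    }
    sub <- Biostrings::nucleotideSubstitutionMatrix(2, -2, baseOnly = FALSE)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(sq), Biostrings::DNAString(ref),
      type = "global-local", substitutionMatrix = sub,
      gapOpening = 6, gapExtension = 2)
    pat <- strsplit(as.character(Biostrings::alignedPattern(aln)),
                    "")[[1]]
    sbj <- strsplit(as.character(Biostrings::alignedSubject(aln)),
                    "")[[1]]
    rpos <- Biostrings::start(Biostrings::subject(aln)) - 1L
    for (k in seq_along(sbj)) {
      if (sbj[k] != "-") {
        rpos <- rpos + 1L
        if (pat[k] %in% rownames(votes))
          votes[pat[k], rpos] <<- votes[pat[k], rpos] + 1L
      }
    }
    invisible()
  }
  for (sq in seqs) add_votes(sq)
  covered <- colSums(votes) > 0
  paste(rownames(votes)[apply(votes[, covered, drop = FALSE], 2,
                              which.max)], collapse = "")
}

#' Cluster elements of one genome into subfamilies (80/80 rule)
#'
#' Single-linkage clustering under the predicate identity >= 80\% AND
#' coverage >= 80\% of the shorter element; consensus is a majority vote
#' from a star alignment onto the longest member.
#'
#' @param elements data.frame with at least `element_id` and `seq`
#'   columns (one genome); an optional `ltr_len` column is carried to the
#'   subfamily level (median of members).
#' @param genome_id Genome identifier recorded on each subfamily.
#' @param min_identity,min_coverage Linking thresholds (default 0.80 each).
#' @return List: `subfamilies` (data.frame: subfamily_id, genome_id,
#'   n_members, consensus, consensus_length, ltr_length), `membership`
#'   (element_id -> subfamily_id).
#' @export
cluster_subfamilies <- function(elements, genome_id = "genome1",
                                min_identity = 0.80, min_coverage = 0.80) {
  n <- nrow(elements)
  if (n == 0)
    return(list(subfamilies = data.frame(subfamily_id = character(0),
                                         genome_id = character(0),
                                         n_members = integer(0),
                                         consensus = character(0),
                                         consensus_length = integer(0),
                                         ltr_length = integer(0)),
                membership = data.frame(element_id = character(0),
                                        subfamily_id = character(0))))
  seqs <- elements$seq
  cl <- .single_linkage(n, function(i, j) {
    ci <- pairwise_coverage_identity(seqs[i], seqs[j])
    ci$identity >= min_identity && ci$coverage >= min_coverage
  })
  ids <- sprintf("%s_SF%03d", genome_id, cl)
  subf <- do.call(rbind, lapply(sort(unique(cl)), function(k) {
    idx <- which(cl == k)
    cons <- .star_consensus(seqs[idx])
    data.frame(subfamily_id = sprintf("%s_SF%03d", genome_id, k),
               genome_id = genome_id,
               n_members = length(idx),
               consensus = cons,
               consensus_length = nchar(cons),
               ltr_length = if ("ltr_len" %in% names(elements))
                 as.integer(stats::median(elements$ltr_len[idx]))
               else NA_integer_)
  }))
  list(subfamilies = subf,
       membership = data.frame(element_id = elements$element_id,
                               subfamily_id = ids))
}

#' Group subfamily consensuses across genomes into families
#'
#' Two subfamilies link iff the best local alignment of their consensuses
#' spans >= `min_bp` bp and >= `min_frac` of the query consensus length at
#' >= `min_identity` identity (the identity floor replaces an E-value
#' cutoff since no external search engine is used); linking is symmetric
#' by requiring the span condition in at least one direction. Families are
#' the single-linkage closure.
#'
#' @param subfamilies data.frame with `subfamily_id`, `genome_id`,
#'   `consensus`.
#' @param min_bp Minimum aligned span, bp (default 50).
#' @param min_frac Minimum aligned fraction of the query consensus
#'   (default 0.05).
#' @param min_identity Identity floor on the linking alignment
#'   (default 0.70).
#' @return data.frame: subfamily_id, genome_id, family_id.
#' @export
group_families <- function(subfamilies, min_bp = 50L, min_frac = 0.05,
                           min_identity = 0.70) {
  n <- nrow(subfamilies)
  if (n == 0)
    return(cbind(subfamilies, data.frame(family_id = character(0))))
  cons <- subfamilies$consensus
  cl <- .single_linkage(n, function(i, j) {
    aln <- .local_align(cons[i], cons[j], match = 2, mismatch = -4,
                        gap_open = -8, gap_ext = -4)
    if (aln$ncol == 0) return(FALSE)
    if (aln$nmatch / aln$ncol < min_identity) return(FALSE)
    span_i <- aln$qend - aln$qstart + 1
    span_j <- aln$send - aln$sstart + 1
    (span_i >= min_bp && span_i >= min_frac * nchar(cons[i])) ||
      (span_j >= min_bp && span_j >= min_frac * nchar(cons[j]))
  })
  out <- subfamilies
  out$family_id <- sprintf("FAM%03d", cl)
  out
}

#' Label family conservation from a genome taxonomy
#'
#' `shared_between_plant_families` if members span two or more plant
#' taxonomic families; `family_specific` if two or more genomes of a
#' single plant family; `species_specific` if exactly one genome.
#'
#' @param families data.frame from [group_families()] (needs `family_id`,
#'   `genome_id`).
#' @param taxonomy data.frame with `genome_id` and `plant_family`.
#' @return data.frame: family_id, n_genomes, n_plant_families,
#'   conservation.
#' @export
classify_conservation <- function(families, taxonomy) {
  missing_g <- setdiff(unique(families$genome_id), taxonomy$genome_id)
  if (length(missing_g))
    stop("genomes missing from taxonomy: ",
         paste(missing_g, collapse = ", "))
  pf <- taxonomy$plant_family[match(families$genome_id,
                                    taxonomy$genome_id)]
  out <- do.call(rbind, lapply(split(seq_len(nrow(families)),
                                     families$family_id), function(idx) {
    genomes <- unique(families$genome_id[idx])
    pfs <- unique(pf[idx])
    data.frame(family_id = families$family_id[idx[1]],
               n_genomes = length(genomes),
               n_plant_families = length(pfs),
               conservation = if (length(pfs) >= 2)
                 "shared_between_plant_families"
               else if (length(genomes) >= 2) "family_specific"
               else "species_specific")
  }))
  rownames(out) <- NULL
  out
}

#' Extract element sequences for clustering
#'
#' Convenience: attach a `seq` column to an element table using the genome
#' it was annotated on.
#'
#' @param elements data.frame with chrom/start/end.
#' @param genome Genome.
#' @return The input with a `seq` column (and `element_id` if absent).
#' @export
add_element_seqs <- function(elements, genome) {
  g <- .as_genome(genome)
  if (!"element_id" %in% names(elements) && nrow(elements) > 0)
    elements$element_id <- sprintf("el%04d", seq_len(nrow(elements)))
  elements$seq <- vapply(seq_len(nrow(elements)), function(i)
    substr(g[[elements$chrom[i]]], elements$start[i], elements$end[i]),
    character(1))
  elements
}
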