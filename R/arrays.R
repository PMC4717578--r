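## Tandemly arrayed elements (TA-TRIMs): runs of >= 3 LTR segments with
## interleaved internal regions, described by structure strings LnIm,
## with inverted arrangements flagged and whole-array TSDs reported.

#' Detect tandem arrays from segment-level annotation
#'
#' Groups consecutive L/I segments whose inter-segment gaps are within
#' `gap_tol` bp into runs; a run with three or more L segments (elements
#' sharing LTRs) is a tandem array. Ordinary two-LTR elements are not
#' arrays. A whole-array TSD is looked up on the full array interval and
#' reported but not filtered on.
#'
#' @param segments Segment data.frame from [annotate_segments()].
#' @param genome Genome (for whole-array TSD lookup); optional.
#' @param gap_tol Maximum gap between adjacent segments, bp (default 10).
#' @return data.frame: chrom, start, end, structure, n_ltr, n_internal,
#'   inverted, non_canonical, tsd, segments (list column of the member
#'   segment rows).
#' @export
detect_arrays <- function(segments, genome = NULL, gap_tol = 10L) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), structure = character(0),
                      n_ltr = integer(0), n_internal = integer(0),
                      inverted = logical(0), non_canonical = logical(0),
                      tsd = character(0))
  if (nrow(segments) == 0) return(empty)
  segments <- segments[order(segments$chrom, segments$start), ,
                       drop = FALSE]
  out <- list()
  for (chrom in unique(segments$chrom)) {
    ss <- segments[segments$chrom == chrom, , drop = FALSE]
    gap_prev <- c(Inf, ss$start[-1] - ss$end[-nrow(ss)] - 1L)
    run_id <- cumsum(gap_prev > gap_tol)
    for (r in unique(run_id)) {
      run <- ss[run_id == r, , drop = FALSE]
      if (sum(run$kind == "L") < 3L) next
      st <- structure_string(run)
      tsd <- NA_character_
      if (!is.null(genome)) {
        g <- .as_genome(genome)
        arr <- data.frame(chrom = chrom, start = min(run$start),
                          end = max(run$end))
        if (arr$start > 6L && arr$end + 6L <= nchar(g[[chrom]]))
          tsd <- detect_tsd(arr, g)
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = min(run$start), end = max(run$end),
        structure = st$structure, n_ltr = sum(run$kind == "L"),
        n_internal = sum(run$kind == "I"), inverted = st$inverted,
        non_canonical = st$non_canonical, tsd = tsd)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty)
  rownames(res) <- NULL
  res
}

#' Structure string of an ordered segment run
#'
#' Counts L and I segments into "L\{n\}I\{m\}". `inverted` is TRUE iff the
#' strand changes within the run (e.g. two tail-to-tail elements);
#' `non_canonical` flags runs that start or end with an internal segment
#' rather than an LTR.
#'
#' @param segments data.frame of one run with `kind` and `strand`,
#'   ordered by coordinate.
#' @return List: structure, inverted, non_canonical.
#' @export
structure_string <- function(segments) {
  stopifnot(nrow(segments) > 0)
  k <- segments$kind
  list(structure = sprintf("L%dI%d", sum(k == "L"), sum(k == "I")),
       inverted = length(unique(segments$strand)) > 1L,
       non_canonical = k[1] != "L" || k[length(k)] != "L")
}

#' Frequency table of tandem-array structures
#'
#' @param arrays data.frame from [detect_arrays()], or any data.frame
#'   with a `structure` column.
#' @return data.frame: structure, count, percent (of all arrays),
#'   sorted by count descending.
#' @export
array_summary <- function(arrays) {
  if (nrow(arrays) == 0)
    return(data.frame(structure = character(0), count = integer(0),
                      percent = numeric(0)))
  tab <- table(arrays$structure)
  out <- data.frame(structure = names(tab), count = as.integer(tab),
                    percent = 100 * as.integer(tab) / nrow(arrays))
  out <- out[order(-out$count, out$structure), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Validate a whole-array TSD
#'
#' TRUE iff identical 4-6 bp copies flank the full array interval.
#'
#' @param array One-row data.frame with chrom/start/end.
#' @param genome Genome.
#' @return Logical.
#' @export
validate_array_tsd <- function(array, genome) {
  !is.na(detect_tsd(array[, c("chrom", "start", "end")], genome))
}
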