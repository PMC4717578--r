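## Low-level sequence helpers shared across the scanner, masker and simulator.
## Sequences travel as plain character scalars internally; user-facing
## functions also accept Biostrings objects and coerce on entry.

#' @import methods
#' @importFrom stats rbinom rpois runif setNames p.adjust pbinom t.test
#'   chisq.test wilcox.test cor
#' @importFrom utils head tail write.table read.table
NULL

# Integer codes A=0 C=1 G=2 T=3, NA for anything else (incl. N).
.DNA_CODE_MAP <- local({
  m <- rep(NA_integer_, 127L)
  m[utf8ToInt("A")] <- 0L; m[utf8ToInt("C")] <- 1L
  m[utf8ToInt("G")] <- 2L; m[utf8ToInt("T")] <- 3L
  m[utf8ToInt("a")] <- 0L; m[utf8ToInt("c")] <- 1L
  m[utf8ToInt("g")] <- 2L; m[utf8ToInt("t")] <- 3L
  m
})

.dna_codes <- function(s) {
  .DNA_CODE_MAP[utf8ToInt(s)]
}

.as_seq_string <- function(x) {
  if (is(x, "XString") || is(x, "XStringSet")) as.character(x) else
    as.character(x)
}

# A genome is a named character vector of chromosome sequences.
.as_genome <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    g <- as.character(genome)
  } else if (is(genome, "DNAString")) {
    g <- stats::setNames(as.character(genome), "chr1")
  } else {
    g <- stats::setNames(as.character(genome), names(genome))
  }
  if (is.null(names(g)) || any(!nzchar(names(g))))
    names(g) <- paste0("chr", seq_along(g))
  bad <- grepl("[^ACGTNacgtn]", g)
  if (any(bad))
    stop("genome contains non-IUPAC characters (only A/C/G/T/N supported) ",
         "on: ", paste(names(g)[bad], collapse = ", "))
  toupper(g)
}

#' Generate a random DNA sequence
#'
#' I.i.d. background sequence with a configurable GC content, used as the
#' neutral host sequence into which elements are implanted.
#'
#' @param n Sequence length in bp.
#' @param gc GC content as a fraction in (0, 1).
#' @return A character scalar of length-`n` DNA.
#' @export
random_dna <- function(n, gc = 0.45) {
  stopifnot(n >= 0, gc > 0, gc < 1)
  if (n == 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Apply random substitutions to a sequence
#'
#' Each position is substituted with probability `rate`, drawing uniformly
#' from the three alternative bases. Indels are not modelled.
#'
#' @param s Character scalar (DNA).
#' @param rate Per-site substitution probability in [0, 1].
#' @return Mutated character scalar.
#' @export
mutate_sequence <- function(s, rate) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0 || nchar(s) == 0) return(s)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(v)) < rate & v %in% c("A", "C", "G", "T"))
  if (length(hit)) {
    alt <- vapply(v[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1))
    v[hit] <- alt
  }
  paste(v, collapse = "")
}

#' Reverse complement
#' @param s Character scalar (DNA).
#' @return Reverse complement as a character scalar.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Gapless identity between two equal-length sequences
#'
#' Fraction of positions with identical bases; positions where either
#' sequence has a non-ACGT character count as mismatches.
#'
#' @param a,b Character scalars of equal length.
#' @return Identity fraction in [0, 1].
#' @export
seq_identity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (nchar(a) == 0) return(NA_real_)
  ca <- .dna_codes(a); cb <- .dna_codes(b)
  mean(!is.na(ca) & !is.na(cb) & ca == cb)
}

# Rolling k-mer codes over an integer code vector. Codes are in
# [0, 4^k), NA where the window touches a non-ACGT base. k <= 15.
.kmer_codes <- function(v, k) {
  n <- length(v)
  if (n < k) return(integer(0))
  m <- n - k + 1L
  code <- numeric(m)
  for (j in 0:(k - 1L)) code <- code * 4 + v[(1L + j):(m + j)]
  code  # double to stay exact up to 4^15; NA propagates
}

# Local alignment wrapper. Returns list(score, identity, qstart, qend,
# sstart, send, ncol) for the best local alignment of query in subject.
.local_align <- function(query, subject, match = 2, mismatch = -2,
                         gap_open = -6, gap_ext = -2) {
  sub <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = sub,
    gapOpening = -gap_open, gapExtension = -gap_ext)
  pat <- Biostrings::pattern(aln)
  sbj <- Biostrings::subject(aln)
  ncol <- nchar(as.character(Biostrings::alignedPattern(aln)))
  list(score  = Biostrings::score(aln),
       nmatch = Biostrings::nmatch(aln),
       ncol   = ncol,
       identity = if (ncol > 0) Biostrings::nmatch(aln) / ncol else NA_real_,
       qstart = Biostrings::start(pat), qend = Biostrings::end(pat),
       sstart = Biostrings::start(sbj), send = Biostrings::end(sbj))
}

# Derive a deterministic child seed from a base seed and a tag; keeps
# results < 2^31 and independent across tags.
.child_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) * 7919 + sum(utf8ToInt(tag)) * 131) %%
               2147483) + 1L
}
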