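## Synthetic genomes with implanted TRIMs and full ground truth.
##
## Elements are inserted the way retroelements integrate: the target site
## (4-6 bp) is duplicated, so a complete implant reads
## TSD + LTR + internal + LTR' + TSD with both TSD copies identical, and
## the pre-insertion background carries exactly one copy. The 3' LTR is a
## point-substitution copy of the 5' LTR at the configured divergence.
## Coordinates are 1-based inclusive throughout; GFF3 output is 1-based
## inclusive as the format requires.

#' Simulation specification
#'
#' Parameters for [simulate_genome()]. LTR lengths are constrained to
#' 30-500 bp and internal spacing to 30-2000 bp, the size envelope of
#' miniature LTR elements.
#'
#' @param genome_length Background length in bp.
#' @param gc_content Background GC fraction.
#' @param n_trims Number of complete elements to implant.
#' @param n_subfamilies Number of distinct element templates; copies are
#'   assigned round-robin.
#' @param ltr_len_range Integer pair, LTR length range (within 30-500).
#' @param internal_len_range Integer pair, internal-region length range
#'   (within 30-2000).
#' @param divergence Per-site substitution rate (0-0.3) applied between the
#'   two LTRs of one element and between copies and their template.
#' @param tsd_len_range Integer pair within 4-6; each insertion draws its
#'   TSD length uniformly from this range.
#' @param n_solo_ltrs Number of solo LTRs (single LTR with its own TSD pair).
#' @param array_specs Character vector of tandem-array structures to implant,
#'   e.g. `"L3I2"`, `"L5I4"`; the token `"INV"` implants two adjacent
#'   inverted elements.
#' @param n_genes Number of multi-exon gene models annotated on the
#'   background.
#' @param partner_spec Optional list describing a large autonomous-partner
#'   element; see [simulate_partner()].
#' @param n_decoy_tandem Number of decoy microsatellite-like tandem repeats
#'   (false-positive bait for the scanner).
#' @param place_in Placement of element insertions: `"anywhere"` (uniform),
#'   `"introns"`, or `"large_genes"` (introns of the top-quintile genes).
#' @param min_flank Minimum background on each side of any insertion point
#'   and between insertion points, bp.
#' @param seed Integer seed; fixes all randomness.
#' @return A validated list of class `trim_sim_spec`.
#' @export
simulation_spec <- function(genome_length = 100000L, gc_content = 0.45,
                            n_trims = 10L, n_subfamilies = 3L,
                            ltr_len_range = c(80L, 300L),
                            internal_len_range = c(100L, 800L),
                            divergence = 0.02,
                            tsd_len_range = c(4L, 6L),
                            n_solo_ltrs = 0L,
                            array_specs = character(0),
                            n_genes = 0L,
                            partner_spec = NULL,
                            n_decoy_tandem = 0L,
                            place_in = c("anywhere", "introns", "large_genes"),
                            min_flank = 800L,
                            seed = 1L) {
  place_in <- match.arg(place_in)
  spec <- list(genome_length = as.integer(genome_length),
               gc_content = gc_content,
               n_trims = as.integer(n_trims),
               n_subfamilies = max(1L, as.integer(n_subfamilies)),
               ltr_len_range = as.integer(ltr_len_range),
               internal_len_range = as.integer(internal_len_range),
               divergence = divergence,
               tsd_len_range = as.integer(tsd_len_range),
               n_solo_ltrs = as.integer(n_solo_ltrs),
               array_specs = array_specs,
               n_genes = as.integer(n_genes),
               partner_spec = partner_spec,
               n_decoy_tandem = as.integer(n_decoy_tandem),
               place_in = place_in,
               min_flank = as.integer(min_flank),
               seed = as.integer(seed))
  stopifnot(spec$genome_length > 0,
            spec$gc_content > 0, spec$gc_content < 1,
            spec$n_trims >= 0, spec$n_solo_ltrs >= 0, spec$n_genes >= 0,
            length(spec$ltr_len_range) == 2,
            spec$ltr_len_range[1] >= 30, spec$ltr_len_range[2] <= 500,
            spec$ltr_len_range[1] <= spec$ltr_len_range[2],
            length(spec$internal_len_range) == 2,
            spec$internal_len_range[1] >= 30,
            spec$internal_len_range[2] <= 2000,
            spec$divergence >= 0, spec$divergence <= 0.3,
            all(spec$tsd_len_range >= 4), all(spec$tsd_len_range <= 6),
            spec$tsd_len_range[1] <= spec$tsd_len_range[2])
  class(spec) <- "trim_sim_spec"
  spec
}

# An LTR template: canonical TG...CA termini over random interior.
.random_ltr <- function(len, gc) {
  paste0("TG", random_dna(len - 4L, gc), "CA")
}

.rint <- function(range) {
  if (range[1] == range[2]) range[1] else
    sample(seq(range[1], range[2]), 1L)
}

# Subfamily templates: one LTR + one internal sequence each.
.subfamily_templates <- function(spec) {
  lapply(seq_len(spec$n_subfamilies), function(i) {
    list(id = sprintf("SF%02d", i),
         ltr = .random_ltr(.rint(spec$ltr_len_range), spec$gc_content),
         internal = random_dna(.rint(spec$internal_len_range),
                               spec$gc_content))
  })
}

# One element copy from a template: LTR5 diverges from the template, LTR3
# diverges from LTR5 by `div` (the within-element LTR divergence).
.element_copy <- function(tmpl, div) {
  ltr5 <- mutate_sequence(tmpl$ltr, div)
  ltr3 <- mutate_sequence(ltr5, div)
  internal <- mutate_sequence(tmpl$internal, div)
  list(seq = paste0(ltr5, internal, ltr3),
       ltr_len = nchar(tmpl$ltr), internal_len = nchar(internal),
       structure = "L2I1")
}

# Tandem-array construct. "LnIm" alternates L,I,...,L on one strand;
# "INV" is two adjacent elements, the second reverse-complemented.
.array_copy <- function(tmpl, structure, div) {
  if (identical(structure, "INV")) {
    half <- .element_copy(tmpl, div)$seq
    return(list(seq = paste0(half, revcomp(.element_copy(tmpl, div)$seq)),
                ltr_len = nchar(tmpl$ltr),
                internal_len = nchar(tmpl$internal), structure = "INV"))
  }
  m <- regmatches(structure, regexec("^L([0-9]+)I([0-9]+)$", structure))[[1]]
  if (length(m) != 3) stop("bad array structure string: ", structure)
  nL <- as.integer(m[2]); nI <- as.integer(m[3])
  if (nL != nI + 1L) stop("array structure must have one more L than I: ",
                          structure)
  parts <- character(0)
  for (i in seq_len(nI)) {
    parts <- c(parts, mutate_sequence(tmpl$ltr, div),
               mutate_sequence(tmpl$internal, div))
  }
  parts <- c(parts, mutate_sequence(tmpl$ltr, div))
  list(seq = paste(parts, collapse = ""), ltr_len = nchar(tmpl$ltr),
       internal_len = nchar(tmpl$internal), structure = structure)
}

.decoy_tandem <- function(gc) {
  motif <- random_dna(sample(3:8, 1L), gc)
  paste(rep(motif, sample(15:40, 1L)), collapse = "")
}

# Gene models on the background: non-overlapping, with >= 2 kb clearance
# for the upstream window. Returns per-gene exon layout in background
# coordinates.
.place_genes <- function(spec) {
  if (spec$n_genes == 0) return(NULL)
  genes <- vector("list", spec$n_genes)
  cursor <- 2500L
  for (i in seq_len(spec$n_genes)) {
    n_ex <- sample(2:6, 1L)
    ex_len <- sample(150:400, n_ex, replace = TRUE)
    in_len <- if (n_ex > 1) sample(200:600, n_ex - 1L, replace = TRUE)
              else integer(0)
    glen <- sum(ex_len) + sum(in_len)
    gap <- sample(2200:4000, 1L)
    start <- cursor + gap
    if (start + glen + 2500L > spec$genome_length) break
    ex_start <- start + c(0L, cumsum(ex_len[-n_ex] + in_len))
    genes[[i]] <- data.frame(
      gene_id = sprintf("gene%03d", i),
      start = start, end = start + glen - 1L,
      strand = sample(c("+", "-"), 1L),
      exon_start = I(list(ex_start)),
      exon_end = I(list(ex_start + ex_len - 1L)))
    cursor <- start + glen
  }
  genes <- genes[!vapply(genes, is.null, logical(1))]
  if (length(genes) == 0) NULL else do.call(rbind, genes)
}

# Pick insertion points on the background with pairwise spacing and edge
# clearance >= min_flank. Points are "insert after position p".
.place_insertions <- function(spec, n, genes = NULL) {
  if (n == 0) return(integer(0))
  lo <- spec$min_flank
  hi <- spec$genome_length - spec$min_flank - 6L
  need <- 2L * spec$min_flank + (n - 1L) * spec$min_flank
  if (hi < lo || need > spec$genome_length)
    stop("genome too small to host requested elements: need >= ",
         need, " bp of background, have ", spec$genome_length,
         " (deficit ", need - spec$genome_length, " bp)")
  pool <- NULL
  if (spec$place_in != "anywhere") {
    if (is.null(genes)) stop("place_in='", spec$place_in,
                             "' requires n_genes > 0")
    gsel <- genes
    if (spec$place_in == "large_genes") {
      glen <- genes$end - genes$start + 1L
      gsel <- genes[glen >= stats::quantile(glen, 0.8), , drop = FALSE]
    }
    pool <- unlist(lapply(seq_len(nrow(gsel)), function(i) {
      es <- gsel$exon_start[[i]]; ee <- gsel$exon_end[[i]]
      if (length(es) < 2) return(integer(0))
      unlist(lapply(seq_len(length(es) - 1L),
                    function(j) seq(ee[j] + 5L, es[j + 1L] - 10L)))
    }))
    pool <- pool[pool >= lo & pool <= hi]
    if (length(pool) < n) stop("not enough intron space for placement")
  }
  # pooled (intron-restricted) placement packs tighter than the open
  # genome; flank clearance for flank-based analyses is the caller's
  # concern there
  spacing <- if (is.null(pool)) spec$min_flank else
    min(spec$min_flank, 100L)
  pts <- integer(0)
  for (tries in seq_len(n * 500L)) {
    p <- if (is.null(pool)) sample(lo:hi, 1L) else sample(pool, 1L)
    if (all(abs(p - pts) >= spacing)) {
      pts <- c(pts, p)
      if (length(pts) == n) break
    }
  }
  if (length(pts) < n)
    stop("genome too small to host requested elements: placed ",
         length(pts), " of ", n, " (deficit ", n - length(pts),
         " insertions); increase genome_length or reduce min_flank")
  sort(pts)
}

# Assemble the final chromosome from background + planned insertions and
# lift background coordinates. `plan` rows: p (insert after), tsd_len,
# seq, plus metadata carried through.
.assemble <- function(background, plan) {
  if (nrow(plan) == 0) {
    lift <- function(x) x
    return(list(seq = background, plan = plan, lift = lift))
  }
  plan <- plan[order(plan$p), , drop = FALSE]
  pieces <- character(0)
  prev <- 0L
  shift <- 0L
  plan$start <- NA_integer_; plan$end <- NA_integer_
  plan$tsd <- NA_character_
  for (i in seq_len(nrow(plan))) {
    p <- plan$p[i]; tl <- plan$tsd_len[i]
    tsd <- substr(background, p + 1L, p + tl)
    pieces <- c(pieces, substr(background, prev + 1L, p + tl),
                plan$seq[i], tsd)
    plan$start[i] <- p + tl + shift + 1L
    plan$end[i] <- plan$start[i] + nchar(plan$seq[i]) - 1L
    plan$tsd[i] <- tsd
    shift <- shift + nchar(plan$seq[i]) + tl
    prev <- p + tl
  }
  pieces <- c(pieces, substr(background, prev + 1L, nchar(background)))
  ins_p <- plan$p; ins_tl <- plan$tsd_len
  ins_add <- nchar(plan$seq) + ins_tl
  lift <- function(x) {
    vapply(x, function(xx) {
      xx + sum(ins_add[ins_p + ins_tl < xx])
    }, numeric(1))
  }
  list(seq = paste(pieces, collapse = ""), plan = plan, lift = lift)
}

#' Simulate a genome with implanted TRIM elements and ground truth
#'
#' Builds an i.i.d. background sequence, annotates gene models on it, then
#' implants complete elements, solo LTRs, tandem arrays, an optional
#' autonomous partner with its derived miniature element, and optional
#' decoy tandem repeats. Every insertion duplicates its 4-6 bp target site.
#' Identical spec (including seed) gives byte-identical output.
#'
#' @param spec A [simulation_spec()].
#' @return A list with elements `genome` (named character vector, one
#'   chromosome `chr1`), `truth` (data.frame: element_id, chrom, start, end,
#'   kind, tsd, subfamily_id, structure, ltr_len, internal_len; 1-based
#'   inclusive), `genes` (data.frame of gene models in final coordinates or
#'   NULL), `templates` (per-subfamily template sequences), and `partner`
#'   (the [simulate_partner()] result, if requested).
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "trim_sim_spec"))
  set.seed(spec$seed)
  background <- random_dna(spec$genome_length, spec$gc_content)
  genes_bg <- .place_genes(spec)
  templates <- .subfamily_templates(spec)

  builds <- list()
  add_build <- function(kind, sf, obj) {
    builds[[length(builds) + 1L]] <<- c(list(kind = kind, subfamily = sf),
                                        obj)
  }
  for (i in seq_len(spec$n_trims)) {
    si <- 1L + (i - 1L) %% spec$n_subfamilies
    add_build("complete", templates[[si]]$id,
              .element_copy(templates[[si]], spec$divergence))
  }
  for (i in seq_len(spec$n_solo_ltrs)) {
    si <- 1L + (i - 1L) %% spec$n_subfamilies
    tmpl <- templates[[si]]
    add_build("solo_ltr", tmpl$id,
              list(seq = mutate_sequence(tmpl$ltr, spec$divergence),
                   ltr_len = nchar(tmpl$ltr), internal_len = 0L,
                   structure = "L1"))
  }
  for (st in spec$array_specs) {
    si <- sample.int(spec$n_subfamilies, 1L)
    add_build("array", templates[[si]]$id,
              .array_copy(templates[[si]], st, spec$divergence))
  }
  partner <- NULL
  if (!is.null(spec$partner_spec)) {
    partner <- simulate_partner(spec)
    add_build("partner", "partner",
              list(seq = partner$partner, ltr_len = partner$ltr_len,
                   internal_len = nchar(partner$partner) -
                     2L * partner$ltr_len, structure = "partner"))
    add_build("complete", "partner_derived",
              list(seq = partner$trim, ltr_len = partner$ltr_len,
                   internal_len = nchar(partner$trim) - 2L * partner$ltr_len,
                   structure = "L2I1"))
  }
  for (i in seq_len(spec$n_decoy_tandem)) {
    add_build("decoy", "decoy",
              list(seq = .decoy_tandem(spec$gc_content), ltr_len = 0L,
                   internal_len = 0L, structure = "tandem_repeat"))
  }

  n <- length(builds)
  pts <- .place_insertions(spec, n, genes_bg)
  plan <- if (n == 0) {
    data.frame(p = integer(0), tsd_len = integer(0), seq = character(0))
  } else {
    data.frame(p = pts,
               tsd_len = vapply(seq_len(n), function(i)
                 .rint(spec$tsd_len_range), integer(1)),
               seq = vapply(builds, `[[`, character(1), "seq"))
  }
  # random element order over the sorted points
  if (n > 1) {
    ord <- sample.int(n)
    builds <- builds[ord]
    plan$seq <- vapply(builds, `[[`, character(1), "seq")
  }
  asm <- .assemble(background, plan)

  truth <- if (n == 0) {
    data.frame(element_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0), kind = character(0),
               tsd = character(0), subfamily_id = character(0),
               structure = character(0), ltr_len = integer(0),
               internal_len = integer(0))
  } else {
    data.frame(
      element_id = sprintf("el%03d", seq_len(n)),
      chrom = "chr1",
      start = asm$plan$start, end = asm$plan$end,
      kind = vapply(builds, `[[`, character(1), "kind"),
      tsd = asm$plan$tsd,
      subfamily_id = vapply(builds, `[[`, character(1), "subfamily"),
      structure = vapply(builds, `[[`, character(1), "structure"),
      ltr_len = vapply(builds, function(b) as.integer(b$ltr_len),
                       integer(1)),
      internal_len = vapply(builds, function(b) as.integer(b$internal_len),
                            integer(1)))
  }

  genes <- NULL
  if (!is.null(genes_bg)) {
    genes <- genes_bg
    genes$start <- as.integer(asm$lift(genes_bg$start))
    genes$end <- as.integer(asm$lift(genes_bg$end))
    genes$exon_start <- I(lapply(genes_bg$exon_start,
                                 function(v) as.integer(asm$lift(v))))
    genes$exon_end <- I(lapply(genes_bg$exon_end,
                               function(v) as.integer(asm$lift(v))))
    genes$chrom <- "chr1"
  }

  list(genome = stats::setNames(asm$seq, "chr1"),
       truth = truth, genes = genes,
       templates = templates, partner = partner,
       background = background, spec = spec)
}

#' Simulate an autonomous partner and its derived miniature element
#'
#' The partner is a large LTR retroelement from which the miniature element
#' derives by one internal deletion. A short "duplicated internal sequence"
#' sits immediately 5' of the deletion breakpoint and a near-identical copy
#' immediately 3' of it; deleting the segment between (and including) the
#' second copy yields the miniature element exactly.
#'
#' `spec$partner_spec` fields: `partner_length` (bp), `dup_seq_length` (bp),
#' `breakpoint_offset` (bp from the element 5' end at which the 5' block,
#' ending with the duplicated sequence, stops; default 130),
#' `trim_length` (default 408), `ltr_len` (default 115), `orf_aa`
#' (optional: embed a back-translated retroelement protein of this many
#' amino acids into the partner internal region).
#'
#' @param spec A [simulation_spec()] with a non-NULL `partner_spec`.
#' @return List with `partner`, `trim`, `dup_seq` (character sequences),
#'   `breakpoint` (bp, identical on miniature element and partner),
#'   `deleted_length`, `ltr_len`, and `protein` (the embedded protein or
#'   NULL).
#' @export
simulate_partner <- function(spec) {
  stopifnot(inherits(spec, "trim_sim_spec"), !is.null(spec$partner_spec))
  ps <- spec$partner_spec
  partner_len <- as.integer(ps$partner_length)
  dup_len <- as.integer(ps$dup_seq_length)
  bp <- as.integer(ps$breakpoint_offset %||% 130L)
  trim_len <- as.integer(ps$trim_length %||% 408L)
  ltr_len <- as.integer(ps$ltr_len %||% 115L)
  internal_len <- trim_len - 2L * ltr_len
  if (internal_len < 1L) stop("trim_length too small for ltr_len")
  if (dup_len >= internal_len)
    stop("dup_seq length (", dup_len, ") must be smaller than the internal ",
         "region (", internal_len, " bp)")
  if (bp <= dup_len || bp > trim_len - ltr_len)
    stop("breakpoint_offset must lie after the duplicated sequence and ",
         "before the 3' LTR")
  if (partner_len < trim_len)
    stop("partner_length must be >= trim_length")
  set.seed(.child_seed(spec$seed, "partner"))
  ltr <- .random_ltr(ltr_len, spec$gc_content)
  internal <- random_dna(internal_len, spec$gc_content)
  trim <- paste0(ltr, internal, mutate_sequence(ltr, spec$divergence))
  dup <- substr(trim, bp - dup_len + 1L, bp)
  del_len <- partner_len - trim_len
  protein <- NULL
  if (del_len == 0L) {
    partner <- trim
    dup2 <- ""
  } else {
    if (del_len < dup_len)
      stop("partner_length - trim_length must be 0 or >= dup_seq_length")
    x_len <- del_len - dup_len
    x_seq <- if (!is.null(ps$orf_aa)) {
      protein <- simulate_retro_protein(as.integer(ps$orf_aa),
                                        seed = .child_seed(spec$seed, "orf"))
      orf <- back_translate(protein)
      if (nchar(orf) > x_len - 20L)
        stop("orf_aa too large for the deleted segment (need >= ",
             nchar(orf) + 20L, " bp, have ", x_len, ")")
      pad <- x_len - nchar(orf)
      paste0(random_dna(floor(pad / 2), spec$gc_content), orf,
             random_dna(ceiling(pad / 2), spec$gc_content))
    } else {
      random_dna(x_len, spec$gc_content)
    }
    # Keep the planted structure identifiable: the second copy diverges
    # only away from the junction-defining bases (first base and last
    # three stay exact), and the base preceding the second copy must
    # differ from the base preceding the first so the copy boundaries
    # are unambiguous.
    core <- if (dup_len > 8L)
      paste0(substr(dup, 1L, 4L),
             mutate_sequence(substr(dup, 5L, dup_len - 3L),
                             min(spec$divergence, 0.04)),
             substr(dup, dup_len - 2L, dup_len))
    else dup
    dup2 <- core
    a_prev <- substr(trim, bp - dup_len, bp - dup_len)
    if (x_len > 0L && substr(x_seq, x_len, x_len) == a_prev) {
      alt <- setdiff(c("A", "C", "G", "T"), a_prev)[1L]
      substr(x_seq, x_len, x_len) <- alt
    }
    b_first <- substr(trim, bp + 1L, bp + 1L)
    if (x_len > 0L && substr(x_seq, 1L, 1L) == b_first) {
      alt <- setdiff(c("A", "C", "G", "T"), b_first)[1L]
      substr(x_seq, 1L, 1L) <- alt
    }
    partner <- paste0(substr(trim, 1L, bp), x_seq, dup2,
                      substr(trim, bp + 1L, trim_len))
  }
  list(partner = partner, trim = trim, dup_seq = dup,
       breakpoint = bp, deleted_length = del_len,
       ltr_len = ltr_len, protein = protein)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a pair of genomes with shared and genome-specific insertions
#'
#' Both genomes share one background; a fraction of the planned element
#' insertions occurs at homologous points in both genomes, the rest are
#' specific to one genome. Genome-specific insertions carry a 5-bp TSD; at
#' the orthologous point the partner genome retains the uninterrupted
#' background with a single copy of the target site.
#'
#' @param spec A [simulation_spec()]; `n_trims` is the per-genome element
#'   count.
#' @param shared_fraction Fraction (0-1) of each genome's insertions that
#'   are shared.
#' @return List with `genome_a`, `genome_b` (named character vectors),
#'   `truth_a`, `truth_b` (as in [simulate_genome()] plus a `shared`
#'   column), and `templates`.
#' @export
make_genome_pair <- function(spec, shared_fraction) {
  stopifnot(inherits(spec, "trim_sim_spec"),
            shared_fraction >= 0, shared_fraction <= 1)
  set.seed(spec$seed)
  background <- random_dna(spec$genome_length, spec$gc_content)
  templates <- .subfamily_templates(spec)
  n <- spec$n_trims
  n_shared <- round(shared_fraction * n)
  n_spec <- n - n_shared
  total <- n_shared + 2L * n_spec
  pts <- .place_insertions(spec, total)
  role <- sample(rep(c("shared", "a", "b"), c(n_shared, n_spec, n_spec)))
  build_one <- function(idx) {
    si <- 1L + (idx - 1L) %% spec$n_subfamilies
    .element_copy(templates[[si]], spec$divergence)
  }
  copies <- lapply(seq_len(total), build_one)
  mk <- function(which_g) {
    keep <- role %in% c("shared", which_g)
    plan <- data.frame(p = pts[keep], tsd_len = 5L,
                       seq = vapply(copies[keep], `[[`, character(1), "seq"))
    asm <- .assemble(background, plan)
    truth <- data.frame(
      element_id = sprintf("%s_el%03d", which_g, seq_len(sum(keep))),
      chrom = "chr1", start = asm$plan$start, end = asm$plan$end,
      kind = "complete", tsd = asm$plan$tsd,
      subfamily_id = vapply(which(keep), function(i)
        templates[[1L + (i - 1L) %% spec$n_subfamilies]]$id, character(1)),
      structure = "L2I1",
      ltr_len = vapply(copies[keep], function(b) as.integer(b$ltr_len),
                       integer(1)),
      internal_len = vapply(copies[keep], function(b)
        as.integer(b$internal_len), integer(1)),
      shared = role[keep] == "shared",
      bg_point = pts[keep])
    list(genome = stats::setNames(asm$seq, "chr1"), truth = truth)
  }
  a <- mk("a"); b <- mk("b")
  list(genome_a = a$genome, genome_b = b$genome,
       truth_a = a$truth, truth_b = b$truth, templates = templates)
}

#' Simulate a retroelement-like protein
#'
#' Random amino-acid sequence (uniform over the 20 standard residues after
#' an initial methionine), used as a stand-in retrotransposase for
#' coding-capacity tests. Synthetic: it has no real protein homology.
#'
#' @param n_aa Protein length in amino acids.
#' @param seed Integer seed.
#' @return Character scalar of amino acids.
#' @export
simulate_retro_protein <- function(n_aa, seed = 1L) {
  set.seed(seed)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste0("M", paste(sample(aas, n_aa - 1L, replace = TRUE), collapse = ""))
}

#' Back-translate a protein to DNA
#'
#' Picks a synonymous codon uniformly at random per residue (standard
#' genetic code), yielding an open reading frame with no internal stops.
#'
#' @param protein Character scalar of amino acids.
#' @return Character scalar of DNA, length `3 * nchar(protein)`.
#' @export
back_translate <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), gc)
  aa <- strsplit(protein, "")[[1]]
  bad <- setdiff(aa, names(by_aa))
  if (length(bad)) stop("unknown residues: ", paste(bad, collapse = ","))
  paste(vapply(aa, function(a) {
    cods <- by_aa[[a]]
    if (length(cods) == 1) cods else sample(cods, 1L)
  }, character(1)), collapse = "")
}
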