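# Synthetic-data generator: ground-truth structure, determinism, and the
# reconstruction property.

test_that("empty spec yields a bare background and determinism holds", {
  spec <- simulation_spec(genome_length = 20000, n_trims = 0,
                          n_genes = 0, seed = 11)
  sim <- simulate_genome(spec)
  expect_equal(nrow(sim$truth), 0)
  expect_equal(nchar(sim$genome[["chr1"]]), 20000)
  sim2 <- simulate_genome(spec)
  expect_identical(sim$genome, sim2$genome)
  expect_identical(sim$truth, sim2$truth)
})

test_that("implanted elements have the promised anatomy", {
  spec <- simulation_spec(genome_length = 80000, n_trims = 12,
                          n_solo_ltrs = 2, divergence = 0, seed = 3)
  sim <- simulate_genome(spec)
  g <- sim$genome[["chr1"]]
  comp <- sim$truth[sim$truth$kind == "complete", ]
  expect_equal(nrow(comp), 12)
  for (i in seq_len(nrow(comp))) {
    el <- substr(g, comp$start[i], comp$end[i])
    L <- comp$ltr_len[i]
    # divergence 0: the two LTR substrings are exactly equal
    expect_identical(substr(el, 1, L),
                     substr(el, nchar(el) - L + 1, nchar(el)))
    # both TSD copies identical and flanking
    tl <- nchar(comp$tsd[i])
    expect_identical(substr(g, comp$start[i] - tl, comp$start[i] - 1),
                     comp$tsd[i])
    expect_identical(substr(g, comp$end[i] + 1, comp$end[i] + tl),
                     comp$tsd[i])
    expect_true(tl >= 4 && tl <= 6)
  }
  solo <- sim$truth[sim$truth$kind == "solo_ltr", ]
  expect_equal(solo$end - solo$start + 1, solo$ltr_len)
})

test_that("deleting every element plus one TSD copy recovers background", {
  spec <- simulation_spec(genome_length = 50000, n_trims = 6,
                          divergence = 0.05, seed = 9)
  sim <- simulate_genome(spec)
  g <- sim$genome[["chr1"]]
  tr <- sim$truth[order(-sim$truth$start), ]
  for (i in seq_len(nrow(tr))) {
    tl <- nchar(tr$tsd[i])
    g <- paste0(substr(g, 1, tr$start[i] - 1),
                substr(g, tr$end[i] + tl + 1, nchar(g)))
  }
  expect_identical(g, sim$background)
})

test_that("an oversized request raises a sizing error naming the deficit", {
  spec <- simulation_spec(genome_length = 5000, n_trims = 40, seed = 1)
  expect_error(simulate_genome(spec), "genome too small.*deficit")
})

test_that("simulate_partner builds the deletion geometry exactly", {
  spec <- simulation_spec(seed = 4, divergence = 0.02,
                          partner_spec = list(partner_length = 8504,
                                              dup_seq_length = 25,
                                              breakpoint_offset = 130,
                                              trim_length = 408,
                                              ltr_len = 115))
  p <- simulate_partner(spec)
  expect_equal(nchar(p$dup_seq), 25)
  expect_equal(nchar(p$partner), 8504)
  expect_equal(nchar(p$trim), 408)
  # partner minus derived element equals the deleted segment
  expect_equal(nchar(p$partner) - nchar(p$trim), p$deleted_length)
  # the copy 5' of the breakpoint is the reported dup_seq
  expect_identical(substr(p$partner, p$breakpoint - 24, p$breakpoint),
                   p$dup_seq)
  # zero-length deletion: derived element equals the partner
  spec0 <- simulation_spec(seed = 4,
                           partner_spec = list(partner_length = 408,
                                               dup_seq_length = 25,
                                               breakpoint_offset = 130,
                                               trim_length = 408,
                                               ltr_len = 115))
  p0 <- simulate_partner(spec0)
  expect_identical(p0$partner, p0$trim)
  # dup longer than the internal region errors
  specbad <- simulation_spec(seed = 4,
                             partner_spec = list(partner_length = 1000,
                                                 dup_seq_length = 200,
                                                 breakpoint_offset = 250,
                                                 trim_length = 408,
                                                 ltr_len = 115))
  expect_error(simulate_partner(specbad), "dup_seq length")
})

test_that("genome pairs share and segregate insertions as requested", {
  spec <- simulation_spec(genome_length = 150000, n_trims = 10,
                          divergence = 0.01, seed = 6, min_flank = 1200)
  all_shared <- make_genome_pair(spec, shared_fraction = 1)
  expect_equal(sum(!all_shared$truth_a$shared), 0)
  expect_equal(sum(!all_shared$truth_b$shared), 0)

  none <- make_genome_pair(spec, shared_fraction = 0)
  expect_equal(sum(!none$truth_a$shared) + sum(!none$truth_b$shared), 20)
  # a genome-specific insertion is absent in the partner genome: the
  # orthologous site keeps one target-site copy with contiguous flanks
  ta <- none$truth_a[!none$truth_a$shared, ][1, ]
  ga <- none$genome_a[["chr1"]]
  left <- substr(ga, ta$start - 60 - nchar(ta$tsd), ta$start - 1)
  right <- substr(ga, ta$end + nchar(ta$tsd) + 1, ta$end + nchar(ta$tsd) + 60)
  empty_site <- paste0(left, right)
  expect_true(grepl(empty_site, none$genome_b[["chr1"]], fixed = TRUE))
  # and the element itself is absent from the partner genome
  el <- substr(ga, ta$start, ta$end)
  expect_false(grepl(el, none$genome_b[["chr1"]], fixed = TRUE))
})

test_that("methylome emission matches configured rates and determinism", {
  spec <- simulation_spec(genome_length = 40000, n_trims = 6,
                          n_subfamilies = 3, divergence = 0.01, seed = 2)
  sim <- simulate_genome(spec)
  els <- sim$truth[sim$truth$kind == "complete", ]
  types <- c(SF01 = "I", SF02 = "II", SF03 = "III")
  mc <- emit_methylome(sim$genome, els, types, seed = 7)
  expect_identical(mc, emit_methylome(sim$genome, els, types, seed = 7))
  expect_true(all(mc$mC <= mc$total))
  # Type III body: CHH stays at the low rate
  e3 <- els[els$subfamily_id == "SF03", ][1, ]
  chh <- weighted_level(e3, mc, "CHH")
  expect_lt(chh, 0.1)
  # body rates converge to configured rates within 3 binomial SE
  e1 <- els[els$subfamily_id == "SF01", ][1, ]
  sel <- mc$pos >= e1$start & mc$pos <= e1$end
  ntot <- sum(mc$total[sel])
  se <- sqrt(0.85 * 0.15 / ntot)
  expect_lt(abs(weighted_level(e1, mc, "CG") - 0.85), 3 * se + 1e-9)
  # zero coverage mean gives an empty table
  expect_equal(nrow(emit_methylome(sim$genome, els, types,
                                   coverage_mean = 0, seed = 1)), 0)
})

test_that("unknown context symbols in a methylation file are rejected", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tstrand\tcontext\tmC\ttotal",
               "chr1\t10\t+\tCXG\t1\t2"), f)
  expect_error(read_methylation_tsv(f), "unknown methylation context")
})
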