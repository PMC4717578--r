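# The three TRIM-defining criteria and their supporting operations.

make_two_copy_genome <- function(seed = 1, divergence = 0,
                                 n_copies = 2, ltr_bp = 120,
                                 internal_bp = 300) {
  set.seed(seed)
  ltr <- paste0("TG", random_dna(ltr_bp - 4), "CA")
  el <- paste0(ltr, random_dna(internal_bp), ltr)
  host <- random_dna(8000 * (n_copies + 1))
  tsds <- c("AACAT", "GGGTT", "CTTCA", "ATAAT")[seq_len(n_copies)]
  coords <- list()
  g <- host
  for (i in rev(seq_len(n_copies))) {  # right to left keeps coords stable
    el_i <- mutate_sequence(el, divergence)
    im <- implant(g, 6000 * i, el_i, tsds[i])
    g <- im$seq
  }
  list(genome = c(chr1 = g), element = el, ltr = ltr)
}

test_that("solo LTRs are found apart from candidate LTR pairs", {
  fix <- make_two_copy_genome(seed = 2, n_copies = 1)
  g <- fix$genome[[1]]
  im <- implant(g, 2000, fix$ltr, "TTGCA")  # one solo LTR
  genome <- c(chr1 = im$seq)
  cands <- scan_genome(genome)
  expect_equal(nrow(cands), 1)
  solos <- find_solo_ltrs(genome, fix$ltr, candidates = cands)
  expect_equal(nrow(solos), 1)
  expect_equal(solos$start, im$start)
  expect_identical(solos$tsd, "TTGCA")

  # no solo LTR present: empty (candidates from the same genome)
  cands0 <- scan_genome(fix$genome)
  solos0 <- find_solo_ltrs(fix$genome, fix$ltr, candidates = cands0)
  expect_equal(nrow(solos0), 0)

  # a 30%-diverged copy is below the identity floor
  set.seed(3)
  far <- mutate_sequence(fix$ltr, 0.30)
  im2 <- implant(g, 2000, far, "TTGCA")
  solos2 <- find_solo_ltrs(c(chr1 = im2$seq), fix$ltr,
                           candidates = cands)
  expect_equal(nrow(solos2), 0)
})

test_that("coding capacity triggers on an embedded retro protein only", {
  prot <- simulate_retro_protein(400, seed = 5)
  frag <- substr(prot, 50, 199)  # 150-aa fragment
  set.seed(6)
  embedded <- paste0(random_dna(200), back_translate(frag),
                     random_dna(150))
  expect_true(coding_capacity(embedded, prot)$coding)
  set.seed(7)
  expect_false(coding_capacity(random_dna(800), prot)$coding)
  # empty protein set is false by definition
  expect_false(coding_capacity(embedded, character(0))$coding)
  # too short to host a 100-aa ORF
  expect_false(coding_capacity(random_dna(250), prot)$coding)
})

test_that("each defining criterion rejects its violating fixture", {
  # (1a) size >= 1500
  set.seed(11)
  ltr <- paste0("TG", random_dna(296), "CA")
  big <- paste0(ltr, random_dna(1000), ltr)  # 1600 bp
  host <- random_dna(20000)
  im1 <- implant(host, 5000, big, "AATCG")
  im2 <- implant(im1$seq, 12000, mutate_sequence(big, 0.01), "GGTAC")
  cands <- scan_genome(c(chr1 = im2$seq))
  res <- apply_trim_criteria(cands, c(chr1 = im2$seq))
  expect_equal(nrow(res$elements), 0)
  expect_true(all(res$rejected$reason == "size_ge_1500"))

  # (2) single copy, no solo LTR
  fix <- make_two_copy_genome(seed = 12, n_copies = 1)
  cands <- scan_genome(fix$genome)
  res <- apply_trim_criteria(cands, fix$genome)
  expect_equal(nrow(res$elements), 0)
  expect_equal(res$rejected$reason, "single_copy")

  # (2) two copies with different TSDs pass as multi_complete
  fix2 <- make_two_copy_genome(seed = 13, n_copies = 2)
  cands2 <- scan_genome(fix2$genome)
  res2 <- apply_trim_criteria(cands2, fix2$genome)
  expect_equal(nrow(res2$elements), 2)
  expect_true(all(res2$elements$copy_support == "multi_complete"))

  # (2) identical TSDs count as one supporting copy -> rejected
  set.seed(14)
  ltr3 <- paste0("TG", random_dna(116), "CA")
  el3 <- paste0(ltr3, random_dna(300), ltr3)
  host3 <- random_dna(20000)
  j1 <- implant(host3, 5000, el3, "CCATG")
  j2 <- implant(j1$seq, 14000, el3, "CCATG")
  cands3 <- scan_genome(c(chr1 = j2$seq))
  expect_equal(nrow(cands3), 2)
  res3 <- apply_trim_criteria(cands3, c(chr1 = j2$seq))
  expect_equal(nrow(res3$elements), 0)
  expect_true(all(res3$rejected$reason == "single_copy"))

  # (3) embedded retrotransposase
  prot <- simulate_retro_protein(400, seed = 15)
  set.seed(16)
  ltr4 <- paste0("TG", random_dna(96), "CA")
  el4 <- paste0(ltr4, back_translate(substr(prot, 1, 150)),
                random_dna(100), ltr4)
  host4 <- random_dna(20000)
  k1 <- implant(host4, 5000, el4, "AAGTC")
  k2 <- implant(k1$seq, 14000, mutate_sequence(el4, 0.01), "TTCAG")
  cands4 <- scan_genome(c(chr1 = k2$seq))
  res4 <- apply_trim_criteria(cands4, c(chr1 = k2$seq), prot)
  expect_equal(nrow(res4$elements), 0)
  expect_true(all(res4$rejected$reason == "retrotransposase"))
})

test_that("retained plus rejected partitions the input, and support is
           monotone in copy number", {
  spec <- simulation_spec(genome_length = 90000, n_trims = 8,
                          n_subfamilies = 2, divergence = 0.02, seed = 19)
  sim <- simulate_genome(spec)
  cands <- scan_genome(sim$genome)
  res <- apply_trim_criteria(cands, sim$genome)
  expect_equal(nrow(res$elements) + nrow(res$rejected), nrow(cands))
  expect_gt(nrow(res$elements), 0)
  # every retained element satisfies the criteria directly
  g <- sim$genome[["chr1"]]
  for (i in seq_len(nrow(res$elements))) {
    e <- res$elements[i, ]
    sq <- substr(g, e$start, e$end)
    expect_lt(nchar(sq), 1500)
    expect_false(grepl("N", sq, fixed = TRUE))
    expect_false(is.na(e$tsd))
  }
  # single-copy fixture: adding a diverged second copy with a different
  # TSD flips rejection into retention (monotonicity)
  fix1 <- make_two_copy_genome(seed = 23, n_copies = 1)
  c1 <- scan_genome(fix1$genome)
  r1 <- apply_trim_criteria(c1, fix1$genome)
  expect_equal(nrow(r1$elements), 0)
  fix2 <- make_two_copy_genome(seed = 23, n_copies = 2,
                               divergence = 0.01)
  c2 <- scan_genome(fix2$genome)
  r2 <- apply_trim_criteria(c2, fix2$genome)
  expect_equal(nrow(r2$elements), 2)
})

test_that("one complete copy plus one solo LTR satisfies criterion 2", {
  fix <- make_two_copy_genome(seed = 29, n_copies = 1)
  im <- implant(fix$genome[[1]], 2500, fix$ltr, "GTACA")
  genome <- c(chr1 = im$seq)
  cands <- scan_genome(genome)
  expect_equal(nrow(cands), 1)
  res <- apply_trim_criteria(cands, genome)
  expect_equal(nrow(res$elements), 1)
  expect_equal(res$elements$copy_support, "complete_plus_solo")
})
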