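# Autonomous partners, deletion breakpoints, coding autonomy and
# two-genome insertion polymorphisms.

partner_sim <- function(seed, divergence = 0.02, orf_aa = NULL) {
  simulate_genome(simulation_spec(
    genome_length = 120000, n_trims = 4, divergence = divergence,
    seed = seed,
    partner_spec = list(partner_length = 8504, dup_seq_length = 25,
                        breakpoint_offset = 130, trim_length = 408,
                        ltr_len = 115, orf_aa = orf_aa)))
}

test_that("a planted partner with the published geometry is found", {
  sim <- partner_sim(seed = 9)
  p <- sim$partner
  pf <- find_partners(p$trim, p$ltr_len, sim$genome)
  tr <- sim$truth[sim$truth$kind == "partner", ]
  expect_equal(nrow(pf), 1)
  expect_lt(abs(pf$start - tr$start), 10)
  expect_lt(abs(pf$end - tr$end), 10)
  expect_gt(pf$ltr_identity_to_trim, 0.9)
  # a genome without large elements yields nothing
  spec0 <- simulation_spec(genome_length = 60000, n_trims = 3,
                           divergence = 0.02, seed = 10)
  sim0 <- simulate_genome(spec0)
  expect_equal(nrow(find_partners(p$trim, p$ltr_len, sim0$genome)), 0)
  # heavily diverged LTRs fall below the identity floor
  set.seed(11)
  far_ltr <- mutate_sequence(substr(p$trim, 1, 115), 0.40)
  far_trim <- paste0(far_ltr, substr(p$trim, 116, 293),
                     mutate_sequence(far_ltr, 0.02))
  expect_equal(nrow(find_partners(far_trim, 115, sim$genome)), 0)
})

test_that("breakpoint and duplicated internal sequence round-trip", {
  for (sd in c(9, 12, 15)) {
    sim <- partner_sim(seed = sd)
    tr <- sim$truth[sim$truth$kind == "partner", ]
    partner_g <- substr(sim$genome[["chr1"]], tr$start, tr$end)
    bk <- locate_breakpoint(sim$partner$trim, partner_g)
    expect_true(bk$found)
    expect_lte(abs(bk$breakpoint - sim$partner$breakpoint), 3)
    expect_identical(bk$dup_seq, sim$partner$dup_seq)
    expect_equal(bk$dup_len, 25)
  }
})

test_that("degenerate breakpoint inputs are refused cleanly", {
  spec <- simulation_spec(seed = 2,
                          partner_spec = list(partner_length = 408,
                                              dup_seq_length = 25,
                                              breakpoint_offset = 130,
                                              trim_length = 408,
                                              ltr_len = 115))
  p <- simulate_partner(spec)
  # no deletion: partner equals the element
  bk <- locate_breakpoint(p$trim, p$partner)
  expect_false(bk$found)
  # unrelated sequences: no homology
  set.seed(3)
  bk2 <- locate_breakpoint(random_dna(400), random_dna(8000))
  expect_false(bk2$found)
})

test_that("dup copies below the identity floor are reported absent", {
  # hand-built: 5' block + deletion whose dup copy is ~88% identical
  set.seed(21)
  ltr <- paste0("TG", random_dna(111), "CA")
  a <- random_dna(12); dup <- random_dna(25); b <- random_dna(140)
  trim <- paste0(ltr, a, dup, b, mutate_sequence(ltr, 0.01))
  x <- random_dna(4000)
  dup_far <- mutate_sequence(dup, 0.12)   # ~3 substitutions: < 90%
  partner <- paste0(ltr, a, dup, x, dup_far, b,
                    mutate_sequence(ltr, 0.01))
  bk <- locate_breakpoint(trim, partner)
  expect_true(bk$found)
  if (bk$dup_len > 0) expect_gte(bk$dup_identity, 0.90)
})

test_that("coding autonomy needs a near-full-length retrotransposase", {
  sim_full <- partner_sim(seed = 17, orf_aa = 1409)
  tr <- sim_full$truth[sim_full$truth$kind == "partner", ]
  partner_g <- substr(sim_full$genome[["chr1"]], tr$start, tr$end)
  au <- classify_autonomy(partner_g, sim_full$partner$protein)
  expect_identical(au$autonomy, "putative_autonomous")
  expect_gte(au$longest_orf_aa, 1409)

  # a ~400-aa truncated ORF is non-autonomous
  prot400 <- simulate_retro_protein(400, seed = 18)
  set.seed(18)
  partner_short <- paste0(random_dna(1500), back_translate(prot400),
                          random_dna(1500))
  au2 <- classify_autonomy(partner_short, prot400)
  expect_identical(au2$autonomy, "non_autonomous")
  expect_lt(au2$longest_orf_aa, 900)

  # random sequence is non-autonomous
  set.seed(19)
  au3 <- classify_autonomy(random_dna(5000), prot400)
  expect_identical(au3$autonomy, "non_autonomous")

  # monotone in ORF length: extending the embedded ORF cannot flip an
  # autonomous call off
  prot950 <- simulate_retro_protein(950, seed = 20)
  set.seed(20)
  p950 <- paste0(random_dna(500), back_translate(prot950),
                 random_dna(500))
  a950 <- classify_autonomy(p950, prot950)
  expect_identical(a950$autonomy, "putative_autonomous")
  prot1300 <- paste0(prot950, substr(simulate_retro_protein(351,
                                                            seed = 21), 2,
                                     351))
  set.seed(21)
  p1300 <- paste0(random_dna(500), back_translate(prot1300),
                  random_dna(500))
  a1300 <- classify_autonomy(p1300, prot950)
  expect_identical(a1300$autonomy, "putative_autonomous")
})

test_that("polymorphic insertions are called with their 5-bp TSDs and
           shared ones are not", {
  spec <- simulation_spec(genome_length = 250000, n_trims = 12,
                          divergence = 0.01, seed = 25, min_flank = 1200)
  pair <- make_genome_pair(spec, shared_fraction = 0.5)
  calls <- call_polymorphic_insertions(pair$genome_a, pair$genome_b,
                                       pair$truth_a)
  spec_rows <- !pair$truth_a$shared
  expect_true(all(calls$status[spec_rows] == "polymorphic"))
  expect_true(all(calls$status[!spec_rows] == "shared"))
  tsds <- calls$tsd[calls$status == "polymorphic"]
  expect_true(all(nchar(tsds) == 5))
  # the reported empty-site copy equals the planted target site
  expect_identical(tsds, pair$truth_a$tsd[spec_rows])

  # symmetry: swapping genome roles yields the b-specific set
  calls_b <- call_polymorphic_insertions(pair$genome_b, pair$genome_a,
                                         pair$truth_b)
  expect_equal(sum(calls_b$status == "polymorphic"),
               sum(!pair$truth_b$shared))
  expect_true(all(calls_b$status[!pair$truth_b$shared] == "polymorphic"))
})
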