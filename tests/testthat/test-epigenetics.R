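# Methylation calls, weighted levels, metaprofiles, sRNA abundance and
# epigenetic typing.

test_that("binomial methylation calls match the closed-form tail", {
  counts <- data.frame(mC = c(5, 0, 1), total = c(5, 5, 5))
  calls <- call_methylated_cytosines(counts, 0.01)
  # 5/5 at rate 0.01: raw tail 1e-10, survives any correction
  expect_true(calls[1])
  expect_false(calls[2])  # mC = 0 is never methylated
  expect_false(calls[3])
  # zero-coverage positions are skipped (NA)
  counts2 <- data.frame(mC = c(0, 3), total = c(0, 3))
  calls2 <- call_methylated_cytosines(counts2, 0.01)
  expect_true(is.na(calls2[1]))
  # null fixture: false-call rate stays at the FDR level
  set.seed(3)
  null <- data.frame(total = rpois(2000, 20))
  null$mC <- rbinom(nrow(null), null$total, 0.01)
  fc <- call_methylated_cytosines(null, 0.01)
  expect_lte(mean(fc, na.rm = TRUE), 0.01)
})

test_that("weighted level is the pooled count ratio and pools across
           splits", {
  counts <- data.frame(chrom = "c", pos = c(10, 20), strand = "+",
                       context = "CG", mC = c(3, 1), total = c(4, 4))
  r <- weighted_level(list(chrom = "c", start = 1, end = 100), counts,
                      "CG")
  expect_equal(r, 0.5)  # (3+1)/(4+4), not the mean of 0.75 and 0.25
  # all mC == total
  counts2 <- transform(counts, mC = total)
  expect_equal(weighted_level(list(chrom = "c", start = 1, end = 100),
                              counts2, "CG"), 1.0)
  # empty region is NA
  expect_true(is.na(weighted_level(list(chrom = "c", start = 200,
                                        end = 300), counts, "CG")))
  # split-and-recombine invariance with count weights
  left <- weighted_level(list(chrom = "c", start = 1, end = 15), counts,
                         "CG")
  right <- weighted_level(list(chrom = "c", start = 16, end = 100),
                          counts, "CG")
  ct <- function(a, b) sum(counts$total[counts$pos >= a &
                                          counts$pos <= b])
  pooled <- (left * ct(1, 15) + right * ct(16, 100)) / ct(1, 100)
  expect_equal(pooled, r)
})

test_that("metaprofiles recover flat and bordered patterns", {
  spec <- simulation_spec(genome_length = 50000, n_trims = 4,
                          n_subfamilies = 1, divergence = 0.01, seed = 4)
  sim <- simulate_genome(spec)
  els <- sim$truth
  # uniform methylome at the background rate: all cells near 0.05
  mc_u <- emit_methylome(sim$genome, els[0, ], character(0), seed = 5)
  mp_u <- metaprofile(els, mc_u)
  for (ctx in names(mp_u)) {
    cells <- mp_u[[ctx]][1, ]
    expect_lt(abs(mean(cells, na.rm = TRUE) - 0.05), 0.01)
    expect_true(all(abs(cells - 0.05) < 0.10, na.rm = TRUE))
  }
  # Type I fixture: sharp body/flank CHH contrast
  mc_1 <- emit_methylome(sim$genome, els, c(SF01 = "I"), seed = 6)
  mp_1 <- metaprofile(els, mc_1)
  body <- mean(mp_1$CHH[1, 21:40], na.rm = TRUE)
  flank <- mean(mp_1$CHH[1, c(1:20, 41:60)], na.rm = TRUE)
  expect_gt(body - flank, 0.3)
  # single element: matrix equals that element's own binned levels
  mp_one <- metaprofile(els[1, ], mc_1)
  e <- els[1, ]
  third_bin <- list(chrom = e$chrom,
                    start = e$start + floor(2 / 20 * (e$end - e$start + 1)),
                    end = e$start + ceiling(3 / 20 * (e$end - e$start + 1)) - 1)
  expect_equal(mp_one$CG[1, "body3"],
               weighted_level(third_bin, mc_1, "CG"),
               tolerance = 0.15)
})

test_that("sRNA abundance follows the TPM formula with 1/k multi-mapping
           weights", {
  els <- data.frame(element_id = "e1", chrom = "chr1", start = 1000,
                    end = 1200)
  # 10 overlapping 24-nt reads among 1,000 total: TPM = 10,000
  reads <- data.frame(chrom = "chr1",
                      start = c(seq(1010, 1190, by = 20), seq(5000, by = 30,
                                                              length.out = 990)),
                      length = 24L, n_loci = 1L)
  reads$end <- reads$start + reads$length - 1L
  ab <- srna_abundance(els, reads)
  expect_equal(ab$tpm24, 10 * 1e6 / 1000)
  expect_equal(ab$tpm21, 0)
  # no overlap: zero
  ab0 <- srna_abundance(data.frame(element_id = "e2", chrom = "chr1",
                                   start = 90000, end = 90100), reads)
  expect_equal(ab0$tpm24, 0)
  # a read at 2 loci contributes 1/2 per locus
  reads2 <- data.frame(chrom = "chr1", start = c(1010, 3000),
                       length = 24L, n_loci = 2L)
  reads2$end <- reads2$start + 23L
  ab2 <- srna_abundance(els, reads2)
  expect_equal(ab2$tpm24, 0.5 * 1e6 / 1)
})

test_that("family typing recovers simulated types and is stable on
           degenerate input", {
  spec <- simulation_spec(genome_length = 100000, n_trims = 9,
                          n_subfamilies = 3, divergence = 0.01, seed = 8,
                          min_flank = 2600)
  sim <- simulate_genome(spec)
  els <- sim$truth[sim$truth$kind == "complete", ]
  types <- c(SF01 = "I", SF02 = "II", SF03 = "III")
  mc <- emit_methylome(sim$genome, els, types, seed = 9)
  reads <- emit_srna(sim$genome, els, types, seed = 9)
  et <- family_epitypes(els, mc, reads)
  expect_identical(stats::setNames(et$type, et$subfamily_id)[names(types)],
                   types)
  # all-zero methylation and no sRNA: deterministic fallback class
  t0 <- classify_family_type(c(CG = 0, CHG = 0, CHH = 0),
                             c(CG = 0, CHG = 0, CHH = 0), 0)
  expect_identical(t0, "II")
  tna <- classify_family_type(c(CG = NA, CHG = 0, CHH = 0),
                              c(CG = 0, CHG = 0, CHH = 0), 0)
  expect_identical(tna, "unclassified")
})

test_that("gene methylation classes follow the rule set", {
  mk_counts <- function(cg, chg, chh, n = 40) {
    data.frame(chrom = "c", pos = seq_len(3 * n), strand = "+",
               context = rep(c("CG", "CHG", "CHH"), each = n),
               mC = c(rbinom(n, 20, cg), rbinom(n, 20, chg),
                      rbinom(n, 20, chh)),
               total = 20L)
  }
  gene <- list(chrom = "c", start = 1, end = 200)
  set.seed(11)
  expect_identical(
    classify_gene_methylation(gene, mk_counts(0.6, 0.01, 0.01)),
    "CG_body_methylated")
  expect_identical(
    classify_gene_methylation(gene, mk_counts(0.05, 0.01, 0.30)),
    "C_methylated")
  expect_identical(
    classify_gene_methylation(gene, mk_counts(0, 0, 0)),
    "unmethylated")
  empty <- mk_counts(0, 0, 0)[0, ]
  expect_identical(classify_gene_methylation(gene, empty), "uncallable")
})

test_that("host genes of CG-only elements read as CG-body-methylated
           and hosts of all-context elements as C-methylated", {
  spec <- simulation_spec(genome_length = 150000, n_trims = 6,
                          n_subfamilies = 2, n_genes = 12,
                          ltr_len_range = c(200, 300),
                          internal_len_range = c(1200, 1600),
                          divergence = 0.01, seed = 23,
                          place_in = "introns")
  sim <- simulate_genome(spec)
  els <- sim$truth[sim$truth$kind == "complete", ]
  types <- c(SF01 = "III", SF02 = "I")
  mc <- emit_methylome(sim$genome, els, types, seed = 24)
  ctx <- classify_insertions(els, sim$genes)
  hosts <- split(els$subfamily_id[!is.na(ctx$gene_id)],
                 ctx$gene_id[!is.na(ctx$gene_id)])
  for (gid in names(hosts)) {
    gene <- sim$genes[sim$genes$gene_id == gid, ]
    cls <- classify_gene_methylation(gene, mc)
    if (any(hosts[[gid]] == "SF02")) {
      # any all-context (Type I) element drives non-CG methylation
      expect_identical(cls, "C_methylated")
    } else {
      expect_identical(cls, "CG_body_methylated")
    }
  }
})
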