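# Genic context, TRG statistics, densities, gene capture, Ka/Ks.

make_genic_sim <- function(seed = 5, place = "introns", n_trims = 10) {
  spec <- simulation_spec(genome_length = 150000, n_trims = n_trims,
                          n_genes = 15, divergence = 0.02, seed = seed,
                          place_in = place)
  simulate_genome(spec)
}

test_that("insertion categories follow the precedence and dedup rule", {
  sim <- make_genic_sim(seed = 5)
  g <- sim$genes[1, ]
  tss <- if (g$strand == "+") g$start else g$end
  exon1 <- c(g$exon_start[[1]][1], g$exon_end[[1]][1])

  hits <- data.frame(
    chrom = "chr1",
    start = c(exon1[1] + 5,                  # fully inside an exon
              exon1[2] - 10,                 # spans exon/intron boundary
              if (g$strand == "+") g$start - 800 else g$end + 700,
              if (g$strand == "+") g$start - 1600 else g$end + 1550),
    end = c(exon1[1] + 60,
            exon1[2] + 40,
            if (g$strand == "+") g$start - 700 else g$end + 800,
            if (g$strand == "+") g$start - 1550 else g$end + 1600))
  ctx <- classify_insertions(hits, sim$genes)
  expect_equal(ctx$category[1], "exon")
  expect_equal(ctx$category[2], "exon")     # boundary-spanning: one exon
  expect_equal(ctx$category[3], "upstream_1500")
  expect_equal(ctx$category[4], "intergenic")  # beyond the 1.5-kb window
  # dedup: every hit has exactly one category
  expect_equal(nrow(ctx), nrow(hits))
  expect_true(all(table(ctx$hit_id) == 1))
  # category percentages over hits sum to 100
  pc <- 100 * table(ctx$category) / nrow(ctx)
  expect_equal(sum(pc), 100, tolerance = 1e-9)
})

test_that("genes annotated without exons raise an annotation error", {
  sim <- make_genic_sim(seed = 6)
  bad <- sim$genes
  bad$exon_start[[1]] <- integer(0)
  bad$exon_end[[1]] <- integer(0)
  hits <- data.frame(chrom = "chr1", start = 1000, end = 1100)
  expect_error(classify_insertions(hits, bad), "without exon")
})

test_that("element-bearing genes in an enriched design test larger", {
  sim <- make_genic_sim(seed = 7, place = "large_genes", n_trims = 12)
  hits <- sim$truth[sim$truth$kind == "complete", ]
  ctx <- classify_insertions(hits, sim$genes)
  ts <- trg_stats(ctx, sim$genes)
  gl <- ts$tests[ts$tests$metric == "gene_length", ]
  expect_gt(gl$trg_mean, gl$ntrg_mean)
  expect_lt(gl$p_value, 0.05)
  # an element-free genome has an empty TRG set
  spec0 <- simulation_spec(genome_length = 80000, n_trims = 0,
                           n_genes = 10, seed = 8)
  sim0 <- simulate_genome(spec0)
  ctx0 <- classify_insertions(
    data.frame(chrom = character(0), start = integer(0),
               end = integer(0)), sim0$genes)
  expect_warning(ts0 <- trg_stats(ctx0, sim0$genes), "fewer than 2")
  expect_equal(sum(ts0$genes$class == "TRG"), 0)
})

test_that("size-class density reproduces published worked-example
           arithmetic", {
  # large genes: 1,554 insertions over 9,273 genes covering 84,971 kb
  large <- density_from_counts(9273, 84971, 1554, "large")
  expect_equal(large$insertions_per_gene, 0.17)
  expect_equal(large$insertions_per_kb, 0.0183)
  # small genes: 21 insertions over 9,273 genes covering 7,621 kb
  small <- density_from_counts(9273, 7621, 21, "small")
  expect_equal(small$insertions_per_kb, 0.0028)
  # per-kb ratio ~6.5; per-gene ratio ~74
  expect_equal(round(large$insertions_per_kb /
                       small$insertions_per_kb, 1), 6.5)
  expect_equal(round(1554 / 21), 74)
})

test_that("size-class density handles simulated data and zero counts", {
  sim <- make_genic_sim(seed = 9)
  hits <- sim$truth[sim$truth$kind == "complete", ]
  ctx <- classify_insertions(hits, sim$genes)
  d <- size_class_density(ctx, sim$genes)
  expect_equal(sum(d$table$insertions),
               sum(ctx$category %in% c("exon", "intron")))
  expect_equal(sum(d$table$n_genes), nrow(sim$genes))
  # no insertions: densities 0 and NA ratios
  ctx0 <- ctx[0, ]
  d0 <- size_class_density(ctx0, sim$genes)
  expect_true(all(d0$table$insertions_per_gene == 0))
  expect_true(is.na(d0$ratios$per_gene))
})

test_that("gene capture distinguishes spliced from genomic fragments", {
  sim <- make_genic_sim(seed = 12)
  multi <- sim$genes[vapply(sim$genes$exon_start, length,
                            integer(1)) >= 3, ][1, ]
  g <- sim$genome[["chr1"]]
  exons <- vapply(seq_along(multi$exon_start[[1]]), function(k)
    substr(g, multi$exon_start[[1]][k], multi$exon_end[[1]][k]),
    character(1))
  spliced <- paste(exons, collapse = "")
  if (multi$strand == "-") spliced <- revcomp(spliced)
  # a 346-bp spliced fragment at ~76% identity spanning exon junctions
  frag <- substr(spliced, nchar(exons[1]) - 100, nchar(exons[1]) + 245)
  set.seed(13)
  captured <- mutate_sequence(frag, 0.24)
  internals <- data.frame(element_id = "trim1", seq = captured)
  rep1 <- detect_gene_capture(internals, sim$genes, sim$genome)
  rep1 <- rep1[rep1$gene_id == multi$gene_id, ]
  expect_equal(nrow(rep1), 1)
  expect_gte(rep1$aligned_bp, 50)
  expect_true(rep1$exon_only)

  # an unspliced genomic fragment spanning an intron: not exon-only
  genomic <- substr(g, multi$exon_start[[1]][1] + 50,
                    multi$exon_start[[1]][2] + 80)
  if (multi$strand == "-") genomic <- revcomp(genomic)
  set.seed(14)
  internals2 <- data.frame(element_id = "trim2",
                           seq = mutate_sequence(genomic, 0.05))
  rep2 <- detect_gene_capture(internals2, sim$genes, sim$genome)
  rep2 <- rep2[rep2$gene_id == multi$gene_id, ]
  expect_equal(nrow(rep2), 1)
  expect_false(rep2$exon_only)

  # no homology: empty report
  set.seed(15)
  rep3 <- detect_gene_capture(
    data.frame(element_id = "trim3", seq = random_dna(400)),
    sim$genes, sim$genome)
  expect_equal(nrow(rep3), 0)
})

test_that("NG86 handles canonical small cases", {
  # identical sequences
  r <- ka_ks_ng86("ATGAAA", "ATGAAA")
  expect_equal(r$Ka, 0)
  expect_equal(r$Ks, 0)
  expect_true(is.na(r$ratio))
  # one synonymous change: Ks > 0, Ka = 0
  r2 <- ka_ks_ng86("AAAGGGTTT", "AAAGGATTT")  # GGG->GGA synonymous
  expect_equal(r2$Ka, 0)
  expect_gt(r2$Ks, 0)
  expect_equal(r2$Sd, 1)
  expect_equal(r2$Nd, 0)
  # errors
  expect_error(ka_ks_ng86("ATG", "ATGAAA"), "length")
  expect_error(ka_ks_ng86("ATGA", "ATGC"), "multiple of 3")
  expect_error(ka_ks_ng86("TAAATG", "TAAATG"), "stop")
})

test_that("NG86 agrees with the exhaustive pathway enumerator", {
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  set.seed(31)
  pairs <- cbind(sample(sense, 150, replace = TRUE),
                 sample(sense, 150, replace = TRUE))
  for (k in seq_len(nrow(pairs))) {
    r <- ka_ks_ng86(pairs[k, 1], pairs[k, 2])
    o <- oracle_ng86_codon(pairs[k, 1], pairs[k, 2])
    expect_equal(r$S, o$S, tolerance = 1e-9)
    expect_equal(r$Sd, o$Sd, tolerance = 1e-9)
    expect_equal(r$Nd, o$Nd, tolerance = 1e-9)
  }
})
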