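model <- test_model()

test_that("linked-read simulation respects edge cases and errors", {
  out <- simulate_linked_reads(model, 0)
  expect_equal(nrow(out$reads), 0L)
  expect_equal(nrow(out$truth), 0L)
  expect_error(simulate_linked_reads(model, 5, molecule_len = 50,
                                     read_len = 100),
               "molecule_len")
  expect_error(simulate_linked_reads(model, 5, molecule_len = 31000),
               "hap_wt")
})

test_that("every emitted read has exactly one truth record, for all assays", {
  lr <- simulate_linked_reads(model, 50, seed = 2)
  expect_setequal(lr$reads$read_id, lr$truth$read_id)
  tg <- simulate_tag_reads(model, assay_profile("tag", depth = 30), seed = 3)
  expect_setequal(tg$reads$read_id, tg$truth$read_id)
  bs <- simulate_bisulfite(model, assay_profile("bisulfite", depth = 40),
                           seed = 4)
  expect_setequal(bs$reads$read_id, bs$truth$read_id)
  cc <- simulate_contacts(model, assay_profile("contact"), 500,
                          assay_tag = "hic", seed = 5)
  expect_setequal(cc$contacts$pair_id, cc$truth$pair_id)
})

test_that("simulators are byte-identical under a fixed seed", {
  a <- simulate_linked_reads(model, 40, seed = 7)
  b <- simulate_linked_reads(model, 40, seed = 7)
  expect_identical(a, b)
  c1 <- simulate_contacts(model, assay_profile("contact"), 300,
                          assay_tag = "capturec", seed = 9)
  c2 <- simulate_contacts(model, assay_profile("contact"), 300,
                          assay_tag = "capturec", seed = 9)
  expect_identical(c1, c2)
})

test_that("error-free linked reads give a conflict-free barcode-allele matrix", {
  lr <- simulate_linked_reads(model, 200, molecule_len = 3000,
                              reads_per_molecule = 40, seed = 11)
  mat <- collect_barcode_allele_matrix(lr$reads, model$snps)
  expect_false(any(mat$call == "conflict"))
  expect_equal(attr(mat, "other_bases"), 0L)
})

test_that("molecule haplotype sampling is a fair coin within 3 binomial SDs", {
  n <- 10000
  lr <- simulate_linked_reads(model, n, reads_per_molecule = 1, seed = 13)
  frac <- mean(lr$truth$haplotype == "hap_wt")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
})

test_that("tag reads hit the configured allelic ratio and SNP alleles", {
  prof <- assay_profile("tag", depth = 1000, allelic_ratio = 1)
  sim <- simulate_tag_reads(model, prof, seed = 17)
  frac <- mean(sim$truth$haplotype == "hap_wt")
  n <- nrow(sim$truth)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))

  prof2 <- assay_profile("rna_stranded", depth = 2000, allelic_ratio = 7.4)
  sim2 <- simulate_tag_reads(model, prof2, seed = 19)
  frac2 <- mean(sim2$truth$haplotype == "hap_wt")
  p <- 7.4 / 8.4
  expect_lt(abs(frac2 - p), 3 * sqrt(p * (1 - p) / nrow(sim2$truth)))
  expect_true(all(sim2$reads$tx_strand == "sense"))

  # depth 0 gives an empty set
  expect_equal(nrow(simulate_tag_reads(model,
                                       assay_profile("tag", depth = 0))$reads),
               0L)
  # reads carry the true haplotype's allele at the targeted SNP (error-free)
  ct <- count_alleles(sim2$reads, model$snps, assay = "RNA")
  expect_equal(sum(ct$n_other), 0L)
  expect_equal(sum(ct$n_hap1 + ct$n_hap2), nrow(sim2$reads))
})

test_that("bisulfite extremes read out all-methylated and all-unmethylated", {
  cfg1 <- genome_config(meth_truth = c(hap_wt = 1, hap_rearr = 1))
  m1 <- build_genome(cfg1, seed = 2)
  prof <- assay_profile("bisulfite", depth = 30, conversion_rate = 1)
  bs1 <- simulate_bisulfite(m1, prof, seed = 3)
  mp1 <- haplotype_methylation(bs1$reads, "snp2", m1$snps,
                               unique(m1$meth_truth$cpg_pos))
  expect_true(all(mp1$ratio[mp1$coverage > 0] == 1))

  cfg0 <- genome_config(meth_truth = c(hap_wt = 0, hap_rearr = 0))
  m0 <- build_genome(cfg0, seed = 2)
  bs0 <- simulate_bisulfite(m0, prof, seed = 3)
  mp0 <- haplotype_methylation(bs0$reads, "snp2", m0$snps,
                               unique(m0$meth_truth$cpg_pos))
  expect_true(all(mp0$ratio[mp0$coverage > 0] == 0))
})

test_that("incomplete conversion biases estimates upward by (1-m)(1-c)", {
  cfg <- genome_config(meth_truth = c(hap_wt = 0.1, hap_rearr = 0.1))
  m <- build_genome(cfg, seed = 4)
  prof <- assay_profile("bisulfite", depth = 3000, conversion_rate = 0.9)
  bs <- simulate_bisulfite(m, prof, seed = 5)
  mp <- haplotype_methylation(bs$reads, "snp2", m$snps,
                              unique(m$meth_truth$cpg_pos))
  est <- mean(mp$ratio, na.rm = TRUE)
  expected <- 0.1 + (1 - 0.1) * (1 - 0.9)
  expect_lt(abs(est - expected), 0.02)
})

test_that("contact simulation honours n_pairs edge cases and decay recovery", {
  expect_error(simulate_contacts(model, assay_profile("contact"), -1),
               "non-negative")
  e <- simulate_contacts(model, assay_profile("contact"), 0,
                         assay_tag = "hic", boosts = NULL)
  expect_equal(nrow(e$contacts), 0L)

  prof <- assay_profile("contact", decay_exponent = 1)
  sim <- simulate_contacts(model, prof, 40000, assay_tag = "hic",
                           boosts = NULL, seed = 21)
  fit <- fit_decay_exponent(sim$contacts, d_min = 1500, d_max = 12000)
  expect_lt(abs(fit$exponent - 1) / 1, 0.15)
})

test_that("without boosts, anchor-pair counts are consistent with background decay", {
  prof <- assay_profile("contact", decay_exponent = 1)
  sim <- simulate_contacts(model, prof, 30000, assay_tag = "hic",
                           boosts = NULL, seed = 23)
  anch <- model$anchors
  emu <- anch[anch$name == "Emu", ]
  prom <- anch[anch$name == "Igmu_promoter", ]
  obs <- count_anchor_pairs(sim$contacts, emu, prom)
  # background estimate from pairs at comparable separation
  d_ab <- 13800 + 400  # edge-to-edge plus anchor widths, midpoint scale
  intra <- sim$contacts[sim$contacts$contig1 == "chrL" &
                          sim$contacts$contig2 == "chrL", ]
  d <- abs(intra$pos2 - intra$pos1)
  band <- sum(d >= d_ab / sqrt(2) & d <= d_ab * sqrt(2))
  exp_ct <- band * (550 * 550) / ((30000 - d_ab) * d_ab * (sqrt(2) - 1 / sqrt(2)))
  # anchor footprint approx (width + read_len) each side
  expect_lt(obs, exp_ct * 4 + 3 * sqrt(exp_ct) + 10)
  expect_gt(obs + 3 * sqrt(max(obs, 1)) + 10, exp_ct / 4)
})
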