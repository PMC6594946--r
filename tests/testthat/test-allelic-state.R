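model <- test_model()

test_that("read-to-haplotype assignment follows SNP alleles, flags discord and prefilter violations", {
  snps <- tibble::tibble(
    snp_id = c("s1", "s2"), contig = "c1", pos = c(110L, 150L),
    allele_a = c("A", "A"), allele_b = c("T", "G")
  )
  mk <- function(id, bases_at = c(`110` = "A")) {
    seq <- paste(rep("C", 100), collapse = "")
    for (p in names(bases_at)) {
      i <- as.integer(p) - 100L + 1L
      substr(seq, i, i) <- bases_at[[p]]
    }
    tibble::tibble(read_id = id, contig = "c1", start = 100L, end = 200L,
                   seq = seq)
  }
  r1 <- assign_read_to_haplotype(mk("r1", c(`110` = "A", `150` = "A")), snps)
  expect_equal(r1$hap_call, "hap1")
  r2 <- assign_read_to_haplotype(mk("r2", c(`110` = "T", `150` = "G")), snps)
  expect_equal(r2$hap_call, "hap2")
  # discordant alleles across two SNPs on one read
  r3 <- assign_read_to_haplotype(mk("r3", c(`110` = "A", `150` = "G")), snps)
  expect_equal(r3$hap_call, "ambiguous")
  # non-allelic bases only
  r4 <- assign_read_to_haplotype(mk("r4", c(`110` = "C", `150` = "C")), snps)
  expect_equal(r4$hap_call, "other")
  # a read overlapping no SNP is a caller error
  off <- tibble::tibble(read_id = "r5", contig = "c1", start = 300L,
                        end = 400L, seq = paste(rep("A", 100), collapse = ""))
  expect_error(assign_read_to_haplotype(off, snps), "prefilter")
})

test_that("haplotype calls are perfect on error-free simulated reads", {
  sim <- simulate_tag_reads(model, assay_profile("tag", depth = 150), seed = 51)
  calls <- assign_read_to_haplotype(sim$reads, model$snps)
  joined <- dplyr::left_join(calls, sim$truth, by = "read_id")
  expect_true(all((joined$hap_call == "hap1") ==
                    (joined$haplotype == "hap_wt")))
})

test_that("allele counting conserves reads, honours dedup and exon restriction", {
  snps <- tibble::tibble(snp_id = "s1", contig = "c1", pos = 110L,
                         allele_a = "A", allele_b = "T")
  mk_n <- function(base, n, dup = FALSE) {
    seq <- paste(rep("C", 100), collapse = "")
    substr(seq, 11, 11) <- base
    tibble::tibble(read_id = sprintf("%s%03d", base, seq_len(n)),
                   contig = "c1", start = 100L, end = 200L, seq = seq,
                   dup = dup)
  }
  reads <- dplyr::bind_rows(mk_n("A", 74), mk_n("T", 10))
  ct <- count_alleles(reads, snps, assay = "RNA")
  expect_equal(unlist(ct[1, c("n_hap1", "n_hap2", "n_other", "n_ambiguous")],
                      use.names = FALSE),
               c(74L, 10L, 0L, 0L))
  # duplicate-flagged reads drop when dedup is on
  reads2 <- dplyr::bind_rows(reads, mk_n("A", 6, dup = TRUE))
  expect_equal(count_alleles(reads2, snps)$n_hap1, 74L)
  expect_equal(count_alleles(reads2, snps, dedup = FALSE)$n_hap1, 80L)
  # exon restriction keeps only exonic SNPs
  exons <- tibble::tibble(start = 500L, end = 600L)
  expect_equal(nrow(count_alleles(reads, snps, exons = exons)), 0L)
})

test_that("exact binomial tail probabilities match closed forms", {
  r <- binomial_imbalance(10, 0)
  expect_equal(r$p_value, 0.5^10)
  expect_equal(r$fold, Inf)
  expect_equal(binomial_imbalance(0, 10)$p_value, 1.0)
  expect_equal(binomial_imbalance(5, 5)$p_value, 638 / 1024)
  expect_error(binomial_imbalance(-1, 5), "non-negative")
  expect_error(binomial_imbalance(0, 0), ">= 1")
  # monotone: p decreases as n_hap1 grows at fixed total
  ps <- vapply(0:20, function(k) binomial_imbalance(k, 20 - k)$p_value,
               numeric(1))
  expect_true(all(diff(ps) < 0))
  # stars at the conventional thresholds
  expect_equal(binomial_imbalance(10, 0)$stars, "***")
  expect_equal(binomial_imbalance(5, 0)$stars, "*")
})

test_that("fold estimation at a strong configured ratio stays within the exact binomial band", {
  # ratio 10.4 at depth 500: the 95% binomial band for the per-dataset
  # pooled fold, checked over seeded replicates
  hits <- 0
  n_rep <- 40
  for (s in seq_len(n_rep)) {
    sim <- simulate_tag_reads(model,
                              assay_profile("tag", depth = 500,
                                            allelic_ratio = 10.4),
                              seed = 500 + s)
    ct <- count_alleles(sim$reads, model$snps)
    i <- 1  # per-SNP estimate at the first SNP, depth 500
    fold <- ct$n_hap1[i] / ct$n_hap2[i]
    if (fold >= 7.8 && fold <= 13.9) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.85)  # 95% band, small-sample slack
})

test_that("long-read classification recovers all three transcript classes and their haplotypes", {
  lt <- simulate_long_transcripts(model, n_per_class = 6, seed = 53)
  segs <- model_segments(model)
  calls <- classify_long_read(lt$reads, model$snps, segs)
  joined <- dplyr::left_join(calls, lt$truth, by = "read_id",
                             suffix = c("_called", "_true"))
  expect_true(all(joined$class_called == joined$class_true))
  expect_true(all(joined$haplotype_called == joined$haplotype_true))
  # functional transcripts carry the wild-type (A-A-A) alleles
  f <- joined[joined$class_true == "functional_IgM", ]
  expect_true(all(f$haplotype_called == "hap_wt"))
  # a read covering no SNP and no cassette is ambiguous
  bare <- tibble::tibble(read_id = "b1", start = 1000L, end = 1500L,
                         tx_strand = "+",
                         seq = substr(model$haplotypes[["hap_wt"]], 1001, 1500))
  expect_equal(classify_long_read(bare, model$snps, segs)$class, "ambiguous")
  expect_equal(classify_long_read(bare, model$snps, segs)$haplotype,
               "undetermined")
  # unaligned reads are an error
  expect_error(classify_long_read(dplyr::mutate(bare, start = NA_integer_),
                                  model$snps, segs), "unaligned")
})
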