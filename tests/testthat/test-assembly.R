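model <- test_model()

test_that("barcode recruitment enforces the read threshold and pulls distal mates", {
  # a barcode with 19 reads in-region is excluded at threshold 20
  mk_reads <- function(bc, n_in, n_out) {
    dplyr::bind_rows(
      tibble::tibble(read_id = sprintf("%s_in%d", bc, seq_len(n_in)),
                     barcode = bc, contig = "chrL",
                     start = 28500L, end = 28600L, seq = "A"),
      if (n_out > 0) {
        tibble::tibble(read_id = sprintf("%s_out%d", bc, seq_len(n_out)),
                       barcode = bc, contig = "chrD",
                       start = 10L, end = 110L, seq = "A")
      }
    )
  }
  reads <- dplyr::bind_rows(mk_reads("bc19", 19, 5), mk_reads("bc20", 20, 7))
  region <- list(contig = "chrL", start = 28400L, end = 29200L)
  rec <- recruit_barcodes(reads, region, min_reads = 20)
  expect_equal(rec$barcodes$barcode, "bc20")
  # all reads of the qualifying barcode are recruited, including distal ones
  expect_equal(nrow(rec$reads), 27L)
  expect_true(all(rec$reads$barcode == "bc20"))

  # empty alignment set
  rec0 <- recruit_barcodes(reads[0, ], region)
  expect_equal(nrow(rec0$barcodes), 0L)
  expect_equal(nrow(rec0$reads), 0L)

  # lowering the threshold never shrinks the qualifying set
  for (thr in c(25, 20, 15, 5, 1)) {
    r <- recruit_barcodes(reads, region, min_reads = thr)
    if (exists("prev")) expect_true(all(prev %in% r$barcodes$barcode))
    prev <- r$barcodes$barcode
  }
})

test_that("recruitment against simulator truth finds exactly the overlapping molecules", {
  lr <- simulate_linked_reads(model, 150, molecule_len = 2000,
                              reads_per_molecule = 25, seed = 41)
  region <- list(contig = "chrL", start = 5000L, end = 5400L)
  rec <- recruit_barcodes(lr$reads, region, min_reads = 1)
  # truth: molecules overlapping the region on the wild-type coordinate
  # system (region is upstream of all edits so coordinates agree)
  tr <- lr$truth %>%
    dplyr::left_join(lr$reads, by = "read_id") %>%
    dplyr::filter(contig == "chrL", start < 5400, end > 5000) %>%
    dplyr::distinct(molecule)
  expect_setequal(rec$barcodes$barcode, tr$molecule)
  # every recruited read's barcode qualifies
  expect_true(all(rec$reads$barcode %in% rec$barcodes$barcode))
})

test_that("error-free reads tiling one sequence assemble into that sequence", {
  truth_seq <- model$paralogs$seq[model$paralogs$canonical]
  starts <- c(seq(1, nchar(truth_seq) - 100, by = 20),
              nchar(truth_seq) - 99)
  reads <- substring(truth_seq, starts, starts + 99)
  ctg <- assemble_overlap(reads, k = 31)
  expect_equal(nrow(ctg), 1L)
  expect_true(ctg$seq[1] == truth_seq ||
                hapase:::revcomp(ctg$seq[1]) == truth_seq)
  expect_error(assemble_overlap(reads, k = 100), "k")
})

test_that("assembly forks at a heterozygous site instead of joining across it", {
  base <- substr(model$haplotypes[["hap_wt"]], 14801, 15200)  # covers snp1
  alt <- substr(model$haplotypes[["hap_rearr"]],
                lift_to_haplotype(model, "hap_rearr", 14800L) + 1,
                lift_to_haplotype(model, "hap_rearr", 14800L) + 400)
  starts <- seq(1, 301, by = 10)
  reads <- c(substring(base, starts, starts + 99),
             substring(alt, starts, starts + 99))
  ctg <- assemble_overlap(reads, k = 31)
  # no contig contains both alleles' contexts joined; every contig is a
  # substring of one of the two haplotype windows
  expect_gt(nrow(ctg), 1L)
  for (s in ctg$seq) {
    expect_true(grepl(s, base, fixed = TRUE) || grepl(s, alt, fixed = TRUE))
  }
})

test_that("assembled contigs from clean simulated reads are substrings of a true haplotype and span the cassette junction", {
  lr <- simulate_linked_reads(model, 1500, molecule_len = 3000,
                              reads_per_molecule = 60, seed = 43)
  region <- list(contig = "chrL", start = 28400L, end = 29200L)
  rec <- recruit_barcodes(lr$reads, region, min_reads = 10)
  rearr_ids <- lr$truth$read_id[lr$truth$haplotype == "hap_rearr"]
  reads <- rec$reads[rec$reads$read_id %in% rearr_ids, ]
  ctg <- assemble_overlap(reads, k = 31)
  hap <- model$haplotypes[["hap_rearr"]]
  for (s in ctg$seq[ctg$length >= 60]) {
    expect_true(grepl(s, hap, fixed = TRUE) ||
                  grepl(hapase:::revcomp(s), hap, fixed = TRUE))
  }
  # some contig contains the flank-cassette junction; with a two-copy
  # repeat cassette, unitigs can extend at most k - 1 bases past the
  # junction before the repeat-entry branch point, so probe within that
  junction <- substr(hap, model$config$breakpoint - 24,
                     model$config$breakpoint + 26)
  hit <- any(vapply(ctg$seq, function(s) {
    grepl(junction, s, fixed = TRUE) ||
      grepl(junction, hapase:::revcomp(s), fixed = TRUE)
  }, logical(1)))
  expect_true(hit)
})

test_that("paralog attribution ranks by mismatches with correct identity and margin", {
  canon <- model$paralogs$seq[model$paralogs$canonical]
  att <- paralog_attribution(canon, model$paralogs)
  expect_equal(att$paralog_name[1], "DUXL_canon")
  expect_equal(att$identity[1], 100)
  expect_equal(att$margin[1], 4L)  # nearest neighbour is 4 substitutions away
  expect_true(attr(att, "exclusive"))

  # 4 mismatches over 1200 aligned bp give 99.667% identity
  expect_equal(round(att$identity[2], 3), 99.667)

  # simulated cassette sequence attributes to the canonical source
  att2 <- paralog_attribution(substr(model$cassette_seq, 1, 1200),
                              model$paralogs)
  expect_equal(att2$paralog_name[1], "DUXL_canon")
  expect_equal(att2$mismatches[1], 0L)
  expect_equal(att2$margin[1], 4L)

  # short contigs are refused
  expect_error(paralog_attribution(substr(canon, 1, 150), model$paralogs),
               "minimum")
})

test_that("scaffolding concatenates parts with declared lengths, junctions and orientation", {
  one <- tibble::tibble(part_id = "p1", source = "contig",
                        seq = "ACGTACGTAA", orientation = "+")
  sc1 <- scaffold_haplotype(one)
  expect_equal(sc1$seq, "ACGTACGTAA")
  expect_equal(nrow(sc1$junctions), 0L)

  # the published part lengths under zero declared overlap sum exactly
  withr::with_seed(1, {
    parts <- tibble::tibble(
      part_id = c("ighm_contig", "ref_linker", "dux4_contig"),
      source = c("contig", "reference_segment", "contig"),
      seq = c(hapase:::random_dna(8063), hapase:::random_dna(6104),
              hapase:::random_dna(4670)),
      orientation = "+"
    )
  })
  sc <- scaffold_haplotype(parts)
  expect_equal(sc$total_length, 8063 + 6104 + 4670)
  expect_equal(sc$junctions$pos, c(8063L, 8063L + 6104L))

  # reverse-orientation parts are reverse complemented
  rev <- tibble::tibble(part_id = "p1", source = "contig",
                        seq = "AACCGGTT", orientation = "-")
  expect_equal(scaffold_haplotype(rev)$seq, hapase:::revcomp("AACCGGTT"))

  # empty/gapped parts are rejected
  bad <- tibble::tibble(part_id = "p1", source = "contig", seq = "",
                        orientation = "+")
  expect_error(scaffold_haplotype(bad), "spacer")
})
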