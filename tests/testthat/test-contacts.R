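model <- test_model()
anch <- model$anchors
emu <- anch[anch$name == "Emu", ]
prom <- anch[anch$name == "Igmu_promoter", ]
copies <- anch[anch$role == "oncogene_array_copy", ]

test_that("anchor-pair counting is symmetric, union-aware and rejects overlapping anchors", {
  expect_equal(count_anchor_pairs(tibble::tibble(
    pair_id = character(), contig1 = character(), pos1 = integer(),
    contig2 = character(), pos2 = integer(), mult = integer()
  ), emu, prom), 0L)

  contacts <- tibble::tibble(
    pair_id = c("p1", "p2"),
    contig1 = c("chrL", "chrL"), pos1 = c(28100L, 13900L),
    contig2 = c("chrL", "chrL"), pos2 = c(13900L, 28100L),
    mult = 1L
  )
  # counted once per pair regardless of end order
  expect_equal(count_anchor_pairs(contacts, emu, prom), 2L)
  expect_equal(count_anchor_pairs(contacts, prom, emu), 2L)

  # union rule over the paralog copy set
  cc <- tibble::tibble(pair_id = "q1", contig1 = "chrL", pos1 = 28100L,
                       contig2 = "chrD", pos2 = copies$start[2] + 10L,
                       mult = 3L)
  expect_equal(count_anchor_pairs(cc, emu, copies), 3L)

  # overlapping anchors are ambiguous
  expect_error(count_anchor_pairs(contacts, emu, emu), "overlap")
})

test_that("end-swap invariance holds on random contact sets", {
  withr::with_seed(71, {
    n <- 500
    contacts <- tibble::tibble(
      pair_id = sprintf("r%03d", 1:n),
      contig1 = sample(c("chrL", "chrD"), n, TRUE),
      pos1 = sample.int(20000L, n),
      contig2 = sample(c("chrL", "chrD"), n, TRUE),
      pos2 = sample.int(20000L, n),
      mult = sample(1:3, n, TRUE)
    )
  })
  swapped <- contacts
  swapped$contig1 <- contacts$contig2; swapped$pos1 <- contacts$pos2
  swapped$contig2 <- contacts$contig1; swapped$pos2 <- contacts$pos1
  for (pair in list(list(emu, prom), list(emu, copies), list(prom, copies))) {
    expect_equal(count_anchor_pairs(contacts, pair[[1]], pair[[2]]),
                 count_anchor_pairs(swapped, pair[[1]], pair[[2]]))
  }
  # canonical storage makes swapped sets identical
  expect_equal(hapase:::canonicalize_pairs(contacts)[, -1],
               hapase:::canonicalize_pairs(swapped)[, -1])
})

test_that("peak coverage reports the maximum per-base depth with viewpoint exclusion", {
  # 7 reads stacked on the same spot: uniform coverage 7
  contacts <- tibble::tibble(
    pair_id = sprintf("s%d", 1:7),
    contig1 = "chrL", pos1 = 28100L,
    contig2 = "chrL", pos2 = 14000L, mult = 1L
  )
  win <- list(contig = "chrL", start = 13950L, end = 14150L)
  expect_equal(peak_coverage(contacts, emu, win), 7L)
  expect_equal(peak_coverage(contacts[0, ], emu, win), 0L)
  # a window inside the exclusion zone errors
  expect_error(peak_coverage(contacts, emu,
                             list(contig = "chrL", start = 28500L,
                                  end = 28600L)),
               "exclusion")
  # other-ends inside the exclusion zone are filtered
  near <- tibble::tibble(pair_id = "n1", contig1 = "chrL", pos1 = 28100L,
                         contig2 = "chrL", pos2 = 28600L, mult = 1L)
  expect_equal(peak_coverage(dplyr::bind_rows(contacts, near), emu, win), 7L)
})

test_that("the simulated boosted anchor produces the peak at the expected position", {
  sim <- simulate_contacts(model, assay_profile("contact"), 2000,
                           assay_tag = "capturec", seed = 73)
  resc <- multimapping_rescue(sim$contacts, model)
  canon <- copies[copies$name == "DUXL_canon", ]
  pk_canon <- peak_coverage(resc$contacts, emu,
                            list(contig = "chrD", start = canon$start,
                                 end = canon$end))
  # control window on the far copy should be near-empty after rescue
  far <- copies[copies$name == "DUXL_far", ]
  pk_far <- peak_coverage(resc$contacts, emu,
                          list(contig = "chrD", start = far$start,
                               end = far$end))
  expect_gt(pk_canon, pk_far)
})

test_that("multimapping rescue is monotone, complete on canonical reads and bounded on divergent ones", {
  sim <- simulate_contacts(model, assay_profile("contact"), 1500,
                           assay_tag = "capturec", seed = 75)
  canon <- copies[copies$name == "DUXL_canon", ]
  win <- list(contig = "chrD", start = canon$start, end = canon$end)
  pre <- peak_coverage(sim$contacts, emu, win)
  resc <- multimapping_rescue(sim$contacts, model)
  post <- peak_coverage(resc$contacts, emu, win)
  expect_gte(post, pre)
  expect_gt(resc$n_rescued, 0L)
  # the only unrescuable clean reads are those crossing the spacer/second
  # copy junction, which does not exist in the canonical region
  expect_lt(resc$n_unrescued / resc$n_candidates, 0.1)

  # reads drawn wholly from the canonical copy are rescued 100%
  canon_seq <- model$paralogs$seq[model$paralogs$canonical]
  offs <- seq(1, 1100, by = 50)
  clean <- tibble::tibble(
    pair_id = sprintf("c%03d", seq_along(offs)),
    contig1 = "chrL", pos1 = 28100L,
    contig2 = "chrD",
    pos2 = model$paralogs$start[model$paralogs$name == "DUXL_near"] + offs,
    mult = 1L, seq1 = NA_character_,
    seq2 = substring(canon_seq, offs, offs + 74)
  )
  rc <- multimapping_rescue(clean, model)
  expect_equal(rc$n_rescued, length(offs))
  expect_equal(rc$n_unrescued, 0L)

  # a read carrying >2 distinguishing substitutions is not rescued
  canon_seq <- model$paralogs$seq[model$paralogs$canonical]
  readseq <- substr(canon_seq, 101, 175)
  for (i in c(10, 35, 60)) {
    b <- substr(readseq, i, i)
    substr(readseq, i, i) <- setdiff(c("A", "C", "G", "T"), b)[1]
  }
  far <- model$paralogs[model$paralogs$name == "DUXL_far", ]
  cc <- tibble::tibble(pair_id = "d1", contig1 = "chrL", pos1 = 28100L,
                       contig2 = "chrD", pos2 = far$start + 100L, mult = 1L,
                       seq1 = NA_character_, seq2 = readseq)
  r2 <- multimapping_rescue(cc, model, max_mismatch = 2L)
  expect_equal(r2$n_rescued, 0L)
  expect_equal(r2$n_unrescued, 1L)
})

test_that("interaction folds report float and half-away-from-zero rounding", {
  f <- interaction_fold(953, 75)
  expect_equal(f$ratio, 953 / 75)
  expect_equal(f$rounded, 13L)
  expect_equal(interaction_fold(10, 10)$ratio, 1)
  expect_equal(interaction_fold(24, 8)$ratio, 3)
  expect_equal(interaction_fold(5, 2)$rounded, 3L)  # 2.5 rounds away from zero
  z <- interaction_fold(10, 0)
  expect_false(z$defined)
  expect_true(is.na(z$ratio))
})

test_that("haplotype distances expand with insertions and contract with deletions", {
  # adjacent anchors without edits: the reference gap
  expect_equal(haplotype_distance(model, "Emu", "Igmu_promoter", "hap_wt"),
               28000L - 14200L)
  # a 60 kb-scale deletion inside a gap contracts it (scaled example)
  cfg <- genome_config(deletion = c(20000L, 26000L))
  md <- build_genome(cfg, seed = 7)
  expect_equal(haplotype_distance(md, "Emu", "Igmu_promoter", "hap_rearr"),
               28000L - 14200L - 6000L)
  # an anchor wiped out by a deletion errors with the deletion's name
  cfg2 <- genome_config(deletion = c(13700L, 14300L))
  m2 <- build_genome(cfg2, seed = 7)
  expect_error(haplotype_distance(m2, "Emu", "Igmu_promoter", "hap_rearr"),
               "deletion")
  # replica of the published geometry: enhancer-promoter distance exceeds
  # enhancer-cassette distance even though the promoter interaction is
  # stronger
  d_prom <- haplotype_distance(model, "Emu", "Igmu_promoter", "hap_wt")
  d_cass <- haplotype_distance(model, "Emu", "cassette_copy1", "hap_rearr")
  expect_gt(d_prom, d_cass)
  expect_equal(d_cass, model$config$breakpoint - model$config$enhancer[2])
})

test_that("region adjacency calls recover a reciprocal translocation and nothing else", {
  # background only, single contig: no adjacency calls
  bg <- simulate_contacts(model, assay_profile("contact"), 5000,
                          assay_tag = "hic", boosts = NULL, seed = 77)
  intra <- bg$contacts[bg$contacts$contig1 == "chrL" &
                         bg$contacts$contig2 == "chrL", ]
  regions1 <- tibble::tibble(
    name = c("A", "B", "C"), contig = "chrL",
    start = c(1000L, 12000L, 24000L), end = c(3000L, 14000L, 26000L)
  )
  adj1 <- region_adjacency(intra, regions1)
  expect_false(any(adj1$adjacent))

  # a reciprocal translocation: derivative molecules join chrL's end to
  # chrD's start and vice versa; cross-junction background pairs appear as
  # junction-proximal inter-contig contacts
  withr::with_seed(79, {
    n <- 3000
    # derivative 1: chrL[0,28800) + chrD[1000,7600): positions near the
    # junction contact each other across contigs with decay
    d <- hapase:::sample_decay_distance(n, 1, 200, 20000)
    p1 <- pmax(28800 - floor(runif(n) * pmin(d, 27000)), 0)
    p2 <- pmin(1000 + (d - (28800 - p1)), 7500)
    der1 <- tibble::tibble(pair_id = sprintf("t%04d", 1:n),
                           contig1 = "chrL", pos1 = as.integer(p1),
                           contig2 = "chrD", pos2 = as.integer(pmax(p2, 1000)),
                           mult = 1L)
    der1 <- der1[p2 > 1000, ]
  })
  contacts <- dplyr::bind_rows(intra, der1)
  regions <- tibble::tibble(
    name = c("L_distal", "L_junction", "D_junction", "D_distal"),
    contig = c("chrL", "chrL", "chrD", "chrD"),
    start = c(2000L, 27000L, 1000L, 6000L),
    end = c(4000L, 28800L, 2800L, 7600L)
  )
  cn <- tibble::tibble(name = regions$name, cn = c(2L, 2L, 1L, 1L))
  adj <- region_adjacency(contacts, regions, copy_number = cn)
  junc <- adj[adj$region_a == "L_junction" & adj$region_b == "D_junction", ]
  expect_true(junc$adjacent)
  distal <- adj[adj$region_a == "L_distal" & adj$region_b == "D_distal", ]
  expect_false(distal$adjacent)
  # a region pair with zero contacts is never adjacent
  expect_false(any(adj$adjacent[adj$observed == 0]))
  # no contacts at all: background unavailable
  expect_error(region_adjacency(intra[0, ], regions), "background")
})
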