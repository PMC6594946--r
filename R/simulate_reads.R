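#' Simulate linked (barcoded) whole-genome reads
#'
#' Emulates a linked-read library: long DNA molecules are drawn uniformly
#' from the two haplotypes, each molecule's short reads share one barcode
#' (emitted SAM-style as a `BX`-like column), and reads carry the SNP
#' alleles of their haplotype of origin. Reads are reported in reference
#' coordinates (`chrL`, or `chrD` for reads internal to the inserted
#' cassette, which a real aligner would place at the donor paralog array).
#'
#' @param model A [build_genome()] model.
#' @param n_molecules Number of molecules.
#' @param molecule_len Molecule length in bp (must exceed `read_len` and
#'   fit inside both haplotypes).
#' @param reads_per_molecule Reads emitted per molecule.
#' @param read_len Read length in bp.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return A list with `reads` (tibble: `read_id`, `barcode`, `contig`,
#'   `start`, `end`, `strand`, `seq`, `assay`) and `truth` (tibble:
#'   `read_id`, `haplotype`, `molecule`, `hap_start`, `hap_end`). One truth
#'   record per read.
#' @export
simulate_linked_reads <- function(model, n_molecules, molecule_len = 2000L,
                                  reads_per_molecule = 20L, read_len = 100L,
                                  error_rate = 0, seed = 1L) {
  stopifnot_scalar_int(n_molecules, "n_molecules", min = 0L)
  if (molecule_len <= read_len) abort("molecule_len must exceed read length")
  for (h in c("hap_wt", "hap_rearr")) {
    if (molecule_len > haplotype_length(model, h)) {
      abort(sprintf("molecule_len %d exceeds the length of %s (%d bp)",
                    molecule_len, h, haplotype_length(model, h)))
    }
  }
  empty <- list(
    reads = tibble(read_id = character(), barcode = character(),
                   contig = character(), start = integer(), end = integer(),
                   strand = character(), seq = character(), assay = character()),
    truth = tibble(read_id = character(), haplotype = character(),
                   molecule = character(), hap_start = integer(),
                   hap_end = integer())
  )
  if (n_molecules == 0) return(empty)
  withr::local_seed(seed)

  haps <- sample(c("hap_wt", "hap_rearr"), n_molecules, replace = TRUE)
  hap_lens <- setNames(nchar(model$haplotypes), names(model$haplotypes))
  mol_start <- floor(runif(n_molecules) * (hap_lens[haps] - molecule_len))
  barcode <- sprintf("BX%06d", seq_len(n_molecules))

  k <- reads_per_molecule
  idx <- rep(seq_len(n_molecules), each = k)
  rstart <- mol_start[idx] +
    floor(runif(n_molecules * k) * (molecule_len - read_len + 1L))
  rstart <- as.integer(rstart)
  hap <- haps[idx]

  seqs <- character(length(idx))
  for (h in c("hap_wt", "hap_rearr")) {
    sel <- hap == h
    seqs[sel] <- substring(model$haplotypes[[h]], rstart[sel] + 1L,
                           rstart[sel] + read_len)
  }
  seqs <- apply_seq_errors(seqs, error_rate)

  # map by read midpoint back to reference coordinates
  mapped_start <- integer(length(idx))
  mapped_contig <- character(length(idx))
  for (h in c("hap_wt", "hap_rearr")) {
    sel <- hap == h
    if (!any(sel)) next
    mid <- rstart[sel] + read_len %/% 2L
    m <- hap_point_to_ref(model, h, mid)
    mapped_contig[sel] <- m$contig
    mapped_start[sel] <- m$pos - read_len %/% 2L
  }

  reads <- tibble(
    read_id = sprintf("lr%07d", seq_along(idx)),
    barcode = barcode[idx],
    contig = mapped_contig,
    start = pmax(mapped_start, 0L),
    end = pmax(mapped_start, 0L) + read_len,
    strand = "+",
    seq = seqs,
    assay = "wgs_linked"
  )
  truth <- tibble(
    read_id = reads$read_id,
    haplotype = hap,
    molecule = barcode[idx],
    hap_start = rstart,
    hap_end = rstart + read_len
  )
  list(reads = reads, truth = truth)
}

#' Simulate SNP-targeted tag or stranded RNA reads
#'
#' Draws `profile$depth` reads over every phased het SNP; each read
#' originates from `hap_wt` with probability `r / (1 + r)` where `r` is the
#' profile's `allelic_ratio`, and carries that haplotype's allele at the
#' SNP (subject to `error_rate`). Stranded RNA reads carry a
#' transcription-strand label in `tx_strand`.
#'
#' @param model A genome model.
#' @param profile An [assay_profile()] with `assay` `"rna_stranded"` or
#'   `"tag"`.
#' @param seed Integer seed (defaults to the profile's).
#' @return A list with `reads` and `truth` tibbles (one truth record per
#'   read; truth carries `haplotype` and target `snp_id`).
#' @export
simulate_tag_reads <- function(model, profile, seed = profile$seed) {
  if (!profile$assay %in% c("rna_stranded", "tag")) {
    abort("profile$assay must be 'rna_stranded' or 'tag'")
  }
  snps <- model$snps
  n_per <- as.integer(profile$depth)
  read_len <- profile$read_len
  empty <- list(
    reads = tibble(read_id = character(), barcode = character(),
                   contig = character(), start = integer(), end = integer(),
                   strand = character(), seq = character(), assay = character(),
                   tx_strand = character(), dup = logical()),
    truth = tibble(read_id = character(), haplotype = character(),
                   snp_id = character())
  )
  if (n_per == 0 || nrow(snps) == 0) return(empty)
  withr::local_seed(seed)

  p_wt <- profile$allelic_ratio / (1 + profile$allelic_ratio)
  idx <- rep(seq_len(nrow(snps)), each = n_per)
  n <- length(idx)
  hap <- if_else(runif(n) < p_wt, "hap_wt", "hap_rearr")
  offset <- floor(runif(n) * read_len)
  ref_start <- as.integer(snps$pos[idx] - offset)

  seqs <- character(n)
  for (h in c("hap_wt", "hap_rearr")) {
    sel <- hap == h
    if (!any(sel)) next
    hs <- lift_to_haplotype(model, h, ref_start[sel])
    seqs[sel] <- substring(model$haplotypes[[h]], hs + 1L, hs + read_len)
  }
  seqs <- apply_seq_errors(seqs, profile$error_rate)

  reads <- tibble(
    read_id = sprintf("%s%07d", substr(profile$assay, 1, 2), seq_len(n)),
    barcode = NA_character_,
    contig = "chrL",
    start = ref_start,
    end = ref_start + read_len,
    strand = "+",
    seq = seqs,
    assay = profile$assay,
    tx_strand = if (profile$assay == "rna_stranded") "sense" else NA_character_,
    dup = FALSE
  )
  truth <- tibble(read_id = reads$read_id, haplotype = hap,
                  snp_id = snps$snp_id[idx])
  list(reads = reads, truth = truth)
}

#' Simulate bisulfite reads over the CpG window of the methylation SNP
#'
#' Each read spans the full `+/- window` CpG region around the model's
#' methylation-anchor SNP and the SNP itself. Reads derive from the
#' original top (`OT`) or bottom (`OB`) strand with equal probability;
#' unmethylated cytosines are converted (C to T on OT; the paired G to A on
#' OB, in top-strand coordinates) with probability `conversion_rate`, while
#' methylated CpG cytosines are retained. Per-read methylation states are
#' drawn from the model's per-haplotype CpG truth.
#'
#' @param model A genome model (must define CpG methylation truth).
#' @param profile An [assay_profile()] with `assay = "bisulfite"`; `depth`
#'   is the total number of reads.
#' @param seed Integer seed.
#' @return A list with `reads` (tibble incl. `conv_strand`) and `truth`
#'   (tibble: `read_id`, `haplotype`, `conv_strand`).
#' @export
simulate_bisulfite <- function(model, profile, seed = profile$seed) {
  if (profile$assay != "bisulfite") abort("profile$assay must be 'bisulfite'")
  cfg <- model$config
  msnp <- model$snps[model$snps$snp_id == cfg$meth_snp, ]
  w <- cfg$meth_window
  island <- sort(unique(model$meth_truth$cpg_pos))
  if (length(island) == 0) {
    abort("model has no CpG methylation truth in the target window")
  }
  n <- as.integer(profile$depth)
  read_len <- max(profile$read_len, 2L * w + 20L)
  empty <- list(
    reads = tibble(read_id = character(), barcode = character(),
                   contig = character(), start = integer(), end = integer(),
                   strand = character(), seq = character(), assay = character(),
                   conv_strand = character()),
    truth = tibble(read_id = character(), haplotype = character(),
                   conv_strand = character())
  )
  if (n == 0) return(empty)
  withr::local_seed(seed)

  p_wt <- profile$allelic_ratio / (1 + profile$allelic_ratio)
  hap <- if_else(runif(n) < p_wt, "hap_wt", "hap_rearr")
  conv <- if_else(runif(n) < 0.5, "OT", "OB")
  # every read covers [snp - w - 1, snp + w + 2): all CpGs plus the SNP
  jitter <- floor(runif(n) * (read_len - (2L * w + 3L)))
  ref_start <- as.integer(msnp$pos - w - 1L - jitter)

  truth_wide <- model$meth_truth %>%
    select("cpg_pos", "haplotype", "prob")
  probs <- list(
    hap_wt = truth_wide$prob[truth_wide$haplotype == "hap_wt"][
      order(truth_wide$cpg_pos[truth_wide$haplotype == "hap_wt"])],
    hap_rearr = truth_wide$prob[truth_wide$haplotype == "hap_rearr"][
      order(truth_wide$cpg_pos[truth_wide$haplotype == "hap_rearr"])]
  )

  seqs <- character(n)
  for (i in seq_len(n)) {
    h <- hap[i]
    hs <- lift_to_haplotype(model, h, ref_start[i])
    chars <- strsplit(substring(model$haplotypes[[h]], hs + 1L,
                                hs + read_len), "")[[1]]
    meth_state <- runif(length(island)) < probs[[h]]
    # island CpG C positions within the read (0-based read offsets)
    isl_off <- island - ref_start[i]
    if (conv[i] == "OT") {
      c_idx <- which(chars == "C")
      protected <- (c_idx - 1L) %in% isl_off[meth_state]
      convert <- !protected & runif(length(c_idx)) < profile$conversion_rate
      chars[c_idx[convert]] <- "T"
    } else {
      g_idx <- which(chars == "G")
      # the G of a methylated island CpG (C at off, G at off + 1) is retained
      protected <- (g_idx - 2L) %in% isl_off[meth_state]
      convert <- !protected & runif(length(g_idx)) < profile$conversion_rate
      chars[g_idx[convert]] <- "A"
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs <- apply_seq_errors(seqs, profile$error_rate)

  reads <- tibble(
    read_id = sprintf("bs%06d", seq_len(n)),
    barcode = NA_character_,
    contig = "chrL",
    start = ref_start,
    end = ref_start + read_len,
    strand = "+",
    seq = seqs,
    assay = "bisulfite",
    conv_strand = conv
  )
  truth <- tibble(read_id = reads$read_id, haplotype = hap,
                  conv_strand = conv)
  list(reads = reads, truth = truth)
}

#' Simulate full-length transcript reads
#'
#' Generates error-free long reads of the three transcript classes seen at
#' an enhancer-hijacked locus: the functional heavy-chain transcript from
#' the wild-type haplotype (sense, constant-region exons, wild-type SNP
#' alleles), antisense transcription through the inserted cassette into the
#' constant region from the rearranged haplotype, and a sense fusion
#' transcript joining the upstream flank to the cassette.
#'
#' @param model A genome model with a cassette insertion.
#' @param n_per_class Reads per transcript class.
#' @param seed Integer seed.
#' @return A list with `reads` (tibble: `read_id`, `start`, `end` in
#'   `hap_rearr` scaffold coordinates, `tx_strand`, `seq`, `haplotype_seq`)
#'   and `truth` (tibble: `read_id`, `class`, `haplotype`).
#' @export
simulate_long_transcripts <- function(model, n_per_class = 5L, seed = 1L) {
  ins <- model$edits %>%
    filter(.data$haplotype == "hap_rearr", .data$op == "insert")
  if (nrow(ins) != 1) abort("model must carry exactly one cassette insertion")
  withr::local_seed(seed)
  cfg <- model$config
  ins_start <- lift_to_haplotype(model, "hap_rearr", ins$ref_pos - 1L) + 1L
  ins_end <- ins_start + ins$length
  gene_start <- cfg$promoter[1]
  gene_end <- max(vapply(cfg$exons, max, numeric(1)))

  mk <- function(class, n0) {
    purrr::map_dfr(seq_len(n0), function(i) {
      if (class == "functional_IgM") {
        s <- gene_start + sample(0:50, 1)
        e <- gene_end + sample(0:50, 1)
        hap <- "hap_wt"; strand <- "+"
      } else if (class == "antisense_oncogene") {
        s <- cfg$exons[[2]][1] - sample(0:50, 1)
        e <- ins_end - sample(0:50, 1)
        hap <- "hap_rearr"; strand <- "-"
      } else { # sense_fusion
        s <- ins$ref_pos - 300L - sample(0:50, 1)
        e <- ins_start + 600L + sample(0:50, 1)
        hap <- "hap_rearr"; strand <- "+"
      }
      # scaffold (hap_rearr) coordinates; the wild-type transcript lies in
      # the shared region upstream of the breakpoint so coordinates agree
      hs <- if (hap == "hap_rearr") s else lift_to_haplotype(model, "hap_wt", s)
      seq <- substring(model$haplotypes[[hap]], hs + 1L,
                       hs + (e - s))
      tibble(read_id = sprintf("iso_%s_%03d", class, i),
             start = as.integer(s), end = as.integer(e),
             tx_strand = strand, seq = seq, class = class, haplotype = hap)
    })
  }
  all <- bind_rows(mk("functional_IgM", n_per_class),
                   mk("antisense_oncogene", n_per_class),
                   mk("sense_fusion", n_per_class))
  list(
    reads = all %>% select("read_id", "start", "end", "tx_strand", "seq"),
    truth = all %>% select("read_id", "class", "haplotype")
  )
}
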