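#' Is a bisulfite read's conversion strand informative for a SNP?
#'
#' Bisulfite conversion destroys some SNPs on one strand: C-to-T
#' conversion on original-top (OT) reads makes a C/T SNP unreadable there,
#' and the complementary G-to-A conversion on original-bottom (OB) reads
#' (in top-strand coordinates) makes a G/A SNP unreadable there. Only
#' reads on which the two alleles remain distinguishable may be used for
#' haplotype assignment.
#'
#' @param allele_a,allele_b The SNP's two alleles (single bases).
#' @param conv_strand `"OT"` or `"OB"` (vectorised).
#' @return Logical: `TRUE` iff the alleles remain distinguishable on that
#'   strand.
#' @export
informative_orientation <- function(allele_a, allele_b, conv_strand) {
  if (any(is.na(conv_strand))) abort("conversion-strand label missing")
  if (!all(conv_strand %in% c("OT", "OB"))) {
    abort("conv_strand must be 'OT' or 'OB'")
  }
  pair <- sort(c(allele_a, allele_b))
  ct <- identical(pair, c("C", "T"))
  ga <- identical(pair, c("A", "G"))
  if_else(conv_strand == "OT", !ct, !ga)
}

#' Haplotype-resolved CpG methylation around a het SNP
#'
#' From bisulfite reads overlapping a phased het SNP, computes per-CpG,
#' per-haplotype methylation ratios within a window around the SNP.
#' Reads are first filtered to the informative conversion orientation for
#' the SNP's allele pair, assigned to a haplotype by the (post-conversion)
#' base they show at the SNP, and then their CpG calls are accumulated: on
#' OT reads C = methylated / T = unmethylated at the CpG's C position; on
#' OB reads G = methylated / A = unmethylated at the CpG's G position
#' (top-strand coordinates). Filter counts are conserved and reported.
#'
#' @param reads Bisulfite read tibble with `conv_strand` (e.g. from
#'   [simulate_bisulfite()]).
#' @param snp_id Which phased SNP anchors the window.
#' @param phased Phased SNP table (hap1 = wild type for a model table).
#' @param cpg_sites Integer vector of 0-based C positions of the CpGs
#'   (e.g. `unique(model$meth_truth$cpg_pos)`).
#' @param window Half-width in bp; CpGs outside `snp +/- window` are
#'   dropped (default 45).
#' @param min_coverage Sites below this coverage get `NA` ratio but are
#'   still reported with their coverage (default 1, i.e. no hidden
#'   threshold).
#' @return A tibble of class `methylation_profile`: `cpg_pos`,
#'   `haplotype`, `n_meth`, `n_unmeth`, `coverage`, `ratio`. Attribute
#'   `filter_counts` reports `reads_in`, `passing`, `orientation_filtered`,
#'   `non_overlapping`, `other_allele`.
#' @export
haplotype_methylation <- function(reads, snp_id, phased, cpg_sites,
                                  window = 45L, min_coverage = 1L) {
  phased_n <- normalize_phased(phased)
  s <- phased_n[phased_n$snp_id == snp_id, ]
  if (nrow(s) != 1) abort(sprintf("SNP '%s' not found in phased set", snp_id))
  cpg_sites <- sort(unique(as.integer(cpg_sites)))
  cpg_sites <- cpg_sites[cpg_sites >= s$pos - window &
                           cpg_sites <= s$pos + window]
  n_in <- nrow(reads)

  # reads must overlap the SNP (G position for OB decoding handled below)
  over <- reads$contig == s$contig & reads$start <= s$pos & reads$end > s$pos
  non_overlapping <- sum(!over)
  r <- reads[over, , drop = FALSE]

  informative <- informative_orientation(s$allele_a, s$allele_b,
                                         r$conv_strand)
  orientation_filtered <- sum(!informative)
  r <- r[informative, , drop = FALSE]

  base <- substr(r$seq, s$pos - r$start + 1L, s$pos - r$start + 1L)
  hap <- case_when(
    base == s$hap1_allele ~ "hap_wt",
    base == s$hap2_allele ~ "hap_rearr",
    TRUE ~ "other"
  )
  other_allele <- sum(hap == "other")
  keep <- hap != "other"
  r <- r[keep, , drop = FALSE]
  hap <- hap[keep]
  passing <- nrow(r)

  grid <- tidyr::expand_grid(cpg_pos = cpg_sites,
                             haplotype = c("hap_wt", "hap_rearr"))
  tallies <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    cp <- grid$cpg_pos[i]; h <- grid$haplotype[i]
    sel <- hap == h
    rr <- r[sel, , drop = FALSE]
    if (nrow(rr) == 0) {
      return(tibble(cpg_pos = cp, haplotype = h, n_meth = 0L, n_unmeth = 0L))
    }
    # decode at the C (OT) or G (OB) position of the CpG
    read_pos <- if_else(rr$conv_strand == "OT", cp, cp + 1L)
    covered <- rr$start <= read_pos & rr$end > read_pos
    rr <- rr[covered, , drop = FALSE]
    read_pos <- read_pos[covered]
    b <- substr(rr$seq, read_pos - rr$start + 1L, read_pos - rr$start + 1L)
    meth_base <- if_else(rr$conv_strand == "OT", "C", "G")
    unmeth_base <- if_else(rr$conv_strand == "OT", "T", "A")
    tibble(cpg_pos = cp, haplotype = h,
           n_meth = sum(b == meth_base),
           n_unmeth = sum(b == unmeth_base))
  })
  out <- tallies %>%
    mutate(coverage = .data$n_meth + .data$n_unmeth,
           ratio = if_else(.data$coverage >= min_coverage,
                           .data$n_meth / .data$coverage, NA_real_),
           snp_id = snp_id)
  if (passing == 0) {
    warn("no reads passed the orientation and allele filters; profile is all-NA")
  }
  attr(out, "filter_counts") <- tibble(
    reads_in = n_in, passing = passing,
    orientation_filtered = orientation_filtered,
    non_overlapping = non_overlapping, other_allele = other_allele
  )
  class(out) <- c("methylation_profile", class(out))
  out
}
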