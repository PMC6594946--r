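#' Assign reads to haplotypes at phased het SNPs
#'
#' The per-read kernel of allele-specific counting: each read is called by
#' the phased SNP alleles it carries. Reads whose SNPs all agree on one
#' haplotype are called for it; discordant alleles across SNPs give
#' `"ambiguous"`; a base matching neither allele gives `"other"` (unless
#' another covered SNP decides the read).
#'
#' @param reads Alignment tibble (`contig`, `start`, `end`, `seq`; an
#'   optional `qual` list-column of per-base qualities is honoured).
#' @param phased A `phased_snps` table; `hap1` is taken to be the
#'   haplotype carrying `hap1_allele` (for a genome model's snps table,
#'   `hap_wt`).
#' @param min_base_quality Bases below this quality are ignored (only
#'   relevant when `qual` is present; default 20).
#' @return The input tibble with columns `hap_call` (`"hap1"`, `"hap2"`,
#'   `"other"`, `"ambiguous"`) and `n_snps_covered`. Reads overlapping no
#'   phased SNP raise an error — callers prefilter.
#' @export
assign_read_to_haplotype <- function(reads, phased, min_base_quality = 20L) {
  phased <- normalize_phased(phased)
  if (nrow(reads) == 0) {
    return(reads %>% mutate(hap_call = character(0), n_snps_covered = integer(0)))
  }
  calls <- character(nrow(reads))
  ncov <- integer(nrow(reads))
  has_qual <- "qual" %in% names(reads)
  for (r in seq_len(nrow(reads))) {
    rr <- reads[r, ]
    hit <- phased$contig == rr$contig & phased$pos >= rr$start &
      phased$pos < rr$end
    if (!any(hit)) {
      abort(sprintf(
        "read %s overlaps no phased SNP; prefilter reads before assignment",
        rr$read_id %||% as.character(r)))
    }
    s <- phased[hit, ]
    off <- s$pos - rr$start + 1L
    base <- substr(rep(rr$seq, nrow(s)), off, off)
    if (has_qual && !is.null(rr$qual[[1]])) {
      q <- rr$qual[[1]][off]
      keep <- q >= min_base_quality
      s <- s[keep, , drop = FALSE]; base <- base[keep]
    }
    ncov[r] <- length(base)
    votes <- case_when(
      base == s$hap1_allele ~ "hap1",
      base == s$hap2_allele ~ "hap2",
      TRUE ~ "other"
    )
    informative <- votes[votes != "other"]
    calls[r] <- if (length(base) == 0) {
      "ambiguous"
    } else if (length(informative) == 0) {
      "other"
    } else if (all(informative == "hap1")) {
      "hap1"
    } else if (all(informative == "hap2")) {
      "hap2"
    } else {
      "ambiguous"
    }
  }
  reads %>% mutate(hap_call = calls, n_snps_covered = ncov)
}

# accept phased_snps (hap1_allele), model snps (allele_wt/rearr), or a
# bare allele_a/allele_b table (hap1 taken as allele_a); adds hap2_allele
normalize_phased <- function(phased) {
  p <- as_tibble(phased)
  if (!"hap1_allele" %in% names(p)) {
    if ("allele_wt" %in% names(p)) {
      p <- p %>% mutate(allele_a = .data$allele_wt,
                        allele_b = .data$allele_rearr,
                        hap1_allele = .data$allele_wt)
    } else if ("allele_a" %in% names(p)) {
      p <- p %>% mutate(hap1_allele = .data$allele_a)
    } else {
      abort("phased must carry hap1_allele, allele_wt/allele_rearr or allele_a/allele_b")
    }
  }
  p %>% mutate(hap2_allele = if_else(.data$hap1_allele == .data$allele_a,
                                     .data$allele_b, .data$allele_a))
}

#' Per-SNP allele counts for one assay
#'
#' Tabulates haplotype-assigned reads per phased SNP. Duplicate-flagged
#' reads are excluded when `dedup = TRUE`; RNA counting is restricted to
#' SNPs inside annotated exons when an exon table is supplied. The
#' conservation invariant holds per SNP:
#' `n_hap1 + n_hap2 + n_other + n_ambiguous` equals the number of filtered
#' reads overlapping the SNP.
#'
#' @param reads Alignment tibble.
#' @param phased Phased SNP table.
#' @param assay Label stored in the output (e.g. `"RNA"`, `"H3K27ac"`,
#'   `"ATAC"`).
#' @param exons Optional tibble of exon intervals (`start`, `end`); when
#'   given, only SNPs inside an exon are counted (the RNA read-out rule).
#' @param dedup Drop reads with `dup == TRUE` (default TRUE for tag
#'   assays).
#' @param min_base_quality Passed to [assign_read_to_haplotype()].
#' @return Tibble of class `allele_count_tbl`: `snp_id`, `assay`,
#'   `n_hap1`, `n_hap2`, `n_other`, `n_ambiguous`.
#' @export
count_alleles <- function(reads, phased, assay = "tag", exons = NULL,
                          dedup = TRUE, min_base_quality = 20L) {
  phased_n <- normalize_phased(phased)
  if (!is.null(exons)) {
    ex <- as_tibble(exons)
    inside <- vapply(seq_len(nrow(phased_n)), function(i) {
      any(phased_n$pos[i] >= ex$start & phased_n$pos[i] < ex$end)
    }, logical(1))
    phased_n <- phased_n[inside, , drop = FALSE]
  }
  if (dedup && "dup" %in% names(reads)) {
    reads <- reads %>% filter(!.data$dup)
  }
  base <- tibble(snp_id = phased_n$snp_id, assay = assay, n_hap1 = 0L,
                 n_hap2 = 0L, n_other = 0L, n_ambiguous = 0L)
  if (nrow(reads) == 0 || nrow(phased_n) == 0) {
    class(base) <- c("allele_count_tbl", class(base))
    return(base)
  }
  counts <- purrr::map_dfr(seq_len(nrow(phased_n)), function(i) {
    s <- phased_n[i, ]
    over <- reads %>%
      filter(.data$contig == s$contig, .data$start <= s$pos,
             .data$end > s$pos)
    if (nrow(over) == 0) {
      return(tibble(snp_id = s$snp_id, assay = assay, n_hap1 = 0L,
                    n_hap2 = 0L, n_other = 0L, n_ambiguous = 0L))
    }
    # per-SNP call: the base this read shows at this SNP
    off <- s$pos - over$start + 1L
    b <- substr(over$seq, off, off)
    tibble(
      snp_id = s$snp_id, assay = assay,
      n_hap1 = sum(b == s$hap1_allele),
      n_hap2 = sum(b == s$hap2_allele),
      n_other = sum(b != s$hap1_allele & b != s$hap2_allele),
      n_ambiguous = 0L
    )
  })
  class(counts) <- c("allele_count_tbl", class(counts))
  counts
}

#' Exact one-tailed binomial allelic-imbalance test
#'
#' Tests enrichment of the pre-specified first haplotype (the wild-type
#' haplotype in the enhancer-hijacking setting) against an expected read
#' probability of 0.5:
#' `p = P(X >= n_hap1 | n = n_hap1 + n_hap2, p = 0.5)`, computed by exact
#' summation of binomial probabilities (no normal approximation).
#' Significance stars follow the conventional 0.05 / 0.01 / 0.001
#' thresholds.
#'
#' @param n_hap1,n_hap2 Non-negative read counts supporting each
#'   haplotype; total must be at least 1.
#' @param two_tailed If `TRUE`, doubles the smaller tail (capped at 1);
#'   off by default — the direction is fixed a priori.
#' @return A list of class `imbalance_result`: `n_hap1`, `n_hap2`, `fold`
#'   (`Inf` when `n_hap2 == 0` and `n_hap1 > 0`), `p_value`, `direction`,
#'   `stars`.
#' @export
binomial_imbalance <- function(n_hap1, n_hap2, two_tailed = FALSE) {
  if (n_hap1 < 0 || n_hap2 < 0) abort("counts must be non-negative")
  n <- n_hap1 + n_hap2
  if (n < 1) abort("n_hap1 + n_hap2 must be >= 1")
  p <- sum(dbinom(n_hap1:n, n, 0.5))
  if (two_tailed) {
    p_lo <- sum(dbinom(0:n_hap1, n, 0.5))
    p <- min(1, 2 * min(p, p_lo))
  }
  p <- min(p, 1)
  fold <- if (n_hap2 == 0) {
    if (n_hap1 > 0) Inf else NaN
  } else {
    n_hap1 / n_hap2
  }
  structure(list(
    n_hap1 = n_hap1, n_hap2 = n_hap2, fold = fold, p_value = p,
    direction = if (n_hap1 >= n_hap2) "hap1" else "hap2",
    stars = significance_stars(p)
  ), class = "imbalance_result")
}

significance_stars <- function(p) {
  case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*", TRUE ~ "")
}

#' @export
print.imbalance_result <- function(x, ...) {
  cat(sprintf("<imbalance_result> %d vs %d (fold %s), one-tailed p = %.4g %s\n",
              x$n_hap1, x$n_hap2,
              if (is.infinite(x$fold)) "Inf" else sprintf("%.3g", x$fold),
              x$p_value, x$stars))
  invisible(x)
}

#' Imbalance tests for a whole allele-count table
#'
#' Applies [binomial_imbalance()] to every row of an `allele_count_tbl`,
#' mirroring a per-SNP, per-assay imbalance figure. An optional Bonferroni
#' correction across rows is available but off by default (per-SNP stars
#' are reported uncorrected).
#'
#' @param counts An `allele_count_tbl`.
#' @param bonferroni Multiply p-values by the number of rows (capped at
#'   1)?
#' @return The table with `fold`, `p_value`, `direction`, `stars` added.
#' @export
imbalance_table <- function(counts, bonferroni = FALSE) {
  res <- purrr::map_dfr(seq_len(nrow(counts)), function(i) {
    r <- binomial_imbalance(counts$n_hap1[i], counts$n_hap2[i])
    tibble(fold = r$fold, p_value = r$p_value, direction = r$direction)
  })
  out <- bind_cols(as_tibble(counts), res)
  if (bonferroni) out$p_value <- pmin(1, out$p_value * nrow(out))
  out$stars <- significance_stars(out$p_value)
  class(out) <- c("allele_count_tbl", setdiff(class(out), "allele_count_tbl"))
  out
}

#' Classify full-length transcript reads
#'
#' Applies the rule set for transcripts at an enhancer-hijacked locus, on
#' reads aligned to the rearranged-haplotype scaffold:
#' * `functional_IgM` — sense strand, covers a constant-region exon,
#'   carries first-haplotype (wild-type) SNP alleles, no cassette overlap;
#' * `antisense_oncogene` — antisense over the cassette joined to
#'   constant-region exons;
#' * `sense_fusion` — sense over the cassette joined to the upstream
#'   flank;
#' * `ambiguous` — anything else.
#' Haplotype is called from observed SNP alleles; reads covering no SNP
#' but overlapping the cassette are `hap_rearr` (the cassette exists only
#' there), otherwise `undetermined`.
#'
#' @param reads Long-read tibble (`read_id`, `start`, `end`, `tx_strand`,
#'   `seq`) in scaffold coordinates; unaligned reads (NA start) raise an
#'   error.
#' @param phased Phased SNP table, positions in scaffold coordinates;
#'   hap1 = wild type.
#' @param segments Tibble (`name`, `start`, `end`, `role`) with roles
#'   `constant_exon`, `cassette`, `flank` (and optionally others).
#' @return Tibble of class `transcript_calls`: `read_id`, `class`,
#'   `haplotype`, `evidence`.
#' @export
classify_long_read <- function(reads, phased, segments) {
  if (any(is.na(reads$start) | is.na(reads$end))) {
    abort("unaligned reads cannot be classified")
  }
  phased_n <- normalize_phased(phased)
  seg <- as_tibble(segments)
  out <- purrr::map_dfr(seq_len(nrow(reads)), function(i) {
    r <- reads[i, ]
    ov <- function(role) {
      s <- seg[seg$role == role, ]
      any(overlaps_interval(r$start, r$end, s$start, s$end))
    }
    covers_exon <- ov("constant_exon")
    covers_cassette <- ov("cassette")
    covers_flank <- ov("flank")
    # observed SNP alleles
    hit <- phased_n$pos >= r$start & phased_n$pos < r$end
    hap <- "undetermined"
    alleles <- character(0)
    if (any(hit)) {
      s <- phased_n[hit, ]
      off <- s$pos - r$start + 1L
      alleles <- substr(rep(r$seq, nrow(s)), off, off)
      votes <- case_when(alleles == s$hap1_allele ~ "hap_wt",
                         alleles == s$hap2_allele ~ "hap_rearr",
                         TRUE ~ "other")
      v <- votes[votes != "other"]
      if (length(v) > 0 && all(v == "hap_wt")) hap <- "hap_wt"
      if (length(v) > 0 && all(v == "hap_rearr")) hap <- "hap_rearr"
    }
    if (hap == "undetermined" && covers_cassette) hap <- "hap_rearr"
    cls <- if (r$tx_strand == "+" && covers_exon && !covers_cassette &&
               hap %in% c("hap_wt", "undetermined")) {
      "functional_IgM"
    } else if (r$tx_strand == "-" && covers_cassette && covers_exon) {
      "antisense_oncogene"
    } else if (r$tx_strand == "+" && covers_cassette && covers_flank) {
      "sense_fusion"
    } else {
      "ambiguous"
    }
    tibble(read_id = r$read_id, class = cls, haplotype = hap,
           evidence = sprintf("alleles=%s;strand=%s;exon=%d;cassette=%d",
                              paste(alleles, collapse = ""), r$tx_strand,
                              covers_exon, covers_cassette))
  })
  class(out) <- c("transcript_calls", class(out))
  out
}

#' Default scaffold segment annotation from a genome model
#'
#' Builds the segment table used by [classify_long_read()] in
#' rearranged-haplotype coordinates: constant-region exons, enhancer,
#' inserted cassette, and the upstream flank adjoining the breakpoint.
#'
#' @param model A genome model with a cassette insertion.
#' @param flank_len Length of the upstream flank segment.
#' @return Tibble with `name`, `start`, `end`, `role`, `strand`.
#' @export
model_segments <- function(model, flank_len = 500L) {
  cfg <- model$config
  ins <- model$edits %>%
    filter(.data$haplotype == "hap_rearr", .data$op == "insert")
  if (nrow(ins) != 1) abort("model must carry exactly one cassette insertion")
  ins_start <- lift_to_haplotype(model, "hap_rearr", ins$ref_pos - 1L) + 1L
  exon_rows <- purrr::map_dfr(seq_along(cfg$exons), function(i) {
    tibble(name = sprintf("constant_exon%d", i),
           start = lift_to_haplotype(model, "hap_rearr", cfg$exons[[i]][1]),
           end = lift_to_haplotype(model, "hap_rearr",
                                   cfg$exons[[i]][2] - 1L) + 1L,
           role = "constant_exon", strand = "+")
  })
  bind_rows(
    exon_rows,
    tibble(name = "Emu",
           start = lift_to_haplotype(model, "hap_rearr", cfg$enhancer[1]),
           end = lift_to_haplotype(model, "hap_rearr",
                                   cfg$enhancer[2] - 1L) + 1L,
           role = "enhancer", strand = "*"),
    tibble(name = "cassette", start = ins_start,
           end = ins_start + ins$length, role = "cassette", strand = "+"),
    tibble(name = "upstream_flank", start = ins_start - flank_len,
           end = ins_start, role = "flank", strand = "+")
  )
}
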