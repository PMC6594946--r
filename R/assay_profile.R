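#' Assay simulation profile
#'
#' Bundles the per-assay simulation parameters: sequencing depth, expected
#' haplotype read ratio, substitution error rate, bisulfite conversion
#' rate, and the contact distance-decay exponent.
#'
#' @param assay One of `"wgs_linked"`, `"rna_stranded"`, `"tag"` (ChIP/ATAC
#'   style), `"bisulfite"`, `"contact"`.
#' @param depth Mean reads per target (per SNP for tag/RNA assays; total
#'   reads over the CpG window for bisulfite).
#' @param allelic_ratio Expected `hap_wt:hap_rearr` read ratio; reads are
#'   drawn from `hap_wt` with probability `r / (1 + r)`.
#' @param error_rate Per-base substitution probability (must be `< 0.05`).
#' @param conversion_rate Bisulfite conversion probability for
#'   unmethylated cytosines (default 0.993, a typical mitochondria-derived
#'   estimate).
#' @param decay_exponent Power-law exponent of contact distance decay.
#' @param read_len Simulated read length in bp.
#' @param seed Integer seed for the simulator that consumes this profile.
#' @return A list of class `assay_profile`.
#' @export
assay_profile <- function(assay = c("wgs_linked", "rna_stranded", "tag",
                                    "bisulfite", "contact"),
                          depth = 200, allelic_ratio = 1, error_rate = 0,
                          conversion_rate = 0.993, decay_exponent = 1,
                          read_len = 100L, seed = 1L) {
  assay <- match.arg(assay)
  if (!is.numeric(allelic_ratio) || allelic_ratio <= 0) {
    abort("allelic_ratio must be > 0")
  }
  if (error_rate < 0 || error_rate >= 0.05) {
    abort("error_rate must be in [0, 0.05)")
  }
  if (conversion_rate <= 0 || conversion_rate > 1) {
    abort("conversion_rate must be in (0, 1]")
  }
  if (assay == "contact" && decay_exponent <= 0) {
    abort("decay_exponent must be > 0")
  }
  structure(list(assay = assay, depth = depth, allelic_ratio = allelic_ratio,
                 error_rate = error_rate, conversion_rate = conversion_rate,
                 decay_exponent = decay_exponent,
                 read_len = as.integer(read_len), seed = as.integer(seed)),
            class = "assay_profile")
}
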