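# broom-style tidiers for the package's result objects

#' Tidy an imbalance test result
#' @param x An `imbalance_result`.
#' @param ... Unused.
#' @return One-row tibble: counts, fold, p-value, direction, stars.
#' @export
tidy.imbalance_result <- function(x, ...) {
  tibble(n_hap1 = x$n_hap1, n_hap2 = x$n_hap2, fold = x$fold,
         p_value = x$p_value, direction = x$direction, stars = x$stars)
}

#' Tidy a cohort expression summary
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @return A tibble with one row per statistic (`term`, `estimate`).
#' @export
tidy.cohort_summary <- function(x, ...) {
  tibble(
    term = c(paste0("median_", x$gene1), paste0("median_", x$gene2),
             "t_p_one_tailed", "pearson_r", "pearson_p", "ratio_mean",
             "ratio_ci_low", "ratio_ci_high"),
    estimate = c(x$median1, x$median2, x$t_p_one_tailed, x$pearson_r,
                 x$pearson_p, x$ratio_mean, x$ratio_ci[1], x$ratio_ci[2])
  )
}

#' One-row summary of a cohort expression summary
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.cohort_summary <- function(x, ...) {
  tibble(n = x$n, median1 = x$median1, median2 = x$median2,
         t_p_one_tailed = x$t_p_one_tailed, pearson_r = x$pearson_r,
         pearson_p = x$pearson_p, ratio_mean = x$ratio_mean)
}

#' Tidy an interaction fold
#' @param x An `interaction_fold`.
#' @param ... Unused.
#' @return One-row tibble with the float ratio and the rounded report.
#' @export
tidy.interaction_fold <- function(x, ...) {
  tibble(ratio = x$ratio, rounded = x$rounded, defined = x$defined)
}

#' One-row summary of a pipeline report's qualitative conclusions
#' @param x A `pipeline_report`.
#' @param ... Unused.
#' @return A one-row tibble of flags (NA for stages that did not run).
#' @export
glance.pipeline_report <- function(x, ...) {
  f <- x$ase$flags
  tibble(
    rna_flag = f[["RNA"]] %||% NA_character_,
    chip_flag = f[["H3K27ac"]] %||% NA_character_,
    atac_flag = f[["ATAC"]] %||% NA_character_,
    methylation_flag = x$methylation$flag %||% NA_character_,
    contact_flag = x$contacts$flag %||% NA_character_,
    switch_error = x$phasing$switch_error %||% NA_real_
  )
}
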