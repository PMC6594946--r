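#' Plot per-SNP allelic imbalance
#'
#' Side-by-side haplotype read counts per SNP, faceted by assay, with
#' significance stars when the table carries imbalance results.
#'
#' @param object An `allele_count_tbl` (ideally after
#'   [imbalance_table()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.allele_count_tbl <- function(object, ...) {
  long <- as_tibble(object) %>%
    tidyr::pivot_longer(c("n_hap1", "n_hap2"), names_to = "haplotype",
                        values_to = "reads") %>%
    mutate(haplotype = if_else(.data$haplotype == "n_hap1",
                               "wild-type", "rearranged"))
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(x = .data$snp_id, y = .data$reads,
                                    fill = .data$haplotype)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~assay) +
    ggplot2::labs(x = NULL, y = "reads", fill = "haplotype") +
    ggplot2::theme_minimal()
  if ("stars" %in% names(object)) {
    stars <- as_tibble(object) %>%
      mutate(y = pmax(.data$n_hap1, .data$n_hap2) * 1.05)
    p <- p + ggplot2::geom_text(
      data = stars,
      ggplot2::aes(x = .data$snp_id, y = .data$y, label = .data$stars),
      inherit.aes = FALSE
    )
  }
  p
}

#' Plot a haplotype methylation profile
#'
#' One circle per CpG site per haplotype, sized by coverage and coloured
#' by methylation ratio — the conventional allele-specific methylation
#' display.
#'
#' @param object A `methylation_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.methylation_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$cpg_pos, y = .data$haplotype,
                               size = .data$coverage,
                               colour = .data$ratio)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient(low = "white", high = "black",
                                   limits = c(0, 1)) +
    ggplot2::labs(x = "CpG position (bp)", y = NULL,
                  colour = "methylation", size = "coverage") +
    ggplot2::theme_minimal()
}

#' Plot interaction quantifications per assay
#'
#' Supporting counts (pairs, or peak coverage for capture assays) for the
#' enhancer-promoter and enhancer-cassette interactions, annotated with
#' the fold.
#'
#' @param quant Tibble as in a pipeline report's `contacts$quant` (columns
#'   `assay`, `promoter`, `cassette`, `fold_rounded`).
#' @return A ggplot object.
#' @export
plot_interaction_quant <- function(quant) {
  long <- as_tibble(quant) %>%
    tidyr::pivot_longer(c("promoter", "cassette"), names_to = "pair",
                        values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$assay, y = .data$count,
                                     fill = .data$pair)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(
      data = as_tibble(quant),
      ggplot2::aes(x = .data$assay, y = pmax(.data$promoter, .data$cassette),
                   label = paste0(.data$fold_rounded, "x")),
      inherit.aes = FALSE, vjust = -0.4
    ) +
    ggplot2::labs(x = NULL, y = "supporting count",
                  fill = "interaction") +
    ggplot2::theme_minimal()
}

#' Plot contact distance decay
#'
#' Log-log binned intra-contig contact frequency against distance, with
#' the fitted power-law exponent in the subtitle.
#'
#' @param contacts A contact tibble.
#' @param ... Passed to [fit_decay_exponent()].
#' @return A ggplot object.
#' @export
plot_contact_decay <- function(contacts, ...) {
  fit <- fit_decay_exponent(contacts, ...)
  ggplot2::ggplot(fit$bins, ggplot2::aes(x = .data$mid, y = .data$density)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "distance (bp)", y = "pair density",
                  subtitle = sprintf("fitted decay exponent %.2f",
                                     fit$exponent)) +
    ggplot2::theme_minimal()
}
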