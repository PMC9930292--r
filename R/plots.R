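#' Plot per-gene carrier prevalence
#'
#' Bar chart of the fraction of the screened cohort carrying P/LP variants
#' in each gene, colored by functional category when available.
#'
#' @param object A `poi_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot poi_summary
#' @export
autoplot.poi_summary <- function(object, ...) {
  d <- object$per_gene
  d$gene <- factor(d$gene, levels = rev(d$gene))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$fraction, y = .data$gene))
  if ("category" %in% names(d)) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$category))
  } else {
    p <- p + ggplot2::geom_col()
  }
  p +
    ggplot2::scale_x_continuous(labels = function(x) sprintf("%g%%", 100 * x)) +
    ggplot2::labs(x = "carrier prevalence", y = NULL,
                  title = "P/LP variant prevalence by gene") +
    ggplot2::theme_minimal()
}

#' Plot monogenic vs oligogenic phenotype contrasts
#'
#' Group means with +/- 1 SD error bars for each compared continuous trait.
#'
#' @param object A `poi_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot poi_comparison
#' @export
autoplot.poi_comparison <- function(object, ...) {
  t <- object$traits
  long <- dplyr::bind_rows(
    tibble::tibble(trait = t$trait, group = "monogenic",
                   mean = t$mean_monogenic, sd = t$sd_monogenic),
    tibble::tibble(trait = t$trait, group = "oligogenic",
                   mean = t$mean_oligogenic, sd = t$sd_oligogenic)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.15) +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "years") +
    ggplot2::theme_minimal()
}

#' Plot the variant filtering funnel
#'
#' Counts of variants entering the rarity filter, surviving it, and their
#' P / LP / VUS classification.
#'
#' @param result A `poi_pipeline`.
#' @return A ggplot object.
#' @export
plot_filter_funnel <- function(result) {
  tally <- classification_tally(result$classified)
  d <- tibble::tibble(
    stage = factor(c("input", "rare", "P", "LP", "VUS"),
                   levels = c("input", "rare", "P", "LP", "VUS")),
    count = c(nrow(result$kept) + nrow(result$rejected), nrow(result$kept),
              tally$n_p, tally$n_lp, tally$n_vus)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "variants",
                  title = "Variant filtering and classification") +
    ggplot2::theme_minimal()
}
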