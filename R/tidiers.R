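#' Tidy a cohort summary
#'
#' @param x A `poi_summary`.
#' @param ... Unused.
#' @return The per-gene prevalence tibble (gene, carriers, fraction).
#' @method tidy poi_summary
#' @export
tidy.poi_summary <- function(x, ...) {
  x$per_gene
}

#' One-row cohort summary counts
#'
#' @param x A `poi_summary`.
#' @param ... Unused.
#' @method glance poi_summary
#' @export
glance.poi_summary <- function(x, ...) {
  x$counts
}

#' Tidy an enrichment test
#'
#' @param x A `poi_enrichment`.
#' @param ... Unused.
#' @return A one-row tibble with `estimate` (odds ratio), `p.value`,
#'   cohort/reference frequencies and the unit.
#' @method tidy poi_enrichment
#' @export
tidy.poi_enrichment <- function(x, ...) {
  tibble::tibble(
    estimate = x$estimate, p.value = x$p.value,
    cohort_freq = x$cohort_freq, ref_freq = x$ref_freq,
    unit = x$unit, method = x$method
  )
}

#' @rdname tidy.poi_enrichment
#' @method glance poi_enrichment
#' @export
glance.poi_enrichment <- function(x, ...) tidy.poi_enrichment(x, ...)

#' Tidy a subgroup comparison
#'
#' @param x A `poi_comparison`.
#' @param ... Unused.
#' @return One row per compared trait (continuous traits and the
#'   primary-amenorrhea categorical test).
#' @method tidy poi_comparison
#' @export
tidy.poi_comparison <- function(x, ...) {
  rows <- x$traits
  if (!is.null(x$pa_test)) {
    g <- x$groups
    mono <- g[g$group == "monogenic", ]
    oligo <- g[g$group == "oligogenic", ]
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      trait = "pa_fraction",
      n_monogenic = mono$n_pa_known, mean_monogenic = mono$pa_fraction,
      sd_monogenic = NA_real_,
      n_oligogenic = oligo$n_pa_known, mean_oligogenic = oligo$pa_fraction,
      sd_oligogenic = NA_real_,
      p.value = x$pa_test$p.value, method = x$pa_test$method
    ))
  }
  rows
}

#' Group sizes of a subgroup comparison
#'
#' @param x A `poi_comparison`.
#' @param ... Unused.
#' @method glance poi_comparison
#' @export
glance.poi_comparison <- function(x, ...) {
  g <- x$groups
  tibble::tibble(
    n_monogenic = g$n[g$group == "monogenic"],
    n_oligogenic = g$n[g$group == "oligogenic"],
    min_p = min(c(x$traits$p.value,
                  if (!is.null(x$pa_test)) x$pa_test$p.value), na.rm = TRUE)
  )
}

#' Overall pipeline counts
#'
#' @param x A `poi_pipeline`.
#' @param ... Unused.
#' @method glance poi_pipeline
#' @export
glance.poi_pipeline <- function(x, ...) {
  x$summary$counts
}
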