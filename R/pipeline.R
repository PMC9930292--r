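#' Run the full variant-interpretation pipeline
#'
#' Chains the four analysis stages on a loaded cohort: rarity filter
#' ([filter_variants()]), P/LP/VUS classification ([classify_variants()]),
#' per-patient causality assignment ([assign_cohort()]) and cohort summary
#' ([summarize_cohort()]). All stages are deterministic.
#'
#' @param cohort A `poi_cohort` (from [read_cohort()], [poi_example_cohort()]
#'   or [simulate_cohort()]).
#' @param panel Panel tibble; defaults to the packaged 28-gene panel.
#' @param cohort_n Total screened cohort size; defaults to the number of
#'   patients in the cohort.
#' @param maf_threshold Rarity threshold (strictly-below), default 0.001.
#' @param cadd_threshold,dann_threshold,lp_rule Classifier settings, see
#'   [classify_variants()].
#' @param mode Causality mode, `"carrier"` (default) or `"strict"`.
#' @return A list of class `poi_pipeline` with elements `kept`, `rejected`,
#'   `classified`, `assignments` and `summary`.
#' @examples
#' res <- run_poi_pipeline(poi_example_cohort(), cohort_n = 500)
#' glance(res$summary)
#' @export
run_poi_pipeline <- function(cohort, panel = poi_default_panel(),
                             cohort_n = nrow(cohort$patients),
                             maf_threshold = 0.001,
                             cadd_threshold = 3, dann_threshold = 0.95,
                             lp_rule = "metasvm_and_either",
                             mode = c("carrier", "strict")) {
  mode <- match.arg(mode)
  filt <- filter_variants(cohort$variants, threshold = maf_threshold)
  classified <- classify_variants(filt$kept, cadd_threshold = cadd_threshold,
                                  dann_threshold = dann_threshold,
                                  lp_rule = lp_rule)
  assignments <- assign_cohort(cohort$genotypes, classified, panel,
                               mode = mode, patients = cohort$patients)
  summary <- summarize_cohort(assignments, classified, cohort$genotypes,
                              cohort_n = cohort_n, panel = panel,
                              patients = cohort$patients)
  structure(
    list(kept = filt$kept, rejected = filt$rejected, classified = classified,
         assignments = assignments, summary = summary),
    class = "poi_pipeline"
  )
}

#' @export
print.poi_pipeline <- function(x, ...) {
  cat("<poi_pipeline>\n")
  cat("  rare variants kept: ", nrow(x$kept),
      " (rejected: ", nrow(x$rejected), ")\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Re-run the packaged example cohort and check the headline numbers
#'
#' Runs the full pipeline on the packaged 72-patient example cohort with a
#' screened cohort size of 500 and compares each headline statistic with
#' its expected value.
#'
#' @param maf_threshold,mode Passed to [run_poi_pipeline()].
#' @return A tibble with columns `metric`, `expected`, `observed`, `pass`.
#' @export
reproduce_headline <- function(maf_threshold = 0.001, mode = "carrier") {
  res <- run_poi_pipeline(poi_example_cohort(), cohort_n = 500,
                          maf_threshold = maf_threshold, mode = mode)
  g <- glance(res$summary)
  foxl2 <- res$summary$per_gene
  nobox_c <- foxl2$carriers[foxl2$gene == "NOBOX"]
  foxl2_c <- foxl2$carriers[foxl2$gene == "FOXL2"]
  pv <- res$summary$per_variant
  r349g <- pv$carriers[pv$gene == "FOXL2" & pv$hgvs_c == "c.1045C>G"]
  biallelic <- sum(purrr::map_lgl(res$assignments$mechanisms, function(m) {
    any(m$mechanism %in% c("AR_hom", "AR_compound_het") &
          m$gene_label %in% c("MSH4", "MSH5"))
  }))
  observed <- c(
    explained_percent = 100 * g$explained_fraction,
    n_plp_variants = g$n_variants,
    n_pathogenic = g$n_p,
    n_likely_pathogenic = g$n_lp,
    n_genes_hit = g$n_genes_hit,
    n_novel = g$n_novel,
    foxl2_carriers = foxl2_c,
    foxl2_r349g_carriers = r349g,
    nobox_carriers = nobox_c,
    n_oligogenic = g$n_oligogenic,
    msh4_msh5_biallelic = biallelic
  )
  expected <- c(
    explained_percent = 14.4, n_plp_variants = 61, n_pathogenic = 18,
    n_likely_pathogenic = 43, n_genes_hit = 19, n_novel = 58,
    foxl2_carriers = 16, foxl2_r349g_carriers = 13, nobox_carriers = 6,
    n_oligogenic = 9, msh4_msh5_biallelic = 5
  )
  obs_ordered <- unname(observed[names(expected)])
  tibble::tibble(
    metric = names(expected),
    expected = unname(expected),
    observed = obs_ordered,
    pass = abs(unname(expected) - obs_ordered) < 1e-9
  )
}
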