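#' Summarize a classified, assigned cohort
#'
#' Computes the cohort-level counts: explained patients, unique P/LP
#' variants (VUS are excluded from causal tables), genes hit, novel variants
#' (not previously reported), and per-gene / per-variant carrier prevalence
#' against the full screened cohort size.
#'
#' @param assignments Assignment tibble from [assign_cohort()].
#' @param classified Classified variant tibble from [classify_variants()].
#' @param genotypes Genotype observation tibble.
#' @param cohort_n Total number of screened patients (may exceed the number
#'   of patients listed with variants; e.g. 500 for a screen in which only
#'   carriers are tabulated).
#' @param panel Optional panel tibble; adds the gene category to the
#'   per-gene prevalence table.
#' @param patients Optional patient phenotype tibble; when supplied, a
#'   monogenic-vs-oligogenic subgroup comparison ([compare_subgroups()]) is
#'   attached.
#' @return An object of class `poi_summary`: a list with `counts` (one-row
#'   tibble), `per_gene`, `per_variant` and optionally `comparison`.
#'   [glance()] returns the counts; [tidy()] the per-gene prevalence table.
#' @examples
#' cohort <- poi_example_cohort()
#' classified <- classify_variants(filter_variants(cohort$variants)$kept)
#' asn <- assign_cohort(cohort$genotypes, classified, poi_default_panel())
#' summ <- summarize_cohort(asn, classified, cohort$genotypes, cohort_n = 500)
#' glance(summ)
#' @export
summarize_cohort <- function(assignments, classified, genotypes, cohort_n,
                             panel = NULL, patients = NULL) {
  n_listed <- dplyr::n_distinct(c(genotypes$patient_id, assignments$patient_id))
  if (cohort_n < n_listed) {
    abort(paste0("cohort_n (", cohort_n, ") is smaller than the number of ",
                 "distinct patients (", n_listed, ")"))
  }
  plp <- classified[classified$verdict %in% c("P", "LP"), , drop = FALSE]
  geno_plp <- dplyr::inner_join(
    genotypes, plp[, c("gene", "hgvs_c", "verdict")], by = c("gene", "hgvs_c"))

  per_gene <- geno_plp |>
    dplyr::group_by(gene = .data$gene) |>
    dplyr::summarise(carriers = dplyr::n_distinct(.data$patient_id), .groups = "drop") |>
    dplyr::mutate(fraction = .data$carriers / cohort_n) |>
    dplyr::arrange(dplyr::desc(.data$carriers), .data$gene)
  if (!is.null(panel)) {
    per_gene <- dplyr::left_join(per_gene, panel[, c("symbol", "category")],
                                 by = c(gene = "symbol"))
  }
  per_variant <- geno_plp |>
    dplyr::group_by(gene = .data$gene, hgvs_c = .data$hgvs_c) |>
    dplyr::summarise(carriers = dplyr::n_distinct(.data$patient_id), .groups = "drop") |>
    dplyr::mutate(fraction = .data$carriers / cohort_n) |>
    dplyr::arrange(dplyr::desc(.data$carriers), .data$gene, .data$hgvs_c)

  tal <- assignment_tally(assignments)
  counts <- tibble::tibble(
    n_patients = as.integer(cohort_n),
    patients_with_plp = tal$n_explained,
    explained_fraction = tal$n_explained / cohort_n,
    n_variants = nrow(plp),
    n_p = sum(plp$verdict == "P"),
    n_lp = sum(plp$verdict == "LP"),
    n_genes_hit = dplyr::n_distinct(plp$gene),
    n_novel = sum(!plp$known_pathogenic),
    n_monogenic_only = tal$n_monogenic_only,
    n_oligogenic = tal$n_oligogenic
  )
  both_groups <- sum(assignments$explained & assignments$oligogenic) > 0L &&
    sum(assignments$explained & !assignments$oligogenic) > 0L
  comparison <- if (!is.null(patients) && both_groups)
    compare_subgroups(assignments, patients) else NULL
  structure(
    list(counts = counts, per_gene = per_gene, per_variant = per_variant,
         comparison = comparison),
    class = "poi_summary"
  )
}

#' @export
print.poi_summary <- function(x, ...) {
  c0 <- x$counts
  cat("<poi_summary>\n")
  cat(sprintf("  %d / %d patients carry P/LP variants (%.1f%%)\n",
              c0$patients_with_plp, c0$n_patients, 100 * c0$explained_fraction))
  cat(sprintf("  %d unique P/LP variants (%d P, %d LP) in %d genes; %d novel\n",
              c0$n_variants, c0$n_p, c0$n_lp, c0$n_genes_hit, c0$n_novel))
  cat(sprintf("  %d monogenic, %d oligogenic patients\n",
              c0$n_monogenic_only, c0$n_oligogenic))
  invisible(x)
}

#' Carrier-frequency enrichment against a reference population
#'
#' Compares the observed carrier count in the cohort with a reference
#' allele frequency by an exact two-sided test on the 2x2 table, with the
#' p-value computed from the hypergeometric distribution (the sum of the
#' probabilities of all tables with the observed margins that are no more
#' probable than the observed one). The odds ratio is the sample
#' (cross-product) odds ratio.
#'
#' With `unit = "allele"` (default) each heterozygous carrier contributes
#' one of the cohort's `2 * cohort_n` alleles; `unit = "carrier"` compares
#' carrier counts against `cohort_n` individuals. Both are provided because
#' cohort screens often report carrier frequencies while databases report
#' allele frequencies.
#'
#' @param carriers Number of (heterozygous) carriers observed in the cohort.
#' @param cohort_n Number of screened patients.
#' @param ref_af Reference allele frequency in `[0, 1]`.
#' @param ref_alleles Number of reference alleles (2 x reference sample
#'   size). The implied reference allele count `ref_alleles * ref_af` is
#'   rounded to the nearest integer with a warning when fractional.
#' @param unit `"allele"` or `"carrier"`.
#' @return An object of class `poi_enrichment` with elements `estimate`
#'   (odds ratio), `p.value`, `table`, `unit`, `cohort_freq`, `ref_freq`.
#' @examples
#' enrichment_test(13, 500, ref_af = 0.0008, ref_alleles = 5008)
#' @export
enrichment_test <- function(carriers, cohort_n, ref_af, ref_alleles,
                            unit = c("allele", "carrier")) {
  unit <- match.arg(unit)
  stopifnot(carriers >= 0, cohort_n > 0, ref_alleles > 0,
            ref_af >= 0, ref_af <= 1)
  x1 <- carriers
  n1 <- if (unit == "allele") 2L * cohort_n else cohort_n
  if (x1 > n1) abort("more carriers than cohort units")
  x2_raw <- ref_alleles * ref_af
  x2 <- round(x2_raw)
  if (abs(x2_raw - x2) > 1e-8) {
    warn(sprintf("reference allele count %.4f is not an integer; rounded to %d",
                 x2_raw, x2))
  }
  n2 <- ref_alleles
  tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2, byrow = TRUE,
                dimnames = list(c("cohort", "reference"),
                                c("variant", "other")))
  p <- hypergeom_p2(x1, n1, x2, n2)
  or <- (x1 * (n2 - x2)) / ((n1 - x1) * x2)
  structure(
    list(estimate = or, p.value = p, table = tab, unit = unit,
         cohort_freq = x1 / n1, ref_freq = x2 / n2,
         method = "two-sided exact hypergeometric test"),
    class = "poi_enrichment"
  )
}

# two-sided exact p for a 2x2 table (x1 of n1 vs x2 of n2):
# condition on the margins and sum hypergeometric probabilities of all
# tables no more probable than the observed one (the fisher.test rule)
hypergeom_p2 <- function(x1, n1, x2, n2) {
  m <- x1 + x2           # total successes
  k <- n1                # cohort column margin
  lo <- max(0L, k - (n1 + n2 - m))
  hi <- min(k, m)
  support <- lo:hi
  d <- dhyper(support, m, n1 + n2 - m, k)
  rel_err <- 1 + 1e-7
  sum(d[d <= d[support == x1] * rel_err])
}

#' @export
print.poi_enrichment <- function(x, ...) {
  cat("<poi_enrichment> ", x$method, "\n", sep = "")
  cat(sprintf("  unit: %s  cohort %d/%d (%.4f) vs reference %d/%d (%.4f)\n",
              x$unit, x$table[1, 1], sum(x$table[1, ]), x$cohort_freq,
              x$table[2, 1], sum(x$table[2, ]), x$ref_freq))
  cat(sprintf("  odds ratio = %.3g, p = %.3g\n", x$estimate, x$p.value))
  invisible(x)
}

#' Compare phenotypes between monogenic and oligogenic patients
#'
#' Restricts to explained patients, splits them into monogenic and
#' oligogenic subgroups, and compares age at menarche and age at POI onset
#' (group means +/- SD over non-missing values, one-way ANOVA, equivalent
#' to a two-sample t-test for two groups) and the primary-amenorrhea
#' fraction (chi-square test, with an automatic fallback to the exact test
#' when any expected cell count is below 5). All p-values are two-sided;
#' missing phenotype values are excluded listwise per trait, with the n
#' used reported. SDs use the n-1 denominator.
#'
#' @param assignments Assignment tibble from [assign_cohort()].
#' @param patients Patient phenotype tibble.
#' @return An object of class `poi_comparison`: list with `groups` (sizes
#'   and PA fractions), `traits` (per-trait means, SDs, n and p-values),
#'   `pa_test` (categorical test) and `skipped` (traits skipped, with
#'   reasons).
#' @export
compare_subgroups <- function(assignments, patients) {
  dat <- assignments |>
    dplyr::filter(.data$explained) |>
    dplyr::mutate(group = ifelse(.data$oligogenic, "oligogenic", "monogenic")) |>
    dplyr::inner_join(patients, by = "patient_id")
  if (dplyr::n_distinct(dat$group) < 2L) {
    abort("both a monogenic and an oligogenic subgroup are required")
  }
  pa_known <- dat[dat$amenorrhea %in% c("PA", "SA"), , drop = FALSE]
  groups <- dat |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(
      pa_known |>
        dplyr::group_by(.data$group) |>
        dplyr::summarise(n_pa_known = dplyr::n(),
                         pa_n = sum(.data$amenorrhea == "PA"),
                         pa_fraction = mean(.data$amenorrhea == "PA"),
                         .groups = "drop"),
      by = "group")

  traits <- list()
  skipped <- list()
  for (trait in c("menarche_age", "onset_age")) {
    v <- dat[[trait]]
    keep <- !is.na(v)
    sub <- dat[keep, , drop = FALSE]
    nm <- sum(sub$group == "monogenic")
    no <- sum(sub$group == "oligogenic")
    if (nm == 0L || no == 0L) {
      skipped[[trait]] <- sprintf("%s entirely missing in the %s group", trait,
                                  if (nm == 0L) "monogenic" else "oligogenic")
      next
    }
    vm <- sub[[trait]][sub$group == "monogenic"]
    vo <- sub[[trait]][sub$group == "oligogenic"]
    if (stats::var(sub[[trait]]) == 0) {
      p <- 1
    } else {
      fit <- aov(sub[[trait]] ~ factor(sub$group))
      p <- summary(fit)[[1]][["Pr(>F)"]][1]
    }
    traits[[trait]] <- tibble::tibble(
      trait = trait,
      n_monogenic = nm, mean_monogenic = mean(vm), sd_monogenic = sd(vm),
      n_oligogenic = no, mean_oligogenic = mean(vo), sd_oligogenic = sd(vo),
      p.value = p, method = "one-way ANOVA"
    )
  }
  traits <- dplyr::bind_rows(traits)

  pa_test <- NULL
  if (nrow(pa_known) > 0L && dplyr::n_distinct(pa_known$group) == 2L) {
    tab <- table(pa_known$group, pa_known$amenorrhea == "PA")
    if (ncol(tab) < 2L) {
      pa_test <- tibble::tibble(p.value = 1, method = "degenerate (one level)")
    } else {
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        ft <- fisher.test(tab)
        pa_test <- tibble::tibble(p.value = ft$p.value, method = "Fisher exact test")
      } else {
        ct <- suppressWarnings(chisq.test(tab))
        pa_test <- tibble::tibble(p.value = ct$p.value, method = "chi-square test")
      }
    }
  } else {
    skipped[["pa"]] <- "amenorrhea type entirely missing in a group"
  }
  structure(
    list(groups = groups, traits = traits, pa_test = pa_test,
         skipped = unlist(skipped)),
    class = "poi_comparison"
  )
}

#' @export
print.poi_comparison <- function(x, ...) {
  cat("<poi_comparison> monogenic vs oligogenic\n")
  g <- x$groups
  for (i in seq_len(nrow(g))) {
    cat(sprintf("  %-10s n = %d, PA %d/%d (%.1f%%)\n", g$group[i], g$n[i],
                g$pa_n[i], g$n_pa_known[i], 100 * g$pa_fraction[i]))
  }
  t <- x$traits
  for (i in seq_len(nrow(t))) {
    cat(sprintf("  %-12s %.2f +/- %.2f (n=%d) vs %.2f +/- %.2f (n=%d), p = %.3f\n",
                t$trait[i], t$mean_monogenic[i], t$sd_monogenic[i], t$n_monogenic[i],
                t$mean_oligogenic[i], t$sd_oligogenic[i], t$n_oligogenic[i],
                t$p.value[i]))
  }
  if (!is.null(x$pa_test)) {
    cat(sprintf("  PA fraction: p = %.3f (%s)\n", x$pa_test$p.value, x$pa_test$method))
  }
  invisible(x)
}
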