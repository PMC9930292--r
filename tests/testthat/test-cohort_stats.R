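pipeline_res <- run_example_pipeline()
summary_500 <- pipeline_res$summary

test_that("summarize_cohort reports the cohort-level counts and prevalences", {
  g <- glance(summary_500)
  expect_equal(g$patients_with_plp, 72)
  expect_equal(g$n_variants, 61)
  expect_equal(g$n_genes_hit, 19)
  expect_equal(g$n_novel, 58)
  pg <- summary_500$per_gene
  expect_equal(pg$carriers[pg$gene == "FOXL2"], 16)
  expect_equal(pg$fraction[pg$gene == "FOXL2"], 0.032)
  expect_equal(pg$carriers[pg$gene == "NOBOX"], 6)
  pv <- summary_500$per_variant
  expect_equal(pv$carriers[pv$gene == "FOXL2" & pv$hgvs_c == "c.1045C>G"], 13)
  expect_equal(pv$fraction[pv$gene == "FOXL2" & pv$hgvs_c == "c.1045C>G"], 0.026)
  # fractions are exactly carriers / cohort_n
  expect_equal(pg$fraction, pg$carriers / 500)
  # a cohort size below the number of listed patients is rejected
  expect_error(summarize_cohort(pipeline_res$assignments, pipeline_res$classified,
                                example_cohort$genotypes, cohort_n = 10),
               "smaller")
})

test_that("summarize_cohort is invariant to input row order", {
  set.seed(41)
  geno_shuffled <- example_cohort$genotypes[sample(91), ]
  class_shuffled <- pipeline_res$classified[sample(61), ]
  asn_shuffled <- pipeline_res$assignments[sample(72), ]
  s2 <- summarize_cohort(asn_shuffled, class_shuffled, geno_shuffled,
                         cohort_n = 500)
  expect_equal(glance(s2), glance(summary_500))
  expect_equal(s2$per_gene[, c("gene", "carriers", "fraction")],
               summary_500$per_gene[, c("gene", "carriers", "fraction")])
})

test_that("the exact enrichment test matches the enumeration oracle exhaustively", {
  # every 2x2 table with total N <= 26 (hence all margins <= 26)
  got <- want <- numeric(0)
  for (N in 2:26) {
    for (n1 in 1:(N - 1)) {
      n2 <- N - n1
      for (m in 0:N) {
        for (x1 in max(0, m - n2):min(m, n1)) {
          x2 <- m - x1
          got <- c(got, poipanel:::hypergeom_p2(x1, n1, x2, n2))
          want <- c(want, oracle_exact_p(x1, n1, x2, n2))
        }
      }
    }
  }
  expect_gt(length(got), 10000)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("the exact test agrees with the canonical implementation", {
  set.seed(51)
  for (i in 1:200) {
    n1 <- sample(2:50, 1); n2 <- sample(2:50, 1)
    x1 <- sample(0:n1, 1); x2 <- sample(0:n2, 1)
    tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2, byrow = TRUE)
    expect_equal(poipanel:::hypergeom_p2(x1, n1, x2, n2),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("carrier-frequency enrichment behaves sensibly", {
  # the recurrent FOXL2 missense variant versus both reference populations
  e1 <- suppressWarnings(enrichment_test(13, 500, 0.0008, 5008))
  expect_lt(e1$p.value, 0.05)
  expect_gt(e1$estimate, 1)
  e2 <- suppressWarnings(enrichment_test(13, 500, 0.0024, 8654))
  expect_lt(e2$p.value, 0.05)
  e3 <- suppressWarnings(enrichment_test(13, 500, 0.0008, 5008, unit = "carrier"))
  expect_lt(e3$p.value, 0.05)
  # equal frequencies give an odds ratio of 1 and p = 1
  e4 <- enrichment_test(5, 50, ref_af = 0.05, ref_alleles = 100)
  expect_equal(e4$estimate, 1)
  expect_equal(e4$p.value, 1)
  # fractional implied reference counts are rounded with a warning
  expect_warning(enrichment_test(13, 500, 0.0008, 5008), "rounded")
})

test_that("compare_subgroups reproduces hand-computed means on a toy table", {
  asn <- tibble::tibble(
    patient_id = paste0("P", 1:6),
    explained = TRUE,
    n_genes_hit = c(1, 1, 1, 2, 2, 2),
    oligogenic = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    mechanism_summary = ""
  )
  pats <- tibble::tibble(
    patient_id = paste0("P", 1:6),
    amenorrhea = c("SA", "SA", "PA", "PA", "PA", "SA"),
    menarche_age = c(12, 14, 16, 15, 17, NA),
    onset_age = c(30, 28, 26, 22, 20, 24),
    fsh = NA_real_, lh = NA_real_, e2 = NA_real_, karyotype = "46,XX"
  )
  cmp <- compare_subgroups(asn, pats)
  t <- cmp$traits
  men <- t[t$trait == "menarche_age", ]
  expect_equal(men$n_monogenic, 3)
  expect_equal(men$mean_monogenic, 14)     # (12+14+16)/3
  expect_equal(men$sd_monogenic, 2)        # n-1 denominator
  expect_equal(men$n_oligogenic, 2)        # the NA is dropped, n reported
  expect_equal(men$mean_oligogenic, 16)
  on <- t[t$trait == "onset_age", ]
  expect_equal(on$mean_monogenic, 28)
  expect_equal(on$mean_oligogenic, 22)
  expect_equal(on$sd_oligogenic, 2)
  # ANOVA on two groups equals the two-sample t-test
  tt <- t.test(c(30, 28, 26), c(22, 20, 24), var.equal = TRUE)
  expect_equal(on$p.value, tt$p.value, tolerance = 1e-12)
  g <- cmp$groups
  expect_equal(g$pa_fraction[g$group == "monogenic"], 1 / 3)
  expect_equal(g$pa_fraction[g$group == "oligogenic"], 2 / 3)
})

test_that("degenerate comparisons are handled", {
  asn <- tibble::tibble(
    patient_id = paste0("P", 1:4), explained = TRUE,
    n_genes_hit = c(1, 1, 2, 2), oligogenic = c(FALSE, FALSE, TRUE, TRUE),
    mechanism_summary = ""
  )
  pats <- tibble::tibble(
    patient_id = paste0("P", 1:4), amenorrhea = "SA",
    menarche_age = c(14, 14, 14, 14), onset_age = NA_real_,
    fsh = NA_real_, lh = NA_real_, e2 = NA_real_, karyotype = "46,XX"
  )
  cmp <- compare_subgroups(asn, pats)
  men <- cmp$traits[cmp$traits$trait == "menarche_age", ]
  # identical values: zero mean difference, p = 1
  expect_equal(men$mean_monogenic, men$mean_oligogenic)
  expect_equal(men$p.value, 1)
  # a trait entirely missing is skipped with a reason
  expect_match(cmp$skipped[["onset_age"]], "missing")
})

test_that("the example cohort's subgroup sizes match the assignment tallies", {
  cmp <- summary_500$comparison
  g <- cmp$groups
  expect_equal(g$n[g$group == "monogenic"], 63)
  expect_equal(g$n[g$group == "oligogenic"], 9)
  expect_equal(g$pa_fraction[g$group == "oligogenic"], 5 / 9)
})
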