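test_that("specs validate their causal configurations", {
  expect_error(
    simulation_spec(causal_configs = tibble::tibble(
      gene = "BRCA1", mechanism = "AD_het", prevalence = 0.01)),
    "absent from panel")
  expect_error(
    simulation_spec(causal_configs = tibble::tibble(
      gene = "GDF9", mechanism = "AD_het", prevalence = 0.01)),
    "incompatible")
  expect_error(
    simulation_spec(causal_configs = tibble::tibble(
      gene = "FOXL2+NOBOX", mechanism = "digenic_heterodimer", prevalence = 0.01)),
    "incompatible")
  expect_error(simulation_spec(menarche_sd = 0))
})

test_that("generation is deterministic and byte-stable under a fixed seed", {
  spec <- simulation_spec(n_patients = 120, seed = 99)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- suppressWarnings(simulate_cohort(spec, dir = d1))
  s2 <- suppressWarnings(simulate_cohort(spec, dir = d2))
  expect_equal(s1$patients, s2$patients)
  expect_equal(s1$genotypes, s2$genotypes)
  expect_equal(s1$truth, s2$truth)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # a different seed produces a different cohort
  s3 <- suppressWarnings(simulate_cohort(simulation_spec(n_patients = 120, seed = 100)))
  expect_false(identical(s1$genotypes, s3$genotypes))
})

test_that("planted mechanisms realize the stated genotype structure", {
  spec <- simulation_spec(
    n_patients = 300, seed = 5,
    causal_configs = tibble::tibble(
      gene = c("FOXL2", "MSH5", "MSH4", "MSH4+MSH5"),
      mechanism = c("AD_het", "AR_hom", "AR_compound_het", "digenic_heterodimer"),
      prevalence = c(0.2, 0.2, 0.2, 0.2),
      planted_class = c("LP", "P", "P", "LP")),
    background_rate = 0, common_contaminant_rate = 0)
  sim <- suppressWarnings(simulate_cohort(spec))
  tr <- sim$truth
  geno <- sim$genotypes
  hom_patients <- tr$patient_id[tr$mechanism == "AR_hom"]
  for (pid in hom_patients) {
    g <- geno[geno$patient_id == pid & geno$gene == "MSH5", ]
    expect_true(any(g$zygosity == "hom"))
  }
  ch_patients <- tr$patient_id[tr$mechanism == "AR_compound_het"]
  for (pid in ch_patients[1:min(5, length(ch_patients))]) {
    g <- geno[geno$patient_id == pid & geno$gene == "MSH4", ]
    expect_gte(dplyr::n_distinct(g$hgvs_c), 2)
    expect_setequal(intersect(g$phase, c("paternal", "maternal")),
                    c("paternal", "maternal"))
  }
  dg_patients <- tr$patient_id[tr$mechanism == "digenic_heterodimer"]
  for (pid in dg_patients[1:min(5, length(dg_patients))]) {
    g <- geno[geno$patient_id == pid, ]
    expect_true(all(c("MSH4", "MSH5") %in% g$gene))
  }
})

test_that("planted prevalence is recovered within the exact binomial interval", {
  target <- 0.032
  n <- 500
  ci <- stats::qbinom(c(0.005, 0.995), n, target)
  for (seed in 1:6) {
    spec <- simulation_spec(
      n_patients = n, seed = seed,
      causal_configs = tibble::tibble(gene = "FOXL2", mechanism = "AD_het",
                                      prevalence = target, planted_class = "LP"),
      background_rate = 0, common_contaminant_rate = 0)
    sim <- suppressWarnings(simulate_cohort(spec))
    res <- run_poi_pipeline(sim, cohort_n = n)
    pg <- res$summary$per_gene
    carriers <- if ("FOXL2" %in% pg$gene) pg$carriers[pg$gene == "FOXL2"] else 0L
    expect_gte(carriers, ci[1])
    expect_lte(carriers, ci[2])
  }
})

test_that("a noiseless planted cohort is recovered perfectly", {
  spec <- simulation_spec(n_patients = 400, seed = 17,
                          background_rate = 0, common_contaminant_rate = 0)
  sim <- suppressWarnings(simulate_cohort(spec))
  res <- run_poi_pipeline(sim, cohort_n = 400)
  rec <- evaluate_recovery(sim, res$assignments, res$classified)
  expect_equal(rec$explained$sensitivity, 1)
  expect_equal(rec$explained$specificity, 1)
  expect_equal(rec$oligogenic$sensitivity, 1)
  expect_equal(rec$oligogenic$specificity, 1)
  # every planted variant is classified exactly as planted
  joined <- dplyr::inner_join(
    sim$variant_truth[sim$variant_truth$origin == "planted", ],
    res$classified[, c("gene", "hgvs_c", "verdict")], by = c("gene", "hgvs_c"))
  expect_gt(nrow(joined), 0)
  expect_equal(joined$verdict, joined$truth_class)
})

test_that("background and contaminant variants never explain a patient", {
  spec <- simulation_spec(n_patients = 200, seed = 23,
                          causal_configs = default_causal_configs()[0, ],
                          background_rate = 1.5, common_contaminant_rate = 1.5)
  sim <- suppressWarnings(simulate_cohort(spec))
  res <- run_poi_pipeline(sim, cohort_n = 200)
  expect_equal(sum(res$assignments$explained), 0)
  # contaminants really are removed by the rarity filter
  expect_gt(nrow(res$rejected), 0)
  expect_true(all(res$rejected$hgvs_c %in%
                    sim$variant_truth$hgvs_c[sim$variant_truth$origin == "contaminant"]))
  # a no-variant spec yields an empty observation table
  empty <- suppressWarnings(simulate_cohort(
    simulation_spec(n_patients = 50, seed = 2,
                    causal_configs = default_causal_configs()[0, ],
                    background_rate = 0, common_contaminant_rate = 0)))
  expect_equal(nrow(empty$genotypes), 0)
  expect_equal(nrow(empty$variants), 0)
})

test_that("lone recessive hits split carrier from strict mode", {
  spec <- simulation_spec(
    n_patients = 300, seed = 13,
    causal_configs = tibble::tibble(gene = "GDF9", mechanism = "AR_single_het",
                                    prevalence = 0.1, planted_class = "LP"),
    background_rate = 0, common_contaminant_rate = 0)
  sim <- suppressWarnings(simulate_cohort(spec))
  filt <- filter_variants(sim$variants)
  classified <- classify_variants(filt$kept)
  carrier <- assign_cohort(sim$genotypes, classified, spec$panel,
                           mode = "carrier", patients = sim$patients)
  strict <- assign_cohort(sim$genotypes, classified, spec$panel,
                          mode = "strict", patients = sim$patients)
  expect_gt(sum(carrier$explained), 0)
  expect_equal(sum(strict$explained), 0)
})

test_that("planted digenic pairs are always flagged oligogenic", {
  spec <- simulation_spec(
    n_patients = 1000, seed = 29,
    causal_configs = tibble::tibble(gene = "MSH4+MSH5",
                                    mechanism = "digenic_heterodimer",
                                    prevalence = 0.01, planted_class = "LP"),
    background_rate = 0.5, common_contaminant_rate = 0.5)
  sim <- suppressWarnings(simulate_cohort(spec))
  res <- run_poi_pipeline(sim, cohort_n = 1000)
  rec <- evaluate_recovery(sim, res$assignments, res$classified)
  expect_equal(rec$oligogenic$sensitivity, 1)
})

test_that("simulation specs round-trip through YAML configuration", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c(
    "n_patients: 80",
    "seed: 12",
    "background_rate: 0.5",
    "delta_onset: -3",
    "causal_configs:",
    "  - gene: FOXL2",
    "    mechanism: AD_het",
    "    prevalence: 0.05",
    "  - gene: MSH4+MSH5",
    "    mechanism: digenic_heterodimer",
    "    prevalence: 0.01",
    "    planted_class: P"
  ), f)
  spec <- read_simulation_spec(f)
  expect_equal(spec$n_patients, 80L)
  expect_equal(spec$delta_onset, -3)
  expect_equal(nrow(spec$causal_configs), 2)
  expect_equal(spec$causal_configs$planted_class, c("LP", "P"))
  s1 <- suppressWarnings(simulate_cohort(spec))
  s2 <- suppressWarnings(simulate_cohort(read_simulation_spec(f)))
  expect_equal(s1$genotypes, s2$genotypes)
  writeLines("not_a_key: 1", f)
  expect_error(read_simulation_spec(f), "unknown simulation spec key")
})
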