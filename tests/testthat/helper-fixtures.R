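# Shared fixtures and oracles, built once per test run.

example_cohort <- poi_example_cohort()
default_panel <- poi_default_panel()
known_plp <- poi_known_pathogenic()

run_example_pipeline <- function(...) {
  run_poi_pipeline(example_cohort, panel = default_panel, cohort_n = 500, ...)
}

# Independent oracle for the two-sided exact 2x2 test: enumerate every table
# with the observed margins and sum the probabilities (computed directly from
# binomial coefficients) of all tables no more probable than the observed one.
oracle_exact_p <- function(x1, n1, x2, n2) {
  m <- x1 + x2
  N <- n1 + n2
  support <- max(0, m - n2):min(m, n1)
  prob <- vapply(support, function(a)
    exp(lchoose(n1, a) + lchoose(n2, m - a) - lchoose(N, m)), numeric(1))
  obs <- prob[support == x1]
  sum(prob[prob <= obs * (1 + 1e-7)])
}

# minimal variant tibble builder for classifier tests
make_variant <- function(gene = "GENE1", hgvs_c = "c.100A>G", hgvs_p = "p.K34E",
                         consequence = "missense", known_pathogenic = FALSE,
                         metasvm = "missing", cadd = NA_real_, dann = NA_real_,
                         af_gnomad = NA_real_, af_1000g = NA_real_) {
  tibble::tibble(
    gene = gene, transcript = "NM_000001.1", hgvs_c = hgvs_c, hgvs_p = hgvs_p,
    consequence = consequence, intronic_offset = NA_integer_,
    rsid = NA_character_, af_gnomad = af_gnomad, af_exac_eas = NA_real_,
    af_1000g = af_1000g, metasvm = metasvm, cadd = cadd, dann = dann,
    known_pathogenic = known_pathogenic, reported_class = NA_character_
  )
}

# write a minimal cohort pair of files and return their paths
write_mini_cohort <- function(dir, genotypes, patients) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gp <- file.path(dir, "genotypes.tsv")
  pp <- file.path(dir, "patients.tsv")
  readr::write_tsv(genotypes, gp)
  readr::write_tsv(patients, pp)
  c(genotypes = gp, patients = pp)
}
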