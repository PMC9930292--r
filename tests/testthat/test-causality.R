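classified_all <- classify_variants(filter_variants(example_cohort$variants)$kept)
assignments_carrier <- assign_cohort(example_cohort$genotypes, classified_all,
                                     default_panel, mode = "carrier",
                                     patients = example_cohort$patients)

geno_for <- function(id) {
  g <- example_cohort$genotypes
  plp <- classified_all[classified_all$verdict %in% c("P", "LP"),
                        c("gene", "hgvs_c", "verdict")]
  dplyr::inner_join(g[g$patient_id == id, ], plp, by = c("gene", "hgvs_c"))
}

test_that("explain_gene resolves each inheritance pattern", {
  # pedigree-phased compound heterozygote in a recessive meiosis gene
  g <- geno_for("POI-63")
  m <- explain_gene(g[g$gene == "MSH4", ], "AR")
  expect_equal(m$mechanism, "AR_compound_het")
  expect_equal(m$phase_support, "pedigree_confirmed")
  # the same pattern without phases is assumed trans
  g_unphased <- g[g$gene == "MSH4", ]
  g_unphased$phase <- "unknown"
  expect_equal(explain_gene(g_unphased, "AR")$phase_support, "assumed_trans")
  # homozygous recessive
  g <- geno_for("POI-49")
  m <- explain_gene(g[g$gene == "MSH5", ], "AR")
  expect_equal(m$mechanism, "AR_hom")
  # single het in a recessive gene is an insufficient lone hit
  g <- geno_for("POI-20")
  expect_equal(explain_gene(g, "AR")$mechanism, "AR_single_het")
  # dominant and X-linked dominant need one het
  g <- geno_for("POI-2")
  expect_equal(explain_gene(g, "AD")$mechanism, "AD_het")
  expect_equal(explain_gene(g, "XLD")$mechanism, "XLD_het")
  expect_null(explain_gene(g[0, ], "AD"))
})

test_that("the heterodimer rule merges lone MSH4/MSH5 hits and respects precedence", {
  # POI-9: one het in each partner gene -> one digenic mechanism
  a9 <- assignments_carrier[assignments_carrier$patient_id == "POI-9", ]
  m9 <- a9$mechanisms[[1]]
  expect_equal(m9$mechanism, "digenic_heterodimer")
  expect_setequal(m9$genes[[1]], c("MSH4", "MSH5"))
  expect_true(a9$oligogenic)
  # POI-72: MSH4 is biallelically explained, so its partner's lone het
  # is not consumed by the merge
  a72 <- assignments_carrier[assignments_carrier$patient_id == "POI-72", ]
  m72 <- a72$mechanisms[[1]]
  expect_true(any(m72$mechanism == "AR_compound_het" & m72$gene_label == "MSH4"))
  expect_true(any(m72$mechanism == "AR_single_het" & m72$gene_label == "MSH5"))
  expect_false(any(m72$mechanism == "digenic_heterodimer"))
  expect_equal(a72$n_genes_hit, 3)
  # a lone MSH4 het with no partner hit is not merged
  g <- geno_for("POI-25")
  mech <- explain_gene(g[g$gene == "MSH4", ], "AR")
  merged <- apply_heterodimer_rule(mech, default_panel)
  expect_equal(merged$mechanism, "AR_single_het")
  # idempotence
  m9_again <- apply_heterodimer_rule(m9, default_panel)
  expect_equal(m9_again, m9)
})

test_that("per-patient assignment separates monogenic from oligogenic", {
  # two variants in one gene stay monogenic
  a61 <- assignments_carrier[assignments_carrier$patient_id == "POI-61", ]
  expect_true(a61$explained)
  expect_false(a61$oligogenic)
  expect_equal(a61$n_genes_hit, 1)
  # hits in two genes are oligogenic
  a54 <- assignments_carrier[assignments_carrier$patient_id == "POI-54", ]
  expect_true(a54$oligogenic)
  # a patient with no P/LP variant is unexplained
  no_plp <- assign_patient("X1", geno_for("POI-2")[0, ], default_panel)
  expect_false(no_plp$explained)
  expect_false(no_plp$oligogenic)
  # genotypes outside the panel are rejected
  bad <- geno_for("POI-2")
  bad$gene <- "BRCA1"
  expect_error(assign_patient("X1", bad, default_panel), "absent from the panel")
})

test_that("cohort tallies and the oligogenic set match the curated cohort", {
  tal <- assignment_tally(assignments_carrier)
  expect_equal(tal$n_explained, 72)
  expect_equal(tal$n_monogenic_only, 63)
  expect_equal(tal$n_oligogenic, 9)
  oligo_ids <- assignments_carrier$patient_id[assignments_carrier$oligogenic]
  expect_setequal(oligo_ids, c("POI-5", "POI-9", "POI-10", "POI-23", "POI-25",
                               "POI-38", "POI-54", "POI-69", "POI-72"))
  # biallelic MSH4/MSH5 mechanisms in exactly 5 patients
  biallelic <- vapply(assignments_carrier$mechanisms, function(m)
    any(m$mechanism %in% c("AR_hom", "AR_compound_het") &
          m$gene_label %in% c("MSH4", "MSH5")), logical(1))
  expect_equal(sum(biallelic), 5)
  expect_setequal(assignments_carrier$patient_id[biallelic],
                  c("POI-6", "POI-11", "POI-49", "POI-63", "POI-72"))
})

test_that("carrier-mode explanations contain strict-mode explanations", {
  strict <- assign_cohort(example_cohort$genotypes, classified_all,
                          default_panel, mode = "strict",
                          patients = example_cohort$patients)
  carrier_set <- assignments_carrier$patient_id[assignments_carrier$explained]
  strict_set <- strict$patient_id[strict$explained]
  expect_true(all(strict_set %in% carrier_set))
  # strict mode drops lone hits in strictly recessive genes (e.g. GDF9 in POI-20)
  expect_false("POI-20" %in% strict_set)
  expect_true("POI-20" %in% carrier_set)
  # but keeps dominant-compatible single hets (AR_AD genes) and biallelic calls
  expect_true("POI-4" %in% strict_set)    # BMPR2 het
  expect_true("POI-49" %in% strict_set)   # MSH5 hom
  expect_true("POI-9" %in% strict_set)    # digenic heterodimer
})

test_that("adding a P/LP genotype never unexplains a patient", {
  plp <- classified_all[classified_all$verdict %in% c("P", "LP"),
                        c("gene", "hgvs_c", "verdict")]
  geno <- dplyr::inner_join(example_cohort$genotypes, plp, by = c("gene", "hgvs_c"))
  extra <- tibble::tibble(gene = "FOXL2", hgvs_c = "c.1045C>G",
                          zygosity = "het", phase = "unknown", verdict = "LP")
  set.seed(31)
  for (id in sample(unique(geno$patient_id), 10)) {
    base <- assign_patient(id, geno[geno$patient_id == id, ], default_panel)
    augmented <- dplyr::bind_rows(
      geno[geno$patient_id == id, ],
      dplyr::mutate(extra, patient_id = id)) |>
      dplyr::distinct(gene, hgvs_c, .keep_all = TRUE)
    after <- assign_patient(id, augmented, default_panel)
    expect_true(after$explained >= base$explained)
    expect_gte(after$n_genes_hit, base$n_genes_hit)
  }
})
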