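#' Specify a synthetic panel-sequencing cohort
#'
#' Defines the generative model for a simulated POI screening cohort:
#' planted causal genotypes under stated inheritance mechanisms, background
#' rare benign variants, common "contaminant" variants that must be removed
#' by the rarity filter, and phenotypes whose distributions shift with the
#' variant burden (oligogenic patients menstruate later and lose ovarian
#' function earlier).
#'
#' Default phenotype parameters reproduce the screened cohort's published
#' clinical profile: menarche 14.62 +/- 3.04 y, POI onset 23.97 +/- 5.71 y,
#' FSH 69.10 +/- 31.79 IU/L truncated above the diagnostic threshold of
#' 25 IU/L, estradiol 21.33 +/- 16.73 pg/ml, and a 22.7% primary-amenorrhea
#' fraction; explained subgroups default to the observed subgroup contrasts
#' (PA 19% monogenic vs 44% oligogenic, onset shifted -4.9 y, menarche
#' +1.9 y in oligogenic patients).
#'
#' @param n_patients Cohort size.
#' @param panel Panel tibble (defaults to the packaged 28-gene panel).
#' @param causal_configs Tibble with columns `gene` (a symbol, or two
#'   partner symbols joined by `+` for `digenic_heterodimer`), `mechanism`
#'   (one of `AD_het`, `XLD_het`, `AR_hom`, `AR_compound_het`,
#'   `AR_single_het`, `digenic_heterodimer`), `prevalence` in `[0, 1]` and
#'   optionally `planted_class` (`P` or `LP`; default `LP`).
#' @param background_rate Mean benign rare missense variants per patient
#'   (Poisson); their in-silico scores fall below the LP thresholds.
#' @param common_contaminant_rate Mean per-patient count of variants with
#'   reference AF at or above 0.001 (Poisson), exercising the rarity filter.
#' @param menarche_mean,menarche_sd,onset_mean,onset_sd Phenotype normals
#'   (years).
#' @param delta_menarche,delta_onset Additive shifts (years) applied to
#'   oligogenic patients.
#' @param fsh_mean,fsh_sd,fsh_min FSH normal (IU/L), truncated below at
#'   `fsh_min` by rejection sampling (the POI inclusion criterion).
#' @param lh_mean,lh_sd LH normal (IU/L), truncated below 0.
#' @param e2_mean,e2_sd Estradiol normal (pg/ml), truncated below 0.
#' @param p_pa,p_pa_mono,p_pa_oligo Primary-amenorrhea probabilities for
#'   unexplained, monogenic and oligogenic patients.
#' @param seed Integer seed; generation is fully reproducible given the
#'   seed, and each component (genotypes, background, contaminants,
#'   phenotypes) draws from its own named sub-stream.
#' @return A list of class `poi_simspec`.
#' @export
simulation_spec <- function(n_patients = 500,
                            panel = poi_default_panel(),
                            causal_configs = default_causal_configs(),
                            background_rate = 1.5,
                            common_contaminant_rate = 1.0,
                            menarche_mean = 14.62, menarche_sd = 3.04,
                            onset_mean = 23.97, onset_sd = 5.71,
                            delta_menarche = 1.9, delta_onset = -4.9,
                            fsh_mean = 69.10, fsh_sd = 31.79, fsh_min = 25,
                            lh_mean = 35, lh_sd = 20,
                            e2_mean = 21.33, e2_sd = 16.73,
                            p_pa = 0.227, p_pa_mono = 0.19, p_pa_oligo = 0.44,
                            seed = 1L) {
  stopifnot(n_patients >= 1,
            background_rate >= 0, common_contaminant_rate >= 0,
            menarche_sd > 0, onset_sd > 0, fsh_sd > 0, lh_sd > 0, e2_sd > 0,
            p_pa >= 0, p_pa <= 1, p_pa_mono >= 0, p_pa_mono <= 1,
            p_pa_oligo >= 0, p_pa_oligo <= 1)
  cc <- causal_configs
  if (nrow(cc) > 0L) {
    if (!"planted_class" %in% names(cc)) cc$planted_class <- "LP"
    cc$planted_class[is.na(cc$planted_class)] <- "LP"
    stopifnot(all(cc$prevalence >= 0), all(cc$prevalence <= 1),
              all(cc$mechanism %in% setdiff(.mechanism_levels, "carrier_hit")),
              all(cc$planted_class %in% c("P", "LP")))
    for (i in seq_len(nrow(cc))) {
      genes <- strsplit(cc$gene[i], "+", fixed = TRUE)[[1]]
      missing_genes <- setdiff(genes, panel$symbol)
      if (length(missing_genes) > 0L) {
        abort(paste0("causal config references gene(s) absent from panel: ",
                     paste(missing_genes, collapse = ", ")))
      }
      modes <- panel$inheritance_mode[match(genes, panel$symbol)]
      mech <- cc$mechanism[i]
      ok <- switch(mech,
        AD_het = length(genes) == 1L && modes %in% c("AD", "AR_AD"),
        XLD_het = length(genes) == 1L && modes == "XLD",
        AR_hom = , AR_compound_het = , AR_single_het =
          length(genes) == 1L && modes == "AR",
        digenic_heterodimer = length(genes) == 2L && all(modes == "AR") &&
          identical(sort(genes),
                    sort(c(genes[1], panel$heterodimer_partner[panel$symbol == genes[1]])))
      )
      if (!isTRUE(ok)) {
        abort(sprintf("mechanism %s is incompatible with gene(s) %s (mode %s)",
                      mech, cc$gene[i], paste(modes, collapse = "/")))
      }
    }
  }
  structure(
    list(n_patients = as.integer(n_patients), panel = panel, causal_configs = cc,
         background_rate = background_rate,
         common_contaminant_rate = common_contaminant_rate,
         menarche_mean = menarche_mean, menarche_sd = menarche_sd,
         onset_mean = onset_mean, onset_sd = onset_sd,
         delta_menarche = delta_menarche, delta_onset = delta_onset,
         fsh_mean = fsh_mean, fsh_sd = fsh_sd, fsh_min = fsh_min,
         lh_mean = lh_mean, lh_sd = lh_sd, e2_mean = e2_mean, e2_sd = e2_sd,
         p_pa = p_pa, p_pa_mono = p_pa_mono, p_pa_oligo = p_pa_oligo,
         seed = as.integer(seed)),
    class = "poi_simspec"
  )
}

#' Default planted causal architecture
#'
#' A small architecture echoing a targeted POI screen: a recurrent dominant
#' FOXL2 hit at 3.2% prevalence, dominant NOBOX hits at 1.2%, X-linked
#' PGRMC1 hits, recessive MSH4 compound heterozygotes, a homozygous MSH5
#' variant and rare MSH4+MSH5 digenic pairs.
#'
#' @return A causal-config tibble (see [simulation_spec()]).
#' @export
default_causal_configs <- function() {
  tibble::tibble(
    gene = c("FOXL2", "NOBOX", "PGRMC1", "MSH4", "MSH5", "MSH4+MSH5"),
    mechanism = c("AD_het", "AD_het", "XLD_het", "AR_compound_het",
                  "AR_hom", "digenic_heterodimer"),
    prevalence = c(0.032, 0.012, 0.016, 0.006, 0.002, 0.002),
    planted_class = c("LP", "P", "LP", "P", "LP", "LP")
  )
}

# deterministic sub-stream seed from a base seed and a stream name;
# kept below 2^31 - 1
stream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(as.numeric(seed)) * 1000003 + h) %% 2147483647)
}

with_stream <- function(seed, name, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, name))
  force(code)
}

rtruncnorm_min <- function(n, mean, sd, lower) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0L) {      # rejection sampling against the bound
    draw <- rnorm(length(need), mean, sd)
    ok <- draw > lower
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

aa1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# synthesize a plausible unique variant for a gene; registry is an
# environment mapping "gene:hgvs_c" -> TRUE
synth_variant <- function(gene, class, registry, af = NULL) {
  repeat {
    res <- sample(20:900, 1)
    pos <- 3L * res - sample(0:2, 1)
    if (class == "P") {
      kind <- sample(c("frameshift", "nonsense", "splice"), 1)
      if (kind == "frameshift") {
        hgvs_c <- sprintf("c.%ddel%s", pos, sample(c("A", "C", "G", "T"), 1))
        hgvs_p <- sprintf("p.%s%dfs", sample(aa1, 1), res)
      } else if (kind == "nonsense") {
        hgvs_c <- sprintf("c.%dC>T", pos)
        hgvs_p <- sprintf("p.%s%dX", sample(setdiff(aa1, "X"), 1), res)
      } else {
        hgvs_c <- sprintf("c.%d+%dG>A", pos, sample(1:2, 1))
        hgvs_p <- ""
      }
      metasvm <- "missing"; cadd <- NA_real_; dann <- NA_real_
    } else if (class == "LP") {
      nt <- sample(c("A", "C", "G", "T"), 2)
      hgvs_c <- sprintf("c.%d%s>%s", pos, nt[1], nt[2])
      res_aa <- sample(seq_along(aa1), 2)
      hgvs_p <- sprintf("p.%s%d%s", aa1[res_aa[1]], res, aa1[res_aa[2]])
      metasvm <- "deleterious"; cadd <- round(runif(1, 10, 35), 1)
      dann <- round(runif(1, 0.96, 0.999), 3)
    } else { # benign background: scores below the LP thresholds
      nt <- sample(c("A", "C", "G", "T"), 2)
      hgvs_c <- sprintf("c.%d%s>%s", pos, nt[1], nt[2])
      res_aa <- sample(seq_along(aa1), 2)
      hgvs_p <- sprintf("p.%s%d%s", aa1[res_aa[1]], res, aa1[res_aa[2]])
      metasvm <- "tolerated"; cadd <- round(runif(1, 0, 2.5), 1)
      dann <- round(runif(1, 0, 0.9), 3)
    }
    key <- variant_key(gene, hgvs_c)
    if (!isTRUE(registry[[key]])) {
      registry[[key]] <- TRUE
      break
    }
  }
  list(
    gene = gene, transcript = sprintf("NM_%06d.1", sum(utf8ToInt(gene))),
    hgvs_c = hgvs_c, hgvs_p = hgvs_p, rsid = NA_character_,
    af_gnomad = if (is.null(af)) signif(runif(1, 0, 5e-5), 3) else af,
    af_exac_eas = NA_real_, af_1000g = NA_real_,
    metasvm = metasvm, cadd = cadd, dann = dann
  )
}

# assemble a tibble from an accumulated list of homogeneous named lists
rows_to_tibble <- function(rows, chr, dbl) {
  cols <- c(
    lapply(setNames(chr, chr), function(f)
      vapply(rows, function(r) as.character(r[[f]]), character(1))),
    lapply(setNames(dbl, dbl), function(f)
      vapply(rows, function(r) as.numeric(r[[f]]), numeric(1)))
  )
  tibble::as_tibble(cols)
}

#' Simulate a panel-sequencing cohort with planted causal genotypes
#'
#' Realizes the generative model of a [simulation_spec()]: each causal
#' config plants its mechanism in an independent Bernoulli fraction of
#' patients with the correct zygosity and gene structure (one het for
#' dominant hits; a homozygous variant or two distinct trans-phased hets
#' for recessive ones; one het in each partner gene for digenic pairs);
#' background benign missense and common contaminant variants are added at
#' Poisson rates; and phenotypes are drawn from the spec's (truncated)
#' normals with burden-dependent shifts.
#'
#' @param spec A `poi_simspec`.
#' @param dir Optional output directory; when given, cohort files in the
#'   formats [read_cohort()] ingests plus a `ground_truth.tsv` table are
#'   written (byte-identical across runs with the same spec).
#' @return A list of class `poi_simcohort`: `patients`, `variants`,
#'   `genotypes` (as a `poi_cohort`), `truth` (one row per planted
#'   mechanism), `variant_truth` (planted class per generated variant) and
#'   the `spec`.
#' @examples
#' spec <- simulation_spec(n_patients = 100, seed = 42)
#' sim <- simulate_cohort(spec)
#' nrow(sim$patients)
#' @export
simulate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "poi_simspec"))
  n <- spec$n_patients
  ids <- sprintf("SIM-%04d", seq_len(n))
  registry <- new.env(parent = emptyenv())

  geno <- list()
  vrec <- list()
  vtruth <- list()
  truth <- list()
  add_obs <- function(pid, v, zygosity, phase = "unknown") {
    list(patient_id = pid, gene = v$gene, hgvs_c = v$hgvs_c,
         zygosity = zygosity, phase = phase)
  }

  cc <- spec$causal_configs
  with_stream(spec$seed, "genotypes", {
    for (i in seq_len(nrow(cc))) {
      genes <- strsplit(cc$gene[i], "+", fixed = TRUE)[[1]]
      mech <- cc$mechanism[i]
      cls <- cc$planted_class[i]
      carrier <- which(rbinom(n, 1L, cc$prevalence[i]) == 1L)
      if (length(carrier) == 0L) next
      # recurrent variants: one planted allele (or pair) shared by carriers
      if (mech == "AR_compound_het") {
        v1 <- synth_variant(genes, cls, registry)
        v2 <- synth_variant(genes, "LP", registry)
        vs <- list(v1, v2)
      } else if (mech == "digenic_heterodimer") {
        vs <- list(synth_variant(genes[1], cls, registry),
                   synth_variant(genes[2], cls, registry))
      } else {
        vs <- list(synth_variant(genes, cls, registry))
      }
      for (v in vs) {
        vrec[[length(vrec) + 1L]] <- v
        vtruth[[length(vtruth) + 1L]] <- list(
          gene = v$gene, hgvs_c = v$hgvs_c,
          truth_class = if (v$metasvm == "deleterious") "LP" else
            if (v$metasvm == "tolerated") "VUS" else "P",
          origin = "planted")
      }
      for (pid in ids[carrier]) {
        if (mech == "AR_hom") {
          geno[[length(geno) + 1L]] <- add_obs(pid, vs[[1]], "hom")
        } else if (mech == "AR_compound_het") {
          geno[[length(geno) + 1L]] <- add_obs(pid, vs[[1]], "het", "paternal")
          geno[[length(geno) + 1L]] <- add_obs(pid, vs[[2]], "het", "maternal")
        } else if (mech == "digenic_heterodimer") {
          geno[[length(geno) + 1L]] <- add_obs(pid, vs[[1]], "het")
          geno[[length(geno) + 1L]] <- add_obs(pid, vs[[2]], "het")
        } else {
          geno[[length(geno) + 1L]] <- add_obs(pid, vs[[1]], "het")
        }
        truth[[length(truth) + 1L]] <- list(
          patient_id = pid, config = cc$gene[i], mechanism = mech,
          genes = paste(genes, collapse = "+"), n_genes = length(genes),
          planted_class = cls)
      }
    }
  })

  with_stream(spec$seed, "background", {
    counts <- rpois(n, spec$background_rate)
    for (j in which(counts > 0L)) {
      for (k in seq_len(counts[j])) {
        g <- sample(spec$panel$symbol, 1)
        v <- synth_variant(g, "benign", registry)
        vrec[[length(vrec) + 1L]] <- v
        vtruth[[length(vtruth) + 1L]] <- list(
          gene = v$gene, hgvs_c = v$hgvs_c, truth_class = "VUS",
          origin = "background")
        geno[[length(geno) + 1L]] <- add_obs(ids[j], v, "het")
      }
    }
  })

  with_stream(spec$seed, "contaminants", {
    counts <- rpois(n, spec$common_contaminant_rate)
    for (j in which(counts > 0L)) {
      for (k in seq_len(counts[j])) {
        g <- sample(spec$panel$symbol, 1)
        v <- synth_variant(g, "LP", registry, af = signif(runif(1, 0.002, 0.05), 3))
        vrec[[length(vrec) + 1L]] <- v
        vtruth[[length(vtruth) + 1L]] <- list(
          gene = v$gene, hgvs_c = v$hgvs_c, truth_class = "common",
          origin = "contaminant")
        geno[[length(geno) + 1L]] <- add_obs(ids[j], v, "het")
      }
    }
  })

  truth <- if (length(truth) > 0L) {
    t0 <- rows_to_tibble(truth, chr = c("patient_id", "config", "mechanism",
                                        "genes", "planted_class"),
                         dbl = "n_genes")
    t0$n_genes <- as.integer(t0$n_genes)
    t0[, c("patient_id", "config", "mechanism", "genes", "n_genes",
           "planted_class")]
  } else {
    tibble::tibble(patient_id = character(), config = character(),
                   mechanism = character(), genes = character(),
                   n_genes = integer(), planted_class = character())
  }
  burden <- if (nrow(truth) > 0L) {
    truth |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(
        genes_hit = dplyr::n_distinct(unlist(strsplit(.data$genes, "+",
                                                      fixed = TRUE))),
        .groups = "drop")
  } else {
    tibble::tibble(patient_id = character(), genes_hit = integer())
  }
  genes_hit <- setNames(rep(0L, n), ids)
  genes_hit[burden$patient_id] <- burden$genes_hit
  group <- ifelse(genes_hit >= 2L, "oligogenic",
                  ifelse(genes_hit == 1L, "monogenic", "none"))

  patients <- with_stream(spec$seed, "phenotypes", {
    oligo <- group == "oligogenic"
    menarche <- rnorm(n, spec$menarche_mean, spec$menarche_sd) +
      spec$delta_menarche * oligo
    menarche <- pmin(pmax(round(menarche), 8), 25)
    onset <- rtruncnorm_min(n, spec$onset_mean, spec$onset_sd, 10) +
      spec$delta_onset * oligo
    onset <- pmin(pmax(round(onset), 11), 39)
    p_pa <- ifelse(oligo, spec$p_pa_oligo,
                   ifelse(group == "monogenic", spec$p_pa_mono, spec$p_pa))
    pa <- rbinom(n, 1L, p_pa) == 1L
    tibble::tibble(
      patient_id = ids,
      amenorrhea = ifelse(pa, "PA", "SA"),
      menarche_age = as.numeric(menarche),
      onset_age = as.numeric(onset),
      fsh = round(rtruncnorm_min(n, spec$fsh_mean, spec$fsh_sd, spec$fsh_min), 2),
      lh = round(rtruncnorm_min(n, spec$lh_mean, spec$lh_sd, 0), 2),
      e2 = round(rtruncnorm_min(n, spec$e2_mean, spec$e2_sd, 0), 2),
      karyotype = "46,XX"
    )
  })

  obs <- if (length(geno) > 0L) {
    rows_to_tibble(geno, chr = c("patient_id", "gene", "hgvs_c", "zygosity",
                                 "phase"), dbl = character())
  } else {
    tibble::tibble(patient_id = character(), gene = character(),
                   hgvs_c = character(), zygosity = character(), phase = character())
  }
  obs <- obs[order(obs$patient_id, obs$gene, obs$hgvs_c), , drop = FALSE]
  vall <- if (length(vrec) > 0L) {
    v0 <- rows_to_tibble(vrec,
                         chr = c("gene", "transcript", "hgvs_c", "hgvs_p",
                                 "rsid", "metasvm"),
                         dbl = c("af_gnomad", "af_exac_eas", "af_1000g",
                                 "cadd", "dann"))
    v0[, c("gene", "transcript", "hgvs_c", "hgvs_p", "rsid", "af_gnomad",
           "af_exac_eas", "af_1000g", "metasvm", "cadd", "dann")]
  } else NULL
  obs_full <- if (is.null(vall)) {
    tibble::tibble(patient_id = character(), gene = character(),
                   transcript = character(), hgvs_c = character(),
                   hgvs_p = character(), rsid = character(),
                   zygosity = character(), phase = character(),
                   af_gnomad = double(), af_exac_eas = double(),
                   af_1000g = double(), metasvm = character(),
                   cadd = double(), dann = double(),
                   reported_class = character())
  } else {
    obs |>
      dplyr::left_join(vall, by = c("gene", "hgvs_c")) |>
      dplyr::mutate(reported_class = NA_character_)
  }
  variants <- consolidate_variants(obs_full)
  variant_truth <- if (length(vtruth) > 0L) {
    rows_to_tibble(vtruth, chr = c("gene", "hgvs_c", "truth_class", "origin"),
                   dbl = character())
  } else {
    tibble::tibble(gene = character(), hgvs_c = character(),
                   truth_class = character(), origin = character())
  }

  out <- structure(
    list(patients = patients, variants = variants, genotypes = obs,
         truth = truth, variant_truth = variant_truth, spec = spec),
    class = c("poi_simcohort", "poi_cohort")
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(obs_full[, c("patient_id", "gene", "transcript", "hgvs_c",
                                  "hgvs_p", "rsid", "zygosity", "phase",
                                  "af_gnomad", "af_exac_eas", "af_1000g",
                                  "metasvm", "cadd", "dann")],
                     file.path(dir, "genotypes.tsv"), progress = FALSE)
    readr::write_tsv(patients, file.path(dir, "patients.tsv"), progress = FALSE)
    readr::write_tsv(truth, file.path(dir, "ground_truth.tsv"), progress = FALSE)
    readr::write_tsv(variant_truth, file.path(dir, "variant_truth.tsv"),
                     progress = FALSE)
  }
  out
}

#' Score pipeline recovery against simulation ground truth
#'
#' Compares the pipeline's explained / oligogenic flags with the planted
#' architecture, and (when a classified variant table is supplied) tabulates
#' a classification confusion matrix of planted class versus verdict.
#'
#' @param sim A `poi_simcohort` from [simulate_cohort()] (carries the
#'   ground-truth tables).
#' @param assignments Assignment tibble from [assign_cohort()] on the
#'   simulated cohort.
#' @param classified Optional classified variant tibble for the confusion
#'   matrix.
#' @return A list of class `poi_recovery`: `explained` and `oligogenic`
#'   (each with sensitivity, specificity and the underlying counts) and
#'   `confusion` (a contingency table, or `NULL`).
#' @export
evaluate_recovery <- function(sim, assignments, classified = NULL) {
  stopifnot(inherits(sim, "poi_simcohort"))
  truth <- sim$truth
  ids <- sim$patients$patient_id
  missing_ids <- setdiff(unique(truth$patient_id), assignments$patient_id)
  if (length(missing_ids) > 0L) {
    abort(paste0("ground truth references patients absent from assignments: ",
                 paste(utils::head(missing_ids, 5), collapse = ", ")))
  }
  genes_hit <- setNames(rep(0L, length(ids)), ids)
  if (nrow(truth) > 0L) {
    b <- truth |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(
        g = dplyr::n_distinct(unlist(strsplit(.data$genes, "+", fixed = TRUE))),
        .groups = "drop")
    genes_hit[b$patient_id] <- b$g
  }
  truth_explained <- genes_hit >= 1L
  truth_oligo <- genes_hit >= 2L
  pred <- assignments[match(ids, assignments$patient_id), , drop = FALSE]
  pred_explained <- dplyr::coalesce(pred$explained, FALSE)
  pred_oligo <- dplyr::coalesce(pred$oligogenic, FALSE)

  rates <- function(truth, pred) {
    tp <- sum(truth & pred); fn <- sum(truth & !pred)
    tn <- sum(!truth & !pred); fp <- sum(!truth & pred)
    list(sensitivity = if (tp + fn == 0L) NA_real_ else tp / (tp + fn),
         specificity = if (tn + fp == 0L) NA_real_ else tn / (tn + fp),
         tp = tp, fn = fn, tn = tn, fp = fp)
  }
  confusion <- NULL
  if (!is.null(classified)) {
    joined <- dplyr::inner_join(
      sim$variant_truth[sim$variant_truth$origin != "contaminant", ],
      classified[, c("gene", "hgvs_c", "verdict")], by = c("gene", "hgvs_c"))
    confusion <- table(planted = joined$truth_class, verdict = joined$verdict)
  }
  structure(
    list(explained = rates(truth_explained, pred_explained),
         oligogenic = rates(truth_oligo, pred_oligo),
         confusion = confusion),
    class = "poi_recovery"
  )
}

#' @export
print.poi_recovery <- function(x, ...) {
  cat("<poi_recovery>\n")
  cat(sprintf("  explained:  sensitivity %.3f, specificity %.3f\n",
              x$explained$sensitivity, x$explained$specificity))
  cat(sprintf("  oligogenic: sensitivity %.3f, specificity %.3f\n",
              x$oligogenic$sensitivity, x$oligogenic$specificity))
  if (!is.null(x$confusion)) {
    cat("  classification confusion:\n")
    print(x$confusion)
  }
  invisible(x)
}

#' Read a simulation spec from a YAML configuration file
#'
#' The file holds top-level keys matching the arguments of
#' [simulation_spec()] (e.g. `n_patients`, `background_rate`, `seed`,
#' `delta_onset`), plus an optional `causal_configs` sequence whose entries
#' carry `gene`, `mechanism`, `prevalence` and optionally `planted_class`.
#' Omitted keys take the defaults.
#'
#' @param path Path to a YAML file.
#' @return A `poi_simspec`.
#' @export
read_simulation_spec <- function(path) {
  if (!file.exists(path)) abort(paste0("spec file not found: ", path))
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(simulation_spec)), c("panel", "causal_configs"))
  bad <- setdiff(names(raw), c(known, "causal_configs"))
  if (length(bad) > 0L) {
    abort(paste0("unknown simulation spec key(s): ", paste(bad, collapse = ", ")))
  }
  args <- raw[intersect(names(raw), known)]
  if (!is.null(raw$causal_configs)) {
    args$causal_configs <- dplyr::bind_rows(lapply(raw$causal_configs, function(x) {
      tibble::tibble(
        gene = x$gene, mechanism = x$mechanism,
        prevalence = as.numeric(x$prevalence),
        planted_class = x$planted_class %||% "LP"
      )
    }))
  }
  do.call(simulation_spec, args)
}
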