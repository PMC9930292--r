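empty_mechanisms <- function() {
  tibble::tibble(
    genes = list(), gene_label = character(), mechanism = character(),
    variant_keys = list(), phase_support = character()
  )
}

#' Resolve the causal mechanism for one patient-gene pair
#'
#' Applies the gene's inheritance mode to the patient's P/LP genotypes in
#' that gene:
#'
#' * `AD` / `AR_AD` mode with at least one heterozygous P/LP variant gives
#'   `AD_het` (dominant-compatible genes need a single hit);
#' * `XLD` gives `XLD_het` (the cohort is all-female, so heterozygosity
#'   suffices and hemizygosity does not arise);
#' * `AR` with a homozygous P/LP variant gives `AR_hom`;
#' * `AR` with two or more distinct heterozygous P/LP variants gives
#'   `AR_compound_het` — phase support is `pedigree_confirmed` when two
#'   variants carry opposite parental phases, otherwise unphased pairs are
#'   `assumed_trans`;
#' * `AR` with exactly one heterozygous P/LP variant gives `AR_single_het`,
#'   which is insufficient alone under strict causality but counts in
#'   carrier mode (and can be merged by the heterodimer rule).
#'
#' @param genotypes Genotype rows for one patient and one gene (columns
#'   `gene`, `hgvs_c`, `zygosity`, `phase`), restricted to P/LP variants.
#' @param inheritance_mode One of `AD`, `AR`, `AR_AD`, `XLD`.
#' @return A one-row mechanism tibble (columns `genes` (list), `gene_label`,
#'   `mechanism`, `variant_keys` (list), `phase_support`), or `NULL` when no
#'   P/LP genotype is present.
#' @export
explain_gene <- function(genotypes, inheritance_mode) {
  if (nrow(genotypes) == 0L) return(NULL)
  if (!inheritance_mode %in% .inheritance_modes) {
    abort(paste0("unknown inheritance mode: ", inheritance_mode))
  }
  gene <- genotypes$gene[1]
  keys <- variant_key(genotypes$gene, genotypes$hgvs_c)
  mech_row <- function(mechanism, keys, phase_support = "not_applicable") {
    tibble::tibble(
      genes = list(gene), gene_label = gene, mechanism = mechanism,
      variant_keys = list(keys), phase_support = phase_support
    )
  }
  if (inheritance_mode %in% c("AD", "AR_AD")) {
    return(mech_row("AD_het", keys))
  }
  if (inheritance_mode == "XLD") {
    return(mech_row("XLD_het", keys))
  }
  # AR
  hom <- genotypes$zygosity == "hom"
  if (any(hom)) {
    return(mech_row("AR_hom", keys[hom]))
  }
  distinct <- !duplicated(genotypes$hgvs_c)
  if (sum(distinct) >= 2L) {
    phases <- genotypes$phase[distinct]
    support <- if (any(phases == "paternal") && any(phases == "maternal"))
      "pedigree_confirmed" else "assumed_trans"
    return(mech_row("AR_compound_het", keys[distinct], support))
  }
  mech_row("AR_single_het", keys)
}

#' Merge single heterozygous hits in heterodimer partner genes
#'
#' When two partner-linked recessive genes (MSH4 and MSH5 in the default
#' panel) each carry exactly one heterozygous P/LP variant in the same
#' patient, the pair is treated as one causal digenic mechanism: loss of the
#' heterodimer function. A gene that is already biallelically explained
#' (`AR_hom` or `AR_compound_het`) is not consumed by the merge; its
#' partner's single hit stays a separate `AR_single_het`.
#'
#' The rule is idempotent.
#'
#' @param mechanisms A mechanism tibble for one patient (rows from
#'   [explain_gene()]).
#' @param panel The panel tibble (for `heterodimer_partner` links).
#' @return The updated mechanism tibble.
#' @export
apply_heterodimer_rule <- function(mechanisms, panel) {
  if (nrow(mechanisms) == 0L) return(mechanisms)
  singles <- mechanisms$mechanism == "AR_single_het"
  if (!any(singles)) return(mechanisms)
  partner_of <- setNames(panel$heterodimer_partner, panel$symbol)
  consumed <- rep(FALSE, nrow(mechanisms))
  merged <- list()
  for (i in which(singles)) {
    if (consumed[i]) next
    g <- mechanisms$gene_label[i]
    p <- partner_of[[g]] %||% NA_character_
    if (is.na(p)) next
    j <- which(mechanisms$gene_label == p & mechanisms$mechanism == "AR_single_het" &
                 !consumed)
    if (length(j) == 0L) next
    j <- j[1]
    consumed[c(i, j)] <- TRUE
    pair <- sort(c(g, p))
    merged[[length(merged) + 1L]] <- tibble::tibble(
      genes = list(pair),
      gene_label = paste(pair, collapse = "+"),
      mechanism = "digenic_heterodimer",
      variant_keys = list(c(mechanisms$variant_keys[[i]],
                            mechanisms$variant_keys[[j]])),
      phase_support = "not_applicable"
    )
  }
  dplyr::bind_rows(mechanisms[!consumed, , drop = FALSE], dplyr::bind_rows(merged))
}

#' Assign causality for one patient
#'
#' @param patient_id Patient identifier.
#' @param genotypes The patient's genotype rows restricted to P/LP variants.
#' @param panel The panel tibble.
#' @param mode `"carrier"` (default): a patient is explained when they carry
#'   at least one P/LP variant in any panel gene. `"strict"`: a patient is
#'   explained only when at least one mechanism fully satisfies a classical
#'   inheritance model (`AD_het`, `AR_hom`, `AR_compound_het`, `XLD_het`,
#'   `digenic_heterodimer`).
#' @return A one-row assignment tibble with columns `patient_id`,
#'   `explained`, `n_genes_hit`, `oligogenic`, `mechanisms` (list column)
#'   and `mechanism_summary`.
#' @export
assign_patient <- function(patient_id, genotypes, panel,
                           mode = c("carrier", "strict")) {
  mode <- match.arg(mode)
  unknown <- setdiff(unique(genotypes$gene), panel$symbol)
  if (length(unknown) > 0L) {
    abort(paste0("genotype in gene(s) absent from the panel: ",
                 paste(unknown, collapse = ", ")))
  }
  mechanisms <- genotypes |>
    dplyr::group_split(.data$gene) |>
    purrr::map(function(g) {
      mode_g <- panel$inheritance_mode[panel$symbol == g$gene[1]]
      explain_gene(g, mode_g)
    }) |>
    dplyr::bind_rows()
  if (nrow(mechanisms) == 0L) mechanisms <- empty_mechanisms()
  mechanisms <- apply_heterodimer_rule(mechanisms, panel)
  n_genes_hit <- dplyr::n_distinct(genotypes$gene)
  explained <- if (mode == "carrier") {
    nrow(genotypes) > 0L
  } else {
    any(mechanisms$mechanism %in% .strong_mechanisms)
  }
  oligogenic <- explained && n_genes_hit >= 2L
  summary <- if (nrow(mechanisms) == 0L) "" else {
    paste(sprintf("%s:%s(%s)", mechanisms$gene_label, mechanisms$mechanism,
                  purrr::map_chr(mechanisms$variant_keys, function(k)
                    paste(sub("^[^:]+:", "", k), collapse = "+"))),
          collapse = "; ")
  }
  tibble::tibble(
    patient_id = patient_id,
    explained = explained,
    n_genes_hit = n_genes_hit,
    oligogenic = oligogenic,
    mechanisms = list(mechanisms),
    mechanism_summary = summary
  )
}

#' Assign causality across a classified cohort
#'
#' Joins the per-variant verdicts onto the genotype observations, keeps P/LP
#' genotypes, and resolves each patient's causal mechanisms under the
#' panel's inheritance modes, including the compound-heterozygote and
#' MSH4-MSH5 digenic-heterodimer logic. A patient is *oligogenic* when
#' explained with P/LP variants spanning two or more distinct genes (a
#' heterodimer pair spans two).
#'
#' @param genotypes Genotype observation tibble (see [read_cohort()]).
#' @param classified Classified variant tibble from [classify_variants()].
#' @param panel Panel tibble from [read_panel()].
#' @param mode `"carrier"` (default) or `"strict"`; see [assign_patient()].
#' @param patients Optional patient tibble; when supplied, phenotype-only
#'   patients without qualifying variants appear as unexplained rows.
#' @return An assignment tibble, one row per patient.
#' @examples
#' cohort <- poi_example_cohort()
#' classified <- classify_variants(filter_variants(cohort$variants)$kept)
#' asn <- assign_cohort(cohort$genotypes, classified, poi_default_panel())
#' assignment_tally(asn)  # 72 explained, 63 monogenic, 9 oligogenic
#' @export
assign_cohort <- function(genotypes, classified, panel,
                          mode = c("carrier", "strict"), patients = NULL) {
  mode <- match.arg(mode)
  plp <- classified[classified$verdict %in% c("P", "LP"),
                    c("gene", "hgvs_c", "verdict")]
  geno_plp <- dplyr::inner_join(genotypes, plp, by = c("gene", "hgvs_c"))
  ids <- unique(genotypes$patient_id)
  if (!is.null(patients)) ids <- union(ids, patients$patient_id)
  carriers <- split(geno_plp, geno_plp$patient_id)
  assignments <- purrr::imap(carriers, function(g, id) {
    assign_patient(id, g, panel, mode = mode)
  }) |>
    dplyr::bind_rows()
  rest <- setdiff(ids, names(carriers))
  if (length(rest) > 0L) {
    empty <- tibble::tibble(
      patient_id = rest, explained = FALSE, n_genes_hit = 0L,
      oligogenic = FALSE,
      mechanisms = rep(list(empty_mechanisms()), length(rest)),
      mechanism_summary = ""
    )
    assignments <- dplyr::bind_rows(assignments, empty)
  }
  assignments[order(assignments$patient_id), , drop = FALSE]
}

#' Tally cohort assignments
#'
#' @param assignments Output of [assign_cohort()].
#' @return A one-row tibble with `n_explained`, `n_monogenic_only` and
#'   `n_oligogenic`.
#' @export
assignment_tally <- function(assignments) {
  tibble::tibble(
    n_explained = sum(assignments$explained),
    n_monogenic_only = sum(assignments$explained & !assignments$oligogenic),
    n_oligogenic = sum(assignments$oligogenic)
  )
}
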