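#' Read a POI gene-panel definition
#'
#' Reads a tab-delimited panel file with one row per gene. The file must
#' carry the columns `symbol`, `category` and `mode`; `omim`, `partner` and
#' `aliases` are optional. Inheritance modes are mapped onto the four
#' supported values `AD`, `AR`, `AR_AD` and `XLD` (the spellings `AR/AD` and
#' `XLD/` used in clinical tables are accepted).
#'
#' @param path Path to a tab-delimited panel file.
#' @return A tibble with columns `symbol`, `category` (one of `meiosis`,
#'   `ligand_receptor`, `transcription_factor`), `inheritance_mode`,
#'   `omim_gene`, `heterodimer_partner` and `aliases`.
#' @examples
#' panel <- poi_default_panel()
#' dplyr::count(panel, category)
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("panel file not found: ", path))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0L) {
    abort(paste0("panel file is empty: ", path))
  }
  required <- c("symbol", "category", "mode")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    abort(paste0("panel file is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(raw$symbol)) {
    dups <- unique(raw$symbol[duplicated(raw$symbol)])
    abort(paste0("duplicate panel entries: ", paste(dups, collapse = ", ")))
  }
  mode <- normalize_mode(raw$mode)
  bad_cat <- setdiff(unique(raw$category),
                     c("meiosis", "ligand_receptor", "transcription_factor"))
  if (length(bad_cat) > 0L) {
    abort(paste0("unknown panel category: ", paste(bad_cat, collapse = ", ")))
  }
  panel <- tibble::tibble(
    symbol = raw$symbol,
    category = raw$category,
    inheritance_mode = mode,
    omim_gene = if ("omim" %in% names(raw)) raw$omim else NA_character_,
    heterodimer_partner = if ("partner" %in% names(raw)) raw$partner else NA_character_,
    aliases = if ("aliases" %in% names(raw)) raw$aliases else NA_character_
  )
  # heterodimer partnerships must be symmetric and stay inside the panel
  with_partner <- panel[!is.na(panel$heterodimer_partner), ]
  for (i in seq_len(nrow(with_partner))) {
    p <- with_partner$heterodimer_partner[i]
    s <- with_partner$symbol[i]
    if (!p %in% panel$symbol) {
      abort(paste0("heterodimer partner of ", s, " (", p, ") is not in the panel"))
    }
    back <- panel$heterodimer_partner[panel$symbol == p]
    if (is.na(back) || back != s) {
      abort(paste0("heterodimer partnership ", s, "-", p, " is not symmetric"))
    }
  }
  panel
}

normalize_mode <- function(x) {
  key <- toupper(gsub("[[:space:]]", "", x))
  key <- sub("/$", "", key)
  map <- c(
    "AD" = "AD", "AR" = "AR", "XLD" = "XLD",
    "AR_AD" = "AR_AD", "AR/AD" = "AR_AD", "AD/AR" = "AR_AD"
  )
  out <- unname(map[key])
  if (anyNA(out)) {
    abort(paste0("unknown inheritance mode: ",
                 paste(unique(x[is.na(out)]), collapse = ", ")))
  }
  out
}

#' Packaged 28-gene POI panel
#'
#' The default targeted panel: 11 meiosis genes, 8 ligand/receptor genes and
#' 9 ovary-expressed transcription factors, each with its curated inheritance
#' mode and, for the MSH4-MSH5 heterodimer, the partner link.
#'
#' @return A panel tibble (see [read_panel()]).
#' @export
poi_default_panel <- function() {
  read_panel(system.file("extdata", "table3_panel.tsv", package = "poipanel",
                         mustWork = TRUE))
}

#' Read a list of previously reported pathogenic variants
#'
#' @param path Path to a tab-delimited file with columns `gene` and `hgvs_c`
#'   (a `note` column is kept when present).
#' @return A tibble with columns `gene`, `hgvs_c` and `note`.
#' @export
read_known_pathogenic <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(c("gene", "hgvs_c"), names(raw))
  if (length(missing_cols) > 0L) {
    abort(paste0("known-pathogenic file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tibble::tibble(
    gene = raw$gene,
    hgvs_c = raw$hgvs_c,
    note = if ("note" %in% names(raw)) raw$note else NA_character_
  )
}

#' Packaged previously-reported pathogenic variants
#'
#' The three panel variants with prior published evidence of pathogenicity:
#' NOBOX p.R355H, NR5A1 p.R313H and MSH5 p.R351G.
#'
#' @return A tibble with columns `gene`, `hgvs_c`, `note`.
#' @export
poi_known_pathogenic <- function() {
  read_known_pathogenic(system.file("extdata", "known_pathogenic.tsv",
                                    package = "poipanel", mustWork = TRUE))
}

# "ND", "" -> NA; "<5.00" (below reporting limit) -> the limit
parse_clinical_numeric <- function(x) {
  x <- trimws(x)
  x[x %in% c("", "ND", "NA")] <- NA_character_
  x <- sub("^<", "", x)
  suppressWarnings(as.numeric(x))
}

parse_af <- function(x, column) {
  x <- trimws(x)
  x[x %in% c("", "ND", "NA")] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(out) & (out < 0 | out > 1))
  if (length(bad) > 0L) {
    abort(paste0("allele frequency out of [0,1] in column ", column, ": ",
                 paste(unique(out[bad]), collapse = ", ")))
  }
  out
}

# map alias symbols (e.g. CSB-PGBD3) onto canonical panel symbols
apply_gene_aliases <- function(gene, panel) {
  if (is.null(panel)) return(gene)
  alias_rows <- panel[!is.na(panel$aliases) & panel$aliases != "", ]
  if (nrow(alias_rows) == 0L) return(gene)
  map <- list()
  for (i in seq_len(nrow(alias_rows))) {
    for (a in strsplit(alias_rows$aliases[i], ",")[[1]]) {
      map[[trimws(a)]] <- alias_rows$symbol[i]
    }
  }
  hit <- gene %in% names(map)
  gene[hit] <- unlist(map[gene[hit]])
  gene
}

#' Read an annotated panel-sequencing cohort
#'
#' Ingests two tab-delimited files: a genotype table (one row per
#' patient-variant observation, with HGVS notation, zygosity, optional phase,
#' reference allele frequencies and in-silico scores) and a patient phenotype
#' table. Observations sharing the same (gene, `hgvs_c`) key are consolidated
#' into a single variant record whose consequence is derived from the HGVS
#' notation via [classify_consequence()].
#'
#' Missing numeric cells may be encoded `ND` or left empty; hormone values
#' printed below a reporting limit (`<5.00`) are parsed to the limit.
#'
#' @param variants_path Path to the genotype observation table.
#' @param patients_path Path to the patient phenotype table.
#' @param panel Optional panel tibble; when supplied, gene aliases are
#'   normalized to panel symbols.
#' @param known_pathogenic Optional tibble (`gene`, `hgvs_c`) of previously
#'   reported pathogenic variants used to set the `known_pathogenic` flag.
#' @return A list of class `poi_cohort` with tibbles `patients`, `variants`
#'   (one row per unique variant) and `genotypes` (one row per observation).
#' @examples
#' cohort <- poi_example_cohort()
#' nrow(cohort$patients)   # 72
#' nrow(cohort$variants)   # 61
#' @export
read_cohort <- function(variants_path, patients_path, panel = NULL,
                        known_pathogenic = NULL) {
  graw <- readr::read_tsv(variants_path,
                          col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
  praw <- readr::read_tsv(patients_path,
                          col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
  needed_p <- c("patient_id", "amenorrhea")
  missing_cols <- setdiff(needed_p, names(praw))
  if (length(missing_cols) > 0L) {
    abort(paste0("patient table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  get_chr <- function(df, col) {
    if (col %in% names(df)) {
      out <- trimws(df[[col]])
      out[out %in% c("", "ND", "NA", "-")] <- NA_character_
      out
    } else {
      rep(NA_character_, nrow(df))
    }
  }
  patients <- tibble::tibble(
    patient_id = praw$patient_id,
    amenorrhea = dplyr::coalesce(get_chr(praw, "amenorrhea"), "ND"),
    menarche_age = parse_clinical_numeric(get_chr(praw, "menarche_age")),
    onset_age = parse_clinical_numeric(get_chr(praw, "onset_age")),
    fsh = parse_clinical_numeric(get_chr(praw, "fsh")),
    lh = parse_clinical_numeric(get_chr(praw, "lh")),
    e2 = parse_clinical_numeric(get_chr(praw, "e2")),
    karyotype = dplyr::coalesce(get_chr(praw, "karyotype"), "46,XX")
  )
  bad_amen <- setdiff(unique(patients$amenorrhea), c("PA", "SA", "ND"))
  if (length(bad_amen) > 0L) {
    abort(paste0("unknown amenorrhea type: ", paste(bad_amen, collapse = ", ")))
  }
  late <- which(!is.na(patients$onset_age) & patients$onset_age >= 40)
  if (length(late) > 0L) {
    abort(paste0("onset_age >= 40 violates the POI definition for: ",
                 paste(patients$patient_id[late], collapse = ", ")))
  }
  odd <- !is.na(patients$menarche_age) & !is.na(patients$onset_age) &
    patients$menarche_age > patients$onset_age
  if (any(odd)) {
    warn(paste0("menarche_age exceeds onset_age for: ",
                paste(patients$patient_id[odd], collapse = ", ")))
  }

  if (nrow(graw) > 0L) {
    needed_g <- c("patient_id", "gene", "hgvs_c")
    missing_cols <- setdiff(needed_g, names(graw))
    if (length(missing_cols) > 0L) {
      abort(paste0("genotype table is missing column(s): ",
                   paste(missing_cols, collapse = ", ")))
    }
  }
  obs <- tibble::tibble(
    patient_id = get_chr(graw, "patient_id"),
    gene = apply_gene_aliases(get_chr(graw, "gene"), panel),
    transcript = get_chr(graw, "transcript"),
    hgvs_c = get_chr(graw, "hgvs_c"),
    hgvs_p = dplyr::coalesce(get_chr(graw, "hgvs_p"), ""),
    rsid = get_chr(graw, "rsid"),
    zygosity = dplyr::coalesce(get_chr(graw, "zygosity"), "het"),
    phase = dplyr::coalesce(get_chr(graw, "phase"), "unknown"),
    af_gnomad = parse_af(get_chr(graw, "af_gnomad"), "af_gnomad"),
    af_exac_eas = parse_af(get_chr(graw, "af_exac_eas"), "af_exac_eas"),
    af_1000g = parse_af(get_chr(graw, "af_1000g"), "af_1000g"),
    metasvm = dplyr::coalesce(get_chr(graw, "metasvm"), "missing"),
    cadd = parse_clinical_numeric(get_chr(graw, "cadd")),
    dann = parse_clinical_numeric(get_chr(graw, "dann")),
    reported_class = get_chr(graw, "reported_class")
  )
  bad_zyg <- setdiff(unique(obs$zygosity), c("het", "hom"))
  if (length(bad_zyg) > 0L && nrow(obs) > 0L) {
    abort(paste0("unknown zygosity: ", paste(bad_zyg, collapse = ", ")))
  }
  bad_phase <- setdiff(unique(obs$phase), c("paternal", "maternal", "unknown"))
  if (length(bad_phase) > 0L && nrow(obs) > 0L) {
    abort(paste0("unknown phase: ", paste(bad_phase, collapse = ", ")))
  }
  if (any(obs$zygosity == "hom" & obs$phase != "unknown")) {
    abort("homozygous genotypes cannot carry a parental phase")
  }
  orphan <- setdiff(unique(obs$patient_id), patients$patient_id)
  if (length(orphan) > 0L) {
    abort(paste0("genotype observations reference unknown patient(s): ",
                 paste(orphan, collapse = ", ")))
  }
  dup <- duplicated(obs[, c("patient_id", "gene", "hgvs_c")])
  if (any(dup)) {
    abort(paste0("duplicate genotype observation(s): ",
                 paste(variant_key(obs$gene[dup], obs$hgvs_c[dup]), collapse = ", ")))
  }

  variants <- consolidate_variants(obs, known_pathogenic = known_pathogenic)
  genotypes <- obs[, c("patient_id", "gene", "hgvs_c", "zygosity", "phase")]
  structure(
    list(patients = patients, variants = variants, genotypes = genotypes),
    class = "poi_cohort"
  )
}

# collapse observation rows into one record per (gene, hgvs_c);
# the first non-missing value wins for annotation fields
consolidate_variants <- function(obs, known_pathogenic = NULL) {
  if (nrow(obs) == 0L) {
    variants <- tibble::tibble(
      gene = character(), transcript = character(), hgvs_c = character(),
      hgvs_p = character(), rsid = character(),
      af_gnomad = double(), af_exac_eas = double(), af_1000g = double(),
      metasvm = character(), cadd = double(), dann = double(),
      reported_class = character()
    )
  } else {
    first_value <- function(x) {
      present <- !is.na(x) & x != ""
      if (any(present)) x[present][1] else x[1]
    }
    variants <- obs |>
      dplyr::group_by(.data$gene, .data$hgvs_c) |>
      dplyr::summarise(
        transcript = first_value(.data$transcript),
        hgvs_p = first_value(.data$hgvs_p),
        rsid = first_value(.data$rsid),
        af_gnomad = first_value(.data$af_gnomad),
        af_exac_eas = first_value(.data$af_exac_eas),
        af_1000g = first_value(.data$af_1000g),
        metasvm = first_value(.data$metasvm),
        cadd = first_value(.data$cadd),
        dann = first_value(.data$dann),
        reported_class = first_value(.data$reported_class),
        .groups = "drop"
      ) |>
      dplyr::relocate("transcript", .after = "gene")
  }
  cons <- classify_consequence(variants$hgvs_c, variants$hgvs_p)
  variants$consequence <- cons$consequence
  variants$intronic_offset <- cons$intronic_offset
  kp_key <- if (is.null(known_pathogenic)) character() else
    variant_key(known_pathogenic$gene, known_pathogenic$hgvs_c)
  variants$known_pathogenic <- variant_key(variants$gene, variants$hgvs_c) %in% kp_key
  variants
}

#' Packaged example cohort (72 POI patients, 61 unique variants)
#'
#' The curated example cohort shipped with the package: 72 patients carrying
#' 91 genotype observations of 61 unique pathogenic/likely-pathogenic panel
#' variants, with phenotypes, curated zygosity (one homozygous MSH5 variant)
#' and pedigree-confirmed phase for two compound-heterozygous pairs.
#'
#' @return A `poi_cohort` list (see [read_cohort()]).
#' @export
poi_example_cohort <- function() {
  read_cohort(
    system.file("extdata", "table1_genotypes.tsv", package = "poipanel", mustWork = TRUE),
    system.file("extdata", "table1_patients.tsv", package = "poipanel", mustWork = TRUE),
    panel = poi_default_panel(),
    known_pathogenic = poi_known_pathogenic()
  )
}

#' @export
print.poi_cohort <- function(x, ...) {
  cat("<poi_cohort>\n")
  cat("  patients:  ", nrow(x$patients), "\n", sep = "")
  cat("  variants:  ", nrow(x$variants), " unique (gene, hgvs_c)\n", sep = "")
  cat("  genotypes: ", nrow(x$genotypes), " observations\n", sep = "")
  invisible(x)
}

#' Write a cohort back to delimited files
#'
#' Emits an observation-level genotype table and a patient table in the same
#' format [read_cohort()] ingests, so that a written cohort round-trips.
#'
#' @param cohort A `poi_cohort` list.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcols <- c("transcript", "hgvs_p", "rsid", "af_gnomad", "af_exac_eas",
             "af_1000g", "metasvm", "cadd", "dann", "reported_class")
  obs <- cohort$genotypes |>
    dplyr::left_join(cohort$variants[, c("gene", "hgvs_c", vcols)],
                     by = c("gene", "hgvs_c"))
  gpath <- file.path(dir, "genotypes.tsv")
  ppath <- file.path(dir, "patients.tsv")
  readr::write_tsv(obs, gpath, progress = FALSE)
  readr::write_tsv(cohort$patients, ppath, progress = FALSE)
  invisible(c(genotypes = gpath, patients = ppath))
}

#' Write pipeline reports
#'
#' Emits a per-variant classification table, a per-patient assignment table
#' and a machine-parseable key-value cohort summary. Output is byte-stable
#' for identical inputs.
#'
#' @param result A pipeline result from [run_poi_pipeline()], or a list with
#'   elements `classified`, `assignments` and `summary`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_reports <- function(result, out_dir) {
  ok <- tryCatch({
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    file.access(out_dir, 2) == 0
  }, error = function(e) FALSE)
  if (!isTRUE(ok)) abort(paste0("cannot write to directory: ", out_dir))

  classified <- result$classified
  vtab <- classified |>
    dplyr::arrange(.data$gene, .data$hgvs_c) |>
    dplyr::mutate(criteria = purrr::map_chr(.data$criteria, paste, collapse = ";")) |>
    dplyr::select("gene", "hgvs_c", "hgvs_p", "consequence", "verdict", "criteria")
  vpath <- file.path(out_dir, "variant_classifications.tsv")
  readr::write_tsv(vtab, vpath, progress = FALSE)

  atab <- result$assignments |>
    dplyr::arrange(.data$patient_id) |>
    dplyr::select("patient_id", "explained", "oligogenic", "n_genes_hit",
                  "mechanism_summary")
  apath <- file.path(out_dir, "patient_assignments.tsv")
  readr::write_tsv(atab, apath, progress = FALSE)

  counts <- glance(result$summary)
  spath <- file.path(out_dir, "cohort_summary.txt")
  lines <- sprintf("%s: %s", names(counts),
                   vapply(counts, function(v) format(v, trim = TRUE, scientific = FALSE),
                          character(1)))
  writeLines(lines, spath)
  invisible(c(variants = vpath, assignments = apath, summary = spath))
}
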