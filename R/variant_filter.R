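#' Parse cDNA-level HGVS notation
#'
#' A minimal parser for the cDNA descriptions used on targeted panels:
#' substitutions (`c.1045C>G`), deletions (`c.2220_2223del`, `c.2054delC`),
#' duplications (`c.2041dupG`), insertions (`c.960_961insCGA`), and
#' deletion-insertions, with optional intronic offsets (`c.566+1G>T`,
#' `c.1978-2A>C`). The intronic offset is the signed distance in base pairs
#' from the nearest exon boundary.
#'
#' @param hgvs_c Character vector of cDNA HGVS strings (must start `c.`).
#' @return A tibble with one row per input: `hgvs_c`, `edit` (one of
#'   `substitution`, `deletion`, `duplication`, `insertion`, `delins`),
#'   `position`, `end_position` and `intronic_offset` (NA for exonic
#'   changes).
#' @examples
#' parse_hgvs_c(c("c.566+1G>T", "c.1978-2A>C", "c.1045C>G"))
#' @export
parse_hgvs_c <- function(hgvs_c) {
  rows <- lapply(hgvs_c, parse_hgvs_c_one)
  tibble::tibble(
    hgvs_c = vapply(rows, `[[`, character(1), "hgvs_c"),
    edit = vapply(rows, `[[`, character(1), "edit"),
    position = vapply(rows, `[[`, integer(1), "position"),
    end_position = vapply(rows, `[[`, integer(1), "end_position"),
    intronic_offset = vapply(rows, `[[`, integer(1), "intronic_offset"),
    edit_seq = vapply(rows, `[[`, character(1), "edit_seq")
  )
}

parse_hgvs_c_one <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    abort("empty HGVS cDNA string")
  }
  s <- gsub("[[:space:]]", "", x)
  if (!startsWith(s, "c.")) {
    abort(paste0("not a cDNA HGVS string (must start 'c.'): ", x))
  }
  body <- substring(s, 3)
  pos_re <- "(\\d+)([+-]\\d+)?"
  out <- function(edit, position, offset, end_position = NA_integer_,
                  edit_seq = NA_character_) {
    list(
      hgvs_c = x, edit = edit,
      position = as.integer(position),
      end_position = as.integer(end_position),
      intronic_offset = if (is.na(offset) || offset == "") NA_integer_ else
        as.integer(offset),
      edit_seq = if (is.na(edit_seq) || !nzchar(edit_seq)) NA_character_ else edit_seq
    )
  }
  m <- regmatches(body, regexec(paste0("^", pos_re, "([ACGT])>([ACGT])$"), body))[[1]]
  if (length(m) > 0L) {
    return(out("substitution", m[2], m[3], edit_seq = m[5]))
  }
  m <- regmatches(body, regexec(
    paste0("^", pos_re, "(?:_", pos_re, ")?del(?:ins([ACGT]+)|([ACGT]*))$"), body))[[1]]
  if (length(m) > 0L) {
    edit <- if (nzchar(m[6])) "delins" else "deletion"
    return(out(edit, m[2], m[3], end_position = if (nzchar(m[4])) m[4] else NA,
               edit_seq = if (nzchar(m[6])) m[6] else m[7]))
  }
  m <- regmatches(body, regexec(
    paste0("^", pos_re, "(?:_", pos_re, ")?dup([ACGT]*)$"), body))[[1]]
  if (length(m) > 0L) {
    return(out("duplication", m[2], m[3], end_position = if (nzchar(m[4])) m[4] else NA,
               edit_seq = m[6]))
  }
  m <- regmatches(body, regexec(
    paste0("^", pos_re, "_", pos_re, "ins([ACGT]+)$"), body))[[1]]
  if (length(m) > 0L) {
    return(out("insertion", m[2], m[3], end_position = m[4], edit_seq = m[6]))
  }
  abort(paste0("unparseable HGVS cDNA string: ", x))
}

#' Derive a variant consequence from HGVS notation
#'
#' Categorizes each variant from its cDNA and protein notation:
#' protein notation containing `fs` is a frameshift; protein notation ending
#' in `X`, `Ter` or `*` is nonsense; a cDNA intronic offset within 2 bp of
#' the exon boundary is a canonical splice-site change (beyond 2 bp,
#' non-canonical); a single-residue protein substitution is missense;
#' everything else (in-frame indels, synonymous changes) is `other`.
#'
#' @param hgvs_c Character vector of cDNA HGVS strings (may be `NA` when the
#'   protein notation is given).
#' @param hgvs_p Character vector of protein HGVS strings (`""`, `"-"` or
#'   `NA` when absent, as for splice-region changes).
#' @return A tibble with columns `consequence` (one of `missense`,
#'   `nonsense`, `frameshift`, `splice_canonical`, `splice_noncanonical`,
#'   `other`) and `intronic_offset` (NA unless a splice-region change).
#' @examples
#' classify_consequence("c.2728C>T", "p.R910X")$consequence   # nonsense
#' classify_consequence("c.566+1G>T", "")$consequence         # splice_canonical
#' @export
classify_consequence <- function(hgvs_c, hgvs_p) {
  n <- max(length(hgvs_c), length(hgvs_p))
  hgvs_c <- rep_len(hgvs_c, n)
  hgvs_p <- rep_len(hgvs_p, n)
  rows <- purrr::map2(hgvs_c, hgvs_p, classify_consequence_one)
  tibble::tibble(
    consequence = vapply(rows, `[[`, character(1), "consequence"),
    intronic_offset = vapply(rows, `[[`, integer(1), "intronic_offset")
  )
}

classify_consequence_one <- function(hgvs_c, hgvs_p) {
  p <- if (is.na(hgvs_p)) "" else gsub("[[:space:]]", "", hgvs_p)
  if (p %in% c("-", ".")) p <- ""
  c_present <- !is.na(hgvs_c) && nzchar(hgvs_c)
  if (!c_present && !nzchar(p)) {
    abort("at least one of hgvs_c / hgvs_p must be non-empty")
  }
  offset <- NA_integer_
  edit <- NA_character_
  parsed <- NULL
  if (c_present) {
    parsed <- parse_hgvs_c_one(hgvs_c)
    offset <- parsed$intronic_offset
    edit <- parsed$edit
  }

  protein_call <- NA_character_
  if (nzchar(p)) {
    if (grepl("fs", p)) {
      protein_call <- "frameshift"
    } else if (grepl("(X|\\*|Ter)$", p)) {
      protein_call <- "nonsense"
    } else if (grepl("^p\\.(\\(?)([A-Z][a-z]{2}|[A-Z])(\\d+)([A-Z][a-z]{2}|[A-Z])(\\)?)$", p)) {
      m <- regmatches(p, regexec(
        "^p\\.\\(?([A-Z][a-z]{2}|[A-Z])(\\d+)([A-Z][a-z]{2}|[A-Z])\\)?$", p))[[1]]
      protein_call <- if (m[2] == m[4]) "other" else "missense"
    } else {
      protein_call <- "other"
    }
  }

  if (!is.na(protein_call) && protein_call %in% c("frameshift", "nonsense", "missense") &&
      !is.na(offset)) {
    abort(paste0("inconsistent notation: protein says ", protein_call,
                 " but cDNA is intronic (", hgvs_c, " / ", hgvs_p, ")"))
  }

  consequence <- if (!is.na(offset)) {
    if (abs(offset) <= 2L) "splice_canonical" else "splice_noncanonical"
  } else if (!is.na(protein_call)) {
    protein_call
  } else {
    # cDNA only, exonic: indels of length not divisible by 3 shift the frame
    len <- indel_length(parsed)
    if (!is.na(len) && len %% 3L != 0L) "frameshift" else "other"
  }
  list(
    consequence = consequence,
    intronic_offset = if (consequence %in%
                          c("splice_canonical", "splice_noncanonical"))
      offset else NA_integer_
  )
}

indel_length <- function(parsed) {
  if (is.null(parsed) || parsed$edit == "substitution") return(NA_integer_)
  if (parsed$edit %in% c("insertion", "delins") && !is.na(parsed$edit_seq)) {
    return(nchar(parsed$edit_seq))
  }
  if (!is.na(parsed$end_position)) {
    abs(parsed$end_position - parsed$position) + 1L
  } else {
    1L
  }
}

#' Rarity filter against reference population frequencies
#'
#' A variant counts as rare when every *present* frequency among the global
#' 1000 Genomes and gnomAD allele frequencies is strictly below the
#' threshold (0.1% by default). Missing frequencies never fail the test:
#' a variant absent from both databases is rare. The East-Asian ExAC
#' frequency is reported but deliberately not consulted.
#'
#' @param variants A variant tibble with columns `af_1000g` and `af_gnomad`.
#' @param threshold Frequency threshold in (0, 1]; strictly-below comparison.
#' @return A logical vector, one element per variant row.
#' @export
is_rare <- function(variants, threshold = 0.001) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold <= 1)
  g <- variants$af_gnomad %||% rep(NA_real_, nrow(variants))
  k <- variants$af_1000g %||% rep(NA_real_, nrow(variants))
  (is.na(g) | g < threshold) & (is.na(k) | k < threshold)
}

#' Partition a variant set into rare and rejected variants
#'
#' @param variants A variant tibble (see [read_cohort()]).
#' @param threshold Rarity threshold passed to [is_rare()].
#' @return A list with `kept` (rare variants) and `rejected` (a rejection
#'   log tibble with columns `gene`, `hgvs_c`, `reason`).
#' @examples
#' cohort <- poi_example_cohort()
#' filt <- filter_variants(cohort$variants)
#' nrow(filt$kept)  # all 61 example variants are rare
#' @export
filter_variants <- function(variants, threshold = 0.001) {
  rare <- is_rare(variants, threshold)
  rejected <- variants[!rare, , drop = FALSE]
  reason <- character(nrow(rejected))
  for (i in seq_len(nrow(rejected))) {
    offending <- c()
    if (!is.na(rejected$af_1000g[i]) && rejected$af_1000g[i] >= threshold) {
      offending <- c(offending,
                     sprintf("af_1000g=%g >= %g", rejected$af_1000g[i], threshold))
    }
    if (!is.na(rejected$af_gnomad[i]) && rejected$af_gnomad[i] >= threshold) {
      offending <- c(offending,
                     sprintf("af_gnomad=%g >= %g", rejected$af_gnomad[i], threshold))
    }
    reason[i] <- paste(offending, collapse = "; ")
  }
  list(
    kept = variants[rare, , drop = FALSE],
    rejected = tibble::tibble(
      gene = rejected$gene, hgvs_c = rejected$hgvs_c, reason = reason
    )
  )
}

#' Write a rarity-filter rejection log
#'
#' @param rejected The `rejected` tibble from [filter_variants()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_rejection_log <- function(rejected, path) {
  readr::write_tsv(rejected, path, progress = FALSE)
  invisible(path)
}
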