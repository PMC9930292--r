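#' Classify rare variants as pathogenic / likely pathogenic / uncertain
#'
#' Implements a simplified ACMG-style decision tree for rare panel variants:
#'
#' * **P (pathogenic)** — truncating variants (nonsense or frameshift),
#'   canonical splice-site variants (within 2 intronic bp of the exon
#'   boundary), and variants previously reported as pathogenic.
#' * **LP (likely pathogenic)** — non-synonymous missense variants predicted
#'   "Deleterious" by MetaSVM combined with a CADD score above
#'   `cadd_threshold` or a DANN score above `dann_threshold`.
#' * **VUS** — everything else. Missing in-silico scores never satisfy their
#'   clause.
#'
#' The LP clause is configurable: `"metasvm_and_either"` (default) requires
#' the MetaSVM call and lets either score suffice;
#' `"metasvm_and_cadd_or_dann_alone"` reads the rule as
#' (MetaSVM-Deleterious AND CADD) OR (DANN alone).
#'
#' @param variants A variant tibble with columns `consequence`,
#'   `known_pathogenic`, `metasvm`, `cadd`, `dann` (see [read_cohort()]).
#' @param cadd_threshold CADD score threshold (exclusive), default 3.
#' @param dann_threshold DANN score threshold (exclusive), default 0.95.
#' @param lp_rule Which reading of the likely-pathogenic clause to apply.
#' @return The input tibble with columns `verdict` (`P`/`LP`/`VUS`) and
#'   `criteria` (list column of fired rule tags among `truncating`,
#'   `canonical_splice`, `previously_reported`, `metasvm_cadd`,
#'   `metasvm_dann`) appended.
#' @examples
#' cohort <- poi_example_cohort()
#' classified <- classify_variants(cohort$variants)
#' classification_tally(classified)  # 18 P, 43 LP, 0 VUS
#' @export
classify_variants <- function(variants, cadd_threshold = 3, dann_threshold = 0.95,
                              lp_rule = c("metasvm_and_either",
                                          "metasvm_and_cadd_or_dann_alone")) {
  lp_rule <- match.arg(lp_rule)
  n <- nrow(variants)
  consequence <- variants$consequence
  known <- variants$known_pathogenic %||% rep(FALSE, n)
  known[is.na(known)] <- FALSE
  metasvm <- variants$metasvm %||% rep("missing", n)
  metasvm[is.na(metasvm)] <- "missing"
  cadd <- variants$cadd %||% rep(NA_real_, n)
  dann <- variants$dann %||% rep(NA_real_, n)

  deleterious <- metasvm == "deleterious"
  cadd_hit <- !is.na(cadd) & cadd > cadd_threshold
  dann_hit <- !is.na(dann) & dann > dann_threshold
  missense <- consequence == "missense"

  criteria <- vector("list", n)
  verdict <- character(n)
  for (i in seq_len(n)) {
    fired <- character()
    if (consequence[i] %in% c("nonsense", "frameshift")) fired <- c(fired, "truncating")
    if (consequence[i] == "splice_canonical") fired <- c(fired, "canonical_splice")
    if (known[i]) fired <- c(fired, "previously_reported")
    if (length(fired) > 0L) {
      verdict[i] <- "P"
      criteria[[i]] <- fired
      next
    }
    if (missense[i]) {
      if (lp_rule == "metasvm_and_either") {
        if (deleterious[i] && cadd_hit[i]) fired <- c(fired, "metasvm_cadd")
        if (deleterious[i] && dann_hit[i]) fired <- c(fired, "metasvm_dann")
      } else {
        if (deleterious[i] && cadd_hit[i]) fired <- c(fired, "metasvm_cadd")
        if (dann_hit[i]) fired <- c(fired, "metasvm_dann")
      }
    }
    verdict[i] <- if (length(fired) > 0L) "LP" else "VUS"
    criteria[[i]] <- fired
  }
  variants$verdict <- verdict
  variants$criteria <- criteria
  variants
}

#' Tally classification verdicts
#'
#' @param classified Output of [classify_variants()].
#' @return A one-row tibble with counts `n_p`, `n_lp`, `n_vus`.
#' @export
classification_tally <- function(classified) {
  tibble::tibble(
    n_p = sum(classified$verdict == "P"),
    n_lp = sum(classified$verdict == "LP"),
    n_vus = sum(classified$verdict == "VUS")
  )
}
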