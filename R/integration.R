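# Phenotype-proteome integration: Spearman coupling of assay effect sizes
# with term-level enrichment across knockdowns, and deterministic target
# tiering from hits, reversal calls and coupled terms.

#' Correlate assay effect sizes with term enrichment across knockdowns
#'
#' For every (assay, term) pair, computes Spearman rho over the
#' (siRNA, cell line) points pairing the assay's estimated effect size with
#' that knockdown's NES for the term. The raw NES is used whether or not the
#' term was significant in that knockdown, and points from both cell lines
#' are pooled into one correlation. Effects from the LPS-stimulated NFkB
#' assay are excluded (no LPS induction precedes the proteome measurement).
#' Benjamini-Hochberg correction is applied jointly over all (assay, term)
#' pairs.
#'
#' @param effects Effect estimates from [fit_effect_model()] (`assay`,
#'   `dose`, `cell_line`, `sirna`, `effect`).
#' @param enrichments Stacked per-knockdown enrichment results (`target`,
#'   `cell_line`, `term`, `nes`).
#' @param min_points Minimum paired (siRNA, cell line) observations per
#'   (assay, term); pairs with fewer, or with a constant vector on either
#'   side, are skipped.
#' @param exclude_assay,exclude_dose The stimulated stratum to drop
#'   (defaults: the `"nfkb"` assay under `"LPS"`).
#' @return Tibble: `assay`, `dose`, `term`, `rho`, `n`, `p`, `p_adj`.
#' @export
correlate_assay_terms <- function(effects, enrichments, min_points = 8,
                                  exclude_assay = "nfkb", exclude_dose = "LPS") {
  effects <- tibble::as_tibble(effects)
  if (!"dose" %in% names(effects)) effects$dose <- NA_character_
  effects <- effects[!(effects$assay == exclude_assay &
                         !is.na(effects$dose) & effects$dose == exclude_dose), ]
  enrichments <- tibble::as_tibble(enrichments)
  pts <- dplyr::inner_join(
    dplyr::select(effects, "assay", "dose", "cell_line", sirna = "sirna", "effect"),
    dplyr::select(enrichments, sirna = "target", "cell_line", "term", "nes"),
    by = c("sirna", "cell_line"),
    relationship = "many-to-many"
  )
  empty <- tibble::tibble(assay = character(), dose = character(),
                          term = character(), rho = numeric(), n = integer(),
                          p = numeric(), p_adj = numeric())
  if (nrow(pts) == 0) return(empty)
  out <- pts |>
    dplyr::group_by(.data$assay, .data$dose, .data$term) |>
    dplyr::summarise(
      n = dplyr::n(),
      rho = if (dplyr::n() >= min_points && sd(.data$effect) > 0 && sd(.data$nes) > 0) {
        unname(suppressWarnings(
          cor.test(.data$effect, .data$nes, method = "spearman", exact = FALSE))$estimate)
      } else NA_real_,
      p = if (dplyr::n() >= min_points && sd(.data$effect) > 0 && sd(.data$nes) > 0) {
        suppressWarnings(
          cor.test(.data$effect, .data$nes, method = "spearman", exact = FALSE))$p.value
      } else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::filter(!is.na(.data$rho))
  if (nrow(out) == 0) return(empty)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out[, c("assay", "dose", "term", "rho", "n", "p", "p_adj")]
}

#' Assemble per-target scorecards and tier labels
#'
#' Combines the three evidence streams into one row per target:
#'
#' * `phenotype_hits` -- significant assay effects from [fit_effect_model()];
#' * `reversal_domains` -- biodomains where the knockdown's profile is
#'   significantly anti-correlated with the reference disease signature;
#' * `coupled_terms` -- (assay, term) pairs significant in
#'   [correlate_assay_terms()] for which the target's own enrichment of the
#'   term is also significant.
#'
#' Tiers partition targets by predicate: `top` (hit and reversal and coupled
#' term), `supported` (hit and reversal), `phenotype_only` (hit),
#' `proteome_only` (reversal), `none`. Adding evidence can only promote a
#' target.
#'
#' @param hits Effect estimates from [fit_effect_model()].
#' @param concordance Concordance calls ([concordance_table()] and/or
#'   [pearson_protein_concordance()], row-bound).
#' @param integration Output of [correlate_assay_terms()].
#' @param enrichments Stacked per-knockdown enrichment results (`target`,
#'   `cell_line`, `term`, `p_adj`).
#' @param alpha Significance threshold used throughout.
#' @return Tibble: `target`, `n_hits`, `n_reversal_domains`,
#'   `n_coupled_terms`, `tier`, plus list columns `phenotype_hits`,
#'   `reversal_domains`, `coupled_terms` with the supporting rows.
#' @export
build_scorecards <- function(hits, concordance, integration, enrichments,
                             alpha = 0.05) {
  hits <- tibble::as_tibble(hits)
  concordance <- tibble::as_tibble(concordance)
  integration <- tibble::as_tibble(integration)
  enrichments <- tibble::as_tibble(enrichments)
  targets <- sort(unique(c(hits$sirna, concordance$target, enrichments$target)))
  sig_pairs <- integration[!is.na(integration$p_adj) & integration$p_adj <= alpha, ]
  rows <- lapply(targets, function(t) {
    h <- hits[hits$sirna == t & hits$hit, ]
    rev <- concordance[concordance$target == t & concordance$call == "anti_correlated", ]
    sig_terms <- enrichments$term[enrichments$target == t &
                                    !is.na(enrichments$p_adj) &
                                    enrichments$p_adj <= alpha]
    coupled <- sig_pairs[sig_pairs$term %in% sig_terms, c("assay", "dose", "term", "rho")]
    tier <- if (nrow(h) && nrow(rev) && nrow(coupled)) "top"
    else if (nrow(h) && nrow(rev)) "supported"
    else if (nrow(h)) "phenotype_only"
    else if (nrow(rev)) "proteome_only"
    else "none"
    tibble::tibble(
      target = t,
      n_hits = nrow(h),
      n_reversal_domains = length(unique(rev$domain)),
      n_coupled_terms = length(unique(coupled$term)),
      tier = tier,
      phenotype_hits = list(h[, intersect(c("assay", "dose", "cell_line", "effect", "p_adj"), names(h))]),
      reversal_domains = list(rev[, intersect(c("domain", "method", "cell_line", "stat", "p_adj"), names(rev))]),
      coupled_terms = list(coupled)
    )
  })
  dplyr::bind_rows(rows)
}
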