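# Phenotype hit calling: per-batch log2 fold changes against the control
# siRNA, a batch random-intercept model per assay, marginal means per
# (siRNA, cell line), and BH-corrected hit calls. Also 2^-ddCt
# knockdown-efficiency quantification from qPCR Ct tables.

.assay_cols <- c("assay", "cell_line", "sirna", "batch", "replicate", "value")

#' Per-batch log2 fold changes against the control siRNA
#'
#' Within each stratum (assay, cell line, batch and, where applicable, dose),
#' averages the raw replicate readouts per siRNA arithmetically and computes
#' `log2(mean target / mean control)`. Control-siRNA rows are retained with a
#' log2 fold change of exactly zero.
#'
#' @param measurements Tibble of raw well-level readouts with columns
#'   `assay`, `cell_line`, `sirna`, `batch`, `replicate`, `value` and
#'   optionally `dose` (`NA` for dose-free assays). All values must be
#'   positive.
#' @param control Label of the control siRNA; must be present in every
#'   stratum.
#' @return Tibble with one row per (assay, dose, cell line, batch, siRNA):
#'   columns `assay`, `cell_line`, `sirna`, `dose`, `batch`, `log2fc`. The
#'   control label is recorded in the `"control"` attribute.
#' @export
batch_log2fc <- function(measurements, control) {
  measurements <- tibble::as_tibble(measurements)
  if (!"dose" %in% names(measurements)) measurements$dose <- NA_character_
  missing_cols <- setdiff(.assay_cols, names(measurements))
  if (length(missing_cols)) stopf("missing columns: %s", paste(missing_cols, collapse = ", "))
  if (any(!is.finite(measurements$value) | measurements$value <= 0)) {
    stopf("input error: all assay values must be positive (log2 must be defined)")
  }
  means <- measurements |>
    dplyr::group_by(.data$assay, .data$cell_line, .data$dose, .data$batch, .data$sirna) |>
    dplyr::summarise(mean_value = mean(.data$value), .groups = "drop")
  ctrl <- means |>
    dplyr::filter(.data$sirna == control) |>
    dplyr::select("assay", "cell_line", "dose", "batch", ctrl_value = "mean_value")
  strata <- dplyr::distinct(means, .data$assay, .data$cell_line, .data$dose, .data$batch)
  missing_ctrl <- dplyr::anti_join(strata, ctrl,
                                   by = c("assay", "cell_line", "dose", "batch"))
  if (nrow(missing_ctrl) > 0) {
    stopf("stratum error: control siRNA '%s' missing in: %s", control,
          paste(apply(missing_ctrl, 1, paste, collapse = "/"), collapse = "; "))
  }
  out <- means |>
    dplyr::left_join(ctrl, by = c("assay", "cell_line", "dose", "batch")) |>
    dplyr::mutate(log2fc = ifelse(.data$sirna == control, 0,
                                  log2(.data$mean_value / .data$ctrl_value))) |>
    dplyr::select("assay", "cell_line", "sirna", "dose", "batch", "log2fc")
  attr(out, "control") <- control
  out
}

# Fit one (assay, dose) stratum: batch random intercept where estimable,
# ordinary least squares otherwise; marginal means per (siRNA, cell line).
.fit_one_assay <- function(dat, key, separate_lines) {
  dat$sirna <- factor(dat$sirna)
  dat$batch <- factor(dat$batch)
  if (!"cell_line" %in% names(dat)) dat$cell_line <- key$cell_line[1]
  assay_label <- key$assay[1]
  multi_line <- length(unique(dat$cell_line)) > 1 && !separate_lines
  if (multi_line) dat$cell_line <- factor(dat$cell_line)
  fixed <- if (multi_line) log2fc ~ sirna * cell_line else log2fc ~ sirna
  model <- "ols"
  fit <- NULL
  if (nlevels(dat$batch) >= 2) {
    mixed_formula <- stats::update(fixed, . ~ . + (1 | batch))
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(mixed_formula, data = dat, REML = TRUE)
      )),
      error = function(e) NULL
    )
    if (!is.null(fit) && lme4::isSingular(fit, tol = 1e-6)) {
      warnf("estimated batch variance is zero for assay '%s'; falling back to ordinary least squares",
            assay_label)
      fit <- NULL
    } else if (!is.null(fit)) {
      model <- "mixed"
    }
  } else {
    warnf("single batch for assay '%s'; using ordinary least squares", assay_label)
  }
  specs <- if (multi_line) c("sirna", "cell_line") else "sirna"
  s <- NULL
  if (!is.null(fit)) {
    s <- tryCatch(
      as.data.frame(emmeans::emmeans(fit, specs, lmer.df = "asymptotic")),
      error = function(e) NULL
    )
    if (is.null(s)) {
      warnf("degenerate mixed fit for assay '%s'; falling back to ordinary least squares",
            assay_label)
    }
  }
  if (is.null(s)) {
    model <- "ols"
    fit <- stats::lm(fixed, data = dat)
    s <- as.data.frame(emmeans::emmeans(fit, specs))
  }
  out <- tibble::tibble(
    sirna = as.character(s$sirna),
    cell_line = if (multi_line) as.character(s$cell_line) else dat$cell_line[1],
    effect = s$emmean,
    se = s$SE,
    model = model
  )
  if (separate_lines) out$cell_line <- NULL  # carried by the grouping key
  out[is.finite(out$effect), ]
}

#' Fit per-assay effect models and call hits
#'
#' Per assay (and LPS dose, where applicable): fits the per-batch log2 fold
#' changes with fixed effects siRNA x cell line and a batch random intercept
#' (restricted maximum likelihood). When the estimated batch variance is zero
#' (a singular fit) or only one batch is available, the model falls back to
#' ordinary least squares with a warning. The effect size per (siRNA, cell
#' line) is the estimated marginal mean; its p value tests the marginal mean
#' against zero with a normal (z) reference; Benjamini-Hochberg correction is
#' applied within each assay/dose family and hits are flagged at
#' `p_adj <= alpha`.
#'
#' @param fcs Output of [batch_log2fc()] (control rows, which are identically
#'   zero, are excluded from the fit).
#' @param control Control siRNA label; defaults to the attribute recorded by
#'   [batch_log2fc()].
#' @param separate_lines If `TRUE`, fit each cell line separately
#'   (`log2fc ~ sirna + (1 | batch)` per line) instead of the interaction
#'   model.
#' @param alpha Hit threshold on the BH-adjusted p value.
#' @return Tibble with columns `assay`, `dose`, `cell_line`, `sirna`,
#'   `effect`, `se`, `p`, `p_adj`, `hit`, `model`.
#' @export
fit_effect_model <- function(fcs, control = attr(fcs, "control"),
                             separate_lines = FALSE, alpha = 0.05) {
  if (is.null(control)) stopf("control label not supplied and not recorded on the input")
  dat <- dplyr::filter(tibble::as_tibble(fcs), .data$sirna != control)
  if (nrow(dat) == 0) stopf("no non-control fold changes to fit")
  groups <- if (separate_lines) c("assay", "dose", "cell_line") else c("assay", "dose")
  fitted <- dat |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::group_modify(~ .fit_one_assay(.x, .y, separate_lines = separate_lines)) |>
    dplyr::ungroup()
  fitted |>
    dplyr::mutate(p = z_pvalue(.data$effect, .data$se)) |>
    dplyr::group_by(.data$assay, .data$dose) |>
    dplyr::mutate(p_adj = p.adjust(.data$p, method = "BH")) |>
    dplyr::ungroup() |>
    dplyr::mutate(hit = .data$p_adj <= alpha) |>
    dplyr::select("assay", "dose", "cell_line", "sirna",
                  "effect", "se", "p", "p_adj", "hit", "model")
}

#' Knockdown efficiency by the 2^-ddCt method
#'
#' Computes the relative expression fold change of a target gene after
#' knockdown, normalised to an internal reference gene:
#' `dCt = mean(Ct_target) - mean(Ct_reference)` per condition,
#' `ddCt = dCt_knockdown - dCt_control`, `fold_change = 2^-ddCt`, and
#' `percent_knockdown = 100 * (1 - fold_change)`.
#'
#' @param ct Tibble with columns `gene`, `condition`, `replicate`, `ct`
#'   containing the target and reference gene under both conditions.
#' @param target,reference Gene labels.
#' @param control_condition,knockdown_condition Condition labels.
#' @return One-row tibble: `gene`, `ddct`, `fold_change`,
#'   `percent_knockdown`.
#' @export
ddct_fold_change <- function(ct, target, reference = "Gapdh",
                             control_condition = "control",
                             knockdown_condition = "knockdown") {
  ct <- tibble::as_tibble(ct)
  need <- tidyr::expand_grid(gene = c(target, reference),
                             condition = c(control_condition, knockdown_condition))
  have <- dplyr::distinct(ct, .data$gene, .data$condition)
  missing <- dplyr::anti_join(need, have, by = c("gene", "condition"))
  if (nrow(missing) > 0) {
    stopf("input error: missing Ct values for %s",
          paste(missing$gene, missing$condition, sep = "/", collapse = ", "))
  }
  mean_ct <- function(g, cond) mean(ct$ct[ct$gene == g & ct$condition == cond])
  dct <- function(cond) mean_ct(target, cond) - mean_ct(reference, cond)
  ddct <- dct(knockdown_condition) - dct(control_condition)
  fc <- 2^(-ddct)
  tibble::tibble(gene = target, ddct = ddct, fold_change = fc,
                 percent_knockdown = 100 * (1 - fc))
}

#' Summarise hit calls across targets and assays
#'
#' @param estimates Output of [fit_effect_model()].
#' @return A list of three tibbles: `by_target` (hit counts per target),
#'   `by_assay` (hit counts per assay/dose/cell line), and `overall`
#'   (number of targets with at least one significant hit in any assay, and
#'   the hit rate as a percentage).
#' @export
summarize_hits <- function(estimates) {
  estimates <- tibble::as_tibble(estimates)
  by_target <- estimates |>
    dplyr::group_by(target = .data$sirna) |>
    dplyr::summarise(n_tests = dplyr::n(), n_hits = sum(.data$hit),
                     any_hit = any(.data$hit), .groups = "drop")
  by_assay <- estimates |>
    dplyr::group_by(.data$assay, .data$dose, .data$cell_line) |>
    dplyr::summarise(n_tests = dplyr::n(), n_hits = sum(.data$hit), .groups = "drop")
  overall <- tibble::tibble(
    n_targets = nrow(by_target),
    n_with_hit = sum(by_target$any_hit),
    hit_rate_pct = 100 * sum(by_target$any_hit) / max(1L, nrow(by_target))
  )
  list(by_target = by_target, by_assay = by_assay, overall = overall)
}
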