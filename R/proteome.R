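# Proteome differential abundance: sample QC by protein-identification
# count, then per-protein one-way ANOVA across (siRNA) groups within each
# cell line with Tukey HSD contrasts of each knockdown against the control.
# The ANOVA is computed vectorised across proteins from group sums and sums
# of squares; Tukey p values come from the studentized range distribution
# with the Tukey-Kramer standard error, so results match aov()/TukeyHSD()
# while scaling to thousands of proteins.

#' QC-filter proteomic samples by protein identification count
#'
#' Removes samples in which fewer than `min_proteins` proteins were
#' quantified (non-missing rows). Groups left with fewer than two replicates
#' are flagged with a warning; they remain in the matrix but are untestable
#' downstream.
#'
#' @param values Numeric matrix of log2 intensities, proteins x samples
#'   (dimnames required); missing values `NA`.
#' @param meta Tibble with columns `sample`, `cell_line`, `sirna`,
#'   `replicate`; one row per column of `values`.
#' @param min_proteins Minimum number of non-missing proteins per sample.
#' @return A list: `values` and `meta` (filtered), `excluded` (tibble of
#'   removed samples), and `report` (per-sample protein counts and median
#'   log2 intensity for all input samples).
#' @export
qc_filter_samples <- function(values, meta, min_proteins = 6100) {
  meta <- tibble::as_tibble(meta)
  if (ncol(values) != nrow(meta)) stopf("metadata rows must match matrix columns")
  if (!identical(colnames(values), meta$sample)) {
    values <- values[, meta$sample, drop = FALSE]
  }
  counts <- colSums(!is.na(values))
  med <- apply(values, 2, median, na.rm = TRUE)
  report <- tibble::tibble(sample = colnames(values),
                           n_proteins = as.integer(counts),
                           median_log2_intensity = med,
                           excluded = counts < min_proteins)
  keep <- !report$excluded
  if (!any(keep)) stopf("all samples fall below the QC threshold of %d proteins", min_proteins)
  out_meta <- meta[keep, , drop = FALSE]
  small <- out_meta |>
    dplyr::count(.data$cell_line, .data$sirna) |>
    dplyr::filter(.data$n < 2)
  if (nrow(small) > 0) {
    warnf("group(s) left with < 2 replicates after QC (untestable): %s",
          paste(small$cell_line, small$sirna, sep = "/", collapse = ", "))
  }
  list(values = values[, keep, drop = FALSE],
       meta = out_meta,
       excluded = report[!keep, c("sample", "n_proteins", "median_log2_intensity")],
       report = report)
}

# Vectorised one-way ANOVA + Tukey-Kramer contrasts within one cell line.
.anova_tukey_line <- function(X, groups, control, cell_line) {
  lev <- unique(groups)
  if (!control %in% lev) stopf("control group '%s' absent in cell line '%s'", control, cell_line)
  M <- !is.na(X)
  Xz <- X; Xz[!M] <- 0
  as_mat <- function(m) if (is.null(dim(m))) matrix(m, nrow = 1) else m
  n_mat <- as_mat(vapply(lev, function(l) rowSums(M[, groups == l, drop = FALSE]), numeric(nrow(X))))
  s_mat <- as_mat(vapply(lev, function(l) rowSums(Xz[, groups == l, drop = FALSE]), numeric(nrow(X))))
  q_mat <- as_mat(vapply(lev, function(l) rowSums(Xz[, groups == l, drop = FALSE]^2), numeric(nrow(X))))
  mean_mat <- s_mat / n_mat                       # NaN where a group is empty
  n_tot <- rowSums(n_mat)
  k <- rowSums(n_mat >= 1)
  df <- n_tot - k
  ssw <- rowSums(q_mat - n_mat * ifelse(n_mat > 0, mean_mat, 0)^2, na.rm = TRUE)
  ssw <- pmax(ssw, 0)                             # guard tiny negative rounding
  mse <- ifelse(df > 0, ssw / df, NA_real_)
  grand <- rowSums(s_mat) / n_tot
  ssb <- rowSums(n_mat * (ifelse(n_mat > 0, mean_mat, 0) - grand)^2, na.rm = TRUE)
  f <- ifelse(k > 1 & mse > 0, (ssb / (k - 1)) / mse, NA_real_)
  anova_tbl <- tibble::tibble(
    protein = rownames(X), cell_line = cell_line,
    f = unname(f), df1 = unname(k - 1), df2 = unname(df),
    p = unname(ifelse(is.na(f), NA_real_, stats::pf(f, k - 1, df, lower.tail = FALSE)))
  )
  ci <- match(control, lev)
  rows <- lapply(setdiff(lev, control), function(t) {
    ti <- match(t, lev)
    n_t <- n_mat[, ti]; n_c <- n_mat[, ci]
    diff <- mean_mat[, ti] - mean_mat[, ci]
    se_q <- sqrt(mse / 2 * (1 / n_t + 1 / n_c))
    q <- abs(diff) / se_q
    testable <- n_t >= 2 & n_c >= 2 & df >= 1 & !is.na(mse)
    zero_var <- testable & mse <= 0
    p <- rep(NA_real_, nrow(X))
    ok <- testable & !zero_var
    # k = 2: the studentized range is sqrt(2)*|t|; the t form is numerically
    # exact where ptukey carries ~1e-7 quadrature error
    p[ok] <- ifelse(k[ok] == 2,
                    2 * stats::pt(q[ok] / sqrt(2), df[ok], lower.tail = FALSE),
                    ptukey(q[ok], nmeans = k[ok], df = df[ok], lower.tail = FALSE))
    tibble::tibble(
      protein = rownames(X), cell_line = cell_line, sirna = t,
      log2fc = unname(diff), q = unname(q),
      n_target = as.integer(unname(n_t)), n_control = as.integer(unname(n_c)),
      p = unname(p),
      flag = unname(dplyr::case_when(zero_var ~ "zero_variance",
                                     !testable ~ "untestable",
                                     TRUE ~ NA_character_))
    )
  })
  list(contrasts = dplyr::bind_rows(rows), anova = anova_tbl)
}

#' Per-protein differential abundance: one-way ANOVA with Tukey HSD
#'
#' Within each cell line, runs a per-protein one-way ANOVA across all siRNA
#' groups (control plus every knockdown) and computes Tukey honestly
#' significant difference p values for each knockdown-versus-control
#' contrast, using the studentized range distribution with the pooled
#' within-group variance (Tukey-Kramer for unequal group sizes). The log2
#' fold change is the group mean difference. Missing protein values are
#' handled complete-case per protein. Benjamini-Hochberg correction is
#' applied across proteins within each (cell line, siRNA) contrast. Proteins
#' with zero pooled variance are flagged `"zero_variance"` and excluded from
#' ranking (p `NA`).
#'
#' @param values Numeric matrix of log2 intensities, proteins x samples.
#' @param meta Sample metadata (`sample`, `cell_line`, `sirna`).
#' @param control Control siRNA label.
#' @return Tibble with columns `protein`, `cell_line`, `sirna`, `log2fc`,
#'   `q`, `n_target`, `n_control`, `p`, `p_adj`, `flag`; the per-protein
#'   ANOVA table (`f`, `df1`, `df2`, `p`) is attached as attribute
#'   `"anova"`.
#' @export
anova_tukey <- function(values, meta, control = "siCtrl") {
  meta <- tibble::as_tibble(meta)
  if (!identical(colnames(values), meta$sample)) values <- values[, meta$sample, drop = FALSE]
  per_line <- lapply(unique(meta$cell_line), function(cl) {
    idx <- meta$cell_line == cl
    .anova_tukey_line(values[, idx, drop = FALSE], meta$sirna[idx], control, cl)
  })
  contrasts <- dplyr::bind_rows(lapply(per_line, `[[`, "contrasts")) |>
    dplyr::group_by(.data$cell_line, .data$sirna) |>
    dplyr::mutate(p_adj = p.adjust(.data$p, method = "BH")) |>
    dplyr::ungroup() |>
    dplyr::select("protein", "cell_line", "sirna", "log2fc", "q",
                  "n_target", "n_control", "p", "p_adj", "flag")
  attr(contrasts, "anova") <- dplyr::bind_rows(lapply(per_line, `[[`, "anova"))
  contrasts
}

#' Count significantly differential proteins per contrast
#'
#' @param results Output of [anova_tukey()].
#' @param alpha Threshold on the BH-adjusted p value.
#' @return Tibble `cell_line`, `sirna`, `n_significant`, `n_tested` (zero
#'   rows for empty input).
#' @export
count_significant <- function(results, alpha = 0.05) {
  results <- tibble::as_tibble(results)
  if (nrow(results) == 0) {
    return(tibble::tibble(cell_line = character(), sirna = character(),
                          n_significant = integer(), n_tested = integer()))
  }
  results |>
    dplyr::group_by(.data$cell_line, .data$sirna) |>
    dplyr::summarise(n_significant = sum(.data$p_adj <= alpha, na.rm = TRUE),
                     n_tested = sum(!is.na(.data$p)), .groups = "drop")
}
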