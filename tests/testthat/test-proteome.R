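# Small abundance fixtures built in code.
make_matrix <- function(groups, values_by_group, proteins = NULL) {
  # values_by_group: list of matrices proteins x replicates
  values <- do.call(cbind, values_by_group)
  n_rep <- vapply(values_by_group, ncol, integer(1))
  sirna <- rep(groups, n_rep)
  samples <- paste0("s", seq_len(ncol(values)))
  colnames(values) <- samples
  if (is.null(proteins)) proteins <- paste0("p", seq_len(nrow(values)))
  rownames(values) <- proteins
  meta <- tibble::tibble(sample = samples, cell_line = "line1",
                         sirna = sirna, replicate = sequence(n_rep))
  list(values = values, meta = meta)
}

test_that("sample QC removes exactly the samples below the identification threshold", {
  n_prot <- 6500
  counts <- c(6500, 6200, 6100, 6099, 565)
  values <- withr::with_seed(8, matrix(rnorm(n_prot * 5, 20, 2), n_prot, 5))
  for (j in seq_along(counts)) {
    if (counts[j] < n_prot) values[seq(counts[j] + 1, n_prot), j] <- NA
  }
  dimnames(values) <- list(paste0("p", 1:n_prot), paste0("s", 1:5))
  meta <- tibble::tibble(sample = paste0("s", 1:5), cell_line = "l",
                         sirna = paste0("g", 1:5), replicate = 1L)
  qc <- suppressWarnings(qc_filter_samples(values, meta, min_proteins = 6100))
  expect_identical(qc$excluded$sample, c("s4", "s5"))
  expect_identical(colnames(qc$values), c("s1", "s2", "s3"))
  expect_identical(qc$report$n_proteins, as.integer(counts))
  # threshold 0 removes nothing
  qc0 <- suppressWarnings(qc_filter_samples(values, meta, min_proteins = 0))
  expect_identical(ncol(qc0$values), 5L)
  # everything below threshold is an error
  expect_error(qc_filter_samples(values, meta, min_proteins = n_prot + 1), "QC threshold")
})

test_that("ANOVA F and Tukey p match aov()/TukeyHSD() on a three-group fixture", {
  vals <- withr::with_seed(21, {
    list(ctl = matrix(rnorm(15, 10, 1), 5, 3),
         t1 = matrix(rnorm(15, 11, 1), 5, 3),
         t2 = matrix(rnorm(15, 10, 1), 5, 3))
  })
  fx <- make_matrix(c("ctl", "t1", "t2"), vals)
  res <- anova_tukey(fx$values, fx$meta, control = "ctl")
  av <- attr(res, "anova")
  for (i in 1:5) {
    y <- fx$values[i, ]
    g <- factor(fx$meta$sirna)
    fit <- stats::aov(y ~ g)
    expect_equal(av$f[i], summary(fit)[[1]]$`F value`[1], tolerance = 1e-10)
    tk <- stats::TukeyHSD(fit)$g
    for (t in c("t1", "t2")) {
      row <- res[res$protein == paste0("p", i) & res$sirna == t, ]
      ref <- tk[paste0(t, "-ctl"), ]
      expect_equal(row$log2fc, unname(ref["diff"]), tolerance = 1e-10)
      expect_equal(row$p, unname(ref["p adj"]), tolerance = 1e-8)
    }
  }
})

test_that("with two groups the Tukey contrast equals the pooled t test", {
  for (seed in 1:20) {
    fx <- withr::with_seed(seed, {
      make_matrix(c("ctl", "t1"),
                  list(ctl = matrix(rnorm(12, 10, 1), 3, 4),
                       t1 = matrix(rnorm(9, 10.5, 1), 3, 3)))
    })
    res <- anova_tukey(fx$values, fx$meta, control = "ctl")
    for (i in 1:3) {
      y1 <- fx$values[i, fx$meta$sirna == "t1"]
      y0 <- fx$values[i, fx$meta$sirna == "ctl"]
      tt <- stats::t.test(y1, y0, var.equal = TRUE)
      expect_equal(res$p[res$protein == paste0("p", i)], tt$p.value,
                   tolerance = 1e-8)
    }
  }
})

test_that("differential abundance is invariant to sample order and antisymmetric in group roles", {
  fx <- withr::with_seed(33, {
    make_matrix(c("ctl", "t1", "t2"),
                list(matrix(rnorm(40, 10, 1), 10, 4),
                     matrix(rnorm(40, 10.8, 1), 10, 4),
                     matrix(rnorm(40, 10, 1), 10, 4)))
  })
  res <- anova_tukey(fx$values, fx$meta, control = "ctl")
  perm <- withr::with_seed(5, sample(ncol(fx$values)))
  res_p <- anova_tukey(fx$values[, perm], fx$meta[perm, ], control = "ctl")
  res_p <- dplyr::arrange(res_p, .data$protein, .data$sirna)
  res_s <- dplyr::arrange(res, .data$protein, .data$sirna)
  expect_equal(res_s$p, res_p$p, tolerance = 1e-12)
  expect_equal(res_s$log2fc, res_p$log2fc, tolerance = 1e-12)

  # two-group antisymmetry: swapping which group is "control" negates log2fc
  fx2 <- make_matrix(c("a", "b"),
                     list(fx$values[, 1:4], fx$values[, 5:8]))
  r_ab <- anova_tukey(fx2$values, fx2$meta, control = "a")
  r_ba <- anova_tukey(fx2$values, fx2$meta, control = "b")
  expect_equal(r_ab$log2fc, -r_ba$log2fc, tolerance = 1e-12)
  expect_equal(r_ab$p, r_ba$p, tolerance = 1e-12)
})

test_that("missing values are handled complete-case per protein", {
  fx <- withr::with_seed(44, {
    make_matrix(c("ctl", "t1"),
                list(matrix(rnorm(20, 10, 1), 5, 4),
                     matrix(rnorm(20, 11, 1), 5, 4)))
  })
  fx$values[2, c(1, 6)] <- NA
  res <- anova_tukey(fx$values, fx$meta, control = "ctl")
  y <- fx$values[2, ]
  keep <- !is.na(y)
  tt <- stats::t.test(y[keep & fx$meta$sirna == "t1"],
                      y[keep & fx$meta$sirna == "ctl"], var.equal = TRUE)
  expect_equal(res$p[res$protein == "p2"], tt$p.value, tolerance = 1e-8)
  expect_identical(res$n_target[res$protein == "p2"], 3L)
})

test_that("degenerate proteins are flagged and identical means give a null contrast", {
  fx <- make_matrix(c("ctl", "t1"),
                    list(matrix(c(5, 1, 2, 5, 1.5, 2, 5, 0.5, 2), 3, 3),
                         matrix(c(5, 3, 2, 5, 3.5, 2, 5, 2.5, 2), 3, 3)))
  res <- anova_tukey(fx$values, fx$meta, control = "ctl")
  # p1: identical group means with zero variance -> zero_variance flag, p NA
  expect_identical(res$flag[res$protein == "p1"], "zero_variance")
  expect_true(is.na(res$p[res$protein == "p1"]))
  # p3: all values equal -> also zero variance
  expect_identical(res$flag[res$protein == "p3"], "zero_variance")
  # p2 is testable
  expect_false(is.na(res$p[res$protein == "p2"]))
})

test_that("significant counts respect the alpha threshold and empty input", {
  res <- tibble::tibble(protein = paste0("p", 1:4), cell_line = "l",
                        sirna = "t", log2fc = 1, q = 1,
                        n_target = 3L, n_control = 3L,
                        p = c(0.001, 0.2, 0.01, NA),
                        p_adj = c(0.004, 0.4, 0.04, NA), flag = NA_character_)
  cnt <- count_significant(res)
  expect_identical(cnt$n_significant, 2L)
  expect_identical(cnt$n_tested, 3L)
  empty <- count_significant(res[0, ])
  expect_identical(nrow(empty), 0L)
})
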