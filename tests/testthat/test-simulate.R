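small_cfg <- function(seed = 3, ...) {
  sim_config(seed = seed, n_targets = 4, assays = "viability",
             n_domains = 2, terms_per_domain = 3, genes_per_term = 20,
             n_perm = 200, ...)
}

test_that("identical configurations generate identical data", {
  cfg <- small_cfg()
  expect_identical(gen_assay_data(cfg), gen_assay_data(cfg))
  ann <- gen_biodomain_annotation(cfg)
  ref1 <- gen_reference_signature(cfg, ann)
  ref2 <- gen_reference_signature(cfg, ann)
  expect_identical(ref1, ref2)
  expect_identical(gen_knockdown_proteomes(cfg, ref1)$values,
                   gen_knockdown_proteomes(cfg, ref2)$values)
  # a different seed changes the data but not the schema
  cfg2 <- small_cfg(seed = 4)
  a1 <- gen_assay_data(cfg); a2 <- gen_assay_data(cfg2)
  expect_false(isTRUE(all.equal(a1$value, a2$value)))
  expect_identical(names(a1), names(a2))
})

test_that("assay tables have the full design and exact effects in the noise-free limit", {
  cfg <- sim_config(seed = 1, n_targets = 29, assays = "viability",
                    n_batches = 3, n_replicates = 3,
                    terms_per_domain = 10, genes_per_term = 10)
  tbl <- gen_assay_data(cfg)
  # 3 batches x 3 replicates x 2 lines x (29 targets + control)
  expect_identical(nrow(tbl), 3L * 3L * 2L * 30L)
  expect_true(all(table(tbl$batch) == 3 * 2 * 30))

  cfg0 <- sim_config(seed = 1, n_targets = 3, assays = "viability",
                     batch_sd = 0, residual_sd = 0,
                     terms_per_domain = 5, genes_per_term = 10)
  fc <- batch_log2fc(gen_assay_data(cfg0), control = cfg0$control_sirna)
  truth <- dplyr::rename(cfg0$assay_effects, sirna = "target")
  merged <- dplyr::inner_join(fc, truth, by = c("assay", "cell_line", "sirna"))
  expect_equal(merged$log2fc, merged$effect, tolerance = 1e-10)
})

test_that("the annotation geometry follows the configuration and rejects infeasible sizes", {
  cfg <- small_cfg()
  ann <- gen_biodomain_annotation(cfg)
  expect_length(ann$collection, 6)
  expect_true(all(lengths(ann$collection) == 20))
  # terms are disjoint at overlap 0 and cover the universe
  all_genes <- unlist(ann$collection)
  expect_identical(anyDuplicated(all_genes), 0L)
  expect_setequal(all_genes, cfg$genes)
  expect_identical(nrow(ann$term_to_domain), 6L)

  cfg_ov <- small_cfg(overlap = 0.5)
  ann_ov <- gen_biodomain_annotation(cfg_ov)
  two_labels <- table(ann_ov$term_to_domain$term)
  expect_identical(sum(two_labels == 2), 3L)   # half of the 6 terms

  expect_error(sim_config(n_genes = 10, n_domains = 1, terms_per_domain = 1,
                          genes_per_term = 50), "configuration error")
  expect_error(small_cfg(batch_sd = -1), "configuration error")
})

test_that("the reference signature enriches signal domains with the configured signs", {
  cfg <- sim_config(seed = 9, n_targets = 2, terms_per_domain = 8,
                    genes_per_term = 20, proteome_noise_sd = 0.1,
                    domain_effect = c(immune_response = 1,
                                      mitochondrial_metabolism = -1),
                    n_perm = 300)
  ann <- gen_biodomain_annotation(cfg)
  ref <- gen_reference_signature(cfg, ann)
  sig <- ref$terms[ref$terms$p_adj <= 0.05, ]
  expect_gt(nrow(sig), 0)
  imm <- grepl("^immune_response", sig$term)
  expect_true(all(sig$nes[imm] > 0))
  expect_true(all(sig$nes[!imm] < 0))
})

test_that("knockdown proteomes couple to the reference through c and the self-effect", {
  # c = 0 with a self-effect: only the targeted protein is truly shifted
  cfg <- small_cfg(concordance_coeff = tidyr::expand_grid(
    target = sim_config(seed = 3, n_targets = 4, assays = "viability",
                        n_domains = 2, terms_per_domain = 3,
                        genes_per_term = 20)$targets,
    cell_line = c("scramble", "sensitized"), c = 0
  ), proteome_noise_sd = 0)
  ann <- gen_biodomain_annotation(cfg)
  ref <- suppressWarnings(gen_reference_signature(cfg, ann))  # noise-free: tied stats
  prot <- gen_knockdown_proteomes(cfg, ref)
  tgt <- cfg$targets[1]
  ctl_cols <- prot$meta$sample[prot$meta$sirna == cfg$control_sirna &
                                 prot$meta$cell_line == "scramble"]
  kd_cols <- prot$meta$sample[prot$meta$sirna == tgt &
                                prot$meta$cell_line == "scramble"]
  delta <- rowMeans(prot$values[, kd_cols]) - rowMeans(prot$values[, ctl_cols])
  expect_equal(unname(delta[tgt]), cfg$knockdown_self_effect, tolerance = 1e-10)
  expect_true(all(abs(delta[setdiff(cfg$genes, tgt)]) < 1e-10))

  # negative c on an up-shifted domain pushes in-domain proteins down
  cfg2 <- small_cfg(proteome_noise_sd = 0,
                    domain_effect = c(immune_response = 1,
                                      mitochondrial_metabolism = 0))
  ann2 <- gen_biodomain_annotation(cfg2)
  ref2 <- suppressWarnings(gen_reference_signature(cfg2, ann2))
  prot2 <- gen_knockdown_proteomes(cfg2, ref2)
  rev_t <- cfg2$targets[1]   # default c = -0.6
  kd2 <- prot2$meta$sample[prot2$meta$sirna == rev_t &
                             prot2$meta$cell_line == "scramble"]
  ctl2 <- prot2$meta$sample[prot2$meta$sirna == cfg2$control_sirna &
                              prot2$meta$cell_line == "scramble"]
  delta2 <- rowMeans(prot2$values[, kd2]) - rowMeans(prot2$values[, ctl2])
  immune_genes <- setdiff(unlist(ann2$collection[grepl("^immune", names(ann2$collection))]),
                          rev_t)
  expect_lt(mean(delta2[immune_genes]), -0.3)
})

test_that("Ct tables encode the configured knockdown fold change", {
  cfg <- small_cfg(ct_fold_change = 0.25, ct_sd = 0)
  ct <- gen_ct_table(cfg, genes = cfg$targets[1])
  one <- ct[ct$experiment == cfg$targets[1], ]
  res <- ddct_fold_change(one, cfg$targets[1], "Gapdh")
  expect_equal(res$ddct, 2)             # fold 0.25 -> dCt shift of +2
  expect_equal(res$fold_change, 0.25)
  expect_equal(res$percent_knockdown, 75)
})

test_that("ground truth matches the generating configuration", {
  cfg <- small_cfg()
  gt <- ground_truth(cfg)
  # defaults: all 4 targets carry c = -0.6 in the first 5 slots
  expect_true(all(gt$true_reversals$expected_call == "anti_correlated"))
  expect_setequal(unique(gt$true_reversals$domain),
                  c("immune_response", "mitochondrial_metabolism"))
  null_cfg <- as_null_config(cfg)
  gt0 <- ground_truth(null_cfg)
  expect_identical(nrow(gt0$true_hits), 0L)
  expect_identical(nrow(gt0$true_reversals), 0L)
})
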