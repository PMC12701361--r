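ann_fixture <- tibble::tibble(
  term = paste0("t", 1:8),
  domain = rep(c("immune", "mito"), each = 4)
)

enr_fixture <- function(nes, p_adj, terms = paste0("t", seq_along(nes))) {
  tibble::tibble(term = terms, nes = nes, p_adj = p_adj)
}

test_that("zero-filling keeps significant values verbatim and fills the rest with zero", {
  query <- enr_fixture(c(2, -1, 0.5, 1.2), c(0.01, 0.2, 0.01, 0.04))
  ref <- enr_fixture(c(1.5, -2, 1, -0.5), c(0.03, 0.01, 0.2, 0.3))
  aligned <- zero_fill_align(query, ref, ann_fixture, "immune")
  aligned <- aligned[order(aligned$term), ]
  # t1 significant in both: both kept verbatim
  expect_equal(aligned[aligned$term == "t1", ]$nes_query, 2)
  expect_equal(aligned[aligned$term == "t1", ]$nes_reference, 1.5)
  # t2 significant only in the reference: query side zero-filled
  expect_equal(aligned[aligned$term == "t2", ]$nes_query, 0)
  expect_equal(aligned[aligned$term == "t2", ]$nes_reference, -2)
  # t3 significant only in the query: reference side zero-filled (symmetric rule)
  expect_equal(aligned[aligned$term == "t3", ]$nes_reference, 0)
  # t4 significant in query only; universe is the union restricted to the domain
  expect_setequal(aligned$term, c("t1", "t2", "t3", "t4"))
  # a domain with no significant terms anywhere is skipped
  none <- zero_fill_align(enr_fixture(c(1, 1, 1, 1), rep(0.9, 4),
                                      terms = paste0("t", 5:8)),
                          enr_fixture(c(1, 1, 1, 1), rep(0.9, 4),
                                      terms = paste0("t", 5:8)),
                          ann_fixture, "mito")
  expect_identical(nrow(none), 0L)
})

test_that("Kendall concordance is 1 for identity, -1 for pure reversal, and tie-corrected", {
  x <- c(2.2, 1.1, -0.7, 1.9, -2.5)
  aligned <- tibble::tibble(term = paste0("t", 1:5), nes_query = x, nes_reference = x)
  expect_equal(kendall_concordance(aligned, min_terms = 5)$stat, 1)
  aligned$nes_query <- -x
  expect_equal(kendall_concordance(aligned, min_terms = 5)$stat, -1)

  # zero-filled vectors with heavy ties match the exhaustive pair-count oracle
  for (seed in 1:15) {
    ab <- withr::with_seed(seed, {
      n <- sample(8:15, 1)
      a <- round(rnorm(n), 1); b <- round(rnorm(n), 1)
      a[sample(n, 3)] <- 0; b[sample(n, 3)] <- 0
      list(a = a, b = b)
    })
    if (sd(ab$a) == 0 || sd(ab$b) == 0) next
    aligned <- tibble::tibble(term = paste0("t", seq_along(ab$a)),
                              nes_query = ab$a, nes_reference = ab$b)
    expect_equal(kendall_concordance(aligned, min_terms = 5)$stat,
                 taub_bruteforce(ab$a, ab$b), tolerance = 1e-12)
  }

  # degenerate: constant side gives an ns-style flagged row
  aligned$nes_query <- 0
  r <- kendall_concordance(aligned, min_terms = 5)
  expect_true(is.na(r$stat))
  expect_identical(r$p, 1)
  expect_identical(r$flag, "zero_variance")
  # too few terms is flagged, not an error
  expect_identical(kendall_concordance(aligned[1:3, ], min_terms = 5)$flag,
                   "too_few_terms")
})

test_that("when every universe term is significant in both analyses the zero-fill reduces to plain tau-b", {
  withr::with_seed(7, {
    nes_q <- rnorm(8); nes_r <- rnorm(8)
  })
  query <- enr_fixture(nes_q, rep(0.01, 8), terms = ann_fixture$term)
  ref <- enr_fixture(nes_r, rep(0.01, 8), terms = ann_fixture$term)
  aligned <- zero_fill_align(query, ref, ann_fixture, "immune")
  res <- kendall_concordance(aligned, min_terms = 4)
  idx <- match(aligned$term, query$term)
  expect_identical(res$stat,
                   unname(cor(nes_q[idx], nes_r[idx], method = "kendall")))
  expect_equal(res$stat, taub_bruteforce(nes_q[idx], nes_r[idx]), tolerance = 1e-12)
})

test_that("the concordance table applies BH across the whole family and assigns calls", {
  queries <- dplyr::bind_rows(lapply(1:3, function(i) {
    withr::with_seed(i, dplyr::mutate(
      enr_fixture(rnorm(8), runif(8, 0, 0.05), terms = ann_fixture$term),
      target = paste0("tgt", i), cell_line = "l1"))
  }))
  ref <- enr_fixture(withr::with_seed(99, rnorm(8)), rep(0.01, 8),
                     terms = ann_fixture$term)
  tbl <- concordance_table(queries, ref, ann_fixture, min_terms = 4)
  expect_identical(nrow(tbl), 6L)   # 3 targets x 2 domains
  expect_equal(tbl$p_adj, bh_bruteforce(tbl$p), tolerance = 1e-12)
  expect_true(all(tbl$call[tbl$p_adj <= 0.05 & tbl$stat < 0] == "anti_correlated"))
  expect_true(all(tbl$call[tbl$p_adj > 0.05] == "ns"))
})

test_that("protein-level concordance recovers scale-invariant correlation and skips degenerate domains", {
  genes <- paste0("g", 1:40)
  collection <- list(ti = genes[1:20], tm = genes[21:40])
  ann <- tibble::tibble(term = c("ti", "tm"), domain = c("immune", "mito"))
  ref_eff <- withr::with_seed(12, rnorm(40))
  ref <- tibble::tibble(gene = genes, effect = ref_eff)
  de <- tibble::tibble(protein = genes, cell_line = "l1", sirna = "tgt1",
                       log2fc = 2 * ref_eff)   # query = reference scaled by +2
  res <- pearson_protein_concordance(de, ref, ann, collection, min_proteins = 10)
  expect_equal(res$stat, c(1, 1), tolerance = 1e-12)
  expect_true(all(res$call == "correlated"))

  # zero-variance reference effects in a domain: flagged ns
  ref0 <- ref; ref0$effect[21:40] <- 0
  de0 <- de; de0$log2fc <- withr::with_seed(3, rnorm(40))
  res0 <- pearson_protein_concordance(de0, ref0, ann, collection, min_proteins = 10)
  mito_row <- res0[res0$domain == "mito", ]
  expect_identical(mito_row$flag, "zero_variance")
  expect_identical(mito_row$call, "ns")

  # below the overlap threshold the domain is skipped with a notice
  expect_message(
    pearson_protein_concordance(de[1:5, ], ref, ann, collection, min_proteins = 10),
    "skipped")
})

test_that("quadrant counts partition the union of significant terms", {
  ref <- enr_fixture(c(1, 2, -1, -2), c(0.01, 0.01, 0.01, 0.01),
                     terms = paste0("t", 1:4))
  # identical significant sets with identical signs: diagonal classes only
  q_same <- ref
  tq <- term_quadrants(q_same, ref, ann_fixture, "immune")
  expect_equal(tq$ref_up_query_up, 2)
  expect_equal(tq$ref_down_query_down, 2)
  expect_equal(tq$ref_only + tq$query_only, 0)
  expect_equal(tq$ref_up_query_up + tq$ref_up_query_down +
                 tq$ref_down_query_up + tq$ref_down_query_down +
                 tq$ref_only + tq$query_only, tq$n_union)
  # disjoint significant sets: everything in the one-sided tallies
  q_disj <- enr_fixture(c(1, 1, 1, 1), c(0.9, 0.9, 0.01, 0.01),
                        terms = paste0("t", 1:4))
  ref_disj <- enr_fixture(c(1, 1, 1, 1), c(0.01, 0.01, 0.9, 0.9),
                          terms = paste0("t", 1:4))
  tq2 <- term_quadrants(q_disj, ref_disj, ann_fixture, "immune")
  expect_equal(tq2$ref_only, 2)
  expect_equal(tq2$query_only, 2)
  expect_equal(tq2$ref_up_query_up + tq2$ref_up_query_down +
                 tq2$ref_down_query_up + tq2$ref_down_query_down, 0)
  # a reversal flips mass to the off-diagonal
  q_rev <- enr_fixture(-ref$nes, ref$p_adj, terms = paste0("t", 1:4))
  tq3 <- term_quadrants(q_rev, ref, ann_fixture, "immune")
  expect_equal(tq3$ref_up_query_down, 2)
  expect_equal(tq3$ref_down_query_up, 2)
})

test_that("cell-line comparison recovers a constructed baseline domain shift", {
  cfg <- sim_config(seed = 17, n_targets = 2, assays = "viability",
                    n_domains = 3, terms_per_domain = 12, genes_per_term = 20,
                    n_proteome_replicates = 5, proteome_noise_sd = 0.25,
                    domain_effect = c(immune_response = 1,
                                      mitochondrial_metabolism = 0,
                                      domain_03 = 0),
                    sensitized_line_shift = c(immune_response = 0.8),
                    n_perm = 1000)
  ann <- gen_biodomain_annotation(cfg)
  ref <- gen_reference_signature(cfg, ann)
  prot <- gen_knockdown_proteomes(cfg, ref, ann)
  cmp <- compare_cell_lines(prot$values, prot$meta, cfg$control_sirna,
                            ann$collection, ann, ref,
                            subtype_lists = list(
                              immune_like = unlist(ann$collection[1:12], use.names = FALSE)),
                            n_perm = 1000, seed = 5)
  # immune terms are enriched upward in the sensitized line
  imm <- cmp$enrichment[grepl("^immune", cmp$enrichment$term), ]
  expect_true(all(imm$nes > 0))
  expect_true(all(imm$p_adj <= 0.05))
  # the custom list built from the shifted genes is extreme
  expect_gt(cmp$subtype_enrichment$nes, 0)
  expect_lte(cmp$subtype_enrichment$p, 0.02)
  # and the shift is concordant with an immune-up disease signature
  imm_conc <- cmp$concordance[cmp$concordance$domain == "immune_response", ]
  expect_identical(imm_conc$call, "correlated")
})
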