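# End-to-end synthetic drivers shared by the recovery tests.

# Reversal-screen study conditions: 6 targets (3 generated as signature
# reversers with c = -0.6 and a strong phenotype effect, 3 null), two
# biodomains of 50 terms x 20 genes with a disease-like two-sided reference
# signature (immune up, mitochondrial down), 5 proteome replicates,
# 3 batches x 3 replicates per assay.
reversal_cfg <- function(seed, n_perm = 500) {
  base <- sim_config(seed = seed, n_targets = 6, assays = "viability",
                     n_domains = 2, terms_per_domain = 50, genes_per_term = 20,
                     n_proteome_replicates = 5, proteome_noise_sd = 0.3,
                     sensitized_scale = 1, n_perm = n_perm)
  cc <- base$concordance_coeff
  cc$c <- ifelse(cc$target %in% base$targets[1:3], -0.6, 0)
  ae <- base$assay_effects
  ae$effect <- ifelse(ae$target %in% base$targets[1:3], -0.8, 0)
  sim_config(seed = seed, n_targets = 6, assays = "viability",
             n_domains = 2, terms_per_domain = 50, genes_per_term = 20,
             n_proteome_replicates = 5, proteome_noise_sd = 0.3,
             sensitized_scale = 1, concordance_coeff = cc, assay_effects = ae,
             n_perm = n_perm)
}

# Run the full analysis chain on a configuration; returns every stage table.
full_chain <- function(cfg, n_perm = cfg$n_perm) {
  ann <- gen_biodomain_annotation(cfg)
  ref <- gen_reference_signature(cfg, ann)
  prot <- gen_knockdown_proteomes(cfg, ref, ann)
  de <- anova_tukey(prot$values, prot$meta, control = cfg$control_sirna)
  enr <- knockdown_enrichments(de, ann$collection, n_perm = n_perm,
                               seed = cfg$seed)
  conc_terms <- concordance_table(enr, ref, ann)
  conc_prot <- pearson_protein_concordance(de, ref, ann, ann$collection)
  est <- suppressWarnings(
    fit_effect_model(batch_log2fc(gen_assay_data(cfg), cfg$control_sirna))
  )
  integ <- correlate_assay_terms(est, enr)
  cards <- build_scorecards(est, dplyr::bind_rows(conc_terms, conc_prot),
                            integ, enr)
  list(cfg = cfg, ann = ann, ref = ref, de = de, enr = enr,
       conc_terms = conc_terms, conc_prot = conc_prot,
       est = est, integ = integ, cards = cards)
}
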