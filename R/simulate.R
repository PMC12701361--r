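# Synthetic-data generator. Emulates the statistical structure of an
# integrated knockdown screen -- batch-structured assay readouts, knockdown
# proteomes coupled to a reference disease signature, a biodomain-structured
# gene-set annotation, and qPCR Ct tables -- with known ground truth, so every
# downstream stage is testable without laboratory data.

#' Configuration for the synthetic screen generator
#'
#' Bundles every generating parameter. Defaults mirror a typical screen
#' design: 29 targets, two cell lines (a control "scramble" background and a
#' "sensitized" disease-relevant background whose effects are amplified),
#' three batches of three biological replicates per assay, five proteome
#' replicates per group, and a two-domain reference signature with the immune
#' domain shifted up and the mitochondrial domain shifted down in disease.
#'
#' @param seed Integer; fully determines all generated data.
#' @param n_targets Number of knockdown targets. Target labels are gene
#'   labels drawn evenly from the annotated universe.
#' @param cell_lines Character vector of cell-line labels; the second line is
#'   treated as the sensitized background.
#' @param assays Assay panel. An assay named `"nfkb"` is generated under two
#'   doses (`"vehicle"` and `"LPS"`); all others are dose-free.
#' @param n_batches,n_replicates Batches per assay and biological replicates
#'   per batch.
#' @param batch_sd,residual_sd Standard deviations (log2 units) of the batch
#'   random effect (shared by all siRNAs within a batch, i.e. a plate-batch
#'   intercept) and of the residual well noise.
#' @param n_domains,terms_per_domain,genes_per_term Biodomain annotation
#'   geometry. Terms are disjoint gene blocks by default.
#' @param n_genes Universe size; defaults to exactly
#'   `n_domains * terms_per_domain * genes_per_term` so the annotation covers
#'   the universe.
#' @param overlap Fraction of terms additionally annotated to a second
#'   domain.
#' @param domain_effect Named numeric vector (one entry per domain): mean
#'   reference disease effect of proteins in the domain, log2 units.
#'   Default: `+1` for the first (immune-like) domain, `-1` for the second
#'   (mitochondrial-like) domain, `0` beyond.
#' @param concordance_coeff Tibble `(target, cell_line, c)`: the signed
#'   multiplier coupling a knockdown's proteome to the reference signature
#'   (negative values generate signature reversal). Default: the first
#'   `min(5, n_targets)` targets get `c = -0.6`, the rest 0, in both lines.
#' @param assay_effects Tibble `(target, cell_line, assay, effect)`: true
#'   log2 fold change of each knockdown in each assay. Default couples the
#'   phenotype to the proteome as `effect = 0.8 * c`, scaled by
#'   `sensitized_scale` in the sensitized line.
#' @param knockdown_self_effect Log2 shift added to the targeted protein
#'   itself in its own knockdown (negative: the knockdown suppresses its own
#'   gene product).
#' @param proteome_noise_sd Residual SD (log2) of protein intensities and of
#'   the reference per-protein effects.
#' @param n_proteome_replicates Replicate samples per (siRNA, cell line)
#'   proteome group.
#' @param sensitized_scale Multiplier applied to default assay effects in the
#'   sensitized line (set to 1 for calibration studies).
#' @param sensitized_line_shift Optional named numeric vector (by domain):
#'   coefficient scaling the reference per-protein effects of that domain's
#'   proteins in every sensitized-line sample, so the sensitized background
#'   carries a constitutive disease-like shift of the domain (e.g. `0.8`
#'   moves the domain 0.8 of the way toward the disease signature).
#' @param control_sirna Label of the control siRNA (the log2FC denominator);
#'   the generator names it explicitly.
#' @param baseline Baseline raw assay readout (arbitrary fluorescence
#'   units).
#' @param n_perm,ct_fold_change,ct_sd Permutations used when deriving the
#'   reference term signature; configured knockdown fold change and Ct noise
#'   for the qPCR table.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_targets = 29,
                       cell_lines = c("scramble", "sensitized"),
                       assays = c("viability", "mito_potential", "phagocytosis", "nfkb"),
                       n_batches = 3, n_replicates = 3,
                       batch_sd = 0.1, residual_sd = 0.3,
                       n_domains = 2, terms_per_domain = 50, genes_per_term = 20,
                       n_genes = NULL, overlap = 0,
                       domain_effect = NULL,
                       concordance_coeff = NULL,
                       assay_effects = NULL,
                       knockdown_self_effect = -1,
                       proteome_noise_sd = 0.3,
                       n_proteome_replicates = 5,
                       sensitized_scale = 1.5,
                       sensitized_line_shift = NULL,
                       control_sirna = "siCtrl",
                       baseline = 1000,
                       n_perm = 1000,
                       ct_fold_change = 0.25,
                       ct_sd = 0.1) {
  if (any(c(batch_sd, residual_sd, proteome_noise_sd, ct_sd) < 0)) {
    stopf("configuration error: standard deviations must be nonnegative")
  }
  needed <- n_domains * terms_per_domain * genes_per_term
  n_genes <- n_genes %||% needed
  if (n_genes < needed) {
    stopf("configuration error: n_genes (%d) < n_domains * terms_per_domain * genes_per_term (%d)",
          n_genes, needed)
  }
  if (n_targets > n_genes) stopf("configuration error: more targets than genes")
  if (overlap < 0 || overlap > 1) stopf("configuration error: overlap must be in [0, 1]")

  base_domains <- c("immune_response", "mitochondrial_metabolism")
  domains <- if (n_domains <= 2) base_domains[seq_len(n_domains)] else {
    c(base_domains, sprintf("domain_%02d", seq(3, n_domains)))
  }
  if (is.null(domain_effect)) {
    domain_effect <- setNames(rep(0, n_domains), domains)
    if (n_domains >= 1) domain_effect[1] <- 1
    if (n_domains >= 2) domain_effect[2] <- -1
  }
  if (!setequal(names(domain_effect), domains)) {
    stopf("configuration error: domain_effect must name every domain")
  }
  domain_effect <- domain_effect[domains]

  genes <- sprintf("g%05d", seq_len(n_genes))
  # targets spread evenly across the annotated universe (unique by construction)
  tgt_idx <- unique(round(seq(1, needed, length.out = n_targets)))
  stopifnot(length(tgt_idx) == n_targets)
  targets <- genes[tgt_idx]

  if (is.null(concordance_coeff)) {
    c0 <- rep(0, n_targets)
    c0[seq_len(min(5L, n_targets))] <- -0.6
    concordance_coeff <- tidyr::expand_grid(target = targets, cell_line = cell_lines) |>
      dplyr::left_join(tibble::tibble(target = targets, c = c0), by = "target")
  }
  concordance_coeff <- tibble::as_tibble(concordance_coeff)
  if (!all(c("target", "cell_line", "c") %in% names(concordance_coeff)) ||
      !all(targets %in% concordance_coeff$target)) {
    stopf("configuration error: concordance_coeff must cover every target with columns target, cell_line, c")
  }

  if (is.null(assay_effects)) {
    assay_effects <- tidyr::expand_grid(target = targets, cell_line = cell_lines,
                                        assay = assays) |>
      dplyr::left_join(concordance_coeff, by = c("target", "cell_line")) |>
      dplyr::mutate(effect = 0.8 * .data$c *
                      ifelse(.data$cell_line == cell_lines[length(cell_lines)] &
                               length(cell_lines) > 1, sensitized_scale, 1)) |>
      dplyr::select("target", "cell_line", "assay", "effect")
  }
  assay_effects <- tibble::as_tibble(assay_effects)
  if (!all(c("target", "cell_line", "assay", "effect") %in% names(assay_effects)) ||
      !all(targets %in% assay_effects$target)) {
    stopf("configuration error: assay_effects must cover every target with columns target, cell_line, assay, effect")
  }

  structure(list(
    seed = as.integer(seed), n_targets = n_targets, cell_lines = cell_lines,
    assays = assays, n_batches = n_batches, n_replicates = n_replicates,
    batch_sd = batch_sd, residual_sd = residual_sd,
    n_domains = n_domains, terms_per_domain = terms_per_domain,
    genes_per_term = genes_per_term, n_genes = n_genes, overlap = overlap,
    domains = domains, domain_effect = domain_effect,
    genes = genes, targets = targets,
    concordance_coeff = concordance_coeff, assay_effects = assay_effects,
    knockdown_self_effect = knockdown_self_effect,
    proteome_noise_sd = proteome_noise_sd,
    n_proteome_replicates = n_proteome_replicates,
    sensitized_scale = sensitized_scale,
    sensitized_line_shift = sensitized_line_shift,
    control_sirna = control_sirna, baseline = baseline, n_perm = n_perm,
    ct_fold_change = ct_fold_change, ct_sd = ct_sd
  ), class = "sim_config")
}

#' Zero every generating effect of a configuration
#'
#' Returns a copy of the configuration with all assay effects, domain
#' effects, concordance coefficients, the knockdown self-effect and any
#' sensitized-line shift set to zero -- a complete null screen for
#' calibration studies.
#'
#' @param cfg A [sim_config()].
#' @export
as_null_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  cfg$assay_effects$effect <- 0
  cfg$domain_effect[] <- 0
  cfg$concordance_coeff$c <- 0
  cfg$knockdown_self_effect <- 0
  cfg$sensitized_line_shift <- NULL
  cfg
}

#' Generate the biodomain annotation and gene-set collection
#'
#' Builds `n_domains * terms_per_domain` gene sets as disjoint consecutive
#' blocks of `genes_per_term` genes, assigns each term to one domain, and
#' optionally annotates a fraction of terms to a second domain. Deterministic
#' (direct construction, no randomness).
#'
#' @param cfg A [sim_config()].
#' @return A list with `collection` (named list of gene vectors) and
#'   `term_to_domain` (tibble `term`, `domain`; terms with two domains appear
#'   twice).
#' @export
gen_biodomain_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  gpt <- cfg$genes_per_term
  terms <- character(0); doms <- character(0); collection <- list()
  k <- 0L
  for (d in seq_len(cfg$n_domains)) {
    for (i in seq_len(cfg$terms_per_domain)) {
      k <- k + 1L
      term <- sprintf("%s.t%03d", cfg$domains[d], i)
      collection[[term]] <- cfg$genes[seq((k - 1L) * gpt + 1L, k * gpt)]
      terms <- c(terms, term); doms <- c(doms, cfg$domains[d])
    }
  }
  ann <- tibble::tibble(term = terms, domain = doms)
  n_multi <- round(cfg$overlap * length(terms))
  if (n_multi > 0 && cfg$n_domains > 1) {
    extra_idx <- seq_len(n_multi)
    second <- cfg$domains[(match(doms[extra_idx], cfg$domains) %% cfg$n_domains) + 1L]
    ann <- dplyr::bind_rows(ann, tibble::tibble(term = terms[extra_idx], domain = second)) |>
      dplyr::arrange(.data$term, .data$domain)
  }
  list(collection = collection, term_to_domain = ann)
}

# Primary domain of every gene (first term block it belongs to); genes
# outside the annotation get NA.
.gene_domains <- function(cfg, annotation) {
  first_dom <- annotation$term_to_domain[!duplicated(annotation$term_to_domain$term), ]
  gene_dom <- rep(NA_character_, cfg$n_genes)
  for (term in names(annotation$collection)) {
    idx <- match(annotation$collection[[term]], cfg$genes)
    dom <- first_dom$domain[match(term, first_dom$term)]
    gene_dom[idx[is.na(gene_dom[idx])]] <- dom
  }
  setNames(gene_dom, cfg$genes)
}

#' Generate the reference disease signature
#'
#' Draws a per-protein reference effect as the gene's domain mean effect plus
#' Gaussian noise (emulating a meta-analysis treatment effect from case
#' versus control brain proteomics), then derives the per-term reference
#' enrichment by running [preranked_gsea()] on that effect vector, so the
#' signature's term-level and protein-level components are self-consistent.
#'
#' @param cfg A [sim_config()].
#' @param annotation Output of [gen_biodomain_annotation()].
#' @return A list with `proteins` (tibble `gene`, `effect`) and `terms`
#'   (tibble `term`, `es`, `nes`, `p`, `p_adj`, `size`).
#' @export
gen_reference_signature <- function(cfg, annotation) {
  stopifnot(inherits(cfg, "sim_config"))
  gene_dom <- .gene_domains(cfg, annotation)
  base <- ifelse(is.na(gene_dom), 0, cfg$domain_effect[gene_dom])
  effect <- withr::with_seed(sub_seed(cfg$seed, "reference"),
                             base + rnorm(cfg$n_genes, 0, cfg$proteome_noise_sd))
  proteins <- tibble::tibble(gene = cfg$genes, effect = unname(effect))
  ranked <- setNames(proteins$effect, proteins$gene)
  terms <- preranked_gsea(ranked, annotation$collection,
                          n_perm = cfg$n_perm, seed = sub_seed(cfg$seed, "gsea"),
                          min_size = min(10L, cfg$genes_per_term),
                          max_size = cfg$n_genes)
  list(proteins = proteins,
       terms = terms[, c("term", "es", "nes", "p", "p_adj", "size")])
}

#' Generate raw well-level assay measurements
#'
#' Produces one row per (assay, dose, cell line, siRNA, batch, replicate)
#' with raw readout `baseline * 2^(effect + u_batch + eps)`:
#' a multiplicative (log-normal) noise model, so the log2 transform recovers
#' the additive model the downstream batch random-intercept fit assumes.
#' The batch intercept `u_batch ~ N(0, batch_sd)` is shared by every siRNA
#' (including the control) within a batch; `eps ~ N(0, residual_sd)` is
#' per-well. Control-siRNA rows carry a true effect of zero.
#'
#' @param cfg A [sim_config()].
#' @return Tibble with columns `assay`, `cell_line`, `sirna`, `batch`,
#'   `replicate`, `dose`, `value`.
#' @export
gen_assay_data <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  grids <- lapply(cfg$assays, function(a) {
    tidyr::expand_grid(
      assay = a,
      dose = if (a == "nfkb") c("vehicle", "LPS") else NA_character_,
      cell_line = cfg$cell_lines,
      sirna = c(cfg$control_sirna, cfg$targets),
      batch = sprintf("b%02d", seq_len(cfg$n_batches)),
      replicate = seq_len(cfg$n_replicates)
    )
  })
  tbl <- dplyr::bind_rows(grids)
  eff <- cfg$assay_effects
  tbl <- dplyr::left_join(
    tbl,
    dplyr::rename(eff, sirna = "target"),
    by = c("assay", "cell_line", "sirna")
  )
  tbl$effect[is.na(tbl$effect)] <- 0   # control siRNA
  withr::with_seed(sub_seed(cfg$seed, "assay"), {
    batch_key <- paste(tbl$assay, tbl$dose, tbl$batch)
    ub <- setNames(rnorm(length(unique(batch_key)), 0, cfg$batch_sd), unique(batch_key))
    eps <- rnorm(nrow(tbl), 0, cfg$residual_sd)
    tbl$value <- cfg$baseline * 2^(tbl$effect + ub[batch_key] + eps)
  })
  tbl[, c("assay", "cell_line", "sirna", "batch", "replicate", "dose", "value")]
}

#' Generate knockdown proteome abundance matrices
#'
#' For each (target, cell line) group plus a control-siRNA group per line,
#' draws `n_proteome_replicates` samples of log2 protein intensities:
#' a basal abundance per gene (wide log-normal, drawn once), plus the group
#' mean `c(target, line) * reference_effect(protein)` -- so negative `c`
#' pushes the proteome opposite to the disease signature -- plus the
#' knockdown self-effect on the targeted protein, plus Gaussian noise.
#'
#' @param cfg A [sim_config()].
#' @param reference Output of [gen_reference_signature()].
#' @param annotation Output of [gen_biodomain_annotation()]; required when
#'   `sensitized_line_shift` is configured.
#' @return A list with `values` (genes x samples matrix of log2 intensities)
#'   and `meta` (tibble `sample`, `cell_line`, `sirna`, `replicate`).
#' @export
gen_knockdown_proteomes <- function(cfg, reference, annotation = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!all(cfg$targets %in% reference$proteins$gene)) {
    stopf("configuration error: target gene(s) not in the protein universe")
  }
  ref_eff <- setNames(reference$proteins$effect, reference$proteins$gene)[cfg$genes]
  meta <- tidyr::expand_grid(cell_line = cfg$cell_lines,
                             sirna = c(cfg$control_sirna, cfg$targets),
                             replicate = seq_len(cfg$n_proteome_replicates))
  meta$sample <- paste(meta$cell_line, meta$sirna, meta$replicate, sep = "_")
  cc <- cfg$concordance_coeff
  shift <- rep(0, cfg$n_genes)
  if (!is.null(cfg$sensitized_line_shift)) {
    if (is.null(annotation)) stopf("annotation required when sensitized_line_shift is set")
    gene_dom <- .gene_domains(cfg, annotation)
    hit <- !is.na(gene_dom) & gene_dom %in% names(cfg$sensitized_line_shift)
    shift[hit] <- cfg$sensitized_line_shift[gene_dom[hit]] * ref_eff[hit]
  }
  sens_line <- if (length(cfg$cell_lines) > 1) cfg$cell_lines[length(cfg$cell_lines)] else NA
  vals <- withr::with_seed(sub_seed(cfg$seed, "proteome"), {
    basal <- rnorm(cfg$n_genes, 20, 2)
    m <- matrix(NA_real_, cfg$n_genes, nrow(meta),
                dimnames = list(cfg$genes, meta$sample))
    for (j in seq_len(nrow(meta))) {
      mu <- basal
      if (!is.na(sens_line) && meta$cell_line[j] == sens_line) mu <- mu + shift
      if (meta$sirna[j] != cfg$control_sirna) {
        cj <- cc$c[cc$target == meta$sirna[j] & cc$cell_line == meta$cell_line[j]]
        mu <- mu + cj * ref_eff
        self <- match(meta$sirna[j], cfg$genes)
        mu[self] <- mu[self] + cfg$knockdown_self_effect
      }
      m[, j] <- mu + rnorm(cfg$n_genes, 0, cfg$proteome_noise_sd)
    }
    m
  })
  list(values = vals, meta = meta[, c("sample", "cell_line", "sirna", "replicate")])
}

#' Generate a qPCR Ct table for knockdown-efficiency quantification
#'
#' One experiment per target: triplicate cycle-threshold values for the
#' target gene and the internal reference gene under control and knockdown
#' conditions. The configured knockdown fold change raises the target's Ct by
#' `-log2(fold_change)` in the knockdown condition; the reference gene is
#' unaffected.
#'
#' @param cfg A [sim_config()].
#' @param genes Targets to generate experiments for (default all).
#' @param reference_gene Label of the internal reference gene.
#' @return Tibble with columns `experiment`, `gene`, `condition`
#'   (`"control"`/`"knockdown"`), `replicate`, `ct`.
#' @export
gen_ct_table <- function(cfg, genes = cfg$targets, reference_gene = "Gapdh") {
  stopifnot(inherits(cfg, "sim_config"))
  d_ct <- -log2(cfg$ct_fold_change)
  grid <- tidyr::expand_grid(experiment = genes,
                             gene_role = c("target", "reference"),
                             condition = c("control", "knockdown"),
                             replicate = 1:3)
  grid$gene <- ifelse(grid$gene_role == "target", grid$experiment, reference_gene)
  base <- ifelse(grid$gene_role == "target", 25, 20)
  shift <- ifelse(grid$gene_role == "target" & grid$condition == "knockdown", d_ct, 0)
  grid$ct <- withr::with_seed(sub_seed(cfg$seed, "ct"),
                              base + shift + rnorm(nrow(grid), 0, cfg$ct_sd))
  grid[, c("experiment", "gene", "condition", "replicate", "ct")]
}

#' Ground truth of a synthetic screen
#'
#' Enumerates the generating truth for recovery studies: true assay hits
#' (nonzero generated effect), true reversal/concordance calls per domain
#' (nonzero coefficient crossed with a nonzero domain effect), and the
#' generating parameters themselves.
#'
#' @param cfg A [sim_config()].
#' @return A list with `true_hits`, `true_reversals` (expected calls per
#'   target, cell line and signal domain) and `true_effects`.
#' @export
ground_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  true_hits <- dplyr::filter(cfg$assay_effects, .data$effect != 0)
  signal_domains <- names(cfg$domain_effect)[cfg$domain_effect != 0]
  true_reversals <- tidyr::expand_grid(
    dplyr::filter(cfg$concordance_coeff, .data$c != 0),
    domain = signal_domains
  ) |>
    dplyr::mutate(expected_call = ifelse(.data$c < 0, "anti_correlated", "correlated")) |>
    dplyr::select("target", "cell_line", "domain", "c", "expected_call")
  list(true_hits = true_hits, true_reversals = true_reversals,
       true_effects = list(
         assay_effects = cfg$assay_effects,
         concordance_coeff = cfg$concordance_coeff,
         domain_effect = as.list(cfg$domain_effect),
         knockdown_self_effect = cfg$knockdown_self_effect
       ))
}

#' Generate and write a complete synthetic input set
#'
#' Runs every generator and writes the inputs the pipeline stages read:
#' assay table, Ct table, abundance matrix plus sample metadata, gene sets
#' (GMT), term-to-biodomain table, reference signature (term and protein
#' level), an identity ortholog map for the universe, and the ground truth
#' (JSON). Identical configurations produce byte-identical files.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written file paths.
#' @export
simulate_run <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- gen_biodomain_annotation(cfg)
  ref <- gen_reference_signature(cfg, ann)
  assays <- gen_assay_data(cfg)
  prot <- gen_knockdown_proteomes(cfg, ref, ann)
  ct <- gen_ct_table(cfg)
  gt <- ground_truth(cfg)

  paths <- list(
    assays = file.path(dir, "assays.tsv"),
    ct = file.path(dir, "ct.tsv"),
    abundance = file.path(dir, "abundance.tsv"),
    samples = file.path(dir, "samples.tsv"),
    genesets = file.path(dir, "genesets.gmt"),
    biodomains = file.path(dir, "biodomains.tsv"),
    reference_terms = file.path(dir, "reference_terms.tsv"),
    reference_proteins = file.path(dir, "reference_proteins.tsv"),
    orthologs = file.path(dir, "orthologs.tsv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  readr::write_tsv(assays, paths$assays)
  readr::write_tsv(ct, paths$ct)
  readr::write_tsv(tibble::as_tibble(prot$values, rownames = "protein"), paths$abundance)
  readr::write_tsv(prot$meta, paths$samples)
  write_gmt(ann$collection, paths$genesets)
  readr::write_tsv(ann$term_to_domain, paths$biodomains)
  readr::write_tsv(ref$terms, paths$reference_terms)
  readr::write_tsv(ref$proteins, paths$reference_proteins)
  readr::write_tsv(tibble::tibble(from = cfg$genes, to = cfg$genes), paths$orthologs)
  jsonlite::write_json(
    list(true_hits = gt$true_hits, true_reversals = gt$true_reversals,
         seed = cfg$seed),
    paths$ground_truth, dataframe = "columns", digits = NA, pretty = TRUE
  )
  invisible(paths)
}
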