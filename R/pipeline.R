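# Orchestration: a run configuration, per-knockdown enrichment, the staged
# pipeline (phenotypes -> proteome DE -> GSEA -> concordance -> integration
# -> report) with every stage's outputs on disk before the next starts, and
# a deterministic run manifest.

#' Pipeline run configuration
#'
#' Collects input locations and every threshold of the pipeline. Thresholds
#' are validated against their documented bounds; the configuration
#' round-trips losslessly through JSON/YAML.
#'
#' @param input_dir Directory holding the pipeline inputs (the files
#'   [simulate_run()] writes: `assays.tsv`, `abundance.tsv`, `samples.tsv`,
#'   `genesets.gmt`, `biodomains.tsv`, `reference_terms.tsv`,
#'   `reference_proteins.tsv`, optionally `orthologs.tsv`).
#' @param out_dir Output directory for stage results.
#' @param control_sirna Control siRNA label.
#' @param alpha Significance threshold (BH-adjusted) used by every stage.
#' @param min_proteins Sample QC threshold: minimum proteins identified per
#'   sample.
#' @param min_size,max_size Gene-set size window for enrichment.
#' @param min_terms Minimum aligned terms per biodomain for Kendall
#'   concordance.
#' @param min_points Minimum paired points per (assay, term) correlation.
#' @param min_proteins_corr Minimum in-domain proteins for protein-level
#'   concordance.
#' @param n_perm Permutations per set size for enrichment.
#' @param seed Integer seed governing all randomness in the run.
#' @param separate_lines Fit each cell line separately in the phenotype
#'   model.
#' @param universe_mode `"union"` or `"intersection"` zero-fill universe.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input_dir, out_dir,
                       control_sirna = "siCtrl", alpha = 0.05,
                       min_proteins = 6100, min_size = 10, max_size = 500,
                       min_terms = 5, min_points = 8, min_proteins_corr = 10,
                       n_perm = 1000, seed = 1, separate_lines = FALSE,
                       universe_mode = c("union", "intersection")) {
  universe_mode <- match.arg(universe_mode)
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  if (min_size < 1 || max_size < min_size) stopf("need 1 <= min_size <= max_size")
  if (min_proteins < 0 || min_terms < 2 || min_points < 3 || min_proteins_corr < 3) {
    stopf("threshold out of documented bounds")
  }
  if (n_perm < 1) stopf("n_perm must be positive")
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 control_sirna = control_sirna, alpha = alpha,
                 min_proteins = min_proteins, min_size = min_size,
                 max_size = max_size, min_terms = min_terms,
                 min_points = min_points, min_proteins_corr = min_proteins_corr,
                 n_perm = n_perm, seed = as.integer(seed),
                 separate_lines = separate_lines,
                 universe_mode = universe_mode),
            class = "run_config")
}

#' Per-knockdown preranked enrichment from differential abundance
#'
#' Builds one ranked list per (cell line, siRNA) contrast from the log2 fold
#' changes of [anova_tukey()] and runs [preranked_gsea()] on each, with a
#' distinct deterministic sub-seed per contrast.
#'
#' @param de Differential-abundance table.
#' @param collection Gene-set collection.
#' @param n_perm,seed,min_size,max_size,weight Passed to
#'   [preranked_gsea()].
#' @return Stacked tibble with columns `target`, `cell_line` plus the
#'   [preranked_gsea()] columns.
#' @export
knockdown_enrichments <- function(de, collection, n_perm = 1000, seed = 1,
                                  min_size = 10, max_size = 500, weight = 1) {
  de <- tibble::as_tibble(de)
  combos <- dplyr::distinct(de, .data$cell_line, .data$sirna) |>
    dplyr::arrange(.data$cell_line, .data$sirna)
  out <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- de[de$cell_line == combos$cell_line[i] & de$sirna == combos$sirna[i], ]
    ranked <- setNames(sub$log2fc, sub$protein)
    ranked <- ranked[!is.na(ranked)]
    res <- preranked_gsea(ranked, collection, n_perm = n_perm,
                          seed = (seed + 101L * i) %% 2147483629L,
                          min_size = min_size, max_size = max_size,
                          weight = weight)
    dplyr::mutate(res, target = combos$sirna[i], cell_line = combos$cell_line[i],
                  .before = 1)
  })
  dplyr::bind_rows(out)
}

.require_inputs <- function(input_dir, files) {
  paths <- file.path(input_dir, files)
  missing <- files[!file.exists(paths)]
  if (length(missing)) stopf("missing input file(s): %s", paste(missing, collapse = ", "))
  setNames(as.list(paths), sub("\\..*$", "", files))
}

.write_stage <- function(tbl, out_dir, name) {
  # list columns (e.g. leading edges) are flattened to comma-joined strings
  tbl <- dplyr::mutate(tbl, dplyr::across(
    dplyr::where(is.list), ~ vapply(.x, function(v) paste(unlist(v), collapse = ","), character(1))
  ))
  readr::write_tsv(tbl, file.path(out_dir, name))
}

#' Run the integrated screen pipeline
#'
#' Executes the stages in order -- `phenotypes` (batch log2FC, effect model,
#' hit summary), `proteome` (QC filter, ANOVA + Tukey, significant counts),
#' `gsea` (per-knockdown preranked enrichment), `concordance` (term- and
#' protein-level biodomain scoring plus quadrant counts), `integration`
#' (assay-term correlation and scorecards) and `report` -- writing each
#' stage's outputs to `config$out_dir` before the next starts, and finally a
#' manifest recording the configuration, package version and MD5 checksum of
#' every output. Reruns with an identical configuration reproduce identical
#' outputs.
#'
#' @param config A [run_config()].
#' @param stages Subset of stages to run (later stages read earlier stages'
#'   outputs from `out_dir`).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config,
                         stages = c("phenotypes", "proteome", "gsea",
                                    "concordance", "integration", "report")) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)

  if ("phenotypes" %in% stages) {
    ins <- .require_inputs(config$input_dir, "assays.tsv")
    assays <- read_tsv_quiet(ins$assays)
    fcs <- batch_log2fc(assays, control = config$control_sirna)
    est <- suppressWarnings(
      fit_effect_model(fcs, control = config$control_sirna,
                       separate_lines = config$separate_lines,
                       alpha = config$alpha)
    )
    .write_stage(fcs, config$out_dir, "batch_log2fc.tsv")
    .write_stage(est, config$out_dir, "effect_estimates.tsv")
    hs <- summarize_hits(est)
    .write_stage(hs$by_target, config$out_dir, "hits_by_target.tsv")
    .write_stage(hs$by_assay, config$out_dir, "hits_by_assay.tsv")
    .write_stage(hs$overall, config$out_dir, "hits_overall.tsv")
  }

  if ("proteome" %in% stages) {
    ins <- .require_inputs(config$input_dir, c("abundance.tsv", "samples.tsv"))
    ab <- read_abundance(ins$abundance, ins$samples)
    qc <- qc_filter_samples(ab$values, ab$meta, min_proteins = config$min_proteins)
    de <- anova_tukey(qc$values, qc$meta, control = config$control_sirna)
    .write_stage(qc$report, config$out_dir, "qc_report.tsv")
    .write_stage(de, config$out_dir, "differential_abundance.tsv")
    .write_stage(count_significant(de, alpha = config$alpha),
                 config$out_dir, "de_counts.tsv")
  }

  if ("gsea" %in% stages) {
    ins <- .require_inputs(config$input_dir, "genesets.gmt")
    collection <- read_gmt(ins$genesets)
    de <- read_tsv_quiet(out("differential_abundance.tsv"))
    enr <- knockdown_enrichments(de, collection, n_perm = config$n_perm,
                                 seed = config$seed,
                                 min_size = config$min_size,
                                 max_size = config$max_size)
    .write_stage(enr, config$out_dir, "enrichment.tsv")
  }

  if ("concordance" %in% stages) {
    ins <- .require_inputs(config$input_dir,
                           c("genesets.gmt", "biodomains.tsv",
                             "reference_terms.tsv", "reference_proteins.tsv"))
    collection <- read_gmt(ins$genesets)
    annotation <- read_tsv_quiet(ins$biodomains)
    ref_terms <- read_tsv_quiet(ins$reference_terms)
    ref_proteins <- read_tsv_quiet(ins$reference_proteins)
    enr <- read_tsv_quiet(out("enrichment.tsv"))
    de <- read_tsv_quiet(out("differential_abundance.tsv"))
    mapping <- if (file.exists(file.path(config$input_dir, "orthologs.tsv"))) {
      read_tsv_quiet(file.path(config$input_dir, "orthologs.tsv"))
    }
    conc_terms <- concordance_table(enr, ref_terms, annotation,
                                    min_terms = config$min_terms,
                                    alpha = config$alpha,
                                    mode = config$universe_mode)
    conc_prot <- pearson_protein_concordance(de, ref_proteins, annotation,
                                             collection, mapping = mapping,
                                             min_proteins = config$min_proteins_corr,
                                             alpha = config$alpha)
    quads <- dplyr::bind_rows(lapply(
      split(enr, paste(enr$target, enr$cell_line, sep = "\r")),
      function(q) {
        dplyr::bind_rows(lapply(unique(annotation$domain), function(d) {
          term_quadrants(q, ref_terms, annotation, d, alpha = config$alpha)
        })) |>
          dplyr::mutate(target = q$target[1], cell_line = q$cell_line[1], .before = 1)
      }
    ))
    .write_stage(conc_terms, config$out_dir, "concordance_terms.tsv")
    .write_stage(conc_prot, config$out_dir, "concordance_proteins.tsv")
    .write_stage(quads, config$out_dir, "term_quadrants.tsv")
  }

  if ("integration" %in% stages) {
    est <- read_tsv_quiet(out("effect_estimates.tsv"))
    enr <- read_tsv_quiet(out("enrichment.tsv"))
    conc <- dplyr::bind_rows(read_tsv_quiet(out("concordance_terms.tsv")),
                             read_tsv_quiet(out("concordance_proteins.tsv")))
    integ <- correlate_assay_terms(est, enr, min_points = config$min_points)
    cards <- build_scorecards(est, conc, integ, enr, alpha = config$alpha)
    .write_stage(integ, config$out_dir, "integration.tsv")
    .write_stage(dplyr::select(cards, -dplyr::where(is.list)),
                 config$out_dir, "scorecards.tsv")
  }

  if ("report" %in% stages) {
    report(config$out_dir)
  }

  outputs <- sort(setdiff(list.files(config$out_dir), "manifest.json"))
  manifest <- list(
    config = unclass(config),
    package_version = as.character(utils::packageVersion("screentier")),
    checksums = as.list(tools::md5sum(file.path(config$out_dir, outputs)) |>
                          setNames(outputs))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write a human-readable run summary
#'
#' Collates whatever stage outputs exist in a run directory into
#' `report.md`: overall and per-assay hit tables, per-domain concordance
#' calls, the strongest assay-term correlations, and the target scorecards.
#' Partial runs produce partial reports with explicit gaps; empty tables are
#' rendered with zero rows rather than failing. Deterministic: identical
#' inputs give byte-identical reports.
#'
#' @param run_dir Directory holding pipeline outputs.
#' @return Invisibly, the report path.
#' @export
report <- function(run_dir) {
  path <- file.path(run_dir, "report.md")
  lines <- c("# Integrated screen report", "")
  section <- function(lines, file, title, fmt) {
    f <- file.path(run_dir, file)
    if (!file.exists(f)) {
      return(c(lines, paste0("## ", title), "", "_stage not run_", ""))
    }
    tbl <- read_tsv_quiet(f)
    c(lines, paste0("## ", title), "", fmt(tbl), "")
  }
  md_table <- function(tbl, max_rows = 25) {
    if (nrow(tbl) == 0) return("(no rows)")
    tbl <- utils::head(tbl, max_rows)
    num <- vapply(tbl, is.numeric, logical(1))
    tbl[num] <- lapply(tbl[num], function(x) signif(x, 4))
    header <- paste0("| ", paste(names(tbl), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(tbl)), collapse = "|"), "|")
    body <- apply(tbl, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    c(header, sep, body)
  }
  lines <- section(lines, "hits_overall.tsv", "Phenotype hits (overall)", md_table)
  lines <- section(lines, "hits_by_assay.tsv", "Phenotype hits by assay", md_table)
  lines <- section(lines, "de_counts.tsv", "Differentially abundant proteins per knockdown",
                   md_table)
  lines <- section(lines, "concordance_terms.tsv", "Biodomain concordance (term level)",
                   function(tbl) md_table(dplyr::arrange(tbl, .data$p_adj)))
  lines <- section(lines, "integration.tsv", "Assay-term correlations (strongest first)",
                   function(tbl) md_table(dplyr::arrange(tbl, .data$p_adj)))
  lines <- section(lines, "scorecards.tsv", "Target scorecards",
                   function(tbl) md_table(dplyr::arrange(
                     tbl, factor(.data$tier, levels = c("top", "supported",
                                                        "phenotype_only",
                                                        "proteome_only", "none")),
                     .data$target)))
  lines <- c(lines,
             "Tier definitions: top = significant phenotype hit AND reversal of the",
             "reference signature in at least one biodomain AND at least one",
             "phenotype-coupled enriched term; supported = hit AND reversal;",
             "phenotype_only / proteome_only = one evidence stream; none = neither.")
  writeLines(lines, path)
  invisible(path)
}
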