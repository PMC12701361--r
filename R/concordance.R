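# Biodomain concordance / reversal scoring: group enrichment results and
# proteins into biodomains and correlate each knockdown's profile with a
# reference disease signature. Term level: Kendall tau-b on zero-filled NES
# vectors. Protein level: Pearson correlation of knockdown log2FC with the
# reference per-protein effect over orthologous in-domain proteins.

.term_domain <- function(annotation) {
  td <- if (is.data.frame(annotation)) annotation else annotation$term_to_domain
  if (is.null(td) || !all(c("term", "domain") %in% names(td))) {
    stopf("annotation must be a tibble with columns term, domain (or a list carrying one as term_to_domain)")
  }
  tibble::as_tibble(td)
}

.ref_terms <- function(reference) {
  rt <- if (is.data.frame(reference)) reference else reference$terms
  if (is.null(rt) || !all(c("term", "nes", "p_adj") %in% names(rt))) {
    stopf("reference must carry term, nes, p_adj (a tibble or a list with $terms)")
  }
  tibble::as_tibble(rt)
}

.ref_proteins <- function(reference) {
  rp <- if (is.data.frame(reference)) reference else reference$proteins
  if (is.null(rp) || !all(c("gene", "effect") %in% names(rp))) {
    stopf("reference must carry gene, effect (a tibble or a list with $proteins)")
  }
  tibble::as_tibble(rp)
}

#' Zero-filled alignment of query and reference term enrichments
#'
#' Restricts to the terms of one biodomain and builds paired NES vectors over
#' the union (default) of terms significant (adjusted p <= `alpha`) in either
#' analysis. A term contributes its NES on the side where it is significant
#' and 0 on the side where it is non-significant or absent; zero-filling is
#' applied symmetrically.
#'
#' @param query Enrichment tibble for one knockdown (`term`, `nes`, `p_adj`).
#' @param reference Reference signature: a tibble (`term`, `nes`, `p_adj`)
#'   or a list with a `terms` component.
#' @param annotation Term-to-biodomain table (`term`, `domain`) or the list
#'   from [gen_biodomain_annotation()].
#' @param domain Biodomain label to align.
#' @param alpha Significance threshold defining the aligned universe.
#' @param mode `"union"` (default, terms significant in either analysis) or
#'   `"intersection"` (both) for sensitivity analysis.
#' @return Tibble `term`, `nes_query`, `nes_reference`; zero rows when the
#'   domain has no qualifying terms.
#' @export
zero_fill_align <- function(query, reference, annotation, domain,
                            alpha = 0.05, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  td <- .term_domain(annotation)
  dom_terms <- td$term[td$domain == domain]
  query <- tibble::as_tibble(query)
  ref <- .ref_terms(reference)
  sig_q <- query$term[!is.na(query$p_adj) & query$p_adj <= alpha & query$term %in% dom_terms]
  sig_r <- ref$term[!is.na(ref$p_adj) & ref$p_adj <= alpha & ref$term %in% dom_terms]
  universe <- if (mode == "union") union(sig_q, sig_r) else intersect(sig_q, sig_r)
  if (length(universe) == 0) {
    return(tibble::tibble(term = character(), nes_query = numeric(),
                          nes_reference = numeric()))
  }
  tibble::tibble(
    term = universe,
    nes_query = ifelse(universe %in% sig_q,
                       query$nes[match(universe, query$term)], 0),
    nes_reference = ifelse(universe %in% sig_r,
                           ref$nes[match(universe, ref$term)], 0)
  )
}

#' Kendall concordance of a zero-filled term alignment
#'
#' Kendall rank correlation, tau-b (tie-corrected -- zero-filling
#' mass-produces ties), with a normal-approximation p value, between the
#' query and reference NES vectors of one biodomain. p values are not
#' adjusted here; [concordance_table()] applies Benjamini-Hochberg across
#' the full (target x cell line x domain) family and assigns calls.
#'
#' @param aligned Output of [zero_fill_align()].
#' @param target,cell_line,domain Labels carried into the result.
#' @param min_terms Minimum paired terms; below this the result is flagged
#'   `"too_few_terms"` with `p = NA`.
#' @return One-row tibble: `target`, `cell_line`, `domain`, `method`,
#'   `stat`, `n`, `p`, `flag`. Zero variance on either side gives `stat =
#'   NA`, `p = 1`, flag `"zero_variance"`.
#' @export
kendall_concordance <- function(aligned, target = NA_character_,
                                cell_line = NA_character_,
                                domain = NA_character_, min_terms = 5) {
  n <- nrow(aligned)
  row <- tibble::tibble(target = target, cell_line = cell_line, domain = domain,
                        method = "kendall_terms", stat = NA_real_,
                        n = as.integer(n), p = NA_real_, flag = NA_character_)
  if (n < min_terms) {
    row$flag <- "too_few_terms"
    return(row)
  }
  x <- aligned$nes_query; y <- aligned$nes_reference
  if (sd(x) == 0 || sd(y) == 0) {
    row$p <- 1; row$flag <- "zero_variance"
    return(row)
  }
  ct <- suppressWarnings(cor.test(x, y, method = "kendall", exact = FALSE))
  row$stat <- unname(ct$estimate)
  row$p <- ct$p.value
  row
}

.assign_calls <- function(tbl, alpha) {
  tbl$p_adj <- p.adjust(tbl$p, method = "BH")
  tbl$call <- dplyr::case_when(
    is.na(tbl$p_adj) | is.na(tbl$stat) ~ "ns",
    tbl$p_adj <= alpha & tbl$stat < 0 ~ "anti_correlated",
    tbl$p_adj <= alpha & tbl$stat > 0 ~ "correlated",
    TRUE ~ "ns"
  )
  tbl
}

#' Term-level concordance of every knockdown against the reference
#'
#' For each (target, cell line) enrichment table and each biodomain, aligns
#' significant terms by [zero_fill_align()], computes Kendall tau-b
#' ([kendall_concordance()]), applies Benjamini-Hochberg across the whole
#' family of tests, and classifies each as `correlated` (adjusted p <=
#' `alpha`, tau > 0), `anti_correlated` (tau < 0: a signature reversal) or
#' `ns`.
#'
#' @param enrichments Stacked per-knockdown enrichment results: tibble with
#'   columns `target`, `cell_line`, `term`, `nes`, `p_adj`.
#' @inheritParams zero_fill_align
#' @inheritParams kendall_concordance
#' @param domains Domains to score (default: all in the annotation).
#' @return Tibble with one row per (target, cell line, domain):
#'   `target`, `cell_line`, `domain`, `method`, `stat`, `n`, `p`, `p_adj`,
#'   `call`, `flag`.
#' @export
concordance_table <- function(enrichments, reference, annotation,
                              domains = NULL, min_terms = 5, alpha = 0.05,
                              mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  enrichments <- tibble::as_tibble(enrichments)
  td <- .term_domain(annotation)
  domains <- domains %||% unique(td$domain)
  combos <- dplyr::distinct(enrichments, .data$target, .data$cell_line)
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    q <- enrichments[enrichments$target == combos$target[i] &
                       enrichments$cell_line == combos$cell_line[i], ]
    for (d in domains) {
      aligned <- zero_fill_align(q, reference, td, d, alpha = alpha, mode = mode)
      if (nrow(aligned) == 0) next   # no qualifying terms anywhere in the domain
      rows[[length(rows) + 1L]] <-
        kendall_concordance(aligned, combos$target[i], combos$cell_line[i], d,
                            min_terms = min_terms)
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(target = character(), cell_line = character(),
                          domain = character(), method = character(),
                          stat = numeric(), n = integer(), p = numeric(),
                          p_adj = numeric(), call = character(), flag = character()))
  }
  .assign_calls(dplyr::bind_rows(rows), alpha)
}

#' Protein-level concordance by biodomain
#'
#' For each knockdown contrast and each biodomain, computes the Pearson
#' correlation between the knockdown log2 fold changes and the reference
#' per-protein effects over the orthologous proteins annotated to the
#' domain (a protein belongs to a domain when it is a member of any of the
#' domain's terms). Benjamini-Hochberg correction is applied across all
#' tests and calls assigned as in [concordance_table()].
#'
#' @param de Differential-abundance table from [anova_tukey()] (`protein`,
#'   `cell_line`, `sirna`, `log2fc`).
#' @param reference Reference signature with a protein-level component
#'   (tibble `gene`, `effect` or a list with `$proteins`).
#' @param annotation Term-to-domain table or annotation list.
#' @param collection Named list of gene sets defining term membership.
#' @param mapping Optional two-column ortholog table mapping query protein
#'   labels to the reference namespace (one-to-one rows only; see
#'   [map_orthologs()]).
#' @param min_proteins Minimum in-domain paired proteins; smaller overlaps
#'   are skipped with a notice.
#' @param alpha Significance threshold for calls.
#' @return Tibble as [concordance_table()], with `method =
#'   "pearson_proteins"`.
#' @export
pearson_protein_concordance <- function(de, reference, annotation, collection,
                                        mapping = NULL, min_proteins = 10,
                                        alpha = 0.05) {
  td <- .term_domain(annotation)
  ref <- .ref_proteins(reference)
  gene_dom <- dplyr::bind_rows(lapply(names(collection), function(tm) {
    tibble::tibble(gene = collection[[tm]],
                   domain = td$domain[td$term == tm][1])
  })) |> dplyr::distinct()
  de <- tibble::as_tibble(de)
  combos <- dplyr::distinct(de, .data$cell_line, .data$sirna)
  n_skipped <- 0L
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    sub <- de[de$cell_line == combos$cell_line[i] & de$sirna == combos$sirna[i], ]
    lfc <- setNames(sub$log2fc, sub$protein)
    lfc <- lfc[!is.na(lfc)]
    if (!is.null(mapping)) lfc <- map_orthologs(lfc, mapping)
    paired <- tibble::tibble(gene = names(lfc), lfc = unname(lfc)) |>
      dplyr::inner_join(ref, by = "gene") |>
      dplyr::inner_join(gene_dom, by = "gene", relationship = "many-to-many")
    for (d in unique(td$domain)) {
      pd <- paired[paired$domain == d, ]
      if (nrow(pd) < min_proteins) { n_skipped <- n_skipped + 1L; next }
      row <- tibble::tibble(target = combos$sirna[i],
                            cell_line = combos$cell_line[i], domain = d,
                            method = "pearson_proteins", stat = NA_real_,
                            n = nrow(pd), p = NA_real_, flag = NA_character_)
      if (sd(pd$lfc) == 0 || sd(pd$effect) == 0) {
        row$p <- 1; row$flag <- "zero_variance"
      } else {
        ct <- cor.test(pd$lfc, pd$effect, method = "pearson")
        row$stat <- unname(ct$estimate); row$p <- ct$p.value
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (n_skipped > 0) {
    message(n_skipped, " (contrast, domain) pair(s) skipped: overlap below ",
            min_proteins, " proteins")
  }
  if (length(rows) == 0) {
    return(tibble::tibble(target = character(), cell_line = character(),
                          domain = character(), method = character(),
                          stat = numeric(), n = integer(), p = numeric(),
                          p_adj = numeric(), call = character(), flag = character()))
  }
  .assign_calls(dplyr::bind_rows(rows), alpha)
}

#' Quadrant classification of significant terms in one biodomain
#'
#' Among terms significant in both analyses, counts the four sign classes of
#' (reference NES, query NES); terms significant on only one side are
#' tallied separately. The class counts sum to the union of significant
#' terms in the domain.
#'
#' @inheritParams zero_fill_align
#' @return One-row tibble: `domain`, `ref_up_query_up`, `ref_up_query_down`,
#'   `ref_down_query_up`, `ref_down_query_down`, `ref_only`, `query_only`,
#'   `n_union`.
#' @export
term_quadrants <- function(query, reference, annotation, domain, alpha = 0.05) {
  td <- .term_domain(annotation)
  dom_terms <- td$term[td$domain == domain]
  query <- tibble::as_tibble(query)
  ref <- .ref_terms(reference)
  sig_q <- query[!is.na(query$p_adj) & query$p_adj <= alpha & query$term %in% dom_terms, ]
  sig_r <- ref[!is.na(ref$p_adj) & ref$p_adj <= alpha & ref$term %in% dom_terms, ]
  both <- intersect(sig_q$term, sig_r$term)
  qs <- sign(sig_q$nes[match(both, sig_q$term)])
  rs <- sign(sig_r$nes[match(both, sig_r$term)])
  tibble::tibble(
    domain = domain,
    ref_up_query_up = sum(rs > 0 & qs > 0),
    ref_up_query_down = sum(rs > 0 & qs <= 0),
    ref_down_query_up = sum(rs < 0 & qs > 0),
    ref_down_query_down = sum(rs < 0 & qs <= 0),
    ref_only = length(setdiff(sig_r$term, sig_q$term)),
    query_only = length(setdiff(sig_q$term, sig_r$term)),
    n_union = length(union(sig_q$term, sig_r$term))
  )
}

#' Characterise the sensitized cell line against the control line
#'
#' Reproduces the baseline characterisation chain: differential abundance of
#' control-siRNA samples between the two cell lines (reusing the
#' [anova_tukey()] machinery with the reference line as the "control"
#' group), a ranked list from the resulting log2 fold changes, preranked
#' enrichment over the gene-set collection, optional set enrichment of
#' custom (e.g. microglial subtype) lists, and per-biodomain Kendall
#' concordance with the reference disease signature.
#'
#' @param values,meta Abundance matrix (proteins x samples) and sample
#'   metadata.
#' @param control_sirna Control siRNA label; only these samples are used.
#' @param collection,annotation,reference As elsewhere.
#' @param subtype_lists Optional named list of custom gene lists.
#' @param reference_line,query_line Cell-line labels; default the first and
#'   second line present.
#' @param n_perm,seed,min_size,max_size,min_terms,alpha Passed through to the
#'   enrichment and concordance stages.
#' @return List: `de`, `ranked`, `enrichment`, `subtype_enrichment` (or
#'   `NULL`), `concordance`.
#' @export
compare_cell_lines <- function(values, meta, control_sirna, collection,
                               annotation, reference, subtype_lists = NULL,
                               reference_line = NULL, query_line = NULL,
                               n_perm = 1000, seed = 1, min_size = 10,
                               max_size = 500, min_terms = 5, alpha = 0.05) {
  meta <- tibble::as_tibble(meta)
  keep <- meta$sirna == control_sirna
  if (!any(keep)) stopf("no control-siRNA samples found")
  meta <- meta[keep, ]
  lines <- unique(meta$cell_line)
  reference_line <- reference_line %||% lines[1]
  query_line <- query_line %||% setdiff(lines, reference_line)[1]
  if (is.na(query_line)) stopf("need control-siRNA samples in two cell lines")
  meta2 <- tibble::tibble(sample = meta$sample, cell_line = "pooled",
                          sirna = meta$cell_line, replicate = meta$replicate)
  de <- anova_tukey(values[, meta2$sample, drop = FALSE], meta2,
                    control = reference_line)
  de <- de[de$sirna == query_line, ]
  ranked <- setNames(de$log2fc, de$protein)
  ranked <- ranked[!is.na(ranked)]
  enr <- preranked_gsea(ranked, collection, n_perm = n_perm, seed = seed,
                        min_size = min_size, max_size = max_size)
  sub_enr <- if (!is.null(subtype_lists)) {
    set_enrichment_custom(ranked, subtype_lists, n_perm = n_perm, seed = seed)
  }
  enr_tagged <- dplyr::mutate(enr, target = query_line, cell_line = reference_line)
  conc <- concordance_table(enr_tagged, reference, annotation,
                            min_terms = min_terms, alpha = alpha)
  list(de = de, ranked = ranked, enrichment = enr,
       subtype_enrichment = sub_enr, concordance = conc)
}
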