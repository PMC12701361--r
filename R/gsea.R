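# Preranked gene-set enrichment: weighted Kolmogorov-Smirnov-style running
# sum, gene-label permutation null, sign-stratified NES. Implemented from
# scratch; this statistic is the package's core primitive.

# Running-sum enrichment score from in-set positions within a ranked list.
#
# `pos` are 1-based positions of the set genes in the ranking (any order),
# `w_all` the |statistic|^weight values for the full ranking, `N` the universe
# size. The running sum increments by w/sum(w) at in-set positions and
# decrements by 1/(N - n) elsewhere; candidates for the extremum are the
# values just after each increment (positive side) and just before each
# increment (negative side) -- between hits the path is monotone decreasing
# and it returns to zero at the end, so no other point can be the extremum.
# Ties between a positive and negative extremum of equal magnitude resolve to
# the positive one.
.es_core <- function(pos, w_all, N, details = FALSE) {
  pos <- sort.int(pos)
  n <- length(pos)
  if (n >= N) stopf("gene set equals or exceeds the ranked universe (n = %d, N = %d)", n, N)
  w <- w_all[pos]
  W <- sum(w)
  if (W <= 0) {            # all in-set statistics are zero: fall back to equal weights
    w <- rep.int(1, n)
    W <- n
  }
  cw <- cumsum(w) / W
  miss <- (pos - seq_len(n)) / (N - n)
  after <- cw - miss
  before <- c(0, cw[-n]) - miss
  es_pos <- max(after)
  es_neg <- min(before)
  # exact ties between the two extrema resolve to the positive one; the
  # small tolerance keeps that choice stable under floating-point noise
  es <- if (es_pos + 1e-12 >= -es_neg) es_pos else es_neg
  if (!details) return(es)
  le_pos <- if (es >= 0) pos[seq_len(which.max(after))] else pos[seq(which.min(before), n)]
  list(es = es, leading_edge_pos = le_pos)
}

# Sort a named statistic vector into a ranked list (descending, stable for
# ties) and validate labels.
.as_ranked <- function(ranked) {
  if (is.null(names(ranked)) || anyNA(ranked)) {
    stopf("ranked list must be a named numeric vector with no missing statistics")
  }
  if (anyDuplicated(names(ranked))) stopf("duplicate gene labels in ranked list")
  ranked[order(-ranked)]      # order() is stable: ties keep input order
}

#' Running-sum enrichment score for one gene set
#'
#' Computes the weighted Kolmogorov-Smirnov-style enrichment score of a gene
#' set within a ranked list. The running sum increments by
#' \eqn{|s_i|^w / \sum |s|^w} at in-set genes and decrements by
#' \eqn{1/(N - n)} at out-of-set genes; the score is the signed maximum
#' deviation from zero. The leading edge is the in-set genes at or before the
#' extremum (at or after it, for negative scores).
#'
#' @param ranked Named numeric vector of per-gene statistics. Sorted into
#'   descending order internally (stable for ties).
#' @param geneset Character vector of gene labels; genes absent from the
#'   ranking are ignored.
#' @param weight Exponent applied to the statistic magnitudes (0 gives the
#'   classic unweighted KS statistic; default 1).
#' @return A list with elements `es` (numeric in \[-1, 1\]), `leading_edge`
#'   (character) and `size` (genes in set intersect universe).
#' @examples
#' stats <- setNames(seq(3, -3, length.out = 12), paste0("g", 1:12))
#' enrichment_score(stats, c("g1", "g2", "g3"), weight = 0)
#' @export
enrichment_score <- function(ranked, geneset, weight = 1) {
  ranked <- .as_ranked(ranked)
  pos <- which(names(ranked) %in% geneset)
  if (length(pos) == 0L) stopf("gene set has no overlap with the ranked universe")
  w_all <- abs(ranked)^weight
  res <- .es_core(pos, w_all, length(ranked), details = TRUE)
  list(es = res$es,
       leading_edge = names(ranked)[res$leading_edge_pos],
       size = length(pos))
}

# p value and NES from a sign-stratified permutation null.
.perm_summary <- function(es, null_es) {
  if (es > 0) {
    same <- null_es[null_es > 0]
    p <- (1 + sum(same >= es)) / (1 + length(same))
    nes <- if (length(same)) es / mean(same) else NA_real_
  } else if (es < 0) {
    same <- null_es[null_es < 0]
    p <- (1 + sum(same <= es)) / (1 + length(same))
    nes <- if (length(same)) -abs(es) / mean(abs(same)) else NA_real_
  } else {
    return(list(nes = 0, p = 1, n_same = sum(null_es == 0), flag = NA_character_))
  }
  flag <- if (length(same) == 0L) "no_same_sign_null" else NA_character_
  list(nes = nes, p = p, n_same = length(same), flag = flag)
}

#' Preranked gene-set enrichment with a permutation null
#'
#' For every gene set with adequate overlap, computes the running-sum
#' enrichment score ([enrichment_score()]) and compares it against a null of
#' random gene sets of equal size drawn from the ranked universe (gene-label
#' permutation, the preranked convention). NES is the score divided by the
#' mean magnitude of same-sign null scores; the nominal p value is the
#' one-sided permutation tail `(1 + b) / (1 + m)` among same-sign null draws;
#' adjusted p values are Benjamini-Hochberg across the tested terms.
#'
#' Null draws are shared between gene sets of equal size, so runtime scales
#' with the number of distinct set sizes rather than the number of sets.
#' Results are fully determined by `seed`.
#'
#' @inheritParams enrichment_score
#' @param collection Named list of character vectors (gene sets), e.g. from
#'   [read_gmt()].
#' @param n_perm Number of permutation null draws per set size.
#' @param seed Integer seed for the permutation null.
#' @param min_size,max_size Gene sets whose overlap with the universe falls
#'   outside this range are dropped. A set spanning the whole universe is
#'   untestable and is dropped with a notice.
#' @param adaptive If `TRUE`, the null for a set size is doubled (up to
#'   `max_perm`) until every term of that size has at least 10 same-sign null
#'   draws as extreme as its observed score, sharpening small p values.
#' @param max_perm Cap on null draws per size when `adaptive = TRUE`.
#' @return A tibble with one row per tested term: `term`, `es`, `nes`, `p`,
#'   `p_adj`, `size`, `leading_edge` (list column) and `flag`
#'   (`"no_same_sign_null"` marks low-confidence terms whose p is clamped
#'   to 1).
#' @export
preranked_gsea <- function(ranked, collection, n_perm = 10000, seed = 1,
                           min_size = 10, max_size = 500, weight = 1,
                           adaptive = FALSE, max_perm = 1e6) {
  ranked <- .as_ranked(ranked)
  N <- length(ranked)
  if (N < min_size) stopf("ranked universe (%d genes) smaller than min_size", N)
  if (anyDuplicated(unname(ranked))) {
    warnf("ties in the ranking statistic; broken by stable input order")
  }
  if (is.null(names(collection)) || anyDuplicated(names(collection))) {
    stopf("collection must be a uniquely named list of gene sets")
  }
  w_all <- abs(ranked)^weight
  gene_pos <- setNames(seq_len(N), names(ranked))

  overlap <- lapply(collection, function(g) unname(gene_pos[intersect(unique(g), names(gene_pos))]))
  size <- lengths(overlap)
  dropped <- names(collection)[size == 0L]
  if (length(dropped)) {
    message("skipping ", length(dropped), " term(s) with no overlap with the universe")
  }
  keep <- size >= min_size & size <= max_size & size < N
  if (!any(keep)) {
    return(tibble::tibble(term = character(), es = numeric(), nes = numeric(),
                          p = numeric(), p_adj = numeric(), size = integer(),
                          leading_edge = list(), flag = character()))
  }
  terms <- names(collection)[keep]
  overlap <- overlap[keep]
  size <- size[keep]

  obs <- lapply(overlap, .es_core, w_all = w_all, N = N, details = TRUE)
  es <- vapply(obs, `[[`, numeric(1), "es")

  res <- withr::with_seed(seed, {
    out <- vector("list", length(terms))
    for (s in sort(unique(size))) {
      null_es <- vapply(seq_len(n_perm),
                        function(i) .es_core(sample.int(N, s), w_all, N),
                        numeric(1))
      idx <- which(size == s)
      if (adaptive) {
        repeat {
          exceed <- vapply(idx, function(j) {
            if (es[j] > 0) sum(null_es >= es[j] & null_es > 0)
            else if (es[j] < 0) sum(null_es <= es[j] & null_es < 0)
            else 10L
          }, numeric(1))
          if (all(exceed >= 10) || length(null_es) >= max_perm) break
          null_es <- c(null_es,
                       vapply(seq_along(null_es),
                              function(i) .es_core(sample.int(N, s), w_all, N),
                              numeric(1)))
        }
      }
      for (j in idx) out[[j]] <- .perm_summary(es[j], null_es)
    }
    out
  })

  tbl <- tibble::tibble(
    term = terms,
    es = unname(es),
    nes = vapply(res, `[[`, numeric(1), "nes"),
    p = vapply(res, `[[`, numeric(1), "p"),
    size = as.integer(unname(size)),
    leading_edge = unname(lapply(obs, function(o) names(ranked)[o$leading_edge_pos])),
    flag = vapply(res, `[[`, character(1), "flag")
  )
  tbl$p[!is.na(tbl$flag) & tbl$flag == "no_same_sign_null"] <- 1
  tbl$p_adj <- p.adjust(tbl$p, method = "BH")
  tbl[, c("term", "es", "nes", "p", "p_adj", "size", "leading_edge", "flag")]
}

#' Set-based enrichment of custom gene lists
#'
#' Runs the same permutation engine as [preranked_gsea()] against arbitrary
#' custom gene lists (e.g. microglial subtype signatures), with a lower
#' default minimum set size so that small curated lists are admitted. Empty
#' lists are skipped with a notice.
#'
#' @inheritParams preranked_gsea
#' @param lists Named list of character vectors.
#' @return As [preranked_gsea()].
#' @export
set_enrichment_custom <- function(ranked, lists, n_perm = 10000, seed = 1,
                                  min_size = 3, max_size = Inf, weight = 1, ...) {
  empty <- lengths(lists) == 0L
  if (any(empty)) {
    message("skipping ", sum(empty), " empty gene list(s): ",
            paste(names(lists)[empty], collapse = ", "))
    lists <- lists[!empty]
  }
  preranked_gsea(ranked, lists, n_perm = n_perm, seed = seed,
                 min_size = min_size, max_size = max_size, weight = weight, ...)
}

#' Translate gene labels through an ortholog mapping
#'
#' Applies a two-column ortholog table (source label, mapped label) to a
#' ranked list (named numeric vector) or a gene-set collection (named list of
#' character vectors). Only one-to-one rows are used: rows whose source key
#' maps to several labels, and rows whose mapped label collides with another
#' source, are dropped and counted. Unmapped genes are dropped and counted.
#'
#' @param x A named numeric vector (ranked list) or a named list of character
#'   vectors (collection).
#' @param mapping A data frame whose first two columns are source and mapped
#'   labels.
#' @return The translated object, with an `ortholog_report` attribute:
#'   a list with `n_ambiguous` (one-to-many rows dropped), `n_collision`
#'   (many-to-one rows dropped), `n_unmapped`, and `unmapped` (labels).
#' @export
map_orthologs <- function(x, mapping) {
  mapping <- as.data.frame(mapping)[, 1:2]
  names(mapping) <- c("from", "to")
  amb <- mapping$from %in% mapping$from[duplicated(mapping$from)]
  mapping2 <- mapping[!amb, ]
  col <- mapping2$to %in% mapping2$to[duplicated(mapping2$to)]
  mapping2 <- mapping2[!col, ]
  lut <- setNames(mapping2$to, mapping2$from)

  translate <- function(genes) {
    hit <- genes %in% names(lut)
    list(mapped = unname(lut[genes[hit]]), unmapped = genes[!hit])
  }

  if (is.numeric(x)) {
    tr <- translate(names(x))
    out <- x[names(x) %in% names(lut)]
    names(out) <- tr$mapped
    unmapped <- tr$unmapped
  } else if (is.list(x)) {
    unmapped <- character()
    out <- lapply(x, function(g) {
      tr <- translate(g)
      unmapped <<- union(unmapped, tr$unmapped)
      tr$mapped
    })
  } else {
    stopf("map_orthologs() expects a named numeric vector or a list of gene sets")
  }
  attr(out, "ortholog_report") <- list(
    n_ambiguous = sum(amb), n_collision = sum(col),
    n_unmapped = length(unmapped), unmapped = unmapped
  )
  out
}
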