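# Internal helpers shared across modules.

# Derive a reproducible sub-seed from a base seed and a stage label so that
# each generator is deterministic regardless of the order generators are
# called in. Kept below 2^31 - 1 (R integers are 32-bit).
sub_seed <- function(seed, stage) {
  offs <- c(annotation = 11L, reference = 23L, assay = 37L,
            proteome = 53L, ct = 71L, gsea = 97L)
  if (!stage %in% names(offs)) stop("unknown stage label: ", stage)
  as.integer((as.numeric(seed) * 1009 + offs[[stage]]) %% 2147483629)
}

# Two-sided p value for estimate/se against a standard normal reference.
# Degenerate se = 0: p is 1 for a zero estimate and 0 otherwise.
z_pvalue <- function(estimate, se, tol = 1e-12) {
  p <- 2 * pnorm(-abs(estimate / se))
  deg <- !is.finite(p) | se < tol
  p[deg] <- ifelse(abs(estimate[deg]) < tol, 1, 0)
  p
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(x, y) if (is.null(x)) y else x
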