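#' Randomly reassign group labels
#'
#' Shuffles the group column of a dataset uniformly at random over rows.
#' Group sizes and the pooled multiset of indicator rows are preserved
#' exactly; only the partition into groups changes.
#'
#' @param data a data frame with a group column.
#' @param group name of the group column.
#' @return the data frame with permuted group labels.
#' @export
permute_labels <- function(data, group) {
  if (!group %in% names(data)) stop("no such group column: ", group)
  if (length(unique(data[[group]])) < 2L)
    stop("permutation requires at least 2 groups")
  data[[group]] <- data[[group]][sample.int(nrow(data))]
  data
}

#' Permutation test of configural invariance
#'
#' Tests the null hypothesis that all groups share the same data-generating
#' model configuration, *without* assuming the fitted model is correctly
#' specified.  Group labels are randomly reassigned B times; the configural
#' model is refitted to each permuted dataset, and the observed chi-square,
#' CFI and RMSEA are referred to the resulting empirical null distributions.
#' For each statistic the p-value is the proportion of permuted values
#' indicating *worse* fit than observed (chi-square and RMSEA: greater or
#' equal; CFI: less or equal).
#'
#' Permutation fits are warm-started from a single pooled-data fit;
#' nonconverged permutation fits are excluded from both numerator and
#' denominator and reported in `n_failed` (with a warning above 5%).
#'
#' @param spec a `cfa_spec`.
#' @param data data frame of indicators plus a group column.
#' @param group name of the group column.
#' @param B number of permutations (default 500).
#' @param seed optional integer seed; permutation b uses its own derived
#'   seed, so results are reproducible and independent of execution order.
#' @param pvalue `"plain"` for the simple proportion (can be 0), or
#'   `"addone"` for `(b + 1) / (B + 1)`.
#' @param observed optionally, a pre-computed `cfa_fit` of `spec` to `data`.
#' @return a `cfa_permutation` object: observed statistics, per-statistic
#'   null distributions and p-values, `B`, `n_failed`, `seed`.
#' @export
permutation_test <- function(spec, data, group, B = 500L, seed = NULL,
                             pvalue = c("plain", "addone"),
                             observed = NULL) {
  pvalue <- match.arg(pvalue)
  B <- as.integer(B)
  if (B < 1L) stop("`B` must be >= 1")
  if (length(unique(data[[group]])) < 2L)
    stop("permutation requires at least 2 groups")

  if (is.null(observed))
    observed <- cfa_fit(spec, data = data, group = group)
  if (!observed$converged)
    stop("the observed configural fit did not converge")

  # Warm start: fit the model to the pooled sample once; permuted groups are
  # random mixtures of the pooled data, so this is close to every optimum.
  pooled <- data
  pooled_mom <- sample_moments(
    transform(pooled, ..g.. = "all"), "..g..",
    variables = spec$indicators)
  pooled_spec <- spec
  pooled_spec$n_groups <- 1L
  pooled_spec$ptable <- spec$ptable[spec$ptable$group == 1L, , drop = FALSE]
  pooled_fit <- cfa_fit(pooled_spec, pooled_mom, indices = FALSE)
  warm <- rep(start_from_fit(pooled_fit), spec$n_groups)

  perm_seeds <- derive_seeds(seed, B)
  stat_T <- stat_cfi <- stat_rmsea <- rep(NA_real_, B)
  n_failed <- 0L
  for (b in seq_len(B)) {
    if (!is.null(perm_seeds)) set.seed(perm_seeds[b])
    pd <- permute_labels(data, group)
    f <- tryCatch(
      cfa_fit(spec, data = pd, group = group,
              start = if (pooled_fit$converged) warm else NULL),
      error = function(e) NULL)
    if (is.null(f) || !f$converged) { n_failed <- n_failed + 1L; next }
    stat_T[b] <- f$T
    stat_cfi[b] <- f$cfi
    stat_rmsea[b] <- f$rmsea
  }
  if (n_failed > 0.05 * B)
    warning(n_failed, " of ", B, " permutation fits failed to converge")
  ok <- !is.na(stat_T)
  if (!any(ok)) stop("all permutation fits failed")

  pv <- function(null, obs, worse_is_ge) {
    b <- if (worse_is_ge) sum(null[ok] >= obs) else sum(null[ok] <= obs)
    if (pvalue == "plain") b / sum(ok) else (b + 1) / (sum(ok) + 1)
  }
  structure(
    list(observed = list(chisq = observed$T, cfi = observed$cfi,
                         rmsea = observed$rmsea),
         null = list(chisq = stat_T[ok], cfi = stat_cfi[ok],
                     rmsea = stat_rmsea[ok]),
         p_values = list(chisq = pv(stat_T, observed$T, TRUE),
                         cfi = pv(stat_cfi, observed$cfi, FALSE),
                         rmsea = pv(stat_rmsea, observed$rmsea, TRUE)),
         B = B, n_failed = n_failed, seed = seed, pvalue = pvalue,
         observed_fit = observed),
    class = "cfa_permutation")
}

#' @export
print.cfa_permutation <- function(x, ...) {
  cat("Permutation test of configural invariance (B = ", x$B, ")\n", sep = "")
  cat(sprintf("  chi-square = %.2f, p = %.3f\n",
              x$observed$chisq, x$p_values$chisq))
  cat(sprintf("  CFI        = %.3f, p = %.3f\n",
              x$observed$cfi, x$p_values$cfi))
  cat(sprintf("  RMSEA      = %.3f, p = %.3f\n",
              x$observed$rmsea, x$p_values$rmsea))
  if (x$n_failed > 0L)
    cat("  nonconverged permutation fits excluded:", x$n_failed, "\n")
  invisible(x)
}

# Independent per-replicate seeds derived from one master seed, so serial and
# parallel execution give identical results.  NULL seed -> use the ambient
# RNG stream (no per-replicate reseeding).
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(NULL)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
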