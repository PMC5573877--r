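#' Maximum-likelihood discrepancy of a fully-valued model
#'
#' The multigroup normal-theory ML fitting function
#' \deqn{F = \sum_g (n_g/N)\,[\log|\Sigma_g| - \log|S_g| +
#'       \mathrm{tr}(S_g \Sigma_g^{-1}) - p]}
#' evaluated at the parameter values stored in `spec` (all values must be
#' present, as in a population model or a fitted table).  `F = 0` iff the
#' implied matrices equal the sample matrices; the model test statistic is
#' `T = N F`.
#'
#' @param spec a `cfa_spec` (or `cfa_population`) with complete values.
#' @param moments a `cfa_moments`.
#' @return nonnegative scalar.
#' @export
fml_discrepancy <- function(spec, moments) {
  moments <- align_moments(spec, moments)
  Fg <- vapply(seq_len(spec$n_groups), function(g) {
    mats <- spec_matrices(spec, g, require_values = TRUE)
    cfa_fml_group_cpp(moments$S[[g]], mats$Lambda, mats$Theta, mats$Psi)
  }, numeric(1L))
  sum(moments$n / moments$N * Fg)
}

#' Fit a multigroup CFA by maximum likelihood
#'
#' Minimises the normal-theory ML discrepancy by Fisher scoring with step
#' halving, independently per group (the configural model shares no
#' parameters across groups).  The test statistic is `T = N F_min` with
#' `df = sum_g [p(p+1)/2 - q_g]`, referred to a central chi-square
#' distribution.  Residual variances are not constrained to be positive;
#' Heywood cases are flagged in the convergence record, not prevented.
#'
#' @param spec a `cfa_spec`.
#' @param moments a `cfa_moments`; alternatively supply `data` and `group`
#'   to have [sample_moments()] called for you.
#' @param data,group optional raw-data input path.
#' @param start optional list (one numeric vector per group, in parameter
#'   table order) of starting values; defaults to `0.7 sd` for loadings,
#'   `0.5 var` for residual variances and 0 for covariances.
#' @param tol convergence tolerance on the infinity norm of the gradient of
#'   the per-group discrepancy.
#' @param maxit maximum Fisher-scoring iterations per group.
#' @param indices compute CFI/RMSEA (with 90\% CI) alongside the test
#'   statistic.
#' @return a `cfa_fit` object; see Details.
#' @details The returned list contains the spec with estimates filled into
#'   `ptable$est`, per-group matrices and implied covariances, `F_min`, the
#'   statistic `T`, `df`, `p_value`, fit indices, and a convergence record
#'   (`iterations`, `max_grad`, `converged`, `heywood` per group).
#' @examples
#' pop <- study_population()
#' mom <- population_moments(pop, n = 100)
#' fit <- cfa_fit(configural_spec(pop), mom)
#' round(c(fit$T, fit$df, fit$cfi, fit$rmsea), 3)
#' @export
cfa_fit <- function(spec, moments = NULL, data = NULL, group = NULL,
                    start = NULL, tol = 1e-6, maxit = 500L,
                    indices = TRUE) {
  stopifnot(inherits(spec, "cfa_spec"))
  if (is.null(moments)) {
    if (is.null(data) || is.null(group))
      stop("supply either `moments` or both `data` and `group`")
    moments <- sample_moments(data, group, variables = spec$indicators)
  }
  moments <- align_moments(spec, moments)

  group_fits <- vector("list", spec$n_groups)
  est <- rep(NA_real_, nrow(spec$ptable))
  for (g in seq_len(spec$n_groups)) {
    fm <- free_map(spec, g)
    mats <- spec_matrices(spec, g, fill = 0)
    st <- if (!is.null(start)) start[[g]] else
      default_start(spec, g, fm, moments$S[[g]])
    gf <- cfa_fit_group_cpp(moments$S[[g]], mats$Lambda, mats$Theta,
                            mats$Psi, fm$map, st, tol = tol,
                            maxit = as.integer(maxit))
    gf$ptable_rows <- fm$ptable_rows
    gf$heywood <- any(diag(gf$Theta) < 0)
    group_fits[[g]] <- gf
    est[fm$ptable_rows] <- as.numeric(gf$theta)
  }
  fixed <- !spec$ptable$free
  est[fixed] <- spec$ptable$value[fixed]

  F_g <- vapply(group_fits, function(z) z$F, numeric(1L))
  F_min <- sum(moments$n / moments$N * F_g)
  T_stat <- max(moments$N * F_min, 0)
  df <- model_df(spec)
  fit <- structure(
    list(spec = spec, moments = moments, group_fits = group_fits,
         estimates = transform(spec$ptable, est = est),
         Sigma_hat = lapply(group_fits, function(z) {
           dimnames(z$Sigma) <- list(spec$indicators, spec$indicators)
           z$Sigma
         }),
         F_min = F_min, T = T_stat, df = df,
         p_value = if (df > 0) stats::pchisq(T_stat, df, lower.tail = FALSE)
                   else NA_real_,
         converged = all(vapply(group_fits, function(z) z$converged,
                                logical(1L))),
         max_grad = max(vapply(group_fits, function(z) z$max_grad,
                               numeric(1L))),
         iterations = vapply(group_fits, function(z) z$iterations,
                             integer(1L)),
         heywood = vapply(group_fits, function(z) z$heywood, logical(1L))),
    class = "cfa_fit")

  if (indices) {
    bl <- baseline_fit(moments)
    fit$baseline_T <- bl$T
    fit$baseline_df <- bl$df
    fit$cfi <- cfi(fit, bl)
    if (df > 0) {
      fit$rmsea <- rmsea(fit)
      ci <- rmsea_ci(fit)
      fit$rmsea_ci_low <- ci[[1L]]
      fit$rmsea_ci_high <- ci[[2L]]
    } else {
      fit$rmsea <- fit$rmsea_ci_low <- fit$rmsea_ci_high <- NA_real_
    }
  }
  fit
}

default_start <- function(spec, g, fm, S) {
  pt <- spec$ptable[fm$ptable_rows, , drop = FALSE]
  st <- numeric(nrow(pt))
  for (k in seq_len(nrow(pt))) {
    st[k] <- switch(pt$role[k],
      loading = 0.7 * sqrt(S[pt$row[k], pt$row[k]]),
      residual_variance = 0.5 * S[pt$row[k], pt$row[k]],
      0)
  }
  st
}

#' @export
print.cfa_fit <- function(x, digits = 3L, ...) {
  cat("Multigroup CFA fit (maximum likelihood)\n")
  cat(sprintf("  groups: %d   N = %d\n", x$moments$G, x$moments$N))
  cat(sprintf("  chi-square(%d) = %.2f, p = %s\n", x$df, x$T,
              format.pval(x$p_value, digits = 2L)))
  if (!is.null(x$cfi))
    cat(sprintf("  CFI = %.3f   RMSEA = %.3f, 90%% CI [%.3f, %.3f]\n",
                x$cfi, x$rmsea, x$rmsea_ci_low, x$rmsea_ci_high))
  if (!x$converged) cat("  WARNING: not all groups converged\n")
  if (any(x$heywood))
    cat("  note: negative residual variance (Heywood case) in group(s) ",
        paste(which(x$heywood), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Likelihood-ratio comparison of nested fits
#'
#' `Delta chi-square = T_0 - T_1` with `Delta df = df_0 - df_1`, referred to
#' a central chi-square distribution.  The restricted model's free-parameter
#' set must be a subset of the full model's, and both fits must use the same
#' moments.
#'
#' @param fit_restricted,fit_full `cfa_fit` objects.
#' @return list with `chisq_diff`, `df_diff`, `p_value`.
#' @export
lrt_compare <- function(fit_restricted, fit_full) {
  f0 <- fit_restricted; f1 <- fit_full
  stopifnot(inherits(f0, "cfa_fit"), inherits(f1, "cfa_fit"))
  same <- isTRUE(all.equal(f0$moments$S, f1$moments$S, tolerance = 1e-12)) &&
    identical(f0$moments$n, f1$moments$n)
  if (!same) stop("fits do not share the same sample moments")
  key <- function(f) with(f$spec$ptable, paste(role, row, col, group)[free])
  if (!all(key(f0) %in% key(f1)))
    stop("models are not nested: restricted free set is not a subset")
  dchi <- max(f0$T - f1$T, 0)
  ddf <- f0$df - f1$df
  if (ddf < 0) stop("restricted model has fewer df than the full model")
  list(chisq_diff = dchi, df_diff = ddf,
       p_value = if (ddf > 0) stats::pchisq(dchi, ddf, lower.tail = FALSE)
                 else 1)
}

# Warm-start helper: per-group start vectors taken from a previous fit of the
# same spec (used heavily by the permutation and Monte Carlo loops).
start_from_fit <- function(fit) {
  lapply(fit$group_fits, function(z) as.numeric(z$theta))
}
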