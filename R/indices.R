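#' Independence baseline fit
#'
#' The per-group independence model (all covariances zero, variances free)
#' used as the CFI baseline.  It has the closed-form solution
#' `Sigma_g = diag(S_g)`, so its statistic needs no iteration:
#' `T_b = sum_g n_g [log|diag(S_g)| - log|S_g|]` with
#' `df_b = G p(p-1)/2`.
#'
#' @param moments a `cfa_moments`.
#' @return list with `T`, `df`, `F_min`.
#' @export
baseline_fit <- function(moments) {
  stopifnot(inherits(moments, "cfa_moments"))
  Fg <- vapply(moments$S, function(S) {
    sum(log(diag(S))) - as.numeric(determinant(S, logarithm = TRUE)$modulus)
  }, numeric(1L))
  p <- length(moments$variables)
  list(T = sum(moments$n * Fg), df = moments$G * p * (p - 1L) / 2L,
       F_min = sum(moments$n / moments$N * Fg))
}

#' Comparative fit index
#'
#' Bentler's CFI, `1 - max(T - df, 0) / max(T - df, T_b - df_b, 0)`,
#' comparing the target model's excess noncentrality to that of the
#' independence baseline fitted to the same moments.
#'
#' @param fit a `cfa_fit`.
#' @param baseline result of [baseline_fit()] on the same moments; computed
#'   if omitted.
#' @return value in `[0, 1]`.
#' @export
cfi <- function(fit, baseline = NULL) {
  stopifnot(inherits(fit, "cfa_fit"))
  if (is.null(baseline)) baseline <- baseline_fit(fit$moments)
  num <- max(fit$T - fit$df, 0)
  den <- max(fit$T - fit$df, baseline$T - baseline$df, 0)
  if (den == 0) return(1)
  1 - num / den
}

#' Root mean-squared error of approximation (multigroup)
#'
#' Point estimate `sqrt(G) sqrt(max(T - df, 0) / (df N))`, i.e. noncentrality
#' per degree of freedom per observation with the `sqrt(G)` multigroup
#' multiplier; zero whenever `T <= df`.
#'
#' @param fit a `cfa_fit`, or a list/stat set; see [rmsea_stat()] for the
#'   plain-number interface.
#' @return nonnegative scalar.
#' @export
rmsea <- function(fit) {
  stopifnot(inherits(fit, "cfa_fit"))
  rmsea_stat(fit$T, fit$df, fit$moments$N, fit$moments$G)
}

#' @rdname rmsea
#' @param T,df,N,G chi-square statistic, model degrees of freedom, total
#'   sample size and number of groups.
#' @export
rmsea_stat <- function(T, df, N, G = 1) {
  if (df <= 0) stop("RMSEA is undefined for df = 0")
  sqrt(G) * sqrt(max(T - df, 0) / (df * N))
}

#' RMSEA confidence interval
#'
#' Confidence limits obtained by inverting the noncentral chi-square
#' distribution: the lower (upper) bound's noncentrality `lambda` solves
#' `P[chisq(df, lambda) <= T] = 1 - (1-level)/2` (resp. `(1-level)/2`),
#' clamped at zero, then mapped through
#' `sqrt(G) sqrt(lambda / (df N))`.
#'
#' @param fit a `cfa_fit`.
#' @param level confidence level (default 0.90).
#' @return list with `lower` and `upper`.
#' @export
rmsea_ci <- function(fit, level = 0.90) {
  stopifnot(inherits(fit, "cfa_fit"))
  rmsea_ci_stat(fit$T, fit$df, fit$moments$N, fit$moments$G, level)
}

#' @rdname rmsea_ci
#' @inheritParams rmsea_stat
#' @export
rmsea_ci_stat <- function(T, df, N, G = 1, level = 0.90) {
  if (df <= 0) stop("RMSEA is undefined for df = 0")
  tail <- (1 - level) / 2
  lam_low <- invert_ncp(T, df, 1 - tail)
  lam_high <- invert_ncp(T, df, tail)
  list(lower = sqrt(G) * sqrt(lam_low / (df * N)),
       upper = sqrt(G) * sqrt(lam_high / (df * N)))
}

# Find lambda >= 0 with pchisq(T, df, ncp = lambda) = target, by bisection;
# returns 0 when even lambda = 0 gives a CDF below the target (clamped bound).
invert_ncp <- function(T, df, target, tol = 1e-8) {
  if (stats::pchisq(T, df, ncp = 0) <= target) return(0)
  lo <- 0
  hi <- max(T * 10, df + 10)
  while (stats::pchisq(T, df, ncp = hi) > target) hi <- hi * 2
  while (hi - lo > tol * (1 + hi)) {
    mid <- (lo + hi) / 2
    if (stats::pchisq(T, df, ncp = mid) > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
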