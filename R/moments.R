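#' Per-group sample moments from raw data
#'
#' Splits a data frame by a group column and computes each group's sample
#' covariance matrix with divisor *n* (the maximum-likelihood convention used
#' by the fitting function).  Group order is the order of first appearance in
#' the data, and is recorded in the result.
#'
#' @param data a data frame with numeric indicator columns and one group
#'   column.  Listwise-complete input is required.
#' @param group name of the group column.
#' @param variables optional character vector selecting/ordering the
#'   indicator columns; defaults to all non-group columns.
#' @return a `cfa_moments` object: list with `S` (list of covariance
#'   matrices), `n` (group sizes), `variables`, `groups` (labels), `G`, `N`.
#' @export
sample_moments <- function(data, group, variables = NULL) {
  if (!group %in% names(data)) stop("no such group column: ", group)
  if (is.null(variables)) variables <- setdiff(names(data), group)
  if (!all(variables %in% names(data)))
    stop("unknown variable(s): ",
         paste(setdiff(variables, names(data)), collapse = ", "))
  X <- data[, variables, drop = FALSE]
  if (!all(vapply(X, is.numeric, logical(1L))))
    stop("all indicator columns must be numeric")
  if (anyNA(X) || anyNA(data[[group]]))
    stop("missing values present; supply listwise-complete data")
  labels <- as.character(unique(data[[group]]))
  S <- vector("list", length(labels))
  n <- integer(length(labels))
  for (g in seq_along(labels)) {
    Xg <- as.matrix(X[as.character(data[[group]]) == labels[g], , drop = FALSE])
    n[g] <- nrow(Xg)
    if (n[g] < 2L) stop("group '", labels[g], "' has fewer than 2 rows")
    Sg <- stats::cov(Xg) * (n[g] - 1) / n[g]
    if (!all(is.finite(Sg)) ||
        min(eigen(Sg, symmetric = TRUE, only.values = TRUE)$values) <= 1e-12)
      stop("singular sample covariance in group '", labels[g],
           "' (constant or collinear column?)")
    S[[g]] <- Sg
  }
  group_moments(S, n, variables = variables, groups = labels)
}

#' Assemble group moments from covariance matrices
#'
#' First-class input path for population-level fits: supply per-group
#' covariance matrices and nominal sample sizes directly.
#'
#' @param S list of symmetric p x p covariance matrices, one per group.
#' @param n integer vector of sample sizes, one per group.
#' @param variables indicator names; defaults to the dimnames of `S[[1]]` or
#'   `v1..vp`.
#' @param groups group labels.
#' @return a `cfa_moments` object.
#' @export
group_moments <- function(S, n, variables = NULL, groups = NULL) {
  if (is.matrix(S)) S <- list(S)
  if (length(S) != length(n)) stop("`S` and `n` lengths differ")
  p <- nrow(S[[1L]])
  for (Sg in S) {
    if (!is.matrix(Sg) || nrow(Sg) != p || ncol(Sg) != p)
      stop("covariance matrices must all be p x p")
    if (max(abs(Sg - t(Sg))) > 1e-8) stop("covariance matrix not symmetric")
  }
  if (is.null(variables))
    variables <- colnames(S[[1L]]) %||% paste0("v", seq_len(p))
  if (is.null(groups)) groups <- paste0("g", seq_along(S))
  S <- lapply(S, function(Sg) {
    Sg <- (Sg + t(Sg)) / 2
    dimnames(Sg) <- list(variables, variables)
    Sg
  })
  structure(list(S = S, n = as.integer(n), variables = variables,
                 groups = as.character(groups),
                 G = length(S), N = as.integer(sum(n))),
            class = "cfa_moments")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cfa_moments <- function(x, ...) {
  cat(sprintf("Sample moments: %d group(s), %d variables, N = %d\n",
              x$G, length(x$variables), x$N))
  cat("  n:", paste(sprintf("%s = %d", x$groups, x$n), collapse = ", "), "\n")
  invisible(x)
}

# Align moments to the spec's indicator ordering.
align_moments <- function(spec, moments) {
  if (!setequal(moments$variables, spec$indicators))
    stop("moment variables do not match the model's indicators")
  if (!identical(moments$variables, spec$indicators)) {
    ord <- match(spec$indicators, moments$variables)
    moments$S <- lapply(moments$S, function(Sg) Sg[ord, ord, drop = FALSE])
    moments$variables <- spec$indicators
  }
  if (moments$G != spec$n_groups)
    stop("model has ", spec$n_groups, " group(s) but moments have ", moments$G)
  moments
}
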