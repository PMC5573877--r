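#' Gradient and expected information over free plus candidate parameters
#'
#' Evaluates, at the fitted estimates of one group, the gradient of the ML
#' discrepancy and the expected (Fisher) information matrix over the union of
#' the group's free parameters and the candidate fixed-to-zero constraints.
#' Because no parameter enters more than one group's implied covariance, the
#' full-model information is block-diagonal across groups; this function
#' returns one group's block.
#'
#' @param fit a converged `cfa_fit`.
#' @param group group index.
#' @param candidates candidate identities as returned by
#'   [candidate_constraints()]; defaults to all of them.
#' @return list with `gradient` (length `q_free + q_cand`), `information`
#'   (square matrix in the same order), `n_free`, and the candidate labels.
#' @export
extended_score_info <- function(fit, group, candidates = NULL) {
  stopifnot(inherits(fit, "cfa_fit"))
  if (!fit$group_fits[[group]]$converged)
    stop("group ", group, " fit did not converge; score tests need an MLE")
  spec <- fit$spec
  if (is.null(candidates)) candidates <- candidate_constraints(spec)
  fm <- free_map(spec, group)
  mat_id <- c(loading = 1L, residual_covariance = 2L)[candidates$role]
  cand_map <- cbind(mat_id, candidates$row - 1L, candidates$col - 1L)
  gf <- fit$group_fits[[group]]
  si <- cfa_score_info_cpp(fit$moments$S[[group]], gf$Lambda, gf$Theta,
                           gf$Psi, rbind(fm$map, cand_map))
  list(gradient = as.numeric(si$gradient), information = si$information,
       n_free = nrow(fm$map), labels = candidates$label)
}

# Per-group score pieces for every candidate: score s_a, conditional
# information h_a (both on the per-group discrepancy scale), MI and EPC.
group_score_pieces <- function(fit, group, candidates) {
  si <- extended_score_info(fit, group, candidates)
  qf <- si$n_free
  qc <- length(si$labels)
  H <- si$information
  iF <- seq_len(qf)
  iC <- qf + seq_len(qc)
  HFF <- H[iF, iF, drop = FALSE]
  HFC <- H[iF, iC, drop = FALSE]
  W <- tryCatch(solve(HFF, HFC), error = function(e) NULL)
  if (is.null(W))
    stop("information over the free parameters is singular in group ", group)
  v <- diag(H[iC, iC, drop = FALSE]) - colSums(HFC * W)
  s <- si$gradient[iC]
  bad <- !is.finite(v) | v <= 1e-12
  if (any(bad))
    warning("singular conditioned information for candidate(s) ",
            paste(si$labels[bad], collapse = ", "), " in group ", group,
            "; their modification indices are undefined")
  n_g <- fit$moments$n[group]
  mi <- ifelse(bad, NA_real_, (n_g / 2) * s^2 / v)
  epc <- ifelse(bad, NA_real_, -s / v)
  list(mi = mi, epc = epc, s = s, v = v)
}

#' Modification indices (score / Lagrange multiplier tests)
#'
#' Univariate 1-df modification indices estimate the chi-square drop from
#' freeing one fixed-to-zero parameter in one group; multivariate G-df
#' indices test freeing the *same* parameter simultaneously in all groups
#' (the respecification move consistent with configural invariance).  Both
#' use the expected information evaluated at the constrained MLE; the
#' multivariate statistic is the quadratic form of the stacked per-group
#' scores in their conditional covariance, which is block-diagonal across
#' groups, so it equals the sum of the per-group univariate indices.
#'
#' Univariate rows also carry the expected parameter change (EPC: the value
#' the parameter is predicted to take if freed) and its completely
#' standardized form (SEPC; see [sepc()]).
#'
#' @param fit a converged `cfa_fit`.
#' @param type `"multivariate"` (one row per candidate identity, df = G) or
#'   `"univariate"` (one row per candidate x group, df = 1).
#' @param candidates optional subset of [candidate_constraints()] rows.
#' @return a `cfa_scoretable` data frame sorted by decreasing MI, ties
#'   broken by the canonical candidate order.
#' @examples
#' pop <- study_population()
#' fit <- cfa_fit(configural_spec(pop), population_moments(pop, 100))
#' head(mod_indices(fit), 3)  # the two omitted residual covariances lead
#' @export
mod_indices <- function(fit, type = c("multivariate", "univariate"),
                        candidates = NULL) {
  type <- match.arg(type)
  stopifnot(inherits(fit, "cfa_fit"))
  spec <- fit$spec
  if (is.null(candidates)) candidates <- candidate_constraints(spec)
  if (nrow(candidates) == 0L) {
    out <- data.frame(label = character(), group = character(),
                      mi = numeric(), df = integer(), p_value = numeric(),
                      epc = numeric(), sepc = numeric())
    class(out) <- c("cfa_scoretable", class(out))
    return(out)
  }
  G <- spec$n_groups
  pieces <- lapply(seq_len(G), group_score_pieces, fit = fit,
                   candidates = candidates)
  if (type == "univariate") {
    out <- do.call(rbind, lapply(seq_len(G), function(g) {
      epc <- pieces[[g]]$epc
      data.frame(label = candidates$label,
                 group = fit$moments$groups[g],
                 mi = pieces[[g]]$mi, df = 1L,
                 p_value = stats::pchisq(pieces[[g]]$mi, 1L,
                                         lower.tail = FALSE),
                 epc = epc,
                 sepc = sepc(epc, fit, candidates, group = g),
                 canon = seq_len(nrow(candidates)),
                 stringsAsFactors = FALSE)
    }))
  } else {
    mi <- rowSums(do.call(cbind, lapply(pieces, `[[`, "mi")))
    out <- data.frame(label = candidates$label, group = "all",
                      mi = mi, df = G,
                      p_value = stats::pchisq(mi, G, lower.tail = FALSE),
                      epc = NA_real_, sepc = NA_real_,
                      canon = seq_len(nrow(candidates)),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(-out$mi, out$canon), , drop = FALSE]
  out$canon <- NULL
  rownames(out) <- NULL
  class(out) <- c("cfa_scoretable", class(out))
  out
}

#' @export
print.cfa_scoretable <- function(x, n = 10L, digits = 3L, ...) {
  cat("Modification indices (", if (all(x$group == "all")) "multivariate"
      else "univariate", ")\n", sep = "")
  y <- utils::head(as.data.frame(x), n)
  y$mi <- round(y$mi, digits)
  y$p_value <- signif(y$p_value, 2L)
  y$epc <- round(y$epc, digits)
  y$sepc <- round(y$sepc, digits)
  print(y, row.names = FALSE)
  if (nrow(x) > n) cat("  ... ", nrow(x) - n, " more rows\n", sep = "")
  invisible(x)
}

#' Completely standardized expected parameter change
#'
#' Rescales a raw EPC to the metric of standardized indicators and unit
#' factor variances using the model-implied variances of the fitted model:
#' a loading EPC is multiplied by `sqrt(psi_kk) / sqrt(sigma_ii)` and a
#' residual-covariance EPC by `1 / sqrt(sigma_ii sigma_jj)`.
#'
#' @param epc numeric vector of raw EPCs.
#' @param fit the `cfa_fit` the EPCs came from.
#' @param ref candidate rows (`role`, `row`, `col`) matching `epc`.
#' @param group group index whose implied variances are used.
#' @return numeric vector of SEPCs (`NA` with a warning if an implied
#'   variance is nonpositive).
#' @export
sepc <- function(epc, fit, ref, group) {
  sig <- diag(fit$Sigma_hat[[group]])
  psi <- diag(fit$group_fits[[group]]$Psi)
  if (any(sig <= 0)) warning("nonpositive implied indicator variance; ",
                             "SEPC undefined for affected parameters")
  out <- numeric(length(epc))
  for (k in seq_along(epc)) {
    out[k] <- if (ref$role[k] == "loading") {
      if (sig[ref$row[k]] <= 0) NA_real_
      else epc[k] * sqrt(psi[ref$col[k]]) / sqrt(sig[ref$row[k]])
    } else {
      if (sig[ref$row[k]] <= 0 || sig[ref$col[k]] <= 0) NA_real_
      else epc[k] / sqrt(sig[ref$row[k]] * sig[ref$col[k]])
    }
  }
  out
}

#' Largest significant modification index under a familywise correction
#'
#' Returns the highest-MI row of a score table whose p-value falls below
#' `alpha_family / n_tests` (Bonferroni), or `NULL` when none does.  The
#' table is already sorted with canonical-order tie-breaking, so the first
#' qualifying row is returned deterministically.
#'
#' @param table a `cfa_scoretable`.
#' @param alpha_family familywise alpha (default 0.05).
#' @param n_tests Bonferroni denominator; defaults to the number of rows of
#'   `table` (for iterative modification loops this is the *initial* candidate
#'   count, so pass it explicitly when iterating on a shrinking table).
#' @return a one-row data frame, or `NULL`.
#' @export
largest_significant <- function(table, alpha_family = 0.05,
                                n_tests = nrow(table)) {
  if (nrow(table) == 0L) return(NULL)
  ok <- which(!is.na(table$p_value) &
                table$p_value < alpha_family / n_tests)
  if (length(ok) == 0L) return(NULL)
  as.data.frame(table[ok[1L], , drop = FALSE])
}
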