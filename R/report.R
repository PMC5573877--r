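#' Write a JSON analysis report
#'
#' Serialises a fitted object (`cfa_fit`, `cfa_permutation`,
#' `cfa_scoretable` or `cfa_simulation`) to JSON with a schema version, the
#' seed (when the object carries one), an input fingerprint, all statistics
#' at full precision, and 2-decimal display strings for the headline
#' numbers.  Reports are deterministic: the same object writes byte-identical
#' files.
#'
#' @param x object to report.
#' @param path output file path.
#' @param seed seed to record (overrides any stored in `x`).
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, seed = NULL) {
  rep <- report_body(x)
  rep <- c(list(schema_version = "1.0",
                generator = "permcfa",
                seed = seed %||% rep$seed %||% NA,
                input_md5 = object_md5(x)),
           rep[setdiff(names(rep), "seed")])
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read back a report written by [write_report()]
#' @param path report path.
#' @return the parsed list.
#' @export
read_report <- function(path) jsonlite::read_json(path)

report_body <- function(x) UseMethod("report_body")

#' @export
report_body.cfa_fit <- function(x) {
  est <- x$estimates[x$estimates$free, c("label", "group", "est")]
  list(kind = "fit",
       T = x$T, df = x$df, p = x$p_value,
       cfi = x$cfi, rmsea = x$rmsea,
       rmsea_ci = c(x$rmsea_ci_low, x$rmsea_ci_high),
       display = list(T = sprintf("%.2f", x$T),
                      cfi = sprintf("%.2f", x$cfi %||% NA_real_),
                      rmsea = sprintf("%.2f", x$rmsea %||% NA_real_)),
       n = x$moments$n, groups = x$moments$groups,
       convergence = list(converged = x$converged,
                          iterations = x$iterations,
                          max_grad = x$max_grad,
                          heywood = x$heywood),
       estimates = est)
}

#' @export
report_body.cfa_permutation <- function(x) {
  list(kind = "permutation",
       B = x$B, n_failed = x$n_failed, seed = x$seed,
       pvalue_convention = x$pvalue,
       observed = x$observed, p_values = x$p_values,
       display = lapply(x$p_values, function(p) sprintf("%.2f", p)))
}

#' @export
report_body.cfa_scoretable <- function(x) {
  list(kind = "modification_indices", table = as.data.frame(x))
}

#' @export
report_body.cfa_simulation <- function(x) {
  list(kind = "simulation",
       seed = x$design$seed,
       reps = x$reps_used, n_nonconverged = x$n_nonconverged,
       n_per_group = x$design$n_per_group,
       B_perm = x$design$B_perm,
       rates = x$rates,
       display = lapply(x$rates, function(r)
         if (is.na(r)) NA else sprintf("%.1f%%", 100 * r)))
}

# md5 fingerprint of an arbitrary R object (via a temporary serialisation).
object_md5 <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  con <- file(tf, "wb")
  serialize(x, con, version = 2L)
  close(con)
  unname(tools::md5sum(tf))
}
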