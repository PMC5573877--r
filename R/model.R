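#' Build a configural multigroup CFA specification
#'
#' Constructs the parameter table of a simple-structure confirmatory factor
#' model replicated over `n_groups` groups with no cross-group equality
#' constraints (the *configural* model).  Each group gets its own free
#' on-target loadings, residual variances and factor covariances; all
#' cross-loadings and residual covariances are fixed to zero, and factor
#' variances are fixed to 1 for identification, so every loading is estimated.
#'
#' @param factor_map named list mapping each factor name to the character
#'   vector of its indicator names.  An indicator may appear under only one
#'   factor here; cross-loadings are freed afterwards with
#'   [free_parameters()].
#' @param n_groups number of groups (>= 1).
#' @return an object of class `cfa_spec`: a list with the indicator/factor
#'   bookkeeping and a parameter table `ptable` (one row per parameter per
#'   group) with columns `role`, `row`, `col`, `group`, `free`, `value`,
#'   `label`.
#' @examples
#' spec <- build_configural_spec(
#'   list(visual = c("x1", "x2", "x3"), textual = c("x4", "x5", "x6"),
#'        speed = c("x7", "x8", "x9")), n_groups = 2)
#' model_df(spec)  # 48
#' @export
build_configural_spec <- function(factor_map, n_groups = 1L) {
  if (!is.list(factor_map) || is.null(names(factor_map)) ||
      any(!nzchar(names(factor_map))))
    stop("`factor_map` must be a named list of indicator vectors")
  if (anyDuplicated(names(factor_map)))
    stop("duplicate factor names in `factor_map`")
  if (any(lengths(factor_map) < 1L))
    stop("every factor needs at least one indicator")
  indicators <- unlist(factor_map, use.names = FALSE)
  if (anyDuplicated(indicators))
    stop("indicator assigned to two factors: ",
         paste(unique(indicators[duplicated(indicators)]), collapse = ", "))
  n_groups <- as.integer(n_groups)
  if (n_groups < 1L) stop("`n_groups` must be >= 1")

  factors <- names(factor_map)
  p <- length(indicators)
  m <- length(factors)
  on_target <- match(rep(factors, lengths(factor_map)), factors)

  one_group <- function(g) {
    lam <- expand.grid(row = seq_len(p), col = seq_len(m))
    lam <- lam[order(lam$row, lam$col), , drop = FALSE]
    lam_free <- on_target[lam$row] == lam$col
    th <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
    th <- th[order(th[, "row"], th[, "col"]), , drop = FALSE]
    ps <- which(upper.tri(diag(m), diag = TRUE), arr.ind = TRUE)
    ps <- ps[order(ps[, "row"], ps[, "col"]), , drop = FALSE]
    data.frame(
      role = c(rep("loading", nrow(lam)),
               ifelse(th[, "row"] == th[, "col"],
                      "residual_variance", "residual_covariance"),
               ifelse(ps[, "row"] == ps[, "col"],
                      "factor_variance", "factor_covariance")),
      row = c(lam$row, th[, "row"], ps[, "row"]),
      col = c(lam$col, th[, "col"], ps[, "col"]),
      group = g,
      free = c(lam_free,
               th[, "row"] == th[, "col"],
               ps[, "row"] != ps[, "col"]),
      value = c(ifelse(lam_free, NA_real_, 0),
                ifelse(th[, "row"] == th[, "col"], NA_real_, 0),
                ifelse(ps[, "row"] != ps[, "col"], NA_real_, 1)),
      stringsAsFactors = FALSE)
  }
  ptable <- do.call(rbind, lapply(seq_len(n_groups), one_group))
  rownames(ptable) <- NULL

  spec <- structure(
    list(factor_map = factor_map, factors = factors,
         indicators = indicators, p = p, m = m,
         n_groups = n_groups, ptable = ptable),
    class = "cfa_spec")
  spec$ptable$label <- param_label(spec, ptable$role, ptable$row, ptable$col)
  spec
}

#' @export
print.cfa_spec <- function(x, ...) {
  cat("Multigroup CFA specification\n")
  cat(sprintf("  %d indicators, %d factor(s), %d group(s)\n", x$p, x$m, x$n_groups))
  cat(sprintf("  free parameters: %d (%d per group)   df: %d\n",
              sum(x$ptable$free), sum(x$ptable$free) / x$n_groups,
              model_df(x)))
  invisible(x)
}

# lavaan-style labels: "visual=~x1", "x1~~x4", "visual~~textual"
param_label <- function(spec, role, row, col) {
  ifelse(role == "loading",
         paste0(spec$factors[col], "=~", spec$indicators[row]),
  ifelse(role %in% c("residual_variance", "residual_covariance"),
         paste0(spec$indicators[row], "~~", spec$indicators[col]),
         paste0(spec$factors[row], "~~", spec$factors[col])))
}

#' Model degrees of freedom
#'
#' Total degrees of freedom: `sum_g [p(p+1)/2 - (free parameters in g)]`.
#'
#' @param spec a `cfa_spec`.
#' @return integer degrees of freedom.
#' @export
model_df <- function(spec) {
  stopifnot(inherits(spec, "cfa_spec"))
  moments_per_group <- spec$p * (spec$p + 1L) / 2L
  free_g <- tabulate(spec$ptable$group[spec$ptable$free], spec$n_groups)
  as.integer(sum(moments_per_group - free_g))
}

#' Model-implied covariance matrix for one group
#'
#' Computes `Sigma = Lambda Psi Lambda' + Theta` from the numeric parameter
#' values stored in the specification (free parameters must carry values,
#' e.g. in a population model or a fitted parameter table).
#'
#' @param spec a `cfa_spec` whose `ptable$value` column is complete for
#'   `group`, or a `cfa_population`.
#' @param group group index.
#' @return a symmetric p x p matrix with dimnames from the indicator names.
#' @export
implied_covariance <- function(spec, group = 1L) {
  mats <- spec_matrices(spec, group, require_values = TRUE)
  Sig <- mats$Lambda %*% mats$Psi %*% t(mats$Lambda) + mats$Theta
  Sig <- (Sig + t(Sig)) / 2
  dimnames(Sig) <- list(spec$indicators, spec$indicators)
  Sig
}

# Assemble Lambda/Theta/Psi for one group from ptable values.  Free entries
# lacking values are set to `fill` unless values are required.
spec_matrices <- function(spec, group, require_values = FALSE, fill = 0) {
  pt <- spec$ptable[spec$ptable$group == group, , drop = FALSE]
  if (nrow(pt) == 0L) stop("no such group: ", group)
  v <- pt$value
  if (require_values && anyNA(v))
    stop("missing parameter value(s) for group ", group, ": ",
         paste(pt$label[is.na(v)], collapse = ", "))
  v[is.na(v)] <- fill
  L <- matrix(0, spec$p, spec$m)
  Th <- matrix(0, spec$p, spec$p)
  Ps <- matrix(0, spec$m, spec$m)
  for (k in seq_len(nrow(pt))) {
    if (pt$role[k] == "loading") {
      L[pt$row[k], pt$col[k]] <- v[k]
    } else if (pt$role[k] %in% c("residual_variance", "residual_covariance")) {
      Th[pt$row[k], pt$col[k]] <- v[k]
      Th[pt$col[k], pt$row[k]] <- v[k]
    } else {
      Ps[pt$row[k], pt$col[k]] <- v[k]
      Ps[pt$col[k], pt$row[k]] <- v[k]
    }
  }
  list(Lambda = L, Theta = Th, Psi = Ps)
}

#' Candidate fixed-to-zero constraints of a configural model
#'
#' Lists every cross-loading and residual covariance fixed to zero, i.e. the
#' constraints eligible for score-test modification indices.  Factor
#' (co)variances and fixed unit factor variances are never candidates.  The
#' order is canonical and deterministic: cross-loadings first (by indicator,
#' then factor), then residual covariances (by row, then column); ties in
#' modification-index tables are broken by this order.
#'
#' @param spec a `cfa_spec`.
#' @return a data frame with one row per candidate *identity* (group-agnostic)
#'   and columns `role`, `row`, `col`, `label`.  Each identity expands to one
#'   univariate candidate per group.
#' @export
candidate_constraints <- function(spec) {
  pt <- spec$ptable
  cand <- pt[pt$group == 1L & !pt$free &
               ((pt$role == "loading" & pt$value == 0) |
                (pt$role == "residual_covariance" & pt$value == 0)), ,
             drop = FALSE]
  # verify the same pattern holds in every group (configural structure)
  if (spec$n_groups > 1L) {
    key <- paste(pt$role, pt$row, pt$col)
    for (g in seq_len(spec$n_groups)[-1L]) {
      ptg <- pt[pt$group == g, ]
      if (!identical(pt$free[pt$group == 1L][order(key[pt$group == 1L])],
                     ptg$free[order(paste(ptg$role, ptg$row, ptg$col))]))
        stop("free/fixed pattern differs across groups; not a configural model")
    }
  }
  is_load <- cand$role == "loading"
  cand <- rbind(cand[is_load, ][order(cand$row[is_load], cand$col[is_load]), ],
                cand[!is_load, ][order(cand$row[!is_load], cand$col[!is_load]), ])
  rownames(cand) <- NULL
  cand[, c("role", "row", "col", "label")]
}

#' Free fixed parameters in a specification
#'
#' Returns a new specification in which the given candidate constraint is
#' freed, by default simultaneously in all groups (the respecification move
#' tested by a multivariate modification index).
#'
#' @param spec a `cfa_spec`.
#' @param ref a candidate: either a label such as `"visual=~x9"` /
#'   `"x7~~x8"`, or a one-row data frame with `role`, `row`, `col`.
#' @param groups integer vector of group indices, or `"all"` (default).
#' @return the modified `cfa_spec`; its [model_df()] drops by
#'   `length(groups)`.
#' @export
free_parameters <- function(spec, ref, groups = "all") {
  stopifnot(inherits(spec, "cfa_spec"))
  if (identical(groups, "all")) groups <- seq_len(spec$n_groups)
  groups <- as.integer(groups)
  pt <- spec$ptable
  eligible <- pt$role %in% c("loading", "residual_covariance")
  if (is.character(ref)) {
    hit <- which(pt$label == ref & eligible & pt$group == 1L)
    if (length(hit) != 1L)
      stop("`ref` is not a fixed-to-zero candidate constraint: ", ref)
    ref <- pt[hit, c("role", "row", "col")]
  } else {
    ok <- any(pt$role == ref$role & pt$row == ref$row & pt$col == ref$col &
                eligible)
    if (!ok) stop("`ref` is not a fixed-to-zero candidate constraint: ",
                  ref$role, "(", ref$row, ",", ref$col, ")")
  }
  idx <- with(spec$ptable,
              which(role == ref$role & row == ref$row & col == ref$col &
                    group %in% groups))
  if (length(idx) != length(groups))
    stop("constraint not present in all requested groups")
  if (any(spec$ptable$free[idx]))
    stop("parameter already free in group(s) ",
         paste(spec$ptable$group[idx][spec$ptable$free[idx]], collapse = ", "),
         ": ", spec$ptable$label[idx[1L]])
  spec$ptable$free[idx] <- TRUE
  spec$ptable$value[idx] <- NA_real_
  spec
}

#' Parse a plain-text factor model
#'
#' Minimal lavaan-flavoured model syntax:
#' \itemize{
#'   \item `factor =~ ind1 + ind2 + ...` defines a factor and its indicators;
#'   \item repeating an indicator under a second factor frees that
#'     cross-loading (in all groups);
#'   \item `a ~~ b` frees the residual covariance between indicators `a` and
#'     `b` (in all groups);
#'   \item `#` starts a comment; blank lines are ignored.  Names are
#'     case-sensitive.
#' }
#'
#' @param text model syntax as a single string (may contain newlines) or a
#'   character vector of lines.
#' @param n_groups number of groups for the resulting configural spec.
#' @return a `cfa_spec`.
#' @examples
#' spec <- parse_model("
#'   visual  =~ x1 + x2 + x3
#'   textual =~ x4 + x5 + x6
#'   speed   =~ x7 + x8 + x9", n_groups = 2)
#' @export
parse_model <- function(text, n_groups = 1L) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  factor_map <- list()
  cross <- list()   # (factor, indicator) cross-loadings to free
  rescov <- list()  # (a, b) residual covariances to free
  tok <- "[A-Za-z._][A-Za-z0-9._]*"
  any_content <- FALSE
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    any_content <- TRUE
    if (grepl("=~", ln, fixed = TRUE)) {
      parts <- strsplit(ln, "=~", fixed = TRUE)[[1L]]
      if (length(parts) != 2L)
        stop("line ", i, ": malformed factor definition")
      fac <- trimws(parts[1L])
      if (!grepl(paste0("^", tok, "$"), fac))
        stop("line ", i, ": invalid factor name '", fac, "'")
      inds <- trimws(strsplit(parts[2L], "+", fixed = TRUE)[[1L]])
      if (length(inds) == 0L || any(!grepl(paste0("^", tok, "$"), inds)))
        stop("line ", i, ": invalid indicator list")
      if (fac %in% names(factor_map))
        stop("line ", i, ": duplicate factor '", fac, "'")
      new <- setdiff(inds, unlist(factor_map))
      dup <- setdiff(inds, new)
      factor_map[[fac]] <- new
      for (d in dup) cross[[length(cross) + 1L]] <- c(fac, d)
      if (length(new) == 0L)
        stop("line ", i, ": factor '", fac, "' has no indicator of its own")
    } else if (grepl("~~", ln, fixed = TRUE)) {
      parts <- trimws(strsplit(ln, "~~", fixed = TRUE)[[1L]])
      if (length(parts) != 2L || any(!grepl(paste0("^", tok, "$"), parts)))
        stop("line ", i, ": malformed covariance line")
      rescov[[length(rescov) + 1L]] <- parts
    } else {
      stop("line ", i, ": unrecognised syntax: '", ln, "'")
    }
  }
  if (!any_content) stop("empty model syntax")
  if (length(factor_map) == 0L) stop("model defines no factors")
  spec <- build_configural_spec(factor_map, n_groups)
  for (cl in cross) {
    fi <- match(cl[1L], spec$factors)
    ii <- match(cl[2L], spec$indicators)
    spec <- free_parameters(
      spec, data.frame(role = "loading", row = ii, col = fi))
  }
  for (rc in rescov) {
    ii <- match(rc, spec$indicators)
    if (anyNA(ii))
      stop("residual covariance names unknown: ", paste(rc, collapse = ", "))
    spec <- free_parameters(
      spec, data.frame(role = "residual_covariance",
                       row = min(ii), col = max(ii)))
  }
  spec
}

# Zero-based (mat, row, col) map of free parameters for one group, in ptable
# order, plus the matching ptable row indices.
free_map <- function(spec, group) {
  pt <- spec$ptable
  idx <- which(pt$group == group & pt$free)
  mat_id <- match(pt$role[idx],
                  c("loading", "residual_variance", "residual_covariance",
                    "factor_variance", "factor_covariance"))
  mat_id <- c(1L, 2L, 2L, 3L, 3L)[mat_id]
  list(map = cbind(mat_id, pt$row[idx] - 1L, pt$col[idx] - 1L),
       ptable_rows = idx)
}
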