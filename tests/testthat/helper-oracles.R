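# Brute-force oracles kept independent of the package's computational paths.

# implied covariance by explicit double summation over factors
oracle_implied <- function(L, Ps, Th) {
  p <- nrow(L); m <- ncol(L)
  Sig <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    s <- Th[i, j]
    for (k in seq_len(m)) for (l in seq_len(m))
      s <- s + L[i, k] * Ps[k, l] * L[j, l]
    Sig[i, j] <- s
  }
  Sig
}

# multigroup ML discrepancy from the determinant formula
oracle_fml <- function(S_list, Sig_list, n) {
  N <- sum(n)
  f <- 0
  for (g in seq_along(S_list)) {
    S <- S_list[[g]]; Sig <- Sig_list[[g]]
    f <- f + n[g] / N *
      (as.numeric(determinant(Sig)$modulus) -
         as.numeric(determinant(S)$modulus) +
         sum(diag(S %*% solve(Sig))) - nrow(S))
  }
  f
}

# divisor-n covariance by direct summation
oracle_cov_n <- function(X) {
  n <- nrow(X)
  xb <- colMeans(X)
  Xc <- sweep(X, 2, xb)
  crossprod(Xc) / n
}

# central finite-difference Hessian
fd_hessian <- function(f, x, h = 1e-4) {
  q <- length(x)
  H <- matrix(0, q, q)
  for (a in seq_len(q)) for (b in a:q) {
    ea <- eb <- numeric(q); ea[a] <- h; eb[b] <- h
    H[a, b] <- H[b, a] <-
      (f(x + ea + eb) - f(x + ea - eb) - f(x - ea + eb) + f(x - ea - eb)) /
      (4 * h * h)
  }
  H
}

hs_factor_map <- list(visual = c("x1", "x2", "x3"),
                      textual = c("x4", "x5", "x6"),
                      speed = c("x7", "x8", "x9"))

# a two-group version of the built-in population (still misspecified when
# fitted with the simple-structure configural model)
two_group_population <- function(factor_cor = c(0.3, 0.5), ...)
  study_population(factor_cor = factor_cor, ...)

# evaluate the multigroup discrepancy as a function of one group's free
# parameter vector, for finite-difference checks
group_objective <- function(spec, moments, group) {
  fm <- permcfa:::free_map(spec, group)
  function(theta) {
    sp <- spec
    sp$ptable$value[fm$ptable_rows] <- theta
    mats <- permcfa:::spec_matrices(sp, group, require_values = FALSE)
    oracle_fml(moments$S[group], list(oracle_implied(mats$Lambda, mats$Psi,
                                                     mats$Theta)),
               moments$n[group])
  }
}
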