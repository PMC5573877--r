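test_that("sample moments use divisor n and preserve group order", {
  d <- data.frame(v = c(0, 2), g = c("a", "a"))
  m <- sample_moments(rbind(d, data.frame(v = c(1, 3, 5), g = "b")), "g")
  expect_equal(unname(m$S[[1]]), matrix(1))   # divisor n, not n-1
  expect_equal(m$groups, c("a", "b"))
  expect_equal(m$n, c(2L, 3L))
  expect_equal(m$N, 5L)

  set.seed(7)
  X <- matrix(rnorm(150), 50, 3)
  d2 <- data.frame(X, g = rep(c("p", "q"), 25))
  m2 <- sample_moments(d2, "g")
  Xp <- X[rep(c(TRUE, FALSE), 25), ]
  expect_equal(m2$S[[1]], oracle_cov_n(Xp), ignore_attr = TRUE)
})

test_that("degenerate data is rejected with informative errors", {
  d <- data.frame(a = rnorm(10), b = 1, g = rep(c("x", "y"), 5))
  expect_error(sample_moments(d, "g"), "singular")
  d2 <- data.frame(a = c(NA, rnorm(9)), b = rnorm(10), g = rep(c("x", "y"), 5))
  expect_error(sample_moments(d2, "g"), "missing")
})

test_that("the ML discrepancy is zero at the truth and matches closed forms", {
  pop <- study_population()
  mom <- population_moments(pop, 100)
  expect_equal(fml_discrepancy(pop, mom), 0, tolerance = 1e-12)

  # diagonal S and diagonal implied: sum of weighted scalar discrepancies
  spec <- build_configural_spec(list(f = c("a", "b")), 1)
  spec$ptable$value[spec$ptable$free] <-
    c(0, 0, 0.8, 1.3)  # loadings zero, residual variances 0.8 / 1.3
  S <- diag(c(1.1, 0.9))
  mom2 <- group_moments(list(S), 30, variables = c("a", "b"))
  scalar <- function(s2, sig2) log(sig2) - log(s2) + s2 / sig2 - 1
  expect_equal(fml_discrepancy(spec, mom2),
               scalar(1.1, 0.8) + scalar(0.9, 1.3), tolerance = 1e-12)
})

test_that("a correctly specified model reproduces its population exactly", {
  pop <- study_population()
  spec <- configural_spec(pop)
  spec <- free_parameters(free_parameters(spec, "x1~~x4"), "x2~~x5")
  fit <- cfa_fit(spec, population_moments(pop, 100))
  expect_true(fit$converged)
  expect_equal(fit$df, 24)
  expect_lt(fit$T, 1e-4)
  # recovered parameter values equal the population values
  est <- fit$estimates
  truth <- pop$ptable
  for (k in which(est$free)) {
    hit <- truth$role == est$role[k] & truth$row == est$row[k] &
      truth$col == est$col[k] & truth$group == est$group[k]
    expect_equal(est$est[k], truth$value[hit], tolerance = 1e-4)
  }
})

test_that("the test statistic is invariant to indicator rescaling", {
  pop <- two_group_population()
  set.seed(11)
  dat <- draw_sample(pop, 150)
  spec <- configural_spec(pop)
  f1 <- cfa_fit(spec, data = dat, group = "group")
  dat2 <- dat
  dat2$x3 <- dat2$x3 * 7.3
  f2 <- cfa_fit(spec, data = dat2, group = "group")
  expect_equal(f1$T, f2$T, tolerance = 1e-6)
  expect_equal(f1$df, f2$df)
  expect_equal(f1$cfi, f2$cfi, tolerance = 1e-6)
})

test_that("freeing a parameter never increases the statistic", {
  pop <- two_group_population()
  set.seed(13)
  dat <- draw_sample(pop, 120)
  spec <- configural_spec(pop)
  mom <- sample_moments(dat, "group")
  f0 <- cfa_fit(spec, mom)
  for (lab in c("x1~~x4", "f2=~x1", "x3~~x6")) {
    f1 <- cfa_fit(free_parameters(spec, lab), mom)
    expect_gte(f0$T - f1$T, -1e-4)
  }
})

test_that("nested-model comparison behaves and rejects non-nested fits", {
  pop <- study_population()
  mom <- population_moments(pop, 100)
  spec <- configural_spec(pop)
  f0 <- cfa_fit(spec, mom)
  f1 <- cfa_fit(free_parameters(spec, "x1~~x4"), mom)
  cmp <- lrt_compare(f0, f1)
  expect_equal(cmp$df_diff, 4)
  expect_equal(cmp$chisq_diff, f0$T - f1$T)
  expect_lt(cmp$p_value, 1)

  same <- lrt_compare(f0, f0)
  expect_equal(same$chisq_diff, 0)
  expect_equal(same$df_diff, 0)
  expect_equal(same$p_value, 1)

  fa <- cfa_fit(free_parameters(spec, "x2~~x5"), mom)
  expect_error(lrt_compare(f1, fa), "not nested")
})

test_that("expected information matches a finite-difference Hessian at an exact fit", {
  # at F = 0 the expected and observed information coincide, so the
  # analytic expected information must equal the numerical Hessian
  pop <- two_group_population()
  spec <- configural_spec(pop)
  spec <- free_parameters(free_parameters(spec, "x1~~x4"), "x2~~x5")
  mom <- population_moments(pop, 200)
  fit <- cfa_fit(spec, mom)
  g <- 1
  gf <- fit$group_fits[[g]]
  fm <- permcfa:::free_map(spec, g)
  si <- permcfa:::cfa_score_info_cpp(mom$S[[g]], gf$Lambda, gf$Theta,
                                     gf$Psi, fm$map)
  # group_objective is the single-group discrepancy (unit weight), the same
  # scale as the exported per-group information
  H_fd <- fd_hessian(group_objective(fit$spec, mom, g),
                     as.numeric(gf$theta))
  expect_lt(max(abs(si$information - H_fd)) / max(abs(H_fd)), 1e-3)
})

test_that("fitting recovers population parameters from large samples", {
  pop <- two_group_population()
  spec <- configural_spec(pop)
  spec <- free_parameters(free_parameters(spec, "x1~~x4"), "x2~~x5")
  set.seed(17)
  dat <- draw_sample(pop, 1e5)
  fit <- cfa_fit(spec, data = dat, group = "group")
  expect_true(fit$converged)
  est <- fit$estimates
  truth <- pop$ptable
  for (k in which(est$free)) {
    hit <- truth$role == est$role[k] & truth$row == est$row[k] &
      truth$col == est$col[k] & truth$group == est$group[k]
    # loadings/covariances have asymptotic SE of order 1/sqrt(n); 3 SE at
    # n = 1e5 is well under 0.015 for every parameter of this model
    expect_lt(abs(est$est[k] - truth$value[hit]), 0.015)
  }
})
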