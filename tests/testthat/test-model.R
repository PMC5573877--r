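test_that("configural specs have the right free-parameter counts and df", {
  hs <- build_configural_spec(hs_factor_map, n_groups = 2)
  expect_equal(sum(hs$ptable$free), 2 * 21)
  expect_equal(model_df(hs), 48)

  sim <- build_configural_spec(list(f1 = c("x1", "x2", "x3"),
                                    f2 = c("x4", "x5", "x6")), 4)
  expect_equal(sum(sim$ptable$free) / 4, 13)
  expect_equal(model_df(sim), 32)

  just <- build_configural_spec(list(f = c("a", "b", "c")), 1)
  expect_equal(model_df(just), 0)

  single <- build_configural_spec(hs_factor_map, 1)
  expect_equal(model_df(single), 24)
})

test_that("malformed factor maps are rejected", {
  expect_error(build_configural_spec(list(f1 = c("a", "b"), f2 = c("b", "c")), 2),
               "two factors")
  expect_error(build_configural_spec(list(f1 = "a", f2 = character(0)), 1),
               "at least one indicator")
})

test_that("implied covariance matches a brute-force double-loop oracle", {
  set.seed(101)
  for (rep in 1:5) {
    spec <- build_configural_spec(hs_factor_map, 1)
    pt <- spec$ptable
    free <- which(pt$free)
    vals <- numeric(length(free))
    vals[pt$role[free] == "loading"] <- stats::runif(sum(pt$role[free] == "loading"), 0.3, 1)
    vals[pt$role[free] == "residual_variance"] <- stats::runif(sum(pt$role[free] == "residual_variance"), 0.2, 1.5)
    vals[pt$role[free] == "factor_covariance"] <- stats::runif(sum(pt$role[free] == "factor_covariance"), -0.4, 0.4)
    spec$ptable$value[free] <- vals
    mats <- permcfa:::spec_matrices(spec, 1, require_values = TRUE)
    expect_lt(max(abs(implied_covariance(spec, 1) -
                        oracle_implied(mats$Lambda, mats$Psi, mats$Theta))),
              1e-12)
  }
})

test_that("implied covariance of the study population is as constructed", {
  pop <- study_population()
  for (g in 1:4)
    expect_equal(unname(diag(implied_covariance(pop, g))), rep(1, 6))
  Sig1 <- implied_covariance(pop, 1)
  expect_equal(Sig1["x1", "x2"], 0.6 * 0.7)       # same factor
  expect_equal(Sig1["x1", "x4"], 0.6 * 0.6 * 0.2 + 0.2)  # cross + rescov
})

test_that("zero loadings reduce the implied covariance to Theta", {
  spec <- build_configural_spec(list(f = c("a", "b")), 1)
  spec$ptable$value[spec$ptable$free] <-
    ifelse(spec$ptable$role[spec$ptable$free] == "loading", 0, 0.7)
  expect_equal(unname(implied_covariance(spec, 1)), diag(0.7, 2))
})

test_that("candidate constraints have the expected counts and canonical order", {
  hs <- build_configural_spec(hs_factor_map, 2)
  cand <- candidate_constraints(hs)
  expect_equal(nrow(cand), 54)                     # multivariate sets
  expect_equal(nrow(cand) * hs$n_groups, 108)      # univariate tests
  expect_equal(sum(cand$role == "loading"), 18)
  expect_equal(sum(cand$role == "residual_covariance"), 36)
  # canonical order: cross-loadings first by indicator then factor
  expect_true(all(which(cand$role == "loading") <
                    min(which(cand$role == "residual_covariance"))))
  expect_equal(cand$label[1], "textual=~x1")

  sim <- build_configural_spec(list(f1 = c("x1", "x2", "x3"),
                                    f2 = c("x4", "x5", "x6")), 4)
  expect_equal(nrow(candidate_constraints(sim)), 21)

  one <- build_configural_spec(list(f = c("a", "b", "c")), 1)
  co <- candidate_constraints(one)
  expect_equal(nrow(co), 3)
  expect_true(all(co$role == "residual_covariance"))
})

test_that("candidates, free parameters and fixed factor variances partition the space", {
  for (spec in list(build_configural_spec(hs_factor_map, 2),
                    build_configural_spec(list(f1 = c("x1", "x2", "x3"),
                                               f2 = c("x4", "x5", "x6")), 4))) {
    pt <- spec$ptable
    cand <- candidate_constraints(spec)
    n_cand <- nrow(cand) * spec$n_groups
    n_free <- sum(pt$free)
    n_psi_fixed <- spec$m * spec$n_groups
    expect_equal(n_cand + n_free + n_psi_fixed, nrow(pt))
    # no overlap: no candidate is free
    key <- paste(pt$role, pt$row, pt$col)[pt$free & pt$group == 1]
    expect_length(intersect(key, paste(cand$role, cand$row, cand$col)), 0)
  }
})

test_that("freeing parameters reduces df per affected group and rejects misuse", {
  hs <- build_configural_spec(hs_factor_map, 2)
  hs2 <- free_parameters(hs, "visual=~x9")
  expect_equal(model_df(hs2), 46)
  expect_error(free_parameters(hs2, "visual=~x9"), "already free")
  expect_error(free_parameters(hs, "visual~~textual"), "not a fixed-to-zero")

  sim <- build_configural_spec(list(f1 = c("x1", "x2", "x3"),
                                    f2 = c("x4", "x5", "x6")), 4)
  sim2 <- free_parameters(free_parameters(sim, "x1~~x4"), "x2~~x5")
  expect_equal(model_df(sim2), 32 - 2 * 4)

  one_grp <- free_parameters(hs, "visual=~x9", groups = 2)
  expect_equal(model_df(one_grp), 47)
})

test_that("model syntax parses to the expected configural structure", {
  spec <- parse_model("
    # three correlated mental-ability factors
    visual  =~ x1 + x2 + x3
    textual =~ x4 + x5 + x6
    speed   =~ x7 + x8 + x9", n_groups = 2)
  expect_equal(model_df(spec), 48)
  expect_equal(spec$factors, c("visual", "textual", "speed"))

  with_rescov <- parse_model(c("f1 =~ a + b + c", "f2 =~ d + e + f",
                               "a ~~ d"), n_groups = 4)
  pt <- with_rescov$ptable
  freed <- pt[pt$label == "a~~d", ]
  expect_true(all(freed$free))
  expect_equal(nrow(freed), 4)

  crossed <- parse_model(c("f1 =~ a + b + c", "f2 =~ d + e + a"), 2)
  expect_true(all(crossed$ptable$free[crossed$ptable$label == "f2=~a"]))
})

test_that("syntax errors carry line numbers", {
  expect_error(parse_model(""), "empty")
  expect_error(parse_model("f1 =~ a + b\nwhat is this"), "line 2")
  expect_error(parse_model("f1 =~ a\nf1 =~ b"), "duplicate factor")
  expect_error(parse_model(c("f1 =~ a + b", "a ~~ zz")), "unknown")
})
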