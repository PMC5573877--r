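# shared fixtures: a misspecified and a correctly specified 2-group fit
lg_pop <- two_group_population()
lg_spec_mis <- configural_spec(lg_pop)
lg_spec_ok <- free_parameters(free_parameters(lg_spec_mis, "x1~~x4"),
                              "x2~~x5")

test_that("the gradient over free parameters vanishes at the MLE", {
  set.seed(21)
  dat <- draw_sample(lg_pop, 300)
  fit <- cfa_fit(lg_spec_mis, data = dat, group = "group")
  for (g in 1:2) {
    si <- extended_score_info(fit, g)
    expect_lt(max(abs(si$gradient[seq_len(si$n_free)])), 1e-6)
    expect_true(isSymmetric(si$information, tol = 1e-10))
  }
})

test_that("multivariate indices are the sum of the per-group univariate ones", {
  fits <- list(
    cfa_fit(lg_spec_mis, population_moments(lg_pop, 100), indices = FALSE),
    { set.seed(23); cfa_fit(lg_spec_mis, data = draw_sample(lg_pop, 150),
                            group = "group", indices = FALSE) })
  for (fit in fits) {
    uni <- mod_indices(fit, "univariate")
    mv <- mod_indices(fit, "multivariate")
    sums <- tapply(uni$mi, uni$label, sum)
    expect_equal(mv$mi, as.numeric(sums[mv$label]), tolerance = 1e-8)
    # monotone nesting: each group's 1-df index is below the joint index
    for (k in seq_len(nrow(mv)))
      expect_gte(mv$mi[k] + 1e-10, max(uni$mi[uni$label == mv$label[k]]))
    expect_true(all(mv$mi >= 0 | is.na(mv$mi)))
  }
})

test_that("modification indices estimate the refit likelihood-ratio statistic", {
  # truly-zero candidates of a correctly specified model: the score test and
  # the LRT are asymptotically equal, and agree closely at n = 5000/group
  set.seed(3)
  dat <- draw_sample(lg_pop, 5000)
  mom <- sample_moments(dat, "group")
  fit <- cfa_fit(lg_spec_ok, mom, indices = FALSE)
  mv <- mod_indices(fit)
  for (k in seq_len(nrow(mv))) {
    f2 <- cfa_fit(free_parameters(lg_spec_ok, mv$label[k]), mom,
                  indices = FALSE)
    dchi <- lrt_compare(fit, f2)$chisq_diff
    expect_lt(abs(mv$mi[k] - dchi), max(0.05, 0.01 * mv$mi[k]))
  }
})

test_that("EPC predicts the value a freed parameter takes on refitting", {
  set.seed(29)
  dat <- draw_sample(lg_pop, 5000)
  mom <- sample_moments(dat, "group")
  fit <- cfa_fit(lg_spec_mis, mom, indices = FALSE)
  uni <- mod_indices(fit, "univariate")
  cand <- candidate_constraints(lg_spec_mis)
  for (k in which(uni$label %in% c("x1~~x4", "x2~~x5"))) {
    grp <- match(uni$group[k], mom$groups)
    sp2 <- free_parameters(lg_spec_mis, cand[cand$label == uni$label[k], ],
                           groups = grp)
    f2 <- cfa_fit(sp2, mom, indices = FALSE)
    est <- f2$estimates
    val <- est$est[est$label == uni$label[k] & est$group == grp & est$free]
    expect_equal(sign(uni$epc[k]), sign(val))
    expect_lt(abs(uni$epc[k] - val), 0.05)
  }
})

test_that("SEPC equals the raw EPC after rescaling to the implied metric", {
  set.seed(31)
  dat <- draw_sample(lg_pop, 500)
  fit <- cfa_fit(lg_spec_mis, data = dat, group = "group", indices = FALSE)
  uni <- mod_indices(fit, "univariate")
  # rescale all indicators by group 1's implied standard deviations; the raw
  # EPCs of the rescaled fit (group 1) are the original group-1 SEPCs
  sds <- sqrt(diag(fit$Sigma_hat[[1]]))
  dat2 <- dat
  for (j in seq_along(lg_pop$indicators))
    dat2[[lg_pop$indicators[j]]] <- dat2[[lg_pop$indicators[j]]] / sds[j]
  fit2 <- cfa_fit(lg_spec_mis, data = dat2, group = "group", indices = FALSE)
  uni2 <- mod_indices(fit2, "univariate")
  g1 <- uni$group == fit$moments$groups[1]
  m <- match(paste(uni$label[g1]), paste(uni2$label[uni2$group == uni2$group[1]]))
  u2 <- uni2[uni2$group == fit$moments$groups[1], ]
  for (k in which(g1)) {
    k2 <- which(u2$label == uni$label[k])
    expect_equal(uni$sepc[k], u2$epc[k2], tolerance = 1e-3)
  }
})

test_that("unit implied variances make SEPC equal EPC", {
  pop <- study_population()
  spec <- configural_spec(pop)
  spec <- free_parameters(free_parameters(spec, "x1~~x4"), "x2~~x5")
  fit <- cfa_fit(spec, population_moments(pop, 100), indices = FALSE)
  # the exact fit reproduces unit implied variances, so scaling is identity
  cand <- candidate_constraints(spec)
  ref <- cand[1:3, ]
  epc <- c(0.4, -0.2, 0.1)
  expect_equal(sepc(epc, fit, ref, group = 1), epc, tolerance = 1e-6)
})

test_that("largest_significant applies Bonferroni and canonical tie-breaks", {
  tab <- data.frame(label = c("a", "b", "c"), group = "all",
                    mi = c(20, 20, 3), df = 2,
                    p_value = pchisq(c(20, 20, 3), 2, lower.tail = FALSE),
                    epc = NA, sepc = NA)
  class(tab) <- c("cfa_scoretable", class(tab))
  sel <- largest_significant(tab, 0.05, n_tests = 3)
  expect_equal(sel$label, "a")   # tie broken by table (canonical) order

  none <- largest_significant(tab, 1e-9, n_tests = 3)
  expect_null(none)
  expect_null(largest_significant(tab[0, ]))
})
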