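test_that("harmonic-mean plot size follows the unbalanced-design formula", {
  expect_equal(harmonic_mean_n(matrix(4, 10, 10)), 4)
  expect_equal(harmonic_mean_n(c(2, 4, 4, 4)), 3.2)
  # empty plots are excluded with the plot count reduced
  expect_equal(harmonic_mean_n(c(0, 2, 4, 4, 4)), 3.2)
  expect_error(harmonic_mean_n(c(0, 0)), "empty")
})

test_that("REML equals the ANOVA closed form on balanced one-way data", {
  for (s in 1:3) {
    rec <- make_oneway_records(p = 8, n = 12, v_p = 1, v_e = 2, seed = s)
    vc <- fit_lmm_reml(rec, "y", "wood")
    m <- tapply(rec$y, rec$provenance, mean)
    msb <- 12 * sum((m - mean(rec$y))^2) / 7
    msw <- sum((rec$y - m[rec$provenance])^2) / (8 * 11)
    expect_equal(vc_estimate(vc, "v_p"), (msb - msw) / 12, tolerance = 1e-6)
    expect_equal(vc_estimate(vc, "v_e"), msw, tolerance = 1e-6)
  }
})

test_that("the restricted loglik never decreases across iterations", {
  rec <- simulate_trial(simulation_config(seed = 21))$records
  for (tr in c("dbh", "height")) {
    vc <- fit_lmm_reml(rec, tr, "growth")
    expect_true(all(diff(vc$loglik_trace) >= -1e-6))
  }
})

test_that("estimates are invariant to record order and location shift", {
  rec <- simulate_trial(simulation_config(p = 6, b = 5, n = 4, seed = 13))$records
  vc <- fit_lmm_reml(rec, "dbh", "growth")
  set.seed(1)
  vc_perm <- fit_lmm_reml(rec[sample(nrow(rec)), ], "dbh", "growth")
  expect_equal(vc_perm$components$estimate, vc$components$estimate,
               tolerance = 1e-6)
  rec$dbh <- rec$dbh + 100
  vc_shift <- fit_lmm_reml(rec, "dbh", "growth")
  expect_equal(vc_shift$components$estimate, vc$components$estimate,
               tolerance = 1e-5)
})

test_that("a zero provenance variance is flagged as a boundary (NE) case", {
  cfg <- simulation_config(p = 10, b = 1, n = 5, traits = "y",
                           grand_mean = c(y = 0), G_P = matrix(0),
                           V_PB = 0, R = matrix(4), survival = 1, seed = 6)
  rec <- simulate_wood_samples(cfg, trees_per_provenance = 30)$records
  vc <- fit_lmm_reml(rec, "y", "wood")
  comp <- vc$components
  expect_true(comp$boundary[comp$component == "v_p"] ||
                comp$estimate[comp$component == "v_p"] < 0.01)
})

test_that("unbalanced growth-model fits agree with an independent REML oracle", {
  skip_if_not_installed("lme4")
  rec <- simulate_trial(simulation_config(seed = 7))$records
  vc <- fit_lmm_reml(rec, "height", "growth")
  d <- rec[rec$alive, ]
  d$block <- factor(d$block)
  fm <- suppressMessages(lme4::lmer(
    height ~ block + (1 | provenance) + (1 | provenance:block),
    data = d, REML = TRUE))
  ref <- as.data.frame(lme4::VarCorr(fm))
  ref_v <- setNames(ref$vcov, ref$grp)
  expect_equal(vc_estimate(vc, "v_p"), unname(ref_v["provenance"]),
               tolerance = 1e-3)
  expect_equal(vc_estimate(vc, "v_pb"), unname(ref_v["provenance:block"]),
               tolerance = 2e-3)
  expect_equal(vc_estimate(vc, "v_e"), unname(ref_v["Residual"]),
               tolerance = 1e-3)
})

test_that("the wood model has no provenance-by-block component", {
  cfg <- simulation_config(p = 8, b = 1, n = 5, traits = "y",
                           grand_mean = c(y = 10), G_P = matrix(1),
                           V_PB = 0, R = matrix(3), survival = 1, seed = 4)
  rec <- simulate_wood_samples(cfg, 6)$records
  vc <- fit_lmm_reml(rec, "y", "wood")
  expect_setequal(vc$components$component, c("v_p", "v_e"))
  expect_equal(vc_estimate(vc, "v_pb"), 0)
})

test_that("bivariate components recover identity and independence limits", {
  rec <- make_oneway_records(p = 10, n = 8, v_p = 2, v_e = 3, seed = 11)
  rec$y2 <- rec$y
  cc <- fit_bivariate_reml(rec, "y", "y2", "wood")
  expect_equal(cc$cov_p, vc_estimate(cc$fit1, "v_p"), tolerance = 1e-5)
  expect_equal(genetic_correlation(cc)$estimate, 1, tolerance = 1e-6)
  expect_equal(phenotypic_correlation(cc)$estimate, 1, tolerance = 1e-6)

  # independent traits: provenance covariance near zero on average
  covs <- vapply(1:30, function(s) {
    r <- make_oneway_records(p = 12, n = 6, v_p = 1, v_e = 1, seed = 200 + s)
    r$z <- make_oneway_records(p = 12, n = 6, v_p = 1, v_e = 1,
                               seed = 500 + s)$y
    cc <- fit_bivariate_reml(r, "y", "z", "wood")
    if (cc$ne) NA_real_ else cc$cov_p
  }, numeric(1))
  expect_lt(abs(mean(covs, na.rm = TRUE)), 0.15)
})

test_that("NE marginals propagate to the covariance", {
  cfg <- simulation_config(p = 10, b = 1, n = 5, traits = "y",
                           grand_mean = c(y = 0), G_P = matrix(0),
                           V_PB = 0, R = matrix(4), survival = 1, seed = 99)
  rec <- simulate_wood_samples(cfg, trees_per_provenance = 40)$records
  rec$z <- rec$y + rnorm(nrow(rec))
  cc <- fit_bivariate_reml(rec, "y", "z", "wood")
  if (cc$ne) {
    expect_true(is.na(cc$cov_p))
    expect_true(genetic_correlation(cc)$ne)
  } else {
    succeed("marginal provenance variance not at the boundary for this draw")
  }
})
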