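test_that("log-likelihood matches closed forms and published optimum", {
  # lam = 0: uniform offer (1/11) and coin-flip response
  one <- ug_observations(0.5, 1)
  expect_equal(ug_loglik(one, b = 3, lam = 0), log(1 / 11) + log(1 / 2))
  rej <- ug_observations(0.2, 0)
  expect_equal(ug_loglik(rej, b = 3, lam = 0), log(1 / 11) + log(1 / 2))
  # empty dataset
  expect_equal(ug_loglik(ug_observations(numeric(0), integer(0)), 1, 1), 0)
  # at the 2-dp published estimates the value is within 0.5 of the optimum
  ll <- ug_loglik(ug_fixture("all_resettled"), b = 13.97, lam = 6.83)
  expect_lt(abs(-ll - tab5$all_resettled["nll"]), 0.5)
  # finite across the estimation region, including the lam bound
  d <- ug_fixture("all_traditional")
  for (lam in c(1e-6, 1, 100)) for (b in c(0, 250, 500))
    expect_true(is.finite(ug_loglik(d, b, lam)))
})

test_that("single-group fits reproduce the published estimates", {
  cases <- list(
    list("all_resettled", tab5$all_resettled),
    list("all_traditional", tab5$all_traditional),
    list("pooled_all", tab5$pooled),
    list("sengezi_resettled", tab5$sengezi_res))
  for (cs in cases) {
    fit <- ug_fit(ug_fixture(cs[[1]]))
    expect_equal(unname(coef(fit)["b"]), cs[[2]]["b"], tolerance = 0.02,
                 ignore_attr = TRUE)
    expect_equal(unname(coef(fit)["lam"]), cs[[2]]["lam"], tolerance = 0.02,
                 ignore_attr = TRUE)
    expect_lt(abs(fit$neg_loglik - cs[[2]]["nll"]), 0.5)
    expect_equal(fit$convergence, 0)
  }
})

test_that("parameters are recovered from data simulated at known truth", {
  sim <- ug_simulate(b = 10, lam = 7, n_pairs = 1000, seed = 42)
  fit <- ug_fit(sim)
  expect_lt(abs(coef(fit)["b"] - 10), 1.5)
  expect_lt(abs(coef(fit)["lam"] - 7), 1.5)
})

test_that("restricted joint fits honor sharing constraints and components", {
  groups <- status_groups()
  m3 <- ug_fit_spec(ug_model_spec(groups, lam_sharing = "all"))
  expect_equal(unname(m3$estimates),
               unname(tab5$model3[c("b_r", "b_t", "lam")]),
               tolerance = 0.02)
  # per-group components sum to the joint objective
  expect_lt(abs(sum(m3$components) - m3$neg_loglik), 1e-8)
  expect_equal(unname(m3$lam["resettled"]), unname(m3$lam["traditional"]))
  # Model 1 (all free) equals the sum of independent group fits
  m1 <- ug_fit_spec(ug_model_spec(groups))
  f_r <- ug_fit(groups$resettled)
  f_t <- ug_fit(groups$traditional)
  expect_lt(abs(m1$neg_loglik - (f_r$neg_loglik + f_t$neg_loglik)), 0.02)
  # degenerate one-group spec is the plain group fit
  f1 <- ug_fit_spec(ug_model_spec(list(g = groups$resettled)))
  expect_equal(f1$estimates, coef(f_r), ignore_attr = TRUE,
               tolerance = 1e-6)
})

test_that("pure self-interest restriction fits lambda only and fits worse", {
  groups <- status_groups()
  selfish <- ug_fit_spec(ug_model_spec(groups, b_fixed_zero = TRUE))
  expect_length(selfish$estimates, 2)   # one lambda per group
  expect_true(all(selfish$b == 0))
  free <- ug_fit_spec(ug_model_spec(groups))
  expect_gt(selfish$neg_loglik, free$neg_loglik)
})

test_that("restricted fits are never better than nested unrestricted fits", {
  groups <- status_groups()
  m0 <- ug_fit_spec(ug_model_spec(groups, "all", "all"))
  m2 <- ug_fit_spec(ug_model_spec(groups, b_sharing = "all"))
  m3 <- ug_fit_spec(ug_model_spec(groups, lam_sharing = "all"))
  m1 <- ug_fit_spec(ug_model_spec(groups))
  expect_gte(m0$neg_loglik, m2$neg_loglik - 1e-6)
  expect_gte(m0$neg_loglik, m3$neg_loglik - 1e-6)
  expect_gte(m2$neg_loglik, m1$neg_loglik - 1e-6)
  expect_gte(m3$neg_loglik, m1$neg_loglik - 1e-6)
})

test_that("likelihood-ratio tests reproduce the published statistics", {
  groups <- status_groups()
  m0 <- ug_fit_spec(ug_model_spec(groups, "all", "all"))
  m1 <- ug_fit_spec(ug_model_spec(groups))
  m3 <- ug_fit_spec(ug_model_spec(groups, lam_sharing = "all"))
  t1 <- ug_lr_test(m0, m1)
  expect_equal(t1$df, 2)
  expect_lt(abs(t1$lr - 12.16), 0.2)
  t3 <- ug_lr_test(m0, m3)
  expect_equal(t3$df, 1)
  expect_lt(abs(t3$lr - 11.07), 0.2)
  # indistinguishable groups: free alternative collapses onto the shared
  # null, LR = 0 (tiny negatives clipped), p = 1
  twin <- list(a = groups$resettled, b = groups$resettled)
  t0 <- ug_lr_test(ug_fit_spec(ug_model_spec(twin, "all", "all")),
                   ug_fit_spec(ug_model_spec(twin)))
  expect_lt(t0$lr, 1e-4)
  expect_gt(t0$p_value, 0.999)
  # non-nested and mismatched-data requests fail
  expect_error(ug_lr_test(m1, m0), "nested")
  other <- ug_fit(ug_fixture("mutanda_all"))
  expect_error(ug_lr_test(other, m1), "same grouped data")
})

test_that("flat-likelihood data are flagged, not silently fitted", {
  flat <- ug_observations(rep(0.5, 12), rep(1, 12))
  expect_warning(fit <- ug_fit(flat), "non-identifiable")
  expect_true(fit$non_identifiable[["group"]])
  expect_error(ug_fit(ug_observations(numeric(0), integer(0))), "empty")
})

test_that("the rationality bound is hit and flagged on near-degenerate data", {
  # shared-fairness restriction on the Mutanda groups drives the resettled
  # rationality to its upper bound of 100 (as published)
  groups <- list(res = ug_fixture("mutanda_resettled"),
                 trad = ug_fixture("mutanda_traditional"))
  m2 <- ug_fit_spec(ug_model_spec(groups, b_sharing = "all"))
  expect_equal(unname(m2$lam["res"]), 100, tolerance = 1e-4)
  expect_true(m2$bound_hits[["lam_res"]])
})

test_that("bootstrap is seed-reproducible and handles degenerate data", {
  fit <- ug_fit(ug_fixture("sengezi_resettled"))
  b1 <- ug_bootstrap(fit, n_reps = 30, seed = 9)
  b2 <- ug_bootstrap(fit, n_reps = 30, seed = 9)
  expect_equal(b1$se, b2$se)
  expect_equal(b1$boot_estimates, b2$boot_estimates)
  expect_true(all(is.finite(b1$se)))
  expect_true(all(b1$p_values >= 0 & b1$p_values <= 1))
  # a single-pair group only ever resamples itself
  one <- ug_observations(0.4, 1)
  f1 <- suppressWarnings(ug_fit(one))
  expect_warning(bb <- ug_bootstrap(f1, n_reps = 10, seed = 1),
                 "degenerate")
  expect_true(all(bb$se < 1e-6))
})
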