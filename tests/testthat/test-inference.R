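test_that("maximum likelihood attains the dense-grid optimum on large-n data", {
  truth <- emax_params(0.1, 0.5, 2, 1.5)
  sr <- simulate_series(truth, k = 4, n_per_level = 200, seed = 21)
  fit <- fit_mle(sr)
  oracle <- grid_search_loglik(sr)
  expect_gte(fit$loglik, oracle$max_loglik - 1e-3)
  expect_true(fit$converged)
  # estimates land near the generating curve at this sample size
  expect_lt(abs(height_of_fit(fit)$value - curve_height(truth, 1:4)), 0.1)
})

test_that("flat data yield a near-zero ML height", {
  sr <- make_series(n = rep(200, 4), events = rep(60, 4))
  fit <- fit_mle(sr)
  h <- curve_height(fit$params, 1:4)
  expect_lt(abs(h), 0.05)
})

test_that("degenerate series are flagged, never crash", {
  # two levels, zero events everywhere: likelihood plateau at p ~ 0
  sr <- make_series(n = c(3, 3), events = c(0, 0))
  fit <- fit_mle(sr)
  expect_false(fit$converged)
  expect_true(fit$failure_reason %in% c("boundary", "se_explosion", "no_convergence"))
  expect_lt(emax_prob(fit$params, 1), 0.05)
  expect_lt(emax_prob(fit$params, 2), 0.05)
  expect_error(fitted_curve(fit), "Bayesian")
  expect_error(height_of_fit(fit), "Bayesian")
  single <- analysis_series("s", "DLT", n = 3, events = 0)
  expect_error(fit_mle(single), "fittable")
  expect_error(fit_bayes(single), "fittable")
})

test_that("posterior sampling is bit-reproducible under a fixed seed", {
  sr <- make_series(n = c(3, 3, 6), events = c(0, 1, 2))
  f1 <- fit_bayes(sr, seed = 42, chains = 2, warmup = 200, draws = 200)
  f2 <- fit_bayes(sr, seed = 42, chains = 2, warmup = 200, draws = 200)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_bayes(sr, seed = 43, chains = 2, warmup = 200, draws = 200)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("every posterior draw satisfies the parameter constraints", {
  sr <- make_series(n = c(3, 3, 6), events = c(0, 1, 2))
  f <- fit_bayes(sr, seed = 2)
  d <- f$draws
  expect_true(all(d[, "p_lo"] >= 0 & d[, "p_lo"] <= 1))
  expect_true(all(d[, "p_hi"] >= 0 & d[, "p_hi"] <= 1))
  expect_true(all(d[, "ed50"] > 0))
  expect_true(all(d[, "hill"] > 0))
  expect_true(all(is.finite(f$diagnostics$rhat)))
  expect_true(all(is.finite(f$diagnostics$ess)))
})

test_that("flat data centre the posterior height at zero", {
  sr <- make_series(n = rep(50, 4), events = rep(15, 4))
  f <- fit_bayes(sr, seed = 5)
  h <- height_of_fit(f)
  expect_lt(abs(h$mean), 0.1)
  expect_lt(h$lower, 0)
  expect_gt(h$upper, 0)
})

test_that("prior-dominated small series agree with the grid posterior", {
  # 2 levels, 3 patients, 0 events: ML degenerates, the posterior does not
  sr <- make_series(n = c(3, 3), events = c(0, 0))
  f <- fit_bayes(sr, seed = 9)
  g <- posterior_from_grid(sr, grid_points = 25)
  expect_lt(abs(mean(f$draws[, "p_lo"]) - g$param_means["p_lo"]), 0.05)
  expect_lt(abs(height_of_fit(f)$mean - g$height_mean), 0.05)
  # posterior mass concentrates on low event probabilities at both doses
  fc <- fitted_curve(f)
  expect_true(all(fc$prob < 0.35))
})

test_that("the grid posterior rejects too coarse a grid and centres flat data", {
  sr <- make_series(n = rep(50, 4), events = rep(15, 4))
  expect_error(posterior_from_grid(sr, grid_points = 3), "coarse")
  g <- posterior_from_grid(sr)
  expect_lt(abs(g$height_mean), 0.05)
  expect_lt(g$height_quantiles[[1]], 0)
  expect_gt(g$height_quantiles[[3]], 0)
})

test_that("prior predictive curves are probability-valued, centred, reproducible", {
  pr <- emax_priors(4)
  pp <- prior_predictive(pr, levels = 1:4, n_curves = 4000, seed = 31)
  expect_true(all(pp$curves >= 0 & pp$curves <= 1))
  # symmetric uniform asymptote priors put the mean near 1/2 at every level
  expect_true(all(abs(colMeans(pp$curves) - 0.5) < 0.02))
  pp2 <- prior_predictive(pr, levels = 1:4, n_curves = 4000, seed = 31)
  expect_identical(pp$curves, pp2$curves)
  # the spread covers rising, falling, and flat candidate curves
  h <- pp$curves[, 4] - pp$curves[, 1]
  expect_gt(mean(h > 0.2), 0.1)
  expect_gt(mean(h < -0.2), 0.1)
})

test_that("fitted curves and heights reduce to direct evaluation on one draw", {
  th <- emax_params(0.1, 0.6, 2, 1.5)
  fake <- structure(
    list(draws = matrix(c(th$p_lo, th$p_hi, th$ed50, th$hill), 1,
                        dimnames = list(NULL, c("p_lo", "p_hi", "ed50", "hill"))),
         levels = 1:4),
    class = "emax_bayes_fit"
  )
  fc <- fitted_curve(fake)
  expect_equal(fc$prob, emax_prob(th, 1:4))
  expect_equal(height_of_fit(fake)$mean, curve_height(th, 1:4))
  # flat draws give a flat curve and zero height
  flat <- fake
  flat$draws <- matrix(c(0.3, 0.3, 2, 1), 1,
                       dimnames = list(NULL, c("p_lo", "p_hi", "ed50", "hill")))
  expect_equal(unique(round(fitted_curve(flat)$prob, 12)), 0.3)
  expect_equal(height_of_fit(flat)$mean, 0)
})
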