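test_that("design matrix columns are monomials of the coded levels", {
  terms <- full_quadratic_terms(c("a", "b", "c"))
  expect_equal(nrow(terms), 11)
  X <- build_design_matrix(matrix(c(0, 0, 0,
                                    1, 1, -1,
                                    0, -1.682, 0), 3, byrow = TRUE), terms)
  expect_equal(unname(X[1, ]), c(1, rep(0, 10)))
  expect_equal(unname(X[2, "a:b:c"]), -1)
  expect_equal(round(unname(X[3, "b^2"]), 3), 2.829)  # 1.682^2
})

test_that("the selected model reproduces the published parameter table", {
  fit <- fit_selected()
  # point estimates to 4 significant figures
  for (nm in names(published_beta)) {
    expect_sig_figs(fit$coefficients[[nm]], published_beta[[nm]], 4)
  }
  # 95% CI bounds to 3 decimals
  expect_equal(round(unname(fit$ci[rownames(published_ci), ]), 3),
               unname(round(published_ci, 3)))
  expect_equal(round(fit$r_squared, 4), 0.9834)
  expect_equal(round(fit$adj_r_squared, 4), 0.9713)
  # brute-force normal-equations oracle agrees to machine precision
  orc <- oracle_ols(fit$X, fit$y)
  expect_equal(unname(fit$coefficients), unname(orc$beta), tolerance = 1e-12)
  expect_equal(unname(fit$se), unname(orc$se), tolerance = 1e-12)
  expect_equal(unname(fit$ci), unname(orc$ci), tolerance = 1e-12)
})

test_that("noiseless data are interpolated exactly and edge cases behave", {
  d <- ccd_design(c("a", "b", "c"), n_center = 6, seed = 8)
  terms <- full_quadratic_terms(c("a", "b", "c"))
  beta <- seq(-0.5, 0.5, length.out = 11)
  y <- drop(build_design_matrix(d, terms) %*% beta)
  fit <- fit_rsm(d, y, terms)
  expect_equal(unname(fit$coefficients), beta, tolerance = 1e-10)
  # constant response: intercept only, everything else 0
  fit0 <- fit_rsm(d, rep(0.25, nrow(d)), terms)
  expect_equal(unname(fit0$coefficients), c(0.25, rep(0, 10)),
               tolerance = 1e-12)
  # more terms than runs is refused
  tiny <- d[1:10, ]
  attr(tiny, "factor_names") <- c("a", "b", "c")
  expect_error(fit_rsm(tiny, y[1:10], terms), "more run")
  # a duplicated column is singular
  dup <- model_terms(rbind(c(0, 0), c(1, 0), c(0, 1)), c("a", "b"))
  d2 <- ccd_design(c("a", "b"), n_center = 3, seed = 1)
  d2$b <- d2$a
  expect_error(fit_rsm(coded_levels(d2), rep(1:4, 3)[seq_len(nrow(d2))], dup),
               "singular")
})

test_that("residuals are orthogonal to the design matrix and R2 ordering holds", {
  for (seed in 1:5) {
    d <- ccd_design(c("a", "b", "c"), n_center = 6, seed = seed)
    sim <- simulate_surface_measurements(d, seed = seed)
    fit <- fit_rsm(d, sim$absorbance, glycogen_selected_terms())
    expect_lt(max(abs(crossprod(fit$X, fit$residuals))), 1e-10)
    expect_lte(fit$adj_r_squared, fit$r_squared)
  }
})

test_that("model reduction removes exactly the two non-established terms", {
  red <- reduce_terms(fit_full(), alpha = 0.05)
  expect_setequal(rownames(red),
                  c("(Intercept)", "phenol", "acid", "water", "phenol:acid",
                    "acid:water", "phenol:acid:water", "acid^2", "water^2"))
  expect_false(any(c("phenol^2", "phenol:water") %in% rownames(red)))
  # linear phenol is kept by hierarchy despite p = 0.49
  expect_gt(fit_full()$p_value[["phenol"]], 0.05)
  expect_true("phenol" %in% rownames(red))
})

test_that("reduction keeps strongly supported terms and drops null ones", {
  # all coefficients far from zero: nothing removed
  d <- ccd_design(c("a", "b", "c"), n_center = 6, seed = 4)
  terms <- full_quadratic_terms(c("a", "b", "c"))
  beta_big <- rep(0.5, 11)
  y <- drop(build_design_matrix(d, terms) %*% beta_big)
  set.seed(1); y <- y + rnorm(length(y), 0, 0.001)
  red <- reduce_terms(fit_rsm(d, y, terms))
  expect_equal(nrow(red), 11)

  # a truly-null quadratic term is removed in >= 90% of replicates
  removed <- 0L
  n_rep <- 200L
  for (r in seq_len(n_rep)) {
    sim <- simulate_surface_measurements(d, seed = 1000 + r)
    red_r <- reduce_terms(fit_rsm(d, sim$absorbance, terms))
    if (!"a^2" %in% rownames(red_r)) removed <- removed + 1L
  }
  expect_gte(removed / n_rep, 0.9)
})

test_that("AICc comparison matches the published difference and is antisymmetric", {
  sel <- fit_selected(); full <- fit_full()
  cmp <- compare_aicc(sel, full)
  expect_equal(round(cmp$delta, 2), -20.93)
  expect_gt(cmp$prob_correct, 0.9999)
  rev <- compare_aicc(full, sel)
  expect_equal(rev$delta, -cmp$delta)
  expect_equal(cmp$prob_correct + rev$prob_correct, 1)
  same <- compare_aicc(sel, sel)
  expect_equal(same$delta, 0)
  expect_equal(same$prob_correct, 0.5)
  # AICc needs spare degrees of freedom beyond the variance parameter
  d <- ccd_design(c("a", "b"), n_center = 2, seed = 1)
  lev <- coded_levels(d)[1:8, ]
  terms6 <- full_quadratic_terms(c("a", "b"))  # K = 7, n = 8: n - K - 1 = 0
  expect_error(fit_rsm(lev, rnorm(8), terms6), "AICc undefined")
})

test_that("prediction returns the surface value with a t interval", {
  fit <- fit_selected()
  p0 <- predict(fit, c(0, 0, 0))
  expect_equal(p0$estimate, fit$coefficients[["(Intercept)"]])
  expect_equal(round(c(p0$lower, p0$upper), 4), c(0.2736, 0.3002))
  expect_false(p0$extrapolated)

  # zero-noise fit predicts the true surface exactly
  d <- ccd_design(c("a", "b", "c"), n_center = 6, seed = 2)
  sim <- simulate_surface_measurements(d, noise_sd = 0, seed = 2)
  zfit <- fit_rsm(d, sim$absorbance, glycogen_selected_terms())
  pt <- c(0.3, -0.8, 1.1)
  truth <- drop(build_design_matrix(matrix(pt, 1), zfit$terms) %*%
                  glycogen_surface_coefficients())
  expect_equal(predict(zfit, pt)$estimate, truth, tolerance = 1e-9)

  # CI band matches the direct covariance computation at a printed condition
  cond2 <- c(0.7, 0, -1.682)
  pr <- predict(fit, cond2)
  x0 <- build_design_matrix(matrix(cond2, 1), fit$terms)
  orc <- oracle_ols(fit$X, fit$y)
  se0 <- sqrt(drop(x0 %*% orc$cov %*% t(x0)))
  tcrit <- qt(0.975, orc$df)
  est0 <- drop(x0 %*% orc$beta)
  expect_equal(pr$estimate, est0, tolerance = 1e-12)
  expect_equal(c(pr$lower, pr$upper), c(est0 - tcrit * se0, est0 + tcrit * se0),
               tolerance = 1e-12)

  expect_warning(predict(fit, c(0, 0, 5)), "outside the design region")
})

test_that("center-point drift diagnostics summarize run-order stability", {
  drift <- center_point_drift(glycogen_data, glycogen_data$absorbance)
  expect_equal(drift$order, c(1L, 6L, 7L, 11L, 17L, 20L))
  expect_equal(round(drift$mean, 3), 0.292)
  expect_equal(round(drift$mad, 3), 0.008)
  expect_true(drift$pass)
  expect_equal(drift$residuals, glycogen_data$absorbance[drift$order] - drift$mean)

  flat <- data.frame(point_type = rep("center", 4))
  expect_equal(center_point_drift(flat, rep(0.3, 4))$mad, 0)
  wide <- center_point_drift(data.frame(point_type = c("center", "center")),
                             c(1.0, 1.2))
  expect_equal(wide$mad, 0.1)
  expect_equal(round(wide$mad_over_mean, 3), 0.091)
  expect_false(wide$pass)
  expect_error(center_point_drift(data.frame(point_type = "center"), 1),
               "insufficient replicates")
})

test_that("coefficient CIs attain close-to-nominal coverage on simulated surfaces", {
  d <- ccd_design(c("phenol", "acid", "water"), n_center = 6, seed = 10)
  terms <- glycogen_selected_terms()
  truth <- glycogen_surface_coefficients()
  n_rep <- 500L
  covered <- matrix(0L, n_rep, length(truth))
  for (r in seq_len(n_rep)) {
    sim <- simulate_surface_measurements(d, seed = 20000 + r)
    fit <- fit_rsm(d, sim$absorbance, terms)
    covered[r, ] <- as.integer(fit$ci[, 1] <= truth & truth <= fit$ci[, 2])
  }
  rates <- colMeans(covered)
  expect_true(all(rates >= 0.90 & rates <= 0.98))
})

test_that("fit reports round-trip through JSON", {
  fit <- fit_selected()
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  back <- read_fit_json(path)
  expect_equal(unname(back$coefficients), unname(fit$coefficients))
  expect_equal(rownames(back$terms), rownames(fit$terms))
  expect_equal(back$aicc, fit$aicc)
})
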