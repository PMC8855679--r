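# sign-enumeration oracle: the exact worst relative change of the fitted
# surface over all 2^k +/- assignments of the deltas
oracle_worst_case <- function(fit, point, deltas) {
  k <- length(point)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  pred <- function(x) drop(build_design_matrix(matrix(x, 1), fit$terms) %*%
                             fit$coefficients)
  R <- pred(point)
  worst <- 0
  for (i in seq_len(nrow(signs))) {
    worst <- max(worst, abs(pred(point + signs[i, ] * deltas) - R) / abs(R))
  }
  worst
}

test_that("the worst-case objective vanishes when it must", {
  fit <- fit_selected()
  expect_equal(worst_case_relative_error(fit, c(0.4, -0.3, 0.2), deltas = 0),
               0)
  # at a stationary point of a fitted surface every partial vanishes
  terms <- full_quadratic_terms(c("u", "v"))
  beta <- setNames(c(1, 0.2, -0.1, 0.05, -0.5, -0.4), rownames(terms))
  d <- ccd_design(c("u", "v"), n_center = 5, seed = 6)
  qfit <- fit_rsm(d, drop(build_design_matrix(d, terms) %*% beta), terms)
  Q <- matrix(c(2 * beta[["u^2"]], beta[["u:v"]],
                beta[["u:v"]], 2 * beta[["v^2"]]), 2)
  xstar <- drop(-solve(Q, c(beta[["u"]], beta[["v"]])))
  expect_lt(sqrt(sum(surface_gradient(qfit, xstar)^2)), 1e-8)
  expect_lt(worst_case_relative_error(qfit, xstar, deltas = 0.05), 1e-7)
  expect_error(worst_case_relative_error(fit, c(0, 0, 0), deltas = -0.1),
               ">= 0")
})

test_that("first-order objective tracks the sign-enumeration oracle", {
  fit <- fit_selected()
  pts <- list(c(0, 0, 0), c(1, -1, 0.5), c(-1.2, 0.8, -1.5),
              c(0.7, 0, -1.682), c(0.5, 0.5, 0.5))
  for (p in pts) {
    for (dl in list(rep(0.05, 3), rep(0.02, 3), c(0.05, 0.03, 0.01))) {
      approx <- worst_case_relative_error(fit, p, dl)
      exact <- oracle_worst_case(fit, p, dl)
      # within one percentage point of relative error
      expect_lt(abs(approx - exact), 0.01)
    }
  }
})

test_that("objective is scale-invariant in R and monotone in the deltas", {
  fit <- fit_selected()
  scaled <- fit
  scaled$coefficients <- 7.3 * fit$coefficients
  p <- c(0.9, -0.4, -1.0)
  expect_equal(worst_case_relative_error(fit, p, 0.05),
               worst_case_relative_error(scaled, p, 0.05))
  vals <- sapply(c(0.01, 0.02, 0.05, 0.1), function(dl)
    worst_case_relative_error(fit, p, dl))
  expect_true(all(diff(vals) >= 0))
  # undefined where the surface crosses zero
  zero_fit <- fit
  zero_fit$coefficients[] <- 0
  zero_fit$coefficients[["(Intercept)"]] <- 0
  expect_error(worst_case_relative_error(zero_fit, p, 0.05),
               "undefined relative error")
})

test_that("response maximization finds interior optima and boundary optima", {
  # concave quadratic with a known interior maximum (k = 2)
  terms <- full_quadratic_terms(c("u", "v"))
  beta <- setNames(c(1, 0.2, -0.1, 0.05, -0.5, -0.4),
                   rownames(terms))  # intercept, u, v, uv, u^2, v^2
  d <- ccd_design(c("u", "v"), n_center = 5, seed = 6)
  y <- drop(build_design_matrix(d, terms) %*% beta)
  fit <- fit_rsm(d, y, terms)
  Q <- matrix(c(2 * beta[["u^2"]], beta[["u:v"]],
                beta[["u:v"]], 2 * beta[["v^2"]]), 2)
  xstar <- drop(-solve(Q, c(beta[["u"]], beta[["v"]])))
  res <- find_max_response(fit, seed = 5)
  expect_equal(unname(res$coded_point), xstar, tolerance = 1e-5)
  expect_length(res$constraints_active, 0)

  # the packaged surface peaks on the box boundary, near the volume extremes
  gfit <- fit_selected()
  peak <- find_max_response(gfit, seed = 5)
  expect_gt(length(peak$constraints_active), 0)
  a <- axial_distance(3)
  expect_true(any(abs(abs(peak$coded_point) - a) < 1e-5))

  # with no quadratic part the maximizer is a box corner
  lin_terms <- model_terms(rbind(c(0, 0), c(1, 0), c(0, 1)), c("u", "v"))
  ylin <- drop(build_design_matrix(d, lin_terms) %*% c(1, 0.3, -0.2))
  lin_fit <- fit_rsm(d, ylin, lin_terms)
  corner <- find_max_response(lin_fit, lower = -1, upper = 1, seed = 5)
  expect_equal(unname(corner$coded_point), c(1, -1), tolerance = 1e-6)
})

test_that("the precision search honours pinned factors exactly", {
  fit <- fit_selected()
  res <- find_precise_condition(fit, fixed = c(water = -1.682), seed = 9)
  expect_identical(unname(res$coded_point[["water"]]), -1.682)
  expect_true("water_fixed" %in% res$constraints_active)
  expect_equal(unname(res$objective_value),
               worst_case_relative_error(fit, res$coded_point, 0.05))
})

test_that("the precision search matches a dense grid oracle on a line", {
  fit <- fit_selected()
  # free acid only; phenol and water pinned
  res <- find_precise_condition(fit, fixed = c(phenol = 0.25, water = -1.2),
                                seed = 4)
  grid <- seq(-axial_distance(3), axial_distance(3), length.out = 40001)
  vals <- vapply(grid, function(b)
    worst_case_relative_error(fit, c(0.25, b, -1.2), 0.05), 0)
  expect_lt(abs(res$coded_point[["acid"]] - grid[which.min(vals)]), 1e-4)
})

test_that("volume constraints restrict and can exhaust the search region", {
  fit <- fit_selected()
  phenol <- factor_spec("phenol", 50, 20, allow_negative = TRUE)
  acid <- factor_spec("acid", 250, 50)
  water <- factor_spec("water", 50, 29.7265, allow_negative = TRUE)
  specs <- list(phenol, acid, water)
  res <- find_precise_condition(fit, fixed = c(water = -1.682),
                                factors = specs, min_volume = 300,
                                constant_volume = 50, seed = 4)
  vol <- 50 + decode_level(res$coded_point[["phenol"]], phenol) +
    decode_level(res$coded_point[["acid"]], acid) +
    suppressWarnings(decode_level(res$coded_point[["water"]], water))
  expect_gte(vol, 300 - 1e-6)
  expect_error(
    find_precise_condition(fit, factors = specs, min_volume = 5000,
                           constant_volume = 50),
    "infeasible")
  expect_warning(
    find_precise_condition(fit, deltas = 0, fixed = c(water = -1.682),
                           seed = 2),
    "identically 0")
})
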