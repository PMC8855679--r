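# Shared fixtures: the packaged experiment, its published summaries, and a
# brute-force normal-equations oracle kept independent of fit_rsm().

glycogen_data <- glycogen_ccd()

published_beta <- c(
  `(Intercept)` = 0.2869, phenol = 0.003508, acid = 0.04769,
  water = -0.08491, `phenol:acid` = 0.021, `acid:water` = 0.047,
  `phenol:acid:water` = -0.018, `acid^2` = -0.05295, `water^2` = -0.02061)

published_ci <- rbind(
  `(Intercept)` = c(0.2736, 0.3002), phenol = c(-0.006887, 0.01390),
  acid = c(0.03730, 0.05809), water = c(-0.09531, -0.07452),
  `phenol:acid` = c(0.007418, 0.03458), `acid:water` = c(0.03342, 0.06058),
  `phenol:acid:water` = c(-0.03158, -0.004418),
  `acid^2` = c(-0.06302, -0.04289), `water^2` = c(-0.03068, -0.01054))

# normal-equations OLS oracle: explicit matrix algebra, no lm machinery
oracle_ols <- function(X, y, level = 0.95) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  n <- nrow(X); p <- ncol(X)
  s2 <- sum(res^2) / (n - p)
  covb <- s2 * solve(XtX)
  se <- sqrt(diag(covb))
  tcrit <- qt(1 - (1 - level) / 2, n - p)
  list(beta = drop(beta), se = se, cov = covb,
       ci = cbind(drop(beta) - tcrit * se, drop(beta) + tcrit * se),
       rss = sum(res^2), df = n - p)
}

fit_selected <- function() {
  fit_rsm(glycogen_data, glycogen_data$absorbance, glycogen_selected_terms())
}

fit_full <- function() {
  fit_rsm(glycogen_data, glycogen_data$absorbance)
}

expect_sig_figs <- function(actual, expected, digits) {
  tol <- 10^(ceiling(log10(abs(expected))) - digits) / 2
  expect_lt(abs(actual - expected), tol + 1e-12)
}
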