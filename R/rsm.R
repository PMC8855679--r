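#' Fit a polynomial response surface by ordinary least squares
#'
#' Fits the absorbance response to the coded factor levels for a given term
#' set. Coefficient standard errors come from the residual variance,
#' two-sided t tests address the hypothesis that each population
#' coefficient is zero, and the small-sample corrected AIC is computed
#' under the least-squares convention where the error variance counts as a
#' parameter (K = number of coefficients + 1).
#'
#' @param design A `ccd_design` / data frame with factor columns, or a
#'   coded-level matrix.
#' @param y Response values (absorbance, A.U.), one per run.
#' @param terms A [model_terms()] set; default full quadratic with all
#'   interactions.
#' @param level Confidence level for coefficient intervals (default 0.95).
#' @return An object of class `rsm_fit`: list with `terms`, `coefficients`,
#'   `se`, `cov`, `t_value`, `p_value`, `ci` (matrix lower/upper), `rss`,
#'   `sigma`, `df_residual`, `r_squared`, `adj_r_squared`, `aicc`, `n`,
#'   `fitted`, `residuals`, plus the model frame pieces needed to refit.
#' @examples
#' dat <- glycogen_ccd()
#' fit <- fit_rsm(dat, dat$absorbance)
#' summary(fit)
#' @export
fit_rsm <- function(design, y, terms = NULL, level = 0.95) {
  if (is.null(terms)) {
    nm <- if (is.matrix(design)) colnames(design) else attr(design, "factor_names")
    if (is.null(nm)) nm <- colnames(coded_levels(design))
    terms <- full_quadratic_terms(nm)
  }
  y <- as.numeric(y)
  if (any(!is.finite(y))) stop("non-finite responses", call. = FALSE)
  X <- build_design_matrix(design, terms)
  n <- nrow(X); p <- ncol(X)
  if (n < p + 1L) {
    stop("need at least one more run than model terms (", n, " runs, ",
         p, " terms)", call. = FALSE)
  }
  if (length(y) != n) stop("length(y) must equal the run count", call. = FALSE)
  qrx <- qr(X)
  if (qrx$rank < p) stop("singular design: model terms are confounded in this design",
                         call. = FALSE)
  lf <- stats::lm.fit(X, y)
  beta <- lf$coefficients
  res <- lf$residuals
  rss <- sum(res^2)
  df <- n - p
  sigma2 <- rss / df
  XtX_inv <- chol2inv(qr.R(qrx))
  covb <- sigma2 * XtX_inv
  dimnames(covb) <- list(names(beta), names(beta))
  se <- sqrt(diag(covb))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  tcrit <- stats::qt(1 - (1 - level) / 2, df)
  ci <- cbind(lower = beta - tcrit * se, upper = beta + tcrit * se)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  r2adj <- if (tss > 0) 1 - (1 - r2) * (n - 1) / df else 1
  fit <- structure(
    list(terms = terms, coefficients = beta, se = se, cov = covb,
         t_value = tval, p_value = pval, ci = ci, ci_level = level,
         rss = rss, sigma = sqrt(sigma2), df_residual = df,
         r_squared = r2, adj_r_squared = r2adj,
         n = n, fitted = lf$fitted.values, residuals = res,
         y = y, X = X, coded = coded_levels_or_matrix(design, terms)),
    class = "rsm_fit")
  fit$aicc <- aicc(fit)
  fit
}

coded_levels_or_matrix <- function(design, terms) {
  if (is.matrix(design)) design else coded_levels(design)
}

#' @export
print.rsm_fit <- function(x, ...) {
  cat(sprintf("Response-surface fit: %d terms, n = %d, R^2 = %.4f (adj %.4f), AICc = %.2f\n",
              length(x$coefficients), x$n, x$r_squared, x$adj_r_squared, x$aicc))
  invisible(x)
}

#' @export
summary.rsm_fit <- function(object, ...) {
  tab <- data.frame(estimate = object$coefficients, se = object$se,
                    lower = object$ci[, "lower"], upper = object$ci[, "upper"],
                    t = object$t_value, p = object$p_value)
  structure(list(table = tab, fit = object), class = "summary.rsm_fit")
}

#' @export
print.summary.rsm_fit <- function(x, ...) {
  print(x$fit)
  stats::printCoefmat(as.matrix(x$table), P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
coef.rsm_fit <- function(object, ...) object$coefficients

#' Coefficient table of a fitted surface
#'
#' @param fit An `rsm_fit`.
#' @return Data frame with term, estimate, se, CI bounds, t and p columns.
#' @export
coef_table <- function(fit) {
  stopifnot(inherits(fit, "rsm_fit"))
  data.frame(term = rownames(fit$terms), estimate = fit$coefficients,
             se = fit$se, lower = fit$ci[, "lower"], upper = fit$ci[, "upper"],
             t = fit$t_value, p = fit$p_value, row.names = NULL)
}

#' Small-sample corrected Akaike information criterion
#'
#' The least-squares form `n*log(rss/n) + 2K + 2K(K+1)/(n-K-1)` with
#' `K = p + 1`, counting the error variance as an estimated parameter --
#' the convention common curve-fitting software uses when comparing
#' least-squares models.
#'
#' @param fit An `rsm_fit`.
#' @return The AICc value.
#' @export
aicc <- function(fit) {
  stopifnot(inherits(fit, "rsm_fit"))
  n <- fit$n
  K <- length(fit$coefficients) + 1
  if (n - K - 1 <= 0) {
    stop("AICc undefined: n - K - 1 <= 0", call. = FALSE)
  }
  n * log(fit$rss / n) + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Compare two fits of the same data by AICc
#'
#' @param fit_a,fit_b `rsm_fit` objects fitted to the same response vector.
#' @return List with `delta` (= AICc(a) - AICc(b)) and `prob_correct`, the
#'   evidence-ratio probability `1 / (1 + exp(delta/2))` that model `a` is
#'   the better of the pair (0.5 when the fits tie).
#' @examples
#' dat <- glycogen_ccd()
#' full <- fit_rsm(dat, dat$absorbance)
#' sel  <- fit_rsm(dat, dat$absorbance, reduce_terms(full))
#' compare_aicc(sel, full)$delta   # about -20.9
#' @export
compare_aicc <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "rsm_fit"), inherits(fit_b, "rsm_fit"))
  if (fit_a$n != fit_b$n || !isTRUE(all.equal(fit_a$y, fit_b$y))) {
    stop("fits must be of the same data", call. = FALSE)
  }
  delta <- aicc(fit_a) - aicc(fit_b)
  list(delta = delta, prob_correct = 1 / (1 + exp(delta / 2)))
}

#' Reduce a fitted model, preserving hierarchy
#'
#' Removes terms whose coefficients are statistically indistinguishable
#' from zero (two-sided t test p >= `alpha`), with two exceptions: the
#' intercept is never removed, and a linear term is retained whenever any
#' retained higher-order term (interaction or square) involves that factor,
#' so the reduced polynomial stays well-formed. Higher-order terms are kept
#' only on their own evidence.
#'
#' @param fit An `rsm_fit`, normally of the full quadratic model.
#' @param alpha Significance level below which a term is considered
#'   established (default 0.05).
#' @return A [model_terms()] set for the reduced model.
#' @export
reduce_terms <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "rsm_fit"))
  terms <- fit$terms
  order_ <- rowSums(terms)
  significant <- fit$p_value < alpha
  keep <- significant | order_ == 0
  # hierarchy: linear term survives if a surviving higher-order term uses it
  higher <- which(keep & order_ >= 2)
  for (j in seq_len(ncol(terms))) {
    linear_row <- which(order_ == 1 & terms[, j] == 1)
    if (length(linear_row) == 1L && !keep[linear_row]) {
      if (any(terms[higher, j] >= 1)) keep[linear_row] <- TRUE
    }
  }
  model_terms(terms[keep, , drop = FALSE], colnames(terms))
}

#' Predict the fitted surface at coded points
#'
#' @param object An `rsm_fit`.
#' @param newdata Coded points: numeric vector (one point), matrix or data
#'   frame (one row per point) with factor columns.
#' @param level Confidence level (default 0.95) for the t-based interval on
#'   the mean response, using the coefficient covariance and the residual
#'   degrees of freedom.
#' @param extrapolation_limit Coded radius per factor beyond which the
#'   point is flagged as extrapolation (default the rotatable axial
#'   distance for the fit's factor count).
#' @param ... Unused.
#' @return Data frame with `estimate`, `lower`, `upper`, `extrapolated`.
#' @export
predict.rsm_fit <- function(object, newdata, level = 0.95,
                            extrapolation_limit = NULL, ...) {
  k <- ncol(object$terms)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, ncol = k, byrow = TRUE)
  pts <- as.matrix(as.data.frame(newdata)[, seq_len(k), drop = FALSE])
  colnames(pts) <- colnames(object$terms)
  X0 <- build_design_matrix(pts, object$terms)
  est <- drop(X0 %*% object$coefficients)
  se <- sqrt(rowSums((X0 %*% object$cov) * X0))
  tcrit <- stats::qt(1 - (1 - level) / 2, object$df_residual)
  if (is.null(extrapolation_limit)) extrapolation_limit <- axial_distance(max(k, 2))
  # small slack so printed 3-d.p. axial levels do not count as extrapolation
  extra <- apply(abs(pts) > extrapolation_limit + 1e-3, 1L, any)
  if (any(extra)) {
    warning("prediction outside the design region (|coded| > ",
            format(extrapolation_limit, digits = 4), ")", call. = FALSE)
  }
  data.frame(estimate = est, lower = est - tcrit * se,
             upper = est + tcrit * se, extrapolated = extra)
}

#' Center-point stability diagnostics
#'
#' Center replicates are dispersed through the run order so the process can
#' be monitored for drift (e.g. decay of the colored product over the
#' session). Residuals are each center absorbance minus the center mean,
#' reported against run order; the mean absolute deviation relative to the
#' center mean must stay under 5% for the run to pass.
#'
#' @param design A `ccd_design` (or data frame with a `point_type` column).
#' @param y Absorbances, one per run, in run order.
#' @param threshold Pass threshold on mad/mean (default 0.05).
#' @return List with `order` (run indices of the center points),
#'   `residuals`, `mean`, `mad`, `mad_over_mean`, `pass`.
#' @examples
#' dat <- glycogen_ccd()
#' center_point_drift(dat, dat$absorbance)  # mad ~ 0.008, pass
#' @export
center_point_drift <- function(design, y, threshold = 0.05) {
  pt <- design$point_type
  if (is.null(pt)) stop("design lacks a point_type column", call. = FALSE)
  idx <- which(pt == "center")
  if (length(idx) < 2L) {
    stop("insufficient replicates: need at least 2 center points", call. = FALSE)
  }
  yc <- as.numeric(y)[idx]
  m <- mean(yc)
  res <- yc - m
  mad_ <- mean(abs(res))
  ratio <- mad_ / m
  list(order = idx, residuals = res, mean = m, mad = mad_,
       mad_over_mean = ratio, pass = is.finite(ratio) && ratio < threshold)
}

#' Serialize a fit report to JSON
#'
#' @param fit An `rsm_fit`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The path (invisibly) or a JSON string.
#' @export
write_fit_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "rsm_fit"))
  rep <- list(
    terms = rownames(fit$terms),
    factor_names = colnames(fit$terms),
    exponents = unclass(fit$terms)[, , drop = FALSE],
    beta = as.list(fit$coefficients), se = as.list(fit$se),
    ci95 = list(lower = as.list(fit$ci[, "lower"]),
                upper = as.list(fit$ci[, "upper"])),
    p = as.list(fit$p_value),
    rss = fit$rss, df_residual = fit$df_residual,
    r2 = fit$r_squared, r2_adj = fit$adj_r_squared,
    aicc = fit$aicc, n = fit$n)
  if (is.null(path)) {
    jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

#' Rebuild an `rsm_fit` from a JSON fit report
#'
#' Reconstructs the term set and coefficient vector (plus covariance-free
#' summaries) sufficient for prediction and optimization.
#'
#' @param path JSON file written by [write_fit_json()].
#' @return A list with `terms` and `coefficients`; see Details.
#' @export
read_fit_json <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  terms <- model_terms(rep$exponents, rep$factor_names)
  list(terms = terms, coefficients = stats::setNames(unlist(rep$beta), rownames(terms)),
       r2 = rep$r2, aicc = rep$aicc)
}
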