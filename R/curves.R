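#' Fit a colorimetric standard curve
#'
#' Ordinary least-squares line of absorbance on analyte mass, restricted to
#' the linear (Beer's-law) region: observations with absorbance above the
#' saturation cap are excluded from the fit (the cap itself is inclusive,
#' and configurable). Outliers flagged by [detect_outliers_rout()] can be
#' excluded with `exclude_outliers = TRUE`; flags are otherwise advisory --
#' removing a flagged observation is a deliberate, logged user action, not
#' an automatic one.
#'
#' @param mass_ug Analyte mass per well, micrograms.
#' @param absorbance Blank-uncorrected absorbances, one per observation.
#' @param cap Absorbance cap, default 1.6 A.U.
#' @param exclude_outliers Drop ROUT-flagged observations before fitting.
#' @param q ROUT false-discovery rate (default 0.01) when
#'   `exclude_outliers` is used.
#' @param analyte Label (`"glucose"` or `"glycogen"`), metadata only.
#' @return An object of class `standard_curve`: slope and intercept (A.U.
#'   per ug and A.U.) with standard errors, logical `used` (entered the
#'   fit), `saturated` and `outlier` flags, and the input data.
#' @examples
#' m <- rep(c(0, 5, 10, 20), each = 2)
#' a <- 0.02 + 0.07 * m
#' fit_standard_curve(m, a)
#' @export
fit_standard_curve <- function(mass_ug, absorbance, cap = 1.6,
                               exclude_outliers = FALSE, q = 0.01,
                               analyte = "glycogen") {
  stopifnot(length(mass_ug) == length(absorbance))
  mass_ug <- as.numeric(mass_ug); absorbance <- as.numeric(absorbance)
  saturated <- absorbance > cap
  outlier <- rep(FALSE, length(mass_ug))
  if (exclude_outliers && sum(!saturated) >= 6L) {
    outlier[!saturated] <- detect_outliers_rout(mass_ug[!saturated],
                                                absorbance[!saturated], q = q)
  }
  used <- !saturated & !outlier
  if (length(unique(mass_ug[used])) < 3L) {
    stop("insufficient range: need at least 3 distinct mass levels under the cap",
         call. = FALSE)
  }
  fit <- stats::lm(absorbance[used] ~ mass_ug[used])
  cf <- summary(fit)$coefficients
  structure(
    list(analyte = analyte,
         slope = unname(cf[2L, 1L]), intercept = unname(cf[1L, 1L]),
         slope_se = unname(cf[2L, 2L]), intercept_se = unname(cf[1L, 2L]),
         cap = cap, used = used, saturated = saturated, outlier = outlier,
         mass_ug = mass_ug, absorbance = absorbance,
         df_residual = fit$df.residual, r_squared = summary(fit)$r.squared),
    class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("%s standard curve: slope %.5g A.U./ug (se %.2g), intercept %.4g A.U. (se %.2g)\n",
              x$analyte, x$slope, x$slope_se, x$intercept, x$intercept_se))
  cat(sprintf("  %d/%d observations used (%d saturated > %.3g A.U., %d flagged), R^2 = %.4f\n",
              sum(x$used), length(x$used), sum(x$saturated), x$cap,
              sum(x$outlier), x$r_squared))
  invisible(x)
}

#' Robust FDR-based outlier flagging for a standard line
#'
#' Robust-regression reimplementation of the two-stage outlier
#' identification popularized by curve-fitting software: fit the line by
#' iteratively reweighted least squares (M-estimation), take a robust
#' residual scale from the median absolute residual, and test each
#' absolute studentized residual against the t distribution, flagging at
#' false-discovery rate `q` (Benjamini-Hochberg). Flags never mutate a
#' fit; callers decide what to remove.
#'
#' @param mass_ug,absorbance Observations (at least 6).
#' @param q Target false-discovery rate, default 0.01.
#' @return Logical vector of flags.
#' @export
detect_outliers_rout <- function(mass_ug, absorbance, q = 0.01) {
  n <- length(mass_ug)
  stopifnot(length(absorbance) == n)
  if (n < 6L) stop("need at least 6 observations for outlier detection",
                   call. = FALSE)
  rfit <- suppressWarnings(MASS::rlm(absorbance ~ mass_ug, maxit = 100))
  res <- stats::residuals(rfit)
  scale <- stats::median(abs(res)) / 0.6745
  # a (near-)exact fit leaves nothing to flag except gross departures
  floor_ <- 1e-8 * max(stats::sd(absorbance), 1e-12)
  scale <- max(scale, floor_)
  df <- n - 2L
  t_ <- abs(res) / scale
  p <- 2 * stats::pt(-t_, df)
  ord <- order(p)
  flags <- rep(FALSE, n)
  # Benjamini-Hochberg step-up on the per-point p-values
  thresh <- q * seq_len(n) / n
  passed <- which(p[ord] <= thresh)
  if (length(passed)) flags[ord[seq_len(max(passed))]] <- TRUE
  flags
}

#' Blank-correct absorbances with a fitted curve
#'
#' Subtracts the curve's intercept so zero absorbance corresponds to zero
#' analyte -- the precondition for a meaningful coefficient of variation.
#'
#' @param absorbance Raw absorbances.
#' @param curve A `standard_curve` (or a single intercept value).
#' @return Blank-corrected absorbances.
#' @export
blank_correct <- function(absorbance, curve) {
  b <- if (inherits(curve, "standard_curve")) curve$intercept else as.numeric(curve)
  as.numeric(absorbance) - b
}

#' Select observations eligible for a CV summary
#'
#' Restricts to observations that survived curve-fitting filters (`used`)
#' and belong to a level that still has at least two replicates -- a CV of
#' a single replicate is undefined.
#'
#' @param mass_ug Level of each observation.
#' @param used Logical filter (e.g. a `standard_curve`'s `used` field).
#' @return Logical vector.
#' @export
cv_eligible <- function(mass_ug, used = rep(TRUE, length(mass_ug))) {
  stopifnot(length(mass_ug) == length(used))
  tab <- table(mass_ug[used])
  keep <- as.numeric(names(tab)[tab >= 2])
  used & mass_ug %in% keep
}

#' Intra-assay coefficients of variation
#'
#' Per mass level, `100 * sd / mean` of the blank-corrected replicate
#' absorbances, plus a weighted average across levels with weights equal
#' to the replicate counts. Levels whose mean is not positive get an `NA`
#' CV with an `undefined` flag (a ratio to a non-positive mean is
#' meaningless).
#'
#' @param mass_ug Level of each observation.
#' @param blanked Blank-corrected absorbances (see [blank_correct()]).
#' @return List with `per_level` (data frame: level, n, mean, sd, cv,
#'   undefined) and `weighted_cv` (percent).
#' @examples
#' intra_assay_cv(rep(10, 3), c(9, 10, 11) - 0)  # 10% at the one level
#' @export
intra_assay_cv <- function(mass_ug, blanked) {
  stopifnot(length(mass_ug) == length(blanked))
  lev <- sort(unique(mass_ug))
  rows <- lapply(lev, function(l) {
    v <- blanked[mass_ug == l]
    if (length(v) < 2L) {
      stop("need at least 2 replicates per level (level ", l, ")", call. = FALSE)
    }
    m <- mean(v); s <- stats::sd(v)
    undef <- m <= 0
    data.frame(level = l, n = length(v), mean = m, sd = s,
               cv = if (undef) NA_real_ else 100 * s / m,
               undefined = undef)
  })
  per_level <- do.call(rbind, rows)
  ok <- !per_level$undefined
  weighted <- if (any(ok)) {
    sum(per_level$cv[ok] * per_level$n[ok]) / sum(per_level$n[ok])
  } else NA_real_
  list(per_level = per_level, weighted_cv = weighted)
}
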