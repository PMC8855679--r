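#' Gradient of a fitted polynomial surface at coded points
#'
#' Analytic partial derivatives of the fitted polynomial with respect to
#' each coded factor, obtained by differentiating each term's monomial.
#'
#' @param fit An `rsm_fit` (or a list with `terms` and `coefficients`).
#' @param point Coded point (numeric vector, one entry per factor).
#' @return Named gradient vector.
#' @export
surface_gradient <- function(fit, point) {
  terms <- fit$terms
  beta <- fit$coefficients
  k <- ncol(terms)
  stopifnot(length(point) == k)
  g <- numeric(k)
  for (j in seq_len(k)) {
    e <- terms[, j]
    dterm <- numeric(nrow(terms))
    rows <- which(e >= 1)
    for (r in rows) {
      ex <- terms[r, ]
      val <- ex[j] * point[j]^(ex[j] - 1)
      others <- setdiff(seq_len(k), j)
      if (length(others)) val <- val * prod(point[others]^ex[others])
      dterm[r] <- val
    }
    g[j] <- sum(beta * dterm)
  }
  stats::setNames(g, colnames(terms))
}

#' Worst-case relative error of the predicted response
#'
#' First-order (total differential) propagation of per-factor pipetting
#' errors through the fitted surface, in the worst case where no error
#' cancels: `|1/R| * sum_i |dR/dx_i * delta_i|`, with `R` the predicted
#' response at the coded point and `delta_i` the coded perturbation
#' magnitudes. A 1% volume error on a 50 ul dispense corresponds to a
#' coded delta of about 0.05 for a typical coding map, which is the
#' default.
#'
#' @param fit An `rsm_fit`.
#' @param point Coded point.
#' @param deltas Per-factor coded perturbation magnitudes (>= 0); a scalar
#'   is recycled. Default 0.05.
#' @return The worst-case relative error (dimensionless fraction).
#' @examples
#' dat <- glycogen_ccd()
#' fit <- fit_rsm(dat, dat$absorbance, glycogen_selected_terms())
#' worst_case_relative_error(fit, c(0, 0, -1.682))
#' @export
worst_case_relative_error <- function(fit, point, deltas = 0.05) {
  k <- ncol(fit$terms)
  deltas <- rep_len(as.numeric(deltas), k)
  if (any(deltas < 0)) stop("perturbation deltas must be >= 0", call. = FALSE)
  R <- drop(build_design_matrix(matrix(point, 1), fit$terms) %*% fit$coefficients)
  if (abs(R) < .Machine$double.eps^0.5) {
    stop("undefined relative error: predicted response is zero at this point",
         call. = FALSE)
  }
  g <- surface_gradient(fit, point)
  sum(abs(g * deltas)) / abs(R)
}

condition_result <- function(point, response, objective, active, factor_names) {
  structure(list(coded_point = stats::setNames(point, factor_names),
                 predicted_response = response,
                 objective_value = objective,
                 constraints_active = active),
            class = "condition_result")
}

#' @export
print.condition_result <- function(x, ...) {
  cat("Selected assay condition (coded):\n")
  print(round(x$coded_point, 4))
  cat(sprintf("predicted response: %.4f A.U.; objective: %.5g\n",
              x$predicted_response, x$objective_value))
  if (length(x$constraints_active)) {
    cat("active constraints:", paste(x$constraints_active, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Maximize the predicted response over a coded box
#'
#' Seeded multi-start quasi-Newton search (L-BFGS-B with the analytic
#' gradient) for the condition of maximal signal. On a quadratic surface
#' the basins are few, so a modest number of random starts plus the box
#' corners reliably finds the global box-constrained maximum.
#'
#' @param fit An `rsm_fit`.
#' @param lower,upper Coded box bounds; scalars are recycled. Default the
#'   rotatable axial distance.
#' @param n_starts Number of random starts (default 32).
#' @param seed Seed for the start points.
#' @return A `condition_result`; `constraints_active` names the bounds the
#'   maximizer sits on.
#' @export
find_max_response <- function(fit, lower = NULL, upper = NULL,
                              n_starts = 32L, seed = 1L) {
  k <- ncol(fit$terms)
  a <- axial_distance(max(k, 2))
  if (is.null(lower)) lower <- -a
  if (is.null(upper)) upper <- a
  lower <- rep_len(lower, k); upper <- rep_len(upper, k)
  if (any(lower > upper)) stop("empty box: lower > upper", call. = FALSE)
  pred1 <- function(x) drop(build_design_matrix(matrix(x, 1), fit$terms) %*%
                              fit$coefficients)
  nll <- function(x) -pred1(x)
  ngr <- function(x) -surface_gradient(fit, x)
  starts <- multi_starts(lower, upper, n_starts, seed)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    opt <- stats::optim(starts[i, ], nll, ngr, method = "L-BFGS-B",
                        lower = lower, upper = upper)
    if (is.null(best) || opt$value < best$value - 1e-12) best <- opt
  }
  x <- unname(best$par)
  tol <- 1e-6
  active <- c(label_hits(colnames(fit$terms)[abs(x - lower) < tol], "_lower"),
              label_hits(colnames(fit$terms)[abs(x - upper) < tol], "_upper"))
  condition_result(x, pred1(x), pred1(x), active, colnames(fit$terms))
}

label_hits <- function(names, suffix) {
  if (length(names) == 0L) character(0) else paste0(names, suffix)
}

multi_starts <- function(lower, upper, n_starts, seed) {
  k <- length(lower)
  set.seed(as.integer(seed))
  rnd <- matrix(stats::runif(n_starts * k, rep(lower, each = n_starts),
                             rep(upper, each = n_starts)), ncol = k)
  corners <- as.matrix(expand.grid(Map(c, lower, upper)))
  colnames(corners) <- NULL
  center <- matrix((lower + upper) / 2, 1)
  rbind(rnd, corners, center)
}

#' Find a precise assay condition by minimizing worst-case error
#'
#' Minimizes [worst_case_relative_error()] over the coded box, optionally
#' subject to (i) factors pinned at fixed coded values (e.g. water at its
#' low axial level so no water is pipetted) and (ii) a minimum total
#' reaction volume, expressed through the factors' coding maps plus any
#' constant volume (sample aliquot) present in every reaction. The search
#' is a seeded multi-start Nelder-Mead over the free coordinates with the
#' linear volume constraint handled by an adaptive-barrier method; ties
#' between starts are broken toward the smaller gradient-magnitude sum
#' `sum_i |dR/dx_i|`.
#'
#' @param fit An `rsm_fit`.
#' @param deltas Per-factor coded perturbations, as in
#'   [worst_case_relative_error()].
#' @param lower,upper Coded box over the free factors (default the
#'   rotatable axial distance).
#' @param fixed Named numeric vector of factors pinned at coded values. A
#'   pinned level overrides the box and may sit at (or just beyond) the
#'   edge of the design region -- e.g. water pinned at its low axial level
#'   so no water is pipetted -- at the usual cost of extrapolation.
#' @param factors List of [factor_spec()]s (required when `min_volume` is
#'   given, to decode coded levels into microliters).
#' @param min_volume Minimum total reaction volume in microliters.
#' @param constant_volume Volume present in every reaction regardless of
#'   the factors (e.g. the 50 ul sample aliquot); default 0.
#' @param n_starts,seed Multi-start control.
#' @return A `condition_result` recording the point, its predicted
#'   response, the objective value and the active constraints.
#' @export
find_precise_condition <- function(fit, deltas = 0.05,
                                   lower = NULL, upper = NULL,
                                   fixed = NULL, factors = NULL,
                                   min_volume = NULL, constant_volume = 0,
                                   n_starts = 32L, seed = 1L) {
  nm <- colnames(fit$terms)
  k <- length(nm)
  a <- axial_distance(max(k, 2))
  if (is.null(lower)) lower <- -a
  if (is.null(upper)) upper <- a
  lower <- rep_len(lower, k); upper <- rep_len(upper, k)
  deltas <- rep_len(as.numeric(deltas), k)
  if (all(deltas == 0)) {
    warning("all perturbation deltas are zero: objective is identically 0; ",
            "returning the feasible point with smallest gradient-magnitude sum",
            call. = FALSE)
  }
  fixed_idx <- integer(0)
  x_fixed <- numeric(0)
  if (!is.null(fixed)) {
    if (is.null(names(fixed)) || !all(names(fixed) %in% nm)) {
      stop("'fixed' must be named with factor names", call. = FALSE)
    }
    fixed_idx <- match(names(fixed), nm)
    x_fixed <- as.numeric(fixed)
  }
  free_idx <- setdiff(seq_len(k), fixed_idx)

  # linear volume constraint in coded units: sum_i (center_i + r_i x_i) + c0 >= vmin
  vol_coef <- NULL; vol_rhs <- NULL
  if (!is.null(min_volume)) {
    if (is.null(factors)) {
      stop("'factors' (coding maps) are required for a volume constraint",
           call. = FALSE)
    }
    stopifnot(length(factors) == k)
    centers <- vapply(factors, `[[`, 0, "center")
    ranges <- vapply(factors, `[[`, 0, "half_range")
    base <- constant_volume + sum(centers) +
      sum(ranges[fixed_idx] * x_fixed)
    vol_coef <- ranges[free_idx]
    vol_rhs <- min_volume - base
  }

  assemble <- function(xf) {
    x <- numeric(k)
    x[fixed_idx] <- x_fixed
    x[free_idx] <- xf
    x
  }
  obj <- function(xf) {
    # a vanishing predicted response is an (infinitely) imprecise condition
    tryCatch(worst_case_relative_error(fit, assemble(xf), deltas),
             error = function(e) 1e10)
  }
  grad_norm <- function(x) sum(abs(surface_gradient(fit, x)))

  feasible <- function(xf) {
    all(xf >= lower[free_idx] - 1e-9) && all(xf <= upper[free_idx] + 1e-9) &&
      (is.null(vol_coef) || sum(vol_coef * xf) >= vol_rhs - 1e-9)
  }
  if (!is.null(vol_coef) &&
      sum(pmax(vol_coef * upper[free_idx], vol_coef * lower[free_idx])) < vol_rhs - 1e-9) {
    stop("infeasible constraints: the box cannot reach the minimum volume",
         call. = FALSE)
  }
  if (length(free_idx) == 0L) {
    x <- assemble(numeric(0))
    pred <- drop(build_design_matrix(matrix(x, 1), fit$terms) %*% fit$coefficients)
    return(condition_result(x, pred, worst_case_relative_error(fit, x, deltas),
                            paste0(nm[fixed_idx], "_fixed"), nm))
  }

  # ui %*% x >= ci for constrOptim: box rows plus the volume row
  p <- length(free_idx)
  ui <- rbind(diag(p), -diag(p))
  ci <- c(lower[free_idx], -upper[free_idx])
  if (!is.null(vol_coef)) { ui <- rbind(ui, vol_coef); ci <- c(ci, vol_rhs) }

  starts <- multi_starts(lower[free_idx], upper[free_idx], n_starts, seed)
  starts <- starts[apply(starts, 1L, feasible), , drop = FALSE]
  if (nrow(starts) == 0L) {
    # rejection-sample feasible starts
    set.seed(as.integer(seed))
    tries <- matrix(stats::runif(5000 * p, rep(lower[free_idx], each = 5000),
                                 rep(upper[free_idx], each = 5000)), ncol = p)
    starts <- tries[apply(tries, 1L, feasible), , drop = FALSE]
    if (nrow(starts) == 0L) {
      # vertex of the box with maximal volume is feasible (checked above)
      v <- ifelse(vol_coef >= 0, upper[free_idx], lower[free_idx])
      starts <- matrix(v, 1)
    }
    starts <- starts[seq_len(min(nrow(starts), n_starts)), , drop = FALSE]
  }
  # strictly interior starts for the barrier method
  shrink <- function(xf) {
    eps <- 1e-6
    xf <- pmin(pmax(xf, lower[free_idx] + eps), upper[free_idx] - eps)
    if (!is.null(vol_coef) && sum(vol_coef * xf) < vol_rhs + eps) {
      v <- ifelse(vol_coef >= 0, upper[free_idx], lower[free_idx])
      lam <- 0.5
      while (sum(vol_coef * xf) < vol_rhs + eps && lam < 1) {
        xf <- (1 - lam) * xf + lam * (v - sign(v) * eps)
        lam <- lam + 0.1
      }
    }
    xf
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    x0 <- shrink(starts[i, ])
    if (!feasible(x0)) next
    opt <- if (p == 1L) {
      # Nelder-Mead is unreliable in 1-D; use a dense line search instead
      lo <- lower[free_idx]; hi <- upper[free_idx]
      if (!is.null(vol_coef)) {
        if (vol_coef > 0) lo <- max(lo, vol_rhs / vol_coef)
        if (vol_coef < 0) hi <- min(hi, vol_rhs / vol_coef)
      }
      o <- stats::optimize(obj, c(lo, hi), tol = 1e-9)
      grid <- seq(lo, hi, length.out = 2001)
      vals <- vapply(grid, obj, 0)
      gbest <- grid[which.min(vals)]
      if (min(vals) < o$objective) list(par = gbest, value = min(vals))
      else list(par = o$minimum, value = o$objective)
    } else {
      tryCatch(
        stats::constrOptim(x0, obj, grad = NULL, ui = ui, ci = ci - 1e-9,
                           control = list(reltol = 1e-12, maxit = 2000)),
        error = function(e) NULL)
    }
    if (is.null(opt)) next
    cand <- list(par = opt$par, value = opt$value,
                 gnorm = grad_norm(assemble(opt$par)))
    if (is.null(best) || cand$value < best$value - 1e-10 ||
        (abs(cand$value - best$value) <= 1e-10 && cand$gnorm < best$gnorm)) {
      best <- cand
    }
  }
  if (is.null(best)) stop("optimization failed from every start", call. = FALSE)
  x <- assemble(best$par)
  pred <- drop(build_design_matrix(matrix(x, 1), fit$terms) %*% fit$coefficients)
  tol <- 1e-4
  active <- c(
    label_hits(nm[fixed_idx], "_fixed"),
    label_hits(nm[free_idx][abs(best$par - lower[free_idx]) < tol], "_lower"),
    label_hits(nm[free_idx][abs(best$par - upper[free_idx]) < tol], "_upper"))
  if (!is.null(vol_coef) && abs(sum(vol_coef * best$par) - vol_rhs) < tol * max(1, abs(vol_rhs))) {
    active <- c(active, "min_volume")
  }
  condition_result(x, pred, best$value, active, nm)
}
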