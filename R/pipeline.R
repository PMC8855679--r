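#' Validated pipeline configuration
#'
#' Collects the tunables of the analysis workflow and validates them
#' before any stage runs: the term-removal significance level, the
#' perturbation deltas of the precision objective, the standard-curve
#' saturation cap, the outlier FDR, and the master seed. The config is
#' serialized (with a content hash) into every report so a run can be
#' reproduced from its outputs.
#'
#' @param alpha Term-removal significance level (default 0.05).
#' @param deltas Coded perturbation magnitudes (default 0.05).
#' @param cap Standard-curve absorbance cap (default 1.6).
#' @param q Outlier false-discovery rate (default 0.01).
#' @param seed Master seed (default 1).
#' @param measurements Optional path to a measurement CSV (columns:
#'   `run_index`, `point_type`, coded factor columns, `absorbance`).
#' @param standards Optional path to a standards CSV (columns `level_ug`,
#'   `replicate`, `absorbance`).
#' @param samples Optional path to a samples CSV (columns `sample_id`,
#'   `m_tissue_mg`, `v_sample_ul`, `v_assayed_ul`, `absorbance`).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(alpha = 0.05, deltas = 0.05, cap = 1.6, q = 0.01,
                       seed = 1L, measurements = NULL, standards = NULL,
                       samples = NULL) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  stopifnot(is.numeric(deltas), all(deltas >= 0))
  stopifnot(is.numeric(cap), length(cap) == 1L, cap > 0)
  stopifnot(is.numeric(q), length(q) == 1L, q > 0, q < 1)
  stopifnot(length(seed) == 1L, is.finite(seed))
  for (p in c(measurements, standards, samples)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("input file does not exist: ", p, call. = FALSE)
    }
  }
  structure(list(alpha = alpha, deltas = deltas, cap = cap, q = q,
                 seed = as.integer(seed), measurements = measurements,
                 standards = standards, samples = samples),
            class = "run_config")
}

config_hash <- function(config) {
  # small content hash (djb2) so reports identify their configuration
  s <- paste(utils::capture.output(utils::str(unclass(config))), collapse = "\n")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}

read_measurements_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  required <- c("run_index", "point_type", "absorbance")
  missing <- setdiff(required, names(df))
  if (nrow(df) == 0L || length(missing)) {
    stop("measurement sheet invalid: ",
         if (nrow(df) == 0L) "no data rows" else
           paste("missing columns:", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  coded <- grep("_coded$", names(df), value = TRUE)
  nm <- if (length(coded)) sub("_coded$", "", coded) else
    setdiff(names(df), c(required, "order", "true_mean"))
  if (length(nm) < 2L) stop("measurement sheet invalid: fewer than 2 factor columns",
                            call. = FALSE)
  bad <- which(!is.finite(df$absorbance) | df$absorbance < 0)
  if (length(bad)) {
    stop("measurement sheet invalid: non-finite or negative absorbance in rows ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(run_index = df$run_index, point_type = df$point_type,
                    absorbance = df$absorbance, check.names = FALSE)
  src <- if (length(coded)) coded else nm
  for (i in seq_along(nm)) out[[nm[i]]] <- as.numeric(df[[src[i]]])
  structure(out, class = c("ccd_design", "data.frame"),
            factor_names = nm, factors = NULL, seed = NA_integer_,
            axial = max(abs(as.matrix(out[nm]))))
}

#' Run the analysis pipeline
#'
#' Executes the modelling stages on the configured inputs: full-quadratic
#' fit, hierarchy-preserving reduction, AICc comparison of reduced vs full
#' model, and center-point drift diagnostics; then, if configured, the
#' standard-curve stage (cap filter, outlier flags, blank correction,
#' intra-assay CV) and the sample quantification stage. Inputs are never
#' mutated; a rerun with the same config produces the same report.
#'
#' @param config A [run_config()].
#' @param measurements Optional measurement data frame (a `ccd_design`
#'   with an `absorbance` column), overriding the config's CSV path.
#' @return A report list of class `pipeline_report`; see the elements
#'   `fit_full`, `fit_selected`, `aicc_comparison`, `drift`, `curve`,
#'   `cv`, `quantified`, plus `config`, `config_hash` and `seed`.
#' @examples
#' dat <- glycogen_ccd()
#' rep <- run_pipeline(run_config(), measurements = dat)
#' rep$aicc_comparison$delta
#' @export
run_pipeline <- function(config = run_config(), measurements = NULL) {
  stopifnot(inherits(config, "run_config"))
  log_ <- character(0)
  note <- function(...) log_ <<- c(log_, sprintf(...))

  if (is.null(measurements) && !is.null(config$measurements)) {
    measurements <- read_measurements_csv(config$measurements)
  }
  if (is.null(measurements) && is.null(config$standards)) {
    stop("no measurements: supply a data frame or a CSV path in the config",
         call. = FALSE)
  }

  fit_full <- fit_sel <- cmp <- drift <- sel_terms <- NULL
  if (!is.null(measurements)) {
    if (is.null(measurements$absorbance)) {
      stop("measurements lack an 'absorbance' column", call. = FALSE)
    }
    y <- measurements$absorbance
    nm <- attr(measurements, "factor_names")
    note("fit: %d runs, factors %s", nrow(measurements),
         paste(nm, collapse = ","))

    fit_full <- fit_rsm(measurements, y)
    sel_terms <- reduce_terms(fit_full, alpha = config$alpha)
    fit_sel <- fit_rsm(measurements, y, sel_terms)
    cmp <- compare_aicc(fit_sel, fit_full)
    note("reduce: %d -> %d terms (alpha %.3g); dAICc %.2f",
         nrow(fit_full$terms), nrow(sel_terms), config$alpha, cmp$delta)
    drift <- center_point_drift(measurements, y)
    note("drift: mad/mean %.3f (%s)", drift$mad_over_mean,
         if (drift$pass) "pass" else "FAIL")
  }

  curve <- NULL; cv <- NULL
  if (!is.null(config$standards)) {
    std <- utils::read.csv(config$standards)
    if (nrow(std) == 0L || !all(c("level_ug", "absorbance") %in% names(std))) {
      stop("standards sheet invalid: needs level_ug and absorbance columns",
           call. = FALSE)
    }
    curve <- fit_standard_curve(std$level_ug, std$absorbance, cap = config$cap,
                                exclude_outliers = TRUE, q = config$q)
    use <- cv_eligible(std$level_ug, curve$used)
    cv <- intra_assay_cv(std$level_ug[use],
                         blank_correct(std$absorbance[use], curve))
    note("curve: slope %.5g, weighted CV %.2f%%", curve$slope, cv$weighted_cv)
  }

  quantified <- NULL
  if (!is.null(config$samples)) {
    if (is.null(curve)) stop("sample quantification requires a standards sheet",
                             call. = FALSE)
    smp <- utils::read.csv(config$samples)
    need <- c("sample_id", "m_tissue_mg", "v_sample_ul", "v_assayed_ul",
              "absorbance")
    if (nrow(smp) == 0L || !all(need %in% names(smp))) {
      stop("samples sheet invalid: needs columns ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    m_curve <- blank_correct(smp$absorbance, curve) / curve$slope
    smp$glycogen_ug_per_mg <- tissue_glycogen(pmax(m_curve, 0),
                                              smp$v_assayed_ul,
                                              smp$v_sample_ul,
                                              smp$m_tissue_mg)
    quantified <- smp
    note("quantify: %d samples", nrow(smp))
  }

  structure(list(config = unclass(config), config_hash = config_hash(config),
                 seed = config$seed,
                 fit_full = fit_full, fit_selected = fit_sel,
                 selected_terms = if (!is.null(sel_terms)) rownames(sel_terms),
                 aicc_comparison = cmp, drift = drift,
                 curve = curve, cv = cv, quantified = quantified,
                 log = log_),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("assayrsm pipeline report (config", x$config_hash, ")\n")
  for (l in x$log) cat(" -", l, "\n")
  invisible(x)
}

#' Write a pipeline report to JSON
#'
#' @param report A `pipeline_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "pipeline_report"))
  out <- list(
    config = report$config, config_hash = report$config_hash,
    seed = report$seed, log = report$log)
  fit <- report$fit_selected
  if (!is.null(fit)) {
    out$selected_model <- list(
      terms = rownames(fit$terms), beta = as.list(fit$coefficients),
      se = as.list(fit$se), p = as.list(fit$p_value),
      r2 = fit$r_squared, r2_adj = fit$adj_r_squared, aicc = fit$aicc)
    out$full_model <- list(terms = rownames(report$fit_full$terms),
                           aicc = report$fit_full$aicc)
    out$aicc_comparison <- report$aicc_comparison
    out$drift <- report$drift[c("mean", "mad", "mad_over_mean", "pass")]
  }
  if (!is.null(report$cv)) {
    out$curve <- list(slope = report$curve$slope,
                      intercept = report$curve$intercept,
                      weighted_cv = report$cv$weighted_cv)
  }
  if (!is.null(report$quantified)) out$samples <- report$quantified
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
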