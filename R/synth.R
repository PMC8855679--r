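#' Simulate absorbance measurements on a design
#'
#' Draws one absorbance per design run from a known polynomial surface
#' plus additive iid Gaussian replicate noise. The default surface is the
#' packaged glycogen response surface and the default noise SD (0.013
#' A.U.) is the spread of the packaged experiment's center replicates, so
#' simulated experiments look statistically like the real one.
#'
#' @param design A `ccd_design` (or coded-level data frame / matrix).
#' @param coefficients True coefficient vector, aligned with `terms`.
#' @param terms [model_terms()] of the true surface.
#' @param noise_sd Replicate noise SD, A.U. (>= 0), default 0.013.
#' @param seed Integer seed; calls with the same inputs and seed return
#'   identical measurements.
#' @return The design data frame with an `absorbance` column (and
#'   `true_mean`, the noiseless surface value).
#' @examples
#' d <- ccd_design(c("phenol", "acid", "water"), n_center = 6, seed = 7)
#' sim <- simulate_surface_measurements(d, seed = 7)
#' @export
simulate_surface_measurements <- function(design,
                                          coefficients = glycogen_surface_coefficients(),
                                          terms = glycogen_selected_terms(),
                                          noise_sd = 0.013, seed = 1L) {
  stopifnot(noise_sd >= 0, length(coefficients) == nrow(terms))
  lev <- if (is.matrix(design)) design else coded_levels(design)
  colnames(lev) <- colnames(terms)  # factors are identified positionally
  X <- build_design_matrix(lev, terms)
  mu <- drop(X %*% coefficients)
  set.seed(as.integer(seed))
  y <- mu + stats::rnorm(length(mu), 0, noise_sd)
  out <- as.data.frame(design)
  out$true_mean <- mu
  out$absorbance <- y
  attributes_from(out, design)
}

attributes_from <- function(out, design) {
  for (a in c("factor_names", "factors", "seed", "axial")) {
    attr(out, a) <- attr(design, a)
  }
  if (inherits(design, "ccd_design")) class(out) <- c("ccd_design", "data.frame")
  out
}

#' Simulate a standard-curve plate
#'
#' Absorbance follows a Beer's-law line in analyte mass with
#' multiplicative noise (SD = `cv`, matching how replicate scatter on a
#' curve is summarized as a %CV); readings above the saturation cap are
#' flagged. Defaults mirror the optimized glycogen assay: slope 0.07279
#' A.U./ug, small positive blank, 0-25 ug standards in quadruplicate.
#'
#' @param slope True slope, A.U. per ug (> 0).
#' @param intercept True blank absorbance, A.U.
#' @param cv Multiplicative noise fraction (default 0.07, mid intra-assay
#'   band).
#' @param levels_ug Standard masses, ug.
#' @param reps Replicates per level.
#' @param cap Saturation cap for the `saturating` flag, default 1.6.
#' @param seed Integer seed.
#' @return Data frame: `level_ug`, `replicate`, `absorbance`,
#'   `saturating`.
#' @export
simulate_standard_curve <- function(slope = 0.07279, intercept = 0.02,
                                    cv = 0.07,
                                    levels_ug = c(0, 1, 2.5, 5, 10, 15, 20, 25),
                                    reps = 4L, cap = 1.6, seed = 1L) {
  stopifnot(slope > 0, cv >= 0, reps >= 1)
  lev <- rep(levels_ug, each = reps)
  mu <- intercept + slope * lev
  set.seed(as.integer(seed))
  a <- mu * (1 + stats::rnorm(length(mu), 0, cv))
  data.frame(level_ug = lev, replicate = rep(seq_len(reps), length(levels_ug)),
             absorbance = a, saturating = a > cap)
}

#' Simulate the ethanol precipitation / centrifugation series
#'
#' A control mixture of free glucose and glycogen goes through repeated
#' precipitation-centrifugation rounds. Each spin retains glycogen with
#' the per-spin recovery fraction and carries over only a small fraction
#' of the free glucose (pre-noise, glucose after n spins is exactly
#' `initial * carryover^n`). The total carbohydrate read out after each
#' round carries multiplicative measurement noise. With the defaults the
#' round-1 total is essentially the glycogen content and later rounds are
#' flat: one precipitation suffices to remove free sugar.
#'
#' @param initial_glucose Free glucose in the mixture, mg/dl (default 60).
#' @param initial_glycogen Glycogen in the mixture, mg/dl (default 40).
#' @param glycogen_recovery Per-spin glycogen retention fraction
#'   (default 0.93).
#' @param glucose_carryover Per-spin fraction of free glucose carried into
#'   the next pellet (default 0.005; the true value is not measurable from
#'   the readouts, only that one spin removes essentially all of it).
#' @param n_precipitations Number of rounds (>= 1), default 4.
#' @param noise_cv Measurement noise fraction on the totals, default 0.05.
#' @param seed Integer seed.
#' @return Data frame per round: `precipitation`, `glucose`, `glycogen`,
#'   `total` (all pre-noise, mg/dl) and `measured_total`.
#' @export
simulate_extraction <- function(initial_glucose = 60, initial_glycogen = 40,
                                glycogen_recovery = 0.93,
                                glucose_carryover = 0.005,
                                n_precipitations = 4L, noise_cv = 0.05,
                                seed = 1L) {
  stopifnot(n_precipitations >= 1,
            glycogen_recovery >= 0, glycogen_recovery <= 1,
            glucose_carryover >= 0, glucose_carryover <= 1)
  r <- seq_len(n_precipitations)
  glucose <- initial_glucose * glucose_carryover^r
  glycogen <- initial_glycogen * glycogen_recovery^r
  total <- glucose + glycogen
  set.seed(as.integer(seed))
  measured <- total * (1 + stats::rnorm(length(total), 0, noise_cv))
  data.frame(precipitation = r, glucose = glucose, glycogen = glycogen,
             total = total, measured_total = measured)
}

#' Simulate hydrolysis-yield readings on paired standard curves
#'
#' Generates the paired readings behind a fractional-yield comparison:
#' aliquots of a known glycogen mass read against (i) a glycogen standard
#' curve, which returns the true mass up to noise (same substrate, the
#' incomplete hydrolysis cancels), and (ii) a glucose standard curve,
#' which returns `completeness * (180/162)` times the true mass --
#' hydrolysis releases a fraction `completeness` of the glucosyl units,
#' each gaining back the water of condensation.
#'
#' @param mass_ug True glycogen mass per aliquot.
#' @param completeness Hydrolysis completeness fraction in the
#'   colorimetric reaction (default 0.837, which puts the mass yield near
#'   0.93).
#' @param cv Multiplicative reading noise (default 0.05).
#' @param reps Replicates per curve.
#' @param seed Integer seed.
#' @return List with vectors `from_glycogen_curve_ug` and
#'   `from_glucose_curve_ug`.
#' @export
simulate_yield_readings <- function(mass_ug = 15, completeness = 0.837,
                                    cv = 0.05, reps = 4L, seed = 1L) {
  stopifnot(completeness >= 0, completeness <= 1, reps >= 1)
  set.seed(as.integer(seed))
  gly <- mass_ug * (1 + stats::rnorm(reps, 0, cv))
  glc <- mass_ug * completeness * (180 / 162) * (1 + stats::rnorm(reps, 0, cv))
  list(from_glycogen_curve_ug = gly, from_glucose_curve_ug = glc)
}

#' Simulate a tissue panel end to end
#'
#' Generates tissue samples of known glycogen content, pushes them through
#' the extraction model (one precipitation: glycogen retained with the
#' recovery fraction, free glucose essentially removed), reads the
#' dissolved pellet on a simulated glycogen standard curve in duplicate,
#' and quantifies with [fit_standard_curve()], [blank_correct()] and
#' [tissue_glycogen()]. The default retention of 1.0 encodes the observed
#' behaviour of the one-spin protocol (glycogen is not removed); set it
#' lower to model lossy extractions.
#'
#' @param n_samples Number of tissue samples.
#' @param content_ug_per_mg True glycogen content, ug per mg tissue
#'   (scalar or per sample).
#' @param free_glucose_ug_per_mg Free glucose in the tissue (default 5),
#'   almost all of which the spin removes.
#' @param m_tissue_mg Tissue mass per sample (default 25 mg).
#' @param v_sample_ul Pellet dissolution volume (default 1000 ul).
#' @param v_assayed_ul Aliquot assayed (default 10 ul).
#' @param recovery Per-spin glycogen retention (default 1.0).
#' @param carryover Per-spin free-glucose carryover (default 0.005).
#' @param slope,intercept True curve parameters (defaults 0.07279, 0.02).
#' @param cv Per-well multiplicative noise (default 0.07).
#' @param reps Assay replicates per sample (default 2, averaged).
#' @param seed Integer seed.
#' @return Data frame per sample: `sample`, `true_content`,
#'   `estimated_content` (ug/mg) and `rel_error`.
#' @export
simulate_tissue_panel <- function(n_samples = 6L, content_ug_per_mg = 50,
                                  free_glucose_ug_per_mg = 5,
                                  m_tissue_mg = 25, v_sample_ul = 1000,
                                  v_assayed_ul = 10,
                                  recovery = 1.0, carryover = 0.005,
                                  slope = 0.07279, intercept = 0.02,
                                  cv = 0.07, reps = 2L, seed = 1L) {
  stopifnot(n_samples >= 1, recovery >= 0, recovery <= 1)
  content <- rep_len(content_ug_per_mg, n_samples)
  set.seed(as.integer(seed))
  curve_seed <- sample.int(2^30, 1L)
  std <- simulate_standard_curve(slope = slope, intercept = intercept,
                                 cv = cv, seed = curve_seed)
  curve <- fit_standard_curve(std$level_ug, std$absorbance)

  # pellet carbohydrate after one spin, expressed per assay well
  pellet_ug <- content * m_tissue_mg * recovery +
    free_glucose_ug_per_mg * m_tissue_mg * carryover
  well_ug <- pellet_ug / v_sample_ul * v_assayed_ul
  est <- numeric(n_samples)
  for (i in seq_len(n_samples)) {
    # CV-structured noise on the analyte signal, on top of the true blank
    a <- intercept + slope * well_ug[i] * (1 + stats::rnorm(reps, 0, cv))
    m_curve <- mean(blank_correct(a, curve)) / curve$slope
    est[i] <- tissue_glycogen(max(m_curve, 0), v_assayed_ul, v_sample_ul,
                              m_tissue_mg)
  }
  data.frame(sample = seq_len(n_samples), true_content = content,
             estimated_content = est, rel_error = est / content - 1)
}
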