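#' Tissue glycogen content from a standard-curve readout
#'
#' Converts the mass read off the standard curve for the assayed aliquot
#' into glycogen per milligram of tissue:
#' `(m_curve / V_assayed) * V_sample / m_tissue`, i.e. the aliquot's
#' concentration scaled up to the full dissolution volume and normalized
#' by tissue mass. The result is homogeneous of degree 1 in `m_curve` and
#' `v_sample_ul` and of degree -1 in `v_assayed_ul` and `m_tissue_mg`.
#'
#' @param m_curve_ug Mass determined from the standard curve, micrograms.
#' @param v_assayed_ul Volume of sample solution put into the assay well,
#'   microliters.
#' @param v_sample_ul Volume of water used to dissolve the glycogen
#'   pellet, microliters.
#' @param m_tissue_mg Tissue mass used to make the sample, milligrams.
#' @return Glycogen content, micrograms per milligram of tissue
#'   (equivalently mg/g). Vectorized over all arguments.
#' @examples
#' tissue_glycogen(10, 5, 1000, 20)  # 100 ug/mg
#' @export
tissue_glycogen <- function(m_curve_ug, v_assayed_ul, v_sample_ul, m_tissue_mg) {
  args <- list(m_curve_ug = m_curve_ug, v_assayed_ul = v_assayed_ul,
               v_sample_ul = v_sample_ul, m_tissue_mg = m_tissue_mg)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      stop("'", nm, "' must be finite numeric", call. = FALSE)
    }
  }
  if (any(m_curve_ug < 0)) stop("'m_curve_ug' must be >= 0", call. = FALSE)
  for (nm in c("v_assayed_ul", "v_sample_ul", "m_tissue_mg")) {
    if (any(args[[nm]] <= 0)) stop("'", nm, "' must be > 0", call. = FALSE)
  }
  (m_curve_ug / v_assayed_ul) * v_sample_ul / m_tissue_mg
}

#' Glucose units per glycogen particle
#'
#' A glycogen particle of N glucosyl units has molar mass `162N + 18`
#' g/mol: each unit contributes the 162 g/mol dehydrated residue and the
#' chain carries one extra water. Inverting and truncating gives the whole
#' number of units a particle of the given mass can hold; at N = 1 the
#' formula recovers free glucose (180 g/mol).
#'
#' @param particle_mass Glycogen particle molar mass, g/mol (>= 180).
#' @return Integer number of glucose units, `floor((mass - 18)/162)`.
#' @examples
#' glycogen_units_per_particle(1e6)  # 6172
#' @export
glycogen_units_per_particle <- function(particle_mass) {
  if (any(!is.finite(particle_mass)) || any(particle_mass < 180)) {
    stop("invalid mass: particle mass must be >= 180 g/mol (free glucose)",
         call. = FALSE)
  }
  floor((particle_mass - 18) / 162)
}

#' Molar mass of a glycogen particle with N units
#'
#' @param n_units Number of glucosyl units (positive integer).
#' @return Molar mass `162*N + 18` g/mol.
#' @export
glycogen_particle_mass <- function(n_units) {
  if (any(n_units < 1) || any(n_units != round(n_units))) {
    stop("'n_units' must be positive integers", call. = FALSE)
  }
  162 * n_units + 18
}

#' Convert a carbohydrate mass to micromoles of glucose equivalents
#'
#' Uses 180 g/mol for free glucose and 162 g/mol for a glucosyl residue in
#' glycogen (water is lost on polymerization).
#'
#' @param mass_ug Mass in micrograms (>= 0).
#' @param basis `"free_glucose"` (/180) or `"glucosyl_unit"` (/162).
#' @return Micromoles.
#' @export
glucose_equivalents <- function(mass_ug, basis = c("free_glucose", "glucosyl_unit")) {
  basis <- match.arg(basis)
  if (any(mass_ug < 0)) stop("'mass_ug' must be >= 0", call. = FALSE)
  mass_ug / switch(basis, free_glucose = 180, glucosyl_unit = 162)
}

#' Fractional yield of hydrolyzed glucose against the glycogen reading
#'
#' Ratio of the mass read from a glucose standard curve (the realized
#' signal) to the mass read from a glycogen standard curve (the expected
#' amount). On the `"mass"` scale this is the plain ratio; on the
#' `"molar"` scale the numerator is converted to moles of glucose
#' (180 g/mol) and the denominator to the moles of glucose a particle of
#' the configured molar mass would release on complete hydrolysis
#' (`N / (162N + 18)` mol glucose per gram of glycogen).
#'
#' @param mass_from_glucose_curve_ug Mass via the glucose curve, ug.
#' @param mass_from_glycogen_curve_ug Mass via the glycogen curve, ug (> 0).
#' @param scale `"mass"` or `"molar"`.
#' @param particle_mass Assumed glycogen particle molar mass, g/mol
#'   (default 1e6); the unit count is recomputed from it.
#' @return The fractional yield.
#' @export
fractional_yield <- function(mass_from_glucose_curve_ug,
                             mass_from_glycogen_curve_ug,
                             scale = c("mass", "molar"),
                             particle_mass = 1e6) {
  scale <- match.arg(scale)
  if (any(mass_from_glycogen_curve_ug <= 0)) {
    stop("glycogen-curve mass must be > 0", call. = FALSE)
  }
  if (scale == "mass") {
    return(mass_from_glucose_curve_ug / mass_from_glycogen_curve_ug)
  }
  n <- glycogen_units_per_particle(particle_mass)
  mol_glucose <- mass_from_glucose_curve_ug / 180
  mol_expected <- mass_from_glycogen_curve_ug * n / (162 * n + 18)
  mol_glucose / mol_expected
}

#' Difference of group means with a t confidence interval
#'
#' The interval treats the two groups symmetrically (two-sample t with
#' pooled variance by default; Welch optional) and deliberately does not
#' propagate any model-prediction uncertainty -- when one "group" is a set
#' of model predictions at a condition, the interval reflects only the
#' replicate scatter, as in the verification comparisons this supports.
#'
#' @param group_a,group_b Numeric vectors (>= 2 values each).
#' @param level Confidence level, default 0.95.
#' @param var_equal Pooled variance (default `TRUE`) or Welch.
#' @return List with `difference` (mean(a) - mean(b)), `lower`, `upper`,
#'   `level`, `p_value`.
#' @examples
#' mean_difference_ci(c(6, 7, 8), c(1, 2, 3))$difference  # 5
#' @export
mean_difference_ci <- function(group_a, group_b, level = 0.95,
                               var_equal = TRUE) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("insufficient replicates: each group needs >= 2 values", call. = FALSE)
  }
  tt <- stats::t.test(group_a, group_b, var.equal = var_equal,
                      conf.level = level)
  list(difference = mean(group_a) - mean(group_b),
       lower = tt$conf.int[1L], upper = tt$conf.int[2L],
       level = level, p_value = tt$p.value)
}
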