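#' The packaged glycogen-assay optimization experiment
#'
#' The 20-run rotatable central composite design (three coded reagent
#' volumes: 5% phenol, concentrated sulfuric acid, DI water; eight
#' factorial, six axial, six center runs, center points first and last in
#' the run order) together with the measured 490 nm absorbance of each
#' reaction. Only coded levels are recorded; the uncoded volume grid is a
#' property of the lab's pipetting scheme and is supplied by the user as
#' [factor_spec()]s when needed.
#'
#' @return A `ccd_design` data frame with columns `run_index`,
#'   `point_type`, `absorbance` and coded columns `phenol`, `acid`,
#'   `water`.
#' @examples
#' dat <- glycogen_ccd()
#' table(dat$point_type)
#' @export
glycogen_ccd <- function() {
  path <- system.file("extdata", "glycogen_ccd.csv", package = "assayrsm",
                      mustWork = TRUE)
  df <- utils::read.csv(path)
  out <- data.frame(run_index = df$run_index, point_type = df$point_type,
                    absorbance = df$absorbance,
                    phenol = df$phenol_coded, acid = df$acid_coded,
                    water = df$water_coded)
  structure(out, class = c("ccd_design", "data.frame"),
            factors = NULL, factor_names = c("phenol", "acid", "water"),
            seed = NA_integer_, axial = 1.682)
}

#' Published coefficients of the selected glycogen response surface
#'
#' The nine-term reduced quadratic surface for 490 nm absorbance as a
#' function of coded phenol, sulfuric acid and water volumes: intercept,
#' the three linear terms, phenol:acid, acid:water and the three-way
#' interaction, plus the acid and water pure quadratics. These are the
#' published point estimates; refitting the packaged experiment with
#' [fit_rsm()] reproduces them.
#'
#' @return Named coefficient vector in the order of
#'   [glycogen_selected_terms()].
#' @export
glycogen_surface_coefficients <- function() {
  stats::setNames(
    c(0.2869, 0.003508, 0.04769, -0.08491, 0.021, 0.047, -0.018,
      -0.05295, -0.02061),
    rownames(glycogen_selected_terms()))
}

#' Term set of the selected glycogen surface model
#'
#' The reduced model retained after hypothesis testing on the full
#' quadratic: the phenol pure quadratic and the phenol:water interaction
#' are omitted; the linear phenol term is retained by hierarchy because the
#' retained interactions involve phenol.
#'
#' @return A [model_terms()] object (9 terms).
#' @export
glycogen_selected_terms <- function() {
  drop_terms(full_quadratic_terms(c("phenol", "acid", "water")),
             c("phenol^2", "phenol:water"))
}
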