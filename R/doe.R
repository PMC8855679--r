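#' Axial distance of a rotatable central composite design
#'
#' For a CCD in `k` factors the rotatable choice places the axial (star)
#' points at coded distance \eqn{(2^k)^{1/4}} from the center, so that the
#' prediction variance of the fitted quadratic depends only on the distance
#' from the design center.
#'
#' @param k Number of factors (integer, at least 2).
#' @return The coded axial distance, e.g. `2^(3/4) = 1.682` for `k = 3`.
#' @examples
#' axial_distance(3) # 1.682
#' axial_distance(4) # 2
#' @export
axial_distance <- function(k) {
  if (length(k) != 1L || !is.finite(k) || k != as.integer(k) || k < 2) {
    stop("invalid design: 'k' must be a single integer >= 2", call. = FALSE)
  }
  (2^k)^(1 / 4)
}

#' Describe one controllable factor and its coded/uncoded mapping
#'
#' A factor spec records the center volume and half range used to code a
#' reagent volume: coded level = (volume - center) / half_range, so the
#' factorial levels -1/+1 sit at center -/+ half_range. Axial points at
#' distance `axial_distance(k)` may decode to negative volumes; that is
#' rejected unless `allow_negative = TRUE`, in which case decoding warns.
#'
#' @param name Factor name (e.g. `"phenol"`).
#' @param center Center-point volume, microliters.
#' @param half_range Half the high-minus-low volume span, microliters (> 0).
#' @param units Unit label, default `"ul"`.
#' @param allow_negative Permit coded points that decode below zero volume.
#' @return An object of class `factor_spec`.
#' @examples
#' phenol <- factor_spec("phenol", center = 50, half_range = 20)
#' encode_volume(70, phenol)  # +1
#' @export
factor_spec <- function(name, center, half_range, units = "ul",
                        allow_negative = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(center) || length(center) != 1L || !is.finite(center)) {
    stop("'center' must be a single finite number", call. = FALSE)
  }
  if (!is.numeric(half_range) || length(half_range) != 1L ||
      !is.finite(half_range) || half_range <= 0) {
    stop("'half_range' must be a single positive number", call. = FALSE)
  }
  structure(
    list(name = name, center = center, half_range = half_range,
         units = units, allow_negative = isTRUE(allow_negative)),
    class = "factor_spec"
  )
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("Factor '%s': center %g %s, half range %g %s (levels -1/+1 at %g/%g)\n",
              x$name, x$center, x$units, x$half_range, x$units,
              x$center - x$half_range, x$center + x$half_range))
  invisible(x)
}

#' Code a volume to its dimensionless design level
#'
#' @param volume Volume(s) in the factor's units.
#' @param factor A [factor_spec()].
#' @return Coded level(s), `(volume - center) / half_range`. Values beyond
#'   the usual axial distance are legitimate but imply extrapolation when
#'   used with a fitted surface.
#' @seealso [decode_level()]
#' @export
encode_volume <- function(volume, factor) {
  stopifnot(inherits(factor, "factor_spec"), is.numeric(volume))
  (volume - factor$center) / factor$half_range
}

#' Decode a design level back to a volume
#'
#' Exact inverse of [encode_volume()]. Negative decoded volumes warn (or
#' error when the factor disallows them): a pipette cannot dispense a
#' negative volume, but an axial point may still be pinned there in the design
#' (e.g. water fixed at its low axial level = 0 ul).
#'
#' @param level Coded level(s).
#' @param factor A [factor_spec()].
#' @return Volume(s) in the factor's units.
#' @export
decode_level <- function(level, factor) {
  stopifnot(inherits(factor, "factor_spec"), is.numeric(level))
  v <- factor$center + level * factor$half_range
  if (any(v < 0)) {
    if (factor$allow_negative) {
      warning(sprintf("factor '%s': decoded volume below zero", factor$name),
              call. = FALSE)
    } else {
      stop(sprintf("factor '%s': coded level decodes to a negative volume; %s",
                   factor$name,
                   "set allow_negative = TRUE in factor_spec() to permit"),
           call. = FALSE)
    }
  }
  v
}

#' Generate a rotatable central composite design
#'
#' Builds the 2^k factorial cube, the 2k axial points at the rotatable
#' distance [axial_distance()], and `n_center` center replicates, then
#' randomizes the run order with the seeded generator -- except that one
#' center point is placed first and one last, so the center replicates
#' bracket the sequence and allow run-order drift diagnostics.
#'
#' @param factors A list of [factor_spec()] objects (>= 2), or a character
#'   vector of factor names when only coded levels are needed.
#' @param n_center Number of center replicates (>= 2 so the sequence can be
#'   bracketed).
#' @param seed Integer seed recorded in the design; run order is
#'   deterministic given the seed.
#' @return A data frame of class `ccd_design` with columns `run_index`
#'   (execution order), `point_type` (`factorial`/`axial`/`center`) and one
#'   coded-level column per factor. Attributes: `factors`, `factor_names`,
#'   `seed`, `axial`.
#' @examples
#' d <- ccd_design(c("phenol", "acid", "water"), n_center = 6, seed = 42)
#' nrow(d)               # 20 = 2^3 + 2*3 + 6
#' table(d$point_type)
#' @export
ccd_design <- function(factors, n_center = 6L, seed = 1L) {
  if (is.character(factors)) {
    names <- factors
    specs <- NULL
  } else if (is.list(factors) && all(vapply(factors, inherits, TRUE, "factor_spec"))) {
    names <- vapply(factors, `[[`, "", "name")
    specs <- factors
  } else {
    stop("'factors' must be factor_spec objects or factor names", call. = FALSE)
  }
  k <- length(names)
  if (k < 2) stop("invalid design: need at least 2 factors", call. = FALSE)
  if (anyDuplicated(names)) stop("duplicate factor names", call. = FALSE)
  if (length(n_center) != 1L || n_center != as.integer(n_center) || n_center < 2) {
    stop("invalid design: 'n_center' must be an integer >= 2 (center points must bracket the run order)",
         call. = FALSE)
  }
  n_center <- as.integer(n_center)
  alpha <- axial_distance(k)

  cube <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  star <- rbind(diag(alpha, k), diag(-alpha, k))
  ctr <- matrix(0, n_center, k)
  levels <- rbind(cube, star, ctr)
  colnames(levels) <- names
  point_type <- rep(c("factorial", "axial", "center"),
                    c(nrow(cube), nrow(star), n_center))

  # randomize everything but one leading and one trailing center replicate
  idx_center <- which(point_type == "center")
  first <- idx_center[1L]
  last <- idx_center[2L]
  middle <- setdiff(seq_len(nrow(levels)), c(first, last))
  rng <- local({ set.seed(as.integer(seed)); sample(middle) })
  ord <- c(first, rng, last)

  out <- data.frame(run_index = seq_along(ord),
                    point_type = point_type[ord],
                    levels[ord, , drop = FALSE],
                    row.names = NULL, check.names = FALSE)
  structure(out,
            class = c("ccd_design", "data.frame"),
            factors = specs, factor_names = names,
            seed = as.integer(seed), axial = alpha)
}

#' @export
print.ccd_design <- function(x, ...) {
  nm <- attr(x, "factor_names")
  cat(sprintf("Rotatable central composite design: %d factors (%s), %d runs, axial distance %.3f, seed %d\n",
              length(nm), paste(nm, collapse = ", "), nrow(x),
              attr(x, "axial"), attr(x, "seed")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Coded-level matrix of a design
#'
#' @param design A `ccd_design` or any data frame carrying one column per
#'   factor named in `factor_names`.
#' @param factor_names Optional explicit factor-column names.
#' @return Numeric matrix, runs by factors.
#' @export
coded_levels <- function(design, factor_names = NULL) {
  if (is.null(factor_names)) factor_names <- attr(design, "factor_names")
  if (is.null(factor_names)) {
    factor_names <- setdiff(colnames(design),
                            c("run_index", "point_type", "absorbance",
                              "order", "true_mean"))
  }
  as.matrix(design[, factor_names, drop = FALSE])
}

#' Write / read a design sheet as CSV
#'
#' Coded levels are written with six decimal places so the sheet round-trips
#' bit-stably at that precision; decoded volume columns (`<factor>_ul`) are
#' added when factor specs are present in the design.
#'
#' @param design A `ccd_design`.
#' @param path File path.
#' @return `write_design_csv` returns `path` invisibly; `read_design_csv`
#'   returns a `ccd_design` (coded levels only).
#' @export
write_design_csv <- function(design, path) {
  stopifnot(inherits(design, "ccd_design"))
  nm <- attr(design, "factor_names")
  out <- design
  class(out) <- "data.frame"
  for (f in nm) out[[f]] <- sprintf("%.6f", out[[f]])
  names(out)[match(nm, names(out))] <- paste0(nm, "_coded")
  specs <- attr(design, "factors")
  if (!is.null(specs)) {
    for (i in seq_along(specs)) {
      v <- suppressWarnings(decode_level(design[[nm[i]]],
                                         permissive_spec(specs[[i]])))
      out[[paste0(nm[i], "_ul")]] <- sprintf("%.6f", v)
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# decode without the negative-volume error (sheet output is advisory)
permissive_spec <- function(spec) {
  spec$allow_negative <- TRUE
  spec
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  coded <- grep("_coded$", names(df), value = TRUE)
  if (length(coded) == 0L) stop("no *_coded columns in design sheet", call. = FALSE)
  nm <- sub("_coded$", "", coded)
  out <- data.frame(run_index = df$run_index, point_type = df$point_type,
                    check.names = FALSE)
  for (i in seq_along(nm)) out[[nm[i]]] <- as.numeric(df[[coded[i]]])
  structure(out, class = c("ccd_design", "data.frame"),
            factors = NULL, factor_names = nm, seed = NA_integer_,
            axial = max(abs(as.matrix(out[nm]))))
}
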