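#' Polynomial model terms over coded factors
#'
#' A term set is an integer exponent matrix with one row per model term and
#' one column per factor: `(0,0,0)` is the intercept, `(1,0,0)` a linear
#' term, `(0,2,0)` a pure quadratic, `(1,1,1)` the three-way interaction.
#'
#' @param exponents Integer matrix (terms x factors) of exponents.
#' @param factor_names Factor names (column names).
#' @return An object of class `model_terms`.
#' @export
model_terms <- function(exponents, factor_names = colnames(exponents)) {
  exponents <- as.matrix(exponents)
  if (is.null(factor_names)) {
    factor_names <- paste0("x", seq_len(ncol(exponents)))
  }
  storage.mode(exponents) <- "double"
  if (any(exponents < 0) || any(exponents != round(exponents))) {
    stop("exponents must be non-negative integers", call. = FALSE)
  }
  if (!any(rowSums(exponents) == 0)) {
    stop("intercept term (all-zero exponents) must be present", call. = FALSE)
  }
  if (anyDuplicated(apply(exponents, 1L, paste, collapse = ","))) {
    stop("duplicate model terms", call. = FALSE)
  }
  colnames(exponents) <- factor_names
  rownames(exponents) <- unname(term_labels(exponents, factor_names))
  structure(exponents, class = c("model_terms", "matrix", "array"))
}

term_labels <- function(exponents, factor_names) {
  apply(exponents, 1L, function(e) {
    if (all(e == 0)) return("(Intercept)")
    parts <- character(0)
    for (j in seq_along(e)) {
      if (e[j] == 1) parts <- c(parts, factor_names[j])
      if (e[j] > 1) parts <- c(parts, sprintf("%s^%d", factor_names[j], e[j]))
    }
    paste(parts, collapse = ":")
  })
}

#' @export
print.model_terms <- function(x, ...) {
  cat(sprintf("%d model terms over factors %s:\n  %s\n",
              nrow(x), paste(colnames(x), collapse = ", "),
              paste(rownames(x), collapse = ", ")))
  invisible(x)
}

#' Full quadratic model with all interaction terms
#'
#' Intercept, all linear terms, all pure quadratics, and every product of
#' distinct factors up to the k-way interaction: `2^k + k` terms in all
#' (11 for three factors).
#'
#' @param factor_names Factor names, or a single integer factor count.
#' @return A [model_terms()] object.
#' @examples
#' nrow(full_quadratic_terms(3))  # 11
#' @export
full_quadratic_terms <- function(factor_names) {
  if (is.numeric(factor_names) && length(factor_names) == 1L) {
    factor_names <- paste0("x", seq_len(factor_names))
  }
  k <- length(factor_names)
  subsets <- as.matrix(expand.grid(rep(list(0:1), k)))
  subsets <- subsets[order(rowSums(subsets)), , drop = FALSE]
  squares <- diag(2, k)
  ex <- rbind(subsets, squares)
  model_terms(ex, factor_names)
}

#' Drop terms from a term set by label
#'
#' @param terms A [model_terms()] object.
#' @param labels Row labels to remove (see `rownames(terms)`).
#' @return The reduced [model_terms()].
#' @export
drop_terms <- function(terms, labels) {
  stopifnot(inherits(terms, "model_terms"))
  missing <- setdiff(labels, rownames(terms))
  if (length(missing)) {
    stop("unknown terms: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  keep <- !(rownames(terms) %in% labels)
  model_terms(terms[keep, , drop = FALSE], colnames(terms))
}

#' Build the regression design matrix for a term set
#'
#' Each column is the product of the coded levels raised to the term's
#' exponents; the intercept term yields a column of ones.
#'
#' @param design A `ccd_design`, a data frame with factor columns, or a
#'   numeric matrix of coded levels.
#' @param terms A [model_terms()] object.
#' @return Numeric matrix, runs by terms, with term labels as column names.
#' @export
build_design_matrix <- function(design, terms) {
  stopifnot(inherits(terms, "model_terms"))
  X <- if (is.matrix(design)) design else coded_levels(design)
  X <- as.matrix(X)
  if (ncol(X) != ncol(terms)) {
    stop("design has ", ncol(X), " factor columns but terms expect ",
         ncol(terms), call. = FALSE)
  }
  # factors are matched to term columns positionally
  colnames(X) <- colnames(terms)
  out <- apply(terms, 1L, function(e) {
    apply(sweep(X, 2L, e, `^`), 1L, prod)
  })
  out <- matrix(out, nrow = nrow(X), ncol = nrow(terms),
                dimnames = list(NULL, rownames(terms)))
  out
}
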