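#' Orthogonal polynomial basis for a covariate
#'
#' Builds the degree-1 or degree-2 orthonormal polynomial basis of the
#' observed covariate values (the constant column excluded): columns have
#' zero mean, unit norm and are mutually orthogonal, and the stored
#' recurrence coefficients allow exact evaluation at new covariate values
#' (e.g. a fine puberty grid for the crossing-point procedure).
#'
#' @param x Observed covariate values (at least \code{degree + 1} distinct).
#' @param degree 1 (linear) or 2 (quadratic).
#' @return An object of class \code{orth_poly_basis}: list with \code{knots},
#'   \code{degree}, \code{columns} (n x degree matrix) and \code{transform}
#'   (recurrence coefficients for out-of-sample evaluation).
#' @examples
#' b <- orthogonal_poly_basis(c(1, 2, 3), 1)
#' b$columns  # proportional to centred x, unit norm
#' @export
orthogonal_poly_basis <- function(x, degree = 2) {
  stopifnot(is.numeric(x), degree %in% 1:2)
  if (length(unique(x)) < degree + 1)
    stop(sprintf("need at least %d distinct covariate values for degree %d",
                 degree + 1, degree), call. = FALSE)
  cols <- stats::poly(x, degree = degree)
  structure(list(knots = x, degree = degree,
                 columns = unclass(cols)[, , drop = FALSE],
                 transform = attr(cols, "coefs")),
            class = "orth_poly_basis")
}

#' Evaluate an orthogonal polynomial basis at new covariate values
#'
#' @param basis An \code{\link{orthogonal_poly_basis}}.
#' @param newx Covariate values at which to evaluate.
#' @return Matrix with \code{basis$degree} columns; at the training values it
#'   reproduces \code{basis$columns} exactly.
#' @export
eval_poly_basis <- function(basis, newx) {
  stopifnot(inherits(basis, "orth_poly_basis"))
  out <- stats::poly(newx, degree = basis$degree, coefs = basis$transform)
  unclass(out)[, , drop = FALSE]
}
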