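# Natural cubic spline smooths. Knots are placed at quantiles of the
# training covariate and stored so that prediction re-uses the training
# basis; beyond the boundary knots the spline is linear, which keeps
# extrapolation onto prediction grids tame.

#' Natural cubic spline basis with stored knots
#'
#' @param x Numeric training values of the covariate.
#' @param df Basis dimension (number of columns, >= 2). Interior knots are
#'   placed at quantiles of `x`, boundary knots at its range.
#' @return An object of class `spline_basis` carrying the basis matrix
#'   (`$basis`) and the knots needed to evaluate it on new data with
#'   [predict.spline_basis()].
#' @export
spline_basis <- function(x, df = 3) {
  if (df < 2) stop("df must be >= 2")
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("covariate values must be finite")
  if (length(unique(x)) <= df) {
    stop(sprintf("need more than df = %d distinct covariate values", df))
  }
  B <- splines::ns(x, df = df)
  structure(
    list(
      basis = unclass(B)[, , drop = FALSE],
      df = df,
      knots = attr(B, "knots"),
      boundary = attr(B, "Boundary.knots")
    ),
    class = "spline_basis"
  )
}

#' Evaluate a fitted spline basis on new covariate values
#'
#' @param object A [spline_basis()] object.
#' @param newx New covariate values.
#' @param ... Unused.
#' @return Basis matrix with `object$df` columns, built from the training
#'   knots (linear beyond the training range).
#' @export
predict.spline_basis <- function(object, newx, ...) {
  if (any(!is.finite(newx))) stop("covariate values must be finite")
  B <- splines::ns(newx, knots = object$knots, Boundary.knots = object$boundary)
  unclass(B)[, , drop = FALSE]
}
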