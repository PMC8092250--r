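#' Monotone I-spline basis (order 2, three knots)
#'
#' Evaluates the three integrated monotone spline basis functions on the
#' knot span `knots = c(t1, t2, t3)`. Each basis function is 0 at or below
#' the first knot, 1 at or above the last, and nondecreasing in between, so
#' any non-negative combination is a monotone nondecreasing transform —
#' the property the dissimilarity model relies on.
#'
#' Closed forms (piecewise quadratic, the integrals of the order-2
#' M-spline tent functions on `t1 < t2 < t3`):
#' \itemize{
#'   \item `I1(x) = 1 - ((t2 - x) / (t2 - t1))^2` on `[t1, t2]`, then 1;
#'   \item `I2(x) = (x - t1)^2 / ((t3 - t1)(t2 - t1))` on `[t1, t2]`,
#'     `1 - (t3 - x)^2 / ((t3 - t1)(t3 - t2))` on `[t2, t3]`;
#'   \item `I3(x) = ((x - t2) / (t3 - t2))^2` on `[t2, t3]`, 0 before.
#' }
#'
#' @param x numeric vector of predictor values.
#' @param knots strictly increasing numeric vector of length 3 (default in
#'   the model fit: min / median / max of the observed pairwise values).
#' @return numeric matrix `length(x) x 3`; attribute `knots` carries the
#'   knot vector.
#' @export
ispline_basis <- function(x, knots) {
  if (length(knots) != 3) stop("exactly three knots are required")
  if (any(diff(knots) <= 0))
    stop("degenerate I-spline basis: knots must be strictly increasing ",
         "(binary or constant predictors need a linear term instead)")
  t1 <- knots[1]; t2 <- knots[2]; t3 <- knots[3]
  xc <- pmin(pmax(x, t1), t3)
  b1 <- ifelse(xc <= t2, 1 - ((t2 - xc) / (t2 - t1))^2, 1)
  b2 <- ifelse(xc <= t2,
               (xc - t1)^2 / ((t3 - t1) * (t2 - t1)),
               1 - (t3 - xc)^2 / ((t3 - t1) * (t3 - t2)))
  b3 <- ifelse(xc <= t2, 0, ((xc - t2) / (t3 - t2))^2)
  out <- cbind(b1, b2, b3)
  colnames(out) <- paste0("I", 1:3)
  attr(out, "knots") <- knots
  out
}

# Basis for one predictor: three I-splines when the pairwise values support
# three distinct knots, otherwise a single linear non-negative term rescaled
# to [0, 1] (exactly equivalent to any monotone transform on a binary
# predictor such as the same/different-home indicator).
predictor_basis <- function(x, knots = NULL) {
  if (is.null(knots)) {
    knots <- unname(stats::quantile(x, c(0, 0.5, 1), names = FALSE))
  }
  if (any(diff(knots) <= 0)) {
    rng <- range(x)
    span <- if (diff(rng) > 0) diff(rng) else 1
    b <- matrix((x - rng[1]) / span, ncol = 1, dimnames = list(NULL, "lin"))
    return(list(basis = b, knots = rng, type = "linear"))
  }
  list(basis = ispline_basis(x, knots), knots = knots, type = "ispline")
}
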