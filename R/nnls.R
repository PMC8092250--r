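# Non-negative least squares by Lawson-Hanson active-set iteration:
# minimise ||C x - d||_2 subject to x >= 0. Used by the dissimilarity-model
# IRLS refits, whose weighted designs need a generous iteration budget.
nnls_solve <- function(C, d, itmax = NULL) {
  m <- nrow(C); n <- ncol(C)
  if (is.null(itmax)) itmax <- 50 * n + 100
  tol <- 10 * .Machine$double.eps * norm(C, type = "2") * (max(m, n) + 1)
  x <- rep(0, n)
  passive <- logical(n)
  w <- drop(crossprod(C, d - C %*% x))
  it <- 0
  while (any(!passive) && any(w[!passive] > tol)) {
    cand <- which(!passive)
    passive[cand[which.max(w[cand])]] <- TRUE
    repeat {
      z <- rep(0, n)
      z[passive] <- qr.coef(qr(C[, passive, drop = FALSE]), d)
      z[is.na(z)] <- 0
      if (all(z[passive] > tol)) break
      it <- it + 1
      if (it > itmax) break
      bad <- passive & (z <= tol)
      alpha <- min(x[bad] / (x[bad] - z[bad]))
      x <- x + alpha * (z - x)
      passive <- passive & (x > tol)
      if (!any(passive)) { z <- rep(0, n); break }
    }
    x <- z
    if (it > itmax) break
    w <- drop(crossprod(C, d - C %*% x))
  }
  pmax(x, 0)
}
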