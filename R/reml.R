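#' Repair a kinship matrix to positive semi-definiteness
#'
#' Marker-based relatedness matrices are often slightly indefinite; this
#' clips eigenvalues below `floor` and re-symmetrises, preserving the unit
#' diagonal up to the clip.
#'
#' @param K symmetric relatedness matrix (diagonal 1).
#' @param floor smallest admissible eigenvalue.
#' @return repaired matrix.
#' @export
repair_kinship <- function(K, floor = 1e-8) {
  K <- (K + t(K)) / 2
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) >= floor) return(K)
  v <- pmax(e$values, floor)
  K2 <- e$vectors %*% (v * t(e$vectors))
  (K2 + t(K2)) / 2
}

# Restricted maximum likelihood for the working-scale linear mixed model
#   z = X beta + a + h + eps,
#   cov(a) = sg * K               (kinship-structured child effect)
#   cov(h) = sh * ZZ'             (household effect, Z = home incidence)
#   cov(eps) = se * diag(rvar) + diag(cvar)
# The residual splits into a free variance `se` on the design `rvar`
# (rvar = 1 gives a latent iid residual; rvar = inverse family weights
# gives the classical PQL working residual) plus a fixed known part `cvar`.
# `components` switches sg / sh on or off (off = fixed at zero), which is
# how the reduced models for the likelihood-ratio tests are fitted.
# Optimisation is L-BFGS-B on the non-negative variance scale with the
# analytic REML gradient dL/ds_j = 0.5 (tr(P V_j) - u' V_j u).
# Returns variance estimates, GLS fixed effects, REML log-likelihood and
# the BLUPs of both random effects.
reml_lmm <- function(z, X, K = NULL, home = NULL, cvar = 0, rvar = 1,
                     components = c("genetic", "home"), start = NULL) {
  n <- length(z)
  use_g <- "genetic" %in% components && !is.null(K)
  use_h <- "home" %in% components && !is.null(home)
  H <- NULL
  if (use_h) {
    Zh <- stats::model.matrix(~ 0 + factor(home))
    H <- tcrossprod(Zh)
  }
  if (length(cvar) == 1) cvar <- rep(cvar, n)
  if (length(rvar) == 1) rvar <- rep(rvar, n)
  npar <- 1 + use_g + use_h
  designs <- c(list(diag(rvar, n)),
               if (use_g) list(K),
               if (use_h) list(H))
  build_V <- function(par) {
    V <- diag(par[1] * rvar + cvar, n)
    i <- 2
    if (use_g) { V <- V + par[i] * K; i <- i + 1 }
    if (use_h) V <- V + par[i] * H
    V
  }
  p <- ncol(X)
  # objective and gradient share one factorisation per parameter value
  cache <- new.env(parent = emptyenv())
  cache$par <- NULL
  evaluate <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$val)
    V <- build_V(par)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) {
      cache$par <- par
      cache$val <- list(obj = 1e10, grad = rep(0, npar), bad = TRUE)
      return(cache$val)
    }
    Vi <- chol2inv(ch)
    Vi_X <- Vi %*% X
    XtViX <- crossprod(X, Vi_X)
    ch2 <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(ch2)) {
      cache$par <- par
      cache$val <- list(obj = 1e10, grad = rep(0, npar), bad = TRUE)
      return(cache$val)
    }
    XtViX_inv <- chol2inv(ch2)
    beta <- XtViX_inv %*% crossprod(X, Vi %*% z)
    r <- z - drop(X %*% beta)
    u <- drop(Vi %*% r)
    obj <- 0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(ch2))) + sum(r * u))
    P <- Vi - Vi_X %*% tcrossprod(XtViX_inv, Vi_X)
    grad <- vapply(designs, function(Vj)
      0.5 * (sum(P * Vj) - drop(crossprod(u, Vj %*% u))), numeric(1))
    cache$par <- par
    cache$val <- list(obj = obj, grad = grad, beta = drop(beta), u = u,
                      vi_diag = diag(Vi), bad = FALSE)
    cache$val
  }
  fn <- function(par) evaluate(par)$obj
  gr <- function(par) evaluate(par)$grad
  vz <- max(stats::var(z), 1e-6)
  up <- rep(vz * 50 + 10, npar)
  starts <- list(rep(vz / npar, npar))
  if (!is.null(start) && length(start) == npar) {
    starts <- list(pmin(pmax(start, 0), up))
  } else {
    starts <- c(starts, list(c(vz, rep(vz / 10, npar - 1))))
  }
  best <- NULL
  for (s in starts) {
    opt <- stats::optim(s, fn, gr, method = "L-BFGS-B",
                        lower = rep(0, npar), upper = up,
                        control = list(maxit = 100, factr = 1e7))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  par <- best$par
  # Tie-break on flat likelihood ridges: when a structured component (kinship
  # or household) is indistinguishable from iid residual — e.g. K close to I,
  # or one child per home — REML is flat along an exchange direction and the
  # optimiser parks mass arbitrarily. Prefer the parsimonious attribution:
  # move a structured component's mass into the residual whenever doing so
  # does not worsen the restricted likelihood beyond numerical tolerance.
  if (npar > 1) {
    mr <- mean(rvar)
    for (j in npar:2) {
      if (par[j] <= 0) next
      cand <- par
      cand[1] <- cand[1] + cand[j] * mean(diag(designs[[j]])) / mr
      cand[j] <- 0
      if (fn(cand) <= best$value + 1e-6) {
        par <- cand
        best$value <- fn(cand)
      }
    }
  }
  final <- evaluate(par)
  if (final$bad) stop("REML variance fit failed: singular covariance")
  i <- 2
  sg <- 0; sh <- 0
  blup_g <- rep(0, n); blup_h <- rep(0, n)
  if (use_g) { sg <- par[i]; blup_g <- drop(sg * K %*% final$u); i <- i + 1 }
  if (use_h) { sh <- par[i]; blup_h <- drop(sh * H %*% final$u) }
  ll <- -best$value - 0.5 * (n - p) * log(2 * pi)
  # conditional leverage of each observation: 1 - R_ii [V^-1]_ii with R the
  # residual covariance; used for dispersion estimation upstream
  r_diag <- par[1] * rvar + cvar
  list(sigma2_g = sg, sigma2_home = sh, sigma2_resid = par[1],
       beta = final$beta, loglik = ll, par = par,
       blup_genetic = blup_g, blup_home = blup_h,
       leverage = pmin(pmax(1 - r_diag * final$vi_diag, 0), 0.99),
       converged = best$convergence == 0)
}
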