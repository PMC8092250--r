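#' Fit a kinship-structured generalized linear mixed model by PQL
#'
#' Per-taxon variance partitioning model: a count (abundance), presence or
#' gaussian response with fixed effects intercept + ln(age) + sex, an
#' optional ln(depth) offset (abundance models), a household random effect
#' and a child random effect whose correlation structure is the pairwise
#' relatedness matrix `K`. Estimation is penalized quasi-likelihood:
#' iterate (1) a working response `z = eta + (y - mu) / mu'(eta)` with
#' family weights and (2) a restricted-ML solve of the working linear
#' mixed model, damped until the coefficients and variances settle.
#'
#' The residual term of the working model is `sigma2_resid * I + diag(c)`
#' where `c` is the known counting-level sampling variance of the working
#' response (`1/mu`, the Poisson part, for counts on the log scale;
#' `1/(mu(1-mu))` for presence on the logit scale; 0 for gaussian).
#' `sigma2_resid` is therefore the iid latent-scale residual: for counts it
#' absorbs overdispersion beyond Poisson — the gamma/lognormal mixing noise,
#' whose log-scale variance for a negative binomial with dispersion `theta`
#' is `trigamma(theta)` — together with any other unstructured log-scale
#' variation. This keeps the dispersion out of the estimation loop (a free
#' in-loop `theta` is unidentifiable against the latent residual and makes
#' the PQL alternation ratchet on null data) and puts the mixing noise in
#' the denominator of the variance proportions, where a latent-scale
#' partition needs it. A conditional maximum-likelihood `theta` given the
#' final means is reported as a diagnostic. Set
#' `resid_convention = "working"` for the classical PQL residual in which a
#' single free dispersion multiplies the inverse family weights instead.
#'
#' @param y response: counts (negative_binomial), 0/1 (binomial), or
#'   numeric (gaussian).
#' @param family `"negative_binomial"`, `"binomial"` or `"gaussian"`.
#' @param metadata [sample_metadata] in the canonical child order of `y`.
#' @param K relatedness matrix over the same children (repaired to PSD
#'   internally); `NULL` drops the genetic component.
#' @param offset linear-predictor offset (e.g. `log(depth)`); `NULL` for
#'   none.
#' @param components random components to include
#'   (subset of `c("genetic", "home")`); dropping one gives the reduced
#'   model of the likelihood-ratio test.
#' @param resid_convention `"latent"` (default) or `"working"`.
#' @param max_iter,tol PQL convergence controls.
#' @return An object of class `glmm_fit`: `beta`, `sigma2_g`, `sigma2_home`,
#'   `sigma2_resid`, `theta` (NB), `loglik` (working-scale REML),
#'   `converged`, fitted `mu`.
#' @export
fit_glmm <- function(y, family = c("negative_binomial", "binomial", "gaussian"),
                     metadata, K = NULL, offset = NULL,
                     components = c("genetic", "home"),
                     resid_convention = c("latent", "working"),
                     max_iter = 200, tol = 1e-6) {
  family <- match.arg(family)
  resid_convention <- match.arg(resid_convention)
  metadata <- sample_metadata(metadata)
  n <- length(y)
  if (n < 10) stop("at least 10 children are required")
  if (nrow(metadata) != n) stop("metadata rows do not match response length")
  if (family == "binomial" && (all(y == 0) || all(y == 1)))
    stop("constant presence vector: filter upstream")
  if (family == "negative_binomial" && all(y == 0))
    stop("all-zero count vector: filter upstream")
  if (!is.null(K)) {
    K <- repair_kinship(as.matrix(K))
    if (nrow(K) != n) stop("K dimensions do not match response length")
  }
  X <- cbind(intercept = 1, ln_age = log(metadata$age_years),
             sex = metadata$sex)
  home <- metadata$home_id
  off <- if (is.null(offset)) rep(0, n) else as.numeric(offset)

  if (family == "gaussian") {
    fit <- reml_lmm(y - off, X, K = K, home = home, cvar = 0,
                    components = components)
    return(structure(c(fit, list(family = family, theta = NA_real_,
                                 mu = drop(X %*% fit$beta) + off,
                                 resid_convention = resid_convention,
                                 iterations = 1L)),
                     class = "glmm_fit"))
  }

  if (family == "negative_binomial") {
    mu <- pmax(y, 0.5)
    eta <- log(mu)
  } else {
    mu <- (y + 0.5) / 2
    eta <- stats::qlogis(mu)
  }
  state <- c(rep(0, ncol(X)), 0, 0, 0)
  fit <- NULL
  converged <- FALSE
  warm <- NULL
  for (it in seq_len(max_iter)) {
    if (family == "negative_binomial") {
      # the known sampling variance is the Poisson part only; overdispersion
      # beyond it (gamma/lognormal mixing) is iid on the log scale and is
      # absorbed by the free latent residual, where it belongs in the
      # variance partition (see variance_proportions)
      mu <- pmax(mu, 1e-6)
      z <- (eta - off) + (y - mu) / mu
      cvar <- 1 / mu
    } else {
      mu <- pmin(pmax(mu, 1e-6), 1 - 1e-6)
      z <- eta + (y - mu) / (mu * (1 - mu))
      cvar <- 1 / (mu * (1 - mu))
    }
    if (resid_convention == "working") {
      # classical PQL: one free multiplier on the inverse family weights;
      # report it as the mean working residual variance
      fit <- reml_lmm(z, X, K = K, home = home, cvar = 0, rvar = cvar,
                      components = components, start = warm)
      warm <- fit$par
      fit$sigma2_resid <- fit$sigma2_resid * mean(cvar)
    } else {
      fit <- reml_lmm(z, X, K = K, home = home, cvar = cvar, rvar = 1,
                      components = components, start = warm)
      warm <- fit$par
    }
    eta_new <- drop(X %*% fit$beta) + fit$blup_genetic + fit$blup_home +
      if (family == "negative_binomial") off else 0
    # damped update stabilises the working-response / variance alternation
    eta_new <- if (it == 1) eta_new else (eta + eta_new) / 2
    mu <- if (family == "negative_binomial") exp(pmin(eta_new, 30))
          else stats::plogis(eta_new)
    state_new <- c(fit$beta, fit$sigma2_g, fit$sigma2_home, fit$sigma2_resid)
    delta <- max(abs(state_new - state) / pmax(abs(state), 0.1))
    state <- state_new
    eta <- eta_new
    if (delta < tol && it > 1) { converged <- TRUE; break }
  }
  sg <- fit$sigma2_g; sh <- fit$sigma2_home; se <- fit$sigma2_resid
  if (family == "binomial") {
    # correction of the well-known PQL attenuation for binary responses:
    # the logit-scale marginalisation shrinks latent variance by
    # a = 1 / (1 + c2 * v) with c2 = (16 sqrt(3) / (15 pi))^2, and the
    # attenuation enters the PQL alternation twice (once in the
    # working-response linearisation, once in the variance solve), so the
    # fitted total behaves as v_hat = v / (1 + c2 * v)^2. Invert that
    # relation for the total and rescale all components proportionally.
    c2 <- (16 * sqrt(3) / (15 * pi))^2
    vhat <- sg + sh + se
    if (vhat > 0) {
      disc <- (1 - 2 * c2 * vhat)^2 - 4 * c2^2 * vhat^2
      vtrue <- if (disc > 0 && (1 - 2 * c2 * vhat) > 0)
        ((1 - 2 * c2 * vhat) - sqrt(disc)) / (2 * c2^2 * vhat)
      else vhat * 5   # attenuation too strong to invert; cap the rescale
      scale <- min(vtrue / vhat, 5)
      sg <- sg * scale; sh <- sh * scale; se <- se * scale
    }
  }
  # diagnostic dispersion: conditional ML given the final means (not part
  # of the fitted variance structure)
  theta <- if (family == "negative_binomial") update_theta(y, mu) else NA_real_
  structure(list(family = family,
                 beta = fit$beta,
                 sigma2_g = sg,
                 sigma2_home = sh,
                 sigma2_resid = se,
                 theta = theta,
                 loglik = fit$loglik,
                 mu = mu,
                 components = components,
                 resid_convention = resid_convention,
                 converged = converged && fit$converged,
                 iterations = it),
            class = "glmm_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Update of the negative-binomial dispersion given the current conditional
# means. Plain conditional ML is unstable inside the PQL loop: as the
# variance components grow, the BLUPs absorb more of the response, the
# conditional residuals shrink, theta inflates, the working variance
# shrinks, and the variance components grow further — a ratchet that can
# drive theta to its bound on null data. The leverage-corrected Pearson
# moment equation
#   sum (y - mu)^2 / ((1 - l_i)(mu + mu^2/theta)) = n
# inflates each squared residual by its conditional leverage, which breaks
# the feedback (leverage -> 1 forces theta back down). Falls back to
# conditional ML when no leverage is supplied.
update_theta <- function(y, mu, leverage = NULL) {
  if (is.null(leverage)) {
    nll <- function(lt) -sum(stats::dnbinom(y, size = exp(lt), mu = mu, log = TRUE))
    return(exp(stats::optimize(nll, interval = c(log(1e-3), log(1e5)))$minimum))
  }
  r2 <- (y - mu)^2 / (1 - leverage)
  n <- length(y)
  gap <- function(lt) sum(r2 / (mu + mu^2 * exp(-lt))) - n
  lo <- log(1e-3); hi <- log(1e5)
  if (gap(hi) <= 0) return(1e5)   # underdispersed even at the Poisson limit
  if (gap(lo) >= 0) return(1e-3)
  exp(stats::uniroot(gap, c(lo, hi), tol = 1e-8)$root)
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("glmm_fit [%s]: sigma2_g=%.4f sigma2_home=%.4f sigma2_resid=%.4f%s\n",
              x$family, x$sigma2_g, x$sigma2_home, x$sigma2_resid,
              if (!is.na(x$theta)) sprintf(" theta=%.3f", x$theta) else ""))
  invisible(x)
}

#' Variance proportions from a mixed-model fit
#'
#' `h2 = sigma2_g / (sigma2_g + sigma2_home + sigma2_resid)` and the
#' analogous `e2` for the household component, on the latent (working)
#' scale. All components zero returns `h2 = e2 = 0`.
#'
#' @param fit a [fit_glmm()] fit.
#' @return named numeric vector `c(h2 = , e2 = )`.
#' @export
variance_proportions <- function(fit) {
  stopifnot(inherits(fit, "glmm_fit"))
  tot <- fit$sigma2_g + fit$sigma2_home + fit$sigma2_resid
  if (tot <= 0) return(c(h2 = 0, e2 = 0))
  c(h2 = fit$sigma2_g / tot, e2 = fit$sigma2_home / tot)
}

#' Likelihood-ratio test for one variance component
#'
#' Compares a full fit against a reduced fit lacking exactly one random
#' component: `stat = 2 * (ll_full - ll_reduced)` floored at zero, with the
#' p-value from the chi-square distribution on 1 df (the convention of the
#' cited tooling; conservative at the boundary).
#'
#' @param fit_full,fit_reduced [fit_glmm()] fits on the same data, the
#'   reduced one dropping a single component.
#' @return list with `stat`, `p`, `delta_ll`, `boundary` flag (set when the
#'   full model's likelihood fell below the reduced one beyond numerical
#'   tolerance).
#' @export
lrt_component <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "glmm_fit"), inherits(fit_reduced, "glmm_fit"))
  delta <- fit_full$loglik - fit_reduced$loglik
  boundary <- delta < -1e-6
  stat <- max(2 * delta, 0)
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       delta_ll = delta, boundary = boundary)
}
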