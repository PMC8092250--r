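# Small in-code fixtures shared across test files.

toy_counts <- function() {
  m <- matrix(c(5, 0, 2,
                0, 3, 1,
                4, 4, 0,
                1, 0, 0), nrow = 3,
              dimnames = list(c("c1", "c2", "c3"),
                              c("A1", "A2", "A3", "A4")))
  m
}

toy_table <- function(depth = NULL) {
  asv_table(toy_counts(), depth = depth)
}

toy_metadata <- function(ids = c("c1", "c2", "c3"),
                         homes = c("h1", "h1", "h2")) {
  sample_metadata(data.frame(child_id = ids, home_id = homes,
                             sex = rep_len(c(1, 2), length(ids)),
                             age_years = seq(5, by = 2, length.out = length(ids)),
                             bmi_z = 0))
}

random_table <- function(n_children, n_asvs, lambda = 3) {
  m <- matrix(stats::rpois(n_children * n_asvs, lambda), nrow = n_children,
              dimnames = list(sprintf("c%02d", seq_len(n_children)),
                              sprintf("A%03d", seq_len(n_asvs))))
  # ensure nonzero rows
  zero <- rowSums(m) == 0
  m[zero, 1] <- 1
  asv_table(m)
}

random_sym <- function(n, ids = sprintf("c%02d", seq_len(n))) {
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[upper.tri(m)] <- stats::runif(n * (n - 1) / 2)
  m + t(m)
}

# Study-structured design reused by several files (cached: construction is
# deterministic given the seed).
study_design <- local({
  cache <- NULL
  function(seed = 101) {
    if (is.null(cache)) cache <<- simulate_design(design_config(), seed = seed)
    cache
  }
})

# Information-rich design for parameter-recovery checks: 60 full sibships
# of five, every sibling reared in a different home, with all homes holding
# three mutually unrelated children. Sibships identify the kinship
# component (600 related pairs), co-residence identifies the household
# component (300 within-home pairs), and the two never coincide.
recovery_design <- local({
  cache <- NULL
  function(seed = 202) {
    if (is.null(cache)) {
      cfg <- design_config(
        n_children = 300, n_homes = 100,
        pairs = c(full_together = 0, full_apart = 600, half_together = 0,
                  half_apart = 0, unrelated_together = 300),
        max_sibship = 5)
      cache <<- simulate_design(cfg, seed = seed)
    }
    cache
  }
})

# Simulate one latent-effect response on a design: NB counts, presence
# indicators or a gaussian trait, with chosen variance components.
simulate_response <- function(design, family, sigma2_g = 0, sigma2_home = 0,
                              sigma2_resid = 0.3, theta = 2,
                              intercept = NULL) {
  md <- design$metadata
  n <- nrow(md)
  K <- design$K_true$values
  a <- if (sigma2_g > 0)
    sqrt(sigma2_g) * drop(t(chol(K + diag(1e-8, n))) %*% stats::rnorm(n)) else 0
  homes <- factor(md$home_id)
  h <- if (sigma2_home > 0)
    sqrt(sigma2_home) * stats::rnorm(nlevels(homes))[homes] else 0
  e <- if (sigma2_resid > 0) stats::rnorm(n, sd = sqrt(sigma2_resid)) else 0
  lin <- a + h + e
  if (family == "negative_binomial") {
    if (is.null(intercept)) intercept <- log(2e-4)
    mu <- exp(intercept + lin + log(design$depth))
    stats::rnbinom(n, size = theta, mu = mu)
  } else if (family == "binomial") {
    if (is.null(intercept)) intercept <- 0
    stats::rbinom(n, 1, stats::plogis(intercept + lin))
  } else {
    lin
  }
}

# Independent check on the GDM optimiser: same deviance objective and basis,
# minimised directly with box-constrained BFGS from several starts.
gdm_oracle_deviance <- function(sp) {
  bases <- lapply(sp$predictors, function(x) {
    kn <- unname(stats::quantile(x, c(0, 0.5, 1), names = FALSE))
    if (any(diff(kn) <= 0)) {
      rng <- range(x)
      matrix((x - rng[1]) / max(diff(rng), 1), ncol = 1)
    } else ispline_basis(x, kn)
  })
  X <- cbind(1, do.call(cbind, bases))
  d <- pmin(pmax(sp$d, 1e-9), 1 - 1e-9)
  dev_fun <- function(beta) {
    mu <- pmin(pmax(1 - exp(-drop(X %*% beta)), 1e-9), 1 - 1e-9)
    2 * sum(ifelse(d > 0, d * log(d / mu), 0) +
            ifelse(d < 1, (1 - d) * log((1 - d) / (1 - mu)), 0))
  }
  best <- Inf
  for (s in list(rep(0.01, ncol(X)),
                 c(0.5, rep(0.1, ncol(X) - 1)),
                 rep(0.3, ncol(X)))) {
    o <- stats::optim(s, dev_fun, method = "L-BFGS-B",
                      lower = rep(0, ncol(X)),
                      control = list(maxit = 2000, factr = 10))
    best <- min(best, o$value)
  }
  best
}
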