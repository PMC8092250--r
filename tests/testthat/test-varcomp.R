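test_that("gaussian limit reduces to one LMM solve matching lme4 REML", {
  skip_if_not_installed("lme4")
  d <- study_design()
  md <- d$metadata
  set.seed(2)
  h <- rnorm(length(unique(md$home_id)), sd = 0.8)[factor(md$home_id)]
  y <- 1 + 0.3 * log(md$age_years) - 0.2 * md$sex + h + rnorm(nrow(md), sd = 0.6)
  f <- fit_glmm(y, "gaussian", md, K = NULL, components = "home")
  expect_equal(f$iterations, 1L)
  o <- lme4::lmer(y ~ log(age_years) + sex + (1 | home_id), data = md,
                  REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(o))
  expect_equal(f$sigma2_home, vc$vcov[1], tolerance = 1e-6)
  expect_equal(f$sigma2_resid, vc$vcov[2], tolerance = 1e-6)
  expect_equal(unname(f$beta), unname(lme4::fixef(o)), tolerance = 1e-6)
  expect_equal(f$loglik, as.numeric(stats::logLik(o)), tolerance = 1e-6)
})

test_that("variance proportions follow their definition", {
  mk <- function(sg, sh, se) structure(
    list(sigma2_g = sg, sigma2_home = sh, sigma2_resid = se),
    class = "glmm_fit")
  expect_equal(variance_proportions(mk(1, 1, 1)),
               c(h2 = 1 / 3, e2 = 1 / 3))
  expect_equal(variance_proportions(mk(0, 2, 1))[["h2"]], 0)
  expect_equal(variance_proportions(mk(0, 0, 0)), c(h2 = 0, e2 = 0))
  p <- variance_proportions(mk(0.3, 0.2, 0.5))
  expect_lte(p[["h2"]] + p[["e2"]], 1)
})

test_that("likelihood-ratio test floors at zero and uses chi-square(1)", {
  mk <- function(ll) structure(list(loglik = ll), class = "glmm_fit")
  same <- lrt_component(mk(-10), mk(-10))
  expect_equal(same$stat, 0)
  expect_equal(same$p, 1)
  crit <- stats::qchisq(0.95, df = 1)
  at_crit <- lrt_component(mk(-10 + crit / 2), mk(-10))
  expect_equal(at_crit$p, 0.05, tolerance = 1e-10)
  worse <- lrt_component(mk(-10.5), mk(-10))
  expect_equal(worse$stat, 0)
  expect_true(worse$boundary)
})

test_that("model screening applies BH-FDR and the magnitude floor", {
  base <- data.frame(
    asv_id = paste0("A", 1:4), model_type = "abundance",
    component = "genetic", h2 = c(0.4, 0.3, 0.2, 0.1), e2 = 0,
    lrt_p = c(0.01, 0.02, 0.03, 0.04), delta_ll = 1,
    stringsAsFactors = FALSE)
  s <- screen_models(base)
  expect_equal(s$q_value, rep(0.04, 4))  # BH step-up by hand
  expect_true(all(s$q_value >= s$lrt_p))
  expect_true(all(s$retained))
  # a small-magnitude model is eliminated regardless of q
  tiny <- base[1, ]
  tiny$h2 <- 0.04; tiny$e2 <- 0.03; tiny$lrt_p <- 1e-6
  expect_false(screen_models(tiny)$retained)
  # single p-value: q equals p
  one <- base[1, ]
  expect_equal(screen_models(one)$q_value, one$lrt_p)
  # negative delta_ll blocks retention
  neg <- base; neg$delta_ll <- -0.1
  expect_false(any(screen_models(neg)$retained))
  empty <- screen_models(base[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("variance fits are invariant to reordering children", {
  d <- study_design()
  md <- d$metadata
  K <- d$K_true$values
  set.seed(12)
  y <- simulate_response(d, "negative_binomial", sigma2_g = 1)
  f1 <- fit_glmm(y, "negative_binomial", md, K = K, offset = log(d$depth))
  # feed the same children under a different storage order; sample_metadata
  # restores the canonical order, so inputs must be permuted jointly
  perm <- sample(nrow(md))
  ids <- md$child_id
  md2 <- md[perm, ]
  y2 <- y[perm][match(ids, md2$child_id)]
  expect_identical(y2, y)  # canonical order restored
  f2 <- fit_glmm(y, "negative_binomial", sample_metadata(md2), K = K,
                 offset = log(d$depth))
  expect_equal(f1$sigma2_g, f2$sigma2_g, tolerance = 1e-8)
})

test_that("fully confounded null design yields near-zero components", {
  # K = I and one child per home: genetic, home and residual are confounded;
  # on null data the structured components should collapse to ~0
  n <- 40
  md <- sample_metadata(data.frame(
    child_id = sprintf("c%02d", 1:n), home_id = sprintf("h%02d", 1:n),
    sex = rep(c(1, 2), n / 2), age_years = runif(n, 5, 15), bmi_z = 0))
  set.seed(3)
  y <- rnorm(n)
  f <- fit_glmm(y, "gaussian", md, K = diag(n))
  expect_lt(f$sigma2_g, 0.2)
  expect_lt(f$sigma2_home, 0.2)
})

test_that("null NB data gives small variance components most of the time", {
  # calibration regime: a well-measured taxon (abundant, mild dispersion),
  # identity kinship; the sampling noise of a variance component scales
  # with the taxon's total log-scale variance, so the <0.05 yardstick is
  # only meaningful when measurement noise is small
  d <- study_design()
  md <- d$metadata
  set.seed(21)
  small <- replicate(20, {
    y <- simulate_response(d, "negative_binomial", sigma2_g = 0,
                           sigma2_home = 0, sigma2_resid = 0,
                           theta = 10, intercept = log(1e-3))
    f <- fit_glmm(y, "negative_binomial", md, K = diag(74),
                  offset = log(d$depth))
    f$sigma2_g < 0.05 && f$sigma2_home < 0.05
  })
  expect_gte(mean(small), 0.85)
})

test_that("binomial home-variance recovery lands near the truth in median", {
  # 39 homes of 2 children, sigma2_home = 1
  cfg <- design_config(n_children = 78, n_homes = 39,
                       pairs = c(full_together = 0, full_apart = 0,
                                 half_together = 0, half_apart = 0,
                                 unrelated_together = 39),
                       max_sibship = 2)
  d <- simulate_design(cfg, seed = 7)
  md <- d$metadata
  set.seed(8)
  est <- replicate(15, {
    y <- simulate_response(d, "binomial", sigma2_home = 1, sigma2_resid = 0.3)
    if (all(y == 0) || all(y == 1)) return(NA)
    fit_glmm(y, "binomial", md, K = d$K_true$values)$sigma2_home
  })
  expect_lt(abs(median(est, na.rm = TRUE) - 1), 0.5)
})

test_that("permutation p has the add-one floor and is deterministic", {
  d <- study_design()
  md <- d$metadata
  K <- d$K_true$values
  set.seed(33)
  y <- simulate_response(d, "negative_binomial", sigma2_g = 2,
                         sigma2_resid = 0.2)
  p1 <- permutation_null(y, "negative_binomial", md, K, "genetic",
                         n_perm = 19, seed = 9, offset = log(d$depth))
  p2 <- permutation_null(y, "negative_binomial", md, K, "genetic",
                         n_perm = 19, seed = 9, offset = log(d$depth))
  expect_identical(p1$perm_p, p2$perm_p)
  expect_gte(p1$perm_p, 1 / 20)
  expect_false(p1$unreliable)
})

test_that("the per-ASV runner is deterministic and journal-resumable", {
  d <- study_design()
  sim <- simulate_counts(d, n_asvs = 8, seed = 31)
  tab <- drop_singletons(filter_low_count(sim$table))
  r1 <- run_all_asvs(tab, d$metadata, d$K_true$values, n_perm = 19, seed = 3)
  r2 <- run_all_asvs(tab, d$metadata, d$K_true$values, n_perm = 19, seed = 3)
  expect_identical(r1, r2)
  expect_true(all(c("asv_id", "model_type", "component", "h2", "e2",
                    "lrt_p", "q_value", "perm_p", "significant")
                  %in% names(r1)))
  expect_true(all(r1$component %in% c("genetic", "home")))
  expect_true(all(r1$h2 >= 0 & r1$h2 <= 1))
  expect_true(all(r1$h2 + r1$e2 <= 1 + 1e-8))
  # resumable: journal from a partial run is reused
  jf <- withr::local_tempfile(fileext = ".tsv")
  r3 <- run_all_asvs(tab, d$metadata, d$K_true$values, n_perm = 19, seed = 3,
                     journal = jf)
  expect_true(file.exists(jf))
  r4 <- run_all_asvs(tab, d$metadata, d$K_true$values, n_perm = 19, seed = 3,
                     journal = jf)
  expect_equal(r3, r4)
})

test_that("kinship repair clips negative eigenvalues only", {
  K <- diag(1, 4)
  K[1, 2] <- K[2, 1] <- 0.7
  K[3, 4] <- K[4, 3] <- 1.2   # indefinite block
  K2 <- repair_kinship(K)
  expect_gte(min(eigen(K2, symmetric = TRUE)$values), 0)
  ok <- diag(1, 3)
  expect_identical(repair_kinship(ok), ok)
})
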