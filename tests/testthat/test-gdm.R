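test_that("I-spline basis hits its boundary values and is monotone", {
  knots <- c(0, 0.3, 1)
  b <- ispline_basis(c(0, 1), knots)
  expect_equal(unname(b[1, ]), c(0, 0, 0))
  expect_equal(unname(b[2, ]), c(1, 1, 1))
  x <- seq(0, 1, length.out = 400)
  bx <- ispline_basis(x, knots)
  expect_true(all(diff(bx[, 1]) >= -1e-12))
  expect_true(all(diff(bx[, 2]) >= -1e-12))
  expect_true(all(diff(bx[, 3]) >= -1e-12))
  # values outside the span clamp to the boundary values
  expect_equal(unname(ispline_basis(c(-5, 5), knots)),
               unname(ispline_basis(c(0, 1), knots)))
  expect_error(ispline_basis(x, c(0, 0, 1)), "degenerate")
})

test_that("site-pair tables have n(n-1)/2 rows and correct entries", {
  ids <- c("a", "b", "c")
  dm <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3,
               dimnames = list(ids, ids))
  pm <- pairwise_matrix(dm, "bray_curtis")
  ages <- c(exp(1), exp(2), exp(1.5))
  env <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, dimnames = list(ids, ids))
  sp <- build_site_pairs(pm,
                         site_covars = data.frame(child_id = ids,
                                                  ln_age = log(ages)),
                         matrix_predictors = list(env = env))
  expect_equal(length(sp$d), 3)
  ab <- which(sp$pair_index[, 1] == 1 & sp$pair_index[, 2] == 2)
  expect_equal(sp$predictors$ln_age[ab], 1.0)
  expect_equal(sp$predictors$env, c(1, 1, 1))
  expect_error(build_site_pairs(pm, site_covars = data.frame(
    child_id = c("a", "b", "x"), v = 1:3)), "missing children")
})

test_that("a noiseless monotone signal is recovered almost exactly", {
  set.seed(31)
  ids <- sprintf("c%02d", 1:12)
  x <- random_sym(12, ids)
  d <- 1 - exp(-(0.1 + 0.8 * x))
  diag(d) <- 0
  sp <- build_site_pairs(pairwise_matrix(d, "bray_curtis"),
                         matrix_predictors = list(xp = x))
  m <- fit_gdm(sp)
  expect_gt(m$deviance_explained, 99)
  grid <- seq(min(x[upper.tri(x)]), max(x[upper.tri(x)]), length.out = 100)
  recovered <- m$intercept + gdm_transform(m, "xp", grid)
  expect_lt(max(abs(recovered - (0.1 + 0.8 * grid))), 0.02)
})

test_that("predictors unrelated to the response explain almost nothing", {
  set.seed(77)
  n <- 74
  ids <- sprintf("c%02d", 1:n)
  d <- random_sym(n, ids)
  noise <- random_sym(n, ids)
  sp <- build_site_pairs(pairwise_matrix(d, "bray_curtis"),
                         site_covars = data.frame(child_id = ids,
                                                  v = rnorm(n)),
                         matrix_predictors = list(np = noise))
  m <- fit_gdm(sp)
  expect_lt(m$deviance_explained, 1)
})

test_that("fitted deviance never exceeds null and is relabeling-invariant", {
  set.seed(13)
  ids <- sprintf("c%02d", 1:15)
  x <- random_sym(15, ids)
  d <- 1 - exp(-(0.2 + 0.5 * x + 0.2 * random_sym(15, ids)))
  diag(d) <- 0
  sp <- build_site_pairs(pairwise_matrix(d, "bray_curtis"),
                         matrix_predictors = list(xp = x))
  m <- fit_gdm(sp)
  expect_lte(m$fitted_deviance, m$null_deviance)
  # relabel children: same model up to numerics
  perm <- sample(15)
  ids2 <- ids  # same names, permuted content
  d2 <- d[perm, perm]; dimnames(d2) <- list(ids, ids)
  x2 <- x[perm, perm]; dimnames(x2) <- list(ids, ids)
  sp2 <- build_site_pairs(pairwise_matrix(d2, "bray_curtis"),
                          matrix_predictors = list(xp = x2))
  m2 <- fit_gdm(sp2)
  expect_equal(m2$deviance_explained, m$deviance_explained, tolerance = 1e-6)
})

test_that("adding a duplicated predictor never decreases deviance explained", {
  set.seed(17)
  ids <- sprintf("c%02d", 1:12)
  x <- random_sym(12, ids)
  d <- 1 - exp(-(0.2 + 0.6 * x)); diag(d) <- 0
  pm <- pairwise_matrix(d, "bray_curtis")
  m1 <- fit_gdm(build_site_pairs(pm, matrix_predictors = list(a = x)))
  m2 <- fit_gdm(build_site_pairs(pm, matrix_predictors = list(a = x, b = x)))
  expect_gte(m2$deviance_explained, m1$deviance_explained - 1e-8)
})

test_that("IRLS-NNLS deviance matches a direct constrained optimizer", {
  set.seed(23)
  for (i in 1:6) {
    ids <- sprintf("c%02d", 1:15)
    x <- random_sym(15, ids)
    d <- 1 - exp(-(0.2 + 0.7 * x + 0.3 * random_sym(15, ids)))
    diag(d) <- 0
    sp <- build_site_pairs(pairwise_matrix(d, "bray_curtis"),
                           matrix_predictors = list(xp = x))
    m <- fit_gdm(sp)
    oracle <- gdm_oracle_deviance(sp)
    expect_lt(abs(m$fitted_deviance - oracle) / max(oracle, 1e-8), 1e-6)
  }
})

test_that("permutation importance isolates the generating predictor", {
  set.seed(53)
  n <- 30
  ids <- sprintf("c%02d", 1:n)
  x <- random_sym(n, ids)
  d <- 1 - exp(-(0.1 + 1.2 * x)); diag(d) <- 0
  noise <- random_sym(n, ids)
  sp <- build_site_pairs(pairwise_matrix(d, "bray_curtis"),
                         matrix_predictors = list(signal = x, noise = noise))
  m <- fit_gdm(sp)
  imp <- predictor_importance(sp, m, n_perm = 49, seed = 11)
  sig <- imp[imp$predictor == "signal", ]
  noi <- imp[imp$predictor == "noise", ]
  expect_gt(sig$pct_of_explained, 80)
  expect_equal(sig$permutation_p, 1 / 50)
  expect_lt(abs(noi$pct_of_explained), 10)
  expect_gt(noi$permutation_p, 0.1)
})

test_that("importance and overall p are deterministic given the seed", {
  set.seed(3)
  ids <- sprintf("c%02d", 1:12)
  x <- random_sym(12, ids)
  d <- 1 - exp(-(0.2 + 0.8 * x)); diag(d) <- 0
  sp <- build_site_pairs(pairwise_matrix(d, "bray_curtis"),
                         matrix_predictors = list(xp = x))
  m <- fit_gdm(sp)
  i1 <- predictor_importance(sp, m, n_perm = 19, seed = 4)
  i2 <- predictor_importance(sp, m, n_perm = 19, seed = 4)
  expect_identical(i1, i2)
  o1 <- gdm_overall_p(sp, m, n_perm = 19, seed = 4)
  o2 <- gdm_overall_p(sp, m, n_perm = 19, seed = 4)
  expect_identical(o1$p, o2$p)
})

test_that("backward selection keeps a significant minimal model unchanged and drops noise", {
  set.seed(71)
  n <- 40
  ids <- sprintf("c%02d", 1:n)
  x <- random_sym(n, ids)
  d <- 1 - exp(-(0.1 + 1.5 * x)); diag(d) <- 0
  pm <- pairwise_matrix(d, "bray_curtis")
  sp_min <- build_site_pairs(pm, matrix_predictors = list(signal = x))
  sel_min <- backward_select(sp_min, n_perm = 49, seed = 5)
  expect_length(sel_min$dropped, 0)
  expect_named(sel_min$model$predictors, "signal")

  sp_full <- build_site_pairs(
    pm, site_covars = data.frame(child_id = ids, junk = rnorm(n)),
    matrix_predictors = list(signal = x, noise = random_sym(n, ids)))
  sel <- backward_select(sp_full, n_perm = 49, seed = 5)
  expect_true("signal" %in% names(sel$model$predictors))
  expect_lte(sel$overall_p, 0.05)
})

test_that("all-noise candidate set collapses to the intercept-only model", {
  set.seed(29)
  ids <- sprintf("c%02d", 1:20)
  d <- random_sym(20, ids)
  sp <- build_site_pairs(pairwise_matrix(d, "bray_curtis"),
                         site_covars = data.frame(child_id = ids,
                                                  junk = rnorm(20)))
  expect_warning(sel <- backward_select(sp, n_perm = 29, seed = 2),
                 "intercept-only")
  expect_true(sel$intercept_only)
})

test_that("fitted transforms and predictions are monotone in every predictor", {
  set.seed(91)
  ids <- sprintf("c%02d", 1:14)
  x <- random_sym(14, ids)
  d <- 1 - exp(-(0.15 + 0.9 * x + 0.2 * random_sym(14, ids)))
  diag(d) <- 0
  sp <- build_site_pairs(pairwise_matrix(d, "bray_curtis"),
                         matrix_predictors = list(xp = x,
                                                  env = (x > 0.5) * 1.0))
  m <- fit_gdm(sp)
  grid <- seq(0, 1, length.out = 200)
  for (nm in names(m$predictors)) {
    f <- gdm_transform(m, nm, grid)
    expect_true(all(diff(f) >= -1e-12), label = paste("monotone:", nm))
  }
  mu <- predict_gdm(m, sp)
  expect_true(all(mu >= 0 & mu <= 1))
})
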