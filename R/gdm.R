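#' Build a site-pair table for dissimilarity regression
#'
#' Assembles the response (pairwise community dissimilarity) and the
#' predictors over all n(n-1)/2 unordered child pairs. Site covariates
#' (per-child values such as natural-log age) enter as absolute pairwise
#' differences; matrix predictors (genetic dissimilarity `1 - r`, binary
#' home-environment dissimilarity) enter as-is.
#'
#' @param dissim a [pairwise_matrix] response (Bray-Curtis or Jaccard).
#' @param site_covars optional data.frame of per-child covariates, rows in
#'   the canonical child order of `dissim` (or carrying a `child_id` column);
#'   values are used untransformed — pass `log(age)` for a log-age predictor.
#' @param matrix_predictors optional named list of [pairwise_matrix] objects
#'   (or plain symmetric matrices) over the same children.
#' @return An object of class `site_pairs`: response `d`, named predictor
#'   pair-vectors, the per-child sources needed for permutation tests, and
#'   the pair index.
#' @export
build_site_pairs <- function(dissim, site_covars = NULL, matrix_predictors = NULL) {
  stopifnot(inherits(dissim, "pairwise_matrix"))
  ids <- dissim$child_ids
  n <- length(ids)
  if (n < 3) stop("at least 3 children are required")
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  d <- dissim$values[idx]
  predictors <- list()
  sources <- list()
  if (!is.null(site_covars)) {
    site_covars <- as.data.frame(site_covars)
    if ("child_id" %in% names(site_covars)) {
      missing <- setdiff(ids, site_covars$child_id)
      if (length(missing)) stop("site covariates missing children: ",
                                paste(utils::head(missing, 5), collapse = ", "))
      site_covars <- site_covars[match(ids, site_covars$child_id),
                                 setdiff(names(site_covars), "child_id"),
                                 drop = FALSE]
    } else if (nrow(site_covars) != n) {
      stop("site covariate rows do not match the number of children")
    }
    for (nm in names(site_covars)) {
      v <- as.numeric(site_covars[[nm]])
      predictors[[nm]] <- abs(v[idx[, 1]] - v[idx[, 2]])
      sources[[nm]] <- list(type = "site", values = stats::setNames(v, ids))
    }
  }
  if (!is.null(matrix_predictors)) {
    if (is.null(names(matrix_predictors)) || any(names(matrix_predictors) == ""))
      stop("matrix predictors must be named")
    for (nm in names(matrix_predictors)) {
      m <- matrix_predictors[[nm]]
      if (inherits(m, "pairwise_matrix")) {
        if (!identical(m$child_ids, ids))
          stop("matrix predictor '", nm, "' indexes different children")
        m <- m$values
      } else {
        m <- as.matrix(m)
        if (nrow(m) != n || ncol(m) != n)
          stop("matrix predictor '", nm, "' has wrong dimensions")
      }
      if (any(m[idx] < 0)) stop("matrix predictor '", nm, "' has negative pair values")
      predictors[[nm]] <- m[idx]
      sources[[nm]] <- list(type = "matrix", values = m)
    }
  }
  structure(list(d = d, predictors = predictors, sources = sources,
                 pair_index = idx, child_ids = ids, n_children = n),
            class = "site_pairs")
}

#' @export
print.site_pairs <- function(x, ...) {
  cat(sprintf("site_pairs: %d children, %d pairs, predictors: %s\n",
              x$n_children, length(x$d),
              paste(names(x$predictors), collapse = ", ")))
  invisible(x)
}

# Binomial-form deviance of d against fitted mu, with the one-sided
# convention 0*log(0) = 0 at the boundaries.
gdm_deviance <- function(d, mu) {
  eps <- 1e-9
  mu <- pmin(pmax(mu, eps), 1 - eps)
  t1 <- ifelse(d > 0, d * log(d / mu), 0)
  t2 <- ifelse(d < 1, (1 - d) * log((1 - d) / (1 - mu)), 0)
  2 * sum(t1 + t2)
}

# Core IRLS / non-negative least squares solver on a prepared design matrix
# (first column = intercept). Returns coefficients (all >= 0), deviance and
# convergence information.
gdm_irls <- function(d, X, max_iter = 100, tol = 1e-8) {
  eps <- 1e-9
  d <- pmin(pmax(d, eps), 1 - eps)
  beta <- rep(0, ncol(X))
  beta[1] <- max(-log(1 - mean(d)), eps)
  eta <- drop(X %*% beta)
  dev <- gdm_deviance(d, 1 - exp(-eta))
  trace <- dev
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mu <- 1 - exp(-eta)
    mu <- pmin(pmax(mu, eps), 1 - eps)
    # link mu = 1 - exp(-eta): dmu/deta = 1 - mu; binomial-form variance
    w <- (1 - mu)^2 / (mu * (1 - mu))
    z <- eta + (d - mu) / (1 - mu)
    sw <- sqrt(w)
    beta_new <- nnls_solve(X * sw, z * sw)
    eta_new <- drop(X %*% beta_new)
    dev_new <- gdm_deviance(d, 1 - exp(-eta_new))
    # step-halving keeps the deviance monotone; plain IRLS can 2-cycle when
    # the NNLS active set flips between iterations
    half <- 0
    while (dev_new > dev + 1e-12 && half < 12) {
      beta_new <- (beta + beta_new) / 2   # stays non-negative
      eta_new <- drop(X %*% beta_new)
      dev_new <- gdm_deviance(d, 1 - exp(-eta_new))
      half <- half + 1
    }
    trace <- c(trace, dev_new)
    if (abs(dev - dev_new) < tol) {
      beta <- beta_new; eta <- eta_new; dev <- dev_new
      converged <- TRUE
      break
    }
    beta <- beta_new; eta <- eta_new; dev <- dev_new
  }
  if (!converged && abs(diff(utils::tail(trace, 2))) < 1e-4) converged <- TRUE
  if (!converged)
    stop("GDM IRLS failed to converge; deviance trace: ",
         paste(format(utils::tail(trace, 5), digits = 8), collapse = " -> "))
  list(beta = beta, eta = eta, deviance = dev, iterations = it, trace = trace)
}

#' Fit a generalized dissimilarity model
#'
#' Matrix regression of pairwise community dissimilarity on monotone
#' I-spline transforms of the predictors, with the negative exponential link
#' `mu = 1 - exp(-eta)`. Coefficients (including the intercept) are
#' constrained non-negative and estimated by iteratively reweighted
#' non-negative least squares minimising the binomial-form deviance; the
#' non-negativity guarantees the fitted transform of every predictor is
#' monotone nondecreasing. Deviance explained is reported against the
#' intercept-only null fit.
#'
#' @param pairs a [build_site_pairs()] table with at least one predictor.
#' @param knots optional named list of 3-knot vectors per predictor; by
#'   default knots sit at the 0/50/100th percentiles of each predictor's
#'   pairwise values. Predictors whose values cannot support three distinct
#'   knots (e.g. the binary home indicator) get a single linear
#'   non-negative term instead.
#' @return An object of class `gdm_model`: intercept, per-predictor spline
#'   description, null and fitted deviance, `deviance_explained` (percent).
#' @export
fit_gdm <- function(pairs, knots = NULL) {
  stopifnot(inherits(pairs, "site_pairs"))
  if (!length(pairs$predictors)) stop("at least one predictor is required")
  bases <- lapply(names(pairs$predictors), function(nm)
    predictor_basis(pairs$predictors[[nm]],
                    knots = if (!is.null(knots)) knots[[nm]] else NULL))
  names(bases) <- names(pairs$predictors)
  X <- cbind(intercept = 1,
             do.call(cbind, lapply(bases, function(b) b$basis)))
  d <- pairs$d
  null_fit <- gdm_irls(d, matrix(1, length(d), 1))
  if (stats::var(d) == 0 || null_fit$deviance < 1e-12) {
    # all-constant response: nothing to explain
    fit <- null_fit
    de <- 0
  } else {
    fit <- gdm_irls(d, X)
    de <- 100 * (null_fit$deviance - fit$deviance) / null_fit$deviance
    de <- max(min(de, 100), 0)
  }
  coefs <- fit$beta
  pred_desc <- list()
  pos <- 2
  for (nm in names(bases)) {
    k <- ncol(bases[[nm]]$basis)
    pred_desc[[nm]] <- list(type = bases[[nm]]$type,
                            knots = bases[[nm]]$knots,
                            coef = if (length(coefs) >= pos)
                              coefs[pos:(pos + k - 1)] else rep(0, k))
    pos <- pos + k
  }
  structure(list(intercept = coefs[1],
                 predictors = pred_desc,
                 null_deviance = null_fit$deviance,
                 fitted_deviance = fit$deviance,
                 deviance_explained = de,
                 iterations = fit$iterations),
            class = "gdm_model")
}

#' @export
print.gdm_model <- function(x, ...) {
  cat(sprintf("gdm_model: %d predictor(s), deviance explained %.2f%%\n",
              length(x$predictors), x$deviance_explained))
  for (nm in names(x$predictors)) {
    p <- x$predictors[[nm]]
    cat(sprintf("  %s [%s]: coef sum %.4f\n", nm, p$type, sum(p$coef)))
  }
  invisible(x)
}

#' Evaluate a fitted predictor transform
#'
#' The monotone partial transform `f_p(x) = sum_k alpha_pk I_k(x)` of one
#' predictor, on the scale of the linear predictor.
#'
#' @param model a [fit_gdm()] model.
#' @param predictor predictor name.
#' @param x values at which to evaluate.
#' @return numeric vector of transform values.
#' @export
gdm_transform <- function(model, predictor, x) {
  p <- model$predictors[[predictor]]
  if (is.null(p)) stop("unknown predictor: ", predictor)
  if (p$type == "linear") {
    span <- if (diff(p$knots) > 0) diff(p$knots) else 1
    b <- matrix((pmin(pmax(x, p$knots[1]), p$knots[2]) - p$knots[1]) / span, ncol = 1)
  } else {
    b <- ispline_basis(x, p$knots)
  }
  drop(b %*% p$coef)
}

#' Predicted dissimilarity for a site-pair table
#'
#' @param model a [fit_gdm()] model.
#' @param pairs the [build_site_pairs()] table (must carry the model's
#'   predictors).
#' @return numeric vector of predicted dissimilarities `1 - exp(-eta)`.
#' @export
predict_gdm <- function(model, pairs) {
  eta <- rep(model$intercept, length(pairs$d))
  for (nm in names(model$predictors)) {
    x <- pairs$predictors[[nm]]
    if (is.null(x)) stop("pair table lacks predictor: ", nm)
    eta <- eta + gdm_transform(model, nm, x)
  }
  1 - exp(-eta)
}

# Rebuild one predictor's pair values under a permutation of child identities.
permute_predictor <- function(pairs, name, perm) {
  src <- pairs$sources[[name]]
  idx <- pairs$pair_index
  if (src$type == "site") {
    v <- unname(src$values)[perm]
    abs(v[idx[, 1]] - v[idx[, 2]])
  } else {
    m <- src$values[perm, perm]
    m[idx]
  }
}

site_pairs_with <- function(pairs, new_predictors) {
  out <- pairs
  out$predictors[names(new_predictors)] <- new_predictors
  out
}

#' Permutation importance of GDM predictors
#'
#' For each predictor, child identities are permuted for that predictor only
#' (rows and columns jointly for matrix predictors; values across children
#' for site covariates), the model is refitted, and the drop in deviance
#' explained is recorded. Importance is the mean percentage of the full
#' model's deviance explained that is lost under permutation; the p-value is
#' the fraction of permutations achieving at least the full model's deviance
#' explained, with the add-one correction `(1 + k) / (1 + n_perm)`.
#'
#' The permutation unit is the child, not the pair, which respects the
#' dependence structure of a distance matrix.
#'
#' @param pairs a [build_site_pairs()] table.
#' @param model the fitted full model on `pairs`.
#' @param n_perm number of permutations (study setting: 999).
#' @param seed integer seed governing all permutations.
#' @return data.frame with columns `predictor`, `pct_of_explained`,
#'   `permutation_p`, `n_permutations`.
#' @export
predictor_importance <- function(pairs, model, n_perm = 999, seed = 1) {
  stopifnot(inherits(pairs, "site_pairs"), inherits(model, "gdm_model"))
  if (n_perm < 1) stop("n_perm must be >= 1")
  de_full <- model$deviance_explained
  nms <- names(pairs$predictors)
  res <- with_seed(seed, {
    lapply(nms, function(nm) {
      de_perm <- vapply(seq_len(n_perm), function(b) {
        perm <- sample.int(pairs$n_children)
        pp <- site_pairs_with(pairs, stats::setNames(
          list(permute_predictor(pairs, nm, perm)), nm))
        fit_gdm(pp)$deviance_explained
      }, numeric(1))
      c(imp = if (de_full > 0) 100 * (de_full - mean(de_perm)) / de_full else 0,
        p = (1 + sum(de_perm >= de_full)) / (1 + n_perm))
    })
  })
  data.frame(predictor = nms,
             pct_of_explained = vapply(res, `[[`, numeric(1), "imp"),
             permutation_p = vapply(res, `[[`, numeric(1), "p"),
             n_permutations = n_perm,
             stringsAsFactors = FALSE)
}

#' Overall GDM model permutation p-value
#'
#' All predictors are permuted simultaneously with the same child
#' permutation (preserving the structure among predictors while breaking
#' their link to the response) and the model refitted.
#'
#' @inheritParams predictor_importance
#' @return list with `p`, `de_full`, `de_perm` (vector).
#' @export
gdm_overall_p <- function(pairs, model, n_perm = 999, seed = 1) {
  stopifnot(inherits(pairs, "site_pairs"), inherits(model, "gdm_model"))
  de_full <- model$deviance_explained
  de_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      perm <- sample.int(pairs$n_children)
      new_p <- lapply(names(pairs$predictors), function(nm)
        permute_predictor(pairs, nm, perm))
      names(new_p) <- names(pairs$predictors)
      fit_gdm(site_pairs_with(pairs, new_p))$deviance_explained
    }, numeric(1))
  })
  list(p = (1 + sum(de_perm >= de_full)) / (1 + n_perm),
       de_full = de_full, de_perm = de_perm)
}

#' Backward model selection for a GDM
#'
#' Starting from the full model, repeatedly drops the predictor with the
#' smallest permutation importance while the overall model permutation
#' p-value is non-significant or any predictor's importance is non-positive.
#' Ties in importance are broken by dropping the later predictor in input
#' order. Stops when the model is significant with all importances positive,
#' or when a single predictor remains (or none: the intercept-only model is
#' returned with a warning flag).
#'
#' @param pairs a [build_site_pairs()] table with all candidate predictors.
#' @param alpha significance level for the overall model p-value.
#' @param n_perm permutations per round.
#' @param seed integer seed.
#' @return list with `model` (final [gdm_model] or `NULL` if everything was
#'   eliminated), `importance` (final round), `overall_p`, `dropped`
#'   (in drop order), `intercept_only` flag.
#' @export
backward_select <- function(pairs, alpha = 0.05, n_perm = 999, seed = 1) {
  stopifnot(inherits(pairs, "site_pairs"))
  current <- pairs
  dropped <- character(0)
  round_seed <- seed
  repeat {
    model <- fit_gdm(current)
    imp <- predictor_importance(current, model, n_perm = n_perm, seed = round_seed)
    overall <- gdm_overall_p(current, model, n_perm = n_perm, seed = round_seed + 1)
    keep_going <- (overall$p > alpha || any(imp$pct_of_explained <= 0)) &&
      length(current$predictors) > 1
    if (!keep_going) {
      if (overall$p > alpha && length(current$predictors) == 1) {
        # last predictor still non-significant: fall back to intercept-only
        dropped <- c(dropped, names(current$predictors))
        warning("all predictors eliminated; returning intercept-only model")
        return(list(model = NULL, importance = NULL, overall_p = overall$p,
                    dropped = dropped, intercept_only = TRUE))
      }
      return(list(model = model, importance = imp, overall_p = overall$p,
                  dropped = dropped, intercept_only = FALSE))
    }
    # smallest importance; ties broken towards the later predictor
    ord <- order(imp$pct_of_explained, -seq_len(nrow(imp)))
    victim <- imp$predictor[ord[1]]
    dropped <- c(dropped, victim)
    current$predictors[[victim]] <- NULL
    current$sources[[victim]] <- NULL
    round_seed <- round_seed + 2
  }
}
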