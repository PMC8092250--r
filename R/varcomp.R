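# One ASV, one model family: full fit plus the two single-component
# reductions, with the likelihood-ratio statistics. Returns a two-row
# data.frame (one per component) or NULL when the response is untestable.
fit_asv_components <- function(y, family, metadata, K, offset,
                               resid_convention = "latent") {
  if (family == "binomial" && (all(y == 0) || all(y == 1))) return(NULL)
  if (family == "negative_binomial" && all(y == 0)) return(NULL)
  full <- tryCatch(
    fit_glmm(y, family, metadata, K = K, offset = offset,
             resid_convention = resid_convention),
    error = function(e) NULL)
  if (is.null(full)) return(NULL)
  props <- variance_proportions(full)
  out <- lapply(c("genetic", "home"), function(comp) {
    red <- tryCatch(
      fit_glmm(y, family, metadata, K = K, offset = offset,
               components = setdiff(c("genetic", "home"), comp),
               resid_convention = resid_convention),
      error = function(e) NULL)
    if (is.null(red)) return(NULL)
    lrt <- lrt_component(full, red)
    data.frame(component = comp,
               variance = if (comp == "genetic") full$sigma2_g else full$sigma2_home,
               h2 = unname(props["h2"]), e2 = unname(props["e2"]),
               lrt_stat = lrt$stat, lrt_p = lrt$p, delta_ll = lrt$delta_ll,
               converged = full$converged,
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Screen variance-component models for follow-up testing
#'
#' Two-stage screen before the permutation tests: Benjamini-Hochberg FDR is
#' applied to the likelihood-ratio p-values within each model type and
#' component across all testable ASVs, and an (ASV, model type) is retained
#' when some component improved the log likelihood (`delta_ll > 0`) with
#' `q <= q_threshold`, unless every component's variance proportion is below
#' the magnitude floor.
#'
#' @param results long data.frame from the per-ASV fits with columns
#'   `asv_id`, `model_type`, `component`, `h2`, `e2`, `lrt_p`, `delta_ll`.
#' @param q_threshold FDR level (default 0.05).
#' @param magnitude floor on the variance proportions (default 0.05); an
#'   (ASV, model type) where both `h2 < magnitude` and `e2 < magnitude` is
#'   eliminated regardless of q.
#' @param pool_model_types apply the FDR across abundance and presence
#'   models jointly instead of separately.
#' @return `results` with added columns `q_value` and `retained` (logical,
#'   constant within an (ASV, model type)).
#' @export
screen_models <- function(results, q_threshold = 0.05, magnitude = 0.05,
                          pool_model_types = FALSE) {
  if (!nrow(results)) {
    results$q_value <- numeric(0)
    results$retained <- logical(0)
    return(results)
  }
  grp <- if (pool_model_types) results$component
         else paste(results$model_type, results$component)
  results$q_value <- NA_real_
  for (g in unique(grp)) {
    i <- grp == g
    results$q_value[i] <- stats::p.adjust(results$lrt_p[i], method = "BH")
  }
  key <- paste(results$asv_id, results$model_type)
  pass_comp <- results$delta_ll > 0 & results$q_value <= q_threshold
  any_pass <- tapply(pass_comp, key, any)
  big <- tapply(pmax(results$h2, results$e2) >= magnitude, key, any)
  results$retained <- as.logical(any_pass[key] & big[key])
  results
}

#' Permutation null for one variance component
#'
#' Builds the null distribution of a fitted variance component by
#' permutation and refitting: the household component permutes the
#' child-to-home assignment; the genetic component applies one random
#' permutation jointly to the rows and columns of the relatedness matrix.
#' `perm_p = (1 + #permuted >= observed) / (1 + n_perm)`.
#'
#' @param y response vector (counts or presence indicators).
#' @param family model family as in [fit_glmm()].
#' @param metadata [sample_metadata] in canonical order.
#' @param K relatedness matrix.
#' @param component `"genetic"` or `"home"`.
#' @param n_perm number of permutations (study setting: 499).
#' @param seed integer seed.
#' @param offset linear-predictor offset.
#' @param observed optional observed component variance (refitted when
#'   missing).
#' @param max_iter,tol PQL controls for the permutation refits; the default
#'   is looser than the observed fit's, since each permuted variance
#'   estimate only has to be accurate relative to permutation noise.
#' @return list with `perm_p`, `observed`, `perm_values`, `unreliable`
#'   (set when more than 20% of permutation fits failed).
#' @export
permutation_null <- function(y, family, metadata, K, component,
                             n_perm = 499, seed = 1, offset = NULL,
                             observed = NULL, max_iter = 60, tol = 1e-5) {
  component <- match.arg(component, c("genetic", "home"))
  metadata <- sample_metadata(metadata)
  if (is.null(observed)) {
    full <- fit_glmm(y, family, metadata, K = K, offset = offset)
    observed <- if (component == "genetic") full$sigma2_g else full$sigma2_home
  }
  n <- length(y)
  perm_values <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      perm <- sample.int(n)
      meta_b <- metadata
      K_b <- K
      if (component == "home") meta_b$home_id <- metadata$home_id[perm]
      else K_b <- K[perm, perm]
      fit <- tryCatch(fit_glmm(y, family, meta_b, K = K_b, offset = offset,
                               max_iter = max_iter, tol = tol),
                      error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      if (component == "genetic") fit$sigma2_g else fit$sigma2_home
    }, numeric(1))
  })
  ok <- !is.na(perm_values)
  list(perm_p = (1 + sum(perm_values[ok] >= observed)) / (1 + sum(ok)),
       observed = observed,
       perm_values = perm_values,
       unreliable = mean(!ok) > 0.2)
}

#' Run the variance-component pipeline over every ASV
#'
#' Fits the abundance (negative binomial, ln-depth offset) and presence
#' (binomial, counts binarised at >= 1 read) mixed models for each ASV,
#' screens by likelihood-ratio test + BH-FDR + magnitude floor, and runs
#' the permutation null for each retained component. Component significance
#' is `perm_p <= 0.05` (the permutation test is the final arbiter; the
#' LRT/FDR stage is a screen).
#'
#' @param table a filtered, singleton-free [asv_table].
#' @param metadata [sample_metadata] covering the table's children.
#' @param K relatedness matrix over the same children (child order must
#'   match the table's canonical order).
#' @param n_perm permutations per retained component (study setting: 499).
#' @param seed master seed; per-ASV permutation seeds are derived from it.
#' @param q_threshold,magnitude,pool_model_types screening controls, see
#'   [screen_models()].
#' @param journal optional path to a TSV journal; per-ASV fit results are
#'   appended as they complete and reused on rerun (resumability).
#' @param progress print a line every 50 ASVs.
#' @return long data.frame, one row per (ASV, model type, component), with
#'   the variance estimates, proportions, LRT, q-values, permutation
#'   p-values and significance flags (`model_type` is `abundance` or
#'   `presence`).
#' @export
run_all_asvs <- function(table, metadata, K, n_perm = 499, seed = 1,
                         q_threshold = 0.05, magnitude = 0.05,
                         pool_model_types = FALSE, journal = NULL,
                         progress = FALSE) {
  stopifnot(inherits(table, "asv_table"))
  metadata <- sample_metadata(metadata)
  if (!identical(metadata$child_id, table$child_ids))
    stop("metadata children do not match table children")
  K <- repair_kinship(as.matrix(K))
  offset <- log(table$depth)
  done <- NULL
  if (!is.null(journal) && file.exists(journal)) {
    done <- utils::read.table(journal, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  }
  rows <- list()
  for (j in seq_along(table$asv_ids)) {
    asv <- table$asv_ids[j]
    if (!is.null(done) && asv %in% done$asv_id) {
      rows[[asv]] <- done[done$asv_id == asv, , drop = FALSE]
      next
    }
    y <- table$counts[, j]
    res_a <- fit_asv_components(y, "negative_binomial", metadata, K, offset)
    res_p <- fit_asv_components(as.integer(y > 0), "binomial", metadata, K,
                                offset = NULL)
    if (!is.null(res_a)) res_a$model_type <- "abundance"
    if (!is.null(res_p)) res_p$model_type <- "presence"
    res <- rbind(res_a, res_p)
    if (is.null(res)) next
    res <- cbind(asv_id = asv, res, stringsAsFactors = FALSE)
    rows[[asv]] <- res
    if (!is.null(journal)) {
      utils::write.table(res, journal, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = !file.exists(journal),
                         append = file.exists(journal))
    }
    if (progress && j %% 50 == 0)
      message(sprintf("fitted %d / %d ASVs", j, length(table$asv_ids)))
  }
  if (!length(rows)) return(empty_varcomp_results())
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  results <- screen_models(results, q_threshold = q_threshold,
                           magnitude = magnitude,
                           pool_model_types = pool_model_types)
  results$perm_p <- NA_real_
  results$perm_unreliable <- NA
  ret <- which(results$retained & results$converged)
  for (i in ret) {
    asv <- results$asv_id[i]
    j <- match(asv, table$asv_ids)
    is_ab <- results$model_type[i] == "abundance"
    y <- if (is_ab) table$counts[, j] else as.integer(table$counts[, j] > 0)
    pn <- permutation_null(
      y,
      family = if (is_ab) "negative_binomial" else "binomial",
      metadata = metadata, K = K,
      component = results$component[i],
      n_perm = n_perm,
      seed = derive_seed(seed, paste("perm", asv, results$model_type[i],
                                     results$component[i])),
      offset = if (is_ab) offset else NULL,
      observed = results$variance[i])
    results$perm_p[i] <- pn$perm_p
    results$perm_unreliable[i] <- pn$unreliable
  }
  results$significant <- !is.na(results$perm_p) & results$perm_p <= 0.05
  if (!is.null(table$taxonomy)) {
    results$order <- table$taxonomy$order[match(results$asv_id,
                                                table$taxonomy$asv_id)]
  } else {
    results$order <- NA_character_
  }
  results[c("asv_id", "order", "model_type", "component", "variance",
            "h2", "e2", "lrt_stat", "lrt_p", "q_value", "delta_ll",
            "retained", "perm_p", "perm_unreliable", "significant",
            "converged")]
}

empty_varcomp_results <- function() {
  data.frame(asv_id = character(0), order = character(0),
             model_type = character(0), component = character(0),
             variance = numeric(0), h2 = numeric(0), e2 = numeric(0),
             lrt_stat = numeric(0), lrt_p = numeric(0), q_value = numeric(0),
             delta_ll = numeric(0), retained = logical(0),
             perm_p = numeric(0), perm_unreliable = logical(0),
             significant = logical(0), converged = logical(0),
             stringsAsFactors = FALSE)
}

#' ASVs significant per model type
#'
#' @param results output of [run_all_asvs()].
#' @return named integer vector: number of ASVs with at least one
#'   significant component, per model type.
#' @export
count_significant_asvs <- function(results) {
  vapply(c(abundance = "abundance", presence = "presence"), function(mt) {
    length(unique(results$asv_id[results$model_type == mt & results$significant]))
  }, integer(1))
}
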