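#' Tally significant variance components by model type
#'
#' Builds the 2x2 table of significant components — rows abundance /
#' presence, columns genetic / environment — from a variance-component
#' result table. Counts are of significant components, not ASVs: one ASV
#' with both components significant contributes to both columns.
#'
#' @param results output of [run_all_asvs()] (rows with
#'   `significant == TRUE` are counted).
#' @return 2x2 integer matrix with dimnames
#'   `list(c("abundance", "presence"), c("genetic", "environment"))`.
#' @export
tally_components <- function(results) {
  sig <- results[results$significant %in% TRUE, , drop = FALSE]
  m <- matrix(0L, 2, 2,
              dimnames = list(c("abundance", "presence"),
                              c("genetic", "environment")))
  for (mt in rownames(m)) for (comp in c("genetic", "home")) {
    col <- if (comp == "genetic") "genetic" else "environment"
    m[mt, col] <- sum(sig$model_type == mt & sig$component == comp)
  }
  m
}

#' Chi-square test on the component-by-model-type table
#'
#' Pearson chi-square without continuity correction on the 2x2 tally of
#' significant variance components (abundance vs presence x genetic vs
#' environment), testing whether abundance and presence are differentially
#' explained by genetics and home environment. Closed form
#' `n (ad - bc)^2 / (r1 r2 c1 c2)`, df = 1, upper-tail p.
#'
#' @param tally 2x2 non-negative integer matrix (see [tally_components()]).
#' @return list with `statistic`, `df`, `p`.
#' @export
chi_square_pattern <- function(tally) {
  tally <- as.matrix(tally)
  if (!all(dim(tally) == c(2, 2))) stop("a 2x2 table is required")
  if (any(tally < 0)) stop("negative cell counts")
  rs <- rowSums(tally); cs <- colSums(tally); n <- sum(tally)
  if (any(rs == 0) || any(cs == 0)) stop("zero marginal in the 2x2 table")
  stat <- n * (tally[1, 1] * tally[2, 2] - tally[1, 2] * tally[2, 1])^2 /
    prod(c(rs, cs))
  list(statistic = stat, df = 1L,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Taxonomic-order enrichment among significant ASVs by resampling
#'
#' Tests whether any bacterial order is oversampled among the significant
#' ASVs relative to its share of the testable pool: each permutation draws
#' `length(significant_ids)` ASVs from the pool without replacement, and an
#' order's p-value is the proportion of permutations selecting at least the
#' observed number from that order (with the add-one correction).
#'
#' @param significant_ids character ids of the significant ASVs (must be a
#'   subset of `pool`).
#' @param pool character ids of all testable ASVs.
#' @param taxonomy data.frame with `asv_id` and `order` covering the pool.
#' @param n_perm number of permutations (study setting: 9,999).
#' @param seed integer seed.
#' @return data.frame per order: `order`, `observed`, `pool_count`,
#'   `expected`, `perm_p`, `enriched` (`perm_p < 0.05`).
#' @export
order_enrichment <- function(significant_ids, pool, taxonomy,
                             n_perm = 9999, seed = 1) {
  if (!all(significant_ids %in% pool))
    stop("significant ASVs must belong to the testable pool")
  if (length(significant_ids) > length(pool)) stop("pool smaller than draw")
  ord <- taxonomy$order[match(pool, taxonomy$asv_id)]
  if (anyNA(ord)) stop("every pool member needs an order assignment")
  orders <- sort(unique(ord))
  obs <- table(factor(taxonomy$order[match(significant_ids, taxonomy$asv_id)],
                      levels = orders))
  k <- length(significant_ids)
  ord_f <- factor(ord, levels = orders)
  exceed <- with_seed(seed, {
    e <- rep(0L, length(orders))
    for (b in seq_len(n_perm)) {
      draw <- tabulate(ord_f[sample.int(length(pool), k)], nbins = length(orders))
      e <- e + (draw >= as.integer(obs))
    }
    e
  })
  p <- (1 + exceed) / (1 + n_perm)
  data.frame(order = orders,
             observed = as.integer(obs),
             pool_count = as.integer(table(ord_f)),
             expected = k * as.integer(table(ord_f)) / length(pool),
             perm_p = p,
             enriched = p < 0.05,
             row.names = NULL,
             stringsAsFactors = FALSE)
}
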