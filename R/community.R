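#' Remove low-count ASVs
#'
#' Drops ASVs whose pooled read count across all children is below
#' `min_reads` (default 5: fewer than five reads in the pooled data set is
#' treated as likely sequencing error). Per-child depths are *not*
#' recomputed — they describe the original sequencing effort.
#'
#' @param table an [asv_table].
#' @param min_reads minimum pooled reads to retain an ASV (>= 1).
#' @return A filtered [asv_table].
#' @export
filter_low_count <- function(table, min_reads = 5) {
  stopifnot(inherits(table, "asv_table"))
  if (min_reads < 1) stop("min_reads must be >= 1")
  keep <- colSums(table$counts) >= min_reads
  subset_asvs(table, keep)
}

#' Remove singleton ASVs
#'
#' Drops ASVs observed (>= 1 read) in only one child: a single observation
#' carries no between-child variance and is untestable in the variance
#' component models.
#'
#' @param table an [asv_table].
#' @return A filtered [asv_table].
#' @export
drop_singletons <- function(table) {
  stopifnot(inherits(table, "asv_table"))
  keep <- colSums(table$counts > 0) >= 2
  subset_asvs(table, keep)
}

#' Per-ASV prevalence summary
#'
#' For each ASV: pooled reads, the number of children it occurs in (>= 1
#' read) and the number of distinct homes those children live in, with the
#' taxonomic order when taxonomy is attached.
#'
#' @param table an [asv_table].
#' @param metadata a [sample_metadata] covering every child in the table.
#' @return data.frame with columns `asv_id`, `total_reads`, `n_children`,
#'   `n_homes`, `order`.
#' @export
prevalence_summary <- function(table, metadata) {
  stopifnot(inherits(table, "asv_table"))
  metadata <- sample_metadata(metadata)
  missing <- setdiff(table$child_ids, metadata$child_id)
  if (length(missing)) stop("children absent from metadata: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  home <- metadata$home_id[match(table$child_ids, metadata$child_id)]
  pres <- table$counts > 0
  n_homes <- apply(pres, 2, function(p) length(unique(home[p])))
  ord <- if (!is.null(table$taxonomy)) table$taxonomy$order else NA_character_
  data.frame(asv_id = table$asv_ids,
             total_reads = colSums(table$counts),
             n_children = colSums(pres),
             n_homes = as.integer(n_homes),
             order = ord,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Prevalence bookkeeping counts
#'
#' Summary counts over a prevalence table: total ASVs, ASVs unique to a
#' single sample, unique to a single home, shared across every child of at
#' least one home, and found in multiple children across multiple homes.
#'
#' @param prev output of [prevalence_summary()].
#' @param table,metadata the inputs used for `prev`; needed for the
#'   "shared across all children in a home" count.
#' @return named integer vector.
#' @export
prevalence_counts <- function(prev, table = NULL, metadata = NULL) {
  out <- c(total = nrow(prev),
           single_sample = sum(prev$n_children == 1),
           single_home = sum(prev$n_homes == 1),
           all_children_one_home = NA_integer_,
           multi_child_multi_home = sum(prev$n_children > 1 & prev$n_homes > 1))
  if (!is.null(table) && !is.null(metadata)) {
    metadata <- sample_metadata(metadata)
    home <- metadata$home_id[match(table$child_ids, metadata$child_id)]
    pres <- table$counts > 0
    shared_whole_home <- vapply(seq_len(ncol(pres)), function(j) {
      homes_hit <- unique(home[pres[, j]])
      any(vapply(homes_hit, function(h) all(pres[home == h, j]), logical(1)))
    }, logical(1))
    out["all_children_one_home"] <- sum(shared_whole_home)
  }
  out
}

#' Bray-Curtis dissimilarity between children
#'
#' Abundance-based beta diversity on the raw counts:
#' `BC(a, b) = sum(|a_i - b_i|) / sum(a_i + b_i)`.
#'
#' @param table an [asv_table]; every child must have at least one read.
#' @return A [pairwise_matrix] of kind `"bray_curtis"`.
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "asv_table"))
  x <- table$counts
  tot <- rowSums(x)
  if (any(tot == 0)) stop("Bray-Curtis undefined for children with zero reads: ",
                          paste(table$child_ids[tot == 0], collapse = ", "))
  num <- as.matrix(stats::dist(x, method = "manhattan"))
  den <- outer(tot, tot, `+`)
  pairwise_matrix(num / den, kind = "bray_curtis", child_ids = table$child_ids)
}

#' Jaccard dissimilarity between children
#'
#' Presence-based beta diversity: counts are binarised at >= 1 read and
#' `J(a, b) = 1 - |A intersect B| / |A union B|` — the proportion of
#' unshared taxa between the two children.
#'
#' @param table an [asv_table]; every child must have at least one read.
#' @return A [pairwise_matrix] of kind `"jaccard"`.
#' @export
jaccard <- function(table) {
  stopifnot(inherits(table, "asv_table"))
  b <- (table$counts > 0) * 1
  rich <- rowSums(b)
  if (any(rich == 0)) stop("Jaccard undefined for children with zero reads: ",
                           paste(table$child_ids[rich == 0], collapse = ", "))
  shared <- tcrossprod(b)
  union <- outer(rich, rich, `+`) - shared
  pairwise_matrix(1 - shared / union, kind = "jaccard",
                  child_ids = table$child_ids)
}

#' Shannon diversity per child
#'
#' `H = -sum(p_i * log(p_i))` over the child's relative abundances
#' (natural log).
#'
#' @param table an [asv_table] with nonzero per-child totals.
#' @return named numeric vector of Shannon indices.
#' @export
shannon <- function(table) {
  stopifnot(inherits(table, "asv_table"))
  apply(table$counts, 1, function(x) {
    p <- x[x > 0] / sum(x)
    -sum(p * log(p))
  })
}
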