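#' ASV count table
#'
#' Container for an amplicon sequence variant (ASV) count table: an integer
#' matrix of reads with children as rows and ASVs as columns, a per-child
#' sequencing depth, and an optional per-ASV ranked taxonomy.
#'
#' Depth is the total sequencing effort of the original, unfiltered sample;
#' it is carried alongside the counts so that taxon filtering does not alter
#' the offset later used to normalise abundance models.
#'
#' @param counts integer matrix, children x ASVs; dimnames optional (child and
#'   ASV identifiers are taken from them when present).
#' @param child_ids character vector of child identifiers (defaults to
#'   rownames of `counts`).
#' @param asv_ids character vector of ASV identifiers (defaults to colnames).
#' @param depth per-child total reads; when `NULL`, recomputed as row sums.
#' @param taxonomy optional data.frame with column `asv_id` and ranked lineage
#'   columns (`kingdom`, `phylum`, `class`, `order`, `family`, `genus`).
#'
#' @return An object of class `asv_table`.
#' @export
asv_table <- function(counts, child_ids = NULL, asv_ids = NULL,
                      depth = NULL, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(child_ids)) child_ids <- rownames(counts)
  if (is.null(asv_ids))   asv_ids   <- colnames(counts)
  if (is.null(child_ids)) child_ids <- paste0("child", seq_len(nrow(counts)))
  if (is.null(asv_ids))   asv_ids   <- paste0("ASV", seq_len(ncol(counts)))
  child_ids <- as.character(child_ids)
  asv_ids <- as.character(asv_ids)
  if (anyDuplicated(child_ids)) stop("duplicate child_id in count table")
  if (anyDuplicated(asv_ids)) stop("duplicate asv_id in count table")
  if (length(child_ids) != nrow(counts) || length(asv_ids) != ncol(counts))
    stop("identifier lengths do not match count matrix dimensions")
  storage <- suppressWarnings(as.numeric(counts))
  if (anyNA(storage)) stop("counts contain missing or non-numeric values")
  if (any(storage < 0)) stop("counts must be non-negative")
  if (any(abs(storage - round(storage)) > 1e-8)) stop("counts must be integral")
  counts <- matrix(round(storage), nrow = nrow(counts),
                   dimnames = list(child_ids, asv_ids))
  if (is.null(depth)) depth <- rowSums(counts)
  depth <- as.numeric(depth)
  if (length(depth) != nrow(counts)) stop("depth length must equal number of children")
  names(depth) <- child_ids
  if (!is.null(taxonomy)) {
    taxonomy <- as.data.frame(taxonomy)
    if (!"asv_id" %in% names(taxonomy)) stop("taxonomy must have an asv_id column")
    taxonomy$asv_id <- as.character(taxonomy$asv_id)
    missing <- setdiff(asv_ids, taxonomy$asv_id)
    if (length(missing)) stop("taxonomy missing for ASVs: ",
                              paste(utils::head(missing, 5), collapse = ", "))
    taxonomy <- taxonomy[match(asv_ids, taxonomy$asv_id), , drop = FALSE]
    rownames(taxonomy) <- NULL
  }
  # canonical sorted child order so every pairwise structure lines up
  ord <- order(child_ids)
  structure(list(counts = counts[ord, , drop = FALSE],
                 child_ids = child_ids[ord],
                 asv_ids = asv_ids,
                 depth = depth[ord],
                 taxonomy = taxonomy),
            class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("asv_table: %d children x %d ASVs\n",
              length(x$child_ids), length(x$asv_ids)))
  cat(sprintf("  depth range: %s - %s\n",
              format(min(x$depth)), format(max(x$depth))))
  if (!is.null(x$taxonomy)) cat("  taxonomy: present\n")
  invisible(x)
}

#' @export
dim.asv_table <- function(x) dim(x$counts)

#' Subset an ASV table by ASV
#'
#' Keeps the listed ASVs (by id or logical/integer index) without touching
#' the per-child depths.
#'
#' @param table an [asv_table].
#' @param keep character ids, or logical/integer index over ASV columns.
#' @return An [asv_table] with the selected columns.
#' @export
subset_asvs <- function(table, keep) {
  stopifnot(inherits(table, "asv_table"))
  if (is.character(keep)) keep <- match(keep, table$asv_ids)
  counts <- table$counts[, keep, drop = FALSE]
  tax <- table$taxonomy
  if (!is.null(tax)) tax <- tax[match(colnames(counts), tax$asv_id), , drop = FALSE]
  asv_table(counts, depth = table$depth, taxonomy = tax)
}

#' Sample metadata for an adoption cohort
#'
#' Validates and types the per-child covariates: household identity, sex
#' (coded 1 = male, 2 = female), age in years and an age-corrected BMI Z-score.
#'
#' @param df data.frame with columns `child_id`, `home_id`, `sex`,
#'   `age_years`, `bmi_z`.
#' @return A validated data.frame (class `sample_metadata`), sorted by
#'   `child_id` (the canonical order used throughout).
#' @export
sample_metadata <- function(df) {
  df <- as.data.frame(df)
  needed <- c("child_id", "home_id", "sex", "age_years", "bmi_z")
  missing <- setdiff(needed, names(df))
  if (length(missing)) stop("metadata missing columns: ", paste(missing, collapse = ", "))
  df$child_id <- as.character(df$child_id)
  df$home_id <- as.character(df$home_id)
  if (anyDuplicated(df$child_id)) stop("duplicate child_id in metadata")
  if (anyNA(df$home_id) || any(df$home_id == "")) stop("missing home_id in metadata")
  df$sex <- as.integer(df$sex)
  if (!all(df$sex %in% c(1L, 2L))) stop("sex must be coded 1 (male) or 2 (female)")
  df$age_years <- as.numeric(df$age_years)
  if (anyNA(df$age_years) || any(df$age_years <= 0)) stop("age_years must be positive and complete")
  df$bmi_z <- as.numeric(df$bmi_z)
  if (anyNA(df$bmi_z)) stop("bmi_z must be complete")
  df <- df[order(df$child_id), needed]
  rownames(df) <- NULL
  class(df) <- c("sample_metadata", "data.frame")
  df
}

PAIRWISE_KINDS <- c("bray_curtis", "jaccard", "genetic_dissimilarity",
                    "environment_dissimilarity", "relatedness")

#' Pairwise matrix over children
#'
#' A symmetric matrix indexed by child, used for beta-diversity
#' dissimilarities, genetic dissimilarity (1 - r), binary home-environment
#' dissimilarity, and relatedness itself.
#'
#' @param values numeric square matrix; dimnames give child ids when present.
#' @param kind one of `"bray_curtis"`, `"jaccard"`, `"genetic_dissimilarity"`,
#'   `"environment_dissimilarity"`, `"relatedness"`.
#' @param child_ids character ids; default from dimnames or generated.
#' @param tol symmetry tolerance.
#' @return An object of class `pairwise_matrix`.
#' @export
pairwise_matrix <- function(values, kind, child_ids = NULL, tol = 1e-8) {
  kind <- match.arg(kind, PAIRWISE_KINDS)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("pairwise matrix must be square")
  if (is.null(child_ids)) child_ids <- rownames(values)
  if (is.null(child_ids)) child_ids <- paste0("child", seq_len(nrow(values)))
  child_ids <- as.character(child_ids)
  if (anyDuplicated(child_ids)) stop("duplicate child ids in pairwise matrix")
  asym <- abs(values - t(values))
  if (any(asym > tol)) {
    w <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf("matrix asymmetric beyond %g: worst cell (%s, %s), |M - t(M)| = %g",
                 tol, child_ids[w[1]], child_ids[w[2]], max(asym)))
  }
  values <- (values + t(values)) / 2
  dimnames(values) <- list(child_ids, child_ids)
  dissim <- kind %in% c("bray_curtis", "jaccard", "genetic_dissimilarity",
                        "environment_dissimilarity")
  if (dissim) {
    if (any(abs(diag(values)) > tol)) stop("dissimilarity matrix must have zero diagonal")
    diag(values) <- 0
    if (any(values < -tol) || any(values > 1 + tol))
      stop("dissimilarity values must lie in [0, 1]")
    values[values < 0] <- 0
    values[values > 1] <- 1
  }
  if (kind == "environment_dissimilarity") {
    off <- values[row(values) != col(values)]
    if (!all(off %in% c(0, 1)))
      stop("environment dissimilarity must be binary (same home = 0, different = 1)")
  }
  if (kind == "relatedness") {
    if (any(abs(diag(values) - 1) > 1e-6)) stop("relatedness matrix must have unit diagonal")
  }
  ord <- order(child_ids)
  structure(list(values = values[ord, ord, drop = FALSE],
                 kind = kind,
                 child_ids = child_ids[ord]),
            class = "pairwise_matrix")
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat(sprintf("pairwise_matrix (%s): %d children\n", x$kind, length(x$child_ids)))
  invisible(x)
}

#' Enumerate child pairs with relationship and rearing labels
#'
#' Classifies every unordered pair of children by relatedness band
#' (full ~ 0.5, half ~ 0.25, unrelated ~ 0) and by home co-residence, and
#' records the absolute difference of natural-log ages.
#'
#' @param metadata a [sample_metadata].
#' @param relatedness a [pairwise_matrix] of kind `"relatedness"` over the
#'   same children.
#' @return data.frame with columns `child_a`, `child_b`, `relationship`
#'   (`full`/`half`/`unrelated`), `reared` (`together`/`apart`), `age_diff_ln`.
#' @export
pair_records <- function(metadata, relatedness) {
  stopifnot(inherits(relatedness, "pairwise_matrix"),
            relatedness$kind == "relatedness")
  metadata <- sample_metadata(metadata)
  if (!identical(metadata$child_id, relatedness$child_ids))
    stop("metadata and relatedness matrix index different children")
  n <- nrow(metadata)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  r <- relatedness$values[idx]
  rel <- ifelse(r >= 0.375, "full", ifelse(r >= 0.125, "half", "unrelated"))
  same_home <- metadata$home_id[idx[, 1]] == metadata$home_id[idx[, 2]]
  data.frame(child_a = metadata$child_id[idx[, 1]],
             child_b = metadata$child_id[idx[, 2]],
             relationship = rel,
             reared = ifelse(same_home, "together", "apart"),
             age_diff_ln = abs(log(metadata$age_years[idx[, 1]]) -
                               log(metadata$age_years[idx[, 2]])),
             stringsAsFactors = FALSE)
}

#' Tabulate the pair-design census
#'
#' Counts sibling pairs by relationship x rearing, the quantity an adoption
#' design is built around (e.g. full siblings reared apart decouple genes
#' from home environment).
#'
#' @param pairs output of [pair_records()].
#' @return named integer vector with elements `full_together`, `full_apart`,
#'   `half_together`, `half_apart`, `unrelated_together`.
#' @export
pair_census <- function(pairs) {
  key <- paste(pairs$relationship, pairs$reared, sep = "_")
  out <- c(full_together = 0L, full_apart = 0L, half_together = 0L,
           half_apart = 0L, unrelated_together = 0L)
  tab <- table(key)
  for (k in names(out)) if (k %in% names(tab)) out[k] <- as.integer(tab[[k]])
  out
}
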