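#' Read an ASV count table with covariates
#'
#' Reads a delimited count table (children as rows, ASVs as columns) and its
#' sample metadata. Covariate columns embedded in the count file
#' (`home_id`, `sex`, `age_years`/`age`, `bmi_z`/`bmi`, `depth`) are split out
#' into the metadata; a `depth` column, when present, is taken as the original
#' sequencing depth, otherwise depth is recomputed as the row sum.
#'
#' @param path count table file (TSV or CSV, header row, first column =
#'   child id unless a `child_id` column is named).
#' @param metadata_path optional separate metadata file with columns
#'   `child_id`, `home_id`, `sex`, `age_years`, `bmi_z`.
#' @param taxonomy_path optional taxonomy file: either a column `lineage`
#'   with `k__;p__;c__;o__;f__;g__` strings or separate ranked columns.
#' @param transpose set `TRUE` when the file stores ASVs as rows.
#' @return list with elements `table` ([asv_table]) and `metadata`
#'   ([sample_metadata], `NULL` when no covariates are available).
#' @export
read_asv_table <- function(path, metadata_path = NULL, taxonomy_path = NULL,
                           transpose = FALSE) {
  df <- read_delimited(path)
  id_col <- if ("child_id" %in% names(df)) "child_id" else names(df)[1]
  ids <- as.character(df[[id_col]])
  if (anyDuplicated(ids)) stop("duplicate child_id in ", path)
  df[[id_col]] <- NULL
  covar_names <- c(home_id = "home_id", sex = "sex", age_years = "age_years",
                   age = "age_years", bmi_z = "bmi_z", bmi = "bmi_z",
                   depth = "depth")
  present <- intersect(names(covar_names), names(df))
  covars <- df[present]
  names(covars) <- covar_names[present]
  df <- df[setdiff(names(df), present)]
  counts <- as.matrix(df)
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad)) stop("non-numeric count column(s): ",
                        paste(names(df)[bad], collapse = ", "))
  if (any(abs(counts - round(counts)) > 1e-8)) stop("non-integer counts in ", path)
  rownames(counts) <- ids
  if (transpose) counts <- t(counts)
  depth <- if ("depth" %in% names(covars)) as.numeric(covars$depth) else NULL
  meta <- NULL
  if (!is.null(metadata_path)) {
    meta <- sample_metadata(read_delimited(metadata_path))
  } else if (all(c("home_id", "sex", "age_years", "bmi_z") %in% names(covars))) {
    meta <- sample_metadata(cbind(child_id = ids, covars[c("home_id", "sex", "age_years", "bmi_z")]))
  }
  if (!is.null(meta)) {
    missing <- setdiff(rownames(counts), meta$child_id)
    if (length(missing)) stop("children absent from metadata: ",
                              paste(utils::head(missing, 5), collapse = ", "))
  }
  taxonomy <- if (!is.null(taxonomy_path)) read_taxonomy(taxonomy_path) else NULL
  list(table = asv_table(counts, depth = depth, taxonomy = taxonomy),
       metadata = meta)
}

#' Read a taxonomy table
#'
#' Accepts either a `lineage` column holding `k__;p__;c__;o__;f__;g__`
#' strings or separate ranked columns (`kingdom` ... `genus`).
#'
#' @param path delimited file with an `asv_id` column.
#' @return data.frame with `asv_id` and the six ranks.
#' @export
read_taxonomy <- function(path) {
  df <- read_delimited(path)
  if (!"asv_id" %in% names(df)) names(df)[1] <- "asv_id"
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")
  if ("lineage" %in% names(df)) {
    parts <- strsplit(as.character(df$lineage), ";", fixed = TRUE)
    mat <- t(vapply(parts, function(p) {
      p <- sub("^\\s*[kpcofg]__", "", trimws(p))
      length(p) <- 6
      p
    }, character(6)))
    colnames(mat) <- ranks
    df <- cbind(df["asv_id"], as.data.frame(mat, stringsAsFactors = FALSE))
  }
  missing <- setdiff(ranks, names(df))
  for (r in missing) df[[r]] <- NA_character_
  df[c("asv_id", ranks)]
}

# Delimiter-sniffing reader for TSV/CSV with a header row.
read_delimited <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
}

#' Read a square pairwise matrix
#'
#' Reads the whitespace- or comma-delimited square-matrix dialect used for
#' supplementary dissimilarity/relatedness matrices. A header row and a
#' row-label column are auto-detected (the block is treated as labelled when
#' its first cell is non-numeric). Symmetry is validated to `tol`.
#'
#' @param path matrix file.
#' @param kind the semantic kind to stamp on the result (see
#'   [pairwise_matrix()]); the file itself carries no kind.
#' @param tol symmetry tolerance (default 1e-8).
#' @return A [pairwise_matrix].
#' @export
read_square_matrix <- function(path, kind, tol = 1e-8) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty matrix file: ", path)
  split_row <- function(l) {
    l <- trimws(l)
    if (grepl(",", l)) strsplit(l, "\\s*,\\s*")[[1]] else strsplit(l, "\\s+")[[1]]
  }
  cells <- lapply(lines, split_row)
  is_num <- function(x) !is.na(suppressWarnings(as.numeric(x)))
  has_header <- !all(vapply(cells[[1]], is_num, logical(1)))
  body <- if (has_header) cells[-1] else cells
  if (!length(body)) stop("matrix file has a header but no rows: ", path)
  has_labels <- !is_num(body[[1]][1])
  labels <- NULL
  if (has_labels) {
    labels <- vapply(body, `[`, character(1), 1)
    body <- lapply(body, `[`, -1)
  } else if (has_header) {
    # no row-label column: take ids from the header (drop a stub cell if the
    # header is one longer than the data rows)
    header <- cells[[1]]
    if (length(header) == length(body[[1]]) + 1) header <- header[-1]
    if (length(header) == length(body[[1]])) labels <- header
  }
  ncols <- unique(lengths(body))
  if (length(ncols) != 1) stop("ragged rows in matrix file: ", path)
  m <- do.call(rbind, lapply(body, as.numeric))
  if (anyNA(m)) stop("non-numeric cell in matrix file: ", path)
  if (nrow(m) != ncol(m)) stop(sprintf("matrix in %s is not square (%d x %d)",
                                       path, nrow(m), ncol(m)))
  if (!is.null(labels) && length(labels) != nrow(m)) labels <- NULL
  pairwise_matrix(m, kind = kind, child_ids = labels, tol = tol)
}

#' Write a square pairwise matrix
#'
#' Serialises a [pairwise_matrix] in the tab-delimited labelled dialect that
#' [read_square_matrix()] reads back; values carry 12 significant digits so
#' the round trip is lossless at that precision.
#'
#' @param matrix a [pairwise_matrix].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_square_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "pairwise_matrix"))
  v <- matrix$values
  ids <- matrix$child_ids
  fmt <- function(x) formatC(x, digits = 12, format = "g")
  lines <- c(paste(c("id", ids), collapse = "\t"),
             vapply(seq_along(ids), function(i)
               paste(c(ids[i], fmt(v[i, ])), collapse = "\t"), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Write an ASV table (counts plus covariates) to a delimited file
#'
#' @param table an [asv_table].
#' @param metadata optional [sample_metadata] merged in as covariate columns.
#' @param path output file (TSV).
#' @return `path`, invisibly.
#' @export
write_asv_table <- function(table, path, metadata = NULL) {
  stopifnot(inherits(table, "asv_table"))
  df <- data.frame(child_id = table$child_ids, stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    metadata <- sample_metadata(metadata)
    if (!identical(metadata$child_id, table$child_ids))
      stop("metadata children do not match table children")
    df <- cbind(df, metadata[c("home_id", "sex", "age_years", "bmi_z")])
  }
  df$depth <- table$depth
  df <- cbind(df, as.data.frame(table$counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
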