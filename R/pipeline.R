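#' Assemble and validate a pipeline run configuration
#'
#' A run configuration points at inputs (count table + metadata +
#' relatedness matrix, or a synthetic-cohort block), sets the stage
#' parameters and a mandatory master seed, and names an output directory.
#' Accepts a YAML file path or a list.
#'
#' @param config list or path to a YAML file. Recognised fields:
#'   `inputs` (list: `counts`, `metadata`, `relatedness`, `taxonomy`) or
#'   `simulate` (list: `n_asvs`, plus any [simulate_counts()] /
#'   [design_config()] arguments), `min_reads`, `gdm` (list: `n_perm`),
#'   `varcomp` (list: `n_perm`, `q_threshold`, `magnitude`),
#'   `patterns` (list: `n_perm`), `seed`, `outdir`.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("a seed is mandatory")
  if (is.null(config$outdir)) stop("an output directory is required")
  if (is.null(config$inputs) && is.null(config$simulate))
    stop("either 'inputs' or 'simulate' must be given")
  if (!is.null(config$inputs)) {
    for (f in c("counts", "relatedness")) {
      if (is.null(config$inputs[[f]])) stop("inputs$", f, " is required")
      if (!file.exists(config$inputs[[f]]))
        stop("input file not found: ", config$inputs[[f]])
    }
  }
  defaults <- list(min_reads = 5,
                   gdm = list(n_perm = 999),
                   varcomp = list(n_perm = 499, q_threshold = 0.05,
                                  magnitude = 0.05),
                   patterns = list(n_perm = 9999))
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
    else if (is.list(defaults[[nm]]))
      for (k in names(defaults[[nm]]))
        if (is.null(config[[nm]][[k]])) config[[nm]][[k]] <- defaults[[nm]][[k]]
  }
  structure(config, class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

journal_path <- function(outdir) file.path(outdir, "journal.tsv")

journal_done <- function(outdir, hash) {
  jp <- journal_path(outdir)
  if (!file.exists(jp)) return(character(0))
  j <- utils::read.table(jp, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  j$stage[j$config_hash == hash]
}

journal_mark <- function(outdir, hash, stage) {
  jp <- journal_path(outdir)
  row <- data.frame(stage = stage, config_hash = hash,
                    time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  utils::write.table(row, jp, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = !file.exists(jp), append = file.exists(jp))
}

#' Run the full analysis pipeline
#'
#' Executes prep (load or simulate, filter), dissimilarity, GDM, variance
#' components and pattern tests in order, journaling per-stage completion
#' so an interrupted run resumes (a changed configuration invalidates the
#' journal via its hash). Every stage's randomness derives from the master
#' seed through a named sub-stream, so adding a stage never shifts another
#' stage's stream. Writes: the two dissimilarity matrices, a GDM model
#' table, the variance-component table, the pattern-test report and a run
#' manifest.
#'
#' @param config a [run_config()] (or list / YAML path accepted by it).
#' @param resume reuse journaled stages (default TRUE).
#' @return invisible list of per-stage results.
#' @export
run_pipeline <- function(config, resume = TRUE) {
  config <- run_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  done <- if (resume) journal_done(outdir, hash) else character(0)
  state <- list()

  # --- prep ------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    design <- simulate_design(
      do.call(design_config, sim_args[intersect(names(sim_args),
        names(formals(design_config)))]),
      seed = derive_seed(config$seed, "design"))
    count_args <- sim_args[intersect(names(sim_args),
      setdiff(names(formals(simulate_counts)), c("design", "seed")))]
    sim <- do.call(simulate_counts,
                   c(list(design = design,
                          seed = derive_seed(config$seed, "counts")),
                     count_args))
    state$table_raw <- sim$table
    state$metadata <- design$metadata
    state$K <- design$K_true
    state$truth <- sim$params
  } else {
    loaded <- read_asv_table(config$inputs$counts,
                             metadata_path = config$inputs$metadata,
                             taxonomy_path = config$inputs$taxonomy)
    state$table_raw <- loaded$table
    state$metadata <- loaded$metadata
    state$K <- read_square_matrix(config$inputs$relatedness, kind = "relatedness")
  }
  state$table <- filter_low_count(state$table_raw, config$min_reads)
  state$table_testable <- drop_singletons(state$table)

  # --- dissimilarity ---------------------------------------------------
  state$bray <- bray_curtis(state$table)
  state$jaccard <- jaccard(state$table)
  write_square_matrix(state$bray, file.path(outdir, "bray_curtis.txt"))
  write_square_matrix(state$jaccard, file.path(outdir, "jaccard.txt"))

  # --- gdm -------------------------------------------------------------
  if (!"gdm" %in% done) {
    md <- state$metadata
    env <- outer(md$home_id, md$home_id, function(a, b) as.numeric(a != b))
    dimnames(env) <- list(md$child_id, md$child_id)
    gen <- 1 - state$K$values
    diag(gen) <- 0
    gen[gen < 0] <- 0
    rows <- list()
    for (metric in c("bray_curtis", "jaccard")) {
      dis <- if (metric == "bray_curtis") state$bray else state$jaccard
      pairs <- build_site_pairs(
        dis,
        site_covars = data.frame(child_id = md$child_id,
                                 ln_age = log(md$age_years),
                                 sex = md$sex, bmi_z = md$bmi_z),
        matrix_predictors = list(
          genetic = pairwise_matrix(gen, "genetic_dissimilarity"),
          environment = pairwise_matrix(env, "environment_dissimilarity")))
      sel <- backward_select(pairs, n_perm = config$gdm$n_perm,
                             seed = derive_seed(config$seed,
                                                paste0("gdm_", metric)))
      if (!is.null(sel$model)) {
        imp <- sel$importance
        rows[[metric]] <- data.frame(
          metric = metric,
          total_pct_deviance_explained = sel$model$deviance_explained,
          overall_p = sel$overall_p,
          predictor = imp$predictor,
          pct_of_explained = imp$pct_of_explained,
          permutation_p = imp$permutation_p,
          stringsAsFactors = FALSE)
      }
    }
    state$gdm <- if (length(rows)) do.call(rbind, rows) else
      data.frame(metric = character(0),
                 total_pct_deviance_explained = numeric(0),
                 overall_p = numeric(0), predictor = character(0),
                 pct_of_explained = numeric(0), permutation_p = numeric(0),
                 stringsAsFactors = FALSE)
    rownames(state$gdm) <- NULL
    utils::write.table(state$gdm, file.path(outdir, "gdm_models.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    journal_mark(outdir, hash, "gdm")
  } else {
    state$gdm <- utils::read.table(file.path(outdir, "gdm_models.tsv"),
                                   header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE)
  }

  # --- variance components --------------------------------------------
  if (!"varcomp" %in% done) {
    state$varcomp <- run_all_asvs(
      state$table_testable, state$metadata, state$K$values,
      n_perm = config$varcomp$n_perm,
      seed = derive_seed(config$seed, "varcomp"),
      q_threshold = config$varcomp$q_threshold,
      magnitude = config$varcomp$magnitude,
      journal = file.path(outdir, "varcomp_journal.tsv"))
    utils::write.table(state$varcomp, file.path(outdir, "varcomp.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    journal_mark(outdir, hash, "varcomp")
  } else {
    state$varcomp <- utils::read.table(file.path(outdir, "varcomp.tsv"),
                                       header = TRUE, sep = "\t",
                                       stringsAsFactors = FALSE)
  }

  # --- patterns --------------------------------------------------------
  tally <- tally_components(state$varcomp)
  chi <- tryCatch(chi_square_pattern(tally), error = function(e) NULL)
  enr <- NULL
  tax <- state$table_testable$taxonomy
  if (!is.null(tax) && !anyNA(tax$order)) {
    pool <- state$table_testable$asv_ids
    enr <- lapply(c("abundance", "presence"), function(mt) {
      sig <- unique(state$varcomp$asv_id[state$varcomp$model_type == mt &
                                           state$varcomp$significant])
      if (!length(sig)) return(NULL)
      cbind(model_type = mt,
            order_enrichment(sig, pool, tax,
                             n_perm = config$patterns$n_perm,
                             seed = derive_seed(config$seed,
                                                paste0("enrich_", mt))))
    })
    enr <- do.call(rbind, enr)
  }
  state$patterns <- list(tally = tally, chi_square = chi, enrichment = enr)
  pattern_report <- c(
    "# pattern tests",
    "## significant component tally (rows: model type; cols: genetic, environment)",
    utils::capture.output(print(tally)),
    if (!is.null(chi)) sprintf("chi_square = %.4f  df = %d  p = %.4g",
                               chi$statistic, chi$df, chi$p)
    else "chi-square not computable (zero marginal)",
    "## order enrichment",
    if (!is.null(enr)) utils::capture.output(print(enr, row.names = FALSE))
    else "(no significant ASVs)")
  writeLines(pattern_report, file.path(outdir, "patterns.txt"))
  if (!is.null(enr))
    utils::write.table(enr, file.path(outdir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(package_version = as.character(utils::packageVersion("kinhome")),
                   r_version = R.version.string,
                   seed = config$seed,
                   config_hash = hash,
                   n_children = length(state$table$child_ids),
                   n_asvs_raw = length(state$table_raw$asv_ids),
                   n_asvs_filtered = length(state$table$asv_ids),
                   n_asvs_testable = length(state$table_testable$asv_ids))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(outdir, "manifest.json"))
  invisible(state)
}
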