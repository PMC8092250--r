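#!/usr/bin/env Rscript
# Community-level variance partitioning: ASV filtering, Bray-Curtis and
# Jaccard beta diversity, and the generalized dissimilarity model of
# pairwise community dissimilarity on ln-age difference, genetic
# dissimilarity (1 - r) and the binary home indicator, with permutation
# importance and backward selection.
#
# Reads results/cohort/; writes results/community/.

suppressPackageStartupMessages(library(kinhome))

seed <- 20240902
dir.create("results/community", recursive = TRUE, showWarnings = FALSE)

loaded <- read_asv_table("results/cohort/asv_counts.tsv")
tab_raw <- loaded$table
md <- loaded$metadata
K <- read_square_matrix("results/cohort/relatedness_true.txt", "relatedness")

tab <- filter_low_count(tab_raw, min_reads = 5)
prev <- prevalence_summary(tab_raw, md)
cat(sprintf("ASVs: %d total; %d single-sample; %d single-home; %d after <5-read filter; %d testable\n",
            nrow(prev), sum(prev$n_children == 1), sum(prev$n_homes == 1),
            length(tab$asv_ids), length(drop_singletons(tab)$asv_ids)))

env <- outer(md$home_id, md$home_id, function(a, b) as.numeric(a != b))
dimnames(env) <- list(md$child_id, md$child_id)
gen <- 1 - K$values; diag(gen) <- 0; gen[gen < 0] <- 0

rows <- list()
for (metric in c("bray_curtis", "jaccard")) {
  dis <- if (metric == "bray_curtis") bray_curtis(tab) else jaccard(tab)
  write_square_matrix(dis, file.path("results/community",
                                     paste0(metric, ".txt")))
  sp <- build_site_pairs(
    dis,
    site_covars = data.frame(child_id = md$child_id,
                             ln_age = log(md$age_years),
                             sex = md$sex, bmi_z = md$bmi_z),
    matrix_predictors = list(
      genetic = pairwise_matrix(gen, "genetic_dissimilarity"),
      environment = pairwise_matrix(env, "environment_dissimilarity")))
  sel <- backward_select(sp, n_perm = 199,
                         seed = derive_seed(seed, metric))
  if (is.null(sel$model)) {
    cat(metric, ": no predictor survived selection\n")
    next
  }
  cat(sprintf("%s: %.2f%% deviance explained (overall p = %.3f); dropped: %s\n",
              metric, sel$model$deviance_explained, sel$overall_p,
              if (length(sel$dropped)) paste(sel$dropped, collapse = ", ")
              else "none"))
  print(sel$importance, row.names = FALSE)
  rows[[metric]] <- cbind(metric = metric,
                          total_pct = sel$model$deviance_explained,
                          overall_p = sel$overall_p,
                          sel$importance)
}
gdm_tab <- do.call(rbind, rows)
utils::write.table(gdm_tab, "results/community/gdm_models.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("community tables written to results/community/\n")
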