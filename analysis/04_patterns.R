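#!/usr/bin/env Rscript
# Broad-scale patterns over the variance-component results: the 2x2
# chi-square test of whether abundance and presence are differentially
# explained by genetics vs home environment, and the taxonomic-order
# enrichment test by resampling from the testable pool.
#
# Reads results/cohort/ and results/varcomp/; writes results/patterns/.

suppressPackageStartupMessages(library(kinhome))

seed <- 20240904
dir.create("results/patterns", recursive = TRUE, showWarnings = FALSE)

res <- utils::read.table("results/varcomp/varcomp.tsv", header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE)
loaded <- read_asv_table("results/cohort/asv_counts.tsv",
                         taxonomy_path = "results/cohort/taxonomy.tsv")
tab <- drop_singletons(filter_low_count(loaded$table, min_reads = 5))

tally <- tally_components(res)
cat("significant component tally:\n"); print(tally)
if (all(rowSums(tally) > 0) && all(colSums(tally) > 0)) {
  chi <- chi_square_pattern(tally)
  cat(sprintf("chi-square = %.3f, df = %d, p = %.3g\n",
              chi$statistic, chi$df, chi$p))
} else {
  cat("chi-square not computable (a zero marginal)\n")
}

enr_all <- list()
for (mt in c("abundance", "presence")) {
  sig <- unique(res$asv_id[res$model_type == mt & res$significant])
  if (length(sig) < 2) { cat(mt, ": too few significant ASVs\n"); next }
  enr <- order_enrichment(sig, tab$asv_ids, tab$taxonomy, n_perm = 9999,
                          seed = derive_seed(seed, mt))
  cat("\norder enrichment,", mt, "models:\n")
  print(enr, row.names = FALSE)
  enr_all[[mt]] <- cbind(model_type = mt, enr)
}
if (length(enr_all))
  utils::write.table(do.call(rbind, enr_all),
                     "results/patterns/enrichment.tsv",
                     sep = "\t", quote = FALSE, row.names = FALSE)
cat("pattern results written to results/patterns/\n")
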