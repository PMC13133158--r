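#!/usr/bin/env Rscript

# Stage 3 -- gene-set efficacy by ordinal stage prediction.
#
# Within each predicted TDP-43 stratum, fits the L2-penalised
# cumulative-logit stage model on each gene set (the planted stage
# signature and random decoys), evaluates it by age-matched leave-pair-out
# cross-validation, and compares every AUC against 100 size-matched random
# background sets. Empirical p-values are BH-adjusted across the whole
# (set x stratum) family.

library(driadce)

seed <- 1L
dat <- "results/data"
expr <- read_expression(file.path(dat, "expression.tsv"))
meta <- read_metadata(file.path(dat, "metadata.tsv"))
sets <- read_gmt(file.path(dat, "gene_sets.gmt"))
strat <- read.delim("results/stratification.tsv")
status <- setNames(strat$status, strat$sample_id)

cat(sprintf("Evaluating %d gene sets in 2 strata against 100 random backgrounds each\n",
            length(sets)))
t0 <- proc.time()
res <- suppressWarnings(run_driad_sp(expr, meta, sets, status = status,
                                     n_background = 100, lambda = 1,
                                     seed = seed + 10L))
cat(sprintf("Done in %.0f s\n\n", (proc.time() - t0)[3]))

print(res[, c("drug", "stratum", "auc", "effective_size", "n_pairs", "p",
              "padj")], row.names = FALSE)
cat("\nThe planted stage signature should stand out against the random decoys\n")
cat("in both strata (the default conditions plant the signal cohort-wide).\n")

write.table(as.data.frame(res), "results/efficacy.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
bg <- attr(res, "backgrounds")
bg_df <- data.frame(
  key = rep(names(bg), lengths(bg)),
  auc = unlist(bg, use.names = FALSE))
write.table(bg_df, "results/efficacy_backgrounds.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Wrote results/efficacy.tsv and results/efficacy_backgrounds.tsv\n")
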