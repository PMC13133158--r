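#!/usr/bin/env Rscript

# Stage 1 -- simulate the study inputs.
#
# Generates the synthetic AD cohort (expression, metadata, cryptic-exon
# abundances) and the pooled CRISPR screen under the default study
# conditions, and writes them as plain-text tables under results/data/.
# Every downstream stage reads these files back through the package's own
# readers, so the whole analysis can be audited from disk.

library(driadce)

seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- cohort_config(seed = seed)
cat(sprintf("Simulating cohort: %d samples, %d genes, %d stage genes (effect %.2f log2/stage), %d ISGs (effect %.2f)\n",
            cfg$n_samples, cfg$n_genes, cfg$n_stage_genes, cfg$stage_effect,
            cfg$n_isg, cfg$isg_effect))
co <- generate_cohort(cfg)
write_expression(co$expr, file.path(out, "expression.tsv"))
write.table(co$meta, file.path(out, "metadata.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(co$ce, file.path(out, "ce_abundances.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(
  data.frame(gene = c(co$truth$stage_genes, co$truth$isg_genes),
             role = rep(c("stage", "isg"),
                        c(length(co$truth$stage_genes),
                          length(co$truth$isg_genes)))),
  file.path(out, "ground_truth_genes.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
write.table(
  data.frame(sample_id = names(co$truth$tdp43_status),
             latent_tdp43 = unname(co$truth$tdp43_status)),
  file.path(out, "ground_truth_status.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)

sets <- generate_gene_sets(co$truth, rownames(co$expr), n_random = 3,
                           sizes = length(co$truth$stage_genes), seed = seed)
write_gmt(sets, file.path(out, "gene_sets.gmt"))

scfg <- screen_config(seed = seed)
cat(sprintf("Simulating screen: %d genes x %d sgRNA + %d controls, %d replicates, %d rescue / %d essential genes planted\n",
            scfg$n_genes, scfg$sgrnas_per_gene, scfg$n_controls,
            scfg$n_replicates, scfg$n_rescue, scfg$n_depletion))
sc <- generate_screen(scfg)
write_screen_counts(sc, file.path(out, "screen_counts.tsv"))
write.table(
  data.frame(gene = c(sc$truth$rescue_genes, sc$truth$depletion_genes),
             role = rep(c("rescue", "essential"),
                        c(length(sc$truth$rescue_genes),
                          length(sc$truth$depletion_genes)))),
  file.path(out, "ground_truth_screen.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)

write_ce_bed(build_ce_annotation(), file.path(out, "ce_annotation.bed"))
cat("Wrote study inputs to", out, "\n")
cat(sprintf("Cohort diagnosis split: %s\n",
            paste(names(table(co$meta$diagnosis)), table(co$meta$diagnosis),
                  sep = "=", collapse = ", ")))
cat(sprintf("Latent TDP-43-positive samples: %d of %d\n",
            sum(co$truth$tdp43_status), cfg$n_samples))
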