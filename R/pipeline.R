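#' Run the full analysis end to end on synthetic data
#'
#' Demonstration driver wiring every stage together: generates a synthetic
#' cohort and screen, stratifies samples by cryptic-exon status, evaluates
#' the informative gene set against random backgrounds per stratum, tests
#' ISG enrichment by status, scores the rescue screen, and writes every
#' result as TSV (plus the CE annotation as BED and a run manifest) into
#' `output_dir`. All outputs re-parse through the package's own readers,
#' and the same config and seed reproduce identical files.
#'
#' @param output_dir Directory to create/write into.
#' @param seed Master seed.
#' @param config A [cohort_config()]; defaults to the standard synthetic
#'   conditions with the given seed.
#' @param screen_cfg A [screen_config()]; defaults likewise.
#' @param n_background Random background sets per gene set (reduce for
#'   quick runs).
#' @param n_perm Permutations for the enrichment null.
#' @param lambda Ridge penalty.
#' @return Invisibly, a list with the in-memory results (`stratification`,
#'   `efficacy`, `isg`, `screen_hits`, `dropout`, `paths`).
#' @export
run_demo <- function(output_dir, seed = 1L, config = NULL,
                     screen_cfg = NULL, n_background = 50L, n_perm = 500L,
                     lambda = 1) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(output_dir, f)
  if (is.null(config)) config <- cohort_config(seed = seed)
  if (is.null(screen_cfg)) screen_cfg <- screen_config(seed = seed)

  co <- generate_cohort(config)
  write_expression(co$expr, p("expression.tsv"))
  utils::write.table(co$meta, p("metadata.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(co$ce, p("ce_abundances.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_ce_bed(build_ce_annotation(), p("ce_annotation.bed"))

  calls <- call_ce_presence(read_ce_table(p("ce_abundances.tsv")))
  strat <- classify_tdp43_status(calls)
  utils::write.table(
    data.frame(sample_id = co$ce$sample_id, n_present = strat$n_present,
               status = as.character(strat$status)),
    p("stratification.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  sets <- generate_gene_sets(co$truth, rownames(co$expr), n_random = 2L,
                             sizes = length(co$truth$stage_genes),
                             seed = child_seed(seed, 21L))
  write_gmt(sets, p("gene_sets.gmt"))
  status <- stats::setNames(as.character(strat$status), co$ce$sample_id)
  eff <- run_driad_sp(read_expression(p("expression.tsv")),
                      read_metadata(p("metadata.tsv")),
                      read_gmt(p("gene_sets.gmt")), status = status,
                      n_background = n_background, lambda = lambda,
                      seed = child_seed(seed, 22L))
  utils::write.table(as.data.frame(eff), p("efficacy.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  isg <- isg_by_status(co$expr, co$truth$isg_genes, status,
                       n_perm = n_perm, seed = child_seed(seed, 23L))
  utils::write.table(
    data.frame(set = "ISG", es = isg$enrichment$es, nes = isg$enrichment$nes,
               p = isg$enrichment$p, n_hits = isg$enrichment$n_hits),
    p("isg_enrichment.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  sc <- generate_screen(screen_cfg)
  write_screen_counts(sc, p("screen_counts.tsv"))
  sc2 <- read_screen_counts(p("screen_counts.tsv"))
  reps <- seq_len(screen_cfg$n_replicates)
  hits <- score_screen(sc2, paste0("treatment_", reps),
                       paste0("control_", reps))
  utils::write.table(hits, p("screen_results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  dropout <- differentiation_dropout(sc2, paste0("control_", reps),
                                     "initial_1")
  utils::write.table(dropout, p("differentiation_dropout.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  manifest <- data.frame(
    key = c("package_version", "seed", "n_samples", "n_genes",
            "n_background", "n_perm", "lambda", "screen_n_genes"),
    value = c(as.character(utils::packageVersion("driadce")), seed,
              config$n_samples, config$n_genes, n_background, n_perm,
              lambda, screen_cfg$n_genes))
  utils::write.table(manifest, p("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  invisible(list(stratification = strat, efficacy = eff, isg = isg,
                 screen_hits = hits, dropout = dropout,
                 paths = vapply(list.files(output_dir), p, character(1))))
}
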