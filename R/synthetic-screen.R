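#' Configuration for the synthetic pooled CRISPR screen generator
#'
#' Emulates a genome-scale rescue screen: a library with a fixed number of
#' sgRNAs per gene plus non-targeting control guides, sequenced as
#' negative-binomial counts in three arms (initial library, lipofectamine
#' control, treatment), with planted rescue genes whose guides survive the
#' treatment and planted differentiation-essential genes whose guides drop
#' out of both post-differentiation arms.
#'
#' @param n_genes Number of targeted genes.
#' @param sgrnas_per_gene Guides per gene (library design: 4).
#' @param n_controls Number of non-targeting control sgRNAs (1000).
#' @param n_replicates Replicates per post-differentiation arm (3; the
#'   initial library is a single replicate).
#' @param baseline_dispersion Negative-binomial dispersion (0 switches to
#'   Poisson counts).
#' @param rescue_effect Multiplicative survival factor for rescue-gene
#'   guides in the treatment arm.
#' @param depletion_effect Factor by which differentiation-essential
#'   guides are depleted in both post-differentiation arms.
#' @param n_rescue Number of planted rescue genes.
#' @param n_depletion Number of planted differentiation-essential genes.
#' @param mean_reads Mean sequencing depth per sgRNA.
#' @param seed Master seed.
#' @return A validated list of class `screen_config`.
#' @export
screen_config <- function(n_genes = 1000L, sgrnas_per_gene = 4L,
                          n_controls = 1000L, n_replicates = 3L,
                          baseline_dispersion = 0.2, rescue_effect = 8,
                          depletion_effect = 8, n_rescue = 10L,
                          n_depletion = 8L, mean_reads = 500, seed = 1L) {
  assert_count(n_genes, "n_genes")
  assert_count(sgrnas_per_gene, "sgrnas_per_gene")
  assert_count(n_controls, "n_controls")
  assert_count(n_replicates, "n_replicates")
  assert_finite_scalar(baseline_dispersion, "baseline_dispersion")
  if (baseline_dispersion < 0) stop("'baseline_dispersion' must be >= 0")
  assert_finite_scalar(rescue_effect, "rescue_effect")
  assert_finite_scalar(depletion_effect, "depletion_effect")
  if (rescue_effect <= 0 || depletion_effect <= 0) {
    stop("effects must be positive")
  }
  if (n_rescue < 0 || n_depletion < 0 || n_rescue + n_depletion > n_genes) {
    stop("planted gene counts must be non-negative and sum to at most n_genes")
  }
  assert_finite_scalar(mean_reads, "mean_reads")
  if (mean_reads <= 0) stop("'mean_reads' must be positive")
  assert_finite_scalar(seed, "seed")
  structure(list(n_genes = as.integer(n_genes),
                 sgrnas_per_gene = as.integer(sgrnas_per_gene),
                 n_controls = as.integer(n_controls),
                 n_replicates = as.integer(n_replicates),
                 baseline_dispersion = baseline_dispersion,
                 rescue_effect = rescue_effect,
                 depletion_effect = depletion_effect,
                 n_rescue = as.integer(n_rescue),
                 n_depletion = as.integer(n_depletion),
                 mean_reads = mean_reads,
                 seed = as.integer(seed)), class = "screen_config")
}

#' Generate a synthetic pooled CRISPR screen count table
#'
#' Per-sgRNA baseline abundances are drawn once from a lognormal around
#' `mean_reads` (library composition is shared across arms, so fold
#' changes are paired within sgRNA). Counts in every arm are negative-
#' binomial around the arm-specific expected abundance: rescue-gene
#' guides are multiplied by `rescue_effect` in the treatment arm;
#' differentiation-essential guides are divided by `depletion_effect` in
#' both the control and treatment arms (they drop out before either
#' exposure); control sgRNAs are unaffected everywhere.
#'
#' @param config A [screen_config()].
#' @return A list: `counts` (sgRNA x column integer matrix with columns
#'   `initial_1`, `control_1..r`, `treatment_1..r`), `guide_map`
#'   (data.frame `sgrna`, `gene`; controls have gene `"control"`), and
#'   `truth` (list `rescue_genes`, `depletion_genes`).
#' @export
generate_screen <- function(config) {
  stopifnot(inherits(config, "screen_config"))
  genes <- sprintf("geneS%04d", seq_len(config$n_genes))
  sg_gene <- rep(genes, each = config$sgrnas_per_gene)
  sgrna <- c(paste0(sg_gene, "_sg", seq_len(config$sgrnas_per_gene)),
             sprintf("control_%04d", seq_len(config$n_controls)))
  sg_gene <- c(sg_gene, rep("control", config$n_controls))
  n_sg <- length(sgrna)

  truth <- with_seed(child_seed(config$seed, 1L), {
    planted <- sample(genes, config$n_rescue + config$n_depletion)
    list(rescue_genes = sort(planted[seq_len(config$n_rescue)]),
         depletion_genes = sort(planted[config$n_rescue +
                                          seq_len(config$n_depletion)]))
  })

  base <- with_seed(child_seed(config$seed, 2L), {
    stats::rlnorm(n_sg, log(config$mean_reads), 0.5)
  })

  is_rescue <- sg_gene %in% truth$rescue_genes
  is_depl <- sg_gene %in% truth$depletion_genes
  mu_initial <- base
  mu_control <- base * ifelse(is_depl, 1 / config$depletion_effect, 1)
  mu_treat <- mu_control * ifelse(is_rescue, config$rescue_effect, 1)

  draw <- function(mu) {
    if (config$baseline_dispersion == 0) {
      stats::rpois(length(mu), mu)
    } else {
      stats::rnbinom(length(mu), size = 1 / config$baseline_dispersion,
                     mu = mu)
    }
  }
  counts <- with_seed(child_seed(config$seed, 3L), {
    cols <- list(initial_1 = draw(mu_initial))
    for (r in seq_len(config$n_replicates)) {
      cols[[paste0("control_", r)]] <- draw(mu_control)
    }
    for (r in seq_len(config$n_replicates)) {
      cols[[paste0("treatment_", r)]] <- draw(mu_treat)
    }
    do.call(cbind, cols)
  })
  storage.mode(counts) <- "integer"
  rownames(counts) <- sgrna
  list(counts = counts,
       guide_map = data.frame(sgrna = sgrna, gene = sg_gene,
                              stringsAsFactors = FALSE),
       truth = truth)
}
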