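#' Configuration for the synthetic expression cohort generator
#'
#' Defines the study conditions the generator emulates: a bulk-RNA-seq
#' cohort with Braak stages weakly correlated with age, a latent TDP-43
#' pathology status among AD cases, zero-inflated cryptic-exon (CE)
#' transcript abundances whose presence covaries within patients through
#' that latent status, stage-informative genes whose expression shifts
#' monotonically with Braak stage, and interferon-stimulated genes (ISGs)
#' upregulated only in latent-positive AD samples.
#'
#' @param n_samples Number of patient samples.
#' @param n_genes Size of the gene universe.
#' @param n_stage_genes Number of genes whose log2 expression shifts by
#'   `stage_effect` per Braak-stage step.
#' @param stage_effect Log2-units per stage step for stage genes.
#' @param n_isg Number of interferon-stimulated genes.
#' @param isg_effect Log2-units added to ISGs in latent TDP-43-positive AD
#'   samples.
#' @param ce_expression_prob_positive,ce_expression_prob_negative
#'   Probability that each CE transcript is expressed given latent TDP-43
#'   status.
#' @param ce_lognormal_mu,ce_lognormal_sigma Log-scale parameters of the
#'   expressed-CE abundance distribution (TPM).
#' @param age_stage_slope Years of age per Braak-stage step.
#' @param noise_sd Residual log2 noise standard deviation.
#' @param tdp43_prevalence Latent TDP-43-positive fraction among AD
#'   samples (controls are always negative).
#' @param stage_signal_scope `"all"` plants the stage signal in every
#'   sample; `"ce_positive"` restricts it to latent TDP-43-positive
#'   samples (used to emulate a stratum-specific efficacy signal).
#' @param seed Master seed; all randomness flows from it through
#'   independent child streams per component.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 300L, n_genes = 2000L,
                          n_stage_genes = 20L, stage_effect = 0.5,
                          n_isg = 50L, isg_effect = 1,
                          ce_expression_prob_positive = 0.8,
                          ce_expression_prob_negative = 0.2,
                          ce_lognormal_mu = log(5), ce_lognormal_sigma = 1,
                          age_stage_slope = 2, noise_sd = 1,
                          tdp43_prevalence = 0.37,
                          stage_signal_scope = c("all", "ce_positive"),
                          seed = 1L) {
  assert_count(n_samples, "n_samples")
  assert_count(n_genes, "n_genes")
  assert_count(n_stage_genes, "n_stage_genes")
  assert_count(n_isg, "n_isg")
  if (n_stage_genes + n_isg > n_genes) {
    stop("n_stage_genes + n_isg must not exceed n_genes")
  }
  assert_finite_scalar(stage_effect, "stage_effect")
  assert_finite_scalar(isg_effect, "isg_effect")
  assert_prob(ce_expression_prob_positive, "ce_expression_prob_positive")
  assert_prob(ce_expression_prob_negative, "ce_expression_prob_negative")
  assert_finite_scalar(ce_lognormal_mu, "ce_lognormal_mu")
  assert_finite_scalar(ce_lognormal_sigma, "ce_lognormal_sigma")
  if (ce_lognormal_sigma <= 0) stop("'ce_lognormal_sigma' must be positive")
  assert_finite_scalar(age_stage_slope, "age_stage_slope")
  assert_finite_scalar(noise_sd, "noise_sd")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  assert_prob(tdp43_prevalence, "tdp43_prevalence")
  stage_signal_scope <- match.arg(stage_signal_scope)
  assert_finite_scalar(seed, "seed")
  structure(list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    n_stage_genes = as.integer(n_stage_genes), stage_effect = stage_effect,
    n_isg = as.integer(n_isg), isg_effect = isg_effect,
    ce_expression_prob_positive = ce_expression_prob_positive,
    ce_expression_prob_negative = ce_expression_prob_negative,
    ce_lognormal_mu = ce_lognormal_mu,
    ce_lognormal_sigma = ce_lognormal_sigma,
    age_stage_slope = age_stage_slope, noise_sd = noise_sd,
    tdp43_prevalence = tdp43_prevalence,
    stage_signal_scope = stage_signal_scope,
    seed = as.integer(seed)), class = "cohort_config")
}

#' Generate a synthetic expression cohort with planted structure
#'
#' Draws a genes x samples TPM matrix, per-sample metadata (Braak stage
#' 1-6, age, diagnosis), zero-inflated CE transcript abundances for
#' STMN2-short / UNC13A-CE1 / UNC13A-CE2, and the ground truth used by
#' tests (latent TDP-43 status, stage-gene and ISG identities).
#'
#' Expression model: per-gene baselines drawn once per cohort from
#' N(3, 2) on the log2 scale; the observed log2 value adds the planted
#' stage/ISG shifts and N(0, `noise_sd`) noise; TPM = 2^log2 without
#' per-sample renormalisation (downstream methods standardise features, so
#' renormalisation would only couple genes). Ages are
#' N(60 + slope x (stage - 1), 8) clamped to \[40, 100\]. Diagnosis is AD
#' with probability plogis(stage - 3), coupling diagnosis weakly to stage.
#' Absent CE transcripts are exact zeros with probability 0.8 and
#' sub-threshold noise Uniform(0, 0.5 x threshold) otherwise, so abundance
#' histograms retain a non-trivial low peak for the valley finder.
#'
#' All randomness derives from `config$seed` through independent child
#' streams (1: stages/ages/diagnosis; 2: latent status and CE abundances;
#' 3: gene baselines and identities; 4: expression noise), so adding draws
#' to one component does not perturb the others.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `expr` (genes x samples TPM matrix),
#'   `meta` (data.frame: sample_id, braak, age, diagnosis), `ce`
#'   (data.frame: sample_id, stmn2_short_tpm, unc13a_ce1_tpm,
#'   unc13a_ce2_tpm), and `truth` (list: tdp43_status named logical,
#'   stage_genes, isg_genes, ce_expressed samples x 3 logical matrix of
#'   planted CE expression indicators).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_samples
  G <- config$n_genes
  sample_id <- sprintf("S%04d", seq_len(n))
  gene_id <- sprintf("gene%05d", seq_len(G))

  ## stream 1: clinical covariates
  clin <- with_seed(child_seed(config$seed, 1L), {
    if (n >= 30L) {
      stage <- sample(c(1:6, sample.int(6, n - 6L, replace = TRUE)))
    } else {
      stage <- sample.int(6, n, replace = TRUE)
    }
    age <- pmin(pmax(stats::rnorm(
      n, 60 + config$age_stage_slope * (stage - 1), 8), 40), 100)
    diagnosis <- ifelse(
      stats::runif(n) < stats::plogis(stage - 3), "AD", "control")
    list(stage = stage, age = age, diagnosis = diagnosis)
  })

  ## stream 2: latent TDP-43 status and CE abundances
  thresholds <- unlist(ce_thresholds())
  ce_state <- with_seed(child_seed(config$seed, 2L), {
    is_ad <- clin$diagnosis == "AD"
    status <- is_ad & stats::runif(n) < config$tdp43_prevalence
    p_expr <- ifelse(status, config$ce_expression_prob_positive,
                     config$ce_expression_prob_negative)
    ab <- matrix(0, n, 3L)
    expr_flag <- matrix(FALSE, n, 3L)
    for (k in 1:3) {
      expressed <- stats::runif(n) < p_expr
      val <- numeric(n)
      val[expressed] <- stats::rlnorm(sum(expressed), config$ce_lognormal_mu,
                                      config$ce_lognormal_sigma)
      noisy <- !expressed & stats::runif(n) < 0.2
      val[noisy] <- stats::runif(sum(noisy), 0, 0.5 * thresholds[k])
      ab[, k] <- val
      expr_flag[, k] <- expressed
    }
    list(status = status, abundance = ab, expressed = expr_flag)
  })

  ## stream 3: gene identities and baselines
  genes <- with_seed(child_seed(config$seed, 3L), {
    idx <- sample.int(G, config$n_stage_genes + config$n_isg)
    list(stage_genes = gene_id[idx[seq_len(config$n_stage_genes)]],
         isg_genes = gene_id[idx[config$n_stage_genes + seq_len(config$n_isg)]],
         baseline = stats::rnorm(G, 3, 2))
  })

  ## stream 4: expression values
  expr <- with_seed(child_seed(config$seed, 4L), {
    log2val <- matrix(stats::rnorm(G * n, sd = config$noise_sd), G, n) +
      genes$baseline
    stage_rows <- match(genes$stage_genes, gene_id)
    carries_signal <- if (config$stage_signal_scope == "ce_positive") {
      ce_state$status
    } else {
      rep(TRUE, n)
    }
    shift <- config$stage_effect * (clin$stage - 1) * carries_signal
    log2val[stage_rows, ] <- log2val[stage_rows, ] +
      matrix(shift, length(stage_rows), n, byrow = TRUE)
    isg_rows <- match(genes$isg_genes, gene_id)
    isg_up <- ce_state$status & clin$diagnosis == "AD"
    log2val[isg_rows, ] <- log2val[isg_rows, ] +
      matrix(config$isg_effect * isg_up, length(isg_rows), n, byrow = TRUE)
    2^log2val
  })
  dimnames(expr) <- list(gene_id, sample_id)

  meta <- data.frame(sample_id = sample_id, braak = clin$stage,
                     age = clin$age, diagnosis = clin$diagnosis,
                     stringsAsFactors = FALSE)
  ce <- data.frame(sample_id = sample_id,
                   stmn2_short_tpm = ce_state$abundance[, 1],
                   unc13a_ce1_tpm = ce_state$abundance[, 2],
                   unc13a_ce2_tpm = ce_state$abundance[, 3],
                   stringsAsFactors = FALSE)
  ce_expressed <- ce_state$expressed
  dimnames(ce_expressed) <- list(sample_id,
                                 c("stmn2_short", "unc13a_ce1", "unc13a_ce2"))
  truth <- list(tdp43_status = stats::setNames(ce_state$status, sample_id),
                stage_genes = genes$stage_genes,
                isg_genes = genes$isg_genes,
                ce_expressed = ce_expressed)
  list(expr = expr, meta = meta, ce = ce, truth = truth)
}

#' Generate named gene sets for efficacy evaluation
#'
#' Returns one `"informative"` set equal to the planted stage genes plus
#' `n_random` random sets per requested size, each sampled uniformly
#' without replacement from the gene universe.
#'
#' @param truth Ground-truth list from [generate_cohort()] (or any list
#'   with a `stage_genes` element).
#' @param universe Character vector of candidate gene identifiers.
#' @param n_random Number of random sets per size.
#' @param sizes Integer vector of set sizes.
#' @param seed Integer seed.
#' @return Named list of character vectors; random sets are named
#'   `random<size>_<i>`.
#' @export
generate_gene_sets <- function(truth, universe, n_random = 10L,
                               sizes = 20L, seed = 1L) {
  stopifnot(is.character(universe), length(universe) > 0)
  if (n_random < 0) stop("'n_random' must be non-negative")
  if (any(sizes < 1) || any(sizes > length(universe))) {
    stop("every requested size must be between 1 and the universe size")
  }
  sets <- list(informative = truth$stage_genes)
  with_seed(seed, {
    for (s in sizes) {
      for (i in seq_len(n_random)) {
        sets[[sprintf("random%d_%d", s, i)]] <- sample(universe, s)
      }
    }
  })
  sets
}
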