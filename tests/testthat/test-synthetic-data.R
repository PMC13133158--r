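test_that("cohort generation is deterministic and reproducible from the seed", {
  a <- generate_cohort(cohort_config(seed = 5, n_samples = 40, n_genes = 100,
                                     n_stage_genes = 5))
  b <- generate_cohort(cohort_config(seed = 5, n_samples = 40, n_genes = 100,
                                     n_stage_genes = 5))
  expect_identical(a$expr, b$expr)
  expect_identical(a$meta, b$meta)
  expect_identical(a$ce, b$ce)
  expect_identical(a$truth, b$truth)
  d <- generate_cohort(cohort_config(seed = 6, n_samples = 40, n_genes = 100,
                                     n_stage_genes = 5))
  expect_false(identical(a$expr, d$expr))
})

test_that("generated cohorts satisfy their structural contracts", {
  co <- generate_cohort(cohort_config(seed = 2))
  expect_true(all(co$expr >= 0))
  expect_setequal(unique(co$meta$braak), 1:6)  # all six stages at n >= 30
  expect_true(all(co$meta$age >= 40 & co$meta$age <= 100))
  expect_true(all(co$truth$stage_genes %in% rownames(co$expr)))
  expect_true(all(co$truth$isg_genes %in% rownames(co$expr)))
  # latent status only among AD samples
  ad <- co$meta$diagnosis == "AD"
  expect_true(all(!co$truth$tdp43_status[!ad]))
  # age drifts upward with stage on average
  fit <- stats::lm(co$meta$age ~ co$meta$braak)
  expect_gt(stats::coef(fit)[2], 0)
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(n_samples = 0), "positive integer")
  expect_error(cohort_config(n_genes = 10, n_stage_genes = 8, n_isg = 5),
               "exceed")
  expect_error(cohort_config(ce_expression_prob_positive = 1.2), "probability")
  expect_error(cohort_config(stage_effect = NaN), "finite")
  expect_error(cohort_config(noise_sd = -1), "non-negative")
})

test_that("CE abundance marginal is bimodal with the planted absent mass", {
  co <- generate_cohort(cohort_config(seed = 9, n_samples = 500))
  th <- unlist(ce_thresholds())
  for (k in 1:3) {
    v <- co$ce[[k + 1]]
    frac_low <- mean(v <= 0.5 * th[k])
    expected <- 1 - mean(co$truth$ce_expressed[, k])
    # expressed lognormal mass below 0.5*threshold is negligible for
    # UNC13A CEs and < 1% for STMN2, so absent mass ~ 1 - P(expressed)
    expect_lt(abs(frac_low - expected), 0.05)
    # genuinely zero-inflated: a majority of absent values are exact zeros
    expect_gt(mean(v == 0), 0.3)
  }
})

test_that("separable CE parameters recover latent status exactly", {
  co <- generate_cohort(cohort_config(
    seed = 3, n_samples = 100, ce_expression_prob_positive = 1,
    ce_expression_prob_negative = 0, ce_lognormal_mu = log(1000),
    ce_lognormal_sigma = 0.1))
  cls <- classify_tdp43_status(call_ce_presence(co$ce))
  expect_identical(unname(cls$status == "positive"),
                   unname(co$truth$tdp43_status))
})

test_that("gene set generation yields exact sizes, determinism and uniform coverage", {
  universe <- sprintf("g%05d", 1:100)
  truth <- list(stage_genes = universe[1:7])
  sets <- generate_gene_sets(truth, universe, n_random = 5, sizes = 20,
                             seed = 4)
  expect_named(sets, c("informative", paste0("random20_", 1:5)))
  for (nm in paste0("random20_", 1:5)) {
    expect_length(sets[[nm]], 20)
    expect_false(anyDuplicated(sets[[nm]]) > 0)
    expect_true(all(sets[[nm]] %in% universe))
  }
  expect_identical(sets,
                   generate_gene_sets(truth, universe, n_random = 5,
                                      sizes = 20, seed = 4))
  expect_error(generate_gene_sets(truth, universe, sizes = 101), "universe")

  # inclusion frequency ~ size/universe for large resampling
  big_universe <- sprintf("g%05d", 1:20000)
  many <- generate_gene_sets(list(stage_genes = big_universe[1]),
                             big_universe, n_random = 1000, sizes = 20,
                             seed = 8)
  inc <- table(factor(unlist(many[-1]), levels = big_universe))
  expect_equal(mean(inc) / 1000, 0.001)  # exact by construction
  # no gene appears far beyond the binomial upper tail
  expect_lt(max(inc), qbinom(1 - 1e-6, 1000, 0.001) + 1)
})

test_that("screen generation is deterministic and plants the configured effects", {
  a <- generate_screen(screen_config(seed = 3, n_genes = 50, n_controls = 20))
  b <- generate_screen(screen_config(seed = 3, n_genes = 50, n_controls = 20))
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_length(a$truth$rescue_genes, 10)
  expect_length(a$truth$depletion_genes, 8)
  expect_equal(nrow(a$counts), 50 * 4 + 20)
  expect_equal(colnames(a$counts),
               c("initial_1", paste0("control_", 1:3),
                 paste0("treatment_", 1:3)))
})

test_that("near-noiseless screen counts put planted rescue LFC at log2(effect)", {
  # large library so the planted guides barely perturb the per-million
  # scaling (reads-per-million is compositional)
  sc <- generate_screen(screen_config(
    seed = 7, n_genes = 1000, n_controls = 100, baseline_dispersion = 0,
    rescue_effect = 4, n_rescue = 5, n_depletion = 0, mean_reads = 5000))
  res <- score_screen(sc, paste0("treatment_", 1:3), paste0("control_", 1:3))
  planted <- res[res$gene %in% sc$truth$rescue_genes, ]
  expect_equal(planted$lfc, rep(2, 5), tolerance = 0.05)
  others <- res[!(res$gene %in% sc$truth$rescue_genes), ]
  expect_lt(max(abs(others$lfc)), 0.5)
})

test_that("unit rescue effect leaves planted genes indistinguishable", {
  sc <- generate_screen(screen_config(seed = 11, n_genes = 200,
                                      rescue_effect = 1))
  res <- score_screen(sc, paste0("treatment_", 1:3), paste0("control_", 1:3))
  expect_equal(sum(res$hit == "enriched"), 0)
})

test_that("screen config validation rejects invalid settings", {
  expect_error(screen_config(rescue_effect = 0), "positive")
  expect_error(screen_config(n_genes = 5, n_rescue = 4, n_depletion = 3),
               "at most")
  expect_error(screen_config(baseline_dispersion = -0.1), ">= 0")
})
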