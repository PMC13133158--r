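test_that("Braak stages collapse to the A/B/C severity classes", {
  expect_equal(as.character(encode_braak(c(1, 2, 3, 4, 5, 6))),
               c("A", "A", "B", "B", "C", "C"))
  expect_true(is.ordered(encode_braak(1)))
  expect_warning(lab <- encode_braak(c(2, 7, NA)), "out-of-range")
  expect_equal(as.character(lab), c("A", NA, NA))
})

test_that("the penalised objective derivatives match finite differences", {
  set.seed(10)
  n <- 50; p <- 4
  X <- matrix(rnorm(n * p), n, p)
  yi <- sample(1:3, n, replace = TRUE)
  w <- rnorm(p) * 0.5
  theta <- c(-0.8, 0.9)
  lambda <- 1.7
  d <- driadce:::ordridge_derivs(w, theta, X, yi, 3, lambda)
  par <- c(w, theta)
  eps <- 1e-6
  f <- function(q) driadce:::ordridge_objective(q[1:p], q[p + 1:2], X, yi, 3,
                                                lambda)
  num_grad <- vapply(seq_along(par), function(i) {
    up <- par; up[i] <- up[i] + eps
    dn <- par; dn[i] <- dn[i] - eps
    (f(up) - f(dn)) / (2 * eps)
  }, numeric(1))
  expect_equal(d$grad, num_grad, tolerance = 1e-5)
})

test_that("the fitted optimum beats random perturbations (convexity oracle)", {
  set.seed(11)
  n <- 200
  X <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "g1"))
  stage <- X[, 1] + rnorm(n)
  y <- cut(stage, quantile(stage, c(0, 1/3, 2/3, 1)), include.lowest = TRUE,
           labels = c("A", "B", "C"))
  fit <- fit_ordinal_ridge(X, y, lambda = 1)
  expect_gt(unname(fit$weights[1]), 0)  # informative feature gets + weight
  Xs <- scale(X)
  yi <- as.integer(y)
  obj_opt <- driadce:::ordridge_objective(unname(fit$weights), fit$theta,
                                          Xs, yi, 3, 1)
  expect_equal(obj_opt, fit$objective, tolerance = 1e-8)
  for (r in 1:100) {
    w_p <- unname(fit$weights) + rnorm(1, sd = 0.3)
    th_p <- sort(fit$theta + rnorm(2, sd = 0.3))
    expect_gte(driadce:::ordridge_objective(w_p, th_p, Xs, yi, 3, 1),
               obj_opt - 1e-10)
  }
})

test_that("objective decreases monotonically across Newton iterations", {
  set.seed(12)
  X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, paste0("g", 1:3)))
  y <- factor(sample(c("A", "B", "C"), 100, replace = TRUE))
  fit <- fit_ordinal_ridge(X, y, lambda = 0.5)
  expect_true(all(diff(fit$trace) <= 1e-10))
})

test_that("an overwhelming penalty collapses the weights to zero", {
  set.seed(13)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("g", 1:4)))
  y <- factor(sample(c("A", "B", "C"), 50, replace = TRUE))
  fit <- fit_ordinal_ridge(X, y, lambda = 1e8)
  expect_lt(sqrt(sum(fit$weights^2)), 1e-4)
  s <- score_samples(fit, X)
  expect_lt(max(abs(s)), 1e-3)  # predictions collapse to the class marginal
})

test_that("two-class fits coincide with ridge-penalised logistic regression", {
  skip_if_not_installed("glmnet")
  set.seed(14)
  n <- 20
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("g", 1:3)))
  y <- factor(ifelse(X[, 1] + rnorm(n, sd = 0.8) > 0, "B", "A"))
  lambda <- 2
  fit <- fit_ordinal_ridge(X, y, lambda = lambda)
  g <- suppressWarnings(
    glmnet::glmnet(scale(X), y, family = "binomial", alpha = 0,
                   lambda = lambda / n, standardize = FALSE,
                   thresh = 1e-12))
  ref <- as.numeric(stats::coef(g))[-1]
  expect_equal(unname(fit$weights), ref, tolerance = 1e-3)
})

test_that("degenerate fits are rejected with informative errors", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_ordinal_ridge(X, rep("A", 10)), "two distinct classes")
  expect_error(fit_ordinal_ridge(X, rep(c("A", "B"), 5), lambda = -1),
               "non-negative")
  fit <- fit_ordinal_ridge(X, rep(c("A", "B"), 5), lambda = 1)
  expect_error(score_samples(fit, matrix(0, 2, 2,
                                         dimnames = list(NULL, c("a", "z")))),
               "absent.*b")
})

test_that("scores equal hand-computed standardised dot products", {
  X <- matrix(c(1, 2, 3,
                4, 6, 8), 3, 2,
              dimnames = list(NULL, c("g1", "g2")))
  model <- structure(list(weights = c(g1 = 0.5, g2 = -0.25),
                          theta = 0, lambda = 1,
                          center = colMeans(X), scale = apply(X, 2, sd)),
                     class = "ordinal_ridge")
  expected <- ((X[, 1] - 2) / 1) * 0.5 + ((X[, 2] - 6) / 2) * (-0.25)
  expect_equal(score_samples(model, X), expected)
  # zero weights give all-zero scores
  model$weights[] <- 0
  expect_equal(score_samples(model, X), rep(0, 3))
})

test_that("two samples and two classes yield the single possible pair", {
  pr <- build_age_matched_pairs(factor(c("A", "B")), c(70, 70), seed = 1)
  expect_equal(nrow(pr), 1)
  expect_equal(c(pr$i, pr$j), c(1, 2))
})

test_that("age-gap ties break uniformly at random across seeds", {
  stages <- factor(c("A", "B", "B"))
  ages <- c(60, 59, 61)
  picks <- vapply(1:1000, function(s) {
    pr <- build_age_matched_pairs(stages, ages, seed = s)
    # partner of sample 1 appears in the pair containing sample 1
    row <- pr[pr$i == 1 | pr$j == 1, ][1, ]
    setdiff(c(row$i, row$j), 1)
  }, numeric(1))
  frac59 <- mean(picks == 2)
  expect_gt(frac59, 0.45)
  expect_lt(frac59, 0.55)
})

test_that("pair construction matches exhaustive nearest-age search", {
  set.seed(15)
  for (rep in 1:10) {
    n <- sample(6:10, 1)
    stages <- factor(sample(c("A", "B", "C"), n, replace = TRUE))
    while (length(unique(stages)) < 2) {
      stages <- factor(sample(c("A", "B", "C"), n, replace = TRUE))
    }
    ages <- runif(n, 50, 90)  # continuous ages: unique gaps a.s.
    got <- build_age_matched_pairs(stages, ages, seed = rep)
    got_set <- lapply(seq_len(nrow(got)), function(k)
      sort(c(got$i[k], got$j[k])))
    rank_of <- as.integer(stages)
    want <- unique(lapply(seq_len(n), function(i) {
      cand <- which(rank_of != rank_of[i])
      sort(c(i, cand[which.min(abs(ages[cand] - ages[i]))]))
    }))
    expect_setequal(got_set, want)
    # later-stage member stored second
    expect_true(all(rank_of[got$i] < rank_of[got$j]))
  }
})

test_that("perfectly separable and constant features hit the AUC extremes", {
  stage <- rep(1:6, each = 5)
  y <- encode_braak(stage)
  ages <- 50 + stage * 2 + runif(30)
  X <- matrix(stage, 30, 1, dimnames = list(NULL, "g1"))
  expect_equal(as.numeric(lpocv_auc(X, y, ages, lambda = 1, seed = 1)), 1)
  Xc <- matrix(5, 30, 1, dimnames = list(NULL, "g1"))
  expect_equal(as.numeric(lpocv_auc(Xc, y, ages, lambda = 1, seed = 1)), 0.5)
})

test_that("AUC is invariant to monotone transforms of the feature signal", {
  co <- tiny_cohort(seed = 6)
  y <- encode_braak(co$meta$braak)
  X <- t(co$expr[co$truth$stage_genes, ])
  pairs <- build_age_matched_pairs(y, co$meta$age, seed = 2)
  a1 <- lpocv_auc(X, y, pairs = pairs)
  expect_gte(as.numeric(a1), 0)
  expect_lte(as.numeric(a1), 1)
  # scores are a deterministic function of the fit; scaling all features
  # by a positive constant leaves standardised features unchanged
  a2 <- lpocv_auc(X * 3.7, y, pairs = pairs)
  expect_equal(as.numeric(a1), as.numeric(a2))
})

test_that("permuted stage labels give chance-level AUC", {
  co <- tiny_cohort(seed = 7)
  X <- t(co$expr[co$truth$stage_genes, ])
  aucs <- vapply(1:20, function(s) {
    y <- withr::with_seed(s, sample(encode_braak(co$meta$braak)))
    as.numeric(lpocv_auc(X, y, co$meta$age, lambda = 1, seed = s))
  }, numeric(1))
  expect_gte(mean(aucs), 0.45)
  expect_lte(mean(aucs), 0.55)
})

test_that("planted stage-gene weights align with the planted direction", {
  cors <- vapply(1:5, function(s) {
    co <- generate_cohort(cohort_config(seed = s))
    feats <- c(co$truth$stage_genes,
               setdiff(rownames(co$expr), co$truth$stage_genes)[1:20])
    fit <- fit_ordinal_ridge(t(co$expr[feats, ]),
                             encode_braak(co$meta$braak), lambda = 1)
    w <- unname(fit$weights)
    d <- c(rep(1, 20), rep(0, 20))
    sum(w * d) / sqrt(sum(w^2) * sum(d^2))  # alignment with planted direction
  }, numeric(1))
  expect_true(all(cors >= 0.8))
})

test_that("stronger planted stage effects never degrade the informative AUC", {
  mean_auc <- vapply(c(0, 0.25, 0.5), function(eff) {
    mean(vapply(1:5, function(s) {
      co <- generate_cohort(cohort_config(
        seed = 300 + s, n_samples = 80, n_genes = 300, n_stage_genes = 10,
        stage_effect = eff))
      as.numeric(lpocv_auc(t(co$expr[co$truth$stage_genes, ]),
                           encode_braak(co$meta$braak),
                           ages = co$meta$age, seed = s))
    }, numeric(1)))
  }, numeric(1))
  # allow sampling noise but require a monotone trend
  expect_true(all(diff(mean_auc) > -0.02))
  expect_gt(mean_auc[3], mean_auc[1])
})
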