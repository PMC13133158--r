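# Independent oracles used across tests. These deliberately re-derive the
# quantities with naive step-by-step code so they do not share any logic
# with the package implementation.

# Running-sum enrichment score by explicit position-wise bookkeeping.
brute_force_es <- function(metric, gene_set) {
  ord <- order(-metric, names(metric))
  metric <- metric[ord]
  genes <- names(metric)
  N <- length(genes)
  hit <- genes %in% gene_set
  nh <- sum(hit)
  total_hit_weight <- sum(abs(metric[hit]))
  best <- 0
  running <- 0
  for (i in seq_len(N)) {
    if (hit[i]) {
      running <- running + abs(metric[i]) / total_hit_weight
    } else {
      running <- running - 1 / (N - nh)
    }
    if (abs(running) > abs(best)) best <- running
  }
  unname(best)
}

# Hypergeometric tail by exhaustive enumeration of guide-rank placements.
enum_hyper_tail <- function(j, m, N, r) {
  combos <- utils::combn(N, m)
  mean(apply(combos, 2, function(cmb) sum(cmb <= r) >= j))
}

# Nearest-age cross-class pairing and leave-pair-out evaluation, written
# as plain loops. Assumes all pairwise age gaps are unique so no random
# tie-breaking is involved.
brute_force_lpocv <- function(X, y, ages, lambda = 1) {
  n <- length(y)
  rank_of <- as.integer(factor(y, levels = sort(unique(as.character(y)))))
  prs <- list()
  for (i in seq_len(n)) {
    best_j <- NA
    best_gap <- Inf
    for (j in seq_len(n)) {
      if (rank_of[j] == rank_of[i]) next
      gap <- abs(ages[i] - ages[j])
      if (gap < best_gap) {
        best_gap <- gap
        best_j <- j
      }
    }
    prs[[i]] <- sort(c(i, best_j))
  }
  prs <- unique(prs)
  credits <- numeric(length(prs))
  for (k in seq_along(prs)) {
    pr <- prs[[k]]
    fit <- fit_ordinal_ridge(X[-pr, , drop = FALSE], y[-pr], lambda = lambda)
    s <- score_samples(fit, X[pr, , drop = FALSE])
    later <- which.max(rank_of[pr])
    earlier <- 3 - later
    credits[k] <- if (s[later] > s[earlier]) 1 else if (s[later] == s[earlier]) 0.5 else 0
  }
  list(pairs = prs, auc = mean(credits))
}

# Small well-separated cohort used by several tests.
tiny_cohort <- function(seed = 1, ...) {
  generate_cohort(cohort_config(
    seed = seed, n_samples = 60, n_genes = 200, n_stage_genes = 8, ...))
}
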