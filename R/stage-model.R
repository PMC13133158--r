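#' Map Braak stages to ordinal disease-stage labels
#'
#' Braak tangle stages 1-6 collapse to three ordered severity classes:
#' A (early, Braak 1-2), B (intermediate, Braak 3-4), C (late, Braak 5-6).
#' Samples with missing or out-of-range Braak values are returned as `NA`
#' with a warning, so callers can drop them explicitly.
#'
#' @param braak Integer vector of Braak stages in 1..6.
#' @return Ordered factor with levels A < B < C.
#' @examples
#' encode_braak(c(1, 4, 6))
#' @export
encode_braak <- function(braak) {
  braak <- as.numeric(braak)
  bad <- !is.finite(braak) | braak < 1 | braak > 6 | braak != floor(braak)
  if (any(bad)) {
    warning(sum(bad), " sample(s) with missing or out-of-range Braak stage ",
            "encoded as NA and should be excluded")
  }
  lab <- rep(NA_character_, length(braak))
  lab[!bad] <- c("A", "A", "B", "B", "C", "C")[braak[!bad]]
  factor(lab, levels = c("A", "B", "C"), ordered = TRUE)
}

#' Build age-matched cross-class sample pairs
#'
#' Each sample is paired with its closest age match among samples of the
#' *other* stage classes; ties in the age gap are broken uniformly at
#' random from the seeded stream. Unordered duplicates (i paired to j and
#' j paired to i) collapse to a single pair. Pairs are stored with the
#' later-stage member second.
#'
#' @param stages Ordinal stage labels (ordered factor or sortable vector).
#' @param ages Numeric ages, finite, same length as `stages`.
#' @param seed Integer seed for tie-breaking.
#' @return A data.frame with columns `i`, `j` (indices into the input,
#'   later stage in `j`), `stage_i`, `stage_j`, `age_gap`.
#' @export
build_age_matched_pairs <- function(stages, ages, seed = 1L) {
  n <- length(stages)
  if (length(ages) != n) stop("'stages' and 'ages' must have equal length")
  if (any(!is.finite(ages))) stop("all ages must be finite")
  if (anyNA(stages)) stop("all samples must have a stage label")
  rank_of <- as.integer(factor(stages, levels = sort(unique(stages))))
  if (length(unique(rank_of)) < 2L) {
    stop("all samples belong to a single class; no cross-class pairs exist")
  }
  with_seed(seed, {
    partner <- integer(n)
    for (i in seq_len(n)) {
      cand <- which(rank_of != rank_of[i])
      gap <- abs(ages[cand] - ages[i])
      best <- cand[gap == min(gap)]
      partner[i] <- if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
    }
    a <- pmin(seq_len(n), partner)
    b <- pmax(seq_len(n), partner)
    keep <- !duplicated(cbind(a, b))
    a <- a[keep]; b <- b[keep]
    # later-stage member second
    swap <- rank_of[a] > rank_of[b]
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    data.frame(i = a, j = b,
               stage_i = as.character(stages[a]),
               stage_j = as.character(stages[b]),
               age_gap = abs(ages[a] - ages[b]))
  })
}

#' Leave-pair-out cross-validated AUC for ordinal stage prediction
#'
#' For every age-matched pair both members are withheld, an ordinal ridge
#' model is fitted on the remaining samples (feature standardisation is
#' recomputed inside each training fold), and both members are scored.
#' A pair is credited 1 when the later-stage member receives the strictly
#' higher score, 0.5 on an exact tie, 0 otherwise. The mean credit over
#' pairs estimates the area under the ROC curve.
#'
#' @param X Samples x features matrix.
#' @param y Ordinal stage labels (e.g. from [encode_braak()]).
#' @param ages Numeric ages used for pair matching.
#' @param lambda Ridge penalty passed to [fit_ordinal_ridge()].
#' @param seed Seed for the tie-breaking stream in pair construction.
#' @param pairs Optional precomputed pair set from
#'   [build_age_matched_pairs()]; when supplied, `ages` and `seed` are
#'   ignored (used to evaluate many gene sets against identical pairs).
#' @return Numeric AUC in \[0, 1\], with attributes `n_pairs` and
#'   `n_skipped`.
#' @export
lpocv_auc <- function(X, y, ages = NULL, lambda = 1, seed = 1L,
                      pairs = NULL) {
  X <- as.matrix(X)
  if (is.null(pairs)) {
    if (is.null(ages)) stop("either 'ages' or 'pairs' must be supplied")
    pairs <- build_age_matched_pairs(y, ages, seed = seed)
  }
  if (nrow(pairs) < 3L) stop("need at least 3 pairs for cross-validation")
  # warm start every fold from the full-data fit
  full <- tryCatch(fit_ordinal_ridge(X, y, lambda = lambda),
                   error = function(e) NULL)
  init <- if (is.null(full)) NULL else
    list(w = unname(full$weights), theta = full$theta)  # standardised scale
  lv <- if (is.factor(y)) levels(droplevels(y)) else sort(unique(y))
  yi <- as.integer(factor(y, levels = lv))
  credit <- numeric(nrow(pairs))
  skipped <- logical(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    hold <- c(pairs$i[r], pairs$j[r])
    fit <- tryCatch(
      fit_ordinal_ridge(X[-hold, , drop = FALSE], y[-hold], lambda = lambda,
                        init = init),
      error = function(e) NULL)
    if (is.null(fit)) {
      skipped[r] <- TRUE
      next
    }
    s <- score_samples(fit, X[hold, , drop = FALSE])
    later_is_j <- yi[pairs$j[r]] > yi[pairs$i[r]]
    d <- if (later_is_j) s[2] - s[1] else s[1] - s[2]
    credit[r] <- if (d > 0) 1 else if (d == 0) 0.5 else 0
  }
  n_skip <- sum(skipped)
  if (n_skip > 0) {
    warning(n_skip, " fold(s) failed to converge and were skipped")
    if (n_skip > 0.1 * nrow(pairs)) {
      stop("more than 10% of cross-validation folds failed to converge")
    }
  }
  auc <- mean(credit[!skipped])
  attr(auc, "n_pairs") <- nrow(pairs)
  attr(auc, "n_skipped") <- n_skip
  auc
}
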