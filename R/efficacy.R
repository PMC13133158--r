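#' Restrict an expression matrix to a protein-coding universe
#'
#' @param expr Genes x samples matrix with gene rownames.
#' @param coding Character vector of admissible (e.g. protein-coding)
#'   gene identifiers.
#' @return The restricted matrix; its rownames define the feature universe
#'   from which background gene sets are drawn.
#' @export
restrict_universe <- function(expr, coding) {
  if (length(coding) == 0L) stop("'coding' must be non-empty")
  keep <- intersect(rownames(expr), coding)
  if (length(keep) == 0L) {
    stop("no overlap between the expression matrix and the coding list")
  }
  expr[keep, , drop = FALSE]
}

#' Subset an expression matrix to a gene set
#'
#' @param expr Genes x samples matrix.
#' @param gene_set Character vector of gene identifiers.
#' @return A list with `X` (samples x genes feature matrix, or `NULL`),
#'   `effective_size` (size of the intersection; background sets are
#'   matched to this size) and `untestable` (TRUE when the intersection is
#'   empty).
#' @export
subset_features <- function(expr, gene_set) {
  if (length(gene_set) == 0L) stop("'gene_set' must be non-empty")
  genes <- intersect(unique(gene_set), rownames(expr))
  if (length(genes) == 0L) {
    return(list(X = NULL, effective_size = 0L, untestable = TRUE))
  }
  list(X = t(expr[genes, , drop = FALSE]),
       effective_size = length(genes), untestable = FALSE)
}

#' Empirical gene-set p-value against a background AUC distribution
#'
#' p = fraction of background sets with strictly higher AUC than the gene
#' set of interest. The optional `(r + 1) / (N + 1)` correction (which
#' avoids exact zeros) is off by default.
#'
#' @param drug_auc AUC of the gene set under test.
#' @param background_aucs Numeric vector of size-matched random-set AUCs.
#' @param correction Apply the add-one correction.
#' @return Empirical p-value.
#' @examples
#' empirical_pvalue(0.8, c(0.5, 0.6, 0.85, 0.9))
#' @export
empirical_pvalue <- function(drug_auc, background_aucs, correction = FALSE) {
  if (length(background_aucs) == 0L) stop("background must be non-empty")
  r <- sum(background_aucs > drug_auc)
  if (correction) (r + 1) / (length(background_aucs) + 1)
  else r / length(background_aucs)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate control across one family of
#' p-values.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values (monotone, \eqn{\ge} raw p, \eqn{\le} 1).
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Evaluate drug gene sets against size-matched random backgrounds
#'
#' The stratified efficacy analysis: samples are split by predicted
#' TDP-43 pathology status; within each stratum one age-matched pair set
#' is built (pairing depends only on the samples, so every gene set in the
#' stratum is evaluated against identical pairs); each drug gene set's
#' leave-pair-out AUC is compared with `n_background` random gene sets of
#' matching effective size drawn uniformly without replacement from the
#' feature universe. Empirical p-values are the fraction of background
#' sets with higher AUC, and Benjamini-Hochberg adjustment is applied
#' across the whole (drug x stratum) family of the invocation.
#'
#' @param expr Genes x samples TPM matrix (already restricted to the
#'   protein-coding universe via [restrict_universe()] where applicable).
#' @param meta Data.frame with `sample_id`, `braak`, `age`.
#' @param gene_sets Named list of character vectors (drug gene sets).
#' @param status Factor/character vector of predicted TDP-43 status
#'   ("positive"/"negative") named by or aligned with `meta$sample_id`;
#'   `NULL` evaluates the whole cohort as a single stratum `"all"`.
#' @param n_background Number of random background sets per gene set.
#' @param lambda Ridge penalty.
#' @param seed Master seed (pairing tie-breaks and background sampling).
#' @return A data.frame of class `efficacy_result` with one row per
#'   (gene set x stratum): `drug`, `stratum`, `auc`, `effective_size`,
#'   `n_samples`, `n_pairs`, `p`, `padj`. Background AUC vectors are
#'   attached as `attr(, "backgrounds")` (named `drug|stratum`).
#' @export
run_driad_sp <- function(expr, meta, gene_sets, status = NULL,
                         n_background = 1000L, lambda = 1, seed = 1L) {
  stopifnot(is.list(gene_sets), length(gene_sets) > 0)
  if (is.null(names(gene_sets)) || any(names(gene_sets) == "")) {
    stop("'gene_sets' must be a named list")
  }
  common <- intersect(colnames(expr), meta$sample_id)
  if (length(common) == 0L) stop("no samples shared by 'expr' and 'meta'")
  meta <- meta[match(common, meta$sample_id), ]
  expr <- expr[, common, drop = FALSE]
  y_all <- encode_braak(meta$braak)
  usable <- !is.na(y_all) & is.finite(meta$age)
  if (any(!usable)) {
    message(sum(!usable), " sample(s) without usable Braak stage or age dropped")
  }

  strata <- if (is.null(status)) {
    list(all = common[usable])
  } else {
    st <- if (!is.null(names(status))) status[common] else
      status[match(common, meta$sample_id)]
    st <- as.character(st)
    list(positive = common[usable & st == "positive"],
         negative = common[usable & st == "negative"])
  }

  universe <- rownames(expr)
  rows <- list()
  backgrounds <- list()
  for (sname in names(strata)) {
    ids <- strata[[sname]]
    idx <- match(ids, common)
    y <- droplevels(y_all[idx])
    if (length(unique(y)) < 2L) {
      warning(sprintf("stratum '%s' skipped: fewer than 2 stage classes",
                      sname))
      next
    }
    pairs <- build_age_matched_pairs(
      y, meta$age[idx], seed = child_seed(seed, match(sname, names(strata))))
    if (nrow(pairs) < 3L) {
      warning(sprintf("stratum '%s' skipped: only %d usable pair(s)",
                      sname, nrow(pairs)))
      next
    }
    Es <- expr[, ids, drop = FALSE]
    for (dname in names(gene_sets)) {
      sub <- subset_features(Es, gene_sets[[dname]])
      if (sub$untestable) {
        warning(sprintf(
          "gene set '%s' has no overlap with the expression matrix; untestable",
          dname))
        rows[[length(rows) + 1L]] <- data.frame(
          drug = dname, stratum = sname, auc = NA_real_,
          effective_size = 0L, n_samples = length(ids),
          n_pairs = nrow(pairs), p = NA_real_, stringsAsFactors = FALSE)
        next
      }
      auc <- lpocv_auc(sub$X, y, lambda = lambda, pairs = pairs)
      bg_seed <- child_seed(seed, 100L + length(rows))
      bg_sets <- with_seed(bg_seed, {
        lapply(seq_len(n_background), function(i)
          sample(universe, sub$effective_size))
      })
      bg_auc <- vapply(bg_sets, function(gs) {
        as.numeric(lpocv_auc(subset_features(Es, gs)$X, y,
                             lambda = lambda, pairs = pairs))
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        drug = dname, stratum = sname, auc = as.numeric(auc),
        effective_size = sub$effective_size, n_samples = length(ids),
        n_pairs = nrow(pairs),
        p = empirical_pvalue(as.numeric(auc), bg_auc),
        stringsAsFactors = FALSE)
      backgrounds[[paste(dname, sname, sep = "|")]] <- bg_auc
    }
  }
  if (length(rows) == 0L) stop("no stratum could be evaluated")
  out <- do.call(rbind, rows)
  out$padj <- NA_real_
  ok <- !is.na(out$p)
  out$padj[ok] <- bh_adjust(out$p[ok])
  attr(out, "backgrounds") <- backgrounds
  class(out) <- c("efficacy_result", class(out))
  out
}
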