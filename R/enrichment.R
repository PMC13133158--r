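#' Differential expression between two sample groups (Welch stand-in)
#'
#' Per-gene analysis on log2(TPM + 1): the log2 fold change is the
#' difference of group means and the p-value comes from Welch's unequal-
#' variance two-sample t-test, with Benjamini-Hochberg adjustment across
#' genes. This is deliberately a simple, transparent stand-in for
#' count-model differential-expression protocols; it is adequate for the
#' planted-shift structure of the synthetic cohorts but does not model
#' count overdispersion in real RNA-seq data.
#'
#' @param expr Genes x samples TPM matrix.
#' @param groups Two-level factor/character vector aligned with the
#'   columns of `expr`; the *first* level (alphabetical for characters) is
#'   the reference, so LFC = mean(second) - mean(first). Use e.g.
#'   `factor(diagnosis, levels = c("control", "AD"))` for AD vs control.
#' @return A data.frame: `gene`, `lfc`, `p`, `padj`. Genes with zero
#'   variance in both groups and no mean difference get p = 1.
#' @export
differential_expression <- function(expr, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2L) {
    stop("'groups' must have exactly two levels")
  }
  groups <- droplevels(groups)
  if (length(groups) != ncol(expr)) {
    stop("'groups' must align with the columns of 'expr'")
  }
  if (min(table(groups)) < 3L) stop("both groups need at least 3 samples")
  L <- log2(as.matrix(expr) + 1)
  g1 <- L[, groups == levels(groups)[1L], drop = FALSE]
  g2 <- L[, groups == levels(groups)[2L], drop = FALSE]
  n1 <- ncol(g1); n2 <- ncol(g2)
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  v1 <- rowSums((g1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((g2 - m2)^2) / (n2 - 1)
  lfc <- m2 - m1
  se2 <- v1 / n1 + v2 / n2
  tstat <- ifelse(se2 > 0, lfc / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               1)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(tstat), df), 1)
  data.frame(gene = rownames(expr), lfc = lfc, p = p,
             padj = stats::p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Signed significance ranking metric
#'
#' The gene-ranking metric \eqn{-\mathrm{sign}(\mathrm{LFC}) \times
#' \log_{10}(p)}: strongly significant upregulated genes get large
#' positive values, downregulated ones large negative values, and p = 1
#' maps to 0 regardless of the fold change. p-values are floored at
#' 1e-300 (with a warning for exact zeros) to keep the metric finite.
#'
#' @param lfc Numeric log2 fold changes.
#' @param p p-values in (0, 1].
#' @return Numeric metric values.
#' @examples
#' rank_metric(c(2, -1, 0.5), c(0.01, 0.001, 1))
#' @export
rank_metric <- function(lfc, p) {
  if (length(lfc) != length(p)) stop("'lfc' and 'p' must have equal length")
  if (any(!is.finite(lfc))) stop("'lfc' must be finite")
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("'p' must lie in [0, 1]")
  if (any(p == 0)) {
    warning("p-value(s) of exactly 0 floored at 1e-300")
  }
  p <- pmax(p, 1e-300)
  -sign(lfc) * log10(p)
}

#' Pre-ranked gene-set enrichment (weighted running-sum)
#'
#' Classic weighted Kolmogorov-Smirnov-style enrichment on a ranked gene
#' list: walking down the list sorted by decreasing metric, the running
#' sum increases at set members proportionally to |metric| (weight
#' exponent 1, hit increments normalised to sum 1) and decreases by
#' 1/(N - N_hit) at non-members; the enrichment score ES is the maximum
#' signed deviation. The null distribution comes from `n_perm` random
#' gene sets of the same size (gene permutation); the one-sided p-value
#' for positive enrichment is (r + 1)/(n_perm + 1) where r counts null ES
#' \eqn{\ge} observed, and NES = ES / mean(|null ES| of matching sign).
#' Metric ties are broken by gene identifier so the ranking is
#' deterministic.
#'
#' @param metric Named numeric vector (gene -> ranking metric), no
#'   duplicate names, finite.
#' @param gene_set Character vector of member genes.
#' @param n_perm Number of random-set permutations.
#' @param seed Integer seed for the permutation stream.
#' @return A list: `es`, `nes`, `p` (one-sided, positive enrichment),
#'   `n_hits`, `null_es`.
#' @export
gsea_preranked <- function(metric, gene_set, n_perm = 1000L, seed = 1L) {
  if (is.null(names(metric)) || anyDuplicated(names(metric))) {
    stop("'metric' must be named with unique gene identifiers")
  }
  if (any(!is.finite(metric))) stop("'metric' must be finite")
  ord <- order(-metric, names(metric))
  metric <- metric[ord]
  genes <- names(metric)
  N <- length(genes)
  hits <- genes %in% gene_set
  n_hits <- sum(hits)
  if (n_hits == 0L) stop("gene set has no overlap with the ranked list")
  if (n_hits == N) stop("gene set covers the whole ranked list")

  es_of <- function(hit_idx) {
    hit <- logical(N)
    hit[hit_idx] <- TRUE
    w <- abs(metric) * hit
    tw <- sum(w)
    inc <- if (tw > 0) w / tw else hit / sum(hit)  # all-zero metric: equal weights
    dec <- (!hit) / (N - sum(hit))
    running <- cumsum(inc - dec)
    unname(running[which.max(abs(running))])
  }
  es <- es_of(which(hits))
  null_es <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i)
      es_of(sample.int(N, n_hits)), numeric(1))
  })
  p <- (sum(null_es >= es) + 1) / (n_perm + 1)
  same_sign <- if (es >= 0) null_es[null_es > 0] else null_es[null_es < 0]
  nes <- if (length(same_sign) > 0) es / mean(abs(same_sign)) else NA_real_
  list(es = es, nes = nes, p = p, n_hits = n_hits, null_es = null_es)
}

#' ISG expression contrast between predicted TDP-43 strata
#'
#' Compares interferon-stimulated gene expression between predicted
#' TDP-43 pathology-positive and -negative samples: per-gene differential
#' expression (positive vs negative), the signed significance ranking
#' metric, and a set-level pre-ranked enrichment p-value for the ISG list.
#'
#' @param expr Genes x samples TPM matrix.
#' @param isg_genes Character vector of ISG identifiers.
#' @param status Factor/character "positive"/"negative" aligned with (or
#'   named by) the columns of `expr`.
#' @param n_perm,seed Passed to [gsea_preranked()].
#' @return A list: `de` (the per-gene table restricted to ISGs, LFC is
#'   positive-vs-negative), `enrichment` (from [gsea_preranked()] on the
#'   full ranking).
#' @export
isg_by_status <- function(expr, isg_genes, status, n_perm = 1000L,
                          seed = 1L) {
  st <- as.character(if (!is.null(names(status))) status[colnames(expr)]
                     else status)
  if (!all(st %in% c("positive", "negative"))) {
    stop("'status' must be 'positive'/'negative' for every sample")
  }
  if (!any(st == "positive") || !any(st == "negative")) {
    stop("both strata must be non-empty")
  }
  isg <- intersect(isg_genes, rownames(expr))
  if (length(isg) == 0L) {
    stop("ISG list has no overlap with the expression matrix")
  }
  de <- differential_expression(
    expr, factor(st, levels = c("negative", "positive")))
  met <- stats::setNames(rank_metric(de$lfc, de$p), de$gene)
  enr <- gsea_preranked(met, isg, n_perm = n_perm, seed = seed)
  list(de = de[de$gene %in% isg, ], enrichment = enr)
}
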