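#' Decimal round-half-up
#'
#' Rounds to `digits` decimal places on the *decimal* representation of
#' the number, with ties rounded away from zero. Binary floating-point
#' round-to-nearest would map 1.95 (stored slightly below 1.95) to 1.9;
#' the screen's hit rule requires the decimal behaviour, where 1.95
#' rounds to 2.0. Each value is first rendered as its shortest round-trip
#' decimal string (15 significant digits) and the rounding is performed
#' on the digit string, so the result is exact.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (non-negative integer).
#' @return Numeric vector rounded half-up (away from zero) at `digits`
#'   decimals.
#' @examples
#' round_half_up(c(1.95, 2.23825, -1.9875), 1)  # 2.0, 2.2, -2.0
#' @export
round_half_up <- function(x, digits = 1L) {
  stopifnot(is.numeric(x), digits >= 0, digits == floor(digits))
  digits <- as.integer(digits)
  vapply(x, function(xi) {
    if (!is.finite(xi)) return(xi)
    neg <- xi < 0
    s <- format(abs(xi), scientific = FALSE, digits = 15L, trim = TRUE)
    parts <- strsplit(s, ".", fixed = TRUE)[[1]]
    int <- parts[1]
    frac <- if (length(parts) > 1L) parts[2] else ""
    frac <- paste0(frac, strrep("0", max(0L, digits + 1L - nchar(frac))))
    keep <- substr(frac, 1L, digits)
    nxt <- substr(frac, digits + 1L, digits + 1L)
    scaled <- as.numeric(paste0(int, keep))
    if (nxt >= "5") scaled <- scaled + 1
    out <- scaled / 10^digits
    if (neg) -out else out
  }, numeric(1))
}

#' Normalise sgRNA counts to reads per million
#'
#' @param counts Non-negative sgRNA x condition count matrix.
#' @return Matrix of the same shape where each column sums to 1e6.
#' @export
normalize_rpm <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and non-negative")
  }
  tot <- colSums(counts)
  if (any(tot == 0)) {
    stop("all-zero count column(s): ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  }
  sweep(counts, 2, tot, "/") * 1e6
}

#' Per-sgRNA log2 fold change between conditions
#'
#' Replicates are averaged on the RPM scale before the log2 transform;
#' a pseudocount (default 1 RPM) guards against zeros:
#' LFC = log2(mean(treatment RPM) + c) - log2(mean(control RPM) + c).
#'
#' @param treatment_rpm sgRNA x replicate RPM matrix (or vector).
#' @param control_rpm sgRNA x replicate RPM matrix (or vector), same
#'   sgRNA order.
#' @param pseudocount Pseudocount c in RPM.
#' @return Named numeric vector of per-sgRNA LFCs.
#' @export
sgrna_lfc <- function(treatment_rpm, control_rpm, pseudocount = 1) {
  t_mat <- as.matrix(treatment_rpm)
  c_mat <- as.matrix(control_rpm)
  if (nrow(t_mat) != nrow(c_mat)) {
    stop("treatment and control must cover the same sgRNAs")
  }
  if (!is.null(rownames(t_mat)) && !is.null(rownames(c_mat)) &&
      !identical(rownames(t_mat), rownames(c_mat))) {
    stop("sgRNA identifiers differ between treatment and control")
  }
  lfc <- log2(rowMeans(t_mat) + pseudocount) -
    log2(rowMeans(c_mat) + pseudocount)
  names(lfc) <- rownames(t_mat)
  lfc
}

#' Aggregate sgRNA LFCs to genes and call hits
#'
#' Gene-level LFC is the arithmetic mean over the gene's guides, rounded
#' to one decimal with decimal round-half-up; a gene is an enrichment hit
#' when the rounded LFC is \eqn{\ge} 2.0 and a depletion hit when it is
#' \eqn{\le} -2.0. Control sgRNAs (gene label `"control"`) are never
#' aggregated.
#'
#' @param lfc Named per-sgRNA LFC vector.
#' @param guide_map Data.frame with columns `sgrna`, `gene`.
#' @return Data.frame: `gene`, `n_guides`, `lfc`, `lfc_rounded`, `hit`
#'   ("enriched"/"depleted"/"none").
#' @export
gene_lfc_and_hits <- function(lfc, guide_map) {
  stopifnot(all(c("sgrna", "gene") %in% names(guide_map)))
  gene <- guide_map$gene[match(names(lfc), guide_map$sgrna)]
  if (anyNA(gene)) {
    stop("sgRNA(s) missing from the guide map: ",
         paste(utils::head(names(lfc)[is.na(gene)], 5), collapse = ", "))
  }
  keep <- gene != "control"
  if (!any(keep)) stop("no gene-targeting sgRNAs present")
  gmean <- tapply(lfc[keep], gene[keep], mean)
  out <- data.frame(gene = names(gmean),
                    n_guides = as.integer(table(gene[keep])[names(gmean)]),
                    lfc = as.numeric(gmean),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$lfc_rounded <- round_half_up(out$lfc, 1L)
  out$hit <- ifelse(out$lfc_rounded >= 2, "enriched",
                    ifelse(out$lfc_rounded <= -2, "depleted", "none"))
  out
}

#' Hypergeometric gene p-value from guide ranks
#'
#' For a gene with m guides among N ranked sgRNAs (best first), and each
#' j = 1..m whose j-th best guide rank r_j falls within the top
#' `inclusion_fraction` of the list, computes the hypergeometric tail
#' probability of seeing \eqn{\ge j} of the gene's m guides within the
#' top r_j by chance; the gene's p-value is the minimum over admissible
#' j, or 1 when no guide makes the inclusion cut.
#'
#' @param ranked_sgrnas Character vector of all sgRNA identifiers ordered
#'   best-first (e.g. by decreasing LFC for enrichment).
#' @param guide_map Data.frame with columns `sgrna`, `gene`.
#' @param gene Gene identifier to score.
#' @param inclusion_fraction Top fraction of the list in which a guide
#'   rank is admissible.
#' @return p-value.
#' @export
hypergeom_gene_p <- function(ranked_sgrnas, guide_map, gene,
                             inclusion_fraction = 0.1) {
  N <- length(ranked_sgrnas)
  if (N == 0L) stop("empty ranked sgRNA list")
  guides <- guide_map$sgrna[guide_map$gene == gene]
  r <- sort(match(guides, ranked_sgrnas))
  r <- r[!is.na(r)]
  m <- length(r)
  if (m == 0L) stop("gene '", gene, "' has no guides in the ranked list")
  cutoff <- floor(inclusion_fraction * N)
  p <- 1
  for (j in seq_len(m)) {
    if (r[j] <= cutoff) {
      # P(X >= j), X ~ Hypergeom(N, m successes, r_j draws)
      pj <- stats::phyper(j - 1L, m, N - m, r[j], lower.tail = FALSE)
      p <- min(p, pj)
    }
  }
  p
}

#' Score a pooled CRISPR screen end to end
#'
#' RPM-normalises the count table, computes per-sgRNA LFCs of the
#' treatment arm against the lipofectamine control arm, aggregates to
#' genes with the rounded-LFC hit rule, and attaches hypergeometric
#' p-values in both directions (enrichment: guides ranked by decreasing
#' LFC; depletion: increasing).
#'
#' @param screen A screen table list as produced by [generate_screen()]
#'   or [read_screen_counts()]: `counts` (sgRNA x column matrix),
#'   `guide_map` (`sgrna`, `gene`).
#' @param treatment_cols,control_cols Column names of the two arms.
#' @param pseudocount Pseudocount in RPM.
#' @param inclusion_fraction Rank-inclusion fraction for the
#'   hypergeometric model.
#' @return Data.frame: `gene`, `n_guides`, `lfc`, `lfc_rounded`, `hit`,
#'   `p_enrich`, `p_deplete`, sorted by decreasing LFC. Per-sgRNA LFCs
#'   (including controls) are attached as `attr(, "sgrna_lfc")`.
#' @export
score_screen <- function(screen, treatment_cols, control_cols,
                         pseudocount = 1, inclusion_fraction = 0.1) {
  stopifnot(all(treatment_cols %in% colnames(screen$counts)),
            all(control_cols %in% colnames(screen$counts)))
  rpm <- normalize_rpm(screen$counts)
  lfc <- sgrna_lfc(rpm[, treatment_cols, drop = FALSE],
                   rpm[, control_cols, drop = FALSE],
                   pseudocount = pseudocount)
  res <- gene_lfc_and_hits(lfc, screen$guide_map)
  rk_desc <- names(sort(lfc, decreasing = TRUE))
  rk_asc <- rev(rk_desc)
  res$p_enrich <- vapply(res$gene, function(g)
    hypergeom_gene_p(rk_desc, screen$guide_map, g, inclusion_fraction),
    numeric(1))
  res$p_deplete <- vapply(res$gene, function(g)
    hypergeom_gene_p(rk_asc, screen$guide_map, g, inclusion_fraction),
    numeric(1))
  res <- res[order(-res$lfc), ]
  rownames(res) <- NULL
  attr(res, "sgrna_lfc") <- lfc
  res
}

#' Genes depleted during differentiation
#'
#' Applies the screen LFC machinery with the initial library as the
#' control arm: genes whose rounded post-differentiation LFC is
#' \eqn{\le} -2.0 are reported as differentiation-essential candidates,
#' with hypergeometric p-values computed on the ascending (most-depleted
#' first) guide ranking.
#'
#' @param screen Screen table (see [score_screen()]).
#' @param postdiff_cols Column names of the post-differentiation arm.
#' @param initial_cols Column names of the initial library arm.
#' @param pseudocount,inclusion_fraction See [score_screen()].
#' @return Data.frame as in [gene_lfc_and_hits()] plus `p_deplete`,
#'   restricted columns sorted by increasing LFC; the `depleted` subset is
#'   the hit list.
#' @export
differentiation_dropout <- function(screen, postdiff_cols, initial_cols,
                                    pseudocount = 1,
                                    inclusion_fraction = 0.1) {
  rpm <- normalize_rpm(screen$counts)
  lfc <- sgrna_lfc(rpm[, postdiff_cols, drop = FALSE],
                   rpm[, initial_cols, drop = FALSE],
                   pseudocount = pseudocount)
  res <- gene_lfc_and_hits(lfc, screen$guide_map)
  rk_asc <- names(sort(lfc, decreasing = FALSE))
  res$p_deplete <- vapply(res$gene, function(g)
    hypergeom_gene_p(rk_asc, screen$guide_map, g, inclusion_fraction),
    numeric(1))
  res <- res[order(res$lfc), ]
  rownames(res) <- NULL
  res
}
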