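#' Cryptic-exon abundance thresholds
#'
#' Default dichotomisation thresholds for the three TDP-43-associated
#' cryptic-exon (CE) transcripts, in TPM: 1.3 for STMN2-short, 0.09 for
#' UNC13A-CE1 and 0.08 for UNC13A-CE2. A transcript is called present when
#' its abundance is strictly greater than the threshold (configurable to
#' `>=` via `strict = FALSE` in [call_ce_presence()]).
#'
#' @param stmn2_short,unc13a_ce1,unc13a_ce2 Non-negative TPM thresholds.
#' @return A list of class `ce_thresholds`.
#' @export
ce_thresholds <- function(stmn2_short = 1.3, unc13a_ce1 = 0.09,
                          unc13a_ce2 = 0.08) {
  vals <- c(stmn2_short = stmn2_short, unc13a_ce1 = unc13a_ce1,
            unc13a_ce2 = unc13a_ce2)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all thresholds must be finite and non-negative")
  }
  structure(as.list(vals), class = "ce_thresholds")
}

#' Call presence of the three CE transcripts per sample
#'
#' @param abundances A data.frame or matrix with one row per sample and
#'   the three CE abundance columns `stmn2_short_tpm`, `unc13a_ce1_tpm`,
#'   `unc13a_ce2_tpm` (a bare 3-column numeric matrix is accepted in that
#'   order); an optional `sample_id` column names the rows. `NA`
#'   abundances are treated as absent with a warning.
#' @param thresholds A [ce_thresholds()] object.
#' @param strict Use strict `>` comparison (default, as the thresholds are
#'   defined); `FALSE` switches to `>=`.
#' @return Logical matrix (samples x 3) of presence calls with columns
#'   `stmn2_short`, `unc13a_ce1`, `unc13a_ce2`.
#' @examples
#' call_ce_presence(data.frame(stmn2_short_tpm = 2, unc13a_ce1_tpm = 0.1,
#'                             unc13a_ce2_tpm = 0.05))
#' @export
call_ce_presence <- function(abundances, thresholds = ce_thresholds(),
                             strict = TRUE) {
  stopifnot(inherits(thresholds, "ce_thresholds"))
  cols <- c("stmn2_short_tpm", "unc13a_ce1_tpm", "unc13a_ce2_tpm")
  ids <- NULL
  if (is.data.frame(abundances)) {
    if (!all(cols %in% names(abundances))) {
      stop("abundance table must contain columns: ",
           paste(cols, collapse = ", "))
    }
    if ("sample_id" %in% names(abundances)) ids <- abundances$sample_id
    ab <- as.matrix(abundances[, cols])
  } else {
    ab <- as.matrix(abundances)
    if (ncol(ab) != 3L) stop("expected three CE abundance columns")
    ids <- rownames(ab)
  }
  storage.mode(ab) <- "double"
  if (anyNA(ab)) {
    warning("missing CE abundance treated as absent for sample(s): ",
            paste(unique(if (is.null(ids)) which(rowSums(is.na(ab)) > 0)
                         else ids[rowSums(is.na(ab)) > 0]), collapse = ", "))
  }
  bad <- is.finite(ab) & ab < 0
  if (any(bad) || any(is.infinite(ab))) {
    off <- which(rowSums(bad | is.infinite(ab)) > 0)
    off <- if (is.null(ids)) off else ids[off]
    stop("negative or non-finite CE abundance for sample(s): ",
         paste(off, collapse = ", "))
  }
  th <- unlist(unclass(thresholds))
  calls <- if (strict) {
    sweep(ab, 2, th, ">")
  } else {
    sweep(ab, 2, th, ">=")
  }
  calls[is.na(calls)] <- FALSE
  colnames(calls) <- c("stmn2_short", "unc13a_ce1", "unc13a_ce2")
  rownames(calls) <- ids
  calls
}

#' Classify predicted TDP-43 pathology status from CE presence calls
#'
#' A sample expressing two or all three of the CE transcripts is predicted
#' TDP-43 pathology-positive; one or none, negative.
#'
#' @param calls Logical samples x 3 matrix from [call_ce_presence()].
#' @return A list with `status` (factor "negative"/"positive" per sample),
#'   `n_present` (0-3 per sample), `distribution` (named counts of samples
#'   with 0/1/2/3 CEs), `n_positive` and `positive_fraction`.
#' @examples
#' calls <- matrix(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), 2, 3)
#' classify_tdp43_status(calls)$status
#' @export
classify_tdp43_status <- function(calls) {
  calls <- as.matrix(calls)
  if (ncol(calls) != 3L || !is.logical(calls)) {
    stop("'calls' must be a logical samples x 3 matrix")
  }
  n_present <- rowSums(calls)
  status <- factor(ifelse(n_present >= 2, "positive", "negative"),
                   levels = c("negative", "positive"))
  names(status) <- rownames(calls)
  distribution <- stats::setNames(
    tabulate(n_present + 1L, nbins = 4L), as.character(0:3))
  list(status = status,
       n_present = stats::setNames(n_present, rownames(calls)),
       distribution = distribution,
       n_positive = sum(n_present >= 2),
       positive_fraction = mean(n_present >= 2))
}

#' Suggest a presence threshold from an abundance histogram
#'
#' Implements the dichotomisation heuristic "set the threshold above the
#' lowest non-zero peak": non-zero abundances are binned on the log10
#' scale (`n_bins` equal-width bins), bin counts are smoothed with a
#' zero-padded 3-bin moving average, and local maxima reaching at least
#' `max(1.2, min_peak_frac x tallest smoothed bin)` are accepted as peaks
#' (plateaus resolve to their leftmost bin; the height floor suppresses
#' spurious one- or two-count blips in sparse tails). The returned threshold is the abundance at the
#' minimum-count bin between the first (lowest-abundance) peak and the
#' next one. With fewer than two peaks the data are treated as unimodal:
#' the maximum non-zero value x 1.01 is returned with a warning, so that
#' every sample is called absent.
#'
#' @param values Non-negative abundance vector (TPM); needs at least 20
#'   non-zero values.
#' @param n_bins Number of histogram bins on the log10 scale.
#' @param min_peak_frac Minimum peak height as a fraction of the tallest
#'   bin.
#' @return Suggested threshold (TPM).
#' @export
suggest_threshold <- function(values, n_bins = 50L, min_peak_frac = 1/3) {
  values <- values[is.finite(values)]
  if (any(values < 0)) stop("abundances must be non-negative")
  nz <- values[values > 0]
  if (length(nz) < 20L) {
    stop("fewer than 20 non-zero values; use the fixed default thresholds ",
         "(ce_thresholds()) instead")
  }
  lx <- log10(nz)
  brk <- seq(min(lx), max(lx), length.out = n_bins + 1L)
  if (brk[1] == brk[n_bins + 1L]) {  # all non-zero values identical
    warning("degenerate abundance distribution; returning a threshold above ",
            "all values")
    return(max(nz) * 1.01)
  }
  h <- graphics::hist(lx, breaks = brk, plot = FALSE)
  counts <- h$counts
  padded <- c(0, counts, 0)  # zero-padded 3-bin moving average
  sm <- (padded[seq_len(n_bins)] + padded[2:(n_bins + 1L)] +
           padded[3:(n_bins + 2L)]) / 3
  height_floor <- max(1.2, min_peak_frac * max(sm))

  r <- rle(sm)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  is_peak <- logical(nr)
  for (k in seq_len(nr)) {
    left <- if (k == 1L) -Inf else r$values[k - 1L]
    right <- if (k == nr) -Inf else r$values[k + 1L]
    is_peak[k] <- r$values[k] > left && r$values[k] > right &&
      r$values[k] >= height_floor
  }
  peak_bins <- starts[is_peak]    # leftmost bin of each peak run
  peak_h <- r$values[is_peak]
  # prominence merge: sampling wiggles on the flank of one mode produce
  # candidate peak pairs whose intervening dip stays shallow; a genuine
  # between-mode valley drops below half the lower peak
  while (length(peak_bins) >= 2L) {
    dip <- vapply(seq_len(length(peak_bins) - 1L), function(k) {
      min(sm[peak_bins[k]:peak_bins[k + 1L]])
    }, numeric(1))
    shallow <- dip > 0.5 * pmin(peak_h[-length(peak_h)], peak_h[-1])
    if (!any(shallow)) break
    k <- which(shallow)[1L]
    drop_idx <- if (peak_h[k] >= peak_h[k + 1L]) k + 1L else k
    peak_bins <- peak_bins[-drop_idx]
    peak_h <- peak_h[-drop_idx]
  }
  if (length(peak_bins) < 2L) {
    warning("no interior valley found (unimodal abundance distribution); ",
            "returning a threshold above all values")
    return(max(nz) * 1.01)
  }
  lo <- peak_bins[1L]
  hi <- peak_bins[2L]
  between <- if (hi - lo >= 2L) (lo + 1L):(hi - 1L) else integer(0)
  if (length(between) == 0L) {
    warning("adjacent peaks leave no interior valley; returning a threshold ",
            "above all values")
    return(max(nz) * 1.01)
  }
  valley <- between[which.min(counts[between])]  # leftmost minimal bin
  10^h$mids[valley]
}

#' Genomic annotation records for the three cryptic exons
#'
#' The three CE intervals (hg38, stored 1-based inclusive as annotated):
#' UNC13A-CE1 chr19:17,642,414-17,642,541; UNC13A-CE2
#' chr19:17,642,414-17,642,591; STMN2 exon 2a chr8:79,616,822-79,617,048.
#'
#' @return A data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive), `transcript`, `gene`.
#' @export
build_ce_annotation <- function() {
  data.frame(
    chrom = c("chr19", "chr19", "chr8"),
    start = c(17642414L, 17642414L, 79616822L),
    end = c(17642541L, 17642591L, 79617048L),
    transcript = c("UNC13A-CE1", "UNC13A-CE2", "STMN2-short-exon2a"),
    gene = c("UNC13A", "UNC13A", "STMN2"),
    stringsAsFactors = FALSE)
}

#' Write the CE annotation as a BED6 file
#'
#' Converts the stored 1-based inclusive coordinates to BED's 0-based
#' half-open convention (start - 1, end) at serialisation time.
#'
#' @param annotation Data.frame from [build_ce_annotation()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_ce_bed <- function(annotation = build_ce_annotation(), path) {
  stopifnot(all(c("chrom", "start", "end", "transcript") %in%
                  names(annotation)))
  bed <- data.frame(chrom = annotation$chrom,
                    start = annotation$start - 1L,
                    end = annotation$end,
                    name = annotation$transcript,
                    score = 0L,
                    strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
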