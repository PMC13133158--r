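#' Read a gene x sample expression matrix from TSV
#'
#' Expects gene identifiers in the first column and sample identifiers in
#' the header. Duplicate gene rows and non-numeric cells are fatal errors
#' reported with their location; when `meta` is supplied, every metadata
#' sample must be present in the matrix.
#'
#' @param path TSV file path.
#' @param meta Optional metadata data.frame with a `sample_id` column to
#'   validate against.
#' @return Numeric genes x samples matrix.
#' @export
read_expression <- function(path, meta = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  genes <- df[[1]]
  dup <- unique(genes[duplicated(genes)])
  if (length(dup)) {
    stop("duplicated gene row(s): ", paste(utils::head(dup, 5),
                                           collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(m), nrow(m)))) & !is.na(m), arr.ind = TRUE)
    loc <- if (nrow(bad)) sprintf("gene %s, sample %s", genes[bad[1, 1]],
                                  colnames(m)[bad[1, 2]]) else "unknown cell"
    stop("non-numeric expression value at ", loc)
  }
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop(sprintf("missing expression value at gene %s, sample %s",
                 genes[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  rownames(m) <- genes
  if (!is.null(meta)) {
    missing <- setdiff(meta$sample_id, colnames(m))
    if (length(missing)) {
      stop("metadata sample(s) missing from the expression matrix: ",
           paste(missing, collapse = ", "))
    }
  }
  m
}

#' Write a gene x sample expression matrix as TSV
#'
#' @param expr Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_expression <- function(expr, path) {
  # 17 significant digits round-trip IEEE doubles exactly
  chr <- matrix(sprintf("%.17g", expr), nrow(expr),
                dimnames = dimnames(expr))
  df <- data.frame(gene = rownames(expr), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata (sample_id, braak, age, diagnosis) from TSV
#'
#' @param path TSV path.
#' @return Data.frame with at least the columns `sample_id`, `braak`,
#'   `age`, `diagnosis`.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "braak", "age", "diagnosis")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in metadata")
  df
}

#' Read a cryptic-exon abundance table from TSV
#'
#' @param path TSV with columns `sample_id`, `stmn2_short_tpm`,
#'   `unc13a_ce1_tpm`, `unc13a_ce2_tpm`.
#' @return Data.frame.
#' @export
read_ce_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "stmn2_short_tpm", "unc13a_ce1_tpm",
            "unc13a_ce2_tpm")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("CE table is missing column(s): ", paste(missing, collapse = ", "))
  }
  df
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then members. Duplicate members are collapsed with a warning; empty
#' sets are fatal.
#'
#' @param path GMT path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop("GMT set '", f[1], "' has no members")
    }
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (length(members) == 0L) stop("GMT set '", f[1], "' has no members")
    if (anyDuplicated(members)) {
      warning("duplicate member(s) in GMT set '", f[1], "' collapsed")
      members <- unique(members)
    }
    sets[[f[1]]] <- members
  }
  sets
}

#' Write gene sets as a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field written for every set.
#' @return The path, invisibly.
#' @export
write_gmt <- function(sets, path, description = "driadce") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a screen count table from TSV
#'
#' Expects columns `sgrna`, `gene`, then one integer column per
#' condition/replicate.
#'
#' @param path TSV path.
#' @return A list with `counts` (sgRNA x column matrix) and `guide_map`.
#' @export
read_screen_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sgrna", "gene") %in% names(df))) {
    stop("screen table must have 'sgrna' and 'gene' columns")
  }
  if (anyDuplicated(df$sgrna)) stop("duplicated sgRNA identifiers")
  m <- as.matrix(df[, setdiff(names(df), c("sgrna", "gene")), drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric count column(s)")
  rownames(m) <- df$sgrna
  list(counts = m,
       guide_map = data.frame(sgrna = df$sgrna, gene = df$gene,
                              stringsAsFactors = FALSE))
}

#' Write a screen count table as TSV
#'
#' @param screen List with `counts` and `guide_map` (see
#'   [generate_screen()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_screen_counts <- function(screen, path) {
  df <- data.frame(sgrna = rownames(screen$counts),
                   gene = screen$guide_map$gene[
                     match(rownames(screen$counts),
                           screen$guide_map$sgrna)],
                   screen$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
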