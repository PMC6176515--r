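# Reading count tables, median-of-ratios normalization, and per-guide
# log2 fold changes.

#' Read a guide count table
#'
#' Reads a delimited count table in the common screen layout: one header
#' row, first column the sgRNA id, second column the gene id, remaining
#' columns integer counts per sample. Guides whose gene field equals
#' `control_label` are flagged as negative controls.
#'
#' @param path path to a TSV (or CSV, by extension) count file.
#' @param control_label gene-column sentinel marking negative-control
#'   guides.
#' @return a `count_matrix`: list with `guide_id`, `gene_id`, `counts`
#'   (integer matrix, one row per guide), and `is_control`.
#' @export
read_count_table <- function(path, control_label = "negative_control") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 4) stop("need at least 2 sample columns")
  counts <- as.matrix(df[, -(1:2), drop = FALSE])
  count_matrix(guide_id = as.character(df[[1]]),
               gene_id = as.character(df[[2]]),
               counts = counts, control_label = control_label)
}

#' Construct a count matrix
#'
#' @param guide_id character vector of unique guide ids.
#' @param gene_id character vector of gene ids (or the control sentinel).
#' @param counts numeric matrix of non-negative integer counts, one row
#'   per guide, with sample names as column names.
#' @param control_label gene id sentinel for negative controls.
#' @return a validated `count_matrix` object.
#' @export
count_matrix <- function(guide_id, gene_id, counts,
                         control_label = "negative_control") {
  counts <- as.matrix(counts)
  if (anyDuplicated(guide_id)) stop("duplicate guide ids")
  if (length(guide_id) != nrow(counts) || length(gene_id) != nrow(counts)) {
    stop("guide_id, gene_id and counts must agree in length")
  }
  if (ncol(counts) < 2) stop("need at least 2 samples")
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  }
  rownames(counts) <- guide_id
  structure(
    list(guide_id = as.character(guide_id), gene_id = as.character(gene_id),
         counts = counts, is_control = gene_id == control_label,
         control_label = control_label),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", length(x$guide_id), "guides x",
      ncol(x$counts), "samples;",
      sum(x$is_control), "negative-control guides\n")
  invisible(x)
}

#' Write a count matrix to TSV
#'
#' Inverse of [read_count_table()]; the output is MAGeCK-compatible
#' (columns sgRNA, gene, then one per sample).
#'
#' @param x a `count_matrix`.
#' @param path output file path.
#' @export
write_count_table <- function(x, path) {
  df <- data.frame(sgRNA = x$guide_id, gene = x$gene_id,
                   x$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Median-of-ratios size factors
#'
#' Per-sample scale factors computed as the median, over guides with
#' strictly positive counts in every sample, of the ratio of the guide's
#' count to its across-sample geometric mean.
#'
#' @param counts numeric count matrix (guides x samples) or a
#'   `count_matrix`.
#' @return positive numeric vector of length `ncol(counts)`.
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) stop("no guide has nonzero counts in all samples")
  lc <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(lc)
  f <- apply(exp(lc - geo), 2, stats::median)
  stats::setNames(f, colnames(counts))
}

#' Per-guide log2 fold changes between two conditions
#'
#' Counts are divided by their median-of-ratios size factors, a
#' pseudocount is added, and per-replicate-pair log2 ratios
#' (condition_b over condition_a) are averaged into one log2 fold change
#' per guide. When the two conditions have unequal replicate numbers,
#' each sample of the smaller condition is paired with the mean of the
#' other condition's normalized counts.
#'
#' @param x a `count_matrix`.
#' @param condition_a column names or indices of the reference (e.g.
#'   initial) samples.
#' @param condition_b column names or indices of the comparison (e.g.
#'   final) samples.
#' @param pseudocount positive constant added to normalized counts before
#'   taking ratios; stabilizes low-count guides.
#' @return a `guide_table` data frame (guide, gene, lfc, control).
#' @export
compute_lfc <- function(x, condition_a, condition_b, pseudocount = 0.5) {
  stopifnot(inherits(x, "count_matrix"))
  if (length(condition_a) == 0 || length(condition_b) == 0) {
    stop("each condition needs at least one sample")
  }
  if (pseudocount <= 0) stop("'pseudocount' must be positive")
  f <- size_factors(x$counts)
  norm <- sweep(x$counts, 2, f, "/")
  a <- norm[, condition_a, drop = FALSE]
  b <- norm[, condition_b, drop = FALSE]
  # pair replicates; collapse the larger condition to its mean if unequal
  if (ncol(a) != ncol(b)) {
    if (ncol(a) < ncol(b)) b <- rowMeans(b) else a <- rowMeans(a)
  }
  a <- as.matrix(a); b <- as.matrix(b)
  npair <- max(ncol(a), ncol(b))
  a <- a[, rep_len(seq_len(ncol(a)), npair), drop = FALSE]
  b <- b[, rep_len(seq_len(ncol(b)), npair), drop = FALSE]
  lfc <- rowMeans(log2((b + pseudocount) / (a + pseudocount)))
  guide_table(guide = x$guide_id, gene = x$gene_id, lfc = lfc,
              control = x$is_control)
}

#' Construct a guide table
#'
#' The canonical per-guide record used by the modelling functions: guide
#' id, gene id, log2 fold change, and a negative-control flag. Controls
#' are used for null fitting and excluded from gene scoring.
#'
#' @param guide character vector of unique guide ids.
#' @param gene character vector of gene ids.
#' @param lfc finite numeric log2 fold changes.
#' @param control logical negative-control flags.
#' @return a data frame of class `c("guide_table", "data.frame")`.
#' @export
guide_table <- function(guide, gene, lfc, control = FALSE) {
  n <- length(lfc)
  control <- rep_len(as.logical(control), n)
  if (anyDuplicated(guide)) stop("duplicate guide ids")
  if (any(!is.finite(lfc))) stop("non-finite log2 fold changes")
  if (all(control)) stop("no gene-targeting guides present")
  structure(
    data.frame(guide = as.character(guide), gene = as.character(gene),
               lfc = as.numeric(lfc), control = control,
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("guide_table", "data.frame")
  )
}

#' Read a precomputed log2 fold change table
#'
#' For screens where raw counts are unavailable, a four-column TSV
#' (sgRNA, gene, lfc, is_control) can be supplied directly.
#'
#' @param path path to the TSV file.
#' @param control_label guides whose gene equals this label are also
#'   flagged as controls, in addition to any is_control column.
#' @return a `guide_table`.
#' @export
read_guide_table <- function(path, control_label = "negative_control") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  ctrl <- df[[2]] == control_label
  if (ncol(df) >= 4) ctrl <- ctrl | as.logical(df[[4]])
  guide_table(guide = df[[1]], gene = df[[2]], lfc = as.numeric(df[[3]]),
              control = ctrl)
}

#' Write a guide table to TSV
#'
#' @param x a `guide_table`.
#' @param path output file path.
#' @export
write_guide_table <- function(x, path) {
  df <- data.frame(sgRNA = x$guide, gene = x$gene, lfc = x$lfc,
                   is_control = x$control)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
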