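# Per-gene Mann-Whitney test against the negative controls, with
# Benjamini-Hochberg correction: the standard baseline gene-scoring
# strategy for screens with non-targeting controls.
#
# mw_screen computes all U statistics against the shared control sample in
# one vectorized pass (rank counting against the sorted controls), then
# obtains p values from the exact Wilcoxon distribution (stats::pwilcox)
# for small tie-free genes or the tie- and continuity-corrected normal
# approximation otherwise. stats::wilcox.test gives identical p values
# gene by gene but rebuilds the exact null distribution on every call,
# which is prohibitive across thousands of genes sharing one control set.

# U statistic of x against y with half credit for ties, plus tie bookkeeping
mw_u_stat <- function(x, sorted_y) {
  n_le <- findInterval(x, sorted_y)                    # y <= x
  n_lt <- findInterval(x, sorted_y, left.open = TRUE)  # y <  x
  u <- sum(n_lt) + 0.5 * sum(n_le - n_lt)
  list(u = u, ties = any(n_le != n_lt) || anyDuplicated(x) > 0)
}

mw_p_value <- function(u, n, m, ties, tie_vector,
                       alternative = c("less", "greater", "two.sided")) {
  alternative <- match.arg(alternative)
  exact <- !ties && min(n, m) <= 8
  if (exact) {
    switch(alternative,
      less = stats::pwilcox(u, n, m),
      greater = stats::pwilcox(n * m - u, n, m),
      two.sided = min(1, 2 * min(stats::pwilcox(u, n, m),
                                 stats::pwilcox(n * m - u, n, m)))
    )
  } else {
    nm <- n + m
    tie_term <- if (is.null(tie_vector)) 0 else {
      tab <- table(tie_vector)
      sum(tab^3 - tab) / (nm * (nm - 1))
    }
    sigma <- sqrt(n * m / 12 * (nm + 1 - tie_term))
    mu <- n * m / 2
    switch(alternative,
      less = stats::pnorm(u - mu + 0.5, sd = sigma),
      greater = stats::pnorm(-(u - mu - 0.5), sd = sigma),
      two.sided = {
        z <- u - mu
        min(1, 2 * stats::pnorm(-(abs(z) - 0.5), sd = sigma))
      }
    )
  }
}

#' Mann-Whitney test of one gene's guides against the controls
#'
#' One-sided by default: `direction = "depleted"` tests whether the
#' gene's guide log2 fold changes are stochastically smaller than the
#' controls'. The exact Wilcoxon distribution is used when the smaller
#' sample has at most 8 observations and there are no ties; otherwise the
#' normal approximation with tie and continuity corrections.
#'
#' @param x numeric vector of the gene's guide log2 fold changes.
#' @param controls numeric vector of negative-control log2 fold changes,
#'   at least 2.
#' @param direction `"depleted"`, `"enriched"`, or `"two.sided"`.
#' @return list with `statistic` (U of x versus controls) and `p.value`.
#' @export
mw_test <- function(x, controls, direction = c("depleted", "enriched",
                                               "two.sided")) {
  direction <- match.arg(direction)
  if (length(x) < 1) stop("gene has no guides")
  if (length(controls) < 2) stop("need at least 2 control guides")
  sy <- sort(controls)
  st <- mw_u_stat(x, sy)
  alt <- switch(direction, depleted = "less", enriched = "greater",
                two.sided = "two.sided")
  tie_vec <- if (st$ties) c(x, controls) else NULL
  p <- mw_p_value(st$u, length(x), length(controls), st$ties, tie_vec, alt)
  list(statistic = st$u, p.value = p)
}

#' Benjamini-Hochberg adjusted FDRs
#'
#' Step-up adjustment `q_(i) = min_{j >= i} m p_(j) / j`, via
#' [stats::p.adjust()].
#'
#' @param p numeric vector of p values.
#' @return adjusted values on the same order as the input.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Mann-Whitney screen baseline
#'
#' Applies [mw_test()] to every gene against the shared negative-control
#' set and BH-adjusts the p values across genes.
#'
#' @param guides a `guide_table` containing negative-control guides.
#' @param direction as in [mw_test()].
#' @return data frame with columns `gene`, `U`, `p`, `bh_fdr`, sorted by
#'   ascending p (ties broken by gene id).
#' @export
mw_screen <- function(guides, direction = c("depleted", "enriched",
                                            "two.sided")) {
  direction <- match.arg(direction)
  ctrl <- guides$lfc[guides$control]
  if (length(ctrl) < 2) stop("need at least 2 negative-control guides")
  gt <- guides[!guides$control, , drop = FALSE]
  sy <- sort(ctrl)
  m <- length(sy)
  gene <- factor(gt$gene)
  x <- gt$lfc
  n_le <- findInterval(x, sy)
  n_lt <- findInterval(x, sy, left.open = TRUE)
  u <- rowsum(n_lt + 0.5 * (n_le - n_lt), gene)[, 1]
  n <- as.integer(table(gene))
  ties_ctrl <- n_le != n_lt
  has_ties <- as.logical(rowsum(as.numeric(ties_ctrl), gene)[, 1] > 0) |
    tapply(x, gene, anyDuplicated) > 0
  alt <- switch(direction, depleted = "less", enriched = "greater",
                two.sided = "two.sided")
  p <- numeric(nlevels(gene))
  exact <- !has_ties & pmin(n, m) <= 8
  # exact p values share the null distribution within each gene size
  for (nn in unique(n[exact])) {
    idx <- exact & n == nn
    p[idx] <- switch(alt,
      less = stats::pwilcox(u[idx], nn, m),
      greater = stats::pwilcox(nn * m - u[idx], nn, m),
      two.sided = pmin(1, 2 * pmin(stats::pwilcox(u[idx], nn, m),
                                   stats::pwilcox(nn * m - u[idx], nn, m)))
    )
  }
  for (i in which(!exact)) {
    gl <- x[as.integer(gene) == i]
    p[i] <- mw_p_value(u[i], n[i], m, TRUE, c(gl, ctrl), alt)
  }
  out <- data.frame(gene = levels(gene), U = unname(u), p = p,
                    bh_fdr = bh_adjust(p), stringsAsFactors = FALSE,
                    row.names = NULL)
  out[order(out$p, out$gene), , drop = FALSE]
}
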