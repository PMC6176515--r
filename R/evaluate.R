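# Benchmarking: ROC-AUC, TPR and empirical FDR at an estimated-FDR
# threshold, and a grid harness running the mixture model and the
# Mann-Whitney baseline over simulated screens.

#' Area under the ROC curve
#'
#' Rank-based AUC: the probability that a randomly chosen positive
#' receives a better (higher) score than a randomly chosen negative, with
#' half credit for ties.
#'
#' @param score numeric scores, larger = more likely positive. For local
#'   fdrs or adjusted p values pass their negation.
#' @param truth 0/1 (or logical) labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(score, truth) {
  truth <- as.logical(truth)
  if (!any(truth) || all(truth)) stop("both classes must be present")
  r <- rank(score) # midranks give half credit for ties
  n1 <- sum(truth)
  n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' TPR and empirical FDR of a call set
#'
#' @param called logical vector: which genes were called.
#' @param truth 0/1 (or logical) true labels, aligned with `called`.
#' @return list with `tpr` (called true / total true) and `emp_fdr`
#'   (called null / called; `NA` when nothing is called).
#' @export
tpr_emp_fdr <- function(called, truth) {
  truth <- as.logical(truth)
  called <- as.logical(called)
  tpr <- sum(called & truth) / sum(truth)
  emp_fdr <- if (any(called)) sum(called & !truth) / sum(called) else NA_real_
  list(tpr = tpr, emp_fdr = emp_fdr)
}

# run one method on one simulated screen; returns auc/tpr/emp_fdr
run_method_once <- function(method, sim, fdr = 0.1) {
  truth <- sim$truth$genes
  if (method == "hiermix") {
    fit <- screenmix(sim$guides)
    sc <- fit$genes
    truth_ord <- truth$interesting[match(sc$gene, truth$gene)]
    called <- fdr_calls(sc$locfdr, fdr)
    auc <- roc_auc(-sc$locfdr, truth_ord)
  } else if (method == "mw") {
    sc <- mw_screen(sim$guides, direction = "depleted")
    truth_ord <- truth$interesting[match(sc$gene, truth$gene)]
    called <- sc$bh_fdr <= fdr
    auc <- roc_auc(-sc$p, truth_ord)
  } else {
    stop("unknown method: ", method)
  }
  cf <- tpr_emp_fdr(called, truth_ord)
  data.frame(method = method, auc = auc, tpr = cf$tpr,
             emp_fdr = cf$emp_fdr, n_called = sum(called),
             stringsAsFactors = FALSE)
}

#' Benchmark methods over a grid of simulated screens
#'
#' Simulates `n_reps` fully simulated screens per (efficiency, guides per
#' gene) cell, runs each method, and aggregates mean ROC-AUC, TPR at the
#' estimated global FDR threshold, and empirical FDR.
#'
#' @param methods character vector among `"hiermix"`, `"mw"`.
#' @param efficiency numeric vector of effective-guide probabilities.
#' @param guides_per_gene integer vector of guides per gene.
#' @param n_reps replicates per grid cell.
#' @param n_genes_null,n_genes_pos,n_controls screen dimensions, passed
#'   to [simulate_screen()].
#' @param fdr estimated global FDR threshold for calling.
#' @param seed integer seed; each replicate gets a derived sub-seed so
#'   the grid is reproducible.
#' @param verbose print per-cell progress to stderr.
#' @return data frame with one row per method x grid cell: mean `auc`,
#'   `tpr`, `emp_fdr` (over replicates with at least one call), mean
#'   `n_called`, and `n_reps`.
#' @export
benchmark_grid <- function(methods = c("hiermix", "mw"),
                           efficiency = 0.95,
                           guides_per_gene = c(3, 5, 10),
                           n_reps = 10, n_genes_null = 5000,
                           n_genes_pos = 500, n_controls = 1000,
                           fdr = 0.1, seed = 1, verbose = FALSE) {
  grid <- expand.grid(efficiency = efficiency,
                      guides_per_gene = guides_per_gene)
  set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max - 1,
                                 nrow(grid) * n_reps),
                      nrow = nrow(grid))
  out <- list()
  for (i in seq_len(nrow(grid))) {
    cell <- lapply(seq_len(n_reps), function(r) {
      sim <- simulate_screen(n_genes_null = n_genes_null,
                             n_genes_pos = n_genes_pos,
                             guides_per_gene = grid$guides_per_gene[i],
                             efficiency = grid$efficiency[i],
                             n_controls = n_controls,
                             seed = rep_seeds[i, r])
      do.call(rbind, lapply(methods, run_method_once, sim = sim,
                            fdr = fdr))
    })
    cell <- do.call(rbind, cell)
    agg <- do.call(rbind, lapply(split(cell, cell$method), function(d) {
      data.frame(method = d$method[1],
                 efficiency = grid$efficiency[i],
                 guides_per_gene = grid$guides_per_gene[i],
                 auc = mean(d$auc), tpr = mean(d$tpr),
                 emp_fdr = mean(d$emp_fdr, na.rm = TRUE),
                 n_called = mean(d$n_called), n_reps = n_reps,
                 stringsAsFactors = FALSE)
    }))
    if (verbose) {
      message(sprintf("cell %d/%d: eff=%.2f guides=%d done", i,
                      nrow(grid), grid$efficiency[i],
                      grid$guides_per_gene[i]))
    }
    out[[i]] <- agg
  }
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  res
}
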