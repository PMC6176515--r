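# Synthetic screen generators with ground-truth labels.
#
# Two generative models:
#  * simulate_screen: fully simulated guide-level log2 fold changes.
#    Null genes' guides (and ineffective guides of interesting genes)
#    follow a broad-tailed skew-t null; each interesting gene draws an
#    effect size from Normal(-3, 0.75^2) and each of its guides is
#    effective with probability `efficiency`, in which case its LFC is
#    Normal(gene effect, 1^2). Negative-control guides are extra draws
#    from the null.
#  * simulate_semisim: count-level simulation of null genes from an
#    observed (or synthetic) negative-control count matrix; guides per
#    gene ~ NB(mu = 67.8, size = 26.3), counts ~ NB(mean = the sampled
#    control guide's counts, size = 200), with 3 null genes per positive
#    gene so that the positive fraction is 0.25.

#' Fully simulated screen
#'
#' @param n_genes_null number of null genes.
#' @param n_genes_pos number of interesting (positive) genes.
#' @param guides_per_gene guides per gene (integer >= 1).
#' @param efficiency probability that a guide of an interesting gene is
#'   effective, in \[0, 1\].
#' @param n_controls number of negative-control guides drawn from the
#'   null.
#' @param null_params skew-t null parameters as a list (xi, omega, alpha,
#'   nu).
#' @param gene_effect_mean,gene_effect_sd normal distribution of
#'   interesting-gene effect sizes (log2FC units).
#' @param guide_noise_sd standard deviation of effective-guide LFCs
#'   around their gene effect.
#' @param seed optional integer seed.
#' @return list with `guides` (a `guide_table`) and `truth` (list of
#'   per-gene `genes`: gene, interesting; and per-guide `guide_effective`
#'   indicators, zero for all guides of null genes).
#' @export
simulate_screen <- function(n_genes_null = 5000, n_genes_pos = 500,
                            guides_per_gene = 10, efficiency = 0.95,
                            n_controls = 1000,
                            null_params = list(xi = 0, omega = 1,
                                               alpha = -1.5, nu = 6),
                            gene_effect_mean = -3, gene_effect_sd = 0.75,
                            guide_noise_sd = 1, seed = NULL) {
  if (efficiency < 0 || efficiency > 1) stop("efficiency must be in [0, 1]")
  if (guides_per_gene < 1) stop("guides_per_gene must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  rnull <- function(m) {
    rskewt(m, null_params$xi, null_params$omega, null_params$alpha,
           null_params$nu)
  }
  g <- guides_per_gene
  gene_ids <- c(
    if (n_genes_null > 0) sprintf("null_%04d", seq_len(n_genes_null)),
    if (n_genes_pos > 0) sprintf("pos_%04d", seq_len(n_genes_pos))
  )
  z <- c(rep(0L, n_genes_null), rep(1L, n_genes_pos))
  gene_of_guide <- rep(gene_ids, each = g)
  y <- integer(length(gene_of_guide))
  lfc <- numeric(length(gene_of_guide))
  null_idx <- seq_len(n_genes_null * g)
  lfc[null_idx] <- rnull(length(null_idx))
  if (n_genes_pos > 0) {
    effects <- stats::rnorm(n_genes_pos, gene_effect_mean, gene_effect_sd)
    pos_idx <- n_genes_null * g + seq_len(n_genes_pos * g)
    eff <- stats::runif(length(pos_idx)) < efficiency
    y[pos_idx] <- as.integer(eff)
    mu_guide <- rep(effects, each = g)
    lfc[pos_idx[eff]] <- stats::rnorm(sum(eff), mu_guide[eff],
                                      guide_noise_sd)
    lfc[pos_idx[!eff]] <- rnull(sum(!eff))
  }
  guides <- guide_table(
    guide = c(paste0(gene_of_guide, "_sg",
                     rep(seq_len(g), times = length(gene_ids))),
              sprintf("ctrl_sg%05d", seq_len(n_controls))),
    gene = c(gene_of_guide, rep("negative_control", n_controls)),
    lfc = c(lfc, rnull(n_controls)),
    control = c(rep(FALSE, length(lfc)), rep(TRUE, n_controls))
  )
  list(guides = guides,
       truth = list(genes = data.frame(gene = gene_ids, interesting = z,
                                       stringsAsFactors = FALSE),
                    guide_effective = c(y, rep(0L, n_controls))))
}

#' Synthetic negative-control count matrix
#'
#' A stand-in for an observed control count table when none is supplied:
#' per-guide baseline abundances are log-normal across guides, and each
#' sample's counts are negative binomial around that baseline. Labelled
#' synthetic: it mimics library-size and overdispersion structure only.
#'
#' @param n_guides number of control guides.
#' @param n_samples number of samples (columns).
#' @param mean_count mean sequencing depth per guide.
#' @param seed optional integer seed.
#' @return integer matrix `n_guides` x `n_samples`.
#' @export
synthetic_control_counts <- function(n_guides = 1000, n_samples = 2,
                                     mean_count = 400, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- stats::rlnorm(n_guides, log(mean_count) - 0.125, 0.5)
  counts <- matrix(stats::rnbinom(n_guides * n_samples,
                                  mu = rep(base, n_samples), size = 10),
                   nrow = n_guides)
  colnames(counts) <- paste0("sample", seq_len(n_samples))
  counts
}

#' Semi-simulated screen at the count level
#'
#' Null genes are simulated from an observed negative-control count
#' matrix: the number of guides per gene is drawn from a negative
#' binomial (mu = 67.8, size = 26.3; zero draws redrawn), and each
#' simulated guide copies a randomly sampled control guide, with counts
#' drawn per sample as NB(mean = that control guide's observed count,
#' size = 200). Positive-gene counts may be supplied (e.g. from a real
#' screen) or generated synthetically with depleted final-sample means;
#' by default 3 null genes are generated per positive gene so that the
#' positive fraction is 0.25.
#'
#' @param control_counts matrix of observed negative-control counts
#'   (guides x samples); `NULL` for a synthetic stand-in.
#' @param positive_counts optional list with `gene_id` and `counts`
#'   (matrix) for the positive genes; `NULL` generates synthetic
#'   positives.
#' @param n_pos_genes number of synthetic positive genes when
#'   `positive_counts` is `NULL`.
#' @param null_per_pos null genes generated per positive gene.
#' @param guides_mu,guides_size negative binomial parameters for guides
#'   per simulated null gene.
#' @param count_size negative binomial size for simulated counts.
#' @param depletion_lfc mean log2 depletion of synthetic positive genes'
#'   final-sample counts.
#' @param pos_efficiency fraction of synthetic positive-gene guides that
#'   actually deplete.
#' @param seed optional integer seed.
#' @return list with `counts` (a `count_matrix`; samples `initial`,
#'   `final`) and `truth` (per-gene data frame: gene, interesting).
#' @export
simulate_semisim <- function(control_counts = NULL, positive_counts = NULL,
                             n_pos_genes = 33, null_per_pos = 3,
                             guides_mu = 67.8, guides_size = 26.3,
                             count_size = 200, depletion_lfc = -2,
                             pos_efficiency = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(control_counts)) {
    control_counts <- synthetic_control_counts(1000, 2)
  }
  control_counts <- as.matrix(control_counts)
  if (nrow(control_counts) == 0) stop("empty control counts")
  ns <- ncol(control_counts)
  draw_guides_per_gene <- function(k) {
    out <- stats::rnbinom(k, mu = guides_mu, size = guides_size)
    while (any(out == 0)) {
      out[out == 0] <- stats::rnbinom(sum(out == 0), mu = guides_mu,
                                      size = guides_size)
    }
    out
  }
  if (is.null(positive_counts)) {
    npos_guides <- draw_guides_per_gene(n_pos_genes)
    pos_gene <- rep(sprintf("pos_%03d", seq_len(n_pos_genes)), npos_guides)
    base <- control_counts[sample.int(nrow(control_counts),
                                      length(pos_gene), replace = TRUE), ,
                           drop = FALSE]
    eff <- stats::runif(length(pos_gene)) < pos_efficiency
    dep <- ifelse(eff, 2^depletion_lfc, 1)
    pos <- matrix(0L, length(pos_gene), ns)
    # deplete the later half of the samples (the "final" condition)
    final <- seq_len(ns) > ns / 2
    for (s in seq_len(ns)) {
      mu_s <- base[, s] * if (final[s]) dep else 1
      pos[, s] <- stats::rnbinom(length(pos_gene), mu = pmax(mu_s, 0.1),
                                 size = count_size)
    }
    positive_counts <- list(gene_id = pos_gene, counts = pos)
  }
  n_pos <- length(unique(positive_counts$gene_id))
  n_null <- null_per_pos * n_pos
  nguides <- draw_guides_per_gene(n_null)
  null_gene <- rep(sprintf("nullsim_%04d", seq_len(n_null)), nguides)
  src <- sample.int(nrow(control_counts), length(null_gene), replace = TRUE)
  null_cnt <- matrix(0L, length(null_gene), ns)
  for (s in seq_len(ns)) {
    null_cnt[, s] <- stats::rnbinom(length(null_gene),
                                    mu = pmax(control_counts[src, s], 0.1),
                                    size = count_size)
  }
  counts <- rbind(positive_counts$counts, null_cnt, control_counts)
  colnames(counts) <- if (ns == 2) c("initial", "final") else
    paste0(rep(c("initial", "final"), each = ns / 2), "_",
           rep(seq_len(ceiling(ns / 2)), 2))[seq_len(ns)]
  gene <- c(positive_counts$gene_id, null_gene,
            rep("negative_control", nrow(control_counts)))
  cm <- count_matrix(
    guide_id = sprintf("sg%06d", seq_along(gene)),
    gene_id = gene, counts = counts
  )
  genes <- unique(data.frame(
    gene = c(positive_counts$gene_id, null_gene),
    interesting = c(rep(1L, length(positive_counts$gene_id)),
                    rep(0L, length(null_gene))),
    stringsAsFactors = FALSE))
  list(counts = cm, truth = list(genes = genes))
}

#' Downsample a library to a target average guides per gene
#'
#' Per replicate, guides are sampled without replacement within each gene
#' so that the average number of guides per gene across the library hits
#' the target; negative-control guides are always retained in full.
#'
#' @param guides a `guide_table`.
#' @param target_mean_guides target average guides per gene; must not
#'   exceed the current average.
#' @param n_reps number of downsampled replicates.
#' @param seed optional integer seed.
#' @return list of `guide_table`s, one per replicate.
#' @export
downsample_library <- function(guides, target_mean_guides, n_reps = 1,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gt <- guides[!guides$control, , drop = FALSE]
  sizes <- table(gt$gene)
  cur_mean <- mean(sizes)
  if (target_mean_guides > cur_mean) {
    stop("target exceeds the current average guides per gene")
  }
  frac <- target_mean_guides / cur_mean
  ctrl <- guides[guides$control, , drop = FALSE]
  lapply(seq_len(n_reps), function(r) {
    keep <- unlist(lapply(split(seq_len(nrow(gt)), gt$gene), function(idx) {
      k <- floor(length(idx) * frac)
      k <- k + (stats::runif(1) < length(idx) * frac - k)
      sample(idx, max(k, 1))
    }), use.names = FALSE)
    out <- rbind(gt[sort(keep), , drop = FALSE], ctrl)
    guide_table(out$guide, out$gene, out$lfc, out$control)
  })
}
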