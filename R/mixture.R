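# Hierarchical two-groups mixture at the guide level.
#
# Genes are null or interesting; guides of interesting genes are effective
# with probability q, and only effective guides follow the alternative
# distribution f1. p (fraction of interesting genes) and q are not
# separately identifiable from the marginal guide mixture, but tau = p * q
# is: marginally each guide arises from f1 with probability tau. The EM
# below estimates (tau, f1) with f0 fixed from negative controls (or
# jointly estimated as a normal when no controls exist); gene scores then
# marginalize q over a prior.

logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  # both -Inf: pmax gives -Inf and the sum is NaN; fix to -Inf
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# log f1 for the fitted alternative (unimodal or bimodal normal)
f1_logdens <- function(f1, x) {
  if (is.null(f1$lambda)) {
    stats::dnorm(x, f1$mu, f1$sigma, log = TRUE)
  } else {
    logaddexp(log(f1$lambda) + stats::dnorm(x, f1$mu_neg, f1$sigma_neg,
                                            log = TRUE),
              log1p(-f1$lambda) + stats::dnorm(x, f1$mu_pos, f1$sigma_pos,
                                               log = TRUE))
  }
}

#' Fit the marginal guide-level mixture by EM
#'
#' Estimates tau (the probability that a random guide arises from the
#' alternative distribution) and the normal alternative f1 from
#' gene-targeting guide log2 fold changes, treating each guide as an
#' independent draw from `(1 - tau) f0 + tau f1`. `f0` is either fixed
#' (fit from negative controls) or, when `null_fit = NULL`, estimated as a
#' normal alongside f1.
#'
#' @param x numeric vector of gene-targeting guide log2 fold changes,
#'   oriented so that the direction of interest is negative (depletion).
#' @param null_fit a `screenmix_null` object, or `NULL` to estimate a
#'   normal null jointly.
#' @param f1_mode `"unimodal"` (one normal constrained to the negative
#'   side) or `"bimodal"` (two normals, one on each side of zero, for
#'   bidirectional phenotypes).
#' @param tau_init initial mixing proportion.
#' @param tol convergence tolerance on the change in log likelihood.
#' @param max_iter maximum EM iterations.
#' @return an object of class `screenmix_mixture`: `tau`, `f1` (list of
#'   normal parameters), `f0` (the null fit, possibly EM-estimated),
#'   `responsibilities` (per-guide posterior Pr(guide from f1)),
#'   `trace` (log likelihood per iteration), `converged`, `iterations`.
#' @export
em_mixture <- function(x, null_fit = NULL,
                       f1_mode = c("unimodal", "bimodal"),
                       tau_init = 0.1, tol = 1e-6, max_iter = 1000) {
  f1_mode <- match.arg(f1_mode)
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("non-finite log2 fold changes")
  n <- length(x)
  if (n < 100) warning("fewer than 100 gene-targeting guides; ",
                       "mixture estimates may be unstable")
  estimate_f0 <- is.null(null_fit)
  if (estimate_f0) {
    f0p <- list(mean = mean(x), sd = stats::sd(x))
    lf0 <- stats::dnorm(x, f0p$mean, f0p$sd, log = TRUE)
  } else {
    lf0 <- null_logdens(null_fit, x)
  }
  tau <- tau_init
  # SD of a tail decile, falling back to the overall SD for tiny samples
  tail_sd <- function(keep) {
    s <- stats::sd(x[keep])
    if (!is.finite(s) || s == 0) s <- stats::sd(x)
    max(s, 0.25)
  }
  low <- x <= stats::quantile(x, 0.1)
  if (f1_mode == "unimodal") {
    f1 <- list(mu = unname(stats::quantile(x, 0.05)),
               sigma = tail_sd(low))
  } else {
    hi <- x >= stats::quantile(x, 0.9)
    f1 <- list(lambda = 0.5,
               mu_neg = unname(stats::quantile(x, 0.05)),
               sigma_neg = tail_sd(low),
               mu_pos = unname(stats::quantile(x, 0.95)),
               sigma_pos = tail_sd(hi))
  }
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  boundary_warned <- FALSE
  for (it in seq_len(max_iter)) {
    lf1 <- f1_logdens(f1, x)
    la <- log(tau) + lf1
    lb <- log1p(-tau) + lf0
    ll <- sum(logaddexp(la, lb))
    trace <- c(trace, ll)
    r <- stats::plogis(la - lb) # Pr(W_i = 1 | x_i)
    tau <- mean(r)
    if (tau < 1e-4 || tau > 1 - 1e-4) {
      if (!boundary_warned) {
        warning("tau collapsed to the boundary; clamped")
        boundary_warned <- TRUE
      }
      tau <- min(max(tau, 1e-4), 1 - 1e-4)
    }
    if (f1_mode == "unimodal") {
      sw <- sum(r)
      mu <- sum(r * x) / sw
      f1$mu <- min(mu, -1e-8) # depletion-side constraint
      f1$sigma <- max(sqrt(sum(r * (x - f1$mu)^2) / sw), 1e-3)
    } else {
      lneg <- log(f1$lambda) +
        stats::dnorm(x, f1$mu_neg, f1$sigma_neg, log = TRUE)
      lpos <- log1p(-f1$lambda) +
        stats::dnorm(x, f1$mu_pos, f1$sigma_pos, log = TRUE)
      wneg <- r * stats::plogis(lneg - lpos)
      wpos <- r - wneg
      f1$lambda <- min(max(sum(wneg) / sum(r), 1e-4), 1 - 1e-4)
      f1$mu_neg <- min(sum(wneg * x) / sum(wneg), -1e-8)
      f1$sigma_neg <- max(sqrt(sum(wneg * (x - f1$mu_neg)^2) / sum(wneg)),
                          1e-3)
      f1$mu_pos <- max(sum(wpos * x) / sum(wpos), 1e-8)
      f1$sigma_pos <- max(sqrt(sum(wpos * (x - f1$mu_pos)^2) / sum(wpos)),
                          1e-3)
    }
    if (estimate_f0) {
      r0 <- 1 - r
      f0p$mean <- sum(r0 * x) / sum(r0)
      f0p$sd <- max(sqrt(sum(r0 * (x - f0p$mean)^2) / sum(r0)), 1e-3)
      lf0 <- stats::dnorm(x, f0p$mean, f0p$sd, log = TRUE)
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  f0_out <- if (estimate_f0) {
    new_null_fit("normal", f0p,
                 loglik = sum(stats::dnorm(x, f0p$mean, f0p$sd, log = TRUE)),
                 n = n)
  } else {
    null_fit
  }
  structure(
    list(tau = tau, f1 = f1, f0 = f0_out, f1_mode = f1_mode,
         f0_estimated = estimate_f0,
         responsibilities = stats::plogis(
           (log(tau) + f1_logdens(f1, x)) - (log1p(-tau) + lf0)),
         trace = trace, converged = converged, iterations = length(trace)),
    class = "screenmix_mixture"
  )
}

#' @export
print.screenmix_mixture <- function(x, ...) {
  cat("Guide-level mixture fit: tau =", signif(x$tau, 4), "\n")
  cat("  f1:", paste(names(x$f1), signif(unlist(x$f1), 4),
                     sep = " = ", collapse = ", "), "\n")
  cat("  f0:", x$f0$family, if (x$f0_estimated) "(EM-estimated)" else
      "(fixed from controls)", "\n")
  cat("  EM:", x$iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged", "\n")
  invisible(x)
}

#' Prior on guide efficiency q
#'
#' The efficiency q (probability that a guide of an interesting gene is
#' effective) is not identifiable and is marginalized out of the gene
#' posterior over a prior. The prior's support cannot extend below tau,
#' since q < tau would imply a fraction of interesting genes above 1.
#'
#' @param kind `"uniform"` (uniform on \[lower, 1\]), `"point"` (point
#'   mass), or `"grid"` (user-supplied nodes and weights).
#' @param lower lower support bound for the uniform prior; `NULL` means
#'   `max(tau, 0.01)`, resolved at scoring time.
#' @param at location of the point mass.
#' @param nodes,weights nodes in (0, 1\] and non-negative weights for a
#'   discrete prior; weights are normalized to sum to 1.
#' @return an object of class `q_prior`.
#' @export
q_prior <- function(kind = c("uniform", "point", "grid"), lower = NULL,
                    at = 1, nodes = NULL, weights = NULL) {
  kind <- match.arg(kind)
  if (kind == "grid") {
    if (is.null(nodes) || is.null(weights) ||
        length(nodes) != length(weights)) {
      stop("grid prior needs matching nodes and weights")
    }
    if (any(nodes <= 0) || any(nodes > 1)) stop("nodes must lie in (0, 1]")
    if (any(weights < 0)) stop("weights must be non-negative")
    weights <- weights / sum(weights)
  }
  if (kind == "point" && (at <= 0 || at > 1)) stop("'at' must be in (0, 1]")
  structure(list(kind = kind, lower = lower, at = at, nodes = nodes,
                 weights = weights),
            class = "q_prior")
}

# resolve a q_prior into quadrature nodes q and weights w (sum(w) = 1)
resolve_q_prior <- function(prior, tau, n_nodes = 100) {
  if (is.null(prior)) prior <- q_prior("uniform")
  stopifnot(inherits(prior, "q_prior"))
  switch(prior$kind,
    uniform = {
      lo <- if (is.null(prior$lower)) max(tau, 0.01) else prior$lower
      if (lo < tau) stop("q prior support below tau would imply p > 1")
      if (lo >= 1) stop("uniform prior support is empty")
      gl <- pracma::gaussLegendre(n_nodes, lo, 1)
      list(q = gl$x, w = gl$w / (1 - lo))
    },
    point = {
      if (prior$at < tau) stop("q prior support below tau would imply p > 1")
      list(q = prior$at, w = 1)
    },
    grid = {
      if (min(prior$nodes) < tau) {
        stop("q prior support below tau would imply p > 1")
      }
      list(q = prior$nodes, w = prior$weights)
    }
  )
}

# Vectorized gene posteriors.
# lf0, lf1: per-guide log densities; gene: factor of gene ids.
# Returns named vector of posterior interesting probabilities per gene.
gene_posterior_all <- function(lf0, lf1, gene, tau, q, w) {
  gene <- factor(gene)
  s0 <- rowsum(lf0, gene)[, 1]
  post <- numeric(nlevels(gene))
  for (k in seq_along(q)) {
    qk <- q[k]
    lmix <- logaddexp(log(qk) + lf1, log1p(-qk) + lf0)
    s1 <- rowsum(lmix, gene)[, 1]
    la <- log(tau / qk) + s1
    lb <- if (tau / qk >= 1) -Inf else log1p(-tau / qk) + s0
    post <- post + w[k] * stats::plogis(la - lb)
  }
  stats::setNames(post, levels(gene))
}

#' Gene-level posterior probability of being interesting
#'
#' Computes, for one gene with guide log2 fold changes `x`, the posterior
#' probability that the gene is interesting, marginalizing the guide
#' efficiency q over its prior:
#' \deqn{\int \frac{(\hat\tau/q) \prod_i [q f_1(x_i) + (1-q) f_0(x_i)]}
#'   {(\hat\tau/q) \prod_i [q f_1(x_i) + (1-q) f_0(x_i)] +
#'    (1 - \hat\tau/q) \prod_i f_0(x_i)} \, d\psi(q).}
#' With a point mass at q = 1 this collapses to the flat two-groups
#' posterior. The integral is evaluated by Gauss-Legendre quadrature
#' mapped to the prior's support; all products run in log space.
#'
#' @param x numeric vector of the gene's guide log2 fold changes.
#' @param logf0,logf1 functions returning log densities of the null and
#'   alternative, or numeric vectors of per-guide log densities.
#' @param tau estimated marginal mixing proportion, in (0, 1).
#' @param prior a [q_prior()]; default uniform on \[max(tau, 0.01), 1\].
#' @param n_nodes number of Gauss-Legendre nodes for the uniform prior.
#' @return posterior probability in \[0, 1\].
#' @export
gene_posterior <- function(x, logf0, logf1, tau, prior = NULL,
                           n_nodes = 100) {
  if (length(x) == 0) stop("gene has no guides")
  if (!is.numeric(tau) || tau <= 0 || tau >= 1) stop("tau must be in (0, 1)")
  lf0 <- if (is.function(logf0)) logf0(x) else as.numeric(logf0)
  lf1 <- if (is.function(logf1)) logf1(x) else as.numeric(logf1)
  qw <- resolve_q_prior(prior, tau, n_nodes)
  unname(gene_posterior_all(lf0, lf1, rep("g", length(x)), tau,
                            qw$q, qw$w))
}

#' Score genes by local false discovery rate
#'
#' The local fdr of a gene is one minus its posterior probability of
#' being interesting under the fitted mixture. Negative-control guides
#' are excluded. Output is sorted by ascending local fdr (ties broken by
#' gene id) and carries the cumulative-mean global FDR estimate at each
#' rank.
#'
#' @param guides a `guide_table`.
#' @param fit a `screenmix_mixture` from [em_mixture()].
#' @param prior a [q_prior()]; `NULL` for the default uniform prior.
#' @param n_nodes Gauss-Legendre nodes for the uniform prior.
#' @param flip if `TRUE` the guide log2 fold changes are negated before
#'   scoring (enrichment screens).
#' @return data frame with columns `gene`, `locfdr`, `fdr`, `rank`.
#' @export
score_genes <- function(guides, fit, prior = NULL, n_nodes = 100,
                        flip = FALSE) {
  stopifnot(inherits(fit, "screenmix_mixture"))
  gt <- guides[!guides$control, , drop = FALSE]
  if (nrow(gt) == 0) stop("no gene-targeting guides")
  x <- if (flip) -gt$lfc else gt$lfc
  if (any(table(gt$gene) == 1)) {
    warning("some genes have a single guide; their scores rest on ",
            "little evidence")
  }
  qw <- resolve_q_prior(prior, fit$tau, n_nodes)
  post <- gene_posterior_all(null_logdens(fit$f0, x), f1_logdens(fit$f1, x),
                             gt$gene, fit$tau, qw$q, qw$w)
  locfdr <- pmin(pmax(1 - post, 0), 1)
  ord <- order(locfdr, names(locfdr))
  out <- data.frame(gene = names(locfdr)[ord],
                    locfdr = unname(locfdr[ord]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$fdr <- global_fdr(out$locfdr)
  out$rank <- seq_len(nrow(out))
  out
}

#' Global FDR from local fdrs
#'
#' The estimated global FDR of calling the K best genes is the mean of
#' the K smallest local fdrs; averaging over all genes recovers the
#' estimated null proportion.
#'
#' @param locfdr numeric vector of local fdrs in \[0, 1\].
#' @return numeric vector: for each rank K (in ascending-locfdr order),
#'   the cumulative mean of the K smallest local fdrs.
#' @export
global_fdr <- function(locfdr) {
  if (length(locfdr) == 0) stop("empty input")
  if (any(locfdr < 0 | locfdr > 1)) stop("local fdrs must lie in [0, 1]")
  s <- sort(locfdr)
  cumsum(s) / seq_along(s)
}

#' Call genes at a target global FDR
#'
#' @param locfdr numeric vector of local fdrs (any order).
#' @param fdr target global FDR threshold.
#' @return logical vector, aligned with `locfdr`, `TRUE` for the called
#'   genes: the largest set of smallest local fdrs whose mean does not
#'   exceed `fdr`.
#' @export
fdr_calls <- function(locfdr, fdr = 0.1) {
  cm <- global_fdr(locfdr)
  k <- if (any(cm <= fdr)) max(which(cm <= fdr)) else 0L
  called <- logical(length(locfdr))
  if (k > 0) called[order(locfdr)[seq_len(k)]] <- TRUE
  called
}
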