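# Top-level model fit and its S3 methods.

#' Fit the hierarchical mixture model to a screen
#'
#' The full pipeline: fit (or select by BIC) a null distribution on the
#' negative-control guides, deconvolve the marginal guide-level mixture
#' `(1 - tau) f0 + tau f1` by EM on the gene-targeting guides with f0
#' fixed, then score every gene by its local false discovery rate,
#' marginalizing guide efficiency over its prior, and estimate global
#' FDRs by cumulative means of the ordered local fdrs.
#'
#' When the screen has no negative controls, request `null = "estimate"`:
#' f0 is then a normal estimated jointly in the EM (the normal
#' hierarchical mixture variant); the skew-t null requires controls.
#'
#' @param guides a `guide_table` (see [guide_table()]), or a data frame
#'   with columns `guide`, `gene`, `lfc` and optionally `control`.
#' @param direction `"depleted"` (interesting genes have negative log2
#'   fold changes; e.g. essentiality screens), `"enriched"` (inputs are
#'   negated internally), or `"both"` (bimodal alternative).
#' @param null `"auto"` (BIC selection between skew-t and normal on the
#'   controls), `"skewt"`, `"normal"`, or `"estimate"` (no controls:
#'   normal null estimated in the EM).
#' @param prior a [q_prior()] on guide efficiency; `NULL` for the default
#'   uniform prior on \[max(tau, 0.01), 1\].
#' @param n_nodes number of Gauss-Legendre quadrature nodes.
#' @param tau_init,tol,max_iter EM controls, passed to [em_mixture()].
#' @return an object of class `screenmix` with components `null_fit`,
#'   `mixture`, `genes` (gene, locfdr, fdr, rank), `direction`, `guides`
#'   and `call`. Methods: `print`, `summary`, `coef`, `plot`, `predict`,
#'   `simulate`.
#' @examples
#' sim <- simulate_screen(n_genes_null = 200, n_genes_pos = 20,
#'                        guides_per_gene = 5, n_controls = 300, seed = 1)
#' fit <- screenmix(sim$guides)
#' head(fit$genes)
#' sum(fdr_calls(fit$genes$locfdr, 0.1))
#' @export
screenmix <- function(guides,
                      direction = c("depleted", "enriched", "both"),
                      null = c("auto", "skewt", "normal", "estimate"),
                      prior = NULL, n_nodes = 100,
                      tau_init = 0.1, tol = 1e-6, max_iter = 1000) {
  direction <- match.arg(direction)
  null <- match.arg(null)
  if (!inherits(guides, "guide_table")) {
    if (!all(c("guide", "gene", "lfc") %in% names(guides))) {
      stop("'guides' needs columns guide, gene, lfc (and optionally control)")
    }
    ctrl <- if ("control" %in% names(guides)) guides$control else FALSE
    guides <- guide_table(guides$guide, guides$gene, guides$lfc, ctrl)
  }
  flip <- direction == "enriched"
  x_ctrl <- guides$lfc[guides$control]
  if (flip) x_ctrl <- -x_ctrl
  has_controls <- length(x_ctrl) > 0
  if (!has_controls && null != "estimate") {
    stop("no negative-control guides: use null = \"estimate\" ",
         "(normal null fit jointly in the EM)")
  }
  null_fit <- switch(null,
    auto = select_null(x_ctrl),
    skewt = fit_skew_t(x_ctrl),
    normal = fit_normal_null(x_ctrl),
    estimate = NULL
  )
  x <- guides$lfc[!guides$control]
  if (flip) x <- -x
  mix <- em_mixture(x, null_fit = null_fit,
                    f1_mode = if (direction == "both") "bimodal"
                              else "unimodal",
                    tau_init = tau_init, tol = tol, max_iter = max_iter)
  genes <- score_genes(guides, mix, prior = prior, n_nodes = n_nodes,
                       flip = flip)
  structure(
    list(null_fit = mix$f0, mixture = mix, genes = genes,
         direction = direction, prior = prior, n_nodes = n_nodes,
         guides = guides, call = match.call()),
    class = "screenmix"
  )
}

#' @export
print.screenmix <- function(x, ...) {
  g <- x$guides
  cat("Hierarchical mixture screen fit (", x$direction, ")\n", sep = "")
  cat("  ", sum(!g$control), " gene-targeting guides, ",
      length(unique(g$gene[!g$control])), " genes, ",
      sum(g$control), " negative controls\n", sep = "")
  cat("  null: ", x$null_fit$family,
      if (x$mixture$f0_estimated) " (EM-estimated)" else "",
      ";  tau = ", signif(x$mixture$tau, 4), "\n", sep = "")
  cat("  genes at estimated global FDR 0.1: ",
      sum(fdr_calls(x$genes$locfdr, 0.1)), "\n", sep = "")
  invisible(x)
}

#' @export
summary.screenmix <- function(object, fdr = 0.1, ...) {
  structure(
    list(fit = object, fdr = fdr,
         n_called = sum(fdr_calls(object$genes$locfdr, fdr)),
         top = utils::head(object$genes, 10)),
    class = "summary.screenmix"
  )
}

#' @export
print.summary.screenmix <- function(x, ...) {
  print(x$fit)
  cat("\nNull fit:\n")
  print(x$fit$null_fit)
  mx <- x$fit$mixture
  cat("\nEM: ", mx$iterations, " iterations, ",
      if (mx$converged) "converged" else "NOT converged", "\n", sep = "")
  cat("\nGenes called at global FDR ", x$fdr, ": ", x$n_called,
      "\n\nTop genes:\n", sep = "")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' @export
coef.screenmix <- function(object, ...) {
  c(tau = object$mixture$tau,
    unlist(object$mixture$f1),
    stats::setNames(unlist(object$null_fit$params),
                    paste0("f0.", names(object$null_fit$params))))
}

#' Plot the fitted guide-level mixture
#'
#' Histogram of gene-targeting guide log2 fold changes overlaid with the
#' fitted null, alternative, and marginal mixture densities.
#'
#' @param x a `screenmix` fit.
#' @param breaks histogram breaks (passed to [graphics::hist()]).
#' @param ... further arguments passed to [graphics::hist()].
#' @export
plot.screenmix <- function(x, breaks = 60, ...) {
  lfc <- x$guides$lfc[!x$guides$control]
  if (x$direction == "enriched") lfc <- -lfc
  graphics::hist(lfc, breaks = breaks, freq = FALSE,
                 main = "Guide-level mixture fit",
                 xlab = "log2 fold change", border = "grey70", ...)
  xs <- seq(min(lfc), max(lfc), length.out = 512)
  tau <- x$mixture$tau
  d0 <- exp(null_logdens(x$null_fit, xs))
  d1 <- exp(f1_logdens(x$mixture$f1, xs))
  graphics::lines(xs, (1 - tau) * d0, col = "steelblue", lwd = 2)
  graphics::lines(xs, tau * d1, col = "firebrick", lwd = 2)
  graphics::lines(xs, (1 - tau) * d0 + tau * d1, col = "black", lwd = 1,
                  lty = 2)
  graphics::legend("topleft",
                   legend = c("(1-tau) f0", "tau f1", "mixture"),
                   col = c("steelblue", "firebrick", "black"),
                   lwd = c(2, 2, 1), lty = c(1, 1, 2), bty = "n")
  invisible(x)
}

#' Score new genes with a fitted mixture
#'
#' Applies the fitted null, alternative and tau to a new guide table,
#' without refitting, and returns gene-level local fdrs.
#'
#' @param object a `screenmix` fit.
#' @param newdata a `guide_table` (or data frame with guide, gene, lfc).
#' @param ... unused.
#' @return data frame with columns `gene`, `locfdr`, `fdr`, `rank`.
#' @export
predict.screenmix <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$genes)
  if (!inherits(newdata, "guide_table")) {
    ctrl <- if ("control" %in% names(newdata)) newdata$control else FALSE
    newdata <- guide_table(newdata$guide, newdata$gene, newdata$lfc, ctrl)
  }
  score_genes(newdata, object$mixture, prior = object$prior,
              n_nodes = object$n_nodes,
              flip = object$direction == "enriched")
}

#' Simulate guide log2 fold changes from a fitted marginal mixture
#'
#' Draws from the fitted `(1 - tau) f0 + tau f1`; useful for posterior
#' predictive checks of the marginal fit (gene structure is not
#' simulated; see [simulate_screen()] for the full generative model).
#'
#' @param object a `screenmix` fit.
#' @param nsim number of replicate datasets.
#' @param seed optional integer seed.
#' @param n draws per replicate; defaults to the number of gene-targeting
#'   guides in the fit.
#' @param ... unused.
#' @return a data frame with one column per replicate.
#' @export
simulate.screenmix <- function(object, nsim = 1, seed = NULL, n = NULL,
                               ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n)) n <- sum(!object$guides$control)
  tau <- object$mixture$tau
  f1 <- object$mixture$f1
  f0 <- object$null_fit
  draw_f0 <- function(m) {
    p <- f0$params
    if (f0$family == "skew_t") {
      rskewt(m, p$xi, p$omega, p$alpha, p$nu)
    } else {
      stats::rnorm(m, p$mean, p$sd)
    }
  }
  draw_f1 <- function(m) {
    if (is.null(f1$lambda)) {
      stats::rnorm(m, f1$mu, f1$sigma)
    } else {
      neg <- stats::runif(m) < f1$lambda
      ifelse(neg, stats::rnorm(m, f1$mu_neg, f1$sigma_neg),
             stats::rnorm(m, f1$mu_pos, f1$sigma_pos))
    }
  }
  out <- replicate(nsim, {
    w <- stats::runif(n) < tau
    z <- numeric(n)
    z[w] <- draw_f1(sum(w))
    z[!w] <- draw_f0(sum(!w))
    if (object$direction == "enriched") -z else z
  })
  as.data.frame(out)
}
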