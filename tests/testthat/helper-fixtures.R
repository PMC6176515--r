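# Shared fixture builders for the test suite.

# a screenmix_null holding the true skew-t used by the simulators
true_skewt_null <- function(xi = 0, omega = 1, alpha = -1.5, nu = 6) {
  structure(
    list(family = "skew_t",
         params = list(xi = xi, omega = omega, alpha = alpha, nu = nu),
         loglik = NA_real_, n = NA_integer_, df = 4L, bic = NA_real_),
    class = "screenmix_null"
  )
}

# small deterministic count matrix fixture
toy_counts <- function() {
  count_matrix(
    guide_id = c("sg1", "sg2", "sg3", "sg4"),
    gene_id = c("geneA", "geneA", "negative_control", "geneB"),
    counts = matrix(c(10L, 20L,
                      40L, 80L,
                      100L, 200L,
                      7L, 14L), nrow = 4, byrow = TRUE,
                    dimnames = list(NULL, c("initial", "final")))
  )
}

# brute-force gene posterior by dense trapezoid integration over q
brute_gene_posterior <- function(x, logf0, logf1, tau, lower,
                                 n_grid = 1e5) {
  lf0 <- if (is.function(logf0)) logf0(x) else logf0
  lf1 <- if (is.function(logf1)) logf1(x) else logf1
  q <- seq(lower, 1, length.out = n_grid)
  vals <- vapply(q, function(qq) {
    la <- log(tau / qq) + sum(log(qq * exp(lf1) + (1 - qq) * exp(lf0)))
    lb <- if (tau / qq >= 1) -Inf else
      log1p(-tau / qq) + sum(lf0)
    stats::plogis(la - lb)
  }, numeric(1))
  # trapezoid rule, normalized by the support width (uniform prior)
  sum((vals[-1] + vals[-n_grid]) / 2 * diff(q)) / (1 - lower)
}
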