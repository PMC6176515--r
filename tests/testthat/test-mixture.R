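test_that("EM estimates tau near zero when there is no signal", {
  set.seed(41)
  x <- rnorm(10000)
  f0 <- fit_normal_null(rnorm(5000))
  fit <- suppressWarnings(em_mixture(x, null_fit = f0))
  expect_lte(fit$tau, 0.02)
})

test_that("EM recovers tau and f1 from a two-groups sample", {
  set.seed(42)
  n <- 10000
  w <- runif(n) < 0.10
  x <- ifelse(w, rnorm(n, -3, 1), rnorm(n))
  f0 <- new_null_fit <- fit_normal_null(rnorm(20000))
  fit <- em_mixture(x, null_fit = f0)
  expect_gte(fit$tau, 0.08)
  expect_lte(fit$tau, 0.12)
  expect_gte(fit$f1$mu, -3.2)
  expect_lte(fit$f1$mu, -2.8)
  expect_true(fit$converged)
  expect_true(all(fit$responsibilities >= 0 & fit$responsibilities <= 1))
})

test_that("EM log likelihood trace is non-decreasing", {
  set.seed(43)
  for (rep in 1:3) {
    n <- 2000
    w <- runif(n) < 0.15
    x <- ifelse(w, rnorm(n, -2.5, 1.2), rskewt(n, 0, 1, -1, 8))
    f0 <- fit_skew_t(rskewt(2000, 0, 1, -1, 8))
    fit <- em_mixture(x, null_fit = f0)
    expect_true(all(diff(fit$trace) >= -1e-8))
  }
})

test_that("EM with no controls estimates a normal null jointly", {
  set.seed(44)
  n <- 8000
  w <- runif(n) < 0.12
  x <- ifelse(w, rnorm(n, -3, 1), rnorm(n, 0.2, 0.9))
  fit <- em_mixture(x, null_fit = NULL)
  expect_true(fit$f0_estimated)
  expect_equal(fit$f0$params$mean, 0.2, tolerance = 0.1)
  expect_equal(fit$f0$params$sd, 0.9, tolerance = 0.1)
  expect_equal(fit$tau, 0.12, tolerance = 0.03)
  expect_true(all(diff(fit$trace) >= -1e-8))
})

test_that("bimodal alternative captures both directions", {
  set.seed(45)
  n <- 9000
  u <- runif(n)
  x <- ifelse(u < 0.06, rnorm(n, -3, 1),
              ifelse(u < 0.12, rnorm(n, 2.5, 0.8), rnorm(n)))
  f0 <- fit_normal_null(rnorm(20000))
  fit <- em_mixture(x, null_fit = f0, f1_mode = "bimodal")
  expect_lt(abs(fit$tau - 0.12), 0.03)
  expect_lt(fit$f1$mu_neg, -2)
  expect_gt(fit$f1$mu_pos, 1.5)
  expect_true(all(diff(fit$trace) >= -1e-8))
})

test_that("point-mass prior at q = 1 collapses to the two-groups posterior", {
  # single guide with density ratio 9 and tau = 0.1 gives exactly 1/2
  lf0 <- log(0.1)
  lf1 <- log(0.9)
  post <- gene_posterior(0, logf0 = lf0, logf1 = lf1, tau = 0.1,
                         prior = q_prior("point", at = 1))
  expect_equal(post, 0.5, tolerance = 1e-14)
  # general gene: equals tau prod f1 / (tau prod f1 + (1 - tau) prod f0)
  set.seed(51)
  x <- rnorm(4, -1)
  lf0 <- dnorm(x, log = TRUE)
  lf1 <- dnorm(x, -2, 1.3, log = TRUE)
  tau <- 0.07
  expected <- 1 / (1 + exp(log1p(-tau) + sum(lf0) - log(tau) - sum(lf1)))
  post2 <- gene_posterior(x, lf0, lf1, tau, q_prior("point", at = 1))
  expect_equal(post2, expected, tolerance = 1e-14)
})

test_that("posterior has closed form when f1 equals f0 on a gene", {
  # integrand is tau/q; uniform prior on [tau, 1] gives
  # tau log(1/tau) / (1 - tau)
  tau <- 0.1
  x <- c(0.3, -0.8, 1.1)
  lf <- dnorm(x, log = TRUE)
  post <- gene_posterior(x, lf, lf, tau,
                         q_prior("uniform", lower = tau), n_nodes = 100)
  expect_equal(post, tau * log(1 / tau) / (1 - tau), tolerance = 1e-10)
})

test_that("quadrature agrees with brute-force integration", {
  set.seed(52)
  for (m in c(1, 3, 8)) {
    x <- c(rnorm(m, -2, 1))
    lf0 <- dskewt(x, 0, 1, -1.5, 6, log = TRUE)
    lf1 <- dnorm(x, -3, 1.25, log = TRUE)
    tau <- 0.09
    post <- gene_posterior(x, lf0, lf1, tau,
                           q_prior("uniform", lower = tau), n_nodes = 100)
    brute <- brute_gene_posterior(x, lf0, lf1, tau, lower = tau)
    expect_equal(post, brute, tolerance = 1e-6)
  }
})

test_that("adding a supporting guide never decreases the posterior", {
  set.seed(53)
  tau <- 0.1
  lf0fun <- function(x) dskewt(x, 0, 1, -1.5, 6, log = TRUE)
  lf1fun <- function(x) dnorm(x, -3, 1.25, log = TRUE)
  for (i in 1:20) {
    x <- rnorm(3, -1, 1.5)
    extra <- -3 + rnorm(1, 0, 0.5) # f1/f0 ratio > 1 here
    stopifnot(lf1fun(extra) > lf0fun(extra))
    for (pr in list(q_prior("point", at = 1),
                    q_prior("uniform", lower = tau))) {
      p0 <- gene_posterior(x, lf0fun, lf1fun, tau, pr)
      p1 <- gene_posterior(c(x, extra), lf0fun, lf1fun, tau, pr)
      expect_gte(p1, p0 - 1e-12)
    }
  }
})

test_that("q prior validation enforces the support constraint", {
  expect_error(resolve_q_prior(q_prior("uniform", lower = 0.05), tau = 0.2),
               "p > 1")
  expect_error(resolve_q_prior(q_prior("point", at = 0.1), tau = 0.2),
               "p > 1")
  expect_error(q_prior("grid", nodes = c(0.5, 1.5), weights = c(1, 1)),
               "\\(0, 1\\]")
  qw <- resolve_q_prior(q_prior("uniform"), tau = 0.2, n_nodes = 64)
  expect_equal(sum(qw$w), 1, tolerance = 1e-12)
  expect_true(all(qw$q > 0.2 & qw$q < 1))
  # grid weights are normalized
  qw2 <- resolve_q_prior(q_prior("grid", nodes = c(0.5, 0.9),
                                 weights = c(2, 2)), tau = 0.3)
  expect_equal(qw2$w, c(0.5, 0.5))
})

test_that("gene scoring separates signal from null and is exchangeable", {
  set.seed(54)
  sim <- simulate_screen(n_genes_null = 300, n_genes_pos = 40,
                         guides_per_gene = 5, efficiency = 0.9,
                         n_controls = 500, seed = 61)
  fit <- em_mixture(sim$guides$lfc[!sim$guides$control],
                    null_fit = true_skewt_null())
  sc <- score_genes(sim$guides, fit)
  truth <- sim$truth$genes
  to <- truth$interesting[match(sc$gene, truth$gene)]
  expect_gt(mean(sc$locfdr[to == 0]), mean(sc$locfdr[to == 1]))
  # permuting guide rows leaves scores unchanged
  perm <- sim$guides[sample(nrow(sim$guides)), ]
  sc2 <- score_genes(guide_table(perm$guide, perm$gene, perm$lfc,
                                 perm$control), fit)
  expect_equal(sc2, sc)
  # output is sorted with deterministic ranks and ties broken by gene id
  expect_true(!is.unsorted(sc$locfdr))
  expect_identical(sc$rank, seq_len(nrow(sc)))
  # fdr column is the cumulative mean of sorted locfdrs
  expect_equal(sc$fdr, cumsum(sc$locfdr) / seq_along(sc$locfdr))
})

test_that("global FDR is the cumulative mean of ordered local fdrs", {
  expect_equal(global_fdr(c(0.01, 0.05, 0.20)),
               c(0.01, 0.03, 13 / 150))
  expect_equal(sum(fdr_calls(c(0.01, 0.05, 0.20), 0.05)), 2)
  expect_equal(sum(fdr_calls(c(0.01, 0.05, 0.20), 0.1)), 3)
  expect_equal(sum(fdr_calls(rep(1, 5), 0.99)), 0)
  expect_error(global_fdr(numeric(0)), "empty")
  expect_error(global_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  # brute-force oracle on random input
  set.seed(55)
  lf <- runif(200)
  cm <- global_fdr(lf)
  s <- sort(lf)
  oracle <- vapply(seq_along(s), function(k) mean(s[seq_len(k)]),
                   numeric(1))
  expect_equal(cm, oracle)
  # calls are the K smallest, K maximal with cumulative mean <= pi
  called <- fdr_calls(lf, 0.3)
  k <- sum(called)
  expect_true(all(sort(lf[called]) == s[seq_len(k)]))
  expect_lte(mean(s[seq_len(k)]), 0.3)
  if (k < length(s)) expect_gt(mean(s[seq_len(k + 1)]), 0.3)
  # averaging across all genes estimates the null proportion
  expect_equal(cm[length(cm)], mean(lf))
})

test_that("gene_posterior rejects degenerate inputs", {
  expect_error(gene_posterior(numeric(0), log(1), log(1), 0.1), "no guides")
  expect_error(gene_posterior(0, log(1), log(1), tau = 1.2), "\\(0, 1\\)")
  expect_error(gene_posterior(0, log(1), log(1), tau = 0), "\\(0, 1\\)")
})
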