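# Skew-t distribution: density, sampler, and maximum-likelihood null fits.
#
# The null distribution of negative-control guide log2 fold changes is
# typically asymmetric and heavier-tailed than normal; the four-parameter
# skew-t family (location xi, scale omega > 0, slant alpha, degrees of
# freedom nu > 0) captures both features and contains the normal and
# symmetric t as limiting / special cases.

#' Skew-t density
#'
#' Density of the skew-t distribution with location `xi`, scale `omega`,
#' slant `alpha` and degrees of freedom `nu`,
#' \deqn{f(y) = \frac{2}{\omega}\, t_\nu(z)\,
#'   T_{\nu+1}\!\left(\alpha z \sqrt{\frac{\nu+1}{\nu+z^2}}\right),
#'   \quad z = \frac{y-\xi}{\omega},}
#' where \eqn{t_\nu} and \eqn{T_\nu} are the pdf and cdf of the Student-t
#' distribution. `alpha = 0` recovers the scaled-shifted t; `nu = Inf`
#' gives the skew-normal.
#'
#' @param x numeric vector of quantiles.
#' @param xi location parameter (log2FC units).
#' @param omega scale parameter, must be positive.
#' @param alpha slant parameter; the sign sets the direction of skew.
#' @param nu degrees of freedom, must be positive (may be `Inf`).
#' @param log logical; return the log density?
#' @return numeric vector of (log) density values.
#' @examples
#' dskewt(1.3, alpha = 0, nu = 6) # equals dt(1.3, 6)
#' @export
dskewt <- function(x, xi = 0, omega = 1, alpha = 0, nu = Inf, log = FALSE) {
  if (!is.numeric(omega) || omega <= 0) stop("'omega' must be positive")
  if (!is.numeric(nu) || nu <= 0) stop("'nu' must be positive")
  z <- (x - xi) / omega
  # for nu = Inf the tail factor reduces to alpha * z
  s <- if (is.finite(nu)) sqrt((nu + 1) / (nu + z^2)) else 1
  lf <- log(2) - log(omega) + stats::dt(z, df = nu, log = TRUE) +
    stats::pt(alpha * z * s, df = nu + 1, log.p = TRUE)
  if (log) lf else exp(lf)
}

#' Sample from the skew-t distribution
#'
#' Draws via the stochastic representation skew-t = skew-normal divided by
#' \eqn{\sqrt{\chi^2_\nu / \nu}}, with the skew-normal generated from two
#' independent standard normals.
#'
#' @param n number of draws.
#' @inheritParams dskewt
#' @param seed optional integer seed applied before sampling.
#' @return numeric vector of length `n`.
#' @export
rskewt <- function(n, xi = 0, omega = 1, alpha = 0, nu = Inf, seed = NULL) {
  if (omega <= 0) stop("'omega' must be positive")
  if (nu <= 0) stop("'nu' must be positive")
  if (!is.null(seed)) set.seed(seed)
  delta <- alpha / sqrt(1 + alpha^2)
  u0 <- abs(stats::rnorm(n))
  u1 <- stats::rnorm(n)
  sn <- delta * u0 + sqrt(1 - delta^2) * u1
  w <- if (is.finite(nu)) sqrt(stats::rchisq(n, df = nu) / nu) else 1
  xi + omega * sn / w
}

new_null_fit <- function(family, params, loglik, n) {
  k <- switch(family, normal = 2L, skew_t = 4L,
              stop("unknown family: ", family))
  structure(
    list(family = family, params = params, loglik = loglik, n = n,
         df = k, bic = k * log(n) - 2 * loglik),
    class = "screenmix_null"
  )
}

#' @export
print.screenmix_null <- function(x, ...) {
  cat("Null fit (", x$family, "), n = ", x$n, "\n", sep = "")
  cat("  params:",
      paste(names(x$params), signif(unlist(x$params), 4),
            sep = " = ", collapse = ", "), "\n")
  cat("  logLik = ", format(x$loglik, digits = 6),
      ",  BIC = ", format(x$bic, digits = 6), "\n", sep = "")
  invisible(x)
}

# evaluate the log density of a fitted null at x
null_logdens <- function(fit, x) {
  p <- fit$params
  switch(fit$family,
    normal = stats::dnorm(x, p$mean, p$sd, log = TRUE),
    skew_t = dskewt(x, p$xi, p$omega, p$alpha, p$nu, log = TRUE)
  )
}

#' Maximum-likelihood skew-t fit
#'
#' Fits the four-parameter skew-t by direct numerical maximum likelihood in
#' transformed coordinates (xi, log omega, alpha, log nu), using multiple
#' starts initialized from robust moments. Degrees of freedom are bounded
#' to \[1, 1000\] to avoid the flat ridge at the normal limit.
#'
#' @param x numeric vector of observations (e.g. negative-control guide
#'   log2 fold changes); at least 50 observations are recommended.
#' @param n_starts number of perturbed restarts beyond the moment-based
#'   start.
#' @return an object of class `screenmix_null` with `family = "skew_t"`,
#'   fields `params` (xi, omega, alpha, nu), `loglik`, `n` and `bic`.
#' @seealso [fit_normal_null()], [select_null()]
#' @export
fit_skew_t <- function(x, n_starts = 2) {
  x <- as.numeric(x)
  if (length(x) == 0) stop("empty input")
  if (length(x) < 50) {
    warning("skew-t fit on fewer than 50 observations may be unstable")
  }
  nll <- function(par) {
    lf <- dskewt(x, xi = par[1], omega = exp(par[2]), alpha = par[3],
                 nu = exp(par[4]), log = TRUE)
    if (any(!is.finite(lf))) return(1e10)
    -sum(lf)
  }
  s <- stats::sd(x)
  skw <- mean((x - mean(x))^3) / s^3
  base_start <- c(stats::median(x), log(max(stats::mad(x), s / 10, 1e-3)),
                  sign(skw) * 1, log(10))
  starts <- list(base_start)
  for (i in seq_len(n_starts)) {
    starts[[i + 1]] <- base_start + c(0.2 * s * (-1)^i, 0.2 * (-1)^i,
                                      (-1)^i, 0.5 * (-1)^i)
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, nll, method = "L-BFGS-B",
                   lower = c(-Inf, -Inf, -Inf, 0),
                   upper = c(Inf, Inf, Inf, log(1000)),
                   control = list(maxit = 500, factr = 1e-1)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("skew-t optimization failed from all starts")
  p <- best$par
  new_null_fit("skew_t",
               list(xi = p[1], omega = exp(p[2]), alpha = p[3],
                    nu = exp(p[4])),
               loglik = -best$value, n = length(x))
}

#' Maximum-likelihood normal fit
#'
#' @param x numeric vector of observations, at least 2, non-constant.
#' @return an object of class `screenmix_null` with `family = "normal"`.
#' @export
fit_normal_null <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2) stop("need at least 2 observations")
  m <- mean(x)
  sd_mle <- sqrt(mean((x - m)^2))
  if (sd_mle == 0) stop("constant sample: zero variance")
  ll <- sum(stats::dnorm(x, m, sd_mle, log = TRUE))
  new_null_fit("normal", list(mean = m, sd = sd_mle), loglik = ll, n = n)
}

#' Select a null distribution by BIC
#'
#' Fits both the normal and the skew-t to the control sample and returns
#' the fit with the smaller Bayesian information criterion; both candidate
#' fits are kept in the `candidates` attribute for inspection.
#'
#' @inheritParams fit_skew_t
#' @return the winning `screenmix_null` fit.
#' @export
select_null <- function(x) {
  fits <- list(normal = fit_normal_null(x), skew_t = fit_skew_t(x))
  win <- fits[[which.min(vapply(fits, `[[`, numeric(1), "bic"))]]
  attr(win, "candidates") <- lapply(fits, function(f) {
    list(family = f$family, bic = f$bic, loglik = f$loglik)
  })
  win
}
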