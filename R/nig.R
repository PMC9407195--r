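#' Normal-Inverse-Gamma hyperparameters
#'
#' The conjugate joint prior for the mean and variance of a normal model:
#' `sigma2 ~ IG(alpha, beta)` (rate parameterisation, mean `beta/(alpha-1)`)
#' and `theta | sigma2 ~ N(mu, sigma2/lambda)`. The same structure serves as
#' prior and, after [nig_posterior()], as posterior.
#'
#' @param mu Prior location for the mean (finite real).
#' @param lambda Prior precision scale (> 0, dimensionless).
#' @param alpha Inverse-gamma shape (> 0).
#' @param beta Inverse-gamma rate (> 0).
#' @return An object of class `nig`.
#' @export
#' @examples
#' nig(0, 0.01, 1, 1)
nig <- function(mu, lambda, alpha, beta) {
  if (!is_scalar_number(mu)) abort("`mu` must be a finite number.", class = "abcbench_domain_error")
  for (nm in c("lambda", "alpha", "beta")) {
    v <- get(nm)
    if (!is_scalar_number(v) || v <= 0) {
      abort(paste0("`", nm, "` must be a positive finite number."),
            class = "abcbench_domain_error")
    }
  }
  structure(list(mu = mu, lambda = lambda, alpha = alpha, beta = beta),
            class = "nig")
}

#' @export
print.nig <- function(x, ...) {
  cat(sprintf("<NIG(mu = %g, lambda = %g, alpha = %g, beta = %g)>\n",
              x$mu, x$lambda, x$alpha, x$beta))
  invisible(x)
}

#' Draw (theta, sigma2) pairs from a Normal-Inverse-Gamma prior
#'
#' @param prior An [nig()] object.
#' @param n Number of draws.
#' @param seed Optional seed.
#' @return A tibble with columns `theta` and `sigma2`.
#' @export
#' @examples
#' nig_sample(nig(0, 1, 3, 1), 5, seed = 1)
nig_sample <- function(prior, n = 1, seed = NULL) {
  stopifnot(inherits(prior, "nig"), n >= 1)
  with_seed(seed, {
    sigma2 <- 1 / rgamma(n, shape = prior$alpha, rate = prior$beta)
    theta <- rnorm(n, prior$mu, sqrt(sigma2 / prior$lambda))
    tibble(theta = theta, sigma2 = sigma2)
  })
}

#' Simulate i.i.d. normal observations
#'
#' @param theta Mean.
#' @param sigma2 Variance (> 0; values at the double-precision floor are
#'   allowed and return constant data).
#' @param n Number of observations (at least 2: the variance summaries
#'   require it).
#' @param seed Optional seed.
#' @return Numeric vector of length `n`.
#' @export
simulate_normal <- function(theta, sigma2, n, seed = NULL) {
  if (!is_scalar_number(n) || n < 2) {
    abort("`n` must be at least 2.", class = "abcbench_size_error")
  }
  if (!is_scalar_number(sigma2) || sigma2 < 0) {
    abort("`sigma2` must be nonnegative.", class = "abcbench_domain_error")
  }
  with_seed(seed, rnorm(n, theta, sqrt(sigma2)))
}

#' Conjugate Normal-Inverse-Gamma posterior update
#'
#' Closed-form posterior for normal data under an NIG prior:
#' \deqn{\mu^* = \frac{\lambda\mu + n\bar y}{\lambda + n},\quad
#'       \lambda^* = \lambda + n,\quad \alpha^* = \alpha + n/2,}
#' \deqn{\beta^* = \beta + \tfrac12\sum_i(y_i-\bar y)^2 +
#'       \frac{n\lambda}{2(n+\lambda)}(\bar y - \mu)^2.}
#' The sum of squares is the uncorrected \eqn{\sum (y_i - \bar y)^2}.
#'
#' @param prior An [nig()] object.
#' @param y Numeric vector of observations (length at least 2).
#' @return An [nig()] object holding the posterior hyperparameters.
#' @export
#' @examples
#' nig_posterior(nig(0, 1, 1, 1), c(1, 2, 3))
nig_posterior <- function(prior, y) {
  stopifnot(inherits(prior, "nig"))
  n <- length(y)
  if (n < 2 || !is.numeric(y) || anyNA(y)) {
    abort("`y` must be a numeric vector of length >= 2 without NAs.",
          class = "abcbench_size_error")
  }
  ybar <- mean(y)
  ss <- sum((y - ybar)^2)
  lam <- prior$lambda
  nig(
    mu = (lam * prior$mu + n * ybar) / (lam + n),
    lambda = lam + n,
    alpha = prior$alpha + n / 2,
    beta = prior$beta + ss / 2 + n * lam / (2 * (n + lam)) * (ybar - prior$mu)^2
  )
}

#' Marginal moments of a Normal-Inverse-Gamma distribution
#'
#' Marginal mean and variance of the normal mean parameter and marginal mean
#' of the variance parameter: `E[theta] = mu`, `Var[theta] =
#' beta / (lambda (alpha - 1))`, `E[sigma2] = beta / (alpha - 1)`.
#' Moments that require `alpha > 1` are reported as [undefined_marker()]
#' when the shape does not exceed 1.
#'
#' @param x An [nig()] object.
#' @return A one-row tibble with columns `mean_theta`, `var_theta`,
#'   `mean_sigma2`.
#' @export
#' @examples
#' nig_moments(nig(1.5, 4, 2.5, 3.5))
nig_moments <- function(x) {
  stopifnot(inherits(x, "nig"))
  if (x$alpha > 1) {
    ms2 <- x$beta / (x$alpha - 1)
    tibble(mean_theta = x$mu, var_theta = ms2 / x$lambda, mean_sigma2 = ms2)
  } else {
    tibble(mean_theta = x$mu, var_theta = undefined_marker(),
           mean_sigma2 = undefined_marker())
  }
}

#' @exportS3Method generics::tidy
tidy.nig <- function(x, ...) {
  tibble(term = c("mu", "lambda", "alpha", "beta"),
         value = c(x$mu, x$lambda, x$alpha, x$beta))
}
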