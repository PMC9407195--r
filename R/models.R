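#' Generative models for likelihood-free inference
#'
#' A generative model bundles a prior sampler and a simulator, the two
#' ingredients every ABC sampler needs; an optional prior density enables the
#' MCMC samplers. The simulator must be deterministic given the parameters
#' and the RNG state. Any latent structure (such as the genealogy of the
#' coalescent model) stays internal to the simulator.
#'
#' @param prior_sample Function `N -> N x p` numeric matrix of parameter
#'   draws (named columns).
#' @param simulate Function `theta -> dataset` for one parameter vector.
#' @param prior_density Optional function `theta -> nonnegative real`
#'   (required by the MCMC samplers only).
#' @param simulate_matrix Optional vectorised simulator: `N x p` parameter
#'   matrix to an `n_obs x N` data matrix (datasets in columns).
#' @param summary_sample Optional exact shortcut: function
#'   `(theta_matrix, summary_name) -> d x N` summary matrix drawn directly
#'   from the sampling distribution of the named summary, or `NULL` when the
#'   summary is not covered. Must agree in distribution with
#'   simulate-then-summarise; used for very large proposal budgets.
#' @param param_names Character vector of parameter names.
#' @return An object of class `generative_model`.
#' @export
generative_model <- function(prior_sample, simulate, prior_density = NULL,
                             simulate_matrix = NULL, summary_sample = NULL,
                             param_names = NULL) {
  stopifnot(is.function(prior_sample), is.function(simulate))
  structure(
    list(prior_sample = prior_sample, simulate = simulate,
         prior_density = prior_density, simulate_matrix = simulate_matrix,
         summary_sample = summary_sample, param_names = param_names),
    class = "generative_model")
}

#' The conjugate normal benchmark model
#'
#' Normal likelihood `Y_i | theta, sigma2 ~ N(theta, sigma2)` with an NIG
#' prior on `(theta, sigma2)` and a fixed number of observations per dataset.
#' Because the sampling distributions of the built-in summaries are known in
#' closed form (`ybar ~ N(theta, sigma2/n)`; `n * v ~ sigma2 * chisq(n-1)`
#' independently, by Cochran's theorem), the model can optionally draw
#' summaries directly instead of simulating full datasets, which is exact and
#' much faster at large proposal budgets.
#'
#' @param prior An [nig()] prior.
#' @param n_obs Observations per simulated dataset (>= 2).
#' @param direct_summaries If `TRUE`, samplers may draw the `mean` and
#'   `sufficient` summaries from their exact sampling distributions.
#' @return A [generative_model()].
#' @export
#' @examples
#' m <- normal_model(nig(0, 0.01, 1, 1), n_obs = 25)
normal_model <- function(prior, n_obs, direct_summaries = FALSE) {
  stopifnot(inherits(prior, "nig"), n_obs >= 2)
  summary_sample <- NULL
  if (direct_summaries) {
    summary_sample <- function(theta_mat, summary_name) {
      th <- theta_mat[, 1]; s2 <- theta_mat[, 2]
      N <- length(th)
      if (summary_name == "mean") {
        matrix(rnorm(N, th, sqrt(s2 / n_obs)), nrow = 1)
      } else if (summary_name == "sufficient") {
        ybar <- rnorm(N, th, sqrt(s2 / n_obs))
        v <- s2 * rchisq(N, df = n_obs - 1) / n_obs
        rbind(ybar, v, deparse.level = 0)
      } else NULL
    }
  }
  generative_model(
    prior_sample = function(N) {
      d <- nig_sample(prior, N)
      cbind(theta = d$theta, sigma2 = d$sigma2)
    },
    simulate = function(theta) rnorm(n_obs, theta[1], sqrt(theta[2])),
    simulate_matrix = function(theta_mat) {
      N <- nrow(theta_mat)
      matrix(rnorm(n_obs * N,
                   mean = rep(theta_mat[, 1], each = n_obs),
                   sd = rep(sqrt(theta_mat[, 2]), each = n_obs)),
             nrow = n_obs)
    },
    summary_sample = summary_sample,
    prior_density = function(theta) {
      s2 <- theta[2]
      if (s2 <= 0) return(0)
      dig <- prior$beta^prior$alpha / gamma(prior$alpha) *
        s2^(-(prior$alpha + 1)) * exp(-prior$beta / s2)
      dnorm(theta[1], prior$mu, sqrt(s2 / prior$lambda)) * dig
    },
    param_names = c("theta", "sigma2")
  )
}
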