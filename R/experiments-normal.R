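# One ABC replication on the normal benchmark: fresh observed data under the
# truth, ABC posterior-mean estimates of theta and sigma2, absolute errors
# against the conjugate analytic posterior. Returns a one-row tibble;
# acceptance failure (no draws within budget) yields NA errors.
normal_abc_errors <- function(prior, n_obs, truth, scheme,
                              mode = c("knn", "fixed"), epsilon = NULL,
                              n_proposals = NULL, m_retain = 100,
                              max_proposals = 1e7, direct_summaries = FALSE,
                              seed = NULL) {
  mode <- match.arg(mode)
  sc <- abc_scheme(scheme)
  with_seed(seed, {
    y0 <- rnorm(n_obs, truth[1], sqrt(truth[2]))
    post <- nig_posterior(prior, y0)
    mom <- nig_moments(post)
    model <- normal_model(prior, n_obs, direct_summaries = direct_summaries)
    run <- if (mode == "knn") {
      abc_knn(model, y0, sc$summary, sc$distance, n_proposals = n_proposals,
              k = m_retain)
    } else {
      abc_reject(model, y0, sc$summary, sc$distance, epsilon = epsilon,
                 n_accept = m_retain, max_proposals = max_proposals)
    }
    acc <- run$accepted
    if (nrow(acc) == 0) {
      return(tibble(err_theta = NA_real_, err_sigma2 = NA_real_,
                    n_accepted = 0L, n_proposals = run$n_proposals,
                    epsilon_realized = run$epsilon))
    }
    tibble(
      err_theta = abs(mean(acc$theta) - mom$mean_theta),
      err_sigma2 = if (is.na(mom$mean_sigma2)) NA_real_ else
        abs(mean(acc$sigma2) - mom$mean_sigma2),
      n_accepted = nrow(acc),
      n_proposals = run$n_proposals,
      epsilon_realized = run$epsilon
    )
  })
}

aggregate_errors <- function(per_rep, factors) {
  dplyr::summarise(
    dplyr::group_by(per_rep, dplyr::across(dplyr::all_of(factors))),
    mean_err_theta = mean(.data$err_theta, na.rm = TRUE),
    sd_err_theta = sd(.data$err_theta, na.rm = TRUE),
    mean_err_sigma2 = mean(.data$err_sigma2, na.rm = TRUE),
    sd_err_sigma2 = sd(.data$err_sigma2, na.rm = TRUE),
    n_reps = dplyr::n(),
    n_missing = sum(is.na(.data$err_theta) | is.na(.data$err_sigma2)),
    .groups = "drop")
}

#' Prior-sensitivity study on the normal benchmark
#'
#' Sweeps the 12-combination conjugate-prior grid — location
#' `mu in {-10, 0, 10}` (poor, neutral, good prior knowledge), precision
#' scale `lambda in {0.01, 1}` (agnostic vs specific), and
#' `(alpha, beta) in {(1,1), (3,1)}` — crossed with the summary/distance
#' schemes, estimating the posterior mean of the normal mean and variance
#' from the best `m_retain` of a fixed proposal budget (kNN retention) and
#' scoring against the analytic conjugate posterior. Observed data are
#' re-drawn each replication.
#'
#' @param schemes Character vector of `"summary+distance"` schemes.
#' @param n_obs Observations per dataset.
#' @param truth `(theta0, sigma0^2)` generating the observed data.
#' @param n_proposals Proposal budget per cell (default 34600, the size of
#'   the study this driver reproduces).
#' @param m_retain Retained draws per cell.
#' @param n_reps Replications per cell.
#' @param seed Master seed; every cell and replication runs on its own
#'   substream.
#' @return A tibble: one row per (mu, lambda, alpha, beta, scheme) with mean
#'   and SD of the absolute errors over replications.
#' @export
prior_sensitivity <- function(schemes = c("mean+euclidean",
                                          "sufficient+euclidean",
                                          "identity+wasserstein1",
                                          "identity+kl_knn"),
                              n_obs = 25, truth = c(10, 1),
                              n_proposals = 34600, m_retain = 100,
                              n_reps = 5, seed = 1) {
  grid <- tidyr::expand_grid(
    mu = c(-10, 0, 10), lambda = c(0.01, 1),
    ab = list(c(1, 1), c(3, 1)), scheme = schemes)
  grid$alpha <- vapply(grid$ab, `[`, numeric(1), 1)
  grid$beta <- vapply(grid$ab, `[`, numeric(1), 2)
  grid$ab <- NULL
  per_rep <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    cell <- grid[i, ]
    prior <- nig(cell$mu, cell$lambda, cell$alpha, cell$beta)
    purrr::map_dfr(seq_len(n_reps), function(r) {
      res <- normal_abc_errors(prior, n_obs, truth, cell$scheme,
                               mode = "knn", n_proposals = n_proposals,
                               m_retain = m_retain,
                               seed = substream_seed(seed, i, r))
      dplyr::bind_cols(cell, rep = r, res)
    })
  })
  aggregate_errors(per_rep, c("mu", "lambda", "alpha", "beta", "scheme"))
}

#' Worst-case prior-precision error ratio
#'
#' From a [prior_sensitivity()] table restricted to one scheme, computes the
#' ratio of the mean posterior-mean error under the tight prior precision
#' (`lambda = 1`) to the agnostic one (`lambda = 0.01`) at matched
#' `(mu, alpha, beta)`, and returns the maximum: the headline "how much can a
#' confidently wrong prior cost" number of the study.
#'
#' @param tbl Output of [prior_sensitivity()].
#' @param scheme Scheme to restrict to.
#' @return A single number (fold increase).
#' @export
prior_error_ratio <- function(tbl, scheme = "sufficient+euclidean") {
  t1 <- dplyr::filter(tbl, .data$scheme == !!scheme)
  wide <- tidyr::pivot_wider(
    dplyr::select(t1, "mu", "lambda", "alpha", "beta", "mean_err_theta"),
    names_from = "lambda", values_from = "mean_err_theta",
    names_prefix = "lam_")
  max(wide$lam_1 / wide$lam_0.01)
}

#' Approximation-error sweep over the tolerance
#'
#' Errors of ABC posterior-mean estimates of the normal mean and variance
#' against the analytic posterior, across a grid of tolerance, sample size,
#' retained-draw count and data-generating truth, under the diffuse
#' `NIG(0, 0.01, 1, 1)` prior with the sufficient summary and Euclidean
#' distance. `epsilon = Inf` rows return prior draws (the prior limit of
#' ABC).
#'
#' @param eps Tolerance grid.
#' @param n_obs Sample-size grid.
#' @param m_retain Retained-draw grid.
#' @param truths List of `(theta0, sigma0^2)` truths.
#' @param n_reps Replications per cell.
#' @param max_proposals Per-replication proposal cap.
#' @param prior The NIG prior.
#' @param direct_summaries Use the model's exact summary sampling shortcut.
#' @param seed Master seed.
#' @return A tidy error table keyed by the grid factors.
#' @export
epsilon_sweep <- function(eps = c(0.1, 0.25, 0.5, 1, 2),
                          n_obs = c(10, 25), m_retain = c(50, 100, 200),
                          truths = list(c(10, 1)), n_reps = 100,
                          max_proposals = 1e6, prior = nig(0, 0.01, 1, 1),
                          direct_summaries = FALSE, seed = 1) {
  grid <- tidyr::expand_grid(epsilon = eps, n_obs = n_obs,
                             m_retain = m_retain, truth = truths)
  per_rep <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    cell <- grid[i, ]
    purrr::map_dfr(seq_len(n_reps), function(r) {
      res <- normal_abc_errors(prior, cell$n_obs, cell$truth[[1]],
                               "sufficient+euclidean", mode = "fixed",
                               epsilon = cell$epsilon,
                               m_retain = cell$m_retain,
                               max_proposals = max_proposals,
                               direct_summaries = direct_summaries,
                               seed = substream_seed(seed, i, r))
      tibble(epsilon = cell$epsilon, n_obs = cell$n_obs,
             m_retain = cell$m_retain,
             theta0 = cell$truth[[1]][1], sigma0sq = cell$truth[[1]][2],
             rep = r) |> dplyr::bind_cols(res)
    })
  })
  aggregate_errors(per_rep,
                   c("epsilon", "n_obs", "m_retain", "theta0", "sigma0sq"))
}

#' Information-loss study: sufficient versus mean-only summaries
#'
#' Compares ABC posterior-mean errors under the sufficient statistic S1 =
#' (mean, 1/n variance) and the non-sufficient S2 = mean alone over a
#' tolerance grid, reproducing the four-column error-table layout (mean and
#' variance errors under each summary, with replication SDs). S2 carries no
#' information about the variance, whose estimates suffer accordingly.
#'
#' @param eps Tolerance grid (default the printed `{0.01, 0.1, ..., 0.5}`;
#'   the smallest values need very large proposal budgets — see
#'   `max_proposals`).
#' @param n_obs,truth,prior,m_retain,n_reps,max_proposals,direct_summaries,seed
#'   As in [epsilon_sweep()].
#' @return A tidy table keyed by (epsilon, summary).
#' @export
information_loss <- function(eps = c(0.01, 0.1, 0.2, 0.3, 0.4, 0.5),
                             n_obs = 25, truth = c(10, 1),
                             prior = nig(0, 0.01, 1, 1), m_retain = 100,
                             n_reps = 100, max_proposals = 1e6,
                             direct_summaries = FALSE, seed = 1) {
  grid <- tidyr::expand_grid(
    epsilon = eps,
    summary = c("sufficient", "mean"))
  per_rep <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    cell <- grid[i, ]
    purrr::map_dfr(seq_len(n_reps), function(r) {
      res <- normal_abc_errors(prior, n_obs, truth,
                               paste0(cell$summary, "+euclidean"),
                               mode = "fixed", epsilon = cell$epsilon,
                               m_retain = m_retain,
                               max_proposals = max_proposals,
                               direct_summaries = direct_summaries,
                               seed = substream_seed(seed, i, r))
      dplyr::bind_cols(cell, rep = r, res)
    })
  })
  aggregate_errors(per_rep, c("epsilon", "summary"))
}

#' Monte-Carlo-error study at fixed tolerance
#'
#' Fixes the tolerance (default 0.05), uses the sufficient summary, and
#' estimates the posterior mean of the normal mean from `M` retained draws
#' for `M` on a grid: the error falls with `M` but is floored by the bias
#' inherent in any positive tolerance.
#'
#' @param m_grid Retained-draw grid.
#' @param epsilon Fixed tolerance.
#' @inheritParams information_loss
#' @return A tidy table keyed by `m_retain`.
#' @export
mc_error_study <- function(m_grid = seq(100, 1000, by = 100), epsilon = 0.05,
                           n_obs = 25, truth = c(10, 1),
                           prior = nig(0, 0.01, 1, 1), n_reps = 100,
                           max_proposals = 1e7, direct_summaries = TRUE,
                           seed = 1) {
  per_rep <- purrr::map_dfr(seq_along(m_grid), function(i) {
    purrr::map_dfr(seq_len(n_reps), function(r) {
      res <- normal_abc_errors(prior, n_obs, truth, "sufficient+euclidean",
                               mode = "fixed", epsilon = epsilon,
                               m_retain = m_grid[i],
                               max_proposals = max_proposals,
                               direct_summaries = direct_summaries,
                               seed = substream_seed(seed, i, r))
      dplyr::bind_cols(tibble(m_retain = m_grid[i], rep = r), res)
    })
  })
  aggregate_errors(per_rep, "m_retain")
}

#' Error versus tolerance under a fixed proposal budget
#'
#' At a fixed total proposal budget, small tolerances accept too few draws
#' for reliable estimation while large ones accept many poor proposals; the
#' best tolerance is interior. Cells whose replications accept nothing are
#' recorded as missing.
#'
#' @param eps Tolerance grid.
#' @param n_proposals Fixed budget per replication.
#' @inheritParams information_loss
#' @return A tidy table keyed by `epsilon`, including the count of
#'   empty-acceptance replications.
#' @export
fixed_budget_tradeoff <- function(eps = c(0.02, 0.05, 0.1, 0.25, 0.5, 1, 2, 5),
                                  n_proposals = 34600, n_obs = 25,
                                  truth = c(10, 1),
                                  prior = nig(0, 0.01, 1, 1), n_reps = 100,
                                  direct_summaries = FALSE, seed = 1) {
  sc <- abc_scheme("sufficient+euclidean")
  per_rep <- purrr::map_dfr(seq_along(eps), function(i) {
    purrr::map_dfr(seq_len(n_reps), function(r) {
      with_seed(substream_seed(seed, i, r), {
        y0 <- rnorm(n_obs, truth[1], sqrt(truth[2]))
        mom <- nig_moments(nig_posterior(prior, y0))
        model <- normal_model(prior, n_obs, direct_summaries = direct_summaries)
        run <- abc_reject(model, y0, sc$summary, sc$distance,
                          epsilon = eps[i], n_proposals = n_proposals)
        acc <- run$accepted
        tibble(
          epsilon = eps[i], rep = r,
          err_theta = if (nrow(acc) == 0) NA_real_ else
            abs(mean(acc$theta) - mom$mean_theta),
          err_sigma2 = if (nrow(acc) == 0) NA_real_ else
            abs(mean(acc$sigma2) - mom$mean_sigma2),
          n_accepted = nrow(acc), n_proposals = run$n_proposals)
      })
    })
  })
  aggregate_errors(per_rep, "epsilon")
}

#' Parallel-scaling measurement
#'
#' Times the generation of `M` accepted draws (tolerance 0.25, 10
#' observations, truth `(10, 2)`) across worker counts, reporting wall-clock
#' seconds per cell together with the worker-invariance check: under a fixed
#' seed the pooled accepted set is identical for every worker count.
#' Runtimes are machine-relative and reported, never asserted.
#'
#' @param m_grid Accepted-draw targets.
#' @param workers Worker counts.
#' @param epsilon,n_obs,truth,prior Benchmark configuration.
#' @param seed Master seed.
#' @return A tibble with one row per (M, workers): runtime, accepted count,
#'   and whether the pooled set matched the single-worker reference.
#' @export
parallel_scaling <- function(m_grid = c(1, 4, 16, 64, 256),
                             workers = c(1, 2, 4), epsilon = 0.25,
                             n_obs = 10, truth = c(10, 2),
                             prior = nig(0, 0.01, 1, 1), seed = 1) {
  model <- normal_model(prior, n_obs)
  with_seed(substream_seed(seed, 0), {
    y0 <- rnorm(n_obs, truth[1], sqrt(truth[2]))
  })
  # pilot acceptance-rate estimate sets the proposal budget per target M
  pilot <- abc_reject(model, y0, epsilon = epsilon, n_proposals = 2e4,
                      seed = substream_seed(seed, 1))
  p_hat <- max(glance(pilot)$acceptance_rate, 1e-4)
  purrr::map_dfr(m_grid, function(M) {
    budget <- as.integer(ceiling(M / p_hat * 1.5) + 100)
    ref <- NULL
    purrr::map_dfr(workers, function(w) {
      tm <- system.time(
        run <- abc_parallel(model, y0, epsilon = epsilon,
                            n_proposals = budget, n_workers = w,
                            seed = substream_seed(seed, 2))
      )["elapsed"]
      same <- if (is.null(ref)) {
        ref <<- run$accepted
        TRUE
      } else identical(ref, run$accepted)
      tibble(m_target = M, workers = w, budget = budget,
             n_accepted = nrow(run$accepted), seconds = unname(tm),
             pooled_identical = same)
    })
  })
}
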