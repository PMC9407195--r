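# Proposal machinery shared by the rejection-family samplers.
#
# A proposal batch is (theta, S): an N x p parameter matrix and the summaries
# of the datasets simulated under each row. S is a d x N matrix for
# fixed-dimension summaries, or a list of raw datasets for the identity
# summary. The fast paths (vectorised simulator, direct summary sampling) are
# used when the model provides them and must agree with the reference
# per-proposal path (tested).
propose_batch <- function(model, summary, N) {
  theta <- model$prior_sample(N)
  if (!is.matrix(theta)) theta <- matrix(theta, ncol = 1)
  S <- NULL
  if (!is.null(model$summary_sample)) {
    S <- model$summary_sample(theta, summary$name)
  }
  if (is.null(S)) {
    if (!is.na(summary$dim) && !is.null(model$simulate_matrix) &&
        !is.null(summary$map_matrix)) {
      S <- summary$map_matrix(model$simulate_matrix(theta))
    } else {
      ys <- lapply(seq_len(N), function(i) model$simulate(theta[i, ]))
      if (is.na(summary$dim)) {
        S <- lapply(ys, summary$map)
      } else {
        S <- vapply(ys, summary$map, numeric(summary$dim))
        if (summary$dim == 1L) S <- matrix(S, nrow = 1)
      }
    }
  }
  list(theta = theta, S = S)
}

batch_distances <- function(distance, S, s0) {
  if (is.list(S)) {
    vapply(S, function(s) distance$map(s, s0), numeric(1))
  } else if (!is.null(distance$map_batch)) {
    distance$map_batch(S, s0)
  } else {
    apply(S, 2, function(s) distance$map(s, s0))
  }
}

observed_summary <- function(summary, y0) {
  if (is.na(summary$dim)) y0 else summary$map(y0)
}

accepted_tibble <- function(theta, S, d, idx, param_names) {
  out <- as_tibble(as.data.frame(theta[idx, , drop = FALSE]))
  names(out) <- param_names %||% paste0("param", seq_len(ncol(theta)))
  if (!is.list(S)) {
    Sm <- t(S[, idx, drop = FALSE])
    colnames(Sm) <- paste0("s", seq_len(ncol(Sm)))
    out <- dplyr::bind_cols(out, as_tibble(as.data.frame(Sm)))
  }
  out$distance <- d[idx]
  out
}

#' Classical accept/reject sampling from a density
#'
#' Draws from a target density `f` by proposing from `g` and accepting with
#' probability `f / (c g)`, where `c` bounds `f/g` on the support. The
#' empirical acceptance rate (expected value `1/c` when `c` is tight) is
#' reported alongside the draws.
#'
#' @param target_density Function `x -> f(x)`.
#' @param proposal_sampler Function `n -> n` proposal draws.
#' @param proposal_density Function `x -> g(x)`.
#' @param c Envelope constant with `f <= c g` everywhere.
#' @param n_draws Number of accepted draws required.
#' @param seed Optional seed.
#' @return A list with `draws` (length `n_draws`), `acceptance_rate` and
#'   `n_proposals`.
#' @export
accept_reject <- function(target_density, proposal_sampler, proposal_density,
                          c, n_draws, seed = NULL) {
  stopifnot(c > 0, n_draws >= 1)
  with_seed(seed, {
    draws <- numeric(0)
    n_prop <- 0L
    while (length(draws) < n_draws) {
      m <- max(1000L, as.integer(ceiling((n_draws - length(draws)) * c * 1.5)))
      x <- proposal_sampler(m)
      ratio <- target_density(x) / (c * proposal_density(x))
      if (any(ratio > 1 + 1e-12)) {
        abort("Envelope bound violated: f(x) > c * g(x) at a proposal.",
              class = "abcbench_bound_error")
      }
      keep <- runif(m) <= ratio
      draws <- c(draws, x[keep])
      n_prop <- n_prop + m
    }
    list(draws = draws[seq_len(n_draws)],
         acceptance_rate = length(draws) / n_prop,
         n_proposals = n_prop)
  })
}

#' Likelihood-free exact-match posterior sampler
#'
#' Accepts a proposed parameter only when its simulated dataset equals the
#' observed dataset exactly. Practical only for discrete data spaces where
#' equality has positive probability; accepted draws are then exact posterior
#' draws. An empty acceptance set is reported with a warning, not an error.
#'
#' @param model A [generative_model()].
#' @param y0 Observed dataset.
#' @param n_proposals Number of prior proposals.
#' @param seed Optional seed.
#' @return An `abc_run` with `epsilon = 0`.
#' @export
abc_exact_match <- function(model, y0, n_proposals, seed = NULL) {
  with_seed(seed, {
    theta <- model$prior_sample(n_proposals)
    if (!is.matrix(theta)) theta <- matrix(theta, ncol = 1)
    hit <- vapply(seq_len(n_proposals), function(i) {
      y <- model$simulate(theta[i, ])
      length(y) == length(y0) && all(y == y0)
    }, logical(1))
    idx <- which(hit)
    if (length(idx) == 0) {
      rlang::warn("Exact-match run accepted no proposals.",
                  class = "abcbench_empty_run")
    }
    acc <- accepted_tibble(theta, S = list(), d = rep(0, n_proposals), idx,
                           model$param_names)
    new_abc_run(acc, n_proposals, epsilon = 0, seed = seed,
                scheme = "exact", kind = "exact")
  })
}

#' Fixed-tolerance ABC rejection sampler
#'
#' Proposes parameters from the prior, simulates a dataset under each,
#' and accepts those whose summary lies within distance `epsilon` of the
#' observed summary. Accepted draws are i.i.d. from the ABC posterior; with a
#' sufficient summary and `epsilon -> 0` that approximation converges to the
#' exact posterior, while `epsilon = Inf` returns prior draws.
#'
#' Either a fixed proposal budget (`n_proposals`) or a target number of
#' accepted draws (`n_accept`, proposals generated in chunks until reached or
#' `max_proposals` is hit) can be requested. Empty acceptance under a fixed
#' budget is a valid, flagged outcome, never an error.
#'
#' @param model A [generative_model()].
#' @param y0 Observed dataset.
#' @param summary Summary spec or name (see [abc_summary()]).
#' @param distance Distance spec or name (see [abc_distance()]).
#' @param epsilon Tolerance (`>= 0`, `Inf` permitted).
#' @param n_proposals Fixed proposal budget (exclusive with `n_accept`).
#' @param n_accept Target number of accepted draws.
#' @param max_proposals Proposal cap in `n_accept` mode.
#' @param chunk_size Proposals per internal batch.
#' @param seed Optional seed.
#' @return An `abc_run`.
#' @export
#' @examples
#' m <- normal_model(nig(0, 0.01, 1, 1), n_obs = 25)
#' y0 <- simulate_normal(10, 1, 25, seed = 7)
#' run <- abc_reject(m, y0, "sufficient", "euclidean", epsilon = 1,
#'                   n_proposals = 5000, seed = 1)
#' glance(run)
abc_reject <- function(model, y0, summary = "sufficient",
                       distance = "euclidean", epsilon,
                       n_proposals = NULL, n_accept = NULL,
                       max_proposals = 1e7, chunk_size = 1e5, seed = NULL) {
  if (!is_scalar_number(epsilon) && !identical(epsilon, Inf)) {
    abort("`epsilon` must be a single nonnegative number (Inf permitted).",
          class = "abcbench_domain_error")
  }
  if (epsilon < 0) abort("`epsilon` must be >= 0.", class = "abcbench_domain_error")
  if (is.null(n_proposals) == is.null(n_accept)) {
    abort("Supply exactly one of `n_proposals` or `n_accept`.",
          class = "abcbench_domain_error")
  }
  summary <- abc_summary(summary)
  distance <- abc_distance(distance)
  s0 <- observed_summary(summary, y0)
  scheme <- paste0(summary$name, "+", distance$name)

  with_seed(seed, {
    if (!is.null(n_proposals)) {
      acc_parts <- list()
      done <- 0
      while (done < n_proposals) {
        m <- as.integer(min(chunk_size, n_proposals - done))
        b <- propose_batch(model, summary, m)
        d <- batch_distances(distance, b$S, s0)
        idx <- which(d <= epsilon)
        acc_parts[[length(acc_parts) + 1]] <-
          accepted_tibble(b$theta, b$S, d, idx, model$param_names)
        done <- done + m
      }
      acc <- dplyr::bind_rows(acc_parts)
      new_abc_run(acc, n_proposals, epsilon, seed, scheme)
    } else {
      acc <- NULL
      n_prop <- 0
      while ((is.null(acc) || nrow(acc) < n_accept) && n_prop < max_proposals) {
        m <- as.integer(min(chunk_size, max_proposals - n_prop))
        b <- propose_batch(model, summary, m)
        d <- batch_distances(distance, b$S, s0)
        idx <- which(d <= epsilon)
        part <- accepted_tibble(b$theta, b$S, d, idx, model$param_names)
        acc <- if (is.null(acc)) part else dplyr::bind_rows(acc, part)
        n_prop <- n_prop + m
      }
      if (nrow(acc) > n_accept) acc <- acc[seq_len(n_accept), ]
      new_abc_run(acc, n_prop, epsilon, seed, scheme)
    }
  })
}

#' k-nearest-neighbour ABC sampler
#'
#' Generates the same prior/simulate proposal stream as [abc_reject()] but
#' retains exactly the `k` proposals whose summaries are nearest the observed
#' summary, recording the realised tolerance as the (k+1)-th smallest
#' distance. Ties at the retention boundary are broken by proposal index
#' (earlier proposal wins), making results order-reproducible. The default
#' `k` is a tenth of the proposal budget.
#'
#' @inheritParams abc_reject
#' @param k Number of proposals to retain (default `n_proposals / 10`).
#' @return An `abc_run` with `kind = "knn"`.
#' @export
abc_knn <- function(model, y0, summary = "sufficient", distance = "euclidean",
                    n_proposals, k = NULL, chunk_size = 1e5, seed = NULL) {
  k <- k %||% max(1L, as.integer(n_proposals / 10))
  if (k > n_proposals) {
    abort("`k` cannot exceed `n_proposals`.", class = "abcbench_size_error")
  }
  summary <- abc_summary(summary)
  distance <- abc_distance(distance)
  s0 <- observed_summary(summary, y0)
  scheme <- paste0(summary$name, "+", distance$name)

  with_seed(seed, {
    thetas <- list(); Ss <- list(); ds <- list()
    done <- 0
    while (done < n_proposals) {
      m <- as.integer(min(chunk_size, n_proposals - done))
      b <- propose_batch(model, summary, m)
      d <- batch_distances(distance, b$S, s0)
      thetas[[length(thetas) + 1]] <- b$theta
      Ss[[length(Ss) + 1]] <- b$S
      ds[[length(ds) + 1]] <- d
      done <- done + m
    }
    theta <- do.call(rbind, thetas)
    d <- unlist(ds)
    S <- if (is.list(Ss[[1]])) do.call(c, Ss) else do.call(cbind, Ss)
    # stable order: ties broken by proposal index
    o <- order(d)
    keep <- o[seq_len(k)]
    eps_real <- if (k < n_proposals) d[o[k + 1]] else Inf
    acc <- accepted_tibble(theta, S, d, keep, model$param_names)
    new_abc_run(acc, n_proposals, eps_real, seed, scheme, kind = "knn")
  })
}

#' Pseudo-marginal ABC MCMC sampler
#'
#' Likelihood-free Metropolis-Hastings: at each step `J` datasets are
#' simulated under the proposed parameters and the acceptance ratio is
#' weighted by `bhat`, the fraction falling within the `epsilon`-ball around
#' the observed summary. With a symmetric proposal kernel the ratio is
#' `pi(theta') bhat(theta') / (pi(theta) bhat(theta))`. On a discrete data
#' space with `J = 1` and `epsilon = 0` this is the exact likelihood-free
#' MCMC sampler. Initialisation redraws from the prior until a state with
#' positive `bhat` is found (bounded retries).
#'
#' @inheritParams abc_reject
#' @param J Simulated datasets per proposal.
#' @param proposal_sd Scale(s) of the Gaussian random-walk kernel (recycled
#'   over parameters). Zero is permitted (degenerate kernel: the chain never
#'   moves).
#' @param proposal_kernel Optional symmetric proposal function
#'   `theta -> theta'` overriding the Gaussian kernel (e.g. a support-point
#'   flip for discrete parameter spaces).
#' @param n_iter Chain length (post-initialisation).
#' @param init Optional initial parameter vector (default: drawn from prior).
#' @param max_init_tries Initialisation retry bound.
#' @return A tibble with columns `iteration`, the parameters, and `accepted`.
#' @export
abc_mcmc <- function(model, y0, summary = "sufficient", distance = "euclidean",
                     epsilon, J = 1, proposal_sd = 1, n_iter = 1000,
                     proposal_kernel = NULL, init = NULL,
                     max_init_tries = 1000, seed = NULL) {
  if (is.null(model$prior_density)) {
    abort("`model` must provide `prior_density` for MCMC sampling.",
          class = "abcbench_domain_error")
  }
  summary <- abc_summary(summary)
  distance <- abc_distance(distance)
  s0 <- observed_summary(summary, y0)

  bhat <- function(theta) {
    hits <- 0L
    for (j in seq_len(J)) {
      yj <- model$simulate(theta)
      s <- if (is.na(summary$dim)) yj else summary$map(yj)
      if (distance$map(s, s0) <= epsilon) hits <- hits + 1L
    }
    hits / J
  }

  with_seed(seed, {
    theta <- init
    b <- if (is.null(theta)) 0 else bhat(theta)
    tries <- 0L
    while (b == 0) {
      tries <- tries + 1L
      if (tries > max_init_tries) {
        abort("Could not initialise the chain: bhat = 0 after bounded retries.",
              class = "abcbench_init_error")
      }
      theta <- drop(model$prior_sample(1))
      b <- bhat(theta)
    }
    p <- length(theta)
    sdv <- rep_len(proposal_sd, p)
    chain <- matrix(NA_real_, n_iter, p)
    acc_flag <- logical(n_iter)
    pi_cur <- model$prior_density(theta)
    for (it in seq_len(n_iter)) {
      prop <- if (is.null(proposal_kernel)) theta + rnorm(p, 0, sdv) else
        proposal_kernel(theta)
      pi_prop <- model$prior_density(prop)
      if (pi_prop > 0) {
        b_prop <- bhat(prop)
        ratio <- (pi_prop * b_prop) / (pi_cur * b)
        if (runif(1) <= ratio) {
          theta <- prop; b <- b_prop; pi_cur <- pi_prop
          acc_flag[it] <- TRUE
        }
      }
      chain[it, ] <- theta
    }
    out <- as_tibble(as.data.frame(chain))
    names(out) <- model$param_names %||% paste0("param", seq_len(p))
    out$iteration <- seq_len(n_iter)
    out$accepted <- acc_flag
    dplyr::relocate(out, "iteration")
  })
}
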