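test_that("accept_reject recovers a Beta target from uniform proposals", {
  # f = g, c = 1: every proposal accepted
  r0 <- accept_reject(function(x) dnorm(x), function(n) rnorm(n),
                      function(x) dnorm(x), c = 1, n_draws = 500, seed = 1)
  expect_equal(r0$acceptance_rate, 1)

  r <- accept_reject(function(x) dbeta(x, 2, 1), function(n) runif(n),
                     function(x) rep(1, length(x)), c = 2, n_draws = 2e4,
                     seed = 2)
  expect_equal(r$acceptance_rate, 0.5, tolerance = 0.05)
  expect_equal(mean(r$draws), 2 / 3, tolerance = 0.01)
  ks <- suppressWarnings(ks.test(r$draws, function(q) q^2))
  expect_gt(ks$p.value, 0.01)

  expect_error(
    accept_reject(function(x) dbeta(x, 2, 1), function(n) runif(n),
                  function(x) rep(1, length(x)), c = 1.5, n_draws = 100,
                  seed = 3),
    class = "abcbench_bound_error")
})

test_that("exact-match sampling reproduces enumerated discrete posteriors", {
  m <- binom_toy_model(1, c(0.2, 0.8))
  run <- abc_exact_match(m, 1L, n_proposals = 2e4, seed = 4)
  expect_equal(mean(tidy(run)$p == 0.8), 0.8, tolerance = 0.03)
  expect_equal(run$epsilon, 0)

  # observation outside the support: empty run is flagged, not an error
  expect_warning(
    empty <- abc_exact_match(m, 7L, n_proposals = 100, seed = 5),
    class = "abcbench_empty_run")
  expect_equal(nrow(tidy(empty)), 0)

  m3 <- binom_toy_model(5, c(0.1, 0.5, 0.9), weights = c(0.5, 0.3, 0.2))
  post <- binom_toy_posterior(5, c(0.1, 0.5, 0.9), c(0.5, 0.3, 0.2), y0 = 3)
  run3 <- abc_exact_match(m3, 3L, n_proposals = 4e4, seed = 6)
  freq <- as.numeric(table(factor(tidy(run3)$p, levels = c(0.1, 0.5, 0.9))))
  expect_equal(freq / sum(freq), post, tolerance = 0.05)
})

test_that("infinite tolerance accepts everything and returns prior draws", {
  prior <- nig(0, 1, 3, 1)
  model <- normal_model(prior, 10)
  y0 <- simulate_normal(0, 1, 10, seed = 7)
  run <- abc_reject(model, y0, epsilon = Inf, n_proposals = 5000, seed = 8)
  expect_equal(nrow(tidy(run)), 5000)
  ref <- nig_sample(prior, 5000, seed = 9)
  ks <- suppressWarnings(ks.test(tidy(run)$theta, ref$theta))
  expect_gt(ks$p.value, 0.01)
})

test_that("rejection at small tolerance recovers the analytic posterior mean", {
  prior <- nig(10, 1, 3, 1)
  model <- normal_model(prior, 25)
  y0 <- simulate_normal(10, 1, 25, seed = 10)
  mom <- nig_moments(nig_posterior(prior, y0))
  run <- abc_reject(model, y0, "sufficient", "euclidean", epsilon = 0.05,
                    n_accept = 400, max_proposals = 2e6, seed = 11)
  acc <- tidy(run)
  mcse <- sd(acc$theta) / sqrt(nrow(acc))
  expect_lt(abs(mean(acc$theta) - mom$mean_theta), 3 * mcse + 0.05)
})

test_that("posterior error shrinks as the tolerance shrinks", {
  prior <- nig(0, 0.01, 1, 1)
  model <- normal_model(prior, 25)
  eps_grid <- c(2, 0.5, 0.1)
  errs <- vapply(1:10, function(r) {
    set.seed(100 + r)
    y0 <- rnorm(25, 10, 1)
    mu_star <- nig_posterior(prior, y0)$mu
    vapply(eps_grid, function(e) {
      run <- abc_reject(model, y0, epsilon = e, n_accept = 100,
                        max_proposals = 4e5, seed = 1000 + r)
      abs(mean(tidy(run)$theta) - mu_star)
    }, numeric(1))
  }, numeric(length(eps_grid)))
  med <- apply(errs, 1, median)
  expect_true(all(diff(med) < 0))
})

test_that("direct summary sampling matches simulate-then-summarise in distribution", {
  prior <- nig(0, 0.5, 3, 2)
  y0 <- simulate_normal(1, 2, 25, seed = 12)
  full <- abc_reject(normal_model(prior, 25), y0, epsilon = 1.5,
                     n_proposals = 4e4, seed = 13)
  fast <- abc_reject(normal_model(prior, 25, direct_summaries = TRUE), y0,
                     epsilon = 1.5, n_proposals = 4e4, seed = 13)
  # same acceptance probability and same accepted-theta distribution
  expect_equal(nrow(tidy(fast)), nrow(tidy(full)), tolerance = 0.1)
  ks <- suppressWarnings(ks.test(tidy(fast)$theta, tidy(full)$theta))
  expect_gt(ks$p.value, 0.01)
  ks2 <- suppressWarnings(ks.test(tidy(fast)$s2, tidy(full)$s2))
  expect_gt(ks2$p.value, 0.01)
})

test_that("kNN retention equals the k smallest of a full sort and records d(k+1)", {
  prior <- nig(0, 1, 3, 1)
  y0 <- simulate_normal(2, 1, 15, seed = 14)
  model <- normal_model(prior, 15)
  # same stream design: one block, same substream seed
  knn <- abc_parallel(model, y0, sampler = "knn", k = 50, n_proposals = 3000,
                      n_blocks = 4, seed = 15)
  all_run <- abc_parallel(model, y0, sampler = "reject", epsilon = Inf,
                          n_proposals = 3000, n_blocks = 4, seed = 15)
  d_all <- sort(tidy(all_run)$distance)
  expect_equal(sort(tidy(knn)$distance), d_all[1:50], tolerance = 1e-12)
  expect_equal(knn$epsilon, d_all[51])
  expect_true(all(tidy(knn)$distance <= knn$epsilon))

  # k = N returns the entire prior-draw set
  knn_all <- abc_knn(model, y0, n_proposals = 500, k = 500, seed = 16)
  expect_equal(nrow(tidy(knn_all)), 500)
  # default k is a tenth of the budget
  knn_def <- abc_knn(model, y0, n_proposals = 500, seed = 17)
  expect_equal(nrow(tidy(knn_def)), 50)
  expect_error(abc_knn(model, y0, n_proposals = 10, k = 11, seed = 1),
               class = "abcbench_size_error")
})

test_that("acceptance counts behave as a binomial across seeded replicates", {
  prior <- nig(0, 1, 3, 1)
  model <- normal_model(prior, 10)
  y0 <- simulate_normal(0, 1, 10, seed = 18)
  N <- 400
  counts <- vapply(1:200, function(r) {
    nrow(tidy(abc_reject(model, y0, epsilon = 0.8, n_proposals = N,
                         seed = 2000 + r)))
  }, numeric(1))
  p_hat <- mean(counts) / N
  # variance ratio against Binomial(N, p_hat); chi-square bounds at 1%
  ratio <- var(counts) * 199 / (N * p_hat * (1 - p_hat))
  expect_gt(ratio, qchisq(0.005, 199))
  expect_lt(ratio, qchisq(0.995, 199))
})

test_that("pseudo-marginal MCMC matches enumerated posteriors and degenerates sanely", {
  m <- binom_toy_model(1, c(0.2, 0.8))
  flip <- function(theta) ifelse(theta == 0.2, 0.8, 0.2)
  chain <- abc_mcmc(m, 1L, "identity", "euclidean", epsilon = 0, J = 1,
                    proposal_kernel = flip, n_iter = 4000, seed = 19)
  expect_equal(mean(chain$p == 0.8), 0.8, tolerance = 0.05)

  # zero step size: the chain never moves
  prior <- nig(0, 1, 3, 1)
  model <- normal_model(prior, 10)
  y0 <- simulate_normal(0, 1, 10, seed = 20)
  frozen <- abc_mcmc(model, y0, epsilon = Inf, proposal_sd = 0,
                     n_iter = 50, seed = 21)
  expect_equal(length(unique(frozen$theta)), 1)
  expect_true(all(frozen$accepted))
})

test_that("MCMC and rejection agree on the normal benchmark at matched tolerance", {
  prior <- nig(10, 1, 3, 1)
  model <- normal_model(prior, 25)
  y0 <- simulate_normal(10, 1, 25, seed = 22)
  rej <- abc_reject(model, y0, epsilon = 0.3, n_accept = 300,
                    max_proposals = 1e6, seed = 23)
  ch <- abc_mcmc(model, y0, epsilon = 0.3, J = 1,
                 proposal_sd = c(0.4, 0.4), n_iter = 3000, seed = 24)
  keep <- ch[ch$iteration > 500, ]
  joint_se <- sd(tidy(rej)$theta) / sqrt(nrow(tidy(rej))) +
    sd(keep$theta) / sqrt(200)  # generous ESS guess for the chain
  expect_lt(abs(mean(keep$theta) - mean(tidy(rej)$theta)), 4 * joint_se + 0.05)
})

test_that("pooled parallel output is invariant to the worker count", {
  prior <- nig(0, 1, 3, 1)
  model <- normal_model(prior, 10)
  y0 <- simulate_normal(0, 1, 10, seed = 25)
  runs <- lapply(c(1, 4, 8), function(w) {
    abc_parallel(model, y0, sampler = "reject", epsilon = 1,
                 n_proposals = 8123, n_workers = w, seed = 26)
  })
  expect_identical(runs[[1]]$accepted, runs[[2]]$accepted)
  expect_identical(runs[[1]]$accepted, runs[[3]]$accepted)
  expect_equal(runs[[2]]$n_proposals, 8123)

  knn_runs <- lapply(c(1, 3), function(w) {
    abc_parallel(model, y0, sampler = "knn", k = 100, n_proposals = 4000,
                 n_workers = w, seed = 27)
  })
  expect_identical(knn_runs[[1]]$accepted, knn_runs[[2]]$accepted)
  expect_error(abc_parallel(model, y0, epsilon = 1, n_proposals = 10,
                            n_workers = 0, seed = 1),
               class = "abcbench_size_error")
})
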