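test_that("error tables are pure functions of configuration and seed", {
  a <- epsilon_sweep(eps = c(1, 2), n_obs = 10, m_retain = 30,
                     n_reps = 3, max_proposals = 2e4, seed = 5)
  b <- epsilon_sweep(eps = c(1, 2), n_obs = 10, m_retain = 30,
                     n_reps = 3, max_proposals = 2e4, seed = 5)
  expect_identical(a, b)
  expect_true(all(c("epsilon", "mean_err_theta", "sd_err_theta",
                    "mean_err_sigma2", "sd_err_sigma2", "n_reps") %in% names(a)))
  expect_true(all(a$n_reps == 3))
})

test_that("replication aggregates match a naive recomputation", {
  per_rep <- tibble::tibble(
    epsilon = rep(c(0.5, 1), each = 4),
    err_theta = c(1, 2, 3, 4, 5, 6, 7, NA),
    err_sigma2 = c(2, 2, 2, 2, 1, 3, 5, NA))
  agg <- abcbench:::aggregate_errors(per_rep, "epsilon")
  expect_equal(agg$mean_err_theta, c(mean(1:4), mean(5:7)))
  expect_equal(agg$sd_err_theta, c(sd(1:4), sd(5:7)))
  expect_equal(agg$n_missing, c(0, 1))
})

test_that("the prior limit of the sweep reproduces prior-moment error", {
  prior <- nig(0, 0.01, 1, 1)
  tbl <- epsilon_sweep(eps = Inf, n_obs = 25, m_retain = 400,
                       truths = list(c(10, 1)), n_reps = 10,
                       max_proposals = 1e4, prior = prior, seed = 6)
  # accepted draws are prior draws; their mean sits at the prior mu = 0,
  # so the error approaches |mu* - 0| ~ 10 (the posterior mean near 10)
  expect_equal(tbl$mean_err_theta, 10, tolerance = 0.15)
})

test_that("error decreases with the retained sample size at fixed tolerance", {
  tbl <- mc_error_study(m_grid = c(50, 800), epsilon = 0.25, n_reps = 20,
                        max_proposals = 1e6, seed = 7)
  expect_lt(tbl$mean_err_theta[tbl$m_retain == 800],
            tbl$mean_err_theta[tbl$m_retain == 50])
})

test_that("fixed-budget tradeoff records missing cells at starved tolerances", {
  tbl <- fixed_budget_tradeoff(eps = c(0.001, 0.5, 5), n_proposals = 3000,
                               n_reps = 6, seed = 8)
  expect_equal(nrow(tbl), 3)
  # the tiny tolerance accepts (nearly) nothing at this budget
  expect_gt(tbl$n_missing[tbl$epsilon == 0.001],
            tbl$n_missing[tbl$epsilon == 5])
})

test_that("prior sensitivity favours the well-located prior at tight precision", {
  tbl <- prior_sensitivity(schemes = "sufficient+euclidean",
                           n_proposals = 4000, m_retain = 40, n_reps = 2,
                           seed = 9)
  expect_equal(nrow(tbl), 12)
  lam1 <- dplyr::filter(tbl, lambda == 1)
  err_good <- mean(lam1$mean_err_theta[lam1$mu == 10])
  err_poor <- mean(lam1$mean_err_theta[lam1$mu == -10])
  expect_lt(err_good, err_poor)
  expect_gt(prior_error_ratio(tbl), 1)
})

test_that("parallel scaling reports worker-invariant pooled results", {
  tbl <- parallel_scaling(m_grid = c(4, 16), workers = c(1, 2), seed = 10)
  expect_true(all(tbl$pooled_identical))
  expect_true(all(tbl$seconds >= 0))
  expect_equal(nrow(tbl), 4)
})

test_that("popgen replication retains draws inside the prior box, sorted by distance", {
  rep1 <- popgen_replication(schemes = c("hamming", "all4"),
                             n_proposals = 2e4, n_retain = 50, seed = 11)
  r <- tidy(rep1)
  expect_equal(nrow(r), 100)
  expect_true(all(r$alpha >= 0 & r$alpha <= 200))
  expect_true(all(r$theta0 >= 0 & r$theta0 <= 200))
  # retained per scheme are the nearest: distances sorted and nonnegative
  for (w in c("hamming", "all4")) {
    d <- r$distance[r$scheme == w]
    expect_false(is.unsorted(d))
    expect_true(all(d >= 0))
  }
  expect_true(all(c("level", "polygon", "x", "y") %in% names(rep1$hpd)))
  # determinism
  rep2 <- popgen_replication(schemes = c("hamming", "all4"),
                             n_proposals = 2e4, n_retain = 50, seed = 11)
  expect_identical(tidy(rep1), tidy(rep2))
})

test_that("HPD contours are nested and enclose their nominal mass", {
  set.seed(12)
  z <- matrix(rnorm(4000), ncol = 2)
  cont <- hpd_contours(z, levels = c(0.25, 0.9))
  expect_true(all(sort(unique(cont$level)) == c(0.25, 0.9)))
  # nesting: the 0.25 region lies inside the 0.9 region (radius comparison
  # works because the density is radially symmetric)
  r25 <- max(sqrt(cont$x[cont$level == 0.25]^2 + cont$y[cont$level == 0.25]^2))
  r90 <- min(sqrt(cont$x[cont$level == 0.9]^2 + cont$y[cont$level == 0.9]^2))
  expect_lt(r25, r90 + 0.3)
  for (lv in c(0.25, 0.5, 0.9)) {
    expect_lt(abs(hpd_enclosed_mass(z, lv) - lv), 0.05)
  }
  # permutation invariance
  cont_p <- hpd_contours(z[sample(nrow(z)), ], levels = c(0.25, 0.9))
  expect_equal(cont, cont_p)
  expect_error(hpd_contours(z[1:50, ]), class = "abcbench_size_error")
  expect_error(hpd_contours(cbind(z[, 1], z[, 1] * 0)),
               class = "abcbench_degenerate_error")
})
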