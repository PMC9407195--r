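test_that("summary maps give the documented values and conventions", {
  expect_equal(summary_mean()$map(c(1, 2, 3)), 2)
  expect_equal(summary_mean()$map(rep(4.5, 7)), 4.5)
  # sufficient statistic uses the 1/n variance convention
  expect_equal(summary_sufficient()$map(c(1, 2, 3)), c(2, 2 / 3))
  expect_equal(summary_sufficient()$map(rep(2, 5)), c(2, 0))
  # shifting moves only the location component
  y <- rnorm(20)
  s <- summary_sufficient()$map(y)
  s_shift <- summary_sufficient()$map(y + 3)
  expect_equal(s_shift, c(s[1] + 3, s[2]))
  expect_identical(summary_identity()$map(y), y)
  expect_error(abc_summary("nope"), class = "abcbench_lookup_error")
})

test_that("vectorised summary maps agree with per-dataset maps", {
  set.seed(1)
  Y <- matrix(rnorm(25 * 50), 25)
  for (spec in list(summary_mean(), summary_sufficient())) {
    expect_equal(spec$map_matrix(Y),
                 vapply(seq_len(50), function(j) spec$map(Y[, j]),
                        numeric(spec$dim)) |> matrix(nrow = spec$dim),
                 tolerance = 1e-12)
  }
})

test_that("euclidean distance is a metric and matches direct summation", {
  expect_equal(euclidean(c(0, 0), c(3, 4)), 5)
  expect_error(euclidean(1:2, 1:3), class = "abcbench_size_error")
  set.seed(2)
  for (i in 1:25) {
    a <- rnorm(4); b <- rnorm(4)
    expect_equal(euclidean(a, b), sqrt(sum((a - b)^2)))
    expect_equal(euclidean(a, a), 0)
    expect_equal(euclidean(a, b), euclidean(b, a))
  }
  # batch form agrees with scalar form
  S <- matrix(rnorm(3 * 40), 3)
  s0 <- rnorm(3)
  d <- abc_distance("euclidean")
  expect_equal(d$map_batch(S, s0),
               apply(S, 2, function(s) euclidean(s, s0)))
})

test_that("wasserstein1 breakpoint integral matches the sorted-difference identity", {
  expect_equal(wasserstein1(c(0, 1), c(1, 2)), 1)
  set.seed(3)
  for (i in 1:100) {
    n <- sample(2:40, 1)
    y <- rnorm(n, sd = runif(1, 0.5, 3)); y0 <- rnorm(n, runif(1, -2, 2))
    expect_equal(wasserstein1(y, y0), mean(abs(sort(y) - sort(y0))),
                 tolerance = 1e-12)
    expect_equal(wasserstein1(y, y), 0)
    # metric axioms and translation equivariance
    expect_equal(wasserstein1(y, y0), wasserstein1(y0, y))
    cshift <- runif(1, -5, 5)
    expect_equal(wasserstein1(y + cshift, y0 + cshift), wasserstein1(y, y0))
  }
})

test_that("wasserstein1 handles unequal sizes and weights", {
  # mass 1 at 0 vs mass split at 0 and 2: CDFs differ by 1/2 on (0, 2)
  expect_equal(wasserstein1(0, c(0, 2)), 1)
  # weighted point masses: |F diff| = 0.3 on (0, 1)
  expect_equal(wasserstein1(c(0, 1), c(0, 1), w = c(0.5, 0.5),
                            w0 = c(0.8, 0.2)), 0.3)
  expect_error(wasserstein1(numeric(0), 1), class = "abcbench_size_error")
  expect_error(wasserstein1(c(0, 1), c(0, 1), w = c(0.6, 0.6)),
               class = "abcbench_domain_error")
  # cross-check against a fine-grid Riemann integral of |F1 - F2|
  set.seed(4)
  y <- rnorm(13); y0 <- rnorm(29, 0.5)
  grid <- seq(-6, 6.5, by = 1e-4)
  F1 <- ecdf(y)(grid); F2 <- ecdf(y0)(grid)
  expect_equal(wasserstein1(y, y0), sum(abs(F1 - F2)) * 1e-4, tolerance = 1e-3)
})

test_that("kl_knn estimates the Gaussian KL divergence and is asymmetric", {
  set.seed(5)
  y0 <- rnorm(1e4); y <- rnorm(1e4)
  expect_lt(abs(kl_knn(y0, y)), 0.05)
  y1 <- rnorm(1e4, 1)
  est <- kl_knn(y0, y1)
  expect_lt(abs(est - 0.5), 0.1)  # KL(N(0,1) || N(1,1)) = 1/2
  expect_false(isTRUE(all.equal(est, kl_knn(y1, y0))))
  expect_error(kl_knn(1, 1:5), class = "abcbench_size_error")
})

test_that("kl_knn error shrinks with sample size on matched Gaussians", {
  set.seed(6)
  med_err <- vapply(c(1e2, 1e3, 1e4), function(n) {
    median(vapply(1:50, function(i) abs(kl_knn(rnorm(n), rnorm(n))),
                  numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med_err) < 0))
})

test_that("kl_knn survives ties via jitter and supports k > 1", {
  set.seed(7)
  y0 <- round(rnorm(500), 1)  # heavy ties
  y <- round(rnorm(500), 1)
  expect_true(is.finite(kl_knn(y0, y)))
  y0b <- rnorm(2000); y1b <- rnorm(2000, 1)
  expect_lt(abs(kl_knn(y0b, y1b, k = 5) - 0.5), 0.15)
})

test_that("scheme strings resolve to registered summary/distance pairs", {
  sc <- abc_scheme("sufficient+euclidean")
  expect_equal(sc$summary$name, "sufficient")
  expect_equal(sc$distance$name, "euclidean")
  sc2 <- abc_scheme("identity+kl_knn")
  expect_false(sc2$distance$metric)
  expect_error(abc_scheme("sufficient"), class = "abcbench_lookup_error")
})
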