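# Independent oracles and toy models used across the suite.

# Inverse-gamma quantile (rate parameterisation) via the gamma quantile
qinvgamma <- function(p, shape, rate) 1 / qgamma(1 - p, shape = shape, rate = rate)

# Brute-force 2-D quadrature of likelihood x NIG-prior density, returning the
# marginal posterior moments (E theta, Var theta, E sigma2). Independent of
# nig_posterior(): the grid is placed from the data and prior alone, Simpson
# weights in theta and in log(sigma2).
nig_quadrature_moments <- function(prior, y, n_theta = 1601, n_s = 1601) {
  n <- length(y)
  ybar <- mean(y); s2hat <- var(y)
  sd_lik <- sqrt(s2hat / n)
  sd_pri <- sqrt((prior$beta / prior$alpha) / prior$lambda)
  th_lo <- min(ybar - 14 * sd_lik, prior$mu - 14 * sd_pri)
  th_hi <- max(ybar + 14 * sd_lik, prior$mu + 14 * sd_pri)
  theta <- seq(th_lo, th_hi, length.out = n_theta)
  ls <- seq(log(min(s2hat, prior$beta / (prior$alpha + 1)) / 400),
            log(max(s2hat, prior$beta) * 400), length.out = n_s)
  s <- exp(ls)

  simpson_w <- function(m) {
    w <- rep(c(4, 2), length.out = m - 2)
    c(1, w[-(m - 1)], 4, 1)[seq_len(m)] / 3
  }
  wt <- simpson_w(n_theta) * (theta[2] - theta[1])
  ws <- simpson_w(n_s) * (ls[2] - ls[1])

  # log unnormalised posterior on the grid (theta rows, sigma2 cols)
  ssq <- sum((y - ybar)^2)
  lp <- outer(theta, s, function(th, sg) {
    -(n / 2) * log(2 * pi * sg) - (ssq + n * (ybar - th)^2) / (2 * sg) +
      0.5 * log(prior$lambda / (2 * pi * sg)) -
      prior$lambda * (th - prior$mu)^2 / (2 * sg) +
      prior$alpha * log(prior$beta) - lgamma(prior$alpha) -
      (prior$alpha + 1) * log(sg) - prior$beta / sg
  })
  f <- exp(lp - max(lp))
  f <- sweep(f, 2, s, "*")  # Jacobian for the log-sigma2 grid
  Z <- as.numeric(wt %*% f %*% ws)
  Eth <- as.numeric((wt * theta) %*% f %*% ws) / Z
  Eth2 <- as.numeric((wt * theta^2) %*% f %*% ws) / Z
  Es <- as.numeric(wt %*% f %*% (ws * s)) / Z
  c(mean_theta = Eth, var_theta = Eth2 - Eth^2, mean_sigma2 = Es)
}

# Discrete toy: Binomial(size, p) observation with p on a finite support.
binom_toy_model <- function(size, support, weights = NULL) {
  weights <- weights %||% rep(1 / length(support), length(support))
  generative_model(
    prior_sample = function(N) {
      matrix(sample(support, N, replace = TRUE, prob = weights), ncol = 1)
    },
    simulate = function(theta) rbinom(1, size, theta[1]),
    prior_density = function(theta) {
      i <- match(theta[1], support)
      if (is.na(i)) 0 else weights[i]
    },
    param_names = "p")
}

# Exhaustive posterior over the toy's support
binom_toy_posterior <- function(size, support, weights, y0) {
  w <- weights * dbinom(y0, size, support)
  w / sum(w)
}

# Straight-from-definition reimplementations of the frequency-spectrum
# statistics, used as the independent route against the package's.
ref_tajimas_d <- function(states) {
  n <- nrow(states)
  cs <- colSums(states)
  seg <- cs > 0 & cs < n
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  # pi as the literal average over all unordered row pairs
  pr <- utils::combn(n, 2)
  pihat <- mean(vapply(seq_len(ncol(pr)), function(k) {
    sum(states[pr[1, k], ] != states[pr[2, k], ])
  }, numeric(1)))
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (pihat - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

ref_faywu_h <- function(states) {
  n <- nrow(states)
  cs <- colSums(states)
  cs <- cs[cs > 0 & cs < n]
  if (length(cs) == 0) return(NA_real_)
  th_pi <- sum(2 * cs * (n - cs)) / (n * (n - 1))
  th_H <- sum(2 * cs^2) / (n * (n - 1))
  th_pi - th_H
}

# Random segregating haplotype matrix (each column has both states)
random_haplotypes <- function(n, S) {
  states <- matrix(0L, n, S)
  for (j in seq_len(S)) {
    c_j <- sample(n - 1, 1)
    states[sample(n, c_j), j] <- 1L
  }
  haplotype_matrix(states, sort(runif(S)))
}
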