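#' Discrepancy-measure specifications
#'
#' A distance spec maps two summary vectors (or two raw samples, for the
#' sample-based measures) to a real discrepancy. Euclidean and Wasserstein-1
#' are metrics; the kNN Kullback-Leibler estimator is neither symmetric nor
#' guaranteed nonnegative and is flagged accordingly.
#'
#' @param name Identifier.
#' @param map Function `(a, b) -> numeric(1)`.
#' @param map_batch Optional vectorised form: given a `d x N` matrix of
#'   candidate summaries and the observed summary `s0`, return `N` distances.
#' @param metric Logical: does the map satisfy the metric axioms?
#' @return An object of class `distance_spec`.
#' @export
distance_spec <- function(name, map, map_batch = NULL, metric = TRUE) {
  stopifnot(is.character(name), is.function(map))
  structure(list(name = name, map = map, map_batch = map_batch, metric = metric),
            class = "distance_spec")
}

#' @export
print.distance_spec <- function(x, ...) {
  cat(sprintf("<distance_spec '%s'%s>\n", x$name, if (x$metric) "" else " (non-metric)"))
  invisible(x)
}

#' Euclidean distance between summary vectors
#'
#' @param a,b Numeric vectors of equal length.
#' @return Nonnegative real.
#' @export
#' @examples
#' euclidean(c(0, 0), c(3, 4))
euclidean <- function(a, b) {
  if (length(a) != length(b)) {
    abort("Summary vectors must have equal length.", class = "abcbench_size_error")
  }
  sqrt(sum((a - b)^2))
}

#' Exact Wasserstein-1 distance between empirical distributions
#'
#' Computes \eqn{W_1(F_y, F_{y_0}) = \int |F_y(t) - F_{y_0}(t)| dt} exactly:
#' both empirical CDFs are piecewise constant, so the integral is a finite sum
#' over the merged breakpoint partition. Unequal sample sizes and nonuniform
#' weights are supported; for equal-size uniform-weight samples the result
#' coincides with the mean absolute difference of the sorted samples.
#'
#' @param y,y0 Numeric samples (nonempty).
#' @param w,w0 Optional nonnegative weights summing to 1 (default uniform).
#' @return Nonnegative real.
#' @export
#' @examples
#' wasserstein1(c(0, 1), c(1, 2))
wasserstein1 <- function(y, y0, w = NULL, w0 = NULL) {
  if (length(y) == 0 || length(y0) == 0) {
    abort("Samples must be nonempty.", class = "abcbench_size_error")
  }
  w <- w %||% rep(1 / length(y), length(y))
  w0 <- w0 %||% rep(1 / length(y0), length(y0))
  for (wt in list(w, w0)) {
    if (any(wt < 0) || abs(sum(wt) - 1) > 1e-12) {
      abort("Weights must be nonnegative and sum to 1.", class = "abcbench_domain_error")
    }
  }
  # merged breakpoints; signed weight jumps; |CDF difference| integrated
  z <- c(y, y0)
  dw <- c(w, -w0)
  o <- order(z)
  z <- z[o]
  f <- cumsum(dw[o])
  k <- length(z)
  sum(abs(f[-k]) * diff(z))
}

#' k-nearest-neighbour Kullback-Leibler divergence estimate
#'
#' Sample-based estimate of \eqn{D_{KL}(p_{y_0} \| p_y)} for one-dimensional
#' samples, after Wang, Kulkarni and Verdu (2009):
#' \deqn{\hat D = \frac{1}{n}\sum_i \log\frac{\nu_k(i)}{\rho_k(i)} +
#'       \log\frac{m}{n-1}}
#' with \eqn{\rho_k(i)} the distance from \eqn{y_{0i}} to its k-th neighbour
#' within \eqn{y_0} (excluding itself) and \eqn{\nu_k(i)} to its k-th
#' neighbour within \eqn{y}. The estimate may be negative, and the measure is
#' asymmetric in its arguments. Exact ties are broken by a uniform jitter of
#' magnitude `1e-9` times the data scale, since zero neighbour distances make
#' the logarithm undefined.
#'
#' @param y0 Sample from the reference distribution (the "p" of KL(p||q)).
#' @param y Sample from the comparison distribution.
#' @param k Neighbour order (default 1).
#' @return Real (possibly negative).
#' @export
kl_knn <- function(y0, y, k = 1) {
  n <- length(y0); m <- length(y)
  if (n <= k || m < k) {
    abort("Samples too small for the requested neighbour order.",
          class = "abcbench_size_error")
  }
  if (anyDuplicated(y0) || anyDuplicated(c(y0, y))) {
    scale <- max(diff(range(c(y0, y))), abs(mean(y0)), 1e-12)
    jit <- 1e-9 * scale
    y0 <- y0 + runif(n, -jit, jit)
    y <- y + runif(m, -jit, jit)
  }
  rho <- knn_dist_self(y0, k)
  nu <- knn_dist_cross(y0, y, k)
  if (any(rho == 0) || any(nu == 0)) {
    abort("Degenerate zero neighbour distance after tie perturbation.",
          class = "abcbench_degenerate_error")
  }
  mean(log(nu / rho)) + log(m / (n - 1))
}

# k-th smallest |y0_i - y0_j|, j != i, for each i (1-D, sort-based)
knn_dist_self <- function(x, k) {
  n <- length(x)
  o <- order(x)
  xs <- x[o]
  out <- numeric(n)
  for (ii in seq_len(n)) {
    lo <- ii - 1; hi <- ii + 1
    d <- numeric(k)
    for (j in seq_len(k)) {
      dl <- if (lo >= 1) xs[ii] - xs[lo] else Inf
      dr <- if (hi <= n) xs[hi] - xs[ii] else Inf
      if (dl <= dr) { d[j] <- dl; lo <- lo - 1 } else { d[j] <- dr; hi <- hi + 1 }
    }
    out[o[ii]] <- d[k]
  }
  out
}

# k-th smallest |x_i - y_j| over j, for each i (1-D, two-pointer on sorted y)
knn_dist_cross <- function(x, y, k) {
  ys <- sort(y)
  m <- length(ys)
  pos <- findInterval(x, ys)
  out <- numeric(length(x))
  for (ii in seq_along(x)) {
    lo <- pos[ii]; hi <- pos[ii] + 1
    d <- 0
    for (j in seq_len(k)) {
      dl <- if (lo >= 1) x[ii] - ys[lo] else Inf
      dr <- if (hi <= m) ys[hi] - x[ii] else Inf
      if (dl <= dr) { d <- dl; lo <- lo - 1 } else { d <- dr; hi <- hi + 1 }
    }
    out[ii] <- d
  }
  out
}

#' Look up a distance spec by name
#'
#' @param name One of `"euclidean"`, `"wasserstein1"`, `"kl_knn"`, or a
#'   `distance_spec` object (returned unchanged).
#' @param k Neighbour order for `"kl_knn"`.
#' @return A `distance_spec`.
#' @export
abc_distance <- function(name, k = 1) {
  if (inherits(name, "distance_spec")) return(name)
  switch(name,
    euclidean = distance_spec("euclidean", euclidean,
      map_batch = function(S, s0) sqrt(colSums((S - s0)^2))),
    wasserstein1 = distance_spec("wasserstein1",
      function(a, b) wasserstein1(a, b)),
    kl_knn = distance_spec("kl_knn",
      function(a, b) kl_knn(a, b, k = k), metric = FALSE),
    abort(paste0("Unknown distance '", name, "'."), class = "abcbench_lookup_error")
  )
}

#' Parse a scheme string into a summary and a distance
#'
#' Schemes name the summary/discrepancy combinations of the normal benchmark:
#' `"mean+euclidean"`, `"sufficient+euclidean"`, `"identity+wasserstein1"`,
#' `"identity+kl_knn"`.
#'
#' @param scheme A `"summary+distance"` string.
#' @return A list with elements `summary` and `distance`.
#' @export
abc_scheme <- function(scheme) {
  parts <- strsplit(scheme, "+", fixed = TRUE)[[1]]
  if (length(parts) != 2) {
    abort("Scheme must be of the form 'summary+distance'.",
          class = "abcbench_lookup_error")
  }
  list(summary = abc_summary(parts[1]), distance = abc_distance(parts[2]),
       name = scheme)
}
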