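# Harmonic-number helpers shared by the frequency-spectrum statistics.
harmonic <- function(n) sum(1 / seq_len(n))
harmonic2 <- function(n) sum(1 / seq_len(n)^2)

derived_counts <- function(h) {
  stopifnot(inherits(h, "haplotype_matrix"))
  colSums(h$states)
}

# SFS (xi_1..xi_{n-1}) over the segregating columns only
sfs_of <- function(h) {
  n <- nrow(h$states)
  cs <- derived_counts(h)
  cs <- cs[cs > 0 & cs < n]
  tabulate(cs, nbins = n - 1)
}

#' Mean pairwise Hamming distance (nucleotide diversity)
#'
#' \eqn{\hat\pi = \frac{2}{n(n-1)} \sum_{i<j} d_H(row_i, row_j)}: the average
#' number of sites at which two haplotypes differ, an unbiased estimator of
#' the scaled mutation rate under the neutral coalescent.
#'
#' @param h A [haplotype_matrix()] with at least 2 rows.
#' @return Nonnegative real.
#' @export
mean_pairwise_hamming <- function(h) {
  X <- h$states
  n <- nrow(X)
  if (n < 2) abort("Need at least 2 haplotypes.", class = "abcbench_size_error")
  if (ncol(X) == 0) return(0)
  # mismatches(i, j) = X_i.(1-X_j) + (1-X_i).X_j; D holds the first term and
  # its transpose the second, with zero diagonal
  D <- X %*% t(1L - X)
  2 * sum(D) / (n * (n - 1))
}

#' Number of segregating sites
#'
#' Columns with both states present. Simulator output is segregating by
#' construction; monomorphic columns (possible in matrices read from files)
#' are excluded.
#'
#' @param h A [haplotype_matrix()].
#' @return Nonnegative integer.
#' @export
segregating_sites <- function(h) {
  n <- nrow(h$states)
  cs <- derived_counts(h)
  sum(cs > 0 & cs < n)
}

#' Tajima's D
#'
#' Normalised difference between the pairwise-diversity and
#' segregating-sites estimators of the mutation rate,
#' \eqn{D = (\hat\pi - S/a_1) / \sqrt{e_1 S + e_2 S(S-1)}} with the standard
#' constants of Tajima (1989). Near zero under the neutral constant-size
#' model; negative under population growth (excess rare variants). Undefined
#' (reported as [undefined_marker()]) when there are no segregating sites.
#'
#' @param h A [haplotype_matrix()].
#' @return Real, or `NA` when `S = 0`.
#' @export
tajimas_d <- function(h) {
  n <- nrow(h$states)
  S <- segregating_sites(h)
  if (S == 0) return(undefined_marker())
  pihat <- mean_pairwise_hamming(h)
  tajima_d_from(pihat, S, n)
}

tajima_d_from <- function(pihat, S, n) {
  a1 <- harmonic(n - 1); a2 <- harmonic2(n - 1)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pihat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Fay and Wu's H
#'
#' Difference between the pairwise-diversity estimator and the
#' high-frequency-weighted estimator of the mutation rate,
#' \eqn{H = \hat\theta_\pi - \hat\theta_H} with
#' \eqn{\hat\theta_\pi = \sum_i 2\xi_i i(n-i)/(n(n-1))} and
#' \eqn{\hat\theta_H = \sum_i 2\xi_i i^2/(n(n-1))}, where \eqn{\xi_i} counts
#' sites at derived-allele count `i`. Requires a known ancestral state
#' (state 0 here). The unnormalised statistic is the default; the variance-
#' normalised variant of Zeng et al. (2006) is available behind a flag.
#' Undefined when `S = 0`.
#'
#' @param h A [haplotype_matrix()].
#' @param normalized If `TRUE`, divide by the estimated standard deviation.
#' @return Real, or `NA` when `S = 0`.
#' @export
faywu_h <- function(h, normalized = FALSE) {
  n <- nrow(h$states)
  xi <- sfs_of(h)
  S <- sum(xi)
  if (S == 0) return(undefined_marker())
  faywu_h_from(xi, n, normalized)
}

faywu_h_from <- function(xi, n, normalized = FALSE) {
  i <- seq_len(n - 1)
  th_pi <- sum(2 * xi * i * (n - i)) / (n * (n - 1))
  th_H <- sum(2 * xi * i^2) / (n * (n - 1))
  H <- th_pi - th_H
  if (!normalized) return(H)
  S <- sum(xi)
  a1 <- harmonic(n - 1); a2 <- harmonic2(n - 1)
  bn1 <- harmonic2(n)
  th_w <- S / a1
  th_sq <- S * (S - 1) / (a1^2 + a2)
  v <- (n - 2) / (6 * (n - 1)) * th_w +
    (18 * n^2 * (3 * n + 2) * bn1 - (88 * n^3 + 9 * n^2 - 13 * n + 6)) /
      (9 * n * (n - 1)^2) * th_sq
  if (v <= 0) return(undefined_marker())
  H / sqrt(v)
}

#' Population-genetics summary vector
#'
#' The named summary combinations used as ABC statistics: `"hamming"`
#' (pairwise diversity only), `"segsites"`, `"d_and_h"` (Tajima's D and
#' Fay-Wu's H, length 2) and `"all4"` (diversity, segregating sites, D, H in
#' that fixed order). Undefined statistics are substituted by 0 so the
#' Euclidean distance stays computable; the number of substitutions is
#' attached as the `"n_undefined"` attribute.
#'
#' @param h A [haplotype_matrix()].
#' @param which One of `"hamming"`, `"segsites"`, `"d_and_h"`, `"all4"`.
#' @return Named numeric vector.
#' @export
popgen_summaries <- function(h, which = "all4") {
  n <- nrow(h$states)
  xi <- sfs_of(h)
  v <- summaries_from_sfs(matrix(xi, ncol = 1), n, which)
  out <- v$values[, 1]
  attr(out, "n_undefined") <- v$n_undefined
  out
}

# Vectorised summaries from an SFS matrix ((n-1) x N). Returns a d x N value
# matrix with undefined markers already mapped to 0, plus the substitution
# count.
summaries_from_sfs <- function(xi, n, which = "all4") {
  if (!which %in% c("hamming", "segsites", "d_and_h", "all4")) {
    abort(paste0("Unknown summary set '", which, "'."),
          class = "abcbench_lookup_error")
  }
  i <- seq_len(n - 1)
  S <- colSums(xi)
  pihat <- colSums(xi * (2 * i * (n - i) / (n * (n - 1))))
  th_H <- colSums(xi * (2 * i^2 / (n * (n - 1))))
  D <- ifelse(S > 0, tajima_d_from(pihat, pmax(S, 1), n), NA_real_)
  H <- ifelse(S > 0, pihat - th_H, NA_real_)
  vals <- switch(which,
    hamming = rbind(pi_hat = pihat),
    segsites = rbind(s_sites = S),
    d_and_h = rbind(tajimas_d = D, faywu_h = H),
    all4 = rbind(pi_hat = pihat, s_sites = S, tajimas_d = D, faywu_h = H))
  n_undef <- sum(is.na(vals))
  vals[is.na(vals)] <- 0
  list(values = vals, n_undefined = n_undef)
}
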