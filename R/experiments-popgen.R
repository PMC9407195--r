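#' Coalescent growth-and-mutation-rate inference by kNN ABC
#'
#' Replicates the ancestral-inference study: observed haplotypes are
#' simulated at the truth (defaults: 20 haplotypes, mutation rate
#' `theta0 = 50`, growth rate `alpha = 30`), proposals draw
#' `(alpha, theta0)` from independent `U(0, 200)` priors, and the k nearest
#' proposals in summary space are retained, separately for each requested
#' summary scheme (`"hamming"`, `"segsites"`, `"d_and_h"`, `"all4"`).
#'
#' Summary components are standardised by their median absolute deviation
#' across the proposal pool before the Euclidean distance (toggleable):
#' with raw scales the segregating-sites component dominates the
#' four-statistic vector. Undefined summary values (no segregating sites)
#' are substituted by zero and counted.
#'
#' @param schemes Summary schemes to run.
#' @param n_samples Haplotypes per dataset.
#' @param truth Named or positional `(theta0, alpha)` truth.
#' @param prior_max Upper bound of the uniform priors.
#' @param n_proposals Proposal budget (the full study uses 1e6; the scaled
#'   mode uses 1e5).
#' @param n_retain Retained draws (full 1000; scaled 100).
#' @param standardize MAD-standardise summaries before the distance.
#' @param hpd_levels Highest-posterior-density mass levels computed for
#'   reporting.
#' @param seed Master seed (observed data and proposal stream run on
#'   substreams).
#' @return A list of class `popgen_replication`: `retained` (tibble with
#'   scheme, alpha, theta0, distance), `hpd` (contour tibble), `observed`
#'   (the observed [haplotype_matrix()]), `s0` (observed summaries per
#'   scheme), `n_undefined` (zero-substitution counts per scheme).
#' @export
popgen_replication <- function(schemes = c("hamming", "segsites", "d_and_h",
                                           "all4"),
                               n_samples = 20, truth = c(theta0 = 50, alpha = 30),
                               prior_max = 200, n_proposals = 1e5,
                               n_retain = 100, standardize = TRUE,
                               hpd_levels = c(0.25, 0.5, 0.75, 0.9),
                               seed = 1) {
  obs <- simulate_coalescent(n_samples, truth[["theta0"]], truth[["alpha"]],
                             seed = substream_seed(seed, 0))
  with_seed(substream_seed(seed, 1), {
    alpha <- runif(n_proposals, 0, prior_max)
    theta0 <- runif(n_proposals, 0, prior_max)
    xi <- simulate_sfs(n_samples, theta0, alpha)
  })
  s0_list <- list(); nundef <- integer(0)
  retained <- purrr::map_dfr(schemes, function(w) {
    pool <- summaries_from_sfs(xi, n_samples, w)
    s0 <- popgen_summaries(obs, w)
    s0_list[[w]] <<- as.numeric(s0)
    nundef[w] <<- pool$n_undefined + attr(s0, "n_undefined")
    scale <- if (standardize) {
      sc <- apply(pool$values, 1, stats::mad)
      ifelse(sc > 0, sc, 1)
    } else rep(1, nrow(pool$values))
    d <- sqrt(colSums(((pool$values - as.numeric(s0)) / scale)^2))
    keep <- order(d)[seq_len(n_retain)]
    tibble(scheme = w, alpha = alpha[keep], theta0 = theta0[keep],
           distance = d[keep])
  })
  hpd <- if (n_retain >= 100) {
    purrr::map_dfr(schemes, function(w) {
      r <- dplyr::filter(retained, .data$scheme == w)
      dplyr::mutate(hpd_contours(r[, c("alpha", "theta0")],
                                 levels = hpd_levels),
                    scheme = w, .before = 1)
    })
  } else {
    tibble(scheme = character(), level = numeric(), polygon = integer(),
           x = numeric(), y = numeric())
  }
  structure(list(retained = retained, hpd = hpd, observed = obs,
                 s0 = s0_list, n_undefined = nundef,
                 truth = truth, n_proposals = n_proposals,
                 n_retain = n_retain, seed = seed),
            class = "popgen_replication")
}

#' @export
print.popgen_replication <- function(x, ...) {
  cat(sprintf(
    "<popgen_replication: %d retained of %d proposals per scheme (%s)>\n",
    x$n_retain, x$n_proposals,
    paste(unique(x$retained$scheme), collapse = ", ")))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.popgen_replication <- function(x, ...) x$retained

#' @exportS3Method ggplot2::autoplot
autoplot.popgen_replication <- function(object, ...) {
  ggplot2::ggplot(object$retained,
                  ggplot2::aes(x = .data$alpha, y = .data$theta0)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.7) +
    ggplot2::geom_path(data = object$hpd,
                       ggplot2::aes(group = interaction(.data$level, .data$polygon)),
                       colour = "steelblue") +
    ggplot2::geom_point(data = tibble(alpha = object$truth[["alpha"]],
                                      theta0 = object$truth[["theta0"]]),
                        colour = "red", shape = 4, size = 3) +
    ggplot2::facet_wrap(~scheme) +
    ggplot2::labs(x = "growth rate", y = "mutation rate")
}

#' Highest-posterior-density contours from a 2-D sample
#'
#' Kernel-density HPD regions: the density threshold enclosing each
#' requested posterior mass is found on a bivariate normal-kernel density
#' grid, and the corresponding contour polygons are returned. Regions are
#' nested by construction.
#'
#' @param samples Two-column data frame or matrix of draws (at least 100).
#' @param levels Mass levels in (0, 1).
#' @param n_grid Density grid resolution per axis.
#' @return A tibble with columns `level`, `polygon`, `x`, `y`.
#' @export
hpd_contours <- function(samples, levels = c(0.25, 0.5, 0.75, 0.9),
                         n_grid = 128) {
  m <- as.matrix(samples)
  if (nrow(m) < 100) {
    abort("Need at least 100 samples for density contours.",
          class = "abcbench_size_error")
  }
  if (ncol(m) != 2 || any(apply(m, 2, sd) == 0)) {
    abort("Samples must be two-dimensional and non-degenerate.",
          class = "abcbench_degenerate_error")
  }
  pad <- 0.1 * apply(m, 2, function(v) diff(range(v)) + 1e-9)
  kd <- MASS::kde2d(m[, 1], m[, 2], n = n_grid,
                    lims = c(min(m[, 1]) - pad[1], max(m[, 1]) + pad[1],
                             min(m[, 2]) - pad[2], max(m[, 2]) + pad[2]))
  cell <- diff(kd$x[1:2]) * diff(kd$y[1:2])
  dens <- sort(as.numeric(kd$z), decreasing = TRUE)
  mass <- cumsum(dens) * cell
  purrr::map_dfr(sort(levels), function(lv) {
    thr <- dens[which(mass >= lv * mass[length(mass)])[1]]
    cls <- grDevices::contourLines(kd$x, kd$y, kd$z, levels = thr)
    purrr::imap_dfr(cls, function(cl, k) {
      tibble(level = lv, polygon = k, x = cl$x, y = cl$y)
    })
  })
}

#' Mass enclosed by an HPD level on the density grid
#'
#' Companion to [hpd_contours()]: the fraction of total kernel-density mass
#' lying above the threshold for a given level, useful for checking the
#' nominal coverage of the contour construction.
#'
#' @inheritParams hpd_contours
#' @param level Single mass level.
#' @return The enclosed mass fraction.
#' @export
hpd_enclosed_mass <- function(samples, level, n_grid = 128) {
  m <- as.matrix(samples)
  kd <- MASS::kde2d(m[, 1], m[, 2], n = n_grid)
  cell <- diff(kd$x[1:2]) * diff(kd$y[1:2])
  dens <- sort(as.numeric(kd$z), decreasing = TRUE)
  mass <- cumsum(dens) * cell
  thr <- dens[which(mass >= level * mass[length(mass)])[1]]
  sum(dens[dens >= thr]) * cell / (mass[length(mass)])
}
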