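#' Haplotype matrices
#'
#' An `n x S` binary matrix of derived-allele states (0 = ancestral, 1 =
#' derived) with site positions on the unit interval, the output of the
#' infinite-sites coalescent simulator and the input of the
#' population-genetics summaries. Every column of simulator output is
#' segregating by construction; matrices read from external files may carry
#' monomorphic columns, which the statistics ignore.
#'
#' @param states Binary matrix (rows = haplotypes, columns = sites). A
#'   zero-column matrix (`S = 0`) is valid.
#' @param positions Strictly increasing site positions in `(0, 1)`, one per
#'   column.
#' @return An object of class `haplotype_matrix`.
#' @export
haplotype_matrix <- function(states, positions = NULL) {
  states <- as.matrix(states)
  S <- ncol(states)
  positions <- positions %||% (if (S > 0) seq_len(S) / (S + 1) else numeric(0))
  if (length(positions) != S) {
    abort("`positions` must have one entry per column.", class = "abcbench_size_error")
  }
  if (S > 0) {
    if (!all(states %in% c(0, 1))) {
      abort("`states` must be binary (0/1).", class = "abcbench_domain_error")
    }
    if (is.unsorted(positions, strictly = TRUE)) {
      abort("`positions` must be strictly increasing.", class = "abcbench_domain_error")
    }
  }
  storage.mode(states) <- "integer"
  structure(list(states = states, positions = as.numeric(positions)),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("<haplotype_matrix: %d haplotypes x %d sites>\n",
              nrow(x$states), ncol(x$states)))
  invisible(x)
}

#' @export
dim.haplotype_matrix <- function(x) dim(x$states)

#' Simulate a coalescent genealogy
#'
#' Kingman coalescent over `n_samples` leaves under exponential population
#' growth at rate `alpha` (backward-time size `N0 exp(-alpha t)`, `ms`
#' conventions: time in units of `4 N0` generations). While `k` lineages
#' remain, the waiting time solves
#' \eqn{\binom{k}{2} (e^{\alpha(t+\Delta)} - e^{\alpha t})/\alpha = E} with
#' `E ~ Exp(1)`; at `alpha = 0` this is the standard
#' \eqn{\Delta \sim Exp(\binom{k}{2})}.
#'
#' @param n_samples Number of haplotypes (>= 2).
#' @param alpha Growth rate in coalescent time units (0 = constant size).
#' @param seed Optional seed.
#' @return A `coalescent_tree`: branch table (subtended leaves and lengths),
#'   TMRCA and total length.
#' @export
simulate_genealogy <- function(n_samples, alpha = 0, seed = NULL) {
  stopifnot(n_samples >= 2)
  with_seed(seed, {
    # active lineages: list of subtended leaf index vectors + birth times
    leaves <- lapply(seq_len(n_samples), identity)
    born <- rep(0, n_samples)
    br_leaves <- list(); br_len <- numeric(0)
    t <- 0
    k <- n_samples
    while (k >= 2) {
      rate <- k * (k - 1) / 2
      E <- rexp(1)
      dt <- if (alpha == 0) E / rate else
        log(exp(alpha * t) + alpha * E / rate) / alpha - t
      t <- t + dt
      pair <- sample.int(k, 2)
      i <- pair[1]; j <- pair[2]
      # close the two merging branches
      br_leaves <- c(br_leaves, leaves[c(i, j)])
      br_len <- c(br_len, t - born[i], t - born[j])
      leaves[[i]] <- sort(c(leaves[[i]], leaves[[j]]))
      born[i] <- t
      leaves[[j]] <- NULL
      born <- born[-j]
      k <- k - 1
    }
    structure(list(n = n_samples,
                   branches = list(leaves = br_leaves, length = br_len),
                   tmrca = t, total_length = sum(br_len)),
              class = "coalescent_tree")
  })
}

#' @export
print.coalescent_tree <- function(x, ...) {
  cat(sprintf("<coalescent_tree: %d leaves, TMRCA %.3f, total length %.3f>\n",
              x$n, x$tmrca, x$total_length))
  invisible(x)
}

#' Drop infinite-sites mutations on a genealogy
#'
#' The mutation count is Poisson with mean `theta0 * L / 2` (`L` the total
#' branch length, `ms` conventions); each mutation lands uniformly along the
#' branches, receives a fresh position uniform on (0, 1) (re-drawn in the
#' measure-zero event of a duplicate), and its derived state is inherited by
#' the leaves the branch subtends. `theta0 = 0` yields a valid zero-site
#' matrix.
#'
#' @param tree A `coalescent_tree` from [simulate_genealogy()].
#' @param theta0 Scaled mutation rate (`4 N0 mu` per locus, >= 0).
#' @param seed Optional seed.
#' @return A [haplotype_matrix()].
#' @export
drop_mutations <- function(tree, theta0, seed = NULL) {
  stopifnot(inherits(tree, "coalescent_tree"), theta0 >= 0)
  with_seed(seed, {
    n_mut <- rpois(1, theta0 * tree$total_length / 2)
    if (n_mut == 0) {
      return(haplotype_matrix(matrix(0L, tree$n, 0)))
    }
    br <- sample.int(length(tree$branches$length), n_mut, replace = TRUE,
                     prob = tree$branches$length)
    pos <- runif(n_mut)
    while (anyDuplicated(pos)) {
      dup <- duplicated(pos)
      pos[dup] <- runif(sum(dup))
    }
    o <- order(pos)
    states <- matrix(0L, tree$n, n_mut)
    for (jj in seq_len(n_mut)) {
      states[tree$branches$leaves[[br[o[jj]]]], jj] <- 1L
    }
    haplotype_matrix(states, pos[o])
  })
}

#' Simulate haplotypes under the growth coalescent with infinite sites
#'
#' Composition of [simulate_genealogy()] and [drop_mutations()]:
#' genealogy first, then mutations, one replicate per call.
#'
#' @inheritParams simulate_genealogy
#' @inheritParams drop_mutations
#' @return A [haplotype_matrix()].
#' @export
#' @examples
#' h <- simulate_coalescent(10, theta0 = 5, alpha = 0, seed = 1)
#' dim(h)
simulate_coalescent <- function(n_samples, theta0, alpha = 0, seed = NULL) {
  with_seed(seed, drop_mutations(simulate_genealogy(n_samples, alpha), theta0))
}

#' Batch coalescent simulation returning site frequency spectra
#'
#' Fast path for ABC proposal loops: simulates many independent replicates of
#' the same growth-coalescent/infinite-sites model (compiled core) and
#' returns only the site frequency spectrum of each, which determines all
#' four population-genetics summaries. `theta0` and `alpha` may vary per
#' replicate. Distributionally equivalent to summarising
#' [simulate_coalescent()] output replicate by replicate.
#'
#' @param n_samples Haplotypes per replicate (>= 2).
#' @param theta0,alpha Scalars or vectors (recycled to the replicate count).
#' @param n_reps Number of replicates (defaults to the longer of
#'   `theta0`/`alpha`).
#' @param seed Optional seed.
#' @return An `(n_samples - 1) x n_reps` integer matrix: entry `[i, b]` is
#'   the number of sites with derived-allele count `i` in replicate `b`.
#' @export
simulate_sfs <- function(n_samples, theta0, alpha = 0, n_reps = NULL,
                         seed = NULL) {
  n_reps <- n_reps %||% max(length(theta0), length(alpha))
  theta0 <- rep_len(theta0, n_reps)
  alpha <- rep_len(alpha, n_reps)
  with_seed(seed, sfs_batch_cpp(as.integer(n_samples), theta0, alpha))
}
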