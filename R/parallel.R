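#' Worker-parallel ABC with worker-count-invariant output
#'
#' ABC rejection sampling is embarrassingly parallel: the proposal budget is
#' partitioned into fixed blocks (as evenly as possible, remainder to
#' low-index blocks), each block runs on its own RNG substream derived from
#' `(seed, block_index)` via [substream_seed()], and blocks are distributed
#' over workers. Because the block structure depends only on the budget, the
#' pooled accepted set is identical for every worker count under the same
#' seed. kNN retention is applied after pooling, so it too is
#' worker-invariant and equals a full sort of the whole proposal stream.
#'
#' @inheritParams abc_reject
#' @param sampler `"reject"` (fixed tolerance) or `"knn"`.
#' @param k Retention count for `sampler = "knn"`.
#' @param n_workers Number of parallel workers (`>= 1`).
#' @param n_blocks Number of RNG blocks (defaults to a budget-derived value;
#'   must not depend on `n_workers`).
#' @param seed Master seed (required: substreams are derived from it).
#' @return An `abc_run`; `epsilon` is the realised tolerance for kNN runs.
#' @export
abc_parallel <- function(model, y0, summary = "sufficient",
                         distance = "euclidean", sampler = c("reject", "knn"),
                         epsilon = NULL, k = NULL, n_proposals,
                         n_workers = 1L, n_blocks = NULL, seed = 1L) {
  sampler <- match.arg(sampler)
  if (n_workers < 1) abort("`n_workers` must be >= 1.", class = "abcbench_size_error")
  summary <- abc_summary(summary)
  distance <- abc_distance(distance)
  s0 <- observed_summary(summary, y0)
  scheme <- paste0(summary$name, "+", distance$name)
  n_blocks <- n_blocks %||% max(1L, min(64L, as.integer(ceiling(n_proposals / 2000))))
  sizes <- rep(n_proposals %/% n_blocks, n_blocks)
  rem <- n_proposals %% n_blocks
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1
  sizes <- sizes[sizes > 0]

  run_block <- function(b) {
    set.seed(substream_seed(seed, b))
    batch <- propose_batch(model, summary, sizes[b])
    d <- batch_distances(distance, batch$S, s0)
    list(theta = batch$theta, S = batch$S, d = d)
  }
  blocks <- if (n_workers == 1L) {
    lapply(seq_along(sizes), run_block)
  } else {
    parallel::mclapply(seq_along(sizes), run_block, mc.cores = n_workers,
                       mc.preschedule = TRUE)
  }
  theta <- do.call(rbind, lapply(blocks, `[[`, "theta"))
  d <- unlist(lapply(blocks, `[[`, "d"))
  Ss <- lapply(blocks, `[[`, "S")
  S <- if (is.list(Ss[[1]])) do.call(c, Ss) else do.call(cbind, Ss)

  if (sampler == "reject") {
    stopifnot(!is.null(epsilon))
    idx <- which(d <= epsilon)
    acc <- accepted_tibble(theta, S, d, idx, model$param_names)
    new_abc_run(acc, n_proposals, epsilon, seed, scheme)
  } else {
    k <- k %||% max(1L, as.integer(n_proposals / 10))
    o <- order(d)
    keep <- o[seq_len(k)]
    eps_real <- if (k < n_proposals) d[o[k + 1]] else Inf
    acc <- accepted_tibble(theta, S, d, keep, model$param_names)
    new_abc_run(acc, n_proposals, eps_real, seed, scheme, kind = "knn")
  }
}
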