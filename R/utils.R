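#' Derive a reproducible substream seed
#'
#' Hashes a master seed together with one or two stream indices into a new
#' seed in `[1, 2^31 - 2]`. Used throughout so that every experiment stage,
#' replication and parallel worker draws from its own deterministic stream
#' derived from a single master seed.
#'
#' @param seed Master seed (integer).
#' @param ... One or more non-negative integer stream indices.
#' @return A single integer seed.
#' @export
#' @examples
#' substream_seed(1, 3)
#' substream_seed(1, 3, 7)
substream_seed <- function(seed, ...) {
  idx <- c(...)
  stopifnot(length(idx) >= 1, all(idx >= 0))
  # splitmix-style integer mix, kept in double arithmetic below 2^31
  h <- as.double(seed) %% 2147483647
  for (i in idx) {
    h <- (h * 48271 + as.double(i) * 16807 + 12345) %% 2147483647
    h <- (h * 69621) %% 2147483647
  }
  as.integer(h %% 2147483646 + 1)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) set.seed(seed)
  force(code)
}

#' Marker for undefined moments and statistics
#'
#' Quantities that can be undefined (posterior moments when the inverse-gamma
#' shape is at most 1, Tajima's D and Fay-Wu's H when there are no segregating
#' sites) are reported as `NA_real_` rather than raising, so that experiment
#' tables can record them as missing cells.
#'
#' @return `NA_real_`.
#' @export
undefined_marker <- function() NA_real_

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
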