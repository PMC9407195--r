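#' Summary-statistic specifications
#'
#' A summary spec is a named, deterministic contract mapping a dataset to a
#' real vector of fixed dimension. Specs are the pluggable "S" of an ABC
#' sampler; built-ins cover the sample mean, the sufficient statistic of the
#' normal model, and the identity map used by sample-based distances.
#'
#' @param name Identifier.
#' @param dim Output dimension (`NA` for the identity map, whose output
#'   length follows the input).
#' @param map Function from a numeric dataset to a numeric vector.
#' @param map_matrix Optional vectorised form: given an `n_obs x N` matrix of
#'   datasets in columns, return a `dim x N` matrix of summaries. Used by the
#'   samplers to process proposal batches quickly; must agree with `map`
#'   column by column.
#' @return An object of class `summary_spec`.
#' @export
summary_spec <- function(name, dim, map, map_matrix = NULL) {
  stopifnot(is.character(name), is.function(map))
  structure(list(name = name, dim = dim, map = map, map_matrix = map_matrix),
            class = "summary_spec")
}

#' @export
print.summary_spec <- function(x, ...) {
  cat(sprintf("<summary_spec '%s' (dim %s)>\n", x$name, x$dim))
  invisible(x)
}

#' @rdname summary_spec
#' @details `summary_mean()` returns `[mean(y)]`; `summary_sufficient()`
#'   returns `[mean(y), (1/n) sum (y_i - mean(y))^2]` (note the `1/n`, not
#'   `1/(n-1)`, convention); `summary_identity()` returns the dataset itself,
#'   for distances that act on whole samples.
#' @export
summary_mean <- function() {
  summary_spec("mean", 1L,
    map = function(y) mean(y),
    map_matrix = function(Y) matrix(colMeans(Y), nrow = 1))
}

#' @rdname summary_spec
#' @export
summary_sufficient <- function() {
  summary_spec("sufficient", 2L,
    map = function(y) {
      m <- mean(y)
      c(m, mean((y - m)^2))
    },
    map_matrix = function(Y) {
      m <- colMeans(Y)
      v <- colMeans(Y * Y) - m * m
      rbind(m, pmax(v, 0), deparse.level = 0)
    })
}

#' @rdname summary_spec
#' @export
summary_identity <- function() {
  summary_spec("identity", NA_integer_, map = function(y) y)
}

#' Look up a summary spec by name
#'
#' @param name One of `"mean"`, `"sufficient"`, `"identity"`, or a
#'   `summary_spec` object (returned unchanged).
#' @return A `summary_spec`.
#' @export
abc_summary <- function(name) {
  if (inherits(name, "summary_spec")) return(name)
  switch(name,
    mean = summary_mean(),
    sufficient = summary_sufficient(),
    identity = summary_identity(),
    abort(paste0("Unknown summary '", name, "'."), class = "abcbench_lookup_error")
  )
}
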