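#' ABC run results
#'
#' Container for the output of the rejection-family samplers: accepted
#' parameter draws with their summary values and distances, the proposal
#' count, and the tolerance (fixed, or realised as the (k+1)-th smallest
#' distance for kNN runs).
#'
#' @param accepted Tibble of accepted draws: one row per draw, parameter
#'   columns, summary columns (`s1`, `s2`, ... where applicable) and
#'   `distance`.
#' @param n_proposals Total proposals generated.
#' @param epsilon Tolerance (fixed runs) or realised tolerance (kNN runs).
#' @param seed Seed used (may be `NA`).
#' @param scheme Identifier of the summary/distance scheme.
#' @param kind `"fixed"`, `"knn"` or `"exact"`.
#' @return An object of class `abc_run`.
#' @keywords internal
new_abc_run <- function(accepted, n_proposals, epsilon, seed, scheme,
                        kind = "fixed") {
  structure(
    list(accepted = accepted, n_proposals = n_proposals, epsilon = epsilon,
         seed = seed, scheme = scheme, kind = kind),
    class = "abc_run")
}

#' @export
print.abc_run <- function(x, ...) {
  cat(sprintf("<abc_run: %d accepted of %d proposals (%s, scheme '%s', tolerance %s)>\n",
              nrow(x$accepted), x$n_proposals, x$kind, x$scheme,
              format(x$epsilon, digits = 4)))
  invisible(x)
}

#' @describeIn abc_reject Accepted draws as a tibble (one row per draw).
#' @param x An `abc_run`.
#' @exportS3Method generics::tidy
tidy.abc_run <- function(x, ...) x$accepted

#' @describeIn abc_reject One-row run-level overview: acceptance rate,
#'   tolerance, proposal count.
#' @exportS3Method generics::glance
glance.abc_run <- function(x, ...) {
  tibble(
    n_accepted = nrow(x$accepted),
    n_proposals = x$n_proposals,
    acceptance_rate = nrow(x$accepted) / x$n_proposals,
    epsilon = x$epsilon,
    scheme = x$scheme,
    kind = x$kind
  )
}

#' @describeIn abc_reject Histogram (one parameter) or scatter plot (two or
#'   more parameters) of the accepted draws.
#' @param object An `abc_run`.
#' @exportS3Method ggplot2::autoplot
autoplot.abc_run <- function(object, ...) {
  acc <- object$accepted
  pcols <- setdiff(names(acc), c("distance", grep("^s[0-9]+$", names(acc), value = TRUE)))
  if (length(pcols) >= 2) {
    ggplot2::ggplot(acc, ggplot2::aes(x = .data[[pcols[1]]], y = .data[[pcols[2]]])) +
      ggplot2::geom_point(alpha = 0.4) +
      ggplot2::labs(title = sprintf("Accepted draws (%s)", object$scheme))
  } else {
    ggplot2::ggplot(acc, ggplot2::aes(x = .data[[pcols[1]]])) +
      ggplot2::geom_histogram(bins = 40) +
      ggplot2::labs(title = sprintf("Accepted draws (%s)", object$scheme))
  }
}

#' Write an ABC run to disk
#'
#' Serialises the accepted draws to CSV (one row per draw: parameters,
#' summaries, distance) and the run metadata to JSON.
#'
#' @param run An `abc_run`.
#' @param path Base path; `<path>.csv` and `<path>.json` are written.
#' @return `path`, invisibly.
#' @export
write_abc_run <- function(run, path) {
  readr::write_csv(run$accepted, paste0(path, ".csv"))
  meta <- list(n_proposals = run$n_proposals, epsilon = run$epsilon,
               seed = run$seed, scheme = run$scheme, kind = run$kind,
               n_accepted = nrow(run$accepted))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
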