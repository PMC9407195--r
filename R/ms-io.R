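#' Read ms-style haplotype output
#'
#' Parses the classical `ms` text format: replicate blocks introduced by
#' `//`, a `segsites:` count, a `positions:` line (absent when there are no
#' segregating sites), then one 0/1 row per haplotype. Malformed blocks
#' raise a parse error carrying the offending line number.
#'
#' @param path Path to an ms-format text file.
#' @return A list of [haplotype_matrix()] objects, one per replicate.
#' @export
read_ms <- function(path) {
  lines <- readLines(path)
  starts <- which(trimws(lines) == "//")
  if (length(starts) == 0) {
    abort("No '//' replicate blocks found.", class = "abcbench_parse_error")
  }
  parse_block <- function(from, to) {
    i <- from + 1
    while (i <= to && !startsWith(trimws(lines[i]), "segsites:")) i <- i + 1
    if (i > to) {
      abort(sprintf("Block at line %d has no 'segsites:' line.", from),
            class = "abcbench_parse_error")
    }
    S <- as.integer(sub("^segsites:\\s*", "", trimws(lines[i])))
    if (is.na(S)) {
      abort(sprintf("Unparseable segsites count at line %d.", i),
            class = "abcbench_parse_error")
    }
    if (S == 0) {
      # haplotype count is unknowable from an empty block; use 0 rows
      return(haplotype_matrix(matrix(0L, 0, 0)))
    }
    i <- i + 1
    while (i <= to && !startsWith(trimws(lines[i]), "positions:")) i <- i + 1
    if (i > to) {
      abort(sprintf("Block at line %d has no 'positions:' line.", from),
            class = "abcbench_parse_error")
    }
    pos <- as.numeric(strsplit(trimws(sub("^positions:\\s*", "",
                                          trimws(lines[i]))), "\\s+")[[1]])
    if (length(pos) != S || anyNA(pos)) {
      abort(sprintf("Positions at line %d do not match segsites.", i),
            class = "abcbench_parse_error")
    }
    rows <- character(0)
    i <- i + 1
    while (i <= to) {
      ln <- trimws(lines[i])
      if (nzchar(ln)) {
        if (!grepl("^[01]+$", ln)) {
          abort(sprintf("Invalid haplotype row at line %d.", i),
                class = "abcbench_parse_error")
        }
        if (nchar(ln) != S) {
          abort(sprintf("Row length mismatch at line %d (want %d).", i, S),
                class = "abcbench_parse_error")
        }
        rows <- c(rows, ln)
      }
      i <- i + 1
    }
    if (length(rows) == 0) {
      abort(sprintf("Block at line %d has no haplotype rows.", from),
            class = "abcbench_parse_error")
    }
    states <- do.call(rbind, lapply(rows, function(r) {
      as.integer(strsplit(r, "")[[1]])
    }))
    haplotype_matrix(states, pos)
  }
  ends <- c(starts[-1] - 1, length(lines))
  lapply(seq_along(starts), function(b) parse_block(starts[b], ends[b]))
}

#' Write haplotype matrices in ms format
#'
#' Inverse of [read_ms()]: deterministic formatting, positions printed with
#' fixed precision.
#'
#' @param matrices A [haplotype_matrix()] or list of them.
#' @param path Output path.
#' @param digits Decimal places for positions.
#' @return `path`, invisibly.
#' @export
write_ms <- function(matrices, path, digits = 6) {
  if (inherits(matrices, "haplotype_matrix")) matrices <- list(matrices)
  out <- c("abcbench coalescent output", "")
  for (h in matrices) {
    S <- ncol(h$states)
    out <- c(out, "//", paste0("segsites: ", S))
    if (S > 0) {
      out <- c(out,
               paste0("positions: ",
                      paste(formatC(h$positions, digits = digits,
                                    format = "f"), collapse = " ")),
               apply(h$states, 1, paste, collapse = ""))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}
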