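#' Round half-up
#'
#' Decimal rounding where exact halves round away from zero, matching the
#' convention used for every printed percentage in clinical tables (base R's
#' `round()` rounds halves to even). A small epsilon guards against binary
#' floating-point representations of exact halves.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(c(0.25, 0.35), 1) # 0.3 0.4 (round() would give 0.2 0.4)
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Format a proportion as a one-decimal percentage
#'
#' @param p proportion in \[0, 1\] (NA allowed).
#' @return character vector such as `"89.8"`; `NA` formats as `"NA"`.
#' @export
percent1 <- function(p) {
  ifelse(is.na(p), "NA", sprintf("%.1f", round_half_up(100 * p, 1)))
}

# internal: stop with a delabelr-classed condition
abort_delabel <- function(msg, class) {
  stop(structure(
    class = c(class, "delabelr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
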