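# internal helpers shared across modules

# run `expr` under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# per-gene / per-age sub-seed so subsetting a simulation is stable;
# kept strictly below 2^31 - 1 (R integers are 32-bit)
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) s <- (s * 48271 + as.double(k) * 16807 + 1) %% 2147483647
  as.integer(s)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

#' Percent change between two durations
#'
#' Convenience helper for reporting waveform-section changes, e.g. a
#' descending section growing from 16 h to 18 h is `+12.5%`.
#'
#' @param from,to Numeric values (e.g. hours); `from` must be non-zero.
#' @return Percent change `100 * (to - from) / from`.
#' @examples
#' percent_change(16, 18) # +12.5
#' @export
percent_change <- function(from, to) {
  if (any(from == 0)) stop("`from` must be non-zero")
  100 * (to - from) / from
}
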