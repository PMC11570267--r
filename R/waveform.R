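#' Min-max normalize a curve
#'
#' Affine rescaling so the minimum value becomes 0 and the maximum becomes 1.
#' This is the normalization applied before every half-maximum computation.
#'
#' @param values Numeric vector (one daily cycle of measurements).
#' @return Rescaled vector in `[0, 1]`.
#' @export
normalize_minmax <- function(values) {
  r <- range(values)
  if (!all(is.finite(r))) stop("values must be finite")
  if (r[1] == r[2]) stop("constant curve: min-max normalization is degenerate")
  (values - r[1]) / (r[2] - r[1])
}

#' Normalize a curve by its across-time mean
#'
#' Divides every value by the mean across time points, so the output mean is
#' 1. Used to make waveforms of different ages comparable when amplitudes
#' attenuate with age.
#'
#' @param values Numeric vector with positive mean.
#' @return Rescaled vector with mean 1.
#' @export
normalize_by_mean <- function(values) {
  m <- mean(values)
  if (!is.finite(m) || m <= 0) stop("mean must be positive")
  values / m
}

#' Linear-interpolation half-maximum crossing
#'
#' Time at which the line segment through `(t1, f1)` and `(t2, f2)` crosses
#' the half-maximum level 0.5 of a min-max-normalized curve:
#' \deqn{t = \frac{t_2 (f_1 - 0.5) - t_1 (f_2 - 0.5)}{f_1 - f_2}}
#' Endpoint values exactly equal to 0.5 count as a crossing at that sample
#' time (the formula returns the endpoint in that case).
#'
#' @param t1,t2 Sample times (hours).
#' @param f1,f2 Normalized values at `t1`, `t2`; must bracket 0.5.
#' @return Crossing time in hours, in `[t1, t2]`.
#' @examples
#' half_max_crossing(4, 0.8, 6, 0.2) # 5
#' @export
half_max_crossing <- function(t1, f1, t2, f2) {
  if (f1 == f2) stop("degenerate segment: f1 == f2")
  if ((f1 - 0.5) * (f2 - 0.5) > 0) stop("segment does not bracket the half maximum")
  (t2 * (f1 - 0.5) - t1 * (f2 - 0.5)) / (f1 - f2)
}

#' Time of the curve maximum
#'
#' @param times Sample times (hours), strictly increasing.
#' @param values Values at `times`.
#' @return Time of the maximum sample; ties are broken by the earliest time.
#' @export
crest_time <- function(times, values) {
  check_curve(times, values)
  if (diff(range(values)) == 0) stop("constant curve has no crest")
  times[which.max(values)]
}

check_curve <- function(times, values) {
  if (length(times) != length(values)) stop("times and values must have equal length")
  if (length(times) < 3L) stop("a curve needs at least 3 samples")
  if (any(!is.finite(times)) || any(!is.finite(values))) stop("times and values must be finite")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  invisible(TRUE)
}

# Vectorized FWHM over the rows of a curve matrix (curves x time points).
# Each row is min-max normalized; super-half-max membership uses >= 0.5;
# segments are maximal contiguous runs, wrapping across the cycle boundary
# when circular. Crossings use linear interpolation. Returns a data.frame
# with n_segments, ascend, descend, fwhm, crest per row (NA where not a
# single segment; degenerate = constant row).
fwhm_core <- function(vals, times, cycle_length = 24, circular = TRUE) {
  n <- nrow(vals); Tn <- ncol(vals)
  rmin <- vals[, 1]; rmax <- vals[, 1]
  for (j in seq_len(Tn)[-1]) {
    rmin <- pmin(rmin, vals[, j]); rmax <- pmax(rmax, vals[, j])
  }
  rng <- rmax - rmin
  degen <- rng == 0
  rng[degen] <- 1
  norm <- (vals - rmin) / rng
  above <- norm >= 0.5
  if (circular) {
    prev <- above[, c(Tn, seq_len(Tn - 1L)), drop = FALSE]
    nxt <- above[, c(seq_len(Tn)[-1], 1L), drop = FALSE]
  } else {
    prev <- cbind(FALSE, above[, -Tn, drop = FALSE])
    nxt <- cbind(above[, -1L, drop = FALSE], FALSE)
  }
  starts <- above & !prev
  ends <- above & !nxt
  n_seg <- as.integer(rowSums(starts))
  n_seg[degen] <- NA_integer_

  crest <- times[max.col(norm, ties.method = "first")]
  crest[degen] <- NA_real_

  ascend <- descend <- fw <- rep(NA_real_, n)
  single <- !is.na(n_seg) & n_seg == 1L
  if (any(single)) {
    rows <- which(single)
    i0 <- max.col(starts[rows, , drop = FALSE], ties.method = "first")
    j0 <- max.col(ends[rows, , drop = FALSE], ties.method = "first")
    ip <- i0 - 1L
    wrapA <- ip == 0L
    ip[wrapA] <- Tn
    t1a <- times[ip] - ifelse(wrapA, cycle_length, 0)
    t2a <- times[i0]
    f1a <- norm[cbind(rows, ip)]
    f2a <- norm[cbind(rows, i0)]
    jn <- j0 + 1L
    wrapD <- jn > Tn
    jn[wrapD] <- 1L
    t1d <- times[j0]
    t2d <- times[jn] + ifelse(wrapD, cycle_length, 0)
    f1d <- norm[cbind(rows, j0)]
    f2d <- norm[cbind(rows, jn)]
    asc <- (t2a * (f1a - 0.5) - t1a * (f2a - 0.5)) / (f1a - f2a)
    dsc <- (t2d * (f1d - 0.5) - t1d * (f2d - 0.5)) / (f1d - f2d)
    if (!circular) {
      # runs touching the window edge: the boundary sample is the crossing
      asc[wrapA] <- times[1]
      dsc[wrapD] <- times[Tn]
      fw[rows] <- dsc - asc
    } else {
      fw[rows] <- (dsc - asc) %% cycle_length
    }
    ascend[rows] <- asc %% cycle_length
    descend[rows] <- dsc %% cycle_length
  }
  data.frame(n_segments = n_seg, ascend = ascend, descend = descend,
             fwhm = fw, crest = crest, degenerate = degen)
}

#' Full width at half maximum of a daily curve
#'
#' Min-max normalizes the curve, finds all maximal contiguous regions with
#' value >= 0.5 (wrapping across the cycle boundary in circular mode), and —
#' when there is exactly one such region — reports the ascending and
#' descending half-maximum crossings (linear interpolation, see
#' [half_max_crossing()]) and their separation on the circle. With more
#' than one super-half-max region only the segment count is reported;
#' adjudication of multi-peak genes is left to the permutation test
#' ([sog_test()]).
#'
#' @param times Sample times (hours within one cycle), strictly increasing.
#' @param values Values at `times` (raw or normalized; min-max normalization
#'   is applied internally and is idempotent).
#' @param cycle_length Cycle length in hours (24 in diurnal mode).
#' @param circular Treat the curve circularly (default) or as a linear
#'   window (runs touching the window edge then end at the boundary sample).
#' @return An object of class `fwhm_result`: list with `crest_time`,
#'   `ascend_cross`, `descend_cross`, `fwhm` (hours), `n_segments`.
#' @examples
#' tt <- seq(0, 23.9, by = 0.1)
#' fwhm(tt, cos(2 * pi * (tt - 12) / 24)) # symmetric cosine: fwhm = 12
#' @export
fwhm <- function(times, values, cycle_length = 24, circular = TRUE) {
  check_curve(times, values)
  if (diff(range(values)) == 0) stop("constant curve: FWHM undefined")
  res <- fwhm_core(matrix(values, nrow = 1), times, cycle_length, circular)
  structure(
    list(crest_time = res$crest, ascend_cross = res$ascend,
         descend_cross = res$descend, fwhm = res$fwhm,
         n_segments = res$n_segments),
    class = "fwhm_result"
  )
}

#' @export
print.fwhm_result <- function(x, ...) {
  if (x$n_segments == 1L) {
    cat(sprintf("<fwhm> %.3f h | ascend ZT%.3f -> descend ZT%.3f | crest ZT%.3f\n",
                x$fwhm, x$ascend_cross, x$descend_cross, x$crest_time))
  } else {
    cat(sprintf("<fwhm> %d super-half-max segments (no single FWHM) | crest ZT%.3f\n",
                x$n_segments, x$crest_time))
  }
  invisible(x)
}

#' Ascending and descending sections of a daily cycle
#'
#' Splits one cycle at the crest (earliest maximum sample) and trough
#' (earliest minimum sample): `ascending` is the trough-to-crest duration,
#' `descending` the crest-to-trough duration; they sum exactly to the cycle
#' length.
#'
#' @inheritParams fwhm
#' @return List with `ascending`, `descending` (hours), `crest_time`,
#'   `trough_time`, and `tie` (TRUE when the crest or trough value was tied
#'   and the earliest time was taken).
#' @export
sections <- function(times, values, cycle_length = 24) {
  check_curve(times, values)
  if (diff(range(values)) == 0) stop("constant curve has no crest/trough")
  crest <- times[which.max(values)]
  trough <- times[which.min(values)]
  tie <- sum(values == max(values)) > 1L || sum(values == min(values)) > 1L
  asc <- (crest - trough) %% cycle_length
  list(ascending = asc, descending = cycle_length - asc,
       crest_time = crest, trough_time = trough, tie = tie)
}

#' Detrend a trace with a centered running mean
#'
#' Subtracts a centered time-based running mean of width `window` hours
#' (shrinking to the available points near the edges), removing slow drift
#' from multi-day reporter traces before waveform or period analysis.
#'
#' @param trace Data frame with `time_h`, `value`.
#' @param window Window width in hours; should be at least one period
#'   (default 24).
#' @return The trace with `value` replaced by the residual; the removed
#'   baseline is attached as attribute `"baseline"`.
#' @export
detrend_trace <- function(trace, window = 24) {
  stopifnot(all(c("time_h", "value") %in% names(trace)))
  tt <- trace$time_h
  if (window > diff(range(tt))) stop("window is longer than the trace")
  hw <- window / 2
  base <- vapply(seq_along(tt), function(i) {
    mean(trace$value[tt >= tt[i] - hw & tt <= tt[i] + hw])
  }, numeric(1))
  out <- trace
  out$value <- trace$value - base
  attr(out, "baseline") <- base
  out
}

#' Estimate the free-running period by a cosinor scan
#'
#' Fits a single-component cosinor at each candidate period over a scan
#' range and returns the period maximizing the goodness of fit. Intended
#' for detrended circadian (free-running) traces spanning at least two
#' cycles. Traces whose best fit is not significant at `alpha` are flagged
#' non-rhythmic.
#'
#' @param trace Data frame with `time_h`, `value` (detrended).
#' @param scan_range Numeric length-2: period range in hours (default 20-30).
#' @param step Scan step in hours (default 0.05).
#' @param alpha Significance threshold on the best fit's model F-test
#'   p-value (default 0.001).
#' @return List with `period` (hours; `NA` when non-rhythmic), `r_squared`,
#'   `p_value`, `rhythmic`.
#' @export
period_estimate <- function(trace, scan_range = c(20, 30), step = 0.05,
                            alpha = 0.001) {
  stopifnot(all(c("time_h", "value") %in% names(trace)))
  span <- diff(range(trace$time_h))
  if (span < 2 * scan_range[1]) stop("trace must span at least two cycles of the lower scan bound")
  periods <- seq(scan_range[1], scan_range[2], by = step)
  y <- trace$value
  tt <- trace$time_h
  r2 <- vapply(periods, function(p) {
    X <- cbind(1, cos(2 * pi * tt / p), sin(2 * pi * tt / p))
    res <- stats::lm.fit(X, y)$residuals
    1 - sum(res^2) / sum((y - mean(y))^2)
  }, numeric(1))
  best <- which.max(r2)
  n <- length(y)
  Fst <- (r2[best] / 2) / ((1 - r2[best]) / (n - 3))
  p <- stats::pf(Fst, 2, n - 3, lower.tail = FALSE)
  rhythmic <- p < alpha
  list(period = if (rhythmic) periods[best] else NA_real_,
       r_squared = r2[best], p_value = p, rhythmic = rhythmic)
}

#' Split a multi-day trace into single-cycle curves
#'
#' Windows a trace into consecutive cycles of a given length so each window
#' can be analyzed with [fwhm()] or [sections()].
#'
#' @param trace Data frame with `time_h`, `value`.
#' @param period Cycle length in hours.
#' @return List of data.frames, one per complete cycle, each with `time_h`
#'   rebased to `[0, period)`.
#' @export
split_cycles <- function(trace, period = 24) {
  idx <- floor(trace$time_h / period)
  out <- lapply(split(trace, idx), function(d) {
    d$time_h <- d$time_h - min(floor(d$time_h / period)) * period
    d
  })
  out[vapply(out, function(d) diff(range(d$time_h)) >= period * 0.9, logical(1))]
}
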