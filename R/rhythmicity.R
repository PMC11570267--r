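# shared cosinor linear algebra: Y is samples x genes, one design for all
cosinor_core <- function(Y, t, period) {
  if (length(unique(t)) < 4L) stop("cosinor fit needs at least 4 distinct time points")
  X <- cbind(1, cos(2 * pi * t / period), sin(2 * pi * t / period))
  B <- qr.coef(qr(X), Y)                      # 3 x G
  fitted <- X %*% B
  rss <- colSums((Y - fitted)^2)
  tss <- colSums(sweep(Y, 2, colMeans(Y))^2)
  df2 <- length(t) - 3L
  zero_var <- tss == 0
  Fst <- ((tss - rss) / 2) / (rss / df2)
  p <- stats::pf(Fst, 2, df2, lower.tail = FALSE)
  p <- pmax(p, .Machine$double.xmin)          # exact fits: report the floor, not 0
  p[zero_var] <- 1
  amplitude <- sqrt(B[2, ]^2 + B[3, ]^2)
  amplitude[zero_var] <- 0
  acrophase <- (atan2(B[3, ], B[2, ]) * period / (2 * pi)) %% period
  acrophase[zero_var] <- NA_real_
  r2 <- ifelse(zero_var, 0, 1 - rss / tss)
  list(mesor = B[1, ], amplitude = amplitude, acrophase = acrophase,
       r_squared = r2, p_value = p)
}

#' Single-component cosinor regression at a fixed period
#'
#' Ordinary least squares of the measurements on
#' `{1, cos(2*pi*t/period), sin(2*pi*t/period)}`. The fitted rhythm is
#' `mesor + amplitude * cos(2*pi*(t - acrophase)/period)`; the p-value is
#' the F-test of the two rhythm coefficients against the intercept-only
#' model — the statistic used to call a gene rhythmic.
#'
#' @param t Sampling times in hours (replicates repeat the same time);
#'   at least 4 distinct time points required.
#' @param y Measurements at `t`.
#' @param period Fixed period in hours (24 for diurnal data).
#' @return An object of class `cosinor_fit`: list with `mesor`,
#'   `amplitude` (>= 0), `acrophase` (hours in `[0, period)`),
#'   `r_squared`, `p_value`, `period`.
#' @examples
#' t <- rep(c(1, 5, 9, 13, 17, 21), each = 3)
#' y <- 5 + 2 * cos(2 * pi * (t - 9) / 24)
#' cosinor_fit(t, y)
#' @export
cosinor_fit <- function(t, y, period = 24) {
  if (length(t) != length(y)) stop("t and y must have equal length")
  res <- cosinor_core(matrix(y, ncol = 1), t, period)
  structure(
    list(mesor = res$mesor[1], amplitude = res$amplitude[1],
         acrophase = res$acrophase[1], r_squared = res$r_squared[1],
         p_value = res$p_value[1], period = period),
    class = "cosinor_fit"
  )
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(
    "<cosinor, period %g h> mesor %.4g | amplitude %.4g | acrophase ZT%.3f | R2 %.3f | p = %.3g\n",
    x$period, x$mesor, x$amplitude, x$acrophase, x$r_squared, x$p_value
  ))
  invisible(x)
}

#' Detect daily-cycling genes by cosinor regression
#'
#' Fits the fixed-period cosinor to every gene of an expression matrix and
#' calls a gene cycling when the model F-test p-value falls below `alpha`.
#' Following the original procedure, the raw threshold is applied with no
#' multiple-testing correction; `alpha` is exposed so users can tighten or
#' relax the call.
#'
#' @param x A [zt_matrix].
#' @param alpha P-value threshold for the cycling call (default 0.0005).
#' @param period Fixed period in hours.
#' @return Data frame with one row per gene: `gene`, `mesor`, `amplitude`,
#'   `acrophase`, `r_squared`, `p_value`, `is_cycling`.
#' @export
detect_cycling <- function(x, alpha = 5e-4, period = 24) {
  stopifnot(inherits(x, "zt_matrix"))
  res <- cosinor_core(t(x$values), x$samples$zt, period)
  data.frame(
    gene = rownames(x$values), mesor = unname(res$mesor),
    amplitude = unname(res$amplitude), acrophase = unname(res$acrophase),
    r_squared = unname(res$r_squared), p_value = unname(res$p_value),
    is_cycling = unname(res$p_value) < alpha,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Classify amplitude change between two ages
#'
#' Ratio-based three-way classification of commonly cycling genes:
#' `lower` when `amp_old / amp_young < low`, `higher` when the ratio
#' exceeds `high`, `similar` otherwise. The default cutoffs (2/3, 3/2) are
#' symmetric on the log scale.
#'
#' @param amp_young,amp_old Cosinor amplitudes (young must be > 0).
#' @param low,high Ratio cutoffs.
#' @return Character vector in `{"lower", "similar", "higher"}`.
#' @export
amplitude_class <- function(amp_young, amp_old, low = 2 / 3, high = 3 / 2) {
  if (any(amp_young <= 0)) stop("amp_young must be > 0 (amplitude class undefined)")
  ratio <- amp_old / amp_young
  ifelse(ratio < low, "lower", ifelse(ratio > high, "higher", "similar"))
}
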