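#' Replicate-permutation curve ensemble for one gene
#'
#' Builds `n` daily curves by drawing, independently for each curve and each
#' time point, one of the measured replicate values at that time point
#' (uniformly, with replacement across curves). This ensemble is the basis
#' of the single-oscillation-gene test and of the FWHM-change test.
#'
#' @param gene_data Numeric matrix of measurements, time points x replicates
#'   (`NA` for missing replicates; at least one value per time point). Row
#'   order must match `times` order used downstream.
#' @param n Number of curves (default 10000).
#' @param seed Integer seed; ensembles are reproducible.
#' @return Numeric matrix `n x nrow(gene_data)`, one resampled curve per row.
#' @export
permutation_curves <- function(gene_data, n = 10000, seed = 1) {
  gene_data <- as.matrix(gene_data)
  Tn <- nrow(gene_data)
  if (n < 1) stop("n must be >= 1")
  avail <- lapply(seq_len(Tn), function(i) which(!is.na(gene_data[i, ])))
  if (any(lengths(avail) == 0L)) stop("every time point needs at least one replicate value")
  with_seed(seed, {
    out <- matrix(NA_real_, n, Tn)
    for (i in seq_len(Tn)) {
      a <- avail[[i]]
      idx <- if (length(a) == 1L) rep(a, n) else a[sample.int(length(a), n, replace = TRUE)]
      out[, i] <- gene_data[i, idx]
    }
    out
  })
}

#' Does a curve have a single super-half-maximum region?
#'
#' TRUE iff the min-max-normalized curve has exactly one maximal contiguous
#' region with value >= 0.5 under circular wraparound. Constant
#' (degenerate) curves return FALSE.
#'
#' @inheritParams fwhm
#' @return Logical flag.
#' @export
is_single_fwhm <- function(times, values, cycle_length = 24, circular = TRUE) {
  check_curve(times, values)
  if (diff(range(values)) == 0) return(FALSE)
  res <- fwhm_core(matrix(values, nrow = 1), times, cycle_length, circular)
  res$n_segments == 1L
}

#' Single-oscillation-gene (SOG) permutation test
#'
#' Resamples `n` curves from the replicate values ([permutation_curves()]),
#' and reports the fraction with a single super-half-maximum region
#' (`single_ratio`). A gene with `single_ratio > threshold` (default 0.95)
#' is called a single oscillation gene; `fwhm_mean` is the mean FWHM over
#' the single-region curves.
#'
#' @param times Time points in hours (one per row of `gene_data`).
#' @param gene_data Time point x replicate value matrix for one gene.
#' @param n Number of permutation curves (default 10000).
#' @param threshold SOG call threshold on `single_ratio` (default 0.95).
#' @param seed Integer seed.
#' @param cycle_length,circular Passed to the FWHM machinery.
#' @return An object of class `sog_call`: list with `single_ratio`,
#'   `is_sog`, `fwhm_mean`, `crest_mean`, `n`.
#' @export
sog_test <- function(times, gene_data, n = 10000, threshold = 0.95, seed = 1,
                     cycle_length = 24, circular = TRUE) {
  ens <- permutation_curves(gene_data, n = n, seed = seed)
  res <- fwhm_core(ens, times, cycle_length, circular)
  single <- !is.na(res$n_segments) & res$n_segments == 1L
  ratio <- mean(single)
  structure(
    list(single_ratio = ratio, is_sog = ratio > threshold,
         fwhm_mean = if (any(single)) mean(res$fwhm[single]) else NA_real_,
         crest_mean = if (any(single)) circ_mean(res$crest[single], cycle_length) else NA_real_,
         n = n),
    class = "sog_call"
  )
}

#' @export
print.sog_call <- function(x, ...) {
  cat(sprintf("<sog> single_ratio %.4f (n = %d) | %s | mean FWHM %.3f h\n",
              x$single_ratio, x$n, if (x$is_sog) "SOG" else "not a SOG", x$fwhm_mean))
  invisible(x)
}

#' SOG scan over every gene of a matrix
#'
#' Applies [sog_test()] to each gene, with per-gene sub-seeds derived from
#' `seed` so results do not depend on gene order or subsetting.
#'
#' @param x A [zt_matrix].
#' @param n,threshold As in [sog_test()].
#' @param seed Master seed.
#' @param genes Optional subset of gene ids.
#' @return Data frame: `gene`, `single_ratio`, `is_sog`, `fwhm_mean`,
#'   `crest_mean`.
#' @export
sog_scan <- function(x, n = 10000, threshold = 0.95, seed = 1, genes = NULL) {
  stopifnot(inherits(x, "zt_matrix"))
  if (is.null(genes)) genes <- rownames(x$values)
  rows <- lapply(seq_along(genes), function(i) {
    gd <- gene_replicate_matrix(x, genes[i])
    call <- sog_test(attr(gd, "zt"), gd, n = n, threshold = threshold,
                     seed = derive_seed(seed, 5L, i))
    data.frame(gene = genes[i], single_ratio = call$single_ratio,
               is_sog = call$is_sog, fwhm_mean = call$fwhm_mean,
               crest_mean = call$crest_mean, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Permutation test for age-dependent FWHM change
#'
#' Builds replicate-permutation ensembles for the same gene at two ages and
#' compares their FWHM distributions. `delta_fwhm` is the difference of
#' mean FWHM (old minus young) over single-region curves. The p-value is a
#' two-sided label-resampling test: the two ensembles' FWHM values are
#' pooled, group labels resampled `n_null` times, and the tail probability
#' of the observed `|delta|` reported. The change is significant when
#' `p < p_cutoff` AND `|delta_fwhm| > delta_gate` hours (defaults 0.05 and
#' 2 h).
#'
#' @param times Time points in hours.
#' @param young_data,old_data Time point x replicate matrices for the gene
#'   at the two ages.
#' @param n Ensemble size per age (default 10000).
#' @param n_null Number of label resamples for the null (default 1000).
#' @param seed Integer seed.
#' @param p_cutoff,delta_gate Significance gates.
#' @param sog_threshold Both ages must pass this single-ratio threshold
#'   (the test presupposes a single-oscillation gene); set to `NULL` to
#'   skip the check.
#' @param cycle_length,circular Passed to the FWHM machinery.
#' @return An object of class `fwhm_change`: list with `delta_fwhm`,
#'   `p_value`, `significant`, `direction` (`"shortened"`, `"lengthened"`,
#'   `"unchanged"`), `fwhm_young`, `fwhm_old`, `single_ratio_young`,
#'   `single_ratio_old`.
#' @export
fwhm_change_test <- function(times, young_data, old_data, n = 10000,
                             n_null = 1000, seed = 1, p_cutoff = 0.05,
                             delta_gate = 2, sog_threshold = 0.95,
                             cycle_length = 24, circular = TRUE) {
  ens_y <- permutation_curves(young_data, n = n, seed = derive_seed(seed, 6L, 1L))
  ens_o <- permutation_curves(old_data, n = n, seed = derive_seed(seed, 6L, 2L))
  res_y <- fwhm_core(ens_y, times, cycle_length, circular)
  res_o <- fwhm_core(ens_o, times, cycle_length, circular)
  sy <- !is.na(res_y$n_segments) & res_y$n_segments == 1L
  so <- !is.na(res_o$n_segments) & res_o$n_segments == 1L
  ratio_y <- mean(sy); ratio_o <- mean(so)
  if (!is.null(sog_threshold) && (ratio_y <= sog_threshold || ratio_o <= sog_threshold)) {
    stop(sprintf(
      "gene is not a SOG at both ages (single ratios %.3f, %.3f <= %.2f)",
      ratio_y, ratio_o, sog_threshold
    ))
  }
  fy <- res_y$fwhm[sy]; fo <- res_o$fwhm[so]
  delta <- mean(fo) - mean(fy)
  pool <- c(fy, fo)
  N <- length(pool); no <- length(fo)
  S <- sum(pool)
  null_delta <- with_seed(derive_seed(seed, 6L, 3L), {
    vapply(seq_len(n_null), function(b) {
      so_sum <- sum(pool[sample.int(N, no)])
      so_sum / no - (S - so_sum) / (N - no)
    }, numeric(1))
  })
  p <- (1 + sum(abs(null_delta) >= abs(delta))) / (n_null + 1)
  sig <- p < p_cutoff && abs(delta) > delta_gate
  structure(
    list(delta_fwhm = delta, p_value = p, significant = sig,
         direction = if (!sig) "unchanged" else if (delta < 0) "shortened" else "lengthened",
         fwhm_young = mean(fy), fwhm_old = mean(fo),
         single_ratio_young = ratio_y, single_ratio_old = ratio_o),
    class = "fwhm_change"
  )
}

#' @export
print.fwhm_change <- function(x, ...) {
  cat(sprintf(
    "<fwhm change> %.3f h -> %.3f h | delta %+0.3f h | p = %.3g | %s\n",
    x$fwhm_young, x$fwhm_old, x$delta_fwhm, x$p_value, x$direction
  ))
  invisible(x)
}

#' Partition SOG calls from two ages
#'
#' @param calls_young,calls_old Data frames as returned by [sog_scan()],
#'   over the same gene universe.
#' @return List of gene-id vectors: `common`, `young_only`, `old_only`.
#' @export
classify_sog_sets <- function(calls_young, calls_old) {
  if (!setequal(calls_young$gene, calls_old$gene)) {
    stop("SOG calls must come from the same gene universe")
  }
  sy <- calls_young$gene[calls_young$is_sog]
  so <- calls_old$gene[calls_old$is_sog]
  list(common = intersect(sy, so),
       young_only = setdiff(sy, so),
       old_only = setdiff(so, sy))
}

# circular mean of hours on a cycle
circ_mean <- function(h, cycle_length = 24) {
  ang <- 2 * pi * h / cycle_length
  (atan2(mean(sin(ang)), mean(cos(ang))) * cycle_length / (2 * pi)) %% cycle_length
}
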