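#' Parametric single-crest diurnal waveform
#'
#' The generative curve family used by the synthetic time-course generator:
#' a piecewise half-cosine ramp rising 0 to 1 over `rise` hours up to
#' `peak_phase`, falling 1 to 0 over the following `fall` hours, raised to
#' the power `sharpness`, scaled and shifted:
#' \deqn{w(t) = baseline + amplitude \cdot s(t)^{sharpness}}
#' The family was chosen because its parameters independently control phase
#' (`peak_phase`), skew (`rise` vs `fall`) and expression duration / FWHM
#' (`sharpness`), which are exactly the waveform features the downstream
#' estimators recover.
#'
#' @param peak_phase Crest time, hours ZT in `[0, period)`.
#' @param rise Trough-to-crest duration in hours (> 0).
#' @param fall Crest-to-trough duration in hours; defaults to
#'   `period - rise`. `rise + fall` must equal `period`.
#' @param sharpness Dimensionless exponent k > 0. At k = 1 the FWHM is half
#'   the period; k > 1 narrows the super-half-maximum region (shorter FWHM)
#'   and k < 1 broadens it (FWHM beyond half the period).
#' @param amplitude Peak height above baseline, expression units (>= 0).
#' @param baseline Trough level, expression units (>= 0).
#' @param period Hours; 24 in diurnal mode, free in circadian mode.
#' @return An object of class `waveform_params`.
#' @examples
#' p <- waveform_params(peak_phase = 13, rise = 9, sharpness = 2, amplitude = 5,
#'                      baseline = 1)
#' eval_waveform(p, c(13, 13 + 15)) # crest = baseline + amplitude; trough = baseline
#' true_fwhm(p)
#' @export
waveform_params <- function(peak_phase, rise, fall = period - rise, sharpness = 1,
                            amplitude = 1, baseline = 0, period = 24) {
  stopifnot_scalar(rise, "rise", positive = TRUE)
  stopifnot_scalar(fall, "fall", positive = TRUE)
  stopifnot_scalar(period, "period", positive = TRUE)
  stopifnot_scalar(sharpness, "sharpness")
  stopifnot_scalar(amplitude, "amplitude")
  stopifnot_scalar(baseline, "baseline")
  if (abs(rise + fall - period) > 1e-8) {
    stop("rise + fall must equal period")
  }
  if (sharpness <= 0) stop("sharpness must be > 0")
  if (amplitude < 0 || baseline < 0) stop("amplitude and baseline must be >= 0")
  peak_phase <- peak_phase %% period
  structure(
    list(peak_phase = peak_phase, rise = rise, fall = fall,
         sharpness = sharpness, amplitude = amplitude, baseline = baseline,
         period = period),
    class = "waveform_params"
  )
}

#' @export
print.waveform_params <- function(x, ...) {
  cat(sprintf(
    "<waveform> peak ZT%.2f | rise %.2f h, fall %.2f h | k = %.2f | amp %.3g + base %.3g | period %g h\n",
    x$peak_phase, x$rise, x$fall, x$sharpness, x$amplitude, x$baseline, x$period
  ))
  invisible(x)
}

#' Evaluate a waveform at given times
#'
#' @param params A [waveform_params] object.
#' @param t Times in hours (any real values; the waveform is periodic).
#' @return Expression values `w(t)`.
#' @rdname waveform_params
#' @export
eval_waveform <- function(params, t) {
  p <- params
  x <- (t - (p$peak_phase - p$rise)) %% p$period
  s <- ifelse(x <= p$rise,
              (1 - cos(pi * x / p$rise)) / 2,
              (1 + cos(pi * (x - p$rise) / p$fall)) / 2)
  p$baseline + p$amplitude * s^p$sharpness
}

#' @rdname waveform_params
#' @return `make_waveform()` returns a function of time (hours).
#' @export
make_waveform <- function(params) {
  stopifnot(inherits(params, "waveform_params"))
  function(t) eval_waveform(params, t)
}

#' Ground-truth FWHM of a waveform
#'
#' FWHM of the min-max-normalized waveform, computed on a dense time grid
#' with linearly interpolated half-maximum crossings. Used as recovery
#' ground truth for the sparse-sampling estimators.
#'
#' @param params A [waveform_params] object.
#' @param step Grid step in hours (default 0.001).
#' @return FWHM in hours.
#' @export
true_fwhm <- function(params, step = 0.001) {
  stopifnot(inherits(params, "waveform_params"))
  tt <- seq(0, params$period, by = step)
  tt <- tt[tt < params$period]
  v <- eval_waveform(params, tt)
  res <- fwhm(tt, v, cycle_length = params$period, circular = TRUE)
  if (res$n_segments != 1L) stop("waveform does not have a single super-half-max region")
  res$fwhm
}

#' Age effect applied to cycling-gene waveforms
#'
#' Phenomenological aging transform: amplitude attenuation, peak-phase
#' shift, and FWHM change (sharpening shortens, broadening lengthens the
#' super-half-maximum region, realized by scaling the `sharpness`
#' exponent so `rise + fall` stays equal to the period).
#'
#' @param amplitude_scale Multiplies the waveform amplitude (> 0).
#' @param phase_shift Hours added to `peak_phase` (mod period).
#' @param fwhm_delta_mode One of `"none"`, `"sharpen"`, `"broaden"`.
#' @param applies_to Fraction of cycling genes the effect applies to, in
#'   `[0, 1]`; the first `round(applies_to * n_cycling)` genes are affected
#'   so gene subsets stay comparable across configurations.
#' @param sharpness_factor Factor by which `sharpness` is multiplied
#'   (sharpen) or divided, floored at 1 (broaden).
#' @return An object of class `age_effect`.
#' @export
age_effect <- function(amplitude_scale = 1, phase_shift = 0,
                       fwhm_delta_mode = c("none", "sharpen", "broaden"),
                       applies_to = 1, sharpness_factor = 2) {
  fwhm_delta_mode <- match.arg(fwhm_delta_mode)
  stopifnot_scalar(amplitude_scale, "amplitude_scale", positive = TRUE)
  stopifnot_scalar(phase_shift, "phase_shift")
  if (applies_to < 0 || applies_to > 1) stop("applies_to must be in [0, 1]")
  structure(
    list(amplitude_scale = amplitude_scale, phase_shift = phase_shift,
         fwhm_delta_mode = fwhm_delta_mode, applies_to = applies_to,
         sharpness_factor = sharpness_factor),
    class = "age_effect"
  )
}

apply_age_effect <- function(params, effect) {
  k <- switch(effect$fwhm_delta_mode,
    none = params$sharpness,
    sharpen = params$sharpness * effect$sharpness_factor,
    broaden = params$sharpness / effect$sharpness_factor
  )
  waveform_params(
    peak_phase = (params$peak_phase + effect$phase_shift) %% params$period,
    rise = params$rise, fall = params$fall, sharpness = k,
    amplitude = params$amplitude * effect$amplitude_scale,
    baseline = params$baseline, period = params$period
  )
}

#' Simulation configuration for diurnal expression matrices
#'
#' Defines the sampling design and gene population for
#' [simulate_expression_matrix()]. Defaults emulate a diurnal RNA-seq
#' design: 6 time points (ZT1, 5, 9, 13, 17, 21) x 3 replicates under
#' LD 16:8 entrainment, a mix of cycling genes (24-h period, varied peak
#' phase, skew, sharpness, amplitude) and flat noise genes, with
#' multiplicative log-normal replicate noise.
#'
#' @param n_cycling,n_flat Numbers of cycling and flat genes.
#' @param timepoints ZT hours sampled, strictly increasing within `[0, 24)`.
#' @param n_replicates Replicates per time point (>= 1).
#' @param noise_cv Coefficient of variation of replicate noise.
#' @param noise_model `"multiplicative-lognormal"` (default; positive
#'   values, sd proportional to signal) or `"additive-gaussian"`
#'   (sd = `noise_cv` x the gene's mean signal level, for analytic checks).
#' @param seed Integer master seed; per-gene sub-streams are derived from it
#'   so subsetting the gene population is stable.
#' @param ages Named list of [age_effect] objects, one per age group. The
#'   first entry is the reference age.
#' @param period Hours (24 for diurnal designs).
#' @param rise_range,sharpness_range,amplitude_range,baseline_range
#'   Uniform sampling ranges for cycling-gene waveform parameters.
#' @param flat_level_range Uniform range for flat-gene mean levels.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cycling, n_flat,
                       timepoints = c(1, 5, 9, 13, 17, 21),
                       n_replicates = 3, noise_cv = 0.1,
                       noise_model = c("multiplicative-lognormal", "additive-gaussian"),
                       seed = 1,
                       ages = list(young = age_effect()),
                       period = 24,
                       rise_range = c(6, 18), sharpness_range = c(1, 4),
                       amplitude_range = c(0.5, 4), baseline_range = c(0.5, 2),
                       flat_level_range = c(0.5, 4)) {
  noise_model <- match.arg(noise_model)
  if (length(timepoints) == 0) stop("timepoints must be non-empty")
  if (any(diff(timepoints) <= 0) || any(timepoints < 0) || any(timepoints >= period)) {
    stop("timepoints must be strictly increasing within [0, period)")
  }
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (is.null(names(ages)) || any(names(ages) == "")) stop("`ages` must be a named list")
  if (!all(vapply(ages, inherits, logical(1), "age_effect"))) {
    stop("every entry of `ages` must be an age_effect()")
  }
  structure(
    list(n_cycling = n_cycling, n_flat = n_flat, timepoints = timepoints,
         n_replicates = n_replicates, noise_cv = noise_cv,
         noise_model = noise_model, seed = seed, ages = ages, period = period,
         rise_range = rise_range, sharpness_range = sharpness_range,
         amplitude_range = amplitude_range, baseline_range = baseline_range,
         flat_level_range = flat_level_range),
    class = "sim_config"
  )
}

# noise applied to a vector of true signal values mu
add_noise <- function(mu, cv, model, mean_level) {
  if (cv == 0) return(mu)
  if (model == "multiplicative-lognormal") {
    sdlog <- sqrt(log(1 + cv^2))
    mu * exp(stats::rnorm(length(mu), 0, sdlog) - sdlog^2 / 2)
  } else {
    mu + stats::rnorm(length(mu), 0, cv * mean_level)
  }
}

#' Simulate diurnal expression matrices with known ground truth
#'
#' Generates one [zt_matrix] per age group plus a ground-truth table of the
#' waveform parameters each gene was generated from. Deterministic given
#' `config$seed`; every source of randomness flows from per-gene sub-streams
#' derived from it.
#'
#' @param config A [sim_config].
#' @param truth_fwhm If `TRUE` (default) the ground-truth table includes the
#'   dense-grid FWHM of every cycling gene at every age (`true_fwhm()`);
#'   turn off to skip that computation when only the matrices are needed.
#' @return A list with elements `matrices` (named list of [zt_matrix], one
#'   per age) and `truth` (data.frame: gene, age, is_cycling, waveform
#'   parameters, `true_peak`, `true_fwhm`).
#' @examples
#' cfg <- sim_config(n_cycling = 5, n_flat = 2, noise_cv = 0.05, seed = 7)
#' sim <- simulate_expression_matrix(cfg)
#' sim$matrices$young
#' head(sim$truth)
#' @export
simulate_expression_matrix <- function(config, truth_fwhm = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  tps <- cfg$timepoints
  n_genes <- cfg$n_cycling + cfg$n_flat
  gene_ids <- c(sprintf("cyc_%04d", seq_len(cfg$n_cycling)),
                sprintf("flat_%04d", seq_len(cfg$n_flat)))

  base_params <- vector("list", cfg$n_cycling)
  for (g in seq_len(cfg$n_cycling)) {
    base_params[[g]] <- with_seed(derive_seed(cfg$seed, 1L, g), {
      rise <- stats::runif(1, cfg$rise_range[1], cfg$rise_range[2])
      waveform_params(
        peak_phase = stats::runif(1, 0, cfg$period),
        rise = rise, fall = cfg$period - rise,
        sharpness = stats::runif(1, cfg$sharpness_range[1], cfg$sharpness_range[2]),
        amplitude = stats::runif(1, cfg$amplitude_range[1], cfg$amplitude_range[2]),
        baseline = stats::runif(1, cfg$baseline_range[1], cfg$baseline_range[2]),
        period = cfg$period
      )
    })
  }
  flat_levels <- vapply(seq_len(cfg$n_flat), function(g) {
    with_seed(derive_seed(cfg$seed, 2L, g),
              stats::runif(1, cfg$flat_level_range[1], cfg$flat_level_range[2]))
  }, numeric(1))

  t_rep <- rep(tps, each = cfg$n_replicates)
  matrices <- list()
  truth <- list()
  for (a in seq_along(cfg$ages)) {
    age_name <- names(cfg$ages)[a]
    eff <- cfg$ages[[a]]
    n_affected <- round(eff$applies_to * cfg$n_cycling)
    vals <- matrix(NA_real_, n_genes, length(t_rep),
                   dimnames = list(gene_ids, NULL))
    tr <- vector("list", n_genes)
    for (g in seq_len(cfg$n_cycling)) {
      p <- if (g <= n_affected) apply_age_effect(base_params[[g]], eff) else base_params[[g]]
      mu <- eval_waveform(p, t_rep)
      vals[g, ] <- with_seed(
        derive_seed(cfg$seed, 3L, g, a),
        add_noise(mu, cfg$noise_cv, cfg$noise_model, mean(eval_waveform(p, tps)))
      )
      tr[[g]] <- data.frame(
        gene = gene_ids[g], age = age_name, is_cycling = TRUE,
        peak_phase = p$peak_phase, rise = p$rise, fall = p$fall,
        sharpness = p$sharpness, amplitude = p$amplitude, baseline = p$baseline,
        true_peak = p$peak_phase,
        true_fwhm = if (truth_fwhm) true_fwhm(p) else NA_real_,
        stringsAsFactors = FALSE
      )
    }
    for (g in seq_len(cfg$n_flat)) {
      gi <- cfg$n_cycling + g
      mu <- rep(flat_levels[g], length(t_rep))
      vals[gi, ] <- with_seed(
        derive_seed(cfg$seed, 4L, g, a),
        add_noise(mu, cfg$noise_cv, cfg$noise_model, flat_levels[g])
      )
      tr[[gi]] <- data.frame(
        gene = gene_ids[gi], age = age_name, is_cycling = FALSE,
        peak_phase = NA_real_, rise = NA_real_, fall = NA_real_,
        sharpness = NA_real_, amplitude = 0, baseline = flat_levels[g],
        true_peak = NA_real_, true_fwhm = NA_real_, stringsAsFactors = FALSE
      )
    }
    matrices[[age_name]] <- zt_matrix(
      vals, zt = t_rep,
      replicate = rep(seq_len(cfg$n_replicates), times = length(tps)),
      age = age_name
    )
    truth[[age_name]] <- do.call(rbind, tr)
  }
  list(matrices = matrices, truth = do.call(rbind, c(truth, make.row.names = FALSE)))
}

#' Simulate a single reporter-style trace
#'
#' Multi-day, regularly sampled series (luminescence-style) from a waveform
#' plus a linear trend and optional noise; emulates multi-day reporter
#' recordings at ~20-min resolution. In circadian (free-running) mode use a
#' `period` different from 24 h.
#'
#' @param params A [waveform_params].
#' @param duration Total duration in hours; must exceed the waveform period.
#' @param interval Sampling interval in hours; must be < `duration`.
#' @param trend Linear drift in units/hour added to the signal.
#' @param noise_cv Coefficient of variation of the noise on the oscillatory
#'   component.
#' @param noise_model As in [sim_config].
#' @param seed Integer seed (noise determinism).
#' @return Data frame with columns `time_h`, `value`.
#' @examples
#' p <- waveform_params(peak_phase = 10, rise = 12, period = 25.4)
#' tr <- simulate_trace(p, duration = 96, interval = 1 / 3, trend = -0.01, seed = 3)
#' @export
simulate_trace <- function(params, duration, interval, trend = 0, noise_cv = 0,
                           noise_model = c("multiplicative-lognormal", "additive-gaussian"),
                           seed = 1) {
  stopifnot(inherits(params, "waveform_params"))
  noise_model <- match.arg(noise_model)
  if (duration <= params$period) stop("duration must exceed the waveform period")
  if (interval >= duration) stop("interval must be smaller than duration")
  tt <- seq(0, duration, by = interval)
  mu <- eval_waveform(params, tt)
  v <- with_seed(seed, add_noise(mu, noise_cv, noise_model, mean(mu)))
  data.frame(time_h = tt, value = v + trend * tt)
}
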