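# shared fixtures built in code

# the canonical skewed single-crest gene used across permutation tests
canonical_gene <- function() {
  waveform_params(peak_phase = 13, rise = 9, fall = 15, sharpness = 2,
                  amplitude = 5, baseline = 1)
}

# time point x replicate matrix for a waveform under multiplicative noise
replicate_matrix <- function(params, times, n_rep = 3, cv = 0.05, seed = 1) {
  mu <- eval_waveform(params, times)
  sdlog <- sqrt(log(1 + cv^2))
  withr::with_seed(seed, {
    matrix(rep(mu, n_rep) * exp(rnorm(length(times) * n_rep, 0, sdlog) - sdlog^2 / 2),
           nrow = length(times))
  })
}

# dense-grid brute-force FWHM oracle: measures the super-half-max set of the
# *normalized analytic waveform* on a fine grid, independent of the package's
# crossing interpolation
brute_fwhm <- function(params, step = 1e-4) {
  tt <- seq(0, params$period, by = step)
  v <- eval_waveform(params, tt)
  v <- (v - min(v)) / (max(v) - min(v))
  sum(v >= 0.5) * step
}

# closed-form FWHM of the powered half-cosine family: solve s(t)^k = 0.5
analytic_fwhm <- function(params) {
  cc <- 0.5^(1 / params$sharpness)
  t_asc <- params$peak_phase - params$rise + (params$rise / pi) * acos(1 - 2 * cc)
  t_dsc <- params$peak_phase + (params$fall / pi) * acos(2 * cc - 1)
  t_dsc - t_asc
}

two_age_config <- function(n_cycling = 30, n_flat = 10, noise_cv = 0.1, seed = 1,
                           old_effect = age_effect(amplitude_scale = 0.5,
                                                   fwhm_delta_mode = "broaden")) {
  sim_config(
    n_cycling = n_cycling, n_flat = n_flat, noise_cv = noise_cv, seed = seed,
    ages = list(young = age_effect(), old = old_effect)
  )
}

# sharpness exponent that gives a target FWHM for fixed rise/fall
solve_sharpness <- function(target, rise = 9, fall = 15) {
  f <- function(logk) {
    p <- waveform_params(12, rise, fall, sharpness = exp(logk))
    analytic_fwhm(p) - target
  }
  exp(uniroot(f, c(log(0.02), log(80)))$root)
}
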