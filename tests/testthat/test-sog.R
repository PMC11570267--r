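zts6 <- c(1, 5, 9, 13, 17, 21)

test_that("permutation curves draw one replicate per time point, reproducibly", {
  gd <- matrix(1:18, nrow = 6)              # 6 time points x 3 replicates
  ens <- permutation_curves(gd, n = 50, seed = 3)
  expect_equal(dim(ens), c(50, 6))
  for (i in 1:6) expect_true(all(ens[, i] %in% gd[i, ]))
  expect_identical(ens, permutation_curves(gd, n = 50, seed = 3))
  expect_false(identical(ens, permutation_curves(gd, n = 50, seed = 4)))

  # a single replicate per time point: all curves identical
  one <- permutation_curves(matrix(1:6, nrow = 6), n = 20, seed = 1)
  expect_true(all(apply(one, 2, function(c) length(unique(c)) == 1L)))

  expect_error(permutation_curves(rbind(gd, NA), n = 10), "at least one replicate")
})

test_that("draws are uniform over the r^T replicate combinations", {
  # counting oracle: each of the 3^6 combinations has probability 3^-6
  gd <- matrix(rep(1:3, each = 6), nrow = 6)    # value = replicate index
  n <- 1e6
  ens <- permutation_curves(gd, n = n, seed = 9)
  target <- c(1, 3, 2, 2, 1, 3)
  hits <- sum(colSums(t(ens) == target) == 6L)
  ci <- qbinom(c(0.0005, 0.9995), n, 3^-6)
  expect_gte(hits, ci[1])
  expect_lte(hits, ci[2])
})

test_that("single-region detection distinguishes unimodal, bimodal and spike curves", {
  tt <- seq(0, 23.5, by = 0.5)
  expect_true(is_single_fwhm(tt, eval_waveform(canonical_gene(), tt)))
  bim <- eval_waveform(waveform_params(4, 2, 22, sharpness = 8), tt) +
    eval_waveform(waveform_params(16, 2, 22, sharpness = 8), tt)
  expect_false(is_single_fwhm(tt, bim))
  spike <- c(rep(1, 10), 5, rep(1, 37))
  expect_true(is_single_fwhm(tt, spike))       # one maximal region of one sample
  expect_false(is_single_fwhm(tt, rep(2, 48))) # degenerate counts as non-single
})

test_that("sog_test is exact without noise and robust to moderate noise", {
  tt <- seq(0, 23.5, by = 0.5)
  uni <- matrix(rep(eval_waveform(canonical_gene(), tt), 3), ncol = 3)
  call <- sog_test(tt, uni, n = 500, seed = 1)
  expect_identical(call$single_ratio, 1)
  expect_true(call$is_sog)
  expect_equal(call$fwhm_mean, analytic_fwhm(canonical_gene()), tolerance = 0.1)

  bimv <- eval_waveform(waveform_params(4, 2, 22, sharpness = 8), tt) +
    eval_waveform(waveform_params(16, 2, 22, sharpness = 8), tt)
  bim <- matrix(rep(bimv, 3), ncol = 3)
  expect_identical(sog_test(tt, bim, n = 500, seed = 1)$single_ratio, 0)

  # noiseless data always gives a ratio of exactly 0 or 1
  for (s in 1:3) {
    p <- withr::with_seed(s, waveform_params(runif(1, 0, 24), 9, 15,
                                             sharpness = runif(1, 0.8, 4)))
    r <- sog_test(tt, matrix(rep(eval_waveform(p, tt), 3), ncol = 3),
                  n = 200, seed = s)$single_ratio
    expect_true(r %in% c(0, 1))
  }

  # under replicate noise (cv 0.05, 30-min sampling) the ratio is high for
  # most replicate draws: exactly 1 in the median seed
  ratios <- vapply(1:10, function(s) {
    gd <- replicate_matrix(canonical_gene(), tt, cv = 0.05, seed = s)
    sog_test(tt, gd, n = 1000, seed = s)$single_ratio
  }, numeric(1))
  expect_gt(median(ratios), 0.95)
})

test_that("FWHM-change test recovers a known lengthening and respects its gates", {
  tt <- seq(0, 23.5, by = 0.5)
  # a clock-output-like pair on the 6-time-point transcriptome design:
  # expression duration grows from 5.2 h to 12.6 h with age
  young_p <- waveform_params(12, 9, 15, sharpness = solve_sharpness(5.2),
                             amplitude = 3, baseline = 1)
  old_p <- waveform_params(12, 9, 15, sharpness = solve_sharpness(12.6),
                           amplitude = 3, baseline = 1)
  deltas <- vapply(1:10, function(s) {
    ch <- fwhm_change_test(
      zts6,
      replicate_matrix(young_p, zts6, cv = 0.05, seed = s),
      replicate_matrix(old_p, zts6, cv = 0.05, seed = 1000 + s),
      n = 1000, n_null = 199, seed = s
    )
    expect_true(ch$significant)
    expect_identical(ch$direction, "lengthened")
    ch$delta_fwhm
  }, numeric(1))
  expect_lt(abs(mean(deltas) - 7.4), 1)      # recovery of the true lengthening
  expect_true(all(abs(deltas - 7.4) < 1.6))  # per-seed interpolation spread

  # same data at both ages: delta near zero, never significant
  gd <- replicate_matrix(young_p, tt, cv = 0.05, seed = 5)
  ch0 <- fwhm_change_test(tt, gd, gd, n = 1000, n_null = 199, seed = 2)
  expect_lt(abs(ch0$delta_fwhm), 0.2)
  expect_false(ch0$significant)
  expect_identical(ch0$direction, "unchanged")

  # a true 1-h change sits below the 2-h gate regardless of p
  young1 <- waveform_params(12, 9, 15, sharpness = solve_sharpness(8),
                            amplitude = 3, baseline = 1)
  old1 <- waveform_params(12, 9, 15, sharpness = solve_sharpness(9),
                          amplitude = 3, baseline = 1)
  ch1 <- fwhm_change_test(tt, replicate_matrix(young1, tt, cv = 0.02, seed = 1),
                          replicate_matrix(old1, tt, cv = 0.02, seed = 2),
                          n = 1000, n_null = 199, seed = 3)
  expect_false(ch1$significant)

  # non-SOG input errors
  bimv <- eval_waveform(waveform_params(4, 2, 22, sharpness = 8), tt) +
    eval_waveform(waveform_params(16, 2, 22, sharpness = 8), tt)
  bim <- matrix(rep(bimv, 3), ncol = 3)
  expect_error(fwhm_change_test(tt, bim, bim, n = 200, seed = 1), "SOG")
})

test_that("FWHM-change test holds its type-I error and its power at a 4-h effect", {
  tt <- seq(0, 23.5, by = 0.5)
  p <- waveform_params(12, 9, 15, sharpness = 2, amplitude = 3, baseline = 1)
  # null: same waveform at both ages, independent replicate noise
  null_sig <- vapply(1:200, function(g) {
    ch <- fwhm_change_test(tt, replicate_matrix(p, tt, cv = 0.1, seed = 2 * g),
                           replicate_matrix(p, tt, cv = 0.1, seed = 2 * g + 1),
                           n = 1000, n_null = 99, seed = g, sog_threshold = NULL)
    ch$significant
  }, logical(1))
  expect_lte(mean(null_sig), 0.05)

  # power: true delta 4 h at cv 0.1, 3 replicates, 30-min sampling
  young_p <- waveform_params(12, 9, 15, sharpness = solve_sharpness(7),
                             amplitude = 3, baseline = 1)
  old_p <- waveform_params(12, 9, 15, sharpness = solve_sharpness(11),
                           amplitude = 3, baseline = 1)
  power <- vapply(1:10, function(s) {
    ch <- fwhm_change_test(tt, replicate_matrix(young_p, tt, cv = 0.1, seed = s),
                           replicate_matrix(old_p, tt, cv = 0.1, seed = 500 + s),
                           n = 1000, n_null = 99, seed = s, sog_threshold = NULL)
    ch$significant
  }, logical(1))
  expect_gte(mean(power), 0.8)
})

test_that("SOG sets partition exactly and recover a constructed overlap", {
  mk <- function(genes, sog) data.frame(gene = genes, is_sog = sog)
  g <- paste0("g", 1:10)
  both <- classify_sog_sets(mk(g, rep(TRUE, 10)), mk(g, rep(TRUE, 10)))
  expect_identical(both$common, g)
  expect_length(both$young_only, 0)
  disj <- classify_sog_sets(mk(g, c(rep(TRUE, 5), rep(FALSE, 5))),
                            mk(g, c(rep(FALSE, 5), rep(TRUE, 5))))
  expect_length(disj$common, 0)
  expect_identical(disj$young_only, g[1:5])
  expect_identical(disj$old_only, g[6:10])
  expect_error(classify_sog_sets(mk(g, rep(TRUE, 10)), mk(paste0("x", 1:10), rep(TRUE, 10))),
               "universe")

  # constructed run: 5 genes unimodal at both ages, 4 young-only, 3 old-only
  tt <- seq(0, 23.5, by = 0.5)
  uni <- function(peak) eval_waveform(waveform_params(peak, 9, 15, sharpness = 2,
                                                      amplitude = 3, baseline = 1), tt)
  bim <- eval_waveform(waveform_params(4, 2, 22, sharpness = 8), tt) +
    eval_waveform(waveform_params(16, 2, 22, sharpness = 8), tt)
  build <- function(curves) {
    v <- do.call(rbind, curves)
    m <- cbind(v, v, v)                         # 3 identical replicates
    rownames(m) <- paste0("g", seq_along(curves))
    zt_matrix(m, zt = rep(tt, 3), replicate = rep(1:3, each = length(tt)))
  }
  young_curves <- c(lapply(c(2, 6, 10, 14, 18), uni), lapply(c(3, 7, 11, 15), uni),
                    rep(list(bim), 3))
  old_curves <- c(lapply(c(2, 6, 10, 14, 18), uni), rep(list(bim), 4),
                  lapply(c(5, 9, 13), uni))
  sets <- classify_sog_sets(sog_scan(build(young_curves), n = 100, seed = 1),
                            sog_scan(build(old_curves), n = 100, seed = 1))
  expect_length(sets$common, 5)
  expect_length(sets$young_only, 4)
  expect_length(sets$old_only, 3)
  # conservation: |common| + |young_only| = |SOG young|
  expect_identical(length(sets$common) + length(sets$young_only), 9L)
})
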