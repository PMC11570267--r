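# ridge regression via SVD: features standardized on the training set,
# intercept unpenalized; works for p >> n (dual form through the SVD)
ridge_solve <- function(X, y, penalty) {
  ctr <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, sdv, "/")
  sv <- svd(Xs)
  keep <- sv$d > max(sv$d) * 1e-12
  d <- sv$d[keep]
  beta <- sv$v[, keep, drop = FALSE] %*%
    ((d / (d^2 + penalty)) * crossprod(sv$u[, keep, drop = FALSE], y - mean(y)))
  list(beta = drop(beta), center = ctr, scale = sdv, intercept = mean(y))
}

ridge_predict <- function(fit, X) {
  Xs <- sweep(sweep(X, 2, fit$center), 2, fit$scale, "/")
  drop(Xs %*% fit$beta) + fit$intercept
}

#' Fit the circular physiological-time model
#'
#' Two ridge-penalized linear predictors map a per-sample expression
#' profile to the 24-h circle: one predicts `cos(2*pi*t/24)` and the other
#' `sin(2*pi*t/24)` of the sampling time `t`. A profile's physiological
#' time is the angle of the two outputs ([predict_time()]). Features are
#' centered and scaled on the training samples; the intercepts are not
#' penalized.
#'
#' @param x A [zt_matrix] with known sampling times (the reference age).
#' @param penalty Ridge penalty (default 1, the common library default).
#' @param features Gene ids used as predictors (default all genes of `x`;
#'   typically the common-SOG set).
#' @return An object of class `time_model`.
#' @export
fit_time_model <- function(x, penalty = 1, features = NULL) {
  stopifnot(inherits(x, "zt_matrix"))
  if (length(unique(x$samples$zt)) < 3L) stop("need at least 3 distinct time points")
  if (is.null(features)) features <- rownames(x$values)
  missing <- setdiff(features, rownames(x$values))
  if (length(missing)) {
    stop("features missing from the matrix: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  if (penalty < 0) stop("penalty must be >= 0")
  X <- t(x$values[features, , drop = FALSE])
  ang <- 2 * pi * x$samples$zt / 24
  structure(
    list(features = features,
         fit_cos = ridge_solve(X, cos(ang), penalty),
         fit_sin = ridge_solve(X, sin(ang), penalty),
         penalty = penalty, period = 24,
         reference_label = unique(x$samples$age)[1]),
    class = "time_model"
  )
}

#' @export
print.time_model <- function(x, ...) {
  cat(sprintf("<time_model> %d features | penalty %g | reference '%s'\n",
              length(x$features), x$penalty, x$reference_label))
  invisible(x)
}

#' Predict physiological time for expression profiles
#'
#' Runs the two ridge predictors and maps their outputs `(o1, o2)` to the
#' circle: `predicted_time = (24 / 2*pi) * atan2(o2, o1) mod 24`. The norm
#' `sqrt(o1^2 + o2^2)` is reported as a confidence proxy (profiles unlike
#' any training time map near the origin).
#'
#' @param model A [fit_time_model()] result.
#' @param profile Named numeric vector (one profile) or a genes x samples
#'   matrix / [zt_matrix]; all model features must be present (no
#'   imputation).
#' @return Data frame with one row per profile: `o1`, `o2`, `norm`,
#'   `predicted_time` (hours in `[0, 24)`).
#' @export
predict_time <- function(model, profile) {
  stopifnot(inherits(model, "time_model"))
  if (inherits(profile, "zt_matrix")) profile <- profile$values
  if (is.null(dim(profile))) profile <- matrix(profile, ncol = 1, dimnames = list(names(profile), "profile"))
  missing <- setdiff(model$features, rownames(profile))
  if (length(missing)) {
    stop("profile lacks model features: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  X <- t(profile[model$features, , drop = FALSE])
  o1 <- ridge_predict(model$fit_cos, X)
  o2 <- ridge_predict(model$fit_sin, X)
  data.frame(
    sample = colnames(profile),
    o1 = unname(o1), o2 = unname(o2),
    norm = unname(sqrt(o1^2 + o2^2)),
    predicted_time = unname((atan2(o2, o1) * model$period / (2 * pi)) %% model$period),
    stringsAsFactors = FALSE
  )
}

#' Circular error between two daily times
#'
#' Shortest distance on the 24-h circle: `min(|d|, 24 - |d|)` with
#' `d = t_pred - t_true`; range `[0, 12]`.
#'
#' @param t_pred,t_true Times in hours.
#' @param period Circle length (default 24).
#' @return Hours.
#' @examples
#' circular_error(23, 1) # 2
#' @export
circular_error <- function(t_pred, t_true, period = 24) {
  d <- abs(t_pred - t_true) %% period
  pmin(d, period - d)
}

#' Leave-one-time-point-out cross-validation of the time model
#'
#' For each distinct sampling time, refits the model excluding all samples
#' collected at that time, predicts the held-out samples, and reports their
#' circular errors. This is the validation that the predicted time of an
#' unseen time point stays within a couple of hours of the true sampling
#' time.
#'
#' @inheritParams fit_time_model
#' @return Data frame with one row per held-out sample: `zt`, `sample`,
#'   `predicted_time`, `error` (hours); summary attributes `max_error` and
#'   `mean_error`.
#' @export
loocv_by_timepoint <- function(x, penalty = 1, features = NULL) {
  stopifnot(inherits(x, "zt_matrix"))
  zts <- sort(unique(x$samples$zt))
  if (length(zts) < 3L) stop("need at least 3 distinct time points")
  out <- lapply(zts, function(z) {
    tr <- x$samples$zt != z
    xtr <- zt_matrix(x$values[, tr, drop = FALSE], x$samples$zt[tr],
                     x$samples$replicate[tr], x$samples$age[tr])
    m <- fit_time_model(xtr, penalty = penalty, features = features)
    pred <- predict_time(m, x$values[, !tr, drop = FALSE])
    data.frame(zt = z, sample = x$samples$sample[!tr],
               predicted_time = pred$predicted_time,
               error = circular_error(pred$predicted_time, z),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "max_error") <- max(res$error)
  attr(res, "mean_error") <- mean(res$error)
  res
}

#' Subjective-time curve of a query age in the reference frame
#'
#' Predicts, for every sampling time of a query matrix, the physiological
#' (reference-frame) time of its samples, aggregating replicates by the
#' circular mean. `span` gives the reference-frame hours elapsed between
#' consecutive query time points (wrapping around the cycle); over a full
#' cycle the spans sum to 24.
#'
#' @param model A [fit_time_model()] result, trained on the reference age.
#' @param query A [zt_matrix] of the query age.
#' @return Data frame with one row per query ZT: `zt`, `mapped_time`
#'   (hours in the reference frame), `span` (hours to the next query ZT on
#'   the circle), of class `subjective_time_curve`.
#' @export
subjective_time_curve <- function(model, query) {
  stopifnot(inherits(query, "zt_matrix"))
  pred <- predict_time(model, query)
  pred$zt <- query$samples$zt
  zts <- sort(unique(pred$zt))
  mapped <- vapply(zts, function(z) {
    circ_mean(pred$predicted_time[pred$zt == z], model$period)
  }, numeric(1))
  nxt <- c(mapped[-1], mapped[1])
  span <- (nxt - mapped) %% model$period
  out <- data.frame(zt = zts, mapped_time = mapped, span = span)
  class(out) <- c("subjective_time_curve", "data.frame")
  attr(out, "period") <- model$period
  out
}

#' Circular distance of a subjective-time curve from a reference time
#'
#' For each query ZT, the circular distance between the mapped
#' reference-frame time and a fixed reference time of day — e.g. how far
#' each sample of an aged plant is from the young "noon" transcriptome.
#' Mid-light under LD 16:8 is ZT8, the default reference.
#'
#' @param curve A [subjective_time_curve()] result.
#' @param reference_time Hours (default 8 = mid-light under LD 16:8).
#' @return Numeric vector of distances (hours, in `[0, 12]`), one per
#'   query ZT.
#' @export
distance_from_reference_time <- function(curve, reference_time = 8) {
  stopifnot(inherits(curve, "subjective_time_curve"))
  period <- attr(curve, "period")
  circular_error(curve$mapped_time, reference_time, period)
}
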