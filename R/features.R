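#' Least-squares polynomial fit on normalized time
#'
#' Fits a polynomial of order exactly `order` (default 7) to envelope values
#' over one breathing cycle. Time is mapped affinely to `[-1, 1]` before
#' fitting; order-7 fits on absolute seconds are numerically ill-conditioned,
#' on the normalized axis the Vandermonde system is benign at the envelope
#' lengths used here.
#'
#' @param t Time stamps in seconds (strictly increasing span).
#' @param y Envelope values (finite).
#' @param order Polynomial order (default 7, i.e. 8 coefficients).
#' @return A `cycle_polyfit`: `coefficients` (length `order + 1`, ascending
#'   powers of normalized time u), `time_span` `(start_s, end_s)`, and
#'   `rms_residual`.
#' @export
polyfit_envelope <- function(t, y, order = 7L) {
  if (length(t) != length(y)) stop("t and y lengths differ", call. = FALSE)
  if (length(y) < 2L * (order + 1L)) {
    stop(sprintf("need at least %d points for an order-%d fit, got %d",
                 2L * (order + 1L), order, length(y)), call. = FALSE)
  }
  if (anyNA(y) || any(!is.finite(y)) || any(!is.finite(t))) {
    stop("non-finite values in envelope window", call. = FALSE)
  }
  t0 <- min(t); t1 <- max(t)
  if (t1 <= t0) stop("time span must have positive length", call. = FALSE)
  u <- 2 * (t - t0) / (t1 - t0) - 1
  X <- outer(u, 0:order, `^`)
  fit <- stats::lm.fit(X, y)
  coefs <- unname(fit$coefficients)
  coefs[is.na(coefs)] <- 0
  structure(list(
    coefficients = coefs,
    time_span = c(t0, t1),
    rms_residual = sqrt(mean(fit$residuals^2))
  ), class = "cycle_polyfit")
}

#' Fit one breathing cycle of an envelope
#'
#' Selects the envelope points whose windows fall inside the cycle (trimmed
#' by half a variance window at each end) and fits [polyfit_envelope()].
#'
#' @param envelope An `envelope_series` from [moving_variance()]; must carry
#'   `sampling_rate_hz`.
#' @param cycle_window Length-2 integer vector `(start, end)`: the cycle's
#'   sample range in the original signal.
#' @inheritParams polyfit_envelope
#' @return A `cycle_polyfit`.
#' @export
fit_cycle_polynomial <- function(envelope, cycle_window, order = 7L) {
  if (!inherits(envelope, "envelope_series")) {
    stop("`envelope` must be an envelope_series", call. = FALSE)
  }
  idx <- envelope_indices_for_cycle(envelope, cycle_window[1], cycle_window[2])
  tt <- envelope_times(envelope)[idx]
  polyfit_envelope(tt, envelope$values[idx], order = order)
}

# Evaluate the fitted polynomial at normalized times u in [-1, 1].
eval_polyfit_u <- function(fit, u) {
  coefs <- fit$coefficients
  out <- numeric(length(u))
  for (k in rev(seq_along(coefs))) out <- out * u + coefs[k]
  out
}

#' Evaluate a cycle fit at times in seconds
#' @param fit A `cycle_polyfit`.
#' @param t Times in seconds inside the fitted span.
#' @return Fitted values.
#' @export
eval_polyfit <- function(fit, t) {
  span <- fit$time_span
  eval_polyfit_u(fit, 2 * (t - span[1]) / (span[2] - span[1]) - 1)
}

# Real roots of the fitted polynomial inside the open normalized interval.
poly_real_roots_u <- function(coefs, lo = -1, hi = 1) {
  nz <- which(abs(coefs) > 0)
  if (length(nz) <= 1L) return(numeric(0))  # constant: no sign change inside
  r <- polyroot(coefs)
  re <- Re(r[abs(Im(r)) < 1e-8])
  sort(unique(re[re > lo & re < hi]))
}

# Integral of the (unclipped) polynomial over [a, b] in normalized u.
poly_integral_u <- function(coefs, a, b) {
  anti <- coefs / seq_along(coefs)  # coefficient of u^k -> u^(k+1)/(k+1)
  horner <- function(u) {
    out <- 0
    for (k in rev(seq_along(anti))) out <- out * u + anti[k]
    out * u
  }
  horner(b) - horner(a)
}

# Integral over [lo, hi] (normalized u) of max(p(u), 0): split at real roots,
# integrate analytically on segments where the midpoint is positive.
clipped_integral_u <- function(coefs, lo, hi) {
  if (hi <= lo) return(0)
  cuts <- c(lo, poly_real_roots_u(coefs, lo, hi), hi)
  total <- 0
  for (s in seq_len(length(cuts) - 1L)) {
    a <- cuts[s]; b <- cuts[s + 1L]
    mid <- (a + b) / 2
    val <- 0
    for (k in rev(seq_along(coefs))) val <- val * mid + coefs[k]
    if (val > 0) total <- total + poly_integral_u(coefs, a, b)
  }
  max(total, 0)
}

#' Area under a fitted cycle envelope
#'
#' Analytic integral of the fitted polynomial over the cycle span, with
#' negative excursions clipped to zero before integration (a variance
#' envelope is nonnegative; an order-7 fit can undershoot). Units:
#' envelope-units x seconds.
#'
#' @param fit A `cycle_polyfit`.
#' @return Nonnegative AUC.
#' @export
compute_auc <- function(fit) {
  if (!inherits(fit, "cycle_polyfit")) {
    stop("`fit` must be a cycle_polyfit", call. = FALSE)
  }
  jac <- (fit$time_span[2] - fit$time_span[1]) / 2
  jac * clipped_integral_u(fit$coefficients, -1, 1)
}

#' Cumulative AUC over a cycle and its derivative
#'
#' `cumulative_auc_series()` evaluates the running clipped integral of the
#' fitted polynomial at `n_points` evenly spaced times over the cycle span;
#' the series is nondecreasing and its last value equals [compute_auc()].
#' `derivative_of_cumulative()` returns the successive differences (the
#' first element is the first cumulative value), which sum back to the final
#' cumulative value exactly; these increments are the within-cycle
#' lung-volume proxy used downstream for signature matrices.
#'
#' @param fit A `cycle_polyfit`.
#' @param n_points Number of evaluation points (>= 2).
#' @return `cumulative_auc_series()`: list with `time_s` and nondecreasing
#'   `values`. `derivative_of_cumulative()`: numeric vector of increments.
#' @export
cumulative_auc_series <- function(fit, n_points = 40L) {
  if (!is.numeric(n_points) || n_points < 2L) {
    stop("`n_points` must be >= 2", call. = FALSE)
  }
  coefs <- fit$coefficients
  jac <- (fit$time_span[2] - fit$time_span[1]) / 2
  u <- seq(-1, 1, length.out = n_points)
  vals <- numeric(n_points)
  acc <- 0
  for (j in seq_len(n_points)) {
    if (j > 1L) acc <- acc + clipped_integral_u(coefs, u[j - 1L], u[j])
    vals[j] <- jac * acc
  }
  list(
    time_s = fit$time_span[1] + (u + 1) / 2 * diff(fit$time_span),
    values = vals
  )
}

#' @rdname cumulative_auc_series
#' @param series Result of `cumulative_auc_series()` (or its `values`).
#' @export
derivative_of_cumulative <- function(series) {
  v <- if (is.list(series)) series$values else series
  if (length(v) < 2L) stop("need at least 2 points", call. = FALSE)
  c(v[1], diff(v))
}

#' Trapezoid AUC of the raw envelope over a cycle
#'
#' Alternative to the fitted-polynomial AUC: trapezoidal integration of the
#' raw envelope values across the (trimmed) cycle window, without any fit.
#'
#' @inheritParams fit_cycle_polynomial
#' @return Nonnegative AUC in envelope-units x seconds.
#' @export
envelope_auc <- function(envelope, cycle_window) {
  if (!inherits(envelope, "envelope_series")) {
    stop("`envelope` must be an envelope_series", call. = FALSE)
  }
  idx <- envelope_indices_for_cycle(envelope, cycle_window[1], cycle_window[2])
  if (length(idx) < 2L) stop("cycle window holds fewer than 2 envelope points",
                             call. = FALSE)
  tt <- envelope_times(envelope)[idx]
  y <- envelope$values[idx]
  sum((y[-1] + y[-length(y)]) / 2 * diff(tt))
}

#' Per-cycle AUC features for one channel of a recording
#'
#' Runs the full envelope chain for one channel: band filter (default
#' `sound_high` for sound, `ecg_low` for ECG), moving variance, per-cycle
#' order-7 polynomial fit, clipped AUC.
#'
#' @param recording A `multimodal_recording`.
#' @param channel `"sound"` or `"ecg"`.
#' @param band A [filter_spec()]; `NULL` picks the channel's default preset.
#' @param window_samples,hop_samples Moving-variance geometry (defaults:
#'   1000-sample window = 250 ms at 4 kHz, dense hop of 1).
#' @param order Polynomial order.
#' @return A `cycle_features` data.frame with columns `cycle_index`,
#'   `channel`, `auc`, `cum_auc_final`, `is_cough`, `tidal_volume_ml`, and
#'   the per-cycle fits in `attr(, "fits")`.
#' @export
extract_cycle_features <- function(recording, channel = c("sound", "ecg"),
                                   band = NULL, window_samples = 1000L,
                                   hop_samples = 1L, order = 7L) {
  channel <- match.arg(channel)
  validate_recording(recording)
  if (is.null(band)) {
    band <- band_preset(if (channel == "sound") "sound_high" else "ecg_low")
  }
  x <- recording[[channel]]
  filtered <- apply_filter(x, band, recording$sampling_rate_hz)
  env <- moving_variance(filtered, window_samples, hop_samples,
                         sampling_rate_hz = recording$sampling_rate_hz,
                         source_band = band)
  ann <- recording$annotations
  fits <- vector("list", nrow(ann))
  auc <- numeric(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    fits[[i]] <- fit_cycle_polynomial(env, c(ann$start[i], ann$end[i]),
                                      order = order)
    auc[i] <- compute_auc(fits[[i]])
  }
  out <- data.frame(
    cycle_index = ann$cycle,
    channel = channel,
    auc = auc,
    cum_auc_final = auc,
    is_cough = ann$is_cough,
    tidal_volume_ml = ann$tidal_volume_ml
  )
  attr(out, "fits") <- fits
  class(out) <- c("cycle_features", "data.frame")
  out
}

#' Write / read a per-cycle features table
#'
#' CSV with columns `cycle_index,channel,auc,cum_auc_final,is_cough,
#' tidal_volume_ml` (one row per cycle and channel).
#'
#' @param features A data.frame of cycle features (possibly several channels
#'   row-bound together).
#' @param path CSV path.
#' @export
write_features <- function(features, path) {
  cols <- c("cycle_index", "channel", "auc", "cum_auc_final", "is_cough",
            "tidal_volume_ml")
  stopifnot(all(cols %in% names(features)))
  utils::write.csv(as.data.frame(features)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("features file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("cycle_index", "channel", "auc", "cum_auc_final", "is_cough",
            "tidal_volume_ml")
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("features CSV %s is missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df$is_cough <- as.logical(df$is_cough)
  df
}
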