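#' Moving-variance energy envelope
#'
#' Slides a window of `window_samples` samples over the signal in steps of
#' `hop_samples` and returns the population variance (divide by n) of each
#' window. At a 4 kHz sampling rate the default 1000-sample window spans
#' 250 ms. Element `k` of the result covers the window starting at sample
#' `(k - 1) * hop_samples + 1`.
#'
#' The computation runs in O(n) via cumulative sums after centring the
#' signal on its overall mean (which leaves every windowed variance
#' unchanged but keeps the running sums well conditioned).
#'
#' @param x Numeric signal.
#' @param window_samples Window length in samples (> 1).
#' @param hop_samples Step between successive windows (default 1: dense
#'   envelope aligned to the sample grid).
#' @param sampling_rate_hz Optional sampling rate carried along so envelope
#'   elements can be mapped back to seconds.
#' @param source_band Optional [filter_spec()] recording which band the
#'   signal came from; informational.
#' @return An `envelope_series`: list with `values` (nonnegative), and the
#'   window geometry.
#' @export
moving_variance <- function(x, window_samples, hop_samples = 1L,
                            sampling_rate_hz = NULL, source_band = NULL) {
  n <- length(x)
  if (!is.numeric(window_samples) || window_samples != round(window_samples) ||
      window_samples <= 1L) {
    stop("`window_samples` must be an integer > 1", call. = FALSE)
  }
  if (window_samples > n) {
    stop(sprintf("window (%d) exceeds signal length (%d)",
                 as.integer(window_samples), n), call. = FALSE)
  }
  if (!is.numeric(hop_samples) || hop_samples != round(hop_samples) ||
      hop_samples < 1L) {
    stop("`hop_samples` must be a positive integer", call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop("signal contains non-finite values", call. = FALSE)
  }
  w <- as.integer(window_samples)
  h <- as.integer(hop_samples)
  xc <- x - mean(x)
  cs <- c(0, cumsum(xc))
  cs2 <- c(0, cumsum(xc * xc))
  starts <- seq.int(1L, n - w + 1L, by = h)
  s1 <- cs[starts + w] - cs[starts]
  s2 <- cs2[starts + w] - cs2[starts]
  v <- s2 / w - (s1 / w)^2
  v[v < 0] <- 0  # guard against roundoff
  structure(list(
    values = v,
    window_samples = w,
    hop_samples = h,
    sampling_rate_hz = sampling_rate_hz,
    source_band = source_band
  ), class = "envelope_series")
}

#' @export
print.envelope_series <- function(x, ...) {
  cat(sprintf("<envelope_series> %d values, window %d samples, hop %d\n",
              length(x$values), x$window_samples, x$hop_samples))
  invisible(x)
}

# Centre time (seconds) of each envelope window; index-based if no rate.
envelope_times <- function(env) {
  fs <- if (is.null(env$sampling_rate_hz)) 1 else env$sampling_rate_hz
  starts <- (seq_along(env$values) - 1L) * env$hop_samples + 1L
  (starts + (env$window_samples - 1) / 2 - 1) / fs
}

# Envelope indices whose window centre lies inside the cycle trimmed by half
# a window at each end (avoids filter/variance edge artifacts in fits).
envelope_indices_for_cycle <- function(env, start_sample, end_sample) {
  centers <- (seq_along(env$values) - 1L) * env$hop_samples + 1L +
    (env$window_samples - 1) / 2
  lo <- start_sample + env$window_samples / 2
  hi <- end_sample - env$window_samples / 2
  which(centers >= lo & centers <= hi)
}
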