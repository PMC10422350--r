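#' Configuration for a synthetic cardiorespiratory recording
#'
#' Describes a metronome-paced breathing session recorded by a chest-mounted
#' two-channel sensor (lung sound + ECG), both sampled at the same rate.
#' Defaults follow a slow constant-rate protocol: 4 s breathing cycles
#' (2 s inhale, 2 s exhale) at 4 kHz, tidal volumes controlled per cycle.
#'
#' @param n_cycles Number of breathing cycles to simulate.
#' @param tidal_volume_ml Tidal volume per cycle in mL; a scalar or a vector
#'   recycled to `n_cycles`. Protocol levels are 1000 (deep), 750 (moderate)
#'   and 500 (shallow breathing).
#' @param cough_cycles Integer indices (1-based) of cycles simulated as
#'   coughing episodes: a short high-amplitude broadband burst plus a deep
#'   inhalation low-frequency excursion.
#' @param sampling_rate_hz Sampling rate per channel (Hz).
#' @param cycle_duration_s Breathing cycle length in seconds; the first half
#'   is the inhale phase, the second half the exhale phase.
#' @param heart_rate_bpm Heart rate in beats per minute.
#' @param rsa_modulation_depth Fraction in `[0, 1)`: ECG beats whose R peak
#'   falls in the inhale half are scaled by `1 - rsa_modulation_depth`
#'   (respiratory sinus arrhythmia: beat heights decrease during inhalation).
#' @param sound_burst_gain Monotone function mapping tidal volume (mL) to the
#'   amplitude of the high-frequency inhalation sound burst (arbitrary
#'   ADC-like units). Default: linear, `tv / 1000`.
#' @param cough_gain Amplitude of the cough transient, in the same units;
#'   must exceed the largest breathing burst amplitude.
#' @param noise_sd Standard deviation of additive white Gaussian noise per
#'   channel (0 disables).
#' @param seed Integer seed; recordings are a deterministic function of the
#'   configuration including the seed.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_recording()]
#' @export
sim_config <- function(n_cycles,
                       tidal_volume_ml = 1000,
                       cough_cycles = integer(0),
                       sampling_rate_hz = 4000,
                       cycle_duration_s = 4,
                       heart_rate_bpm = 75,
                       rsa_modulation_depth = 0.30,
                       sound_burst_gain = function(tv) tv / 1000,
                       cough_gain = 2.5,
                       noise_sd = 0,
                       seed = 1L) {
  stopifnot(is.function(sound_burst_gain))
  if (!is.numeric(n_cycles) || length(n_cycles) != 1L || n_cycles < 1 ||
      n_cycles != round(n_cycles)) {
    stop("`n_cycles` must be a positive integer", call. = FALSE)
  }
  for (nm in c("sampling_rate_hz", "cycle_duration_s", "heart_rate_bpm",
               "cough_gain")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("`%s` must be a positive number", nm), call. = FALSE)
    }
  }
  if (any(!is.finite(tidal_volume_ml)) || any(tidal_volume_ml <= 0)) {
    stop("`tidal_volume_ml` must be positive", call. = FALSE)
  }
  if (!is.numeric(rsa_modulation_depth) || rsa_modulation_depth < 0 ||
      rsa_modulation_depth >= 1) {
    stop("`rsa_modulation_depth` must be in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be nonnegative", call. = FALSE)
  }
  cycle_samples <- cycle_duration_s * sampling_rate_hz
  if (abs(cycle_samples - round(cycle_samples)) > 1e-9) {
    stop("`cycle_duration_s` x `sampling_rate_hz` must be an integer number of samples",
         call. = FALSE)
  }
  cough_cycles <- as.integer(cough_cycles)
  if (length(cough_cycles) &&
      (any(cough_cycles < 1L) || any(cough_cycles > n_cycles))) {
    stop("`cough_cycles` indices must lie in 1..n_cycles", call. = FALSE)
  }
  tv <- rep_len(as.numeric(tidal_volume_ml), n_cycles)
  structure(list(
    n_cycles = as.integer(n_cycles),
    tidal_volume_ml = tv,
    cough_cycles = cough_cycles,
    sampling_rate_hz = sampling_rate_hz,
    cycle_duration_s = cycle_duration_s,
    heart_rate_bpm = heart_rate_bpm,
    rsa_modulation_depth = rsa_modulation_depth,
    sound_burst_gain = sound_burst_gain,
    cough_gain = cough_gain,
    noise_sd = noise_sd,
    seed = as.integer(seed),
    cycle_samples = as.integer(round(cycle_samples))
  ), class = "sim_config")
}

# One PQRST complex as a sum of Gaussian bumps, evaluated at times `t`
# (seconds) relative to the R peak. Amplitudes in R-peak units.
pqrst_beat <- function(t) {
  g <- function(amp, mu, sig) amp * exp(-((t - mu)^2) / (2 * sig^2))
  g(0.15, -0.20, 0.025) +   # P
    g(-0.10, -0.025, 0.008) + # Q
    g(1.00, 0.00, 0.010) +  # R
    g(-0.15, 0.025, 0.008) + # S
    g(0.30, 0.18, 0.040)    # T
}

# Smooth gate: 1 on [on, off], raised-cosine ramps of length `ramp` outside.
smooth_gate <- function(t, on, off, ramp) {
  up <- pmin(pmax((t - on) / ramp, 0), 1)
  down <- pmin(pmax((off - t) / ramp, 0), 1)
  (0.5 - 0.5 * cos(pi * up)) * (0.5 - 0.5 * cos(pi * down))
}

#' Simulate a synchronized lung-sound + ECG recording
#'
#' Generates a two-channel recording with the features the analysis pipeline
#' measures:
#' * **Sound channel** — band-limited (150–1000 Hz) noise bursts gated over
#'   the inhale half of each cycle, with amplitude `sound_burst_gain(tidal
#'   volume)`, plus a low-frequency (< 2 Hz) chest-motion component scaled by
#'   tidal volume. Cough cycles add a short (~0.5 s) broadband transient of
#'   amplitude `cough_gain` and a deeper low-frequency excursion.
#' * **ECG channel** — a periodic PQRST complex (Gaussian-bump composition)
#'   at `heart_rate_bpm`; beats whose R peak falls in the inhale half are
#'   attenuated by `1 - rsa_modulation_depth`.
#'
#' Both channels receive independent additive white Gaussian noise of
#' standard deviation `noise_sd`. The result is a deterministic function of
#' the configuration (including its seed).
#'
#' @param config A [sim_config()] object.
#' @return A `multimodal_recording`: list with `sampling_rate_hz`, numeric
#'   vectors `sound` and `ecg` (equal length), and `annotations`, a
#'   data.frame with one row per cycle (`cycle`, `start`, `inhale_end`,
#'   `end` sample indices, `tidal_volume_ml`, `is_cough`). Annotations tile
#'   the recording exactly.
#' @examples
#' rec <- simulate_recording(sim_config(n_cycles = 3, seed = 7))
#' length(rec$sound) # 3 cycles x 4 s x 4000 Hz = 48000
#' @export
simulate_recording <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("`config` must be a sim_config object", call. = FALSE)
  }
  fs <- config$sampling_rate_hz
  ns_cycle <- config$cycle_samples
  n <- ns_cycle * config$n_cycles
  inhale_s <- config$cycle_duration_s / 2

  withr::with_seed(config$seed, {
    t_all <- (seq_len(n) - 1) / fs
    t_cyc <- t_all %% config$cycle_duration_s
    cyc_of <- floor(t_all / config$cycle_duration_s) + 1

    # High-frequency carrier: band-limited noise, normalized per cycle over
    # the inhale burst support so the realized burst energy of every cycle
    # is exactly sound_burst_gain(tidal_volume)^2 (the generator's contract
    # ties energy to tidal volume deterministically, not just in
    # expectation).
    bp <- signal::butter(4, c(150, 1000) / (fs / 2), type = "pass")
    carrier <- signal::filtfilt(bp, stats::rnorm(n))
    gate <- smooth_gate(t_cyc, 0.1, inhale_s - 0.1, 0.15)
    for (ci in seq_len(config$n_cycles)) {
      idx <- ((ci - 1L) * ns_cycle + 1L):(ci * ns_cycle)
      support <- idx[gate[idx] > 0.5]
      carrier[idx] <- carrier[idx] / stats::sd(carrier[support])
    }

    amp <- config$sound_burst_gain(config$tidal_volume_ml)[cyc_of]
    sound <- amp * gate * carrier

    # Low-frequency chest-motion component (< 2 Hz), one period per cycle.
    lf_amp <- 0.5 * config$tidal_volume_ml[cyc_of] / 1000
    sound <- sound + lf_amp * sin(2 * pi * t_cyc / config$cycle_duration_s)

    if (length(config$cough_cycles)) {
      cough_carrier <- signal::filtfilt(bp, stats::rnorm(n))
      in_cough <- cyc_of %in% config$cough_cycles
      cough_gate <- smooth_gate(t_cyc, 0.4, 0.9, 0.08) * in_cough
      for (ci in config$cough_cycles) {
        idx <- ((ci - 1L) * ns_cycle + 1L):(ci * ns_cycle)
        support <- idx[cough_gate[idx] > 0.5]
        cough_carrier[idx] <- cough_carrier[idx] / stats::sd(cough_carrier[support])
      }
      sound <- sound + config$cough_gain * cough_gate * cough_carrier
      # deep-inhalation excursion on the low-frequency band
      sound <- sound + in_cough * 0.8 *
        sin(2 * pi * t_cyc / config$cycle_duration_s)
    }

    # ECG: beats laid out over the whole recording, each scaled by the
    # respiration phase of its R peak.
    period <- 60 / config$heart_rate_bpm
    r_times <- seq(0.3, n / fs, by = period)
    r_times <- r_times[r_times < n / fs - 0.01]
    ecg <- numeric(n)
    half_w <- 0.35  # seconds of beat support on each side of the R peak
    for (rt in r_times) {
      phase <- rt %% config$cycle_duration_s
      scale <- if (phase < inhale_s) 1 - config$rsa_modulation_depth else 1
      i0 <- max(1L, floor((rt - half_w) * fs) + 1L)
      i1 <- min(n, ceiling((rt + half_w) * fs))
      idx <- i0:i1
      ecg[idx] <- ecg[idx] + scale * pqrst_beat(t_all[idx] - rt)
    }

    if (config$noise_sd > 0) {
      sound <- sound + stats::rnorm(n, 0, config$noise_sd)
      ecg <- ecg + stats::rnorm(n, 0, config$noise_sd)
    }

    ann <- data.frame(
      cycle = seq_len(config$n_cycles),
      start = (seq_len(config$n_cycles) - 1L) * ns_cycle + 1L,
      inhale_end = (seq_len(config$n_cycles) - 1L) * ns_cycle +
        as.integer(round(inhale_s * fs)),
      end = seq_len(config$n_cycles) * ns_cycle,
      tidal_volume_ml = config$tidal_volume_ml,
      is_cough = seq_len(config$n_cycles) %in% config$cough_cycles
    )

    structure(list(
      sampling_rate_hz = fs,
      sound = sound,
      ecg = ecg,
      annotations = ann
    ), class = "multimodal_recording")
  })
}

#' @export
print.multimodal_recording <- function(x, ...) {
  n <- length(x$sound)
  cat(sprintf(
    "<multimodal_recording> %d samples/channel @ %g Hz (%.1f s), %d cycles (%d cough)\n",
    n, x$sampling_rate_hz, n / x$sampling_rate_hz,
    nrow(x$annotations), sum(x$annotations$is_cough)
  ))
  invisible(x)
}

# Internal validity check used by readers and the pipeline.
validate_recording <- function(rec) {
  if (length(rec$sound) != length(rec$ecg)) {
    stop("sound and ecg channels differ in length", call. = FALSE)
  }
  ann <- rec$annotations
  n <- length(rec$sound)
  if (nrow(ann)) {
    if (ann$start[1] != 1L || ann$end[nrow(ann)] != n ||
        any(ann$end < ann$start) ||
        (nrow(ann) > 1 && any(ann$start[-1] != ann$end[-nrow(ann)] + 1L))) {
      stop("annotations must tile the recording without gaps or overlap",
           call. = FALSE)
    }
    if (any(ann$inhale_end < ann$start) || any(ann$inhale_end > ann$end)) {
      stop("inhale_end indices out of cycle bounds", call. = FALSE)
    }
  }
  invisible(rec)
}
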