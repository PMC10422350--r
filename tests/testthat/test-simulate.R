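test_that("recording length, determinism and annotation tiling hold", {
  cfg <- sim_config(n_cycles = 3, seed = 42)
  rec <- simulate_recording(cfg)
  expect_identical(length(rec$sound), 3L * 4L * 4000L)
  expect_identical(length(rec$ecg), length(rec$sound))

  rec2 <- simulate_recording(sim_config(n_cycles = 3, seed = 42))
  expect_identical(rec$sound, rec2$sound)
  expect_identical(rec$ecg, rec2$ecg)
  expect_identical(rec$annotations, rec2$annotations)

  ann <- rec$annotations
  covered <- unlist(Map(seq.int, ann$start, ann$end))
  expect_identical(covered, seq_along(rec$sound))
  expect_true(all(ann$inhale_end > ann$start & ann$inhale_end < ann$end))
})

test_that("different seeds give different recordings", {
  a <- simulate_recording(sim_config(n_cycles = 1, seed = 1))
  b <- simulate_recording(sim_config(n_cycles = 1, seed = 2))
  expect_false(identical(a$sound, b$sound))
})

test_that("high-frequency inhale sound energy increases with tidal volume", {
  make <- function(tv) simulate_recording(
    sim_config(n_cycles = 2, tidal_volume_ml = tv, noise_sd = 0, seed = 5))
  inhale_hf_var <- function(rec) {
    hf <- apply_filter(rec$sound, band_preset("sound_high"),
                       rec$sampling_rate_hz)
    ann <- rec$annotations
    mean(vapply(seq_len(nrow(ann)), function(i)
      stats::var(hf[ann$start[i]:ann$inhale_end[i]]), 0))
  }
  v <- vapply(c(500, 750, 1000), function(tv) inhale_hf_var(make(tv)), 0)
  expect_true(v[1] < v[2] && v[2] < v[3])
})

test_that("ECG beat heights drop during inhalation (RSA contract)", {
  rec <- simulate_recording(sim_config(n_cycles = 4, noise_sd = 0,
                                       rsa_modulation_depth = 0.3, seed = 3))
  ann <- rec$annotations
  for (i in seq_len(nrow(ann))) {
    inh <- max(rec$ecg[ann$start[i]:ann$inhale_end[i]])
    exh <- max(rec$ecg[(ann$inhale_end[i] + 1L):ann$end[i]])
    expect_lt(inh, exh)
  }
  # attenuation factor on the R peaks is 1 - depth
  expect_equal(max(rec$ecg[ann$start[1]:ann$inhale_end[1]]) /
                 max(rec$ecg[(ann$inhale_end[1] + 1L):ann$end[1]]),
               0.7, tolerance = 0.02)
})

test_that("cough cycles carry a transient louder than normal breathing", {
  rec <- simulate_recording(sim_config(n_cycles = 4, cough_cycles = 2L,
                                       noise_sd = 0, seed = 9))
  ann <- rec$annotations
  hf <- apply_filter(rec$sound, band_preset("sound_high"),
                     rec$sampling_rate_hz)
  peak <- vapply(seq_len(nrow(ann)), function(i)
    max(abs(hf[ann$start[i]:ann$end[i]])), 0)
  expect_true(all(peak[2] > peak[-2]))
  expect_identical(which(ann$is_cough), 2L)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_cycles = 0), "positive integer")
  expect_error(sim_config(n_cycles = 2, sampling_rate_hz = -1), "positive")
  expect_error(sim_config(n_cycles = 2, cough_cycles = 3), "1..n_cycles")
  expect_error(sim_config(n_cycles = 2, rsa_modulation_depth = 1), "\\[0, 1\\)")
  expect_error(sim_config(n_cycles = 2, cycle_duration_s = 1/3),
               "integer number of samples")
  expect_error(sim_config(n_cycles = 2, noise_sd = -0.1), "nonnegative")
})

test_that("recording CSV + sidecar round-trips exactly", {
  rec <- small_recording(n_cycles = 3, seed = 21)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, csv)
  rt <- read_recording(csv)
  expect_identical(rt$sound, rec$sound)
  expect_identical(rt$ecg, rec$ecg)
  expect_identical(rt$annotations, rec$annotations)
  expect_identical(rt$sampling_rate_hz, rec$sampling_rate_hz)
})

test_that("malformed recording files raise informative errors", {
  csv <- withr::local_tempfile(fileext = ".csv")

  writeLines(character(0), csv)
  expect_error(read_recording(csv), "empty")

  writeLines(c("time_s,sound", "0,1"), csv)
  expect_error(read_recording(csv), "ecg")

  writeLines(c("time_s,sound,ecg", "0,1,2", "0.1,oops,3"), csv)
  json <- sub("\\.csv$", ".json", csv)
  jsonlite::write_json(list(sampling_rate_hz = 10,
                            cycles = data.frame(start = 1, inhale_end = 1,
                                                end = 2, tidal_volume_ml = 500,
                                                is_cough = FALSE)),
                       json, auto_unbox = TRUE)
  expect_error(read_recording(csv), "line 3")

  writeLines(c("time_s,sound,ecg", "0,1,2", "0.1,3"), csv)
  expect_error(read_recording(csv), "line 3")
})
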