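test_that("an exactly representable order-7 envelope is recovered", {
  t <- seq(0, 4, length.out = 200)
  u <- 2 * (t - min(t)) / diff(range(t)) - 1
  coefs <- c(0.5, -0.2, 1.1, 0.3, -0.7, 0.05, 0.2, -0.1)
  y <- drop(outer(u, 0:7, `^`) %*% coefs)
  fit <- polyfit_envelope(t, y)
  expect_equal(fit$coefficients, coefs, tolerance = 1e-8)
  expect_lt(fit$rms_residual / max(abs(y)), 1e-8)
})

test_that("a constant envelope fits as a constant", {
  t <- seq(0, 4, length.out = 100)
  fit <- polyfit_envelope(t, rep(2.5, 100))
  expect_equal(fit$coefficients[1], 2.5, tolerance = 1e-10)
  expect_lt(max(abs(fit$coefficients[-1])), 1e-9)
})

test_that("order-7 residual never exceeds the order-6 residual", {
  set.seed(31)
  t <- seq(0, 4, length.out = 300)
  for (rep in 1:5) {
    y <- abs(stats::filter(rnorm(300), rep(1 / 30, 30), circular = TRUE))
    y <- as.numeric(y)
    r7 <- polyfit_envelope(t, y, order = 7)$rms_residual
    r6 <- polyfit_envelope(t, y, order = 6)$rms_residual
    expect_lte(r7, r6 + 1e-12)
  }
})

test_that("fitting rejects short or non-finite input", {
  t <- seq(0, 1, length.out = 10)
  expect_error(polyfit_envelope(t, rnorm(10)), "at least 16")
  t <- seq(0, 1, length.out = 20)
  y <- rnorm(20); y[3] <- NA
  expect_error(polyfit_envelope(t, y), "non-finite")
})

make_fit <- function(coefs, span = c(0, 4)) {
  structure(list(coefficients = coefs, time_span = span, rms_residual = 0),
            class = "cycle_polyfit")
}

test_that("AUC of simple fits is exact", {
  # constant c over span T -> c * T
  expect_equal(compute_auc(make_fit(c(3, rep(0, 7)))), 12)
  # everywhere-negative fit -> clipped to 0
  expect_equal(compute_auc(make_fit(c(-1, 0, -2, rep(0, 5)))), 0)
})

test_that("clipped analytic AUC matches a dense trapezoid oracle", {
  set.seed(77)
  for (rep in 1:10) {
    coefs <- rnorm(8)
    fit <- make_fit(coefs, span = c(0, 4))
    u <- seq(-1, 1, length.out = 10001)
    y <- pmax(drop(outer(u, 0:7, `^`) %*% coefs), 0)
    trap <- sum((y[-1] + y[-length(y)]) / 2 * diff(u)) * 2  # jacobian T/2
    expect_equal(compute_auc(fit), trap, tolerance = 1e-6)
  }
})

test_that("cumulative AUC is nondecreasing, telescopes, and ends at the AUC", {
  set.seed(78)
  for (rep in 1:5) {
    fit <- make_fit(rnorm(8), span = c(0, 4))
    cum <- cumulative_auc_series(fit, n_points = 40)
    expect_true(all(diff(cum$values) >= -1e-12))
    expect_equal(cum$values[length(cum$values)], compute_auc(fit),
                 tolerance = 1e-6)
    d <- derivative_of_cumulative(cum)
    expect_equal(sum(d), cum$values[length(cum$values)], tolerance = 1e-12)
  }
  # constant envelope: cumulative linear, derivative constant
  cum <- cumulative_auc_series(make_fit(c(2, rep(0, 7))), n_points = 21)
  expect_equal(cum$values, seq(0, 8, length.out = 21))
  d <- derivative_of_cumulative(cum)
  expect_equal(d[-1], rep(0.4, 20))
  expect_error(cumulative_auc_series(make_fit(rnorm(8)), n_points = 1), ">= 2")
})

test_that("per-cycle sound AUC increases with tidal volume on clean simulations", {
  aucs <- vapply(c(500, 750, 1000), function(tv) {
    rec <- simulate_recording(sim_config(n_cycles = 2, tidal_volume_ml = tv,
                                         noise_sd = 0, seed = 12))
    mean(extract_cycle_features(rec, "sound")$auc)
  }, 0)
  expect_true(aucs[1] < aucs[2] && aucs[2] < aucs[3])
})

test_that("raw-envelope trapezoid AUC tracks the fitted AUC", {
  rec <- small_recording(n_cycles = 2, seed = 19)
  hf <- apply_filter(rec$sound, band_preset("sound_high"),
                     rec$sampling_rate_hz)
  env <- moving_variance(hf, 1000, sampling_rate_hz = rec$sampling_rate_hz)
  ann <- rec$annotations
  for (i in 1:2) {
    win <- c(ann$start[i], ann$end[i])
    raw <- envelope_auc(env, win)
    fitted <- compute_auc(fit_cycle_polynomial(env, win))
    expect_gt(raw, 0)
    # the order-7 fit smooths the envelope; the two integrals agree broadly
    expect_equal(fitted, raw, tolerance = 0.15)
  }
  expect_error(envelope_auc(env, c(1, 2)), "fewer than 2")
})

test_that("features table round-trips through CSV", {
  rec <- small_recording(n_cycles = 2, seed = 4)
  f <- rbind(as.data.frame(extract_cycle_features(rec, "sound")),
             as.data.frame(extract_cycle_features(rec, "ecg")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_features(f, path)
  rt <- read_features(path)
  expect_equal(rt$auc, f$auc, tolerance = 1e-12)
  expect_identical(rt$channel, f$channel)
  expect_identical(rt$is_cough, f$is_cough)
  expect_error(read_features(tempfile()), "not found")
})
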