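# Independent brute-force oracles used across tests. These deliberately use
# the most literal formulation of each quantity, not the package's code path.

# Population variance of each window, one explicit loop per window.
naive_moving_variance <- function(x, window, hop = 1L) {
  starts <- seq.int(1L, length(x) - window + 1L, by = hop)
  vapply(starts, function(s) {
    w <- x[s:(s + window - 1L)]
    mean((w - mean(w))^2)
  }, 0)
}

# Zone of each value by explicit comparison.
naive_zones <- function(values, t1, t2) {
  vapply(values, function(v) {
    if (v < t1) 1L else if (v < t2) 2L else 3L
  }, 1L)
}

# 3x3 joint zone histogram, counted one pair at a time.
naive_signature <- function(x, y, bx, by) {
  zx <- naive_zones(x, bx[1], bx[2])
  zy <- naive_zones(y, by[1], by[2])
  m <- matrix(0, 3, 3)
  for (k in seq_along(x)) m[zy[k], zx[k]] <- m[zy[k], zx[k]] + 1
  m / length(x)
}

# Sum of squared element differences written out longhand.
naive_sse <- function(a, b) {
  total <- 0
  for (i in 1:3) for (j in 1:3) total <- total + (a[i, j] - b[i, j])^2
  total
}

# Two-group one-way ANOVA from the sum-of-squares definitions.
naive_anova_f <- function(a, b) {
  g <- mean(c(a, b))
  ssb <- length(a) * (mean(a) - g)^2 + length(b) * (mean(b) - g)^2
  ssw <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  (ssb / 1) / (ssw / (length(a) + length(b) - 2))
}

# The published signature matrices, frozen digit-for-digit (row-major rows).
published_signatures <- function() {
  list(
    subject1_1000mL = matrix(c(0, 0, 0.2421,
                               0, 0.5263, 0,
                               0.2211, 0, 0), 3, 3, byrow = TRUE),
    subject1_500mL = matrix(c(0, 0, 0,
                              0, 0.7053, 0,
                              0.2842, 0, 0), 3, 3, byrow = TRUE),
    subject1_cough = matrix(c(0, 0, 0.9053,
                              0, 0.0105, 0.0737,
                              0, 0, 0), 3, 3, byrow = TRUE),
    subject2_1000mL = matrix(c(0, 0.0211, 0.3474,
                               0, 0.2421, 0,
                               0.1474, 0.2316, 0), 3, 3, byrow = TRUE),
    subject2_500mL = matrix(c(0, 0, 0,
                              0, 0.5158, 0,
                              0.4, 0.0737, 0), 3, 3, byrow = TRUE),
    subject1_template = matrix(c(0, 0.0631, 0.0807,
                                 0.0035, 0.5438, 0.0631,
                                 0.2281, 0.007, 0), 3, 3, byrow = TRUE),
    subject2_template = matrix(c(0, 0.0105, 0.4105,
                                 0, 0.2211, 0,
                                 0.1474, 0.2, 0), 3, 3, byrow = TRUE)
  )
}

# Small default recording shared by several tests.
small_recording <- function(n_cycles = 3, tv = 1000, seed = 11, ...) {
  simulate_recording(sim_config(n_cycles = n_cycles, tidal_volume_ml = tv,
                                seed = seed, ...))
}

rel_diff <- function(a, b) {
  d <- max(abs(a - b))
  s <- max(abs(a), abs(b), 1e-300)
  d / s
}
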