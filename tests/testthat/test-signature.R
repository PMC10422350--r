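test_that("zone assignment follows the half-open lower-inclusive convention", {
  th <- c(1, 2)
  expect_identical(assign_zone(0.5, th), 1L)
  expect_identical(assign_zone(1, th), 2L)   # boundary value joins the upper zone
  expect_identical(assign_zone(1.99, th), 2L)
  expect_identical(assign_zone(2, th), 3L)
  expect_identical(assign_zone(10, th), 3L)
  expect_error(assign_zone(NaN, th), "finite")
  expect_error(assign_zone(1, c(2, 1)), "increasing")

  set.seed(90)
  v <- runif(1000, -1, 4)
  expect_identical(assign_zone(v, th), naive_zones(v, th[1], th[2]))
})

test_that("signature matrices are counted correctly", {
  b <- zone_boundaries(c(1, 2), c(10, 20))
  # point mass: every pair in (X zone 2, Y zone 2)
  m <- build_signature_matrix(rep(1.5, 7), rep(15, 7), b)
  expect_equal(unclass(m)[2, 2], 1)
  expect_equal(sum(m), 1)

  # 95 pairs: 23 / 50 / 21 in cells (1,3), (2,2), (3,1) plus one stray pair
  # reproduce the published anti-diagonal deep-breathing pattern at 4 d.p.
  # (and its sum-below-1 anomaly: the visible cells total 94/95)
  x <- c(rep(2.5, 23), rep(1.5, 50), rep(0.5, 21), 2.5)
  y <- c(rep(5, 23), rep(15, 50), rep(25, 21), 15)
  m <- build_signature_matrix(x, y, b)
  expect_equal(sum(m), 1)
  expect_equal(round(unclass(m)[1, 3], 4), 0.2421)
  expect_equal(round(unclass(m)[2, 2], 4), 0.5263)
  expect_equal(round(unclass(m)[3, 1], 4), 0.2211)
  expect_equal(round(unclass(m)[2, 3], 4), 0.0105)
  expect_equal(unclass(m)[1, 3] + unclass(m)[2, 2] + unclass(m)[3, 1],
               94 / 95)
})

test_that("signature construction matches the 9-bin histogram oracle", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(5:200, 1)
    bx <- sort(runif(2)); by <- sort(runif(2))
    if (bx[1] == bx[2] || by[1] == by[2]) next
    x <- runif(n); y <- runif(n)
    b <- zone_boundaries(bx, by)
    m <- build_signature_matrix(x, y, b)
    expect_lt(rel_diff(unclass(m), naive_signature(x, y, bx, by)), 1e-12)
  }
  b <- zone_boundaries(c(1, 2), c(1, 2))
  expect_error(build_signature_matrix(1:3, 1:2, b), "equal length")
  expect_error(build_signature_matrix(numeric(0), numeric(0), b),
               "0 samples")
})

test_that("squared difference and SSE behave as a distance", {
  pub <- published_signatures()
  a <- pub$subject1_1000mL; tpl <- pub$subject1_template
  expect_equal(squared_difference(a, a), matrix(0, 3, 3))
  expect_equal(squared_difference(tpl, a), squared_difference(a, tpl))
  expect_equal(squared_difference(tpl, a), (tpl - a)^2)
  expect_equal(sse(a, a), 0)
  expect_equal(sse(tpl, a), naive_sse(tpl, a), tolerance = 1e-12)
  expect_gt(sse(tpl, a), 0)
  expect_error(sse(a, matrix(0, 2, 2)), "3x3")
})

test_that("published matrices order as expected under the template SSE", {
  pub <- published_signatures()
  # a cough frame is farther from the normal-breathing template than deep breathing
  expect_gt(sse(pub$subject1_template, pub$subject1_cough),
            sse(pub$subject1_template, pub$subject1_1000mL))
  expect_equal(sse(pub$subject2_template, pub$subject2_500mL),
               naive_sse(pub$subject2_template, pub$subject2_500mL),
               tolerance = 1e-12)
})

test_that("classification picks the minimal-SSE template", {
  pub <- published_signatures()
  lib <- template_library(
    deep = signature_matrix(pub$subject1_1000mL),
    cough = signature_matrix(pub$subject1_cough)
  )
  # identical target -> zero SSE, that label
  res <- classify_signature(signature_matrix(pub$subject1_cough), lib)
  expect_identical(res$label, "cough")
  expect_equal(unname(res$sse["cough"]), 0)

  # the shallow-breathing frame classifies by hand-computed SSE
  target <- signature_matrix(pub$subject1_500mL)
  hand <- c(deep = naive_sse(pub$subject1_1000mL, pub$subject1_500mL),
            cough = naive_sse(pub$subject1_cough, pub$subject1_500mL))
  res <- classify_signature(target, lib)
  expect_identical(res$label, names(which.min(hand)))
  expect_equal(unname(res$sse), unname(hand), tolerance = 1e-12)

  # disjoint point masses classify perfectly
  pm <- function(i, j) { m <- matrix(0, 3, 3); m[i, j] <- 1; signature_matrix(m) }
  lib2 <- template_library(a = pm(1, 1), b = pm(2, 2), c = pm(3, 3))
  for (nm in names(lib2$templates)) {
    expect_identical(classify_signature(lib2$templates[[nm]], lib2)$label, nm)
  }
  expect_error(classify_signature(pm(1, 1), list()), "template_library")
})

test_that("tied templates are flagged and broken by insertion order", {
  pm <- function(i, j) { m <- matrix(0, 3, 3); m[i, j] <- 1; signature_matrix(m) }
  lib <- template_library(first = pm(1, 1), second = pm(1, 1))
  res <- classify_signature(pm(1, 1), lib)
  expect_identical(res$label, "first")
  expect_true(res$tie)
})

test_that("template libraries round-trip through JSON with boundaries", {
  rec <- small_recording(n_cycles = 3, seed = 8)
  lib <- build_templates(list(deep = rec))
  path <- withr::local_tempfile(fileext = ".json")
  write_template_library(lib, path)
  rt <- read_template_library(path)
  expect_equal(unclass(rt$templates$deep), unclass(lib$templates$deep),
               ignore_attr = TRUE)
  expect_equal(rt$boundaries$x, lib$boundaries$x)
  expect_equal(rt$boundaries$y, lib$boundaries$y)
  expect_error(read_template_library(tempfile()), "not found")
})

test_that("auto tertile boundaries split pooled values into thirds", {
  set.seed(6)
  x <- runif(300); y <- rnorm(300)
  b <- auto_zone_boundaries(x, y)
  expect_equal(b$x, unname(quantile(x, c(1/3, 2/3), type = 7, names = FALSE)))
  zx <- assign_zone(x, b$x)
  expect_equal(as.numeric(table(zx)) / 300, rep(1/3, 3), tolerance = 0.02)
  expect_error(auto_zone_boundaries(rep(1, 10), y), "degenerate")
})

test_that("packaged reference matrices match the published values digit for digit", {
  lib <- reference_signatures()
  pub <- published_signatures()
  expect_setequal(names(lib$templates), names(pub))
  for (nm in names(pub)) {
    expect_identical(matrix(as.numeric(lib$templates[[nm]]), 3, 3), pub[[nm]],
                     info = nm)
    expect_lte(sum(lib$templates[[nm]]), 1)
  }
  # the published frames count slightly fewer than all windows
  sums <- vapply(lib$templates, sum, 0)
  expect_true(all(sums > 0.98 & sums <= 1))
})
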