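# spectral preprocessing chain

test_that("axis calibration recovers generating polynomials", {
  # two-point line
  cal <- calibrate_axis(data.frame(pixel = c(0, 1023), wavenumber = c(500, 3200)),
                        n_pixels = 1024L, fit_degree = 1L)
  expect_equal(cal$axis, seq(500, 3200, length.out = 1024L), tolerance = 1e-9)
  # collinear pairs: zero residuals
  tab <- data.frame(pixel = c(0, 100, 400, 700, 1023))
  tab$wavenumber <- 500 + 2.6 * tab$pixel
  cal <- calibrate_axis(tab, 1024L, 1L)
  expect_lt(max(abs(cal$residuals)), 1e-9)
  # quadratic round-trip
  tab$wavenumber <- 480 + 2.5 * tab$pixel + 1e-4 * tab$pixel^2
  cal <- calibrate_axis(tab, 1024L, 2L)
  expect_equal(unname(cal$coefficients), c(480, 2.5, 1e-4), tolerance = 1e-9)
  expect_error(calibrate_axis(data.frame(pixel = c(1, 1), wavenumber = c(1, 2)),
                              10L, 1L), "distinct")
  expect_error(calibrate_axis(tab, 10L, 5L), "smaller than")
})

test_that("transmission correction divides channel-wise and round-trips", {
  s <- raman_spectrum(1:10, (1:10)^1.5)
  expect_equal(correct_transmission(s, rep(1, 10))$intensity, s$intensity)
  expect_equal(correct_transmission(s, rep(0.5, 10))$intensity, 2 * s$intensity)
  tr <- withr::with_seed(1L, runif(10, 0.2, 1))
  dimmed <- raman_spectrum(s$wavenumber, s$intensity * tr)
  expect_equal(correct_transmission(dimmed, tr)$intensity, s$intensity,
               tolerance = 1e-12)
  expect_error(correct_transmission(s, c(rep(1, 9), 0)), "> 0")
  expect_error(correct_transmission(s, rep(1, 9)), "per channel")
})

test_that("baseline removal handles pure polynomial, zero and peaked inputs", {
  x <- seq(500, 3200, 4)
  poly3 <- 5 + 1e-3 * (x - 500) + 2e-7 * (x - 500)^2 - 3e-11 * (x - 500)^3
  r <- remove_baseline(raman_spectrum(x, poly3))
  expect_lt(max(abs(r$corrected$intensity)), 1e-6 * max(abs(poly3)))
  expect_true(r$converged)
  # zero vector
  r0 <- remove_baseline(raman_spectrum(x, numeric(length(x))))
  expect_identical(r0$corrected$intensity, numeric(length(x)))
  expect_identical(r0$baseline, numeric(length(x)))
  # polynomial + one Gaussian peak of height A: height recovered within 5%
  A <- 2
  peak <- A * exp(-((x - 1331) / 10)^2)
  r1 <- remove_baseline(raman_spectrum(x, poly3 + peak))
  ch <- which.min(abs(x - 1331))
  expect_lt(abs(r1$corrected$intensity[ch] - A) / A, 0.05)
})

test_that("converged baseline fits stay at or below smooth inputs", {
  x <- seq(500, 3200, 4)
  for (s in 1:5) {
    coefs <- withr::with_seed(s, runif(4, 0, 1))
    y <- drop(outer((x - 500) / 2700, 0:3, `^`) %*% coefs) + 1
    r <- remove_baseline(raman_spectrum(x, y))
    expect_true(r$converged)
    expect_lt(max(r$baseline - y), 1e-6 * max(abs(r$baseline)) * 10)
  }
})

test_that("baseline removal is idempotent at the percent level", {
  x <- seq(500, 3200, 4)
  base <- 3 + 2 * exp(-(x - 500) / 900)
  peaks <- 2 * exp(-((x - 1004) / 9)^2) + 1.5 * exp(-((x - 1445) / 9)^2)
  r1 <- remove_baseline(raman_spectrum(x, base + peaks))
  r2 <- suppressWarnings(remove_baseline(r1$corrected))
  delta <- max(abs(r2$corrected$intensity - r1$corrected$intensity))
  expect_lt(delta, 0.02 * max(r1$corrected$intensity))
})

test_that("Savitzky-Golay preserves polynomials and reduces noise", {
  x <- seq(0, 10, length.out = 200L)
  cubic <- raman_spectrum(x, 2 - x + 0.5 * x^2 - 0.05 * x^3)
  sm <- savitzky_golay(cubic, 21L, 3L)
  expect_lt(max(abs(sm$intensity - cubic$intensity)), 1e-9)
  # constant input unchanged
  cst <- raman_spectrum(x, rep(4.2, 200L))
  expect_equal(savitzky_golay(cst)$intensity, cst$intensity, tolerance = 1e-12)
  # white noise variance shrinks, checked over 100 replicate seeds
  var_ratio <- vapply(1:100, function(s) {
    y <- withr::with_seed(s, rnorm(200L))
    var(savitzky_golay(raman_spectrum(x, y), 21L, 3L)$intensity) / var(y)
  }, numeric(1L))
  expect_true(all(var_ratio < 1))
  expect_error(savitzky_golay(cubic, 20L, 3L), "odd")
  expect_error(savitzky_golay(cubic, 5L, 5L), "smaller")
})

test_that("region cropping keeps exactly the in-region channels", {
  x <- seq(500, 3200, 2)
  s <- raman_spectrum(x, seq_along(x))
  expect_identical(crop_to_regions(s, list(c(500, 3200)))$intensity, s$intensity)
  cr <- crop_to_regions(s, list(c(500, 1700), c(2800, 3000)))
  expect_false(any(cr$wavenumber > 1700 & cr$wavenumber < 2800))
  expect_true(all(diff(cr$wavenumber) > 0))
  # brute-force channel count
  expect_identical(length(cr$wavenumber),
                   sum(x >= 500 & x <= 1700) + sum(x >= 2800 & x <= 3000))
  expect_error(crop_to_regions(s, list(c(10, 20))), "no channels")
  expect_error(crop_to_regions(s, list(c(500, 1800), c(1700, 3000))),
               "non-overlapping")
})

test_that("min-max normalization is exact and affine-invariant", {
  s <- raman_spectrum(1:3, c(2, 4, 6))
  expect_equal(minmax_normalize(s)$intensity, c(0, 0.5, 1))
  unit <- raman_spectrum(1:3, c(0, 0.25, 1))
  expect_equal(minmax_normalize(unit)$intensity, unit$intensity)
  for (seed in 1:10) {
    y <- withr::with_seed(seed, rnorm(50L))
    a <- withr::with_seed(seed + 100L, runif(1, 0.1, 5))
    b <- withr::with_seed(seed + 200L, rnorm(1, 0, 10))
    expect_equal(minmax_normalize(raman_spectrum(1:50, a * y + b))$intensity,
                 minmax_normalize(raman_spectrum(1:50, y))$intensity,
                 tolerance = 1e-10)
  }
  cst <- raman_spectrum(1:3, rep(1, 3))
  expect_error(minmax_normalize(cst), "constant")
  fb <- minmax_normalize(cst, constant_fallback = TRUE)
  expect_identical(fb$intensity, rep(0, 3))
  expect_true(attr(fb, "constant_fallback"))
})

test_that("pipeline composes stages in the documented order", {
  x <- seq(500, 3200, 4)
  y <- withr::with_seed(5L, abs(rnorm(length(x))) + 1)
  s <- raman_spectrum(x, y)
  # identity-configured stages reduce the pipeline to 0-1 normalization:
  # degree-0 baseline subtraction is a constant shift, which min-max
  # normalization cancels; a 3-point order-2 SG window is interpolating
  out <- preprocess_pipeline(s, transmission = rep(1, length(x)),
                             baseline = baseline_config(degree = 0L),
                             sg_window = 3L, sg_order = 2L,
                             regions = list(c(500, 3200)))
  expect_equal(out$intensity, minmax_normalize(s)$intensity, tolerance = 1e-8)
  expect_identical(attr(out, "stages"),
                   c("transmission", "baseline", "savitzky_golay", "crop",
                     "normalize"))
  # output range is exactly [0, 1]
  full <- preprocess_pipeline(simulate_spectrum(make_class_profile("gland", 1L),
                                                tiny_config()))
  expect_identical(range(full$intensity), c(0, 1))
})

test_that("pipeline recovers the generated band structure", {
  # distinct, well-separated dominant bands so the generated amplitude
  # ranking is also the apex ranking (broad CH bands overlap and would
  # confound an apex-based check)
  prof <- band_profile("gland",
                       data.frame(center = c(874, 1004, 1445, 1663),
                                  amplitude = c(0.7, 3, 2, 1),
                                  width = c(14, 14, 14, 14)))
  s <- simulate_spectrum(prof, tiny_config(seed = 42L), seed = 43L)
  out <- preprocess_pipeline(s)
  # top-2 local maxima sit within +/- 4 cm^-1 of the two largest bands
  y <- out$intensity
  loc <- which(diff(sign(diff(y))) == -2) + 1L
  top2 <- loc[order(y[loc], decreasing = TRUE)][1:2]
  truth <- prof$bands$center[order(prof$bands$amplitude, decreasing = TRUE)][1:2]
  expect_true(all(vapply(out$wavenumber[top2],
                         function(w) min(abs(w - truth)) <= 4, logical(1L))))
})

test_that("pipeline equals its batched form and is deterministic", {
  d <- simulate_labeled_dataset(tiny_config(n = 3L))
  batch <- preprocess_set(d)
  single <- preprocess_pipeline(raman_spectrum(d$wavenumber, d$intensity[5L, ]))
  expect_equal(batch$intensity[5L, ], single$intensity, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_identical(preprocess_set(d)$intensity, batch$intensity)
})
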