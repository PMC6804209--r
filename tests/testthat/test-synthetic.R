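# synthetic spectrum / dataset / cube generator

test_that("class profiles enforce the stated band absences", {
  adenomas <- c("corticotroph", "gonadotroph", "somatotroph",
                "plurihormonal", "null_cell")
  for (cls in adenomas) {
    p <- make_class_profile(cls, rng_seed = 3L)
    expect_identical(p$bands$amplitude[p$bands$center == 1004], 0)
  }
  g <- make_class_profile("gonadotroph", rng_seed = 3L)
  expect_identical(g$bands$amplitude[g$bands$center == 1093], 0)
  per <- make_class_profile("periosteal", rng_seed = 3L)
  expect_identical(per$bands$amplitude[per$bands$center %in% c(590, 658, 1004, 1093)],
                   rep(0, 4L))
  gl <- make_class_profile("gland", rng_seed = 3L)
  expect_true(all(gl$bands$amplitude > 0))  # gland expresses all 12 bands
  expect_error(make_class_profile("lactotroph"), "valid classes")
})

test_that("profiles and datasets are seed-deterministic", {
  expect_identical(make_class_profile("gland", rng_seed = 7L),
                   make_class_profile("gland", rng_seed = 7L))
  cfg <- tiny_config(n = 5L, seed = 11L)
  expect_identical(simulate_labeled_dataset(cfg), simulate_labeled_dataset(cfg))
})

test_that("simulate_spectrum matches its construction in edge cases", {
  cfg0 <- tiny_config(noise_sd = 0)
  cfg0$baseline_magnitude <- 0
  # single band: maximum at the axis point nearest the center, height ~ A
  prof <- band_profile("gland", data.frame(center = 1004, amplitude = 2.5,
                                           width = 12))
  s <- simulate_spectrum(prof, cfg0)
  expect_equal(s$wavenumber[which.max(s$intensity)], 1004, tolerance = 1e-12)
  expect_equal(max(s$intensity), 2.5, tolerance = 1e-6)
  # empty profile, zero baseline/noise -> zero vector
  empty <- band_profile("gland", data.frame(center = numeric(0),
                                            amplitude = numeric(0),
                                            width = numeric(0)))
  expect_identical(simulate_spectrum(empty, cfg0)$intensity,
                   numeric(length(s$wavenumber)))
  expect_error(synthetic_config(noise_sd = -0.1), "noise_sd")
})

test_that("empirical mean over many draws converges to the noise-free spectrum", {
  cfg <- tiny_config(seed = 7L)
  prof <- make_class_profile("gland", rng_seed = 7L)
  noise_free <- simulate_spectrum(prof, tiny_config(noise_sd = 0))$intensity
  n_draws <- 1000L
  acc <- withr::with_seed(7L, {
    m <- numeric(length(noise_free))
    for (i in seq_len(n_draws)) {
      m <- m + simulate_spectrum(prof, cfg)$intensity
    }
    m / n_draws
  })
  se <- cfg$noise_sd * max(prof$bands$amplitude) / sqrt(n_draws)
  z <- abs(acc - noise_free) / se
  # ~0.27% of channels are expected beyond 3 SE by chance; none beyond 6
  expect_lt(mean(z > 3), 0.01)
  expect_lt(max(z), 6)
})

test_that("labeled datasets have uniform class composition", {
  d <- simulate_labeled_dataset(tiny_config(n = 10L))
  expect_equal(nrow(d$intensity), 70L)
  expect_identical(unname(table(d$labels)),
                   table(rep(tissue_classes, each = 10L)) |> unname())
})

test_that("cube simulation respects maps, geometry and pattern errors", {
  cfg0 <- tiny_config(noise_sd = 0)
  prof <- make_class_profile("gland", rng_seed = 1L)
  # uniform maps, no noise -> every pixel spectrum identical
  pat <- spatial_pattern(c(4L, 6L), raman_band_positions, "uniform")
  cube <- simulate_cube(prof, pat, cfg0)
  M <- matrix(cube$intensity, nrow = 24L)
  expect_true(all(abs(sweep(M, 2L, M[1L, ])) < 1e-12))
  expect_identical(cube$pitch, c(5, 10))
  # default geometry: 100 um line at 5 um pitch x 500 um travel at 10 um
  pat20 <- spatial_pattern(c(20L, 50L), raman_band_positions, "uniform")
  cube20 <- simulate_cube(prof, pat20, cfg0)
  d <- dim(cube20$intensity)
  expect_identical(d[1:2], c(20L, 50L))
  expect_equal(d[1L] * cube20$pitch[1L], 100)
  expect_equal(d[2L] * cube20$pitch[2L], 500)
  # complementary left/right maps -> anticorrelated band images
  pat2 <- spatial_pattern(c(8L, 12L), raman_band_positions, "two_compartment",
                          bands_a = 1331, bands_b = 1445)
  cube2 <- simulate_cube(prof, pat2, cfg0)
  r <- corr2(extract_band_image(cube2, 1331, 5),
             extract_band_image(cube2, 1445, 5))
  expect_lt(r, 0)
  # shape mismatch between maps is rejected
  bad <- pat2
  bad$maps[["1331"]] <- matrix(0.5, 3L, 3L)
  expect_error(simulate_cube(prof, bad, cfg0), "shape")
  # a missing map for a present band is rejected
  missing <- spatial_pattern(c(8L, 12L), c(1331), "uniform")
  expect_error(simulate_cube(prof, missing, cfg0), "lacks maps")
})

test_that("higher noise does not improve downstream accuracy (light variant)", {
  # full >= 20-seed grid runs in test-acceptance.R; here two well-separated
  # noise levels over 5 seeds
  acc <- vapply(1:5, function(s) {
    c(low = holdout_accuracy(s, 25L, noise_sd = 0.05, axis = c(500, 3200, 4)),
      high = holdout_accuracy(s, 25L, noise_sd = 3, axis = c(500, 3200, 4)))
  }, numeric(2L))
  expect_gt(mean(acc["low", ]) - mean(acc["high", ]), 0)
})

test_that("labeled-set and cube text round-trips preserve data", {
  d <- simulate_labeled_dataset(tiny_config(n = 3L))
  f <- tempfile(fileext = ".csv")
  write_labeled_csv(d, f)
  back <- read_labeled_csv(f)
  expect_equal(back$intensity, d$intensity, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_identical(back$labels, d$labels)
  expect_identical(back$biopsy_id, d$biopsy_id)

  prof <- make_class_profile("somatotroph", rng_seed = 2L)
  pat <- spatial_pattern(c(5L, 7L), raman_band_positions, "two_compartment")
  cube <- simulate_cube(prof, pat, tiny_config(), seed = 2L)
  fc <- tempfile(fileext = ".txt")
  write_cube(cube, fc)
  back <- read_cube(fc)
  expect_equal(back$intensity, cube$intensity, tolerance = 1e-12)
  expect_identical(back$pitch, cube$pitch)
  expect_identical(back$class_label, "somatotroph")
})
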