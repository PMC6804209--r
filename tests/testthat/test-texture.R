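# GLCM texture features and image correlation

test_that("quantization bins linearly between image min and max", {
  expect_identical(quantize_image(matrix(c(0, 1, 0, 1), 2L), 2L),
                   matrix(c(1L, 2L, 1L, 2L), 2L))
  expect_identical(quantize_image(matrix(3.7, 4L, 4L), 8L),
                   matrix(1L, 4L, 4L))
  ramp <- matrix(seq(0, 1, length.out = 64L), 8L)
  expect_identical(unname(table(quantize_image(ramp, 8L))),
                   table(rep(1:8, 8L)) |> unname())
  expect_error(quantize_image(ramp, 1L), ">= 2")
})

test_that("compute_glcm counts ordered pairs and normalizes", {
  q <- rbind(c(1L, 1L), c(2L, 2L))
  g <- compute_glcm(q, c(0L, 1L), n_levels = 2L)
  expect_equal(unclass(g), diag(c(0.5, 0.5)), ignore_attr = TRUE)
  # constant image: one entry equal to 1
  gc <- compute_glcm(matrix(1L, 4L, 4L), c(0L, 1L), n_levels = 2L)
  expect_equal(sum(gc), 1)
  expect_equal(gc[1L, 1L], 1)
  expect_error(compute_glcm(q, c(0L, 0L)), "nonzero")
  expect_error(compute_glcm(q, c(0L, 5L)), "not larger")
})

test_that("GLCM and features match brute-force oracles exhaustively", {
  # all 2-level 3x3 images at all four offsets; deviations accumulated so a
  # single pair of assertions covers the 2048 cases
  count_mismatches <- 0L
  max_feature_dev <- 0
  corr_flag_mismatches <- 0L
  for (code in 0:511) {
    q <- matrix(as.integer(intToBits(code)[1:9]) + 1L, 3L, 3L)
    for (off in glcm_offsets) {
      counts <- oracle_glcm(q, off, 2L)
      got <- compute_glcm(q, off, n_levels = 2L, normalize = FALSE)
      if (!isTRUE(all(unclass(got) == counts))) {
        count_mismatches <- count_mismatches + 1L
      }
      want <- oracle_haralick(counts / sum(counts))
      have <- haralick_features(compute_glcm(q, off, n_levels = 2L))
      for (field in c("contrast", "energy", "homogeneity", "correlation")) {
        a <- have[[field]]; b <- want[[field]]
        if (is.na(a) != is.na(b)) {
          corr_flag_mismatches <- corr_flag_mismatches + 1L
        } else if (!is.na(a)) {
          max_feature_dev <- max(max_feature_dev, abs(a - b))
        }
      }
    }
  }
  expect_identical(count_mismatches, 0L)
  expect_identical(corr_flag_mismatches, 0L)
  expect_lt(max_feature_dev, 1e-12)
})

test_that("haralick features satisfy the printed identities", {
  # constant image: contrast 0, energy 1, homogeneity 1, correlation undefined
  g <- compute_glcm(matrix(1L, 8L, 8L), c(0L, 1L), n_levels = 8L)
  f <- haralick_features(g)
  expect_identical(f$contrast, 0)
  expect_identical(f$energy, 1)
  expect_identical(f$homogeneity, 1)
  expect_true(is.na(f$correlation))
  # diagonal GLCM: homogeneity 1, contrast 0
  q <- matrix(rep(1:4, each = 6L), 4L, 6L, byrow = TRUE)
  gd <- compute_glcm(q, c(0L, 1L), n_levels = 4L)
  expect_true(all(gd[row(gd) != col(gd)] == 0))
  fd <- haralick_features(gd)
  expect_identical(fd$homogeneity, 1)
  expect_identical(fd$contrast, 0)
  # the 2x2 worked example
  f2 <- haralick_features(compute_glcm(rbind(c(1L, 1L), c(2L, 2L)),
                                       c(0L, 1L), n_levels = 2L))
  expect_equal(unlist(f2), c(contrast = 0, correlation = 1, energy = 0.5,
                             homogeneity = 1))
  expect_error(haralick_features(compute_glcm(q, c(0L, 1L), n_levels = 4L,
                                              normalize = FALSE)),
               "normalized")
})

test_that("image_texture aggregates over the four offsets", {
  cst <- matrix(5, 6L, 6L)
  f <- image_texture(cst)
  expect_identical(f$contrast, 0)
  expect_identical(f$energy, 1)
  expect_identical(f$homogeneity, 1)
  expect_true(is.na(f$correlation))
  # checkerboard at the 0-degree offset has contrast 1
  chk <- outer(1:6, 1:6, function(i, j) (i + j) %% 2)
  f0 <- haralick_features(compute_glcm(quantize_image(chk, 2L), c(0L, 1L),
                                       n_levels = 2L))
  expect_identical(f0$contrast, 1)
  # quantization is min-max based: shift invariance
  img <- withr::with_seed(8L, matrix(runif(48L), 6L, 8L))
  expect_identical(unlist(image_texture(img)), unlist(image_texture(img + 17)))
})

test_that("feature bounds hold on random images", {
  for (seed in 1:20) {
    img <- withr::with_seed(seed, matrix(runif(63L), 7L, 9L))
    f <- image_texture(img)
    expect_gte(f$contrast, 0)
    expect_true(f$energy > 0 && f$energy <= 1)
    expect_true(f$homogeneity > 0 && f$homogeneity <= 1)
    if (!is.na(f$correlation)) {
      expect_true(abs(f$correlation) <= 1 + 1e-12)
    }
  }
  # offset symmetry under transposition
  img <- withr::with_seed(3L, matrix(runif(30L), 5L, 6L))
  q <- quantize_image(img, 4L)
  f_orig <- haralick_features(compute_glcm(q, c(1L, 0L), n_levels = 4L))
  f_tr <- haralick_features(compute_glcm(t(q), c(0L, 1L), n_levels = 4L))
  expect_equal(unlist(f_orig), unlist(f_tr), tolerance = 1e-12)
})

test_that("class_texture_summary bookkeeps (class, band) medians", {
  mk <- function(cls, band, seed) {
    band_image(withr::with_seed(seed, matrix(runif(35L), 5L, 7L)),
               band, 5, cls)
  }
  imgs <- list(mk("gland", 1004, 1L), mk("gland", 1004, 2L),
               mk("gland", 1004, 3L), mk("gland", 1445, 4L))
  tab <- class_texture_summary(imgs)
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$n_images, c(3L, 1L))
  # single image per group: summary equals that image's features
  f <- image_texture(imgs[[4L]])
  expect_equal(tab$contrast[tab$band == 1445], f$contrast)
  # median of three feature values is the middle one
  per <- vapply(imgs[1:3], function(im) image_texture(im)$contrast, numeric(1L))
  expect_equal(tab$contrast[tab$band == 1004], sort(per)[2L])
})

test_that("corr2 is a symmetric, affine-equivariant Pearson coefficient", {
  a <- matrix(c(1, 3, 2, 4), 2L)
  b <- matrix(c(1, 3, 2, 5), 2L)
  expect_equal(corr2(a, b), stats::cor(as.numeric(a), as.numeric(b)),
               tolerance = 1e-12)
  expect_identical(corr2(a, a), 1)
  expect_equal(corr2(a, 10 - a), -1)
  expect_identical(corr2(a, b), corr2(b, a))
  for (seed in 1:10) {
    x <- withr::with_seed(seed, matrix(rnorm(24L), 4L))
    y <- withr::with_seed(seed + 50L, matrix(rnorm(24L), 4L))
    expect_equal(corr2(2.5 * x + 3, y), corr2(x, y), tolerance = 1e-10)
    expect_equal(corr2(-x, y), -corr2(x, y), tolerance = 1e-10)
  }
  expect_true(is.na(corr2(matrix(1, 2L, 2L), matrix(2, 2L, 2L))))
  expect_error(corr2(a, matrix(0, 3L, 3L)), "equal shapes")
})

test_that("class-vs-reference correlation matrices behave", {
  mk <- function(m, band, cls) band_image(m, band, 5, cls)
  base <- withr::with_seed(1L, matrix(runif(50L), 5L, 10L))
  # orthogonal indicator maps: left-half vs top-half have zero correlation
  left <- cbind(matrix(1, 6L, 5L), matrix(0, 6L, 5L))
  top <- rbind(matrix(1, 3L, 10L), matrix(0, 3L, 10L))
  imgs <- list(
    gland = list("1004" = mk(base, 1004, "gland"),
                 "1445" = mk(left, 1445, "gland")),
    null_cell = list("1004" = mk(base + 1, 1004, "null_cell"),
                     "1445" = mk(top[1:5, ], 1445, "null_cell"))
  )
  m <- class_band_correlation_matrix(imgs, reference = "gland")
  expect_true(all(m["gland", ] == 1))
  expect_true(all(m >= -1 - 1e-12 & m <= 1 + 1e-12))
  # the indicator maps are exactly uncorrelated after the common crop
  m2 <- class_band_correlation_matrix(
    list(gland = list("1445" = mk(left[1:5, ], 1445, "gland")),
         x = list("1445" = mk(top[1:5, ], 1445, "x"))),
    reference = "gland")
  expect_lt(abs(m2["x", "1445"]), 0.05)
  expect_error(class_band_correlation_matrix(imgs, reference = "nope"),
               "reference class")
})
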