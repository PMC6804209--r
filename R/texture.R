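#' Quantize an image to discrete grey levels
#'
#' Linear binning of `[min, max]` into `n_levels` levels `1..L`; a
#' constant image maps to level 1 everywhere.  Quantization is min-max
#' based, so adding a constant to the image leaves the result unchanged.
#'
#' @param image Numeric matrix or [band_image()].
#' @param n_levels Grey-level count `L >= 2` (default 8).
#' @return Integer matrix of levels in `1..L`.
#' @export
quantize_image <- function(image, n_levels = 8L) {
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop("`n_levels` must be >= 2", call. = FALSE)
  m <- as.matrix(image)
  rng <- range(m)
  if (diff(rng) == 0) {
    return(matrix(1L, nrow(m), ncol(m)))
  }
  q <- pmin(as.integer(floor((m - rng[1L]) / diff(rng) * n_levels)) + 1L,
            n_levels)
  matrix(q, nrow(m), ncol(m))
}

#' The four 1-pixel GLCM offsets at 0, 45, 90 and 135 degrees
#'
#' Offsets are `(delta_row, delta_col)` with the row index increasing
#' downward: `(0,1)`, `(-1,1)`, `(-1,0)`, `(-1,-1)`.
#' @export
glcm_offsets <- list(deg0 = c(0L, 1L), deg45 = c(-1L, 1L),
                     deg90 = c(-1L, 0L), deg135 = c(-1L, -1L))

#' Grey-level co-occurrence matrix
#'
#' Entry `(i, j)` counts ordered pixel pairs `(p, p + offset)` whose
#' quantized levels are `(i, j)`; normalization divides by the total pair
#' count.  The matrix is non-symmetric (ordered pairs) by default.
#'
#' @param qimage Integer level matrix from [quantize_image()].
#' @param offset `c(delta_row, delta_col)`, nonzero; the image must be
#'   larger than the offset in each direction.
#' @param n_levels Grey-level count (default `max(qimage)`).
#' @param normalize Normalize counts to probabilities (default `TRUE`).
#' @param symmetric Also count each pair in the reversed order.
#' @return An `L x L` matrix of class `glcm` with attributes `offset`,
#'   `levels`, `normalized`.
#' @export
compute_glcm <- function(qimage, offset, n_levels = max(qimage),
                         normalize = TRUE, symmetric = FALSE) {
  offset <- as.integer(offset)
  if (length(offset) != 2L || all(offset == 0L)) {
    stop("`offset` must be a nonzero (delta_row, delta_col) pair", call. = FALSE)
  }
  nr <- nrow(qimage); nc <- ncol(qimage)
  if (abs(offset[1L]) >= nr || abs(offset[2L]) >= nc) {
    stop("image (", nr, "x", nc, ") is not larger than the offset", call. = FALSE)
  }
  L <- as.integer(n_levels)
  if (any(qimage < 1L) || any(qimage > L)) {
    stop("`qimage` levels must lie in 1..n_levels", call. = FALSE)
  }
  rows <- max(1L, 1L - offset[1L]):min(nr, nr - offset[1L])
  cols <- max(1L, 1L - offset[2L]):min(nc, nc - offset[2L])
  A <- qimage[rows, cols, drop = FALSE]
  B <- qimage[rows + offset[1L], cols + offset[2L], drop = FALSE]
  counts <- tabulate((B - 1L) * L + A, nbins = L * L)
  G <- matrix(as.numeric(counts), L, L)
  if (symmetric) G <- G + t(G)
  if (normalize) {
    tot <- sum(G)
    if (tot > 0) G <- G / tot
  }
  structure(G, offset = offset, levels = L, normalized = normalize,
            class = c("glcm", "matrix", "array"))
}

#' Haralick features of one normalized GLCM
#'
#' * contrast: `sum p(i,j) (i-j)^2` — 0 for a constant image;
#' * correlation: `sum p(i,j)(i-mu_i)(j-mu_j) / (sigma_i sigma_j)` —
#'   undefined (`NA`) when either marginal is degenerate;
#' * energy: `sum p(i,j)^2` — 1 for a constant image;
#' * homogeneity: `sum p(i,j) / (1 + |i-j|)` — 1 iff the GLCM is diagonal.
#'
#' @param glcm A normalized [compute_glcm()] result.
#' @return An object of class `texture_features`: list with `contrast`,
#'   `correlation`, `energy`, `homogeneity`.
#' @export
haralick_features <- function(glcm) {
  if (!isTRUE(attr(glcm, "normalized"))) {
    stop("`glcm` must be normalized (probabilities summing to 1)", call. = FALSE)
  }
  p <- unclass(glcm)
  attributes(p) <- list(dim = dim(glcm))
  L <- nrow(p)
  I <- row(p); J <- col(p)
  pi_ <- rowSums(p); p_j <- colSums(p)
  mu_i <- sum(seq_len(L) * pi_); mu_j <- sum(seq_len(L) * p_j)
  sd_i <- sqrt(sum((seq_len(L) - mu_i)^2 * pi_))
  sd_j <- sqrt(sum((seq_len(L) - mu_j)^2 * p_j))
  corr <- if (sd_i * sd_j == 0) NA_real_ else
    sum(p * outer(seq_len(L) - mu_i, seq_len(L) - mu_j)) / (sd_i * sd_j)
  structure(list(contrast = sum(p * (I - J)^2),
                 correlation = corr,
                 energy = sum(p^2),
                 homogeneity = sum(p / (1 + abs(I - J)))),
            class = "texture_features")
}

#' @export
print.texture_features <- function(x, ...) {
  cat(sprintf("<texture_features> contrast %.4f, correlation %s, energy %.4f, homogeneity %.4f\n",
              x$contrast,
              if (is.na(x$correlation)) "undefined" else sprintf("%.4f", x$correlation),
              x$energy, x$homogeneity))
  invisible(x)
}

#' Texture features of one image, aggregated over offsets
#'
#' Quantizes the image, computes the GLCM and the four Haralick features
#' at each offset (0/45/90/135 degrees by default), and aggregates by the
#' mean.  Undefined correlations are excluded from the mean; if all are
#' undefined the aggregated correlation is `NA`.
#'
#' @param image Numeric matrix or [band_image()].
#' @param n_levels Grey levels for quantization (default 8).
#' @param offsets List of `(delta_row, delta_col)` offsets (default
#'   [glcm_offsets]).
#' @param symmetric Passed to [compute_glcm()].
#' @return A `texture_features` object with attribute `offsets`.
#' @export
image_texture <- function(image, n_levels = 8L, offsets = glcm_offsets,
                          symmetric = FALSE) {
  q <- quantize_image(image, n_levels)
  per <- lapply(offsets, function(off) {
    haralick_features(compute_glcm(q, off, n_levels = n_levels,
                                   symmetric = symmetric))
  })
  agg <- function(field) {
    v <- vapply(per, `[[`, numeric(1L), field)
    if (field == "correlation") {
      v <- v[!is.na(v)]
      if (length(v) == 0L) return(NA_real_)
    }
    mean(v)
  }
  structure(list(contrast = agg("contrast"),
                 correlation = agg("correlation"),
                 energy = agg("energy"),
                 homogeneity = agg("homogeneity")),
            class = "texture_features",
            offsets = offsets)
}

#' Per-class, per-band texture summary
#'
#' Computes [image_texture()] for every image and takes the median of each
#' feature over the images of each `(class, band)` group — with six
#' imaging classes and twelve bands this yields the 72 values per feature
#' that summarize a study.  Undefined correlations are dropped before the
#' median (all-undefined groups report `NA`).  Empty groups are omitted
#' with a warning.
#'
#' @param images List of [band_image()]s carrying `class_label` and
#'   `center` attributes.
#' @param n_levels,offsets,symmetric Passed to [image_texture()].
#' @return Data frame with columns `class`, `band`, `n_images`,
#'   `contrast`, `correlation`, `energy`, `homogeneity`, one row per
#'   `(class, band)` pair.
#' @export
class_texture_summary <- function(images, n_levels = 8L,
                                  offsets = glcm_offsets,
                                  symmetric = FALSE) {
  cls <- vapply(images, function(im) {
    v <- attr(im, "class_label")
    if (is.null(v)) stop("every image needs a `class_label` attribute",
                         call. = FALSE)
    as.character(v)
  }, character(1L))
  band <- vapply(images, function(im) {
    v <- attr(im, "center")
    if (is.null(v)) stop("every image needs a `center` attribute", call. = FALSE)
    as.numeric(v)
  }, numeric(1L))
  feats <- lapply(images, image_texture, n_levels = n_levels,
                  offsets = offsets, symmetric = symmetric)
  groups <- split(seq_along(images), list(class = cls, band = band),
                  drop = TRUE)
  med <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else stats::median(v)
  }
  rows <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    f <- function(field) med(vapply(feats[idx], `[[`, numeric(1L), field))
    data.frame(class = cls[idx[1L]], band = band[idx[1L]],
               n_images = length(idx),
               contrast = f("contrast"), correlation = f("correlation"),
               energy = f("energy"), homogeneity = f("homogeneity"))
  })
  out <- do.call(rbind, rows)
  out[order(out$class, out$band), , drop = FALSE]
}

#' 2D correlation coefficient of two images
#'
#' Pearson correlation of the mean-centered flattened images; 1 for
#' identical images, -1 for perfectly anti-correlated ones.  When either
#' image is constant the coefficient is undefined and `NA` is returned
#' (never coerced to 0 or 1).
#'
#' @param image_a,image_b Matrices (or [band_image()]s) of equal shape.
#' @return A scalar in `[-1, 1]`, or `NA` when undefined.
#' @export
corr2 <- function(image_a, image_b) {
  a <- as.numeric(as.matrix(image_a)); b <- as.numeric(as.matrix(image_b))
  if (!all(dim(as.matrix(image_a)) == dim(as.matrix(image_b)))) {
    stop("images must have equal shapes", call. = FALSE)
  }
  am <- a - mean(a); bm <- b - mean(b)
  den <- sqrt(sum(am^2) * sum(bm^2))
  if (den == 0) return(NA_real_)
  sum(am * bm) / den
}

#' Class-versus-reference band-image correlation matrix
#'
#' For each class and band, the [corr2()] between that class's band image
#' and the reference class's image at the same band, after center-cropping
#' all images to the common minimal shape.  The reference defaults to
#' gland, the comparison the study narrative uses; `reference = NULL`
#' returns the all-classes-vs-all-classes correlation per band instead.
#'
#' @param images Nested named list: `images[[class]][[as.character(band)]]`
#'   is one representative [band_image()].
#' @param reference Reference class name (default `"gland"`).
#' @param bands Band centers to use (default: the bands of the reference
#'   class entry).
#' @return With a reference: numeric matrix `class x band`.  With
#'   `reference = NULL`: a named list of `class x class` matrices, one per
#'   band.
#' @export
class_band_correlation_matrix <- function(images, reference = "gland",
                                          bands = NULL) {
  stopifnot(is.list(images), length(images) >= 1L, !is.null(names(images)))
  all_imgs <- unlist(images, recursive = FALSE)
  shapes <- vapply(all_imgs, function(im) dim(as.matrix(im)), integer(2L))
  common <- c(min(shapes[1L, ]), min(shapes[2L, ]))
  if (any(common < 1L)) stop("no common croppable shape", call. = FALSE)
  crop <- function(im) center_crop(as.matrix(im), common)
  if (is.null(reference)) {
    if (is.null(bands)) bands <- names(images[[1L]])
    out <- lapply(bands, function(b) {
      cl <- names(images)
      m <- matrix(NA_real_, length(cl), length(cl), dimnames = list(cl, cl))
      for (i in cl) for (j in cl) {
        m[i, j] <- corr2(crop(images[[i]][[b]]), crop(images[[j]][[b]]))
      }
      m
    })
    names(out) <- bands
    return(out)
  }
  if (!reference %in% names(images)) {
    stop("reference class '", reference, "' not among images: ",
         paste(names(images), collapse = ", "), call. = FALSE)
  }
  if (is.null(bands)) bands <- names(images[[reference]])
  cl <- names(images)
  m <- matrix(NA_real_, length(cl), length(bands),
              dimnames = list(cl, bands))
  for (i in cl) for (b in bands) {
    if (!b %in% names(images[[i]])) next
    m[i, b] <- corr2(crop(images[[i]][[b]]), crop(images[[reference]][[b]]))
  }
  m
}
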