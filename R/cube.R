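#' Hyperspectral cube container
#'
#' Intensities on a `(n_line_positions x n_scan_steps x n_channels)` grid
#' with the line-scan pitch metadata: microns between samples along the
#' laser line (first axis, default 5 um) and microns per stage step
#' (second axis, default 10 um).
#'
#' @param intensity 3D numeric array, all finite.
#' @param wavenumber Wavenumber axis, length `dim(intensity)[3]`.
#' @param pitch `c(line_um, step_um)`, both > 0.
#' @param class_label Optional tissue-class label of the imaged sample.
#' @return An object of class `hyper_cube`.
#' @export
hyper_cube <- function(intensity, wavenumber, pitch = c(5, 10),
                       class_label = NULL) {
  if (length(dim(intensity)) != 3L) {
    stop("`intensity` must be a 3D array", call. = FALSE)
  }
  if (dim(intensity)[3L] != length(wavenumber)) {
    stop("third array dimension must match the wavenumber axis", call. = FALSE)
  }
  if (!all(is.finite(intensity))) stop("all intensities must be finite",
                                       call. = FALSE)
  if (length(pitch) != 2L || any(pitch <= 0)) {
    stop("`pitch` must be two positive spacings (um)", call. = FALSE)
  }
  structure(list(intensity = intensity, wavenumber = as.numeric(wavenumber),
                 pitch = as.numeric(pitch), class_label = class_label),
            class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$intensity)
  cat("<hyper_cube> ", d[1L], " x ", d[2L], " pixels x ", d[3L],
      " channels; pitch ", x$pitch[1L], " x ", x$pitch[2L], " um",
      if (!is.null(x$class_label)) paste0("; class ", x$class_label), "\n",
      sep = "")
  invisible(x)
}

#' Preprocess every pixel spectrum of a cube
#'
#' Runs the [preprocess_pipeline()] on each pixel; spatial dimensions are
#' unchanged.  Pixels whose spectrum is constant are handled per
#' `constant_fallback` exactly as in the 1D path.
#'
#' @inheritParams preprocess_pipeline
#' @param cube A [hyper_cube()].
#' @return The preprocessed [hyper_cube()] with per-pixel attributes
#'   `baseline_converged` and `constant_fallback` (matrices in cube
#'   layout).
#' @export
preprocess_cube <- function(cube, transmission = NULL,
                            baseline = baseline_config(),
                            sg_window = 21L, sg_order = 3L,
                            regions = list(c(500, 1700), c(2800, 3000)),
                            resample_uniform = TRUE,
                            constant_fallback = FALSE) {
  d <- dim(cube$intensity)
  Y <- matrix(cube$intensity, nrow = d[1L] * d[2L])  # pixels x channels
  r <- preprocess_matrix(Y, cube$wavenumber, transmission, baseline,
                         sg_window, sg_order, regions, resample_uniform,
                         constant_fallback)
  out <- hyper_cube(array(r$intensity, dim = c(d[1L], d[2L], ncol(r$intensity))),
                    r$wavenumber, cube$pitch, cube$class_label)
  attr(out, "baseline_converged") <- matrix(r$converged, d[1L], d[2L])
  attr(out, "constant_fallback") <- matrix(r$constant_fallback, d[1L], d[2L])
  out
}

#' Band image
#'
#' A 2D image sliced from a hyperspectral cube at one Raman band.
#'
#' @param values Numeric matrix (cube spatial shape).
#' @param center Band center, cm^-1.
#' @param half_window Extraction half-window, cm^-1.
#' @param class_label Optional source tissue class.
#' @return An object of class `band_image` (a matrix with attributes
#'   `center`, `half_window`, `class_label`).
#' @export
band_image <- function(values, center, half_window = 0,
                       class_label = NULL) {
  values <- as.matrix(values)
  structure(values, center = center, half_window = half_window,
            class_label = class_label, class = c("band_image", "matrix", "array"))
}

#' @export
print.band_image <- function(x, ...) {
  cat("<band_image> ", nrow(x), " x ", ncol(x), " at ",
      attr(x, "center"), " cm^-1 (+/- ", attr(x, "half_window"), ")",
      if (!is.null(attr(x, "class_label")))
        paste0("; class ", attr(x, "class_label")), "\n", sep = "")
  invisible(x)
}

#' Extract a band image from a cube
#'
#' Pixel value is the mean intensity over the channels lying within
#' `center +/- half_window` cm^-1; with `half_window = 0` the single
#' nearest channel is used.
#'
#' @param cube A [hyper_cube()].
#' @param center Band center, cm^-1; must fall inside the axis range for
#'   `half_window = 0`, and the window must contain at least one channel
#'   otherwise.
#' @param half_window Half-window in cm^-1 (default 5).
#' @return A [band_image()].
#' @export
extract_band_image <- function(cube, center, half_window = 5) {
  wn <- cube$wavenumber
  if (half_window < 0) stop("`half_window` must be >= 0", call. = FALSE)
  if (half_window == 0) {
    if (center < min(wn) || center > max(wn)) {
      stop("band center ", center, " cm^-1 lies outside the axis range",
           call. = FALSE)
    }
    idx <- which.min(abs(wn - center))
  } else {
    idx <- which(abs(wn - center) <= half_window)
    if (length(idx) == 0L) {
      stop("no channels within ", half_window, " cm^-1 of ", center,
           call. = FALSE)
    }
  }
  slab <- cube$intensity[, , idx, drop = FALSE]
  img <- if (length(idx) == 1L) slab[, , 1L] else
    apply(slab, c(1L, 2L), mean)
  band_image(img, center, half_window, cube$class_label)
}

# min-max scale an image to [0, 1]; a constant image maps to 1 where its
# value is positive and 0 otherwise (so a uniformly "on" band renders at
# full brightness and an absent band renders dark).
scale_unit <- function(m) {
  rng <- range(m)
  if (diff(rng) == 0) {
    return(matrix(as.numeric(rng[1L] > 0), nrow(m), ncol(m)))
  }
  (m - rng[1L]) / diff(rng)
}

#' Two-band magenta/green overlay
#'
#' Pseudo-color composite of two band images: image A (min-max scaled)
#' drives magenta (red + blue), image B drives green.  Pixels where A is
#' maximal and B zero render pure magenta; identical images render grey.
#'
#' @param image_a,image_b [band_image()]s (or matrices) of equal shape.
#' @return Numeric array `nrow x ncol x 3` (RGB in `[0, 1]`) with
#'   attributes `center_a`/`center_b`.
#' @export
two_band_overlay <- function(image_a, image_b) {
  a <- as.matrix(image_a); b <- as.matrix(image_b)
  if (!all(dim(a) == dim(b))) {
    stop("overlay images must have equal shapes", call. = FALSE)
  }
  A <- scale_unit(a); B <- scale_unit(b)
  out <- array(0, dim = c(nrow(a), ncol(a), 3L))
  out[, , 1L] <- A
  out[, , 2L] <- B
  out[, , 3L] <- A
  attr(out, "center_a") <- attr(image_a, "center")
  attr(out, "center_b") <- attr(image_b, "center")
  out
}

#' Center-crop an image to a target shape
#'
#' @param image Matrix or [band_image()].
#' @param shape Target `c(nrow, ncol)`, each no larger than the image.
#' @return The cropped object (attributes preserved for band images).
#' @export
center_crop <- function(image, shape) {
  shape <- as.integer(shape)
  if (any(shape > dim(image)) || any(shape < 1L)) {
    stop("crop shape must fit inside the image", call. = FALSE)
  }
  r0 <- (nrow(image) - shape[1L]) %/% 2L
  c0 <- (ncol(image) - shape[2L]) %/% 2L
  out <- image[r0 + seq_len(shape[1L]), c0 + seq_len(shape[2L]), drop = FALSE]
  if (inherits(image, "band_image")) {
    out <- band_image(out, attr(image, "center"), attr(image, "half_window"),
                      attr(image, "class_label"))
  }
  out
}

# ---- plain-text cube I/O ---------------------------------------------------

#' Write / read a hyperspectral cube as plain text
#'
#' Versioned whitespace format: a header with the dimensions, pitch and
#' class label, one line with the wavenumber axis, then one line of
#' channel intensities per pixel (pixels in column-major spatial order).
#' This text serialization stands in for an HDF5 container and is fully
#' round-trippable.
#'
#' @param cube A [hyper_cube()].
#' @param path File path.
#' @return `read_cube` returns a [hyper_cube()].
#' @export
write_cube <- function(cube, path) {
  d <- dim(cube$intensity)
  fmt <- function(x) paste(format(x, digits = 17, trim = TRUE,
                                  scientific = TRUE), collapse = " ")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("# lsrm-cube v1",
               paste("# dims:", d[1L], d[2L], d[3L]),
               paste("# pitch:", cube$pitch[1L], cube$pitch[2L]),
               paste("# class:", if (is.null(cube$class_label)) "NA" else
                 cube$class_label),
               fmt(cube$wavenumber)), con)
  M <- matrix(cube$intensity, nrow = d[1L] * d[2L])
  writeLines(vapply(seq_len(nrow(M)), function(i) fmt(M[i, ]), character(1L)),
             con)
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  lines <- readLines(path)
  if (lines[1L] != "# lsrm-cube v1") {
    stop("not an lsrm cube file: ", path, call. = FALSE)
  }
  d <- as.integer(strsplit(sub("# dims: ", "", lines[2L]), " ")[[1L]])
  pitch <- as.numeric(strsplit(sub("# pitch: ", "", lines[3L]), " ")[[1L]])
  cls <- sub("# class: ", "", lines[4L])
  if (cls == "NA") cls <- NULL
  wn <- as.numeric(strsplit(lines[5L], " ")[[1L]])
  M <- do.call(rbind, lapply(lines[-(1:5)], function(l) {
    as.numeric(strsplit(l, " ")[[1L]])
  }))
  hyper_cube(array(M, dim = d), wn, pitch, cls)
}

#' Render an image or RGB overlay to PNG
#'
#' The first cube axis (laser line, 5 um pitch) is rendered vertically.
#'
#' @param image A matrix (greyscale, min-max scaled for display) or an
#'   `nrow x ncol x 3` RGB array in `[0, 1]`.
#' @param path Output PNG path.
#' @param scale Pixel magnification (default 4).
#' @return `path`, invisibly.
#' @export
save_image_png <- function(image, path, scale = 4L) {
  rgb_arr <- if (length(dim(image)) == 3L) image else {
    g <- scale_unit(as.matrix(image))
    array(rep(g, 3L), dim = c(dim(g), 3L))
  }
  grDevices::png(path, width = ncol(rgb_arr) * scale,
                 height = nrow(rgb_arr) * scale)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  graphics::plot.new()
  graphics::rasterImage(grDevices::as.raster(rgb_arr), 0, 0, 1, 1,
                        interpolate = FALSE)
  invisible(path)
}
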