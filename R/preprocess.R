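#' Wavenumber-axis calibration from a reference peak table
#'
#' Fits a least-squares polynomial map from detector-pixel index to Raman
#' shift through reference pairs (as obtained from compounds with known
#' bands, e.g. DMSO and paracetamol) and evaluates it at every pixel.
#'
#' @param table Data frame with columns `pixel` (0-based detector index,
#'   distinct) and `wavenumber` (reference Raman shift, cm^-1).
#' @param n_pixels Number of detector pixels.
#' @param fit_degree Polynomial degree; must be smaller than the number of
#'   reference pairs.
#' @return List of class `axis_calibration`: `axis` (length `n_pixels`),
#'   `coefficients`, and `residuals` at the reference pairs.
#' @examples
#' cal <- calibrate_axis(data.frame(pixel = c(0, 1023),
#'                                  wavenumber = c(500, 3200)),
#'                       n_pixels = 1024, fit_degree = 1)
#' range(cal$axis)
#' @export
calibrate_axis <- function(table, n_pixels, fit_degree = 2L) {
  stopifnot(is.data.frame(table),
            all(c("pixel", "wavenumber") %in% names(table)))
  if (nrow(table) < 2L) stop("need at least 2 reference pairs", call. = FALSE)
  if (anyDuplicated(table$pixel)) {
    stop("reference pixel indices must be distinct", call. = FALSE)
  }
  if (fit_degree >= nrow(table)) {
    stop("`fit_degree` (", fit_degree, ") must be smaller than the number ",
         "of reference pairs (", nrow(table), ")", call. = FALSE)
  }
  X <- outer(table$pixel, 0:fit_degree, `^`)
  coefs <- qr.solve(X, table$wavenumber)
  pixels <- 0:(n_pixels - 1L)
  axis <- as.numeric(outer(pixels, 0:fit_degree, `^`) %*% coefs)
  structure(list(axis = axis,
                 coefficients = coefs,
                 residuals = table$wavenumber - as.numeric(X %*% coefs)),
            class = "axis_calibration")
}

#' Correct a spectrum for the system transmission function
#'
#' Divides intensities channel-wise by the per-channel optical
#' transmission/detection efficiency, undoing the wavelength-dependent
#' losses of the instrument.
#'
#' @param spectrum A [raman_spectrum()].
#' @param transmission Numeric vector of per-channel efficiencies in
#'   `(0, 1]`, same length as the spectrum; any value `<= 0` is rejected.
#' @return A corrected [raman_spectrum()].
#' @export
correct_transmission <- function(spectrum, transmission) {
  transmission <- as.numeric(transmission)
  if (length(transmission) != length(spectrum$wavenumber)) {
    stop("`transmission` must have one value per channel", call. = FALSE)
  }
  if (any(!is.finite(transmission)) || any(transmission <= 0)) {
    stop("all transmission values must be finite and > 0", call. = FALSE)
  }
  raman_spectrum(spectrum$wavenumber, spectrum$intensity / transmission)
}

#' Baseline-fit configuration
#'
#' @param degree Polynomial degree of the iterative fit (default 9).
#' @param max_iterations Iteration cap (default 100).
#' @param tolerance Convergence threshold on the maximum relative change of
#'   the fitted baseline between iterations (default 1e-6).
#' @return An object of class `baseline_config`.
#' @export
baseline_config <- function(degree = 9L, max_iterations = 100L,
                            tolerance = 1e-6) {
  if (degree < 0L) stop("`degree` must be >= 0", call. = FALSE)
  if (max_iterations < 1L) stop("`max_iterations` must be >= 1", call. = FALSE)
  if (tolerance <= 0) stop("`tolerance` must be > 0", call. = FALSE)
  structure(list(degree = as.integer(degree),
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance),
            class = "baseline_config")
}

# Batch engine for iterative modified-polyfit baseline estimation.
# Y: n_channels x n_spectra.  Each iteration fits a degree-d polynomial to
# the working signal (least squares via a fixed orthonormal basis), then
# replaces the working signal by the point-wise minimum of itself and the
# fit, driving the fit under the Raman peaks while tracking the smooth
# autofluorescence background.
fit_baseline_matrix <- function(Y, x, degree, max_iterations, tolerance) {
  n <- length(x)
  if (n <= degree + 1L) {
    stop("spectrum length (", n, ") must exceed degree + 1", call. = FALSE)
  }
  B <- if (degree == 0L) matrix(1, n, 1L) else cbind(1, stats::poly(x, degree))
  Q <- qr.Q(qr(B))
  nspec <- ncol(Y)
  baseline <- matrix(0, n, nspec)
  converged <- rep(FALSE, nspec)
  iterations <- rep(max_iterations, nspec)
  col_max <- function(M) {
    tM <- t(M)
    tM[cbind(seq_len(nrow(tM)), max.col(tM, ties.method = "first"))]
  }
  # The iteration is column-separable, so each column is frozen at its own
  # first passing convergence check; a column's trajectory is therefore
  # identical whether it runs alone or in a batch.  The (costly) check runs
  # every `check_every` iterations and always compares consecutive fits.
  check_every <- 5L
  active <- seq_len(nspec)
  W <- Y
  fit_old <- matrix(0, n, nspec)
  iter <- 0L
  while (length(active) > 0L) {
    iter <- iter + 1L
    fit <- Q %*% crossprod(Q, W[, active, drop = FALSE])
    if (iter %% check_every == 0L || iter >= max_iterations) {
      scale <- pmax(col_max(abs(fit)), .Machine$double.xmin)
      rel <- col_max(abs(fit - fit_old[, active, drop = FALSE])) / scale
      done <- rel < tolerance
      if (iter >= max_iterations) done <- rep(TRUE, length(active))
      if (any(done)) {
        baseline[, active[done]] <- fit[, done]
        converged[active[done]] <- rel[done] < tolerance
        iterations[active[done]] <- iter
        active <- active[!done]
        fit <- fit[, !done, drop = FALSE]
        if (length(active) == 0L) break
      }
    }
    fit_old[, active] <- fit
    W[, active] <- pmin(W[, active, drop = FALSE], fit)
  }
  list(baseline = baseline, converged = converged, iterations = iterations)
}

#' Remove the autofluorescence baseline by iterative polynomial fitting
#'
#' Modified-polyfit iteration: fit a degree-`degree` polynomial to the
#' working signal, replace the working signal by the point-wise minimum of
#' itself and the fit, and repeat until the fit changes by less than
#' `tolerance` (relative) or `max_iterations` is reached.  The converged
#' fit is subtracted from the input.
#'
#' @param spectrum A [raman_spectrum()].
#' @param config A [baseline_config()] (degree 9, tolerance 1e-6, at most
#'   100 iterations by default).
#' @return List of class `baseline_result`: `corrected` (a
#'   [raman_spectrum()]), `baseline` (numeric), `converged` (logical, also
#'   signalled by a warning when `FALSE`), `iterations`.
#' @export
remove_baseline <- function(spectrum, config = baseline_config()) {
  r <- fit_baseline_matrix(matrix(spectrum$intensity, ncol = 1L),
                           spectrum$wavenumber,
                           config$degree, config$max_iterations,
                           config$tolerance)
  if (!r$converged[1L]) {
    warning("baseline fit did not converge within ", config$max_iterations,
            " iterations", call. = FALSE)
  }
  structure(list(corrected = raman_spectrum(spectrum$wavenumber,
                                            spectrum$intensity - r$baseline[, 1L]),
                 baseline = r$baseline[, 1L],
                 converged = r$converged[1L],
                 iterations = r$iterations),
            class = "baseline_result")
}

# Savitzky-Golay smoothing operator as an n x n matrix: least-squares
# polynomial convolution in the interior, asymmetric full-window fits at
# the edges (so polynomials up to `order` are preserved exactly everywhere
# and the output length equals the input length).
sg_operator <- function(n, window, order) {
  h <- (window - 1L) %/% 2L
  S <- matrix(0, n, n)
  A <- outer(-h:h, 0:order, `^`)
  G <- solve(crossprod(A), t(A))       # (order+1) x window
  c0 <- G[1L, ]
  for (i in seq.int(h + 1L, n - h)) S[i, (i - h):(i + h)] <- c0
  Ae <- outer(0:(window - 1L), 0:order, `^`)
  Ge <- solve(crossprod(Ae), t(Ae))
  if (h > 0L) {
    for (i in seq_len(h)) {
      S[i, seq_len(window)] <- as.numeric(((i - 1)^(0:order)) %*% Ge)
    }
    for (i in seq.int(n - h + 1L, n)) {
      ti <- window - 1L - (n - i)
      S[i, seq.int(n - window + 1L, n)] <- as.numeric((ti^(0:order)) %*% Ge)
    }
  }
  S
}

#' Savitzky-Golay smoothing
#'
#' Standard Savitzky-Golay polynomial smoothing on a uniformly sampled
#' axis: a window of 21 points and a 3rd-order polynomial by default.
#' Output length equals input length; edge points use asymmetric
#' full-window fits, so polynomials up to `order` pass through unchanged.
#'
#' @param spectrum A [raman_spectrum()] on a (near-)uniform axis; a clearly
#'   non-uniform axis triggers a warning (see [preprocess_pipeline()]'s
#'   resampling flag).
#' @param window Odd window length (default 21).
#' @param order Polynomial order, `< window` (default 3).
#' @return A smoothed [raman_spectrum()].
#' @export
savitzky_golay <- function(spectrum, window = 21L, order = 3L) {
  window <- as.integer(window); order <- as.integer(order)
  if (window %% 2L == 0L) stop("`window` must be odd", call. = FALSE)
  if (order >= window) stop("`order` must be smaller than `window`", call. = FALSE)
  n <- length(spectrum$wavenumber)
  if (window > n) stop("`window` exceeds the number of channels", call. = FALSE)
  d <- diff(spectrum$wavenumber)
  if (n > 2L && (max(d) - min(d)) / mean(d) > 1e-6) {
    warning("axis is not uniform; Savitzky-Golay assumes uniform sampling",
            call. = FALSE)
  }
  S <- sg_operator(n, window, order)
  raman_spectrum(spectrum$wavenumber, as.numeric(S %*% spectrum$intensity))
}

#' Crop a spectrum to a set of wavenumber regions
#'
#' Drops every channel outside the union of the given closed intervals —
#' e.g. keep the fingerprint region (500-1700 cm^-1) and the CH-stretching
#' region (2800-3000 cm^-1) while discarding the silent region between.
#'
#' @param spectrum A [raman_spectrum()].
#' @param regions List of `c(lo, hi)` pairs in cm^-1, sorted and
#'   non-overlapping.
#' @return The cropped [raman_spectrum()]; an empty result is an error.
#' @export
crop_to_regions <- function(spectrum, regions) {
  keep <- region_mask(spectrum$wavenumber, regions)
  if (!any(keep)) stop("no channels fall inside the requested regions",
                       call. = FALSE)
  raman_spectrum(spectrum$wavenumber[keep], spectrum$intensity[keep])
}

region_mask <- function(wavenumber, regions) {
  if (is.matrix(regions)) regions <- split(regions, row(regions))
  stopifnot(is.list(regions), length(regions) >= 1L)
  bounds <- do.call(rbind, lapply(regions, function(r) {
    if (length(r) != 2L || r[1L] > r[2L]) {
      stop("each region must be c(lo, hi) with lo <= hi", call. = FALSE)
    }
    as.numeric(r)
  }))
  if (nrow(bounds) > 1L) {
    o <- order(bounds[, 1L])
    b <- bounds[o, , drop = FALSE]
    if (any(b[-1L, 1L] <= b[-nrow(b), 2L])) {
      stop("regions must be non-overlapping", call. = FALSE)
    }
  }
  Reduce(`|`, lapply(seq_len(nrow(bounds)), function(i) {
    wavenumber >= bounds[i, 1L] & wavenumber <= bounds[i, 2L]
  }))
}

#' 0-1 (min-max) normalization
#'
#' Rescales one spectrum to `(x - min) / (max - min)` so its minimum is 0
#' and maximum 1.  Normalization is per spectrum, the chemometric reading
#' of "0-1 normalization".
#'
#' @param spectrum A [raman_spectrum()].
#' @param constant_fallback If `TRUE`, a constant (zero-range) spectrum is
#'   returned as all zeros with attribute `constant_fallback = TRUE`
#'   instead of raising an error.
#' @return The normalized [raman_spectrum()].
#' @export
minmax_normalize <- function(spectrum, constant_fallback = FALSE) {
  rng <- range(spectrum$intensity)
  if (diff(rng) == 0) {
    if (!constant_fallback) {
      stop("constant spectrum has zero range; set `constant_fallback = TRUE` ",
           "for an all-zeros result", call. = FALSE)
    }
    out <- raman_spectrum(spectrum$wavenumber,
                          numeric(length(spectrum$wavenumber)))
    attr(out, "constant_fallback") <- TRUE
    return(out)
  }
  raman_spectrum(spectrum$wavenumber,
                 (spectrum$intensity - rng[1L]) / diff(rng))
}

# ---- batch pipeline --------------------------------------------------------

# Internal matrix pipeline shared by preprocess_pipeline / preprocess_set /
# preprocess_cube so the 1-spectrum and the batched paths are the same code.
# Y: n_spectra x n_channels.
preprocess_matrix <- function(Y, wavenumber, transmission = NULL,
                              baseline = baseline_config(),
                              sg_window = 21L, sg_order = 3L,
                              regions = list(c(500, 1700), c(2800, 3000)),
                              resample_uniform = TRUE,
                              constant_fallback = FALSE) {
  stages <- character(0L)
  if (resample_uniform && length(wavenumber) > 2L) {
    d <- diff(wavenumber)
    if ((max(d) - min(d)) / mean(d) > 1e-8) {
      grid <- seq(min(wavenumber), max(wavenumber), length.out = length(wavenumber))
      Y <- t(apply(Y, 1L, function(r) {
        stats::approx(wavenumber, r, xout = grid)$y
      }))
      wavenumber <- grid
      stages <- c(stages, "resample_uniform")
    }
  }
  if (!is.null(transmission)) {
    if (length(transmission) != length(wavenumber)) {
      stop("`transmission` must have one value per channel", call. = FALSE)
    }
    if (any(!is.finite(transmission)) || any(transmission <= 0)) {
      stop("all transmission values must be finite and > 0", call. = FALSE)
    }
    Y <- sweep(Y, 2L, transmission, `/`)
    stages <- c(stages, "transmission")
  }
  converged <- rep(TRUE, nrow(Y))
  if (!is.null(baseline)) {
    r <- fit_baseline_matrix(t(Y), wavenumber, baseline$degree,
                             baseline$max_iterations, baseline$tolerance)
    Y <- Y - t(r$baseline)
    converged <- r$converged
    stages <- c(stages, "baseline")
  }
  if (!is.null(sg_window)) {
    sg_window <- as.integer(sg_window); sg_order <- as.integer(sg_order)
    if (sg_window %% 2L == 0L) stop("`sg_window` must be odd", call. = FALSE)
    if (sg_order >= sg_window) stop("`sg_order` must be < `sg_window`", call. = FALSE)
    if (sg_window > ncol(Y)) stop("`sg_window` exceeds channel count", call. = FALSE)
    S <- sg_operator(ncol(Y), sg_window, sg_order)
    Y <- Y %*% t(S)
    stages <- c(stages, "savitzky_golay")
  }
  if (!is.null(regions)) {
    keep <- region_mask(wavenumber, regions)
    if (!any(keep)) stop("no channels fall inside the requested regions",
                         call. = FALSE)
    Y <- Y[, keep, drop = FALSE]
    wavenumber <- wavenumber[keep]
    stages <- c(stages, "crop")
  }
  lo <- apply(Y, 1L, min); hi <- apply(Y, 1L, max)
  flat <- hi - lo == 0
  if (any(flat) && !constant_fallback) {
    stop(sum(flat), " constant spectrum/spectra cannot be 0-1 normalized; ",
         "set `constant_fallback = TRUE`", call. = FALSE)
  }
  span <- ifelse(flat, 1, hi - lo)
  Y <- (Y - lo) / span
  Y[flat, ] <- 0
  stages <- c(stages, "normalize")
  list(intensity = Y, wavenumber = wavenumber, converged = converged,
       constant_fallback = flat, stages = stages)
}

#' Full spectral preprocessing pipeline
#'
#' Applies, in this fixed order: optional linear resampling to a uniform
#' axis, transmission correction, iterative polynomial baseline removal
#' (degree 9), Savitzky-Golay smoothing (window 21, order 3), cropping to
#' the analysis regions (fingerprint 500-1700 plus CH-stretching 2800-3000
#' cm^-1 by default; cropping sits before normalization so the 0-1 scale
#' reflects only retained channels), and per-spectrum 0-1 normalization.
#' Any stage can be disabled by passing `NULL` for its parameter.
#'
#' @param spectrum A [raman_spectrum()].
#' @param transmission Optional per-channel efficiency curve (`NULL` =
#'   identity).
#' @param baseline A [baseline_config()], or `NULL` to skip.
#' @param sg_window,sg_order Savitzky-Golay parameters; `sg_window = NULL`
#'   skips smoothing.
#' @param regions Crop regions as in [crop_to_regions()], or `NULL` for no
#'   cropping.
#' @param resample_uniform Linearly resample a non-uniform axis to a
#'   uniform grid before smoothing (default `TRUE`).
#' @param constant_fallback Passed to the normalization stage.
#' @return A [raman_spectrum()] with attributes `stages` (the applied-stage
#'   log), `baseline_converged` and `constant_fallback`.
#' @export
preprocess_pipeline <- function(spectrum, transmission = NULL,
                                baseline = baseline_config(),
                                sg_window = 21L, sg_order = 3L,
                                regions = list(c(500, 1700), c(2800, 3000)),
                                resample_uniform = TRUE,
                                constant_fallback = FALSE) {
  r <- preprocess_matrix(matrix(spectrum$intensity, nrow = 1L),
                         spectrum$wavenumber, transmission, baseline,
                         sg_window, sg_order, regions, resample_uniform,
                         constant_fallback)
  out <- raman_spectrum(r$wavenumber, r$intensity[1L, ])
  attr(out, "stages") <- r$stages
  attr(out, "baseline_converged") <- r$converged[1L]
  attr(out, "constant_fallback") <- r$constant_fallback[1L]
  out
}

#' Preprocess every spectrum of a labeled set
#'
#' Batched [preprocess_pipeline()] over the rows of a [labeled_spectra()];
#' parameters as there.
#'
#' @inheritParams preprocess_pipeline
#' @param set A [labeled_spectra()].
#' @return The preprocessed [labeled_spectra()] with attributes
#'   `baseline_converged` and `constant_fallback` (per-spectrum logicals).
#' @export
preprocess_set <- function(set, transmission = NULL,
                           baseline = baseline_config(),
                           sg_window = 21L, sg_order = 3L,
                           regions = list(c(500, 1700), c(2800, 3000)),
                           resample_uniform = TRUE,
                           constant_fallback = FALSE) {
  r <- preprocess_matrix(set$intensity, set$wavenumber, transmission,
                         baseline, sg_window, sg_order, regions,
                         resample_uniform, constant_fallback)
  out <- labeled_spectra(r$intensity, r$wavenumber, set$labels, set$biopsy_id)
  attr(out, "baseline_converged") <- r$converged
  attr(out, "constant_fallback") <- r$constant_fallback
  out
}

#' Read a transmission curve from a two-column CSV
#'
#' @param path CSV with columns `wavenumber,transmission`.
#' @param wavenumber Target axis; the curve is linearly interpolated onto
#'   it.
#' @return Numeric efficiency vector aligned with `wavenumber`.
#' @export
read_transmission_csv <- function(path, wavenumber) {
  d <- utils::read.csv(path)
  stats::approx(d[[1L]], d[[2L]], xout = wavenumber, rule = 2L)$y
}
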