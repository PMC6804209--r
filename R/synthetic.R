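#' The twelve diagnostic Raman band positions (cm^-1)
#'
#' Band centers with the largest loading on the first principal component of
#' pituitary-tissue Raman spectra: phosphatidylinositol (590), phenylalanine /
#' tyrosine (658, 1004), carbohydrates / glycogen / collagen (874, 1093),
#' protein and collagen backbone (939, 1254, 1331), lipids and proteins
#' (1445, 1663) and the CH2/CH3 stretching bands (2873, 2945).
#'
#' @export
raman_band_positions <- c(590, 658, 874, 939, 1004, 1093,
                          1254, 1331, 1445, 1663, 2873, 2945)

#' The seven tissue classes the pipeline discriminates
#' @export
tissue_classes <- c("gland", "corticotroph", "gonadotroph", "somatotroph",
                    "plurihormonal", "null_cell", "periosteal")

# Default FWHM (cm^-1) per band: fingerprint bands are narrow, the
# CH-stretching bands broad, as in tissue Raman spectra.
default_band_widths <- c(rep(14, 10), 35, 35)

#' Relative amplitude tiers per (class, band)
#'
#' One editable table encoding the qualitative class signatures: gland shows
#' every band (weaker below ~1100 cm^-1), every adenoma subtype lacks the
#' 1004 cm^-1 phenylalanine band, gonadotroph adenoma additionally lacks
#' 1093 cm^-1, and the collagen-rich periosteal layer lacks 590, 658, 1004
#' and 1093 cm^-1.  Non-zero values are stand-in tiers (low 0.15, small 0.3,
#' medium 0.6, strong 0.8, high 1.0), not measurements.
#'
#' @format A numeric matrix, classes in rows, band centers (cm^-1) in
#'   columns.
#' @export
class_band_tiers <- local({
  m <- rbind(
    gland         = c(0.3, 0.3, 0.3, 0.3, 1.0, 0.3, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0),
    corticotroph  = c(0.3, 0.3, 0.3, 0.3, 0.0, 0.3, 1.0, 1.0, 1.0, 1.0, 0.8, 0.8),
    gonadotroph   = c(0.3, 0.3, 0.3, 0.3, 0.0, 0.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0),
    somatotroph   = c(0.3, 0.3, 0.6, 0.3, 0.0, 0.3, 0.6, 0.6, 1.0, 1.0, 1.0, 1.0),
    plurihormonal = c(0.3, 0.3, 0.8, 0.6, 0.0, 0.6, 0.6, 1.0, 0.8, 0.6, 0.6, 1.0),
    null_cell     = c(0.15, 0.15, 0.15, 0.15, 0.0, 0.15, 0.6, 0.6, 1.0, 0.3, 1.0, 1.0),
    periosteal    = c(0.0, 0.0, 0.6, 1.0, 0.0, 0.0, 1.0, 1.0, 0.6, 0.6, 0.3, 0.6)
  )
  colnames(m) <- as.character(raman_band_positions)
  m
})

maybe_with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Band profile for one tissue class
#'
#' Draws the per-band peak amplitudes for a class: the documented tier value
#' times an independent log-normal jitter (sd `jitter_sd` on the log scale),
#' with the class-specific absent bands held at exactly zero.
#'
#' @param class_name One of [tissue_classes].
#' @param rng_seed Optional integer seed; identical seeds give identical
#'   profiles.  `NULL` uses (and advances) the current RNG state.
#' @param jitter_sd Log-scale standard deviation of the amplitude jitter
#'   (default 0.15).
#'
#' @return An object of class `band_profile`: list with `class_name` and a
#'   data frame `bands` (columns `center`, `amplitude`, `width`).
#' @examples
#' p <- make_class_profile("gonadotroph", rng_seed = 1)
#' subset(p$bands, amplitude == 0)$center  # 1004 and 1093 are absent
#' @export
make_class_profile <- function(class_name, rng_seed = NULL, jitter_sd = 0.15) {
  if (length(class_name) != 1L || !class_name %in% tissue_classes) {
    stop("unknown class '", paste(class_name, collapse = ","),
         "'; valid classes: ", paste(tissue_classes, collapse = ", "),
         call. = FALSE)
  }
  tiers <- class_band_tiers[class_name, ]
  amp <- maybe_with_seed(rng_seed, {
    jitter <- stats::rlnorm(length(tiers), meanlog = 0, sdlog = jitter_sd)
    tiers * jitter
  })
  amp[tiers == 0] <- 0  # stated absences are exact zeros, never jittered
  band_profile(class_name,
               data.frame(center = raman_band_positions,
                          amplitude = unname(amp),
                          width = default_band_widths))
}

#' @rdname make_class_profile
#' @param bands Data frame with columns `center`, `amplitude`, `width`
#'   (FWHM, cm^-1).
#' @export
band_profile <- function(class_name, bands) {
  stopifnot(is.data.frame(bands),
            all(c("center", "amplitude", "width") %in% names(bands)))
  if (any(bands$amplitude < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  if (nrow(bands) > 0L && any(bands$width <= 2 | bands$width >= 60)) {
    stop("band widths (FWHM) must lie in (2, 60) cm^-1", call. = FALSE)
  }
  structure(list(class_name = class_name, bands = bands),
            class = "band_profile")
}

#' @export
print.band_profile <- function(x, ...) {
  cat("<band_profile> class", x$class_name, "-", nrow(x$bands), "bands,",
      sum(x$bands$amplitude > 0), "present\n")
  invisible(x)
}

#' Synthetic-data configuration
#'
#' The stated world of the generator: a 500-3200 cm^-1 axis, a smooth
#' autofluorescence baseline at twice the tallest Raman peak, additive
#' Gaussian noise at 5% of the tallest peak, no cosmic spikes, and a
#' log-normal per-band amplitude jitter of 0.15.
#'
#' @param n_spectra_per_class Spectra drawn per tissue class (default 200).
#' @param axis `c(start, stop, step)` in cm^-1; must cover 500-3200.
#' @param baseline_kind `"polynomial"` (degree-5, positive coefficients in
#'   the reversed, i.e. decreasing, direction) or `"exponential-decay"`.
#' @param baseline_magnitude Baseline maximum relative to the tallest peak
#'   amplitude (default 2).
#' @param noise_sd Gaussian noise sd relative to the tallest peak
#'   amplitude (default 0.05); must be >= 0.
#' @param noise_model `"gaussian"` (default) or `"poisson"`.
#' @param cosmic_spike_rate Expected cosmic-ray spikes per spectrum
#'   (default 0).
#' @param jitter_sd Per-band log-normal amplitude jitter (default 0.15).
#' @param seed Integer seed making [simulate_labeled_dataset()] fully
#'   deterministic.
#'
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_spectra_per_class = 200L,
                             axis = c(500, 3200, 2),
                             baseline_kind = c("polynomial", "exponential-decay"),
                             baseline_magnitude = 2,
                             noise_sd = 0.05,
                             noise_model = c("gaussian", "poisson"),
                             cosmic_spike_rate = 0,
                             jitter_sd = 0.15,
                             seed = 1L) {
  baseline_kind <- match.arg(baseline_kind)
  noise_model <- match.arg(noise_model)
  if (length(axis) != 3L || axis[3L] <= 0) {
    stop("`axis` must be c(start, stop, step) with step > 0", call. = FALSE)
  }
  if (axis[1L] > 500 || axis[2L] < 3200) {
    stop("axis must cover at least 500-3200 cm^-1", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (cosmic_spike_rate < 0) stop("`cosmic_spike_rate` must be >= 0", call. = FALSE)
  if (n_spectra_per_class < 1L) stop("`n_spectra_per_class` must be >= 1", call. = FALSE)
  structure(list(n_spectra_per_class = as.integer(n_spectra_per_class),
                 axis = as.numeric(axis),
                 baseline_kind = baseline_kind,
                 baseline_magnitude = baseline_magnitude,
                 noise_sd = noise_sd,
                 noise_model = noise_model,
                 cosmic_spike_rate = cosmic_spike_rate,
                 jitter_sd = jitter_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

config_axis <- function(config) {
  seq(config$axis[1L], config$axis[2L], by = config$axis[3L])
}

# pseudo-Voigt line shape, unit height, fixed 0.5 Lorentzian fraction
pseudo_voigt <- function(x, center, fwhm, eta = 0.5) {
  hw <- fwhm / 2
  gauss <- exp(-log(2) * ((x - center) / hw)^2)
  lorentz <- 1 / (1 + ((x - center) / hw)^2)
  eta * lorentz + (1 - eta) * gauss
}

# n_bands x n_channels matrix of unit-height line shapes
peak_basis <- function(bands, wavenumber) {
  if (nrow(bands) == 0L) {
    return(matrix(0, nrow = 0L, ncol = length(wavenumber)))
  }
  t(vapply(seq_len(nrow(bands)),
           function(i) pseudo_voigt(wavenumber, bands$center[i], bands$width[i]),
           numeric(length(wavenumber))))
}

# deterministic smooth autofluorescence shape on [0, 1], max = 1.
# polynomial kind: degree-5 with positive coefficients in u = 1 - t so the
# baseline falls with wavenumber, as tissue autofluorescence does under
# 785 nm excitation.
baseline_shape <- function(wavenumber, kind) {
  t <- (wavenumber - min(wavenumber)) / diff(range(wavenumber))
  b <- switch(kind,
    "polynomial" = {
      u <- 1 - t
      0.35 + 0.25 * u + 0.2 * u^2 + 0.1 * u^3 + 0.06 * u^4 + 0.04 * u^5
    },
    "exponential-decay" = 0.15 + 0.85 * exp(-3 * t),
    stop("unknown baseline kind '", kind, "'", call. = FALSE))
  b / max(b)
}

#' Simulate one Raman spectrum
#'
#' Intensity is the sum of pseudo-Voigt peaks at the profile's band centers,
#' a smooth autofluorescence baseline scaled to
#' `baseline_magnitude * max(amplitude)`, and additive noise (Gaussian by
#' default, optional Poisson) scaled to `noise_sd * max(amplitude)`;
#' optional cosmic spikes are drawn Poisson(`cosmic_spike_rate`).  With a
#' peakless profile the noise/baseline reference scale is 1 count.
#'
#' @param profile A [band_profile()].
#' @param config A [synthetic_config()].
#' @param seed Optional integer seed for the noise draw; `NULL` uses the
#'   current RNG state.
#' @return A [raman_spectrum()].
#' @export
simulate_spectrum <- function(profile, config = synthetic_config(), seed = NULL) {
  wn <- config_axis(config)
  if (config$noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  basis <- peak_basis(profile$bands, wn)
  signal <- if (nrow(profile$bands) > 0L) {
    as.numeric(profile$bands$amplitude %*% basis)
  } else {
    numeric(length(wn))
  }
  ref <- max(profile$bands$amplitude, 0)
  if (ref == 0) ref <- 1
  base <- config$baseline_magnitude * ref * baseline_shape(wn, config$baseline_kind)
  if (config$baseline_magnitude == 0) base <- numeric(length(wn)) + 0
  y <- signal + base
  y <- maybe_with_seed(seed, {
    out <- if (config$noise_sd > 0) {
      if (config$noise_model == "gaussian") {
        y + stats::rnorm(length(y), sd = config$noise_sd * ref)
      } else {
        # Poisson on counts, scaled so the sd at the signal level ~ noise_sd*ref
        scale <- pmax(y, 0) / (config$noise_sd * ref)^2
        stats::rpois(length(y), pmax(scale, 0)) * (config$noise_sd * ref)^2
      }
    } else y
    if (config$cosmic_spike_rate > 0) {
      n_spikes <- stats::rpois(1L, config$cosmic_spike_rate)
      if (n_spikes > 0L) {
        pos <- sample.int(length(out), n_spikes, replace = TRUE)
        out[pos] <- out[pos] + (5 + stats::rexp(n_spikes, 1 / 5)) * ref
      }
    }
    out
  })
  raman_spectrum(wn, y)
}

#' Simulate a labeled multi-class dataset
#'
#' Draws `n_spectra_per_class` spectra for each of the seven tissue classes;
#' each spectrum gets a freshly jittered class profile, then baseline and
#' noise via [simulate_spectrum()].  Fully deterministic under
#' `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A [labeled_spectra()] with `7 * n_spectra_per_class` rows and a
#'   synthetic `biopsy_id` (three pseudo-biopsies per class).
#' @export
simulate_labeled_dataset <- function(config = synthetic_config()) {
  wn <- config_axis(config)
  n <- config$n_spectra_per_class
  maybe_with_seed(config$seed, {
    mats <- vector("list", length(tissue_classes))
    for (ci in seq_along(tissue_classes)) {
      cls <- tissue_classes[ci]
      m <- matrix(0, nrow = n, ncol = length(wn))
      for (i in seq_len(n)) {
        prof <- make_class_profile(cls, rng_seed = NULL,
                                   jitter_sd = config$jitter_sd)
        m[i, ] <- simulate_spectrum(prof, config, seed = NULL)$intensity
      }
      mats[[ci]] <- m
    }
    labels <- rep(tissue_classes, each = n)
    biopsy <- paste0(labels, "_b", rep(rep_len(1:3, n), times = length(tissue_classes)))
    labeled_spectra(do.call(rbind, mats), wn, labels, biopsy)
  })
}

#' Spatial concentration pattern for cube simulation
#'
#' Per-band 2D concentration fields in `[0, 1]` on a common grid
#' (`n_line_positions x n_scan_steps`).  Kinds: `"uniform"` (all 1),
#' `"two_compartment"` (bands in `bands_a` high on the left half of the
#' scan direction, bands in `bands_b` on the right — the anticorrelated
#' two-band layout seen in somatotroph adenoma), `"smooth_noise"`
#' (moving-average-smoothed random field, rescaled to `[0, 1]`).
#'
#' @param shape `c(n_line_positions, n_scan_steps)`.
#' @param bands Band centers (cm^-1) that need a map.
#' @param kind Pattern kind.
#' @param bands_a,bands_b Band subsets for `"two_compartment"`; bands in
#'   neither subset get a uniform map.
#' @param seed Optional seed for `"smooth_noise"`.
#' @return An object of class `spatial_pattern`: list with `shape` and a
#'   named list `maps` (one matrix per band).
#' @export
spatial_pattern <- function(shape, bands = raman_band_positions,
                            kind = c("uniform", "two_compartment", "smooth_noise"),
                            bands_a = 1331, bands_b = 1445, seed = NULL) {
  kind <- match.arg(kind)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, all(shape >= 1L))
  half <- function(side) {
    m <- matrix(0, shape[1L], shape[2L])
    mid <- shape[2L] %/% 2L
    if (side == "left") m[, seq_len(mid)] <- 1 else m[, (mid + 1L):shape[2L]] <- 1
    m
  }
  maps <- maybe_with_seed(seed, {
    lapply(bands, function(b) {
      switch(kind,
        uniform = matrix(1, shape[1L], shape[2L]),
        two_compartment = {
          if (b %in% bands_a) half("left")
          else if (b %in% bands_b) half("right")
          else matrix(1, shape[1L], shape[2L])
        },
        smooth_noise = {
          raw <- matrix(stats::runif(prod(shape)), shape[1L], shape[2L])
          sm <- smooth_field(raw, span = 5L)
          rng <- range(sm)
          if (diff(rng) == 0) matrix(1, shape[1L], shape[2L])
          else (sm - rng[1L]) / diff(rng)
        })
    })
  })
  names(maps) <- as.character(bands)
  ok <- vapply(maps, function(m) all(dim(m) == shape) &&
                 all(m >= 0 & m <= 1), logical(1L))
  if (!all(ok)) stop("every map must match `shape` with values in [0, 1]",
                     call. = FALSE)
  structure(list(shape = shape, maps = maps), class = "spatial_pattern")
}

# simple separable moving-average smoother with edge renormalization
smooth_field <- function(m, span = 5L) {
  k <- rep(1, span)
  sm_rows <- apply(m, 2L, function(col) {
    as.numeric(stats::filter(col, k / span, sides = 2L, circular = TRUE))
  })
  t(apply(sm_rows, 1L, function(row) {
    as.numeric(stats::filter(row, k / span, sides = 2L, circular = TRUE))
  }))
}

#' Simulate a hyperspectral cube
#'
#' Each pixel spectrum is a [simulate_spectrum()] draw whose band amplitudes
#' are scaled by that pixel's concentration-map values.  Default geometry
#' follows the line-scan acquisition: a 100 um laser line sampled at 5 um
#' (20 line positions) and 500 um of stage travel at 10 um steps (50 scan
#' steps).
#'
#' @param profile A [band_profile()]; every band with positive amplitude
#'   must have a map in `pattern`.
#' @param pattern A [spatial_pattern()].
#' @param config A [synthetic_config()] (axis, baseline, noise).
#' @param seed Optional integer seed.
#' @return A [hyper_cube()] with pitch `c(5, 10)` um and the profile's
#'   class label.
#' @export
simulate_cube <- function(profile, pattern, config = synthetic_config(),
                          seed = NULL) {
  shapes <- vapply(pattern$maps, dim, integer(2L))
  if (!all(shapes[1L, ] == pattern$shape[1L] & shapes[2L, ] == pattern$shape[2L])) {
    stop("all pattern maps must share `pattern$shape`", call. = FALSE)
  }
  present <- profile$bands$center[profile$bands$amplitude > 0]
  missing <- setdiff(as.character(present), names(pattern$maps))
  if (length(missing) > 0L) {
    stop("pattern lacks maps for bands: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  wn <- config_axis(config)
  ni <- pattern$shape[1L]; nj <- pattern$shape[2L]
  npix <- ni * nj
  basis <- peak_basis(profile$bands, wn)     # n_bands x n_channels
  conc <- vapply(seq_len(nrow(profile$bands)), function(bi) {
    b <- as.character(profile$bands$center[bi])
    m <- if (b %in% names(pattern$maps)) pattern$maps[[b]] else matrix(1, ni, nj)
    as.numeric(m) * profile$bands$amplitude[bi]
  }, numeric(npix))                          # npix x n_bands
  signal <- conc %*% basis                   # npix x n_channels
  ref <- max(profile$bands$amplitude, 0)
  if (ref == 0) ref <- 1
  base <- config$baseline_magnitude * ref * baseline_shape(wn, config$baseline_kind)
  y <- sweep(signal, 2L, base, `+`)
  y <- maybe_with_seed(seed, {
    if (config$noise_sd > 0) {
      y + matrix(stats::rnorm(length(y), sd = config$noise_sd * ref),
                 nrow = npix)
    } else y
  })
  hyper_cube(array(y, dim = c(ni, nj, length(wn))), wn,
             pitch = c(5, 10), class_label = profile$class_name)
}
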