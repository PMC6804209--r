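#' Raman spectrum container
#'
#' A single calibrated Raman spectrum: a strictly increasing wavenumber axis
#' (Raman shift, cm^-1) and one intensity value (counts) per channel.
#'
#' @param wavenumber Numeric vector of Raman shifts in cm^-1, strictly
#'   increasing, all finite.
#' @param intensity Numeric vector of intensities (counts), same length as
#'   `wavenumber`, all finite.
#'
#' @return An object of class `raman_spectrum`: a list with elements
#'   `wavenumber` and `intensity`.
#' @examples
#' s <- raman_spectrum(seq(500, 3200, by = 2), rnorm(1351))
#' s
#' @export
raman_spectrum <- function(wavenumber, intensity) {
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) != length(intensity)) {
    stop("`wavenumber` and `intensity` must have the same length (",
         length(wavenumber), " vs ", length(intensity), ")", call. = FALSE)
  }
  if (length(wavenumber) == 0L) {
    stop("spectrum must contain at least one channel", call. = FALSE)
  }
  if (!all(is.finite(wavenumber)) || !all(is.finite(intensity))) {
    stop("all wavenumbers and intensities must be finite", call. = FALSE)
  }
  if (length(wavenumber) > 1L && any(diff(wavenumber) <= 0)) {
    stop("`wavenumber` must be strictly increasing", call. = FALSE)
  }
  structure(list(wavenumber = wavenumber, intensity = intensity),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat("<raman_spectrum> ", length(x$wavenumber), " channels, ",
      format(min(x$wavenumber)), "-", format(max(x$wavenumber)),
      " cm^-1, intensity range [", format(min(x$intensity)), ", ",
      format(max(x$intensity)), "]\n", sep = "")
  invisible(x)
}

#' @export
length.raman_spectrum <- function(x) length(x$wavenumber)

as_intensity_matrix <- function(x) {
  # internal: accept raman_spectrum / labeled_spectra / plain matrix and
  # return list(intensity = n_spectra x n_channels matrix, wavenumber)
  if (inherits(x, "raman_spectrum")) {
    list(intensity = matrix(x$intensity, nrow = 1L), wavenumber = x$wavenumber)
  } else if (inherits(x, "labeled_spectra")) {
    list(intensity = x$intensity, wavenumber = x$wavenumber)
  } else if (is.matrix(x)) {
    list(intensity = x, wavenumber = NULL)
  } else {
    stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
         " as spectra", call. = FALSE)
  }
}

#' Labeled spectrum set
#'
#' A matrix of spectra sharing one wavenumber axis, with a tissue-class label
#' per spectrum and an optional biopsy identifier (used for grouped holdout
#' splitting).
#'
#' @param intensity Numeric matrix, `n_spectra x n_channels`.
#' @param wavenumber Numeric vector of length `n_channels`, strictly
#'   increasing.
#' @param labels Character (or factor) vector of class labels, length
#'   `n_spectra`.
#' @param biopsy_id Optional vector of biopsy identifiers, length
#'   `n_spectra`.
#'
#' @return An object of class `labeled_spectra`.
#' @export
labeled_spectra <- function(intensity, wavenumber, labels, biopsy_id = NULL) {
  intensity <- as.matrix(intensity)
  wavenumber <- as.numeric(wavenumber)
  labels <- as.character(labels)
  if (ncol(intensity) != length(wavenumber)) {
    stop("ncol(intensity) must equal length(wavenumber)", call. = FALSE)
  }
  if (nrow(intensity) != length(labels)) {
    stop("one label per spectrum required (", nrow(intensity), " spectra, ",
         length(labels), " labels)", call. = FALSE)
  }
  if (length(wavenumber) > 1L && any(diff(wavenumber) <= 0)) {
    stop("`wavenumber` must be strictly increasing", call. = FALSE)
  }
  if (!all(is.finite(intensity))) {
    stop("all intensities must be finite", call. = FALSE)
  }
  if (!is.null(biopsy_id) && length(biopsy_id) != nrow(intensity)) {
    stop("`biopsy_id` must have one entry per spectrum", call. = FALSE)
  }
  structure(list(intensity = intensity, wavenumber = wavenumber,
                 labels = labels, biopsy_id = biopsy_id),
            class = "labeled_spectra")
}

#' @export
print.labeled_spectra <- function(x, ...) {
  cat("<labeled_spectra> ", nrow(x$intensity), " spectra x ",
      ncol(x$intensity), " channels\n", sep = "")
  print(table(x$labels))
  invisible(x)
}

#' Number of spectra in a labeled set
#' @param set A `labeled_spectra` object.
#' @return Integer count of spectra.
#' @export
n_spectra <- function(set) nrow(set$intensity)

#' Subset a labeled spectrum set by spectrum index
#' @param set A `labeled_spectra` object.
#' @param idx Integer or logical index over spectra.
#' @return A `labeled_spectra` with the selected spectra.
#' @export
subset_spectra <- function(set, idx) {
  labeled_spectra(set$intensity[idx, , drop = FALSE], set$wavenumber,
                  set$labels[idx],
                  if (!is.null(set$biopsy_id)) set$biopsy_id[idx])
}

# ---- CSV I/O ---------------------------------------------------------------

#' Read / write a single spectrum as two-column CSV
#'
#' The file holds columns `wavenumber,intensity`.
#'
#' @param path File path.
#' @return `read_spectrum_csv` returns a [raman_spectrum()].
#' @export
read_spectrum_csv <- function(path) {
  d <- utils::read.csv(path)
  raman_spectrum(d[[1L]], d[[2L]])
}

#' @rdname read_spectrum_csv
#' @param spectrum A `raman_spectrum`.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(data.frame(wavenumber = spectrum$wavenumber,
                              intensity = spectrum$intensity),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read / write a labeled spectrum set as CSV
#'
#' Layout: column 1 is the wavenumber axis, one column per spectrum; the
#' header row carries the class labels (optionally `label#biopsy` when a
#' biopsy identifier is present).
#'
#' @param path File path.
#' @return `read_labeled_csv` returns a [labeled_spectra()].
#' @export
read_labeled_csv <- function(path) {
  header <- strsplit(readLines(path, n = 1L), ",")[[1L]]
  d <- utils::read.csv(path, check.names = FALSE)
  labs <- header[-1L]
  has_biopsy <- grepl("#", labs, fixed = TRUE)
  biopsy <- NULL
  if (any(has_biopsy)) {
    parts <- strsplit(labs, "#", fixed = TRUE)
    biopsy <- vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else NA_character_,
                     character(1L))
    labs <- vapply(parts, `[[`, character(1L), 1L)
  }
  labeled_spectra(t(as.matrix(d[, -1L, drop = FALSE])), d[[1L]], labs, biopsy)
}

#' @rdname read_labeled_csv
#' @param set A `labeled_spectra`.
#' @export
write_labeled_csv <- function(set, path) {
  labs <- set$labels
  if (!is.null(set$biopsy_id)) labs <- paste0(labs, "#", set$biopsy_id)
  header <- paste(c("wavenumber", labs), collapse = ",")
  body <- cbind(set$wavenumber, t(set$intensity))
  lines <- apply(body, 1L, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                    scientific = FALSE),
                                             collapse = ","))
  writeLines(c(header, lines), path)
  invisible(path)
}
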