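#' Full-run configuration
#'
#' Collects every tunable of an end-to-end synthetic run: generator
#' settings, preprocessing, PCA variance threshold, kNN and holdout
#' settings, bands of interest and texture parameters.  Validated on
#' construction and serialized verbatim into the output directory by
#' [run_full_analysis()].
#'
#' @param n_spectra_per_class Spectra per class for the classification
#'   stage (default 200).
#' @param noise_sd,baseline_magnitude,jitter_sd Generator settings, see
#'   [synthetic_config()].
#' @param axis Generator axis `c(start, stop, step)`.
#' @param variance_threshold PCA cumulative-variance threshold (default
#'   0.95).
#' @param k Neighbor count (default 1).
#' @param holdout_fraction Held-out fraction (default 0.25).
#' @param split_level `"spectrum"` or `"biopsy"`.
#' @param bands Bands of interest (default [raman_band_positions]).
#' @param n_levels GLCM grey levels (default 8).
#' @param half_window Band-image extraction half-window, cm^-1 (default 5).
#' @param imaging_classes Classes imaged as cubes (default: the six
#'   classes with representative images — all but plurihormonal).
#' @param cube_shape Cube spatial shape (default `c(20, 50)`: a 100 um
#'   line at 5 um pitch by 500 um travel at 10 um steps).
#' @param overlay_bands The two bands of the pseudo-color overlay
#'   (default 1331 and 1445 cm^-1).
#' @param classify,imaging Enable/disable the two stages.
#' @param seed Master seed; every random draw of the run derives from it.
#' @param out_dir Optional output directory for report files.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_spectra_per_class = 200L,
                       noise_sd = 0.05,
                       baseline_magnitude = 2,
                       jitter_sd = 0.15,
                       axis = c(500, 3200, 2),
                       variance_threshold = 0.95,
                       k = 1L,
                       holdout_fraction = 0.25,
                       split_level = c("spectrum", "biopsy"),
                       bands = raman_band_positions,
                       n_levels = 8L,
                       half_window = 5,
                       imaging_classes = c("gland", "corticotroph",
                                           "gonadotroph", "somatotroph",
                                           "null_cell", "periosteal"),
                       cube_shape = c(20L, 50L),
                       overlay_bands = c(1331, 1445),
                       classify = TRUE,
                       imaging = TRUE,
                       seed = 1L,
                       out_dir = NULL) {
  split_level <- match.arg(split_level)
  if (variance_threshold <= 0 || variance_threshold > 1) {
    stop("`variance_threshold` must lie in (0, 1]", call. = FALSE)
  }
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    stop("`holdout_fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  bad <- setdiff(imaging_classes, tissue_classes)
  if (length(bad) > 0L) {
    stop("unknown imaging classes: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(n_spectra_per_class = as.integer(n_spectra_per_class),
                 noise_sd = noise_sd, baseline_magnitude = baseline_magnitude,
                 jitter_sd = jitter_sd, axis = as.numeric(axis),
                 variance_threshold = variance_threshold, k = as.integer(k),
                 holdout_fraction = holdout_fraction, split_level = split_level,
                 bands = as.numeric(bands), n_levels = as.integer(n_levels),
                 half_window = half_window,
                 imaging_classes = imaging_classes,
                 cube_shape = as.integer(cube_shape),
                 overlay_bands = as.numeric(overlay_bands),
                 classify = isTRUE(classify), imaging = isTRUE(imaging),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

# deterministic sub-seed derivation, kept well below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483629)
}

#' Run the full synthetic analysis
#'
#' Executes the study workflow end to end on synthetic data: simulate a
#' labeled dataset, preprocess, PCA at the variance threshold, 1-NN with
#' stratified holdout, then per-class cube simulation, band imaging, GLCM
#' texture summary, the class-vs-gland correlation matrix and the
#' two-band overlay.  Fully deterministic under `config$seed`.  When
#' `config$out_dir` is set, the report (JSON), confusion matrix and
#' texture/correlation tables (CSV) and the effective config are written
#' there.
#'
#' @param config A [run_config()].
#' @return An object of class `lsrm_run`: list with `classification`
#'   (a `classification_report`, plus `n_components`), `texture`
#'   (data frame), `correlation` (matrix), `overlay` (RGB array), and
#'   `config`.
#' @export
run_full_analysis <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out <- list(config = config)

  if (config$classify) {
    sim_cfg <- synthetic_config(n_spectra_per_class = config$n_spectra_per_class,
                                axis = config$axis,
                                baseline_magnitude = config$baseline_magnitude,
                                noise_sd = config$noise_sd,
                                jitter_sd = config$jitter_sd,
                                seed = derive_seed(config$seed, 1L))
    dataset <- simulate_labeled_dataset(sim_cfg)
    pre <- preprocess_set(dataset)
    split <- stratified_holdout_split(pre, fraction = config$holdout_fraction,
                                      level = config$split_level,
                                      seed = derive_seed(config$seed, 2L))
    pca <- fit_pca(split$train)
    ncomp <- n_components_for_variance(pca, config$variance_threshold)
    train_scores <- project(pca, split$train, ncomp)
    test_scores <- project(pca, split$test, ncomp)
    model <- knn_model(train_scores, split$train$labels, k = config$k)
    pred <- knn_classify(model, test_scores)
    report <- evaluate(split$test$labels, pred, split)
    report$n_components <- ncomp
    out$classification <- report
  }

  if (config$imaging) {
    img_cfg <- synthetic_config(axis = config$axis,
                                baseline_magnitude = config$baseline_magnitude,
                                noise_sd = config$noise_sd,
                                jitter_sd = config$jitter_sd,
                                seed = derive_seed(config$seed, 3L))
    images <- list()
    nested <- list()
    for (ci in seq_along(config$imaging_classes)) {
      cls <- config$imaging_classes[ci]
      prof <- make_class_profile(cls, rng_seed = derive_seed(config$seed, 10L + ci),
                                 jitter_sd = config$jitter_sd)
      # somatotroph carries the anticorrelated two-compartment layout the
      # overlay illustrates; other classes get smooth concentration fields
      pattern <- if (cls == "somatotroph") {
        spatial_pattern(config$cube_shape, config$bands, "two_compartment",
                        bands_a = config$overlay_bands[1L],
                        bands_b = config$overlay_bands[2L])
      } else {
        spatial_pattern(config$cube_shape, config$bands, "smooth_noise",
                        seed = derive_seed(config$seed, 20L + ci))
      }
      cube <- simulate_cube(prof, pattern, img_cfg,
                            seed = derive_seed(config$seed, 30L + ci))
      cube <- preprocess_cube(cube, constant_fallback = TRUE)
      cls_imgs <- lapply(config$bands, function(b) {
        extract_band_image(cube, b, config$half_window)
      })
      names(cls_imgs) <- as.character(config$bands)
      nested[[cls]] <- cls_imgs
      images <- c(images, cls_imgs)
      if (cls == "somatotroph") {
        out$overlay <- two_band_overlay(
          cls_imgs[[as.character(config$overlay_bands[1L])]],
          cls_imgs[[as.character(config$overlay_bands[2L])]])
      }
    }
    out$texture <- class_texture_summary(images, n_levels = config$n_levels)
    ref <- if ("gland" %in% names(nested)) "gland" else names(nested)[1L]
    out$correlation <- class_band_correlation_matrix(nested, reference = ref)
  }

  out <- structure(out, class = "lsrm_run")
  if (!is.null(config$out_dir)) write_run_outputs(out, config$out_dir)
  out
}

write_run_outputs <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- run$config
  cfg$out_dir <- NULL
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(run$classification)) {
    rep <- run$classification
    jsonlite::write_json(list(overall_accuracy = rep$overall_accuracy,
                              per_class_accuracy = as.list(rep$per_class_accuracy),
                              n_components = rep$n_components,
                              n = rep$n, split = rep$split),
                         file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(as.data.frame.matrix(rep$confusion),
                     file.path(dir, "confusion.csv"))
  }
  if (!is.null(run$texture)) {
    utils::write.csv(run$texture, file.path(dir, "texture.csv"),
                     row.names = FALSE)
  }
  if (!is.null(run$correlation)) {
    utils::write.csv(run$correlation, file.path(dir, "correlation.csv"))
  }
  if (!is.null(run$overlay)) {
    save_image_png(run$overlay, file.path(dir, "overlay.png"))
  }
  invisible(dir)
}

#' @export
print.lsrm_run <- function(x, ...) {
  cat("<lsrm_run>\n")
  if (!is.null(x$classification)) {
    cat(sprintf("  classification: overall accuracy %.3f with %d components\n",
                x$classification$overall_accuracy,
                x$classification$n_components))
  }
  if (!is.null(x$texture)) {
    cat("  texture summary:", nrow(x$texture), "(class, band) rows\n")
  }
  if (!is.null(x$correlation)) {
    cat("  correlation matrix:", nrow(x$correlation), "classes x",
        ncol(x$correlation), "bands\n")
  }
  invisible(x)
}

#' Generate deterministic on-disk fixtures
#'
#' Small labeled-spectra CSV or plain-text cube files for tests and
#' examples; identical `(kind, size, seed)` always produce byte-identical
#' files.
#'
#' @param kind `"spectra"` or `"cube"`.
#' @param size `"small"` (7 x 20 spectra on a 4 cm^-1 axis; 20 x 50 cube
#'   on an 8 cm^-1 axis) or `"medium"` (7 x 50 spectra at 2 cm^-1;
#'   20 x 50 cube at 4 cm^-1).
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @return The written file path.
#' @export
generate_fixture <- function(kind = c("spectra", "cube"),
                             size = c("small", "medium"),
                             seed = 1L, dir = tempdir()) {
  kind <- match.arg(kind); size <- match.arg(size)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (kind == "spectra") {
    n <- if (size == "small") 20L else 50L
    step <- if (size == "small") 4 else 2
    cfg <- synthetic_config(n_spectra_per_class = n, axis = c(500, 3200, step),
                            seed = as.integer(seed))
    path <- file.path(dir, sprintf("spectra_%s_seed%d.csv", size, seed))
    write_labeled_csv(simulate_labeled_dataset(cfg), path)
  } else {
    step <- if (size == "small") 8 else 4
    cfg <- synthetic_config(axis = c(500, 3200, step), seed = as.integer(seed))
    prof <- make_class_profile("somatotroph", rng_seed = as.integer(seed))
    pattern <- spatial_pattern(c(20L, 50L), raman_band_positions,
                               "two_compartment")
    cube <- simulate_cube(prof, pattern, cfg, seed = as.integer(seed))
    path <- file.path(dir, sprintf("cube_%s_seed%d.txt", size, seed))
    write_cube(cube, path)
  }
  path
}
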