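# shared fixtures, built in code

# compact generator settings for fast tests: coarse 4 cm^-1 axis
tiny_config <- function(n = 10L, noise_sd = 0.05, seed = 1L, ...) {
  synthetic_config(n_spectra_per_class = n, axis = c(500, 3200, 4),
                   noise_sd = noise_sd, seed = seed, ...)
}

# one small preprocessed labeled set reused across chemometrics tests
tiny_preprocessed <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- preprocess_set(simulate_labeled_dataset(tiny_config(n = 12L)))
    }
    cache
  }
})

# full classify pipeline on synthetic data; returns the overall accuracy
holdout_accuracy <- function(seed, n_per_class, noise_sd = 0.05,
                             axis = c(500, 3200, 2)) {
  cfg <- synthetic_config(n_spectra_per_class = n_per_class, axis = axis,
                          noise_sd = noise_sd, seed = seed)
  pre <- preprocess_set(simulate_labeled_dataset(cfg))
  sp <- stratified_holdout_split(pre, 0.25, seed = seed + 10000L)
  pca <- fit_pca(sp$train)
  nc <- n_components_for_variance(pca, 0.95)
  model <- knn_model(project(pca, sp$train, nc), sp$train$labels)
  pred <- knn_classify(model, project(pca, sp$test, nc))
  evaluate(sp$test$labels, pred)$overall_accuracy
}

# brute-force GLCM oracle: explicit loop over pixel pairs
oracle_glcm <- function(qimage, offset, n_levels) {
  G <- matrix(0, n_levels, n_levels)
  nr <- nrow(qimage); nc <- ncol(qimage)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + offset[1L]; c2 <- c + offset[2L]
    if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc) {
      G[qimage[r, c], qimage[r2, c2]] <- G[qimage[r, c], qimage[r2, c2]] + 1
    }
  }
  G
}

# brute-force Haralick oracle: explicit loops over the normalized GLCM
oracle_haralick <- function(p) {
  L <- nrow(p)
  contrast <- 0; energy <- 0; homog <- 0
  mu_i <- 0; mu_j <- 0
  for (i in 1:L) for (j in 1:L) {
    contrast <- contrast + p[i, j] * (i - j)^2
    energy <- energy + p[i, j]^2
    homog <- homog + p[i, j] / (1 + abs(i - j))
    mu_i <- mu_i + i * p[i, j]
    mu_j <- mu_j + j * p[i, j]
  }
  v_i <- 0; v_j <- 0; cov <- 0
  for (i in 1:L) for (j in 1:L) {
    v_i <- v_i + (i - mu_i)^2 * p[i, j]
    v_j <- v_j + (j - mu_j)^2 * p[i, j]
    cov <- cov + (i - mu_i) * (j - mu_j) * p[i, j]
  }
  corr <- if (v_i * v_j == 0) NA_real_ else cov / sqrt(v_i * v_j)
  list(contrast = contrast, correlation = corr, energy = energy,
       homogeneity = homog)
}
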