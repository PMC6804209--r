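#' Principal component analysis of a spectrum set
#'
#' Mean-centered PCA (no scaling) of the preprocessed intensity matrix.
#' Loadings are orthonormal; explained-variance ratios are reported in
#' descending order.  For reproducible score signs each loading is flipped
#' so its largest-magnitude coefficient is positive.
#'
#' @param x A [labeled_spectra()] or a numeric matrix
#'   (`n_spectra x n_channels`) with at least 2 rows.
#' @return An object of class `raman_pca`: `mean`, `loadings`
#'   (`n_channels x n_components`), `sdev`, `variance_ratio`.
#' @export
fit_pca <- function(x) {
  X <- as_intensity_matrix(x)$intensity
  if (nrow(X) < 2L) stop("PCA needs at least 2 spectra", call. = FALSE)
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  L <- pr$rotation
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  v <- pr$sdev^2
  structure(list(mean = pr$center,
                 loadings = L,
                 sdev = pr$sdev,
                 variance_ratio = v / sum(v)),
            class = "raman_pca")
}

#' @export
print.raman_pca <- function(x, ...) {
  cat("<raman_pca> ", ncol(x$loadings), " components over ",
      length(x$mean), " channels; leading variance ratios: ",
      paste(sprintf("%.3f", utils::head(x$variance_ratio, 5L)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Number of components reaching a cumulative variance threshold
#'
#' @param model A `raman_pca` model, or a numeric vector of explained
#'   variance ratios.
#' @param threshold Cumulative explained-variance fraction in `(0, 1]`
#'   (default 0.95).
#' @return The smallest component count whose cumulative ratio reaches the
#'   threshold.
#' @examples
#' n_components_for_variance(c(0.76, 0.07, 0.03, 0.14), 0.76)  # 1
#' @export
n_components_for_variance <- function(model, threshold = 0.95) {
  if (threshold <= 0 || threshold > 1) {
    stop("`threshold` must lie in (0, 1]", call. = FALSE)
  }
  ratios <- if (inherits(model, "raman_pca")) model$variance_ratio else
    as.numeric(model)
  hit <- which(cumsum(ratios) >= threshold - 1e-9)
  if (length(hit) == 0L) length(ratios) else hit[1L]
}

#' Project spectra onto PCA components
#'
#' Centers the data with the model mean and multiplies by the loadings;
#' projecting the training mean itself gives the all-zero score.
#'
#' @param model A `raman_pca` model.
#' @param x A [raman_spectrum()], [labeled_spectra()] or matrix with the
#'   model's channel count.
#' @param n_components Number of leading components to keep (default all).
#' @return Score matrix (`n_spectra x n_components`).
#' @export
project <- function(model, x, n_components = ncol(model$loadings)) {
  X <- as_intensity_matrix(x)$intensity
  if (ncol(X) != length(model$mean)) {
    stop("channel count (", ncol(X), ") does not match the PCA model (",
         length(model$mean), ")", call. = FALSE)
  }
  n_components <- min(n_components, ncol(model$loadings))
  sweep(X, 2L, model$mean) %*% model$loadings[, seq_len(n_components), drop = FALSE]
}

#' Reconstruct spectra from PCA scores
#'
#' @param model A `raman_pca` model.
#' @param scores Score matrix from [project()].
#' @return Reconstructed intensity matrix.
#' @export
reconstruct <- function(model, scores) {
  scores <- as.matrix(scores)
  sweep(scores %*% t(model$loadings[, seq_len(ncol(scores)), drop = FALSE]),
        2L, model$mean, `+`)
}

#' Stratified holdout split
#'
#' Splits a labeled set into train and test partitions holding out
#' `fraction` of the units per class, where a unit is either a single
#' spectrum (default) or a whole biopsy (grouped split, so no biopsy leaks
#' across partitions).  Reproducible under `seed`.
#'
#' @param set A [labeled_spectra()].
#' @param fraction Held-out fraction per class (default 0.25).
#' @param level `"spectrum"` or `"biopsy"`.
#' @param seed Optional integer seed.
#' @return List of class `holdout_split`: `train`, `test`
#'   ([labeled_spectra()]), `test_idx`, plus the split metadata.
#' @export
stratified_holdout_split <- function(set, fraction = 0.25,
                                     level = c("spectrum", "biopsy"),
                                     seed = NULL) {
  level <- match.arg(level)
  if (fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  classes <- unique(set$labels)
  test_idx <- maybe_with_seed(seed, {
    unlist(lapply(classes, function(cl) {
      idx <- which(set$labels == cl)
      if (level == "spectrum") {
        if (length(idx) < 2L) {
          stop("class '", cl, "' has fewer than 2 spectra", call. = FALSE)
        }
        n_test <- max(1L, min(length(idx) - 1L, round(fraction * length(idx))))
        sample(idx, n_test)
      } else {
        ids <- unique(set$biopsy_id[idx])
        if (is.null(set$biopsy_id) || length(ids) < 2L) {
          stop("class '", cl, "' has fewer than 2 biopsies; a biopsy-level ",
               "split needs at least 2 per class", call. = FALSE)
        }
        n_test <- max(1L, min(length(ids) - 1L, round(fraction * length(ids))))
        held <- sample(ids, n_test)
        idx[set$biopsy_id[idx] %in% held]
      }
    }))
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(n_spectra(set)), test_idx)
  structure(list(train = subset_spectra(set, train_idx),
                 test = subset_spectra(set, test_idx),
                 test_idx = test_idx,
                 fraction = fraction, level = level, seed = seed),
            class = "holdout_split")
}

#' k-nearest-neighbor model on PCA scores
#'
#' "Fine" kNN as used for tissue classification: `k = 1`, Euclidean
#' distance, equal weights.  At an exact distance tie the label of the
#' lowest training index wins (documented deterministic rule).
#'
#' @param scores Training score matrix (`n_train x n_components`).
#' @param labels Training labels, one per row.
#' @param k Neighbor count (default 1; must satisfy `1 <= k <= n_train`).
#' @return An object of class `knn_model`.
#' @export
knn_model <- function(scores, labels, k = 1L) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  if (nrow(scores) == 0L) stop("empty training set", call. = FALSE)
  if (nrow(scores) != length(labels)) {
    stop("one label per training score required", call. = FALSE)
  }
  if (k < 1L || k > nrow(scores)) {
    stop("`k` must lie in [1, n_train]", call. = FALSE)
  }
  structure(list(scores = scores, labels = labels, k = as.integer(k),
                 metric = "euclidean", weights = "equal"),
            class = "knn_model")
}

#' Classify query scores with a kNN model
#'
#' @param model A [knn_model()].
#' @param query Query score matrix (or vector for a single query) with the
#'   model's column count.
#' @return Character vector of predicted labels.
#' @export
knn_classify <- function(model, query) {
  if (is.null(dim(query))) query <- matrix(query, nrow = 1L)
  query <- as.matrix(query)
  if (ncol(query) != ncol(model$scores)) {
    stop("query dimension (", ncol(query), ") does not match training scores (",
         ncol(model$scores), ")", call. = FALSE)
  }
  d2 <- outer(rowSums(query^2), rep(1, nrow(model$scores))) +
    outer(rep(1, nrow(query)), rowSums(model$scores^2)) -
    2 * tcrossprod(query, model$scores)
  if (model$k == 1L) {
    # max.col with ties.method "first" realizes the lowest-index tie rule
    return(model$labels[max.col(-d2, ties.method = "first")])
  }
  apply(d2, 1L, function(row) {
    nb <- order(row)[seq_len(model$k)]
    votes <- table(factor(model$labels[nb], levels = unique(model$labels)))
    winners <- names(votes)[votes == max(votes)]
    if (length(winners) == 1L) return(winners)
    # tied vote: the winner containing the lowest training index
    first_of <- vapply(winners, function(w) min(nb[model$labels[nb] == w]),
                       numeric(1L))
    winners[which.min(first_of)]
  })
}

#' Evaluate predictions against ground truth
#'
#' Builds the confusion matrix and reports per-class accuracy (class
#' recall: correct members / class size) and overall accuracy
#' (trace / total).
#'
#' @param truth True labels.
#' @param predicted Predicted labels, same length.
#' @param split Optional [stratified_holdout_split()] whose metadata is
#'   recorded in the report.
#' @return An object of class `classification_report`: `confusion`
#'   (true x predicted), `per_class_accuracy`, `overall_accuracy`, `n`,
#'   `split`.
#' @export
evaluate <- function(truth, predicted, split = NULL) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop("`truth` and `predicted` must have equal length", call. = FALSE)
  }
  if (length(truth) == 0L) stop("nothing to evaluate", call. = FALSE)
  if (!any(predicted %in% truth)) {
    stop("predicted label set is disjoint from the true classes", call. = FALSE)
  }
  levels <- sort(unique(c(truth, predicted)))
  cm <- table(factor(truth, levels = levels),
              factor(predicted, levels = levels),
              dnn = c("true", "predicted"))
  per_class <- diag(cm) / rowSums(cm)
  per_class <- per_class[rowSums(cm) > 0]
  meta <- if (is.null(split)) NULL else
    list(fraction = split$fraction, level = split$level, seed = split$seed)
  structure(list(confusion = cm,
                 per_class_accuracy = per_class,
                 overall_accuracy = sum(diag(cm)) / sum(cm),
                 n = length(truth),
                 split = meta),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report> n =", x$n, "\n")
  cat("overall accuracy:", sprintf("%.3f", x$overall_accuracy), "\n")
  cat("per-class accuracy (recall):\n")
  print(round(x$per_class_accuracy, 3L))
  cat("confusion matrix (true x predicted):\n")
  print(x$confusion)
  invisible(x)
}
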