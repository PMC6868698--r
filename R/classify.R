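#' Classifier configuration
#'
#' Settings for the pair classifier consuming the encoder's feature vectors.
#' The primary backend is a random forest; an SVM (RBF or linear kernel,
#' probability outputs) is available as a comparator.
#'
#' @param backend `"random_forest"` (default) or `"svm"`.
#' @param n_trees Number of trees (default 500).
#' @param max_depth Optional depth cap via `randomForest`'s `maxnodes`
#'   (`NULL` = unlimited).
#' @param svm_kernel `"rbf"` (default) or `"linear"`.
#' @param svm_cost SVM cost parameter C (default 1).
#' @return A list of class `"classifier_config"`.
#' @export
classifier_config <- function(backend = c("random_forest", "svm"),
                              n_trees = 500L, max_depth = NULL,
                              svm_kernel = c("rbf", "linear"), svm_cost = 1) {
  backend <- match.arg(backend)
  svm_kernel <- match.arg(svm_kernel)
  stopifnot(n_trees >= 1, svm_cost > 0)
  structure(list(backend = backend, n_trees = as.integer(n_trees),
                 max_depth = max_depth, svm_kernel = svm_kernel,
                 svm_cost = svm_cost),
            class = "classifier_config")
}

#' Train the pair classifier on encoder features
#'
#' Fits a random forest (or SVM comparator) predicting the association label
#' from feature vectors. Reproducible given `seed`; warns when the classes
#' are badly imbalanced (ratio above 4:1), since the protocol expects
#' near-balanced sampled negatives.
#'
#' @param features Numeric matrix, one row per pair.
#' @param labels Binary labels.
#' @param config A [classifier_config()].
#' @param seed Integer seed.
#' @return A list of class `"pair_classifier"`.
#' @export
train_classifier <- function(features, labels, config = classifier_config(),
                             seed = 1L) {
  features <- as.matrix(features)
  labels <- as.numeric(labels)
  stopifnot(nrow(features) == length(labels), all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2L) {
    stop("classifier training needs both classes present", call. = FALSE)
  }
  tab <- table(labels)
  if (max(tab) / min(tab) > 4) {
    warning("classes are strongly imbalanced (", paste(tab, collapse = ":"),
            "); consider balanced negative sampling", call. = FALSE)
  }
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  set.seed(derive_seed(seed, paste0("classifier-", config$backend)))
  fit <- if (config$backend == "random_forest") {
    randomForest::randomForest(
      x = features, y = factor(labels, levels = c(0, 1)),
      ntree = config$n_trees, maxnodes = config$max_depth)
  } else {
    e1071::svm(x = features, y = factor(labels, levels = c(0, 1)),
               kernel = if (config$svm_kernel == "rbf") "radial" else "linear",
               cost = config$svm_cost, probability = TRUE)
  }
  structure(list(fit = fit, config = config, n_features = ncol(features),
                 seed = seed),
            class = "pair_classifier")
}

#' Score drug-disease pairs with a trained classifier
#'
#' @param model A [train_classifier()] result.
#' @param features Feature matrix with the training dimensionality.
#' @return Probabilities of association, one per row, in `[0, 1]`.
#' @export
score_pairs <- function(model, features) {
  stopifnot(inherits(model, "pair_classifier"))
  features <- as.matrix(features)
  if (ncol(features) != model$n_features) {
    stop(sprintf("feature dimension %d does not match the training dimension %d",
                 ncol(features), model$n_features), call. = FALSE)
  }
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  if (model$config$backend == "random_forest") {
    unname(predict(model$fit, features, type = "prob")[, "1"])
  } else {
    pr <- predict(model$fit, features, probability = TRUE)
    unname(attr(pr, "probabilities")[, "1"])
  }
}

#' @export
print.pair_classifier <- function(x, ...) {
  cat(sprintf("<pair_classifier> backend = %s, %d features\n",
              x$config$backend, x$n_features))
  invisible(x)
}
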