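#' List known positive pairs of an association matrix
#'
#' @param A An [association_matrix()].
#' @return A tibble with columns `drug_id`, `disease_id`, `label` (all 1).
#' @export
positive_pairs <- function(A) {
  idx <- which(unclass(A) == 1, arr.ind = TRUE)
  tibble::tibble(drug_id = colnames(A)[idx[, 2]],
                 disease_id = rownames(A)[idx[, 1]],
                 label = 1)
}

#' Sample negative (unknown) drug-disease pairs
#'
#' Uniform sampling without replacement from the zero cells of the
#' association matrix, i.e. pairs with no known association. Sampled pairs
#' never collide with known positives, and the draw is reproducible per
#' seed. The default size gives a balanced 1:1 design against the positives.
#'
#' @param A An [association_matrix()].
#' @param n Number of negatives (default: the number of positives).
#' @param seed Integer seed.
#' @param exclude Optional data frame of `drug_id`/`disease_id` pairs to
#'   keep out of the pool (e.g. the target disease's row in a case study).
#' @return A tibble with columns `drug_id`, `disease_id`, `label` (all 0).
#' @export
sample_negatives <- function(A, n = NULL, seed = 1L, exclude = NULL) {
  M <- unclass(A)
  pool <- which(M == 0)
  if (!is.null(exclude) && nrow(exclude)) {
    ex_idx <- (match(exclude$drug_id, colnames(A)) - 1L) * nrow(A) +
      match(exclude$disease_id, rownames(A))
    pool <- setdiff(pool, ex_idx)
  }
  n <- n %||% n_associations(A)
  if (n > length(pool)) {
    stop(sprintf("requested %d negatives but only %d unknown pairs exist",
                 n, length(pool)), call. = FALSE)
  }
  set.seed(derive_seed(seed, "negatives"))
  chosen <- sort(sample(pool, n))
  tibble::tibble(drug_id = colnames(A)[((chosen - 1L) %/% nrow(A)) + 1L],
                 disease_id = rownames(A)[((chosen - 1L) %% nrow(A)) + 1L],
                 label = 0)
}

#' Confusion-matrix classification metrics
#'
#' Accuracy, precision, recall and F1 from binary labels and hard binary
#' predictions, as proportions in `[0, 1]`. Degenerate denominators yield 0
#' with a warning (no predicted positives for precision, no true positives
#' for recall, and F1 is 0 when precision + recall is 0).
#'
#' @param labels,predictions Equal-length binary vectors.
#' @return A one-row tibble with columns `accuracy`, `precision`, `recall`,
#'   `f1`.
#' @export
compute_metrics <- function(labels, predictions) {
  labels <- as.numeric(labels); predictions <- as.numeric(predictions)
  if (length(labels) != length(predictions) || !length(labels)) {
    stop("labels and predictions must be non-empty and of equal length",
         call. = FALSE)
  }
  stopifnot(all(labels %in% c(0, 1)), all(predictions %in% c(0, 1)))
  tp <- sum(labels == 1 & predictions == 1)
  fp <- sum(labels == 0 & predictions == 1)
  fn <- sum(labels == 1 & predictions == 0)
  tn <- sum(labels == 0 & predictions == 0)
  prec <- if (tp + fp == 0) {
    warning("no predicted positives; precision set to 0", call. = FALSE); 0
  } else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  tibble::tibble(accuracy = (tp + tn) / length(labels),
                 precision = prec, recall = rec, f1 = f1)
}

#' ROC curve and AUC by the midrank Mann-Whitney estimator
#'
#' The AUC is the probability that a random positive outscores a random
#' negative, computed deterministically from midranks (ties count one half).
#' ROC points are returned at every distinct score threshold.
#'
#' @param labels Binary labels (both classes must be present).
#' @param scores Real-valued scores.
#' @return A list with `points` (tibble `fpr`, `tpr`, `threshold`) and
#'   scalar `auc`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.numeric(labels)
  stopifnot(length(labels) == length(scores), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(-scores)
  thr <- scores[ord]
  tp <- cumsum(labels[ord] == 1)
  fp <- cumsum(labels[ord] == 0)
  keep <- c(diff(thr) != 0, TRUE)  # one point per distinct threshold
  points <- tibble::tibble(fpr = c(0, fp[keep] / n0),
                           tpr = c(0, tp[keep] / n1),
                           threshold = c(Inf, thr[keep]))
  list(points = points, auc = auc)
}

#' Stratified fold assignment for cross-validation
#'
#' Shuffles within each label class and deals pairs round-robin over `k`
#' folds, so fold test sets partition the samples and per-fold positive
#' counts differ by at most one.
#'
#' @param pairs Data frame with a binary `label` column.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return `pairs` as a tibble with an integer `fold` column.
#' @export
make_folds <- function(pairs, k = 10L, seed = 1L) {
  pairs <- tibble::as_tibble(pairs)
  if (sum(pairs$label == 1) < k) {
    stop(sprintf("need at least k = %d positives for %d folds", k, k),
         call. = FALSE)
  }
  set.seed(derive_seed(seed, "folds"))
  fold <- integer(nrow(pairs))
  for (lab in unique(pairs$label)) {
    idx <- which(pairs$label == lab)
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  dplyr::mutate(pairs, fold = fold)
}

#' Training view of the association matrix for a held-out pair set
#'
#' Returns a copy of the association matrix with the held-out pairs' cells
#' set to 0, so kernels, clustering and fusion can be computed without any
#' information from the test fold.
#'
#' @param A An [association_matrix()].
#' @param holdout Data frame with `drug_id`, `disease_id` columns.
#' @return The masked [association_matrix()].
#' @export
training_view <- function(A, holdout) {
  M <- unclass(A)
  if (nrow(holdout)) {
    i <- match(holdout$disease_id, rownames(A))
    j <- match(holdout$drug_id, colnames(A))
    if (anyNA(i) || anyNA(j)) stop("holdout pair outside the matrix", call. = FALSE)
    M[cbind(i, j)] <- 0
  }
  association_matrix(M)
}

fit_and_score_fold <- function(view, drug_side, disease_side, train, test,
                               sims, sim_control, encoder, classifier, seed, tag,
                               n_encoders = 1L) {
  if (is.null(sims)) {
    sims <- similarity_pipeline(view, drug_side, disease_side, sim_control)
  }
  d_train <- build_pair_descriptors(sims$drug, sims$disease, train)
  d_test <- build_pair_descriptors(sims$drug, sims$disease, test)
  encs <- lapply(seq_len(n_encoders), function(s) {
    train_encoder(d_train, train$label, encoder,
                  seed = derive_seed(seed, paste0("encoder-", tag, "-", s)))
  })
  f_train <- do.call(cbind, lapply(encs, encode, descriptors = d_train))
  f_test <- do.call(cbind, lapply(encs, encode, descriptors = d_test))
  clf <- train_classifier(f_train, train$label, classifier,
                          seed = derive_seed(seed, paste0("classifier-", tag)))
  score_pairs(clf, f_test)
}

#' Ten-fold cross-validation of the full prediction pipeline
#'
#' Evaluates the pipeline end to end: balanced negatives are sampled once
#' per experiment, all sampled pairs are dealt into `k` stratified folds,
#' and for each fold (1) the test pairs' positive cells are zeroed out of
#' the association matrix, (2) sigmoid kernels, cohesive-module enhancement
#' and fusion are recomputed from that training view only, (3) the encoder
#' and classifier are trained on the training pairs, and (4) the held-out
#' pairs are scored. Per-fold accuracy/precision/recall/F1 (percent) and
#' AUC are aggregated as mean and standard deviation.
#'
#' `paper_mode = TRUE` instead computes the similarities once from the full
#' matrix — the optimistic protocol some repositioning studies use; it leaks
#' test associations into the similarity stage and is provided only to
#' quantify that effect.
#'
#' @param A An [association_matrix()].
#' @param drug_side Raw drug structure [similarity_matrix()].
#' @param disease_side Raw disease semantic [similarity_matrix()].
#' @param k Number of folds (default 10).
#' @param seed Integer seed controlling sampling, folds and training.
#' @param negative_ratio Negatives per positive (default 1).
#' @param threshold Probability cut for hard predictions (default 0.5).
#' @param paper_mode Compute similarities once from the full matrix.
#' @param sim_control A [similarity_control()].
#' @param encoder An [encoder_config()].
#' @param classifier A [classifier_config()].
#' @param n_encoders Number of independently initialised encoders whose
#'   feature layers are concatenated before classification (default 1; a
#'   small committee reduces the variance of encoder training on small
#'   data).
#' @return An object of class `"cv_result"`; see [tidy()], [glance()],
#'   [autoplot()].
#' @export
run_cross_validation <- function(A, drug_side, disease_side, k = 10L,
                                 seed = 1L, negative_ratio = 1,
                                 threshold = 0.5, paper_mode = FALSE,
                                 sim_control = similarity_control(),
                                 encoder = encoder_config(),
                                 classifier = classifier_config(),
                                 n_encoders = 1L) {
  pos <- positive_pairs(A)
  neg <- sample_negatives(A, n = round(negative_ratio * nrow(pos)), seed = seed)
  pairs <- make_folds(dplyr::bind_rows(pos, neg), k = k, seed = seed)

  full_sims <- if (paper_mode) {
    similarity_pipeline(A, drug_side, disease_side, sim_control)
  } else NULL

  fold_rows <- vector("list", k)
  roc_rows <- vector("list", k)
  scored <- vector("list", k)
  for (i in seq_len(k)) {
    test <- pairs[pairs$fold == i, ]
    train <- pairs[pairs$fold != i, ]
    view <- if (paper_mode) A else training_view(A, test[test$label == 1, ])
    scores <- fit_and_score_fold(view, drug_side, disease_side, train, test,
                                 full_sims, sim_control, encoder, classifier,
                                 seed, paste0("fold", i), n_encoders)
    m <- compute_metrics(test$label, as.numeric(scores >= threshold))
    roc <- roc_auc(test$label, scores)
    fold_rows[[i]] <- dplyr::mutate(m, fold = i, auc = roc$auc,
                                    n_test = nrow(test), .before = 1L)
    roc_rows[[i]] <- dplyr::mutate(roc$points, fold = i, .before = 1L)
    scored[[i]] <- dplyr::mutate(test, score = scores)
  }
  folds <- dplyr::mutate(dplyr::bind_rows(fold_rows),
                         dplyr::across(c("accuracy", "precision", "recall", "f1"),
                                       ~ 100 * .x))
  metric_cols <- c("accuracy", "precision", "recall", "f1", "auc")
  summary <- tibble::tibble(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(folds[[m]]), 1.0,
                  USE.NAMES = FALSE),
    sd = vapply(metric_cols, function(m) stats::sd(folds[[m]]), 1.0,
                USE.NAMES = FALSE))
  structure(list(folds = folds, summary = summary,
                 roc = dplyr::bind_rows(roc_rows),
                 predictions = dplyr::bind_rows(scored),
                 splits = pairs, k = k, seed = seed, threshold = threshold,
                 paper_mode = paper_mode),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold cross-validation (seed %d%s)\n",
              x$k, x$seed, if (x$paper_mode) ", paper mode" else ""))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    unit <- if (s$metric[i] == "auc") "" else "%"
    cat(sprintf("  %-9s %6.2f%s +/- %.2f\n", s$metric[i], s$mean[i], unit, s$sd[i]))
  }
  invisible(x)
}

#' Tidy accessors for cross-validation results
#'
#' `tidy()` returns the per-fold metric table (percent, plus AUC in
#' `[0, 1]`); `glance()` a one-row summary of means and standard deviations;
#' `autoplot()` the per-fold ROC curves.
#'
#' @param x A [run_cross_validation()] result.
#' @param ... Unused.
#' @return A tibble (`tidy`, `glance`) or a ggplot object (`autoplot`).
#' @export
tidy.cv_result <- function(x, ...) x$folds

#' @rdname tidy.cv_result
#' @export
glance.cv_result <- function(x, ...) {
  s <- x$summary
  wide <- c(setNames(s$mean, paste0("mean_", s$metric)),
            setNames(s$sd, paste0("sd_", s$metric)))
  dplyr::bind_cols(tibble::as_tibble(as.list(wide)),
                   tibble::tibble(folds = x$k, seed = x$seed))
}

#' @rdname tidy.cv_result
#' @param object A `cv_result`.
#' @export
autoplot.cv_result <- function(object, ...) {
  auc_mean <- object$summary$mean[object$summary$metric == "auc"]
  ggplot2::ggplot(object$roc,
                  ggplot2::aes(.data$fpr, .data$tpr,
                               group = .data$fold, colour = factor(.data$fold))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = "Fold",
                  title = "Cross-validated ROC curves",
                  subtitle = sprintf("mean AUC = %.3f", auc_mean)) +
    ggplot2::theme_minimal()
}

#' Leave-one-disease-out candidate ranking
#'
#' Case-study protocol: every association of the target disease is removed
#' from the training data, the similarity stage and the encoder/classifier
#' are fitted on what remains (with balanced sampled negatives that avoid
#' the target disease), and then every drug is scored against the target
#' disease and ranked by descending probability.
#'
#' @inheritParams run_cross_validation
#' @param disease_id The target disease.
#' @details With the default strict protocol the similarities themselves are
#'   recomputed without the target disease's associations, so its descriptor
#'   falls back to the semantic side channel — a feature type the model may
#'   never have seen when every training disease has a non-empty profile.
#'   `paper_mode = TRUE` computes the similarities once from the full matrix
#'   (the optimistic case-study protocol of the benchmark literature), which
#'   removes that covariate shift at the price of similarity-stage leakage.
#' @return A tibble of class `"drug_ranking"` with columns `rank`,
#'   `drug_id`, `score`, `known` (the withheld truth), ordered by rank.
#' @export
rank_candidates_for_disease <- function(A, drug_side, disease_side, disease_id,
                                        seed = 1L, paper_mode = FALSE,
                                        sim_control = similarity_control(),
                                        encoder = encoder_config(),
                                        classifier = classifier_config(),
                                        n_encoders = 1L) {
  if (!disease_id %in% rownames(A)) {
    stop("unknown disease identifier: ", disease_id, call. = FALSE)
  }
  target_cells <- tibble::tibble(drug_id = colnames(A),
                                 disease_id = disease_id)
  view <- training_view(A, target_cells)
  train_pos <- positive_pairs(view)
  train_neg <- sample_negatives(view, n = nrow(train_pos), seed = seed,
                                exclude = target_cells)
  train <- dplyr::bind_rows(train_pos, train_neg)
  candidates <- dplyr::mutate(target_cells, label = NA_real_)
  full_sims <- if (paper_mode) {
    similarity_pipeline(A, drug_side, disease_side, sim_control)
  } else NULL
  scores <- fit_and_score_fold(view, drug_side, disease_side, train,
                               candidates, full_sims, sim_control, encoder,
                               classifier, seed, paste0("rank-", disease_id),
                               n_encoders)
  ranking <- tibble::tibble(drug_id = colnames(A), score = scores,
                            known = unclass(A)[disease_id, ])
  ranking <- dplyr::arrange(ranking, dplyr::desc(.data$score), .data$drug_id)
  ranking <- dplyr::mutate(ranking, rank = dplyr::row_number(), .before = 1L)
  attr(ranking, "disease_id") <- disease_id
  attr(ranking, "seed") <- seed
  class(ranking) <- c("drug_ranking", class(ranking))
  ranking
}

#' @export
autoplot.drug_ranking <- function(object, top_n = 20, ...) {
  top <- head(object, top_n)
  top$drug_id <- factor(top$drug_id, levels = rev(top$drug_id))
  ggplot2::ggplot(top, ggplot2::aes(.data$score, .data$drug_id,
                                    colour = factor(.data$known))) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$score,
                                       yend = .data$drug_id), colour = "grey80") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(`0` = "grey40", `1` = "#d1495b"),
                                 labels = c(`0` = "unknown", `1` = "withheld positive")) +
    ggplot2::labs(x = "Predicted association probability", y = NULL,
                  colour = NULL,
                  title = sprintf("Top %d candidates for %s", top_n,
                                  attr(object, "disease_id"))) +
    ggplot2::theme_minimal()
}

#' Write a cross-validation report to disk
#'
#' Writes the per-fold table plus an `Average` row as TSV, the full report
#' (folds, summary, seed, split manifest) as JSON, and the ROC points as
#' TSV, into `dir`.
#'
#' @param cv A [run_cross_validation()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(cv, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  folds <- cv$folds
  cols <- c("accuracy", "precision", "recall", "f1", "auc")
  tab <- data.frame(fold = as.character(folds$fold))
  for (m in cols) tab[[m]] <- sprintf("%.2f", folds[[m]])
  tab <- rbind(tab, c("Average", vapply(cols, function(m) {
    sprintf("%.2f +/- %.2f", mean(folds[[m]]), stats::sd(folds[[m]]))
  }, "")))
  utils::write.table(tab, file.path(dir, "folds.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cv$roc, file.path(dir, "roc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(folds = folds, summary = cv$summary, k = cv$k, seed = cv$seed,
         threshold = cv$threshold, paper_mode = cv$paper_mode,
         splits = cv$splits),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
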