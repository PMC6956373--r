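#' Confusion counts for binary calm/stress predictions
#'
#' @param truth,pred Vectors of 0 (calm) / 1 (stress) labels.
#' @return Named list `TP`, `FP`, `TN`, `FN` with stress = positive.
#' @export
confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  list(TP = sum(truth == 1 & pred == 1),
       FP = sum(truth == 0 & pred == 1),
       TN = sum(truth == 0 & pred == 0),
       FN = sum(truth == 1 & pred == 0))
}

#' Class-wise accuracy: per-class TP / (TP + FP)
#'
#' With the given class treated as positive this is the fraction of
#' predictions of that class that are correct — conventionally called
#' precision. Returned as a percentage; `NA` when the class is never
#' predicted (undefined metric, not an error).
#'
#' @param conf Counts from [confusion_counts()].
#' @param class `"stress"` (positive) or `"calm"`.
#' @return Percentage in \[0, 100\], or `NA_real_`.
#' @export
classwise_accuracy <- function(conf, class = c("stress", "calm")) {
  class <- match.arg(class)
  if (class == "stress") {
    tp <- conf$TP; fp <- conf$FP
  } else {
    tp <- conf$TN; fp <- conf$FN
  }
  if (tp + fp == 0) return(NA_real_)
  100 * tp / (tp + fp)
}

#' Per-class recall: TP / (TP + FN)
#'
#' Reported alongside [classwise_accuracy()] for transparency, since the
#' two differ whenever the test split is imbalanced.
#'
#' @inheritParams classwise_accuracy
#' @return Percentage in \[0, 100\], or `NA_real_`.
#' @export
classwise_recall <- function(conf, class = c("stress", "calm")) {
  class <- match.arg(class)
  if (class == "stress") {
    tp <- conf$TP; fn <- conf$FN
  } else {
    tp <- conf$TN; fn <- conf$FP
  }
  if (tp + fn == 0) return(NA_real_)
  100 * tp / (tp + fn)
}

#' Average accuracy: (TP + TN) / total
#'
#' @param conf Counts from [confusion_counts()].
#' @return Percentage in \[0, 100\].
#' @export
average_accuracy <- function(conf) {
  total <- conf$TP + conf$FP + conf$TN + conf$FN
  if (total == 0) stop("empty confusion: no samples")
  100 * (conf$TP + conf$TN) / total
}

#' Principal-component projection of a feature matrix
#'
#' Correlation-scaled PCA (each column centered and scaled to unit
#' variance) with a deterministic sign convention: the largest-magnitude
#' loading of every component is made positive.
#'
#' @param x Numeric matrix.
#' @param n_components Number of components to keep.
#' @return List with `scores` (n x n_components), `explained_variance`
#'   (ratios over all components), and `apply(newx)` projecting new rows
#'   with the training center/scale/rotation.
#' @export
pca_project <- function(x, n_components = 2) {
  x <- as.matrix(x)
  if (any(apply(x, 2, stats::sd) == 0)) {
    stop("constant column: correlation-scaled PCA undefined")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  if (n_components > ncol(pc$rotation)) {
    stop(sprintf("n_components = %d exceeds rank %d",
                 n_components, ncol(pc$rotation)))
  }
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(pc$rotation, 2, flip, `*`)[, seq_len(n_components), drop = FALSE]
  ctr <- pc$center; scl <- pc$scale
  project <- function(newx) {
    scale(as.matrix(newx), center = ctr, scale = scl) %*% rot
  }
  list(scores = project(x),
       explained_variance = pc$sdev^2 / sum(pc$sdev^2),
       apply = project)
}

#' Run one method variant on a participant dataset
#'
#' The full pipeline: feature extraction, stratified 60/40 split,
#' training-split z-scoring, the variant's feature step (`"proposed"` =
#' shadow-feature ranking keeping confirmed features, `"pca_knn"` =
#' projection onto the leading principal components, `"all_features_knn"`
#' = identity), SMOTE balancing of the training rows, cross-validated k
#' selection, and k-NN prediction of the test rows. All feature-step and
#' scaling parameters are fitted on training rows only; set
#' `config$smote$before_split`/`config$knn$tune_on_test` to reproduce
#' the literal published ordering (SMOTE before the split, k tuned on the
#' test side).
#'
#' @param variant `"proposed"`, `"pca_knn"` or `"all_features_knn"`.
#' @param ds A `participant_dataset`, or a precomputed feature data frame
#'   from [extract_features()] (e.g. a merged dataset).
#' @param config See [default_config()].
#' @param seed Integer master seed for split, SMOTE, ranking and CV.
#' @param dataset_id Identifier copied into the report.
#' @return A `method_report`: confusion counts, class-wise accuracy and
#'   recall per class, average accuracy, `chosen_k`, selected features,
#'   and a `fallback` flag (TRUE when ranking confirmed nothing and all
#'   features were used).
#' @export
run_method <- function(variant = c("proposed", "pca_knn", "all_features_knn"),
                       ds, config = default_config(), seed = 1L,
                       dataset_id = NULL) {
  variant <- match.arg(variant)
  fm <- if (is.data.frame(ds)) ds else extract_features(ds, config)
  if (is.null(dataset_id)) {
    dataset_id <- paste(unique(fm$participant_id), collapse = "+")
  }
  xy <- feature_xy(fm)
  set.seed(seed)
  if (isTRUE(config$smote$before_split)) {
    bal <- smote(xy$x, xy$y, k_neighbors = config$smote$k_neighbors,
                 target_ratio = config$smote$target_ratio)
    xy <- list(x = bal$x, y = bal$y)
  }
  sp <- stratified_split(xy$y, config$knn$train_fraction)
  train_x <- xy$x[sp$train, , drop = FALSE]
  train_y <- xy$y[sp$train]
  test_x <- xy$x[sp$test, , drop = FALSE]
  test_y <- xy$y[sp$test]
  if (isTRUE(config$standardize)) {
    sc <- fit_scaler(train_x)
    train_x <- sc$apply(train_x)
    test_x <- sc$apply(test_x)
  }
  selected <- colnames(train_x)
  fallback <- FALSE
  if (variant == "proposed") {
    br <- boruta_rank(train_x, train_y,
                      n_iterations = config$boruta$n_iterations,
                      rf_trees = config$boruta$rf_trees,
                      significance_alpha = config$boruta$significance_alpha,
                      importance = config$boruta$importance)
    if (length(br$selected) == 0) {
      warning("no confirmed features; falling back to the full pool")
      fallback <- TRUE
    } else {
      selected <- br$selected
      train_x <- train_x[, selected, drop = FALSE]
      test_x <- test_x[, selected, drop = FALSE]
    }
  } else if (variant == "pca_knn") {
    pr <- pca_project(train_x, n_components = config$pca$n_components)
    train_x <- pr$scores
    test_x <- pr$apply(test_x)
    selected <- paste0("PC", seq_len(ncol(train_x)))
  }
  if (!isTRUE(config$smote$before_split)) {
    bal <- smote(train_x, train_y, k_neighbors = config$smote$k_neighbors,
                 target_ratio = config$smote$target_ratio)
    train_x <- bal$x
    train_y <- bal$y
  }
  tune_x <- train_x; tune_y <- train_y
  if (isTRUE(config$knn$tune_on_test)) {
    tune_x <- test_x; tune_y <- test_y
  }
  cv <- select_k(tune_x, tune_y, k_candidates = config$knn$k_candidates,
                 cv_folds = config$knn$cv_folds)
  pred <- knn_predict(train_x, train_y, test_x, cv$chosen_k)
  conf <- confusion_counts(test_y, pred)
  structure(
    list(method = variant, dataset_id = dataset_id, confusion = conf,
         classwise_accuracy = c(calm = classwise_accuracy(conf, "calm"),
                                stress = classwise_accuracy(conf, "stress")),
         classwise_recall = c(calm = classwise_recall(conf, "calm"),
                              stress = classwise_recall(conf, "stress")),
         average_accuracy = average_accuracy(conf),
         chosen_k = cv$chosen_k, selected_features = selected,
         fallback = fallback, n_train = nrow(train_x), n_test = nrow(test_x)),
    class = "method_report")
}

#' @export
print.method_report <- function(x, ...) {
  cat(sprintf("<method_report> %s on dataset %s\n", x$method, x$dataset_id))
  cat(sprintf("  avg accuracy %.2f%% (calm %.2f%%, stress %.2f%%), k = %d\n",
              x$average_accuracy, x$classwise_accuracy["calm"],
              x$classwise_accuracy["stress"], x$chosen_k))
  cat(sprintf("  features: %s%s\n", paste(x$selected_features, collapse = ", "),
              if (x$fallback) " [fallback: none confirmed]" else ""))
  invisible(x)
}

#' One-way fixed-effects analysis of variance
#'
#' @param groups List of numeric vectors (>= 2 groups, each >= 2 values).
#' @return List with `F`, `p`, `df_between`, `df_within`, `group_means`.
#'   `F` is `Inf` when all within-group variances are zero but group means
#'   differ.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, integer(1)) >= 2))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  tab <- stats::anova(stats::aov(values ~ g))
  f <- tab["g", "F value"]
  msb <- tab["g", "Mean Sq"]; msw <- tab["Residuals", "Mean Sq"]
  if (msw <= 1e-12 * msb) {    # all within-group variance numerically zero
    f <- if (msb > 0) Inf else 0
  }
  list(F = f, p = tab["g", "Pr(>F)"],
       df_between = tab["g", "Df"], df_within = tab["Residuals", "Df"],
       group_means = vapply(groups, mean, numeric(1)))
}

#' Decrements of competing methods from a reference method
#'
#' @param accuracies Named numeric vector of average accuracies (%).
#' @param reference Name of the reference entry (default `"proposed"`).
#' @return Named vector of `reference - other` differences, in the order
#'   of `accuracies` without the reference.
#' @export
accuracy_decrements <- function(accuracies, reference = "proposed") {
  stopifnot(reference %in% names(accuracies))
  others <- accuracies[setdiff(names(accuracies), reference)]
  accuracies[[reference]] - others
}

#' Published per-dataset comparison accuracies
#'
#' The 25-dataset average accuracies of the three method variants
#' (PCA + k-NN, all features + k-NN, proposed ranking + k-NN) as published
#' for the DEAP study, bundled for the cross-method ANOVA.
#'
#' @return Data frame with columns `dataset`, `participant_id`,
#'   `pca_knn`, `all_features_knn`, `proposed`.
#' @export
published_dataset_accuracies <- function() {
  utils::read.csv(system.file("extdata", "dataset_accuracies.csv",
                              package = "eegstress"))
}

#' Published merged-dataset average accuracies
#'
#' @return Named numeric vector with entries `pca_knn`,
#'   `all_features_knn`, `proposed` (%).
#' @export
published_merged_accuracies <- function() {
  d <- utils::read.csv(system.file("extdata", "merged_accuracies.csv",
                                   package = "eegstress"))
  stats::setNames(d$avg_accuracy, d$method)
}
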