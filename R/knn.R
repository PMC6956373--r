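#' Euclidean distance between two vectors
#'
#' @param a,b Numeric vectors of equal length.
#' @return `sqrt(sum((a - b)^2))`.
#' @export
euclidean <- function(a, b) {
  if (length(a) != length(b)) {
    stop(sprintf("dimension mismatch: %d vs %d", length(a), length(b)))
  }
  sqrt(sum((a - b)^2))
}

#' Stratified train/test split
#'
#' Samples `round(train_fraction * n_c)` training rows from each class
#' independently, so class proportions on both sides stay within one
#' sample of the input proportions.
#'
#' @param y Label vector.
#' @param train_fraction Fraction of each class assigned to training
#'   (default 0.6).
#' @param seed Optional integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(y, train_fraction = 0.6, seed = NULL) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  classes <- unique(y)
  if (length(classes) < 2) stop("split error: need both classes present")
  train <- integer(0)
  for (cl in classes) {
    idx <- which(y == cl)
    if (length(idx) < 2) {
      stop(sprintf("split error: class '%s' has fewer than 2 rows", cl))
    }
    n_train <- round(train_fraction * length(idx))
    n_train <- min(max(n_train, 1L), length(idx) - 1L)
    train <- c(train, sample(idx, n_train))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

#' k-nearest-neighbour prediction
#'
#' Majority vote among the k nearest training rows in Euclidean distance.
#' Tie-breaks are deterministic: a distance tie at the k-th position is
#' resolved in favour of the lower row index, and a vote tie goes to the
#' class of the single nearest neighbour.
#'
#' @param train_x Numeric training matrix.
#' @param train_y Training labels.
#' @param query_x Numeric matrix of query rows.
#' @param k Neighbour count, at most `nrow(train_x)`.
#' @return Vector of predicted labels, one per query row.
#' @export
knn_predict <- function(train_x, train_y, query_x, k) {
  train_x <- as.matrix(train_x)
  query_x <- as.matrix(query_x)
  if (k > nrow(train_x)) {
    stop(sprintf("k = %d exceeds training size %d", k, nrow(train_x)))
  }
  out <- vector(mode = class(train_y), length = nrow(query_x))
  tx2 <- rowSums(train_x^2)
  for (q in seq_len(nrow(query_x))) {
    v <- query_x[q, ]
    d2 <- tx2 - 2 * (train_x %*% v) + sum(v^2)
    o <- order(d2)           # stable: equal distances keep index order
    nb <- o[seq_len(k)]
    votes <- table(train_y[nb])
    top <- names(votes)[votes == max(votes)]
    out[q] <- if (length(top) == 1) {
      if (is.numeric(train_y)) as.numeric(top) else top
    } else {
      train_y[nb[1]]
    }
  }
  out
}

#' Choose k by stratified cross-validated misclassification error
#'
#' Stratified K-fold cross-validation over a candidate list of k values;
#' the chosen k minimizes the mean misclassification error across folds,
#' with ties resolved toward the smallest k. When a class has fewer rows
#' than `cv_folds`, the fold count is reduced with a warning.
#'
#' @param x Numeric feature matrix.
#' @param y Labels.
#' @param k_candidates Candidate neighbour counts (default odd 1..19).
#' @param cv_folds Number of folds (default 10).
#' @param seed Optional integer seed for the fold assignment.
#' @return List with `chosen_k`, `cv_error` (named mean error per
#'   candidate) and `folds_used`.
#' @export
select_k <- function(x, y, k_candidates = seq(1, 19, by = 2), cv_folds = 10,
                     seed = NULL) {
  x <- as.matrix(x)
  stopifnot(all(k_candidates >= 1), cv_folds >= 2)
  if (!is.null(seed)) set.seed(seed)
  min_class <- min(table(y))
  folds_used <- cv_folds
  if (min_class < cv_folds) {
    folds_used <- max(2L, as.integer(min_class))
    warning(sprintf("fold count reduced to %d (smallest class has %d rows)",
                    folds_used, min_class))
  }
  fold_id <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold_id[idx] <- sample(rep_len(seq_len(folds_used), length(idx)))
  }
  k_candidates <- k_candidates[k_candidates <= min(table(fold_id)) *
                                 (folds_used - 1)]
  errs <- matrix(NA_real_, folds_used, length(k_candidates))
  for (f in seq_len(folds_used)) {
    tr <- fold_id != f
    max_k <- sum(tr)
    for (j in seq_along(k_candidates)) {
      k <- min(k_candidates[j], max_k)
      pred <- knn_predict(x[tr, , drop = FALSE], y[tr],
                          x[!tr, , drop = FALSE], k)
      errs[f, j] <- mean(pred != y[!tr])
    }
  }
  mean_err <- stats::setNames(colMeans(errs), k_candidates)
  chosen <- k_candidates[which.min(mean_err)]  # which.min: first = smallest k
  list(chosen_k = chosen, cv_error = mean_err, folds_used = folds_used)
}
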