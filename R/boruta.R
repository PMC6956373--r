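#' Append shadow features to a feature matrix
#'
#' Each shadow column is an independent row-permutation of its original,
#' so it keeps the marginal distribution but loses any association with
#' the labels. Shadow columns are named `shadow_<original>`.
#'
#' @param x Numeric matrix with at least one column and two rows.
#' @return Matrix `[x | shadows]` with twice the columns.
#' @export
make_shadow <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows to build shadow features")
  if (ncol(x) < 1) stop("need at least 1 feature")
  sh <- apply(x, 2, function(col) col[sample.int(length(col))])
  colnames(sh) <- paste0("shadow_", colnames(x))
  cbind(x, sh)
}

#' Permutation-importance Z scores from a random forest
#'
#' Fits a random forest on the (possibly shadow-extended) block and scores
#' every column by its per-tree out-of-bag permutation importance: the Z
#' score is the mean accuracy loss across trees divided by its standard
#' deviation (0 when the deviation is 0, e.g. for constant columns). The
#' `"impurity"` engine reports mean decrease in Gini instead, behind the
#' same interface.
#'
#' @param x Numeric matrix (originals and/or shadows).
#' @param y Binary labels (coerced to factor); both classes must appear.
#' @param rf_trees Number of trees (default 100).
#' @param importance `"permutation"` (Z scores) or `"impurity"` (MDI).
#' @return Named numeric vector of scores, one per column of `x`.
#' @export
importance_z <- function(x, y, rf_trees = 100, importance = "permutation") {
  y <- factor(y)
  if (nlevels(y) < 2) stop("labels contain a single class")
  rf <- randomForest::randomForest(
    x = as.data.frame(x), y = y, ntree = rf_trees,
    mtry = max(1, floor(sqrt(ncol(x)))), importance = TRUE)
  if (importance == "impurity") {
    z <- rf$importance[, "MeanDecreaseGini"]
  } else {
    m <- rf$importance[, "MeanDecreaseAccuracy"]
    s <- rf$importanceSD[, "MeanDecreaseAccuracy"]
    z <- ifelse(s > 0, m / s, 0)
  }
  stats::setNames(as.numeric(z), colnames(x))
}

#' All-relevant feature ranking with shadow features (Boruta)
#'
#' Repeats for `n_iterations`: build a fresh shadow block, score all
#' columns with [importance_z()], take the maximum shadow score (MZSF),
#' and award each original feature whose score exceeds it one "hit".
#' After the loop each feature's hit count is compared against the
#' Binomial(n, 1/2) null with one-sided binomial tests: significantly
#' more hits than n/2 confirms the feature, significantly fewer rejects
#' it, anything else stays tentative. The selected set is the confirmed
#' features; tentative ones are reported but not selected.
#'
#' @param x Numeric feature matrix.
#' @param y Binary labels.
#' @param n_iterations Number of shadow rounds (default 20).
#' @param rf_trees Trees per forest (default 100).
#' @param significance_alpha One-sided test level (default 0.05).
#' @param importance Importance engine, see [importance_z()].
#' @param seed Optional integer seed for reproducibility.
#' @return Object of class `boruta_result`: `status` (named factor-like
#'   character vector: confirmed/rejected/tentative), `hits`, `selected`
#'   (confirmed feature names), `z_history` (iterations x features),
#'   `mzsf_history`, and `n_iterations`.
#' @export
boruta_rank <- function(x, y, n_iterations = 20, rf_trees = 100,
                        significance_alpha = 0.05,
                        importance = "permutation", seed = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(x)
  hits <- stats::setNames(integer(p), colnames(x))
  z_hist <- matrix(NA_real_, n_iterations, p,
                   dimnames = list(NULL, colnames(x)))
  mzsf_hist <- numeric(n_iterations)
  for (it in seq_len(n_iterations)) {
    ext <- make_shadow(x)
    z <- importance_z(ext, y, rf_trees = rf_trees, importance = importance)
    z_orig <- z[seq_len(p)]
    mzsf <- max(z[(p + 1):(2 * p)])
    hits <- hits + (z_orig > mzsf)
    z_hist[it, ] <- z_orig
    mzsf_hist[it] <- mzsf
  }
  p_more <- stats::pbinom(hits - 1, n_iterations, 0.5, lower.tail = FALSE)
  p_less <- stats::pbinom(hits, n_iterations, 0.5)
  status <- ifelse(p_more < significance_alpha, "confirmed",
                   ifelse(p_less < significance_alpha, "rejected",
                          "tentative"))
  structure(
    list(status = stats::setNames(status, colnames(x)),
         hits = hits,
         selected = colnames(x)[status == "confirmed"],
         z_history = z_hist,
         mzsf_history = mzsf_hist,
         n_iterations = n_iterations),
    class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  cat(sprintf("<boruta_result> %d iterations: %d confirmed, %d tentative, %d rejected\n",
              x$n_iterations, sum(x$status == "confirmed"),
              sum(x$status == "tentative"), sum(x$status == "rejected")))
  if (length(x$selected)) {
    cat("confirmed:", paste(x$selected, collapse = ", "), "\n")
  }
  invisible(x)
}
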