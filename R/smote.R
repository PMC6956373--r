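#' Synthetic minority over-sampling (SMOTE)
#'
#' Equalizes a binary-labeled feature matrix by interpolating new minority
#' rows: each synthetic row is `x_i + u * (x_nn - x_i)` with `u ~ U(0,1)`
#' and `x_nn` one of the `k_neighbors` nearest minority neighbours
#' (Euclidean) of a randomly chosen minority row `x_i`. Original rows are
#' kept unchanged and come first; majority rows are never touched.
#'
#' @param x Numeric feature matrix.
#' @param y Binary label vector (two distinct values).
#' @param k_neighbors Neighbour count (default 5); reduced with a warning
#'   when the minority class has fewer than `k_neighbors + 1` rows.
#' @param target_ratio Desired minority/majority ratio after sampling
#'   (default 1 = full balance).
#' @param seed Optional integer seed.
#' @return List with `x` (matrix, original rows then synthetic minority
#'   rows) and `y`.
#' @export
smote <- function(x, y, k_neighbors = 5, target_ratio = 1.0, seed = NULL) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), target_ratio > 0, target_ratio <= 1)
  classes <- sort(unique(y))
  if (length(classes) != 2) stop("smote requires exactly two classes")
  counts <- table(factor(y, levels = classes))
  min_class <- classes[which.min(counts)]
  n_min <- min(counts); n_maj <- max(counts)
  n_target <- round(target_ratio * n_maj)
  n_new <- n_target - n_min
  if (n_new <= 0) return(list(x = x, y = y))
  if (n_min < 2) stop("cannot oversample: minority class has fewer than 2 rows")
  if (!is.null(seed)) set.seed(seed)
  k <- k_neighbors
  if (n_min <= k) {
    k <- n_min - 1
    warning(sprintf("k_neighbors reduced to %d (minority class has %d rows)",
                    k, n_min))
  }
  xm <- x[y == min_class, , drop = FALSE]
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nn <- matrix(apply(d, 1, function(r) order(r)[seq_len(k)]),
               nrow = n_min, ncol = k, byrow = TRUE)
  syn <- matrix(NA_real_, n_new, ncol(x))
  base_i <- sample.int(n_min, n_new, replace = TRUE)
  for (j in seq_len(n_new)) {
    i <- base_i[j]
    nb <- nn[i, sample.int(k, 1)]
    u <- stats::runif(1)
    syn[j, ] <- xm[i, ] + u * (xm[nb, ] - xm[i, ])
  }
  colnames(syn) <- colnames(x)
  list(x = rbind(x, syn), y = c(y, rep(min_class, n_new)))
}
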