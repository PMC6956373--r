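#' Default analysis configuration
#'
#' Central knobs for the whole pipeline, with the values used in the
#' reference protocol: level-5 db4 packets, 256-sample Hann Welch
#' segments, 20 Boruta iterations over a 100-tree forest, SMOTE with 5
#' neighbours on the training split, odd k-NN candidates 1..19 chosen by
#' stratified 10-fold cross-validation on a 60/40 train/test split, and
#' per-dataset z-scoring from training-split statistics.
#'
#' @return Nested list of configuration values.
#' @export
default_config <- function() {
  list(
    wavelet = list(max_level = 5, wavelet = "db4",
                   welch_nperseg = 256, welch_overlap = 0.5),
    standardize = TRUE,
    boruta = list(n_iterations = 20, rf_trees = 100,
                  significance_alpha = 0.05, importance = "permutation"),
    smote = list(k_neighbors = 5, target_ratio = 1.0, before_split = FALSE),
    knn = list(k_candidates = seq(1, 19, by = 2), cv_folds = 10,
               train_fraction = 0.6, tune_on_test = FALSE),
    pca = list(n_components = 2)
  )
}

#' Names of the 19 hybrid-pool features
#' @return Character vector `F1`..`F19`.
#' @export
feature_names <- function() paste0("F", 1:19)

#' Extract the 19-column hybrid feature matrix of a participant dataset
#'
#' Every (trial, channel) pair is one sample: for each channel of each
#' trial the 11 time-domain features and the 8 wavelet-packet features are
#' computed on that channel's baseline-stripped signal. Rows are ordered
#' by trial (ascending experiment id) then channel; labels are calm = 0,
#' stress = 1. Degenerate channels (zero variance) are skipped with a
#' warning; the skip count is attached as attribute `n_skipped`.
#'
#' @param ds A `participant_dataset` from [assemble_datasets()].
#' @param config Configuration list, see [default_config()].
#' @return Data frame with columns `participant_id`, `experiment_id`,
#'   `channel`, `F1`..`F19`, `label`.
#' @export
extract_features <- function(ds, config = default_config()) {
  stopifnot(inherits(ds, "participant_dataset"))
  wcfg <- config$wavelet
  rows <- list()
  n_skipped <- 0L
  for (i in seq_along(ds$trials)) {
    tr <- ds$trials[[i]]
    if (tr$baseline_samples > 0) {
      tr <- remove_baseline(tr, tr$baseline_samples / tr$fs)
    }
    lab <- if (ds$labels[i] == "stress") 1L else 0L
    for (ch in seq_len(nrow(tr$data))) {
      x <- tr$data[ch, ]
      fv <- tryCatch({
        tree <- wpt_decompose(x, tr$fs, wavelet = wcfg$wavelet,
                              max_level = wcfg$max_level)
        sel <- select_band_nodes(tree)
        c(time_features(x),
          wavelet_features(tree, sel, nperseg = wcfg$welch_nperseg,
                           overlap = wcfg$welch_overlap))
      }, error = function(e) {
        if (grepl("degenerate", conditionMessage(e))) NULL else stop(e)
      })
      if (is.null(fv)) {
        n_skipped <- n_skipped + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = tr$participant_id,
        experiment_id = tr$experiment_id,
        channel = ch,
        as.list(fv),
        label = lab)
    }
  }
  if (n_skipped > 0) {
    warning(sprintf("skipped %d degenerate channel signals", n_skipped))
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || length(unique(out$label)) < 2) {
    stop("dataset error: a class lost all of its rows during extraction")
  }
  rownames(out) <- NULL
  out
}

# Split a feature frame into the numeric matrix X and label vector y.
feature_xy <- function(fm) {
  list(x = as.matrix(fm[, feature_names(), drop = FALSE]),
       y = fm$label)
}

#' Fit / apply z-score standardization
#'
#' @param x Numeric matrix used to estimate per-column mean and sd.
#' @return List with `center`, `scale` and function `apply(newx)`.
#'   Zero-variance columns get scale 1 (centered only).
#' @export
fit_scaler <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl,
       apply = function(newx) scale(newx, center = ctr, scale = scl))
}
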