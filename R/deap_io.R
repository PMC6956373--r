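#' Construct an EEG trial object
#'
#' One participant-by-experiment recording: a channels-by-samples amplitude
#' matrix plus the metadata needed downstream (sampling rate and the length
#' of the leading pre-trial baseline segment).
#'
#' @param participant_id Positive integer participant identifier.
#' @param experiment_id Integer experiment (video) identifier, 1-based.
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param fs Sampling rate in Hz (128 for DEAP-style input).
#' @param baseline_samples Number of leading pre-trial samples still present.
#' @return An object of class `eeg_trial`.
#' @export
eeg_trial <- function(participant_id, experiment_id, data, fs = 128,
                      baseline_samples = 0) {
  stopifnot(is.matrix(data), is.numeric(data))
  if (participant_id < 1) stop("participant_id must be a positive integer")
  structure(
    list(participant_id = as.integer(participant_id),
         experiment_id = as.integer(experiment_id),
         data = data, fs = fs,
         baseline_samples = as.integer(baseline_samples)),
    class = "eeg_trial")
}

#' @export
print.eeg_trial <- function(x, ...) {
  cat(sprintf("<eeg_trial> participant %d, experiment %d: %d ch x %d samples @ %g Hz (baseline %d)\n",
              x$participant_id, x$experiment_id, nrow(x$data), ncol(x$data),
              x$fs, x$baseline_samples))
  invisible(x)
}

#' Keep the EEG channels of a raw 40-channel recording
#'
#' DEAP records 40 channels per trial of which the first 32 are EEG and the
#' last 8 are peripheral (EOG, EMG, GSR, ...). Only the EEG channels enter
#' the analysis; row order is preserved.
#'
#' @param raw Numeric matrix with exactly 40 rows.
#' @return The first 32 rows of `raw`.
#' @export
select_eeg_channels <- function(raw) {
  stopifnot(is.matrix(raw))
  if (nrow(raw) != 40L) {
    stop(sprintf("expected 40 raw channels, got %d", nrow(raw)))
  }
  raw[1:32, , drop = FALSE]
}

#' Drop the pre-trial baseline segment from a trial
#'
#' @param trial An [eeg_trial()].
#' @param baseline_seconds Length of the leading baseline in seconds
#'   (default 3, the DEAP pre-trial segment).
#' @return The trial with the first `round(baseline_seconds * fs)` samples
#'   removed from every channel and `baseline_samples` set to 0.
#' @export
remove_baseline <- function(trial, baseline_seconds = 3) {
  stopifnot(inherits(trial, "eeg_trial"), baseline_seconds >= 0)
  n_drop <- round(baseline_seconds * trial$fs)
  if (n_drop > ncol(trial$data)) {
    stop(sprintf("baseline (%d samples) longer than signal (%d samples)",
                 n_drop, ncol(trial$data)))
  }
  if (n_drop > 0) {
    trial$data <- trial$data[, -seq_len(n_drop), drop = FALSE]
  }
  trial$baseline_samples <- 0L
  trial
}

#' Label a trial calm, stress or unlabeled from its self-assessment rating
#'
#' Thresholds the continuous valence/arousal self-ratings (1-9 scale) with
#' strict inequalities: calm when 4 < valence < 6 and arousal < 4; stress
#' when valence < 3 and arousal > 5; anything else is unlabeled and later
#' dropped. The two regions are disjoint by construction.
#'
#' @param valence,arousal Ratings in \[1, 9\].
#' @return One of `"calm"`, `"stress"`, `"unlabeled"`.
#' @export
label_state <- function(valence, arousal) {
  if (valence < 1 || valence > 9 || arousal < 1 || arousal > 9) {
    stop("valence and arousal must lie in [1, 9]")
  }
  if (valence > 4 && valence < 6 && arousal < 4) return("calm")
  if (valence < 3 && arousal > 5) return("stress")
  "unlabeled"
}

#' Group labeled trials into per-participant datasets
#'
#' Each trial is labeled through [label_state()] using its matching rating
#' row; unlabeled trials are dropped, and participants whose remaining
#' trials do not cover both classes are excluded entirely (they show no
#' distinctive calm/stress contrast). Each participant becomes one dataset.
#'
#' @param trials List of [eeg_trial()] objects.
#' @param ratings Data frame with columns `participant_id`, `experiment_id`,
#'   `valence`, `arousal`.
#' @return List of `participant_dataset` objects sorted by participant id,
#'   each with elements `participant_id`, `trials` and `labels` (character,
#'   `"calm"`/`"stress"`, parallel to `trials`).
#' @export
assemble_datasets <- function(trials, ratings) {
  stopifnot(is.list(trials), is.data.frame(ratings))
  key <- paste(ratings$participant_id, ratings$experiment_id, sep = ":")
  out <- list()
  for (tr in trials) {
    k <- paste(tr$participant_id, tr$experiment_id, sep = ":")
    i <- match(k, key)
    if (is.na(i)) {
      stop(sprintf("no rating for participant %d, experiment %d",
                   tr$participant_id, tr$experiment_id))
    }
    lab <- label_state(ratings$valence[i], ratings$arousal[i])
    if (lab == "unlabeled") next
    pid <- as.character(tr$participant_id)
    if (is.null(out[[pid]])) {
      out[[pid]] <- list(participant_id = tr$participant_id,
                         trials = list(), labels = character())
    }
    out[[pid]]$trials <- c(out[[pid]]$trials, list(tr))
    out[[pid]]$labels <- c(out[[pid]]$labels, lab)
  }
  keep <- vapply(out, function(d) {
    all(c("calm", "stress") %in% d$labels)
  }, logical(1))
  out <- out[keep]
  out <- out[order(vapply(out, `[[`, integer(1), "participant_id"))]
  lapply(unname(out), function(d) {
    # experiment-ID order within a dataset, matching the published layout
    o <- order(vapply(d$trials, `[[`, integer(1), "experiment_id"))
    d$trials <- d$trials[o]
    d$labels <- d$labels[o]
    class(d) <- "participant_dataset"
    d
  })
}

#' @export
print.participant_dataset <- function(x, ...) {
  cat(sprintf("<participant_dataset> participant %d: %d calm + %d stress trials\n",
              x$participant_id, sum(x$labels == "calm"),
              sum(x$labels == "stress")))
  invisible(x)
}

#' Read a ratings table from CSV
#'
#' @param path CSV file with header
#'   `participant_id,experiment_id,valence,arousal` (dot decimal).
#' @return Data frame of rating records.
#' @export
read_ratings <- function(path) {
  r <- utils::read.csv(path)
  need <- c("participant_id", "experiment_id", "valence", "arousal")
  miss <- setdiff(need, names(r))
  if (length(miss)) stop("ratings file missing columns: ",
                         paste(miss, collapse = ", "))
  r
}

#' Read a directory-based study container
#'
#' The container is a directory holding `ratings.csv` plus one
#' `participant_<id>.rds` file per participant, each an array
#' `[trial, channel, sample]` with attributes `fs`, `participant_id` and
#' `baseline_samples`. Experiment ids are 1-based array slices.
#'
#' @param dir Path to the study directory.
#' @return List with `trials` (list of [eeg_trial()]) and `ratings`.
#' @export
read_study <- function(dir) {
  ratings <- read_ratings(file.path(dir, "ratings.csv"))
  files <- sort(list.files(dir, pattern = "^participant_\\d+\\.rds$",
                           full.names = TRUE))
  if (!length(files)) stop("no participant_<id>.rds files in ", dir)
  trials <- list()
  for (f in files) {
    arr <- readRDS(f)
    pid <- attr(arr, "participant_id")
    fs <- attr(arr, "fs")
    bl <- attr(arr, "baseline_samples")
    if (is.null(bl)) bl <- 0L
    for (t in seq_len(dim(arr)[1])) {
      trials[[length(trials) + 1L]] <-
        eeg_trial(pid, t, arr[t, , , drop = TRUE], fs = fs,
                  baseline_samples = bl)
    }
  }
  list(trials = trials, ratings = ratings)
}

#' Write a study to the directory container read by [read_study()]
#'
#' @param trials List of [eeg_trial()] objects.
#' @param ratings Ratings data frame.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(trials, ratings, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(ratings, file.path(dir, "ratings.csv"), row.names = FALSE)
  pids <- sort(unique(vapply(trials, `[[`, integer(1), "participant_id")))
  for (pid in pids) {
    mine <- Filter(function(tr) tr$participant_id == pid, trials)
    o <- order(vapply(mine, `[[`, integer(1), "experiment_id"))
    mine <- mine[o]
    arr <- array(0, dim = c(length(mine), nrow(mine[[1]]$data),
                            ncol(mine[[1]]$data)))
    for (i in seq_along(mine)) arr[i, , ] <- mine[[i]]$data
    attr(arr, "fs") <- mine[[1]]$fs
    attr(arr, "participant_id") <- pid
    attr(arr, "baseline_samples") <- mine[[1]]$baseline_samples
    saveRDS(arr, file.path(dir, sprintf("participant_%02d.rds", pid)))
  }
  invisible(dir)
}
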