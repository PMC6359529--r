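#' Labeled EEG trial sets
#'
#' A `trial_set` holds multichannel EEG trials as a 3-axis numeric array
#' (trials x channels x samples) together with optional integer class labels,
#' the sampling rate in Hz and channel names.
#'
#' @param data numeric array, trials x channels x samples.
#' @param labels integer class labels (1 or 2), one per trial, or `NULL` for
#'   unlabeled test sets.
#' @param sfreq sampling rate in Hz.
#' @param channels optional character vector of channel names.
#' @param metadata free-form named list.
#' @return object of class `trial_set`.
#' @export
trial_set <- function(data, labels = NULL, sfreq, channels = NULL,
                      metadata = list()) {
  if (!is.array(data) || length(dim(data)) != 3 || !is.numeric(data)) {
    stop("'data' must be a numeric 3-axis array (trials x channels x samples)",
         call. = FALSE)
  }
  d <- dim(data)
  if (!is.null(labels)) {
    if (length(labels) != d[1]) {
      stop(sprintf("labels length (%d) does not match trial count (%d)",
                   length(labels), d[1]), call. = FALSE)
    }
    labels <- as.integer(labels)
  }
  if (!is.null(channels)) {
    if (length(channels) != d[2]) {
      stop("channel names length does not match channel count", call. = FALSE)
    }
  } else {
    channels <- sprintf("ch%03d", seq_len(d[2]))
  }
  stopifnot(is.numeric(sfreq), length(sfreq) == 1, sfreq > 0)
  structure(list(data = data, labels = labels, sfreq = sfreq,
                 channels = channels, metadata = metadata),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<trial_set> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$sfreq))
  if (is.null(x$labels)) {
    cat("  unlabeled\n")
  } else {
    tab <- table(x$labels)
    cat("  labels:", paste(sprintf("class %s: %d", names(tab), tab),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of trials in a trial set
#' @param ts a [trial_set()].
#' @return integer trial count.
#' @export
n_trials <- function(ts) dim(ts$data)[1]

#' Extract one trial as a channels x samples matrix
#' @param ts a [trial_set()].
#' @param i trial index.
#' @return numeric matrix, channels x samples.
#' @export
trial_matrix <- function(ts, i) {
  matrix(ts$data[i, , ], nrow = dim(ts$data)[2])
}

#' Subset a trial set by trial index
#' @param ts a [trial_set()].
#' @param idx integer indices of trials to keep.
#' @return a [trial_set()] with the selected trials.
#' @export
subset_trials <- function(ts, idx) {
  trial_set(ts$data[idx, , , drop = FALSE],
            labels = if (is.null(ts$labels)) NULL else ts$labels[idx],
            sfreq = ts$sfreq, channels = ts$channels, metadata = ts$metadata)
}

#' Trace-normalized sample covariance of one trial
#'
#' `C = X X^T / tr(X X^T)` for a channels x samples trial matrix `X`. No mean
#' subtraction is applied: bandpassed EEG is approximately zero-mean and the
#' raw outer product is the estimator the downstream filters assume. The trace
#' normalization removes per-trial global amplitude, so the result is
#' invariant to rescaling the trial.
#'
#' @param X numeric matrix, channels x samples (>= 2 samples).
#' @return symmetric positive semidefinite matrix with unit trace (strictly
#'   SPD when `X` has full row rank).
#' @export
trial_covariance <- function(X) {
  if (!is.matrix(X) || !is.numeric(X)) stop("'X' must be a numeric matrix", call. = FALSE)
  if (ncol(X) < 2) stop("trial must have at least 2 samples", call. = FALSE)
  C <- tcrossprod(X)
  tr <- sum(diag(C))
  if (tr <= 0) stop("all-zero trial: covariance trace is 0", call. = FALSE)
  symmetrize(C / tr)
}

#' Per-trial covariances of a trial set
#'
#' @param ts a [trial_set()].
#' @return list of unit-trace covariance matrices, one per trial.
#' @export
trial_covariances <- function(ts) {
  lapply(seq_len(n_trials(ts)), function(i) trial_covariance(trial_matrix(ts, i)))
}

#' Composite covariance matrix of one class
#'
#' Accumulates the trace-normalized trial covariances of all trials with the
#' given label, either as their literal sum or as their mean. The mean is the
#' default: when a smoothness penalty `alpha * K` is added to a class
#' covariance, a sum would make the effective `alpha` depend on the
#' training-set size, while the mean keeps one `alpha` grid comparable across
#' subjects. `mode = "sum"` is kept for literal reproduction of the summed
#' form.
#'
#' @param ts a labeled [trial_set()].
#' @param class_id class label whose trials to accumulate.
#' @param mode `"mean"` (default) or `"sum"`.
#' @return symmetric positive semidefinite matrix.
#' @export
class_covariance <- function(ts, class_id, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  if (is.null(ts$labels)) stop("trial set is unlabeled", call. = FALSE)
  idx <- which(ts$labels == class_id)
  if (length(idx) == 0) {
    stop(sprintf("no trials with class %s", class_id), call. = FALSE)
  }
  acc <- Reduce(`+`, lapply(idx, function(i) trial_covariance(trial_matrix(ts, i))))
  if (mode == "mean") acc <- acc / length(idx)
  symmetrize(acc)
}
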