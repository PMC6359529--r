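#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end classifier. Defaults follow
#' standard motor-imagery practice: a 7-30 Hz band (alpha + beta rhythms,
#' where event-related (de)synchronization is expressed), a 5th-order
#' Butterworth bandpass applied forward-backward (zero phase), the epoch
#' 0.5-2.5 s after the visual cue, and hyperparameter grids
#' `alpha in 10^-10..10^-1` and `r in 0.01..0.1`.
#'
#' @param band numeric length-2, bandpass edges in Hz.
#' @param filter_order Butterworth order (default 5).
#' @param epoch numeric length-2, epoch window in seconds after the cue;
#'   half-open `[start, end)` so 100 Hz and `c(0.5, 2.5)` give exactly 200
#'   samples.
#' @param k spatial filter pairs (the projected trials have `2k` channels).
#' @param alpha_grid regularization weights searched by [grid_search()].
#' @param r_grid kernel widths searched by [grid_search()].
#' @param cv_folds stratified CV folds; `NULL` (default) uses 5, or
#'   leave-one-out when the smallest class has fewer than 10 trials.
#' @param seed integer seed for fold assignment.
#' @param fgda_components discriminant directions kept by [fit_fgda()].
#' @param shrinkage within-scatter shrinkage for [fit_fgda()].
#' @param covariance_mode `"mean"` or `"sum"` for [class_covariance()].
#' @param zero_phase apply the bandpass forward-backward (default `TRUE`);
#'   `FALSE` gives a single causal pass.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(band = c(7, 30), filter_order = 5L,
                            epoch = c(0.5, 2.5), k = 3L,
                            alpha_grid = 10^seq(-10, -1),
                            r_grid = seq(0.01, 0.1, by = 0.01),
                            cv_folds = NULL, seed = 1L,
                            fgda_components = 1L, shrinkage = 0.05,
                            covariance_mode = c("mean", "sum"),
                            zero_phase = TRUE) {
  covariance_mode <- match.arg(covariance_mode)
  stopifnot(length(band) == 2, band[1] > 0, band[1] < band[2],
            length(epoch) == 2, epoch[1] < epoch[2],
            length(alpha_grid) >= 1, length(r_grid) >= 1,
            all(alpha_grid >= 0), all(r_grid > 0), k >= 1)
  structure(list(band = as.numeric(band), filter_order = as.integer(filter_order),
                 epoch = as.numeric(epoch), k = as.integer(k),
                 alpha_grid = as.numeric(alpha_grid), r_grid = as.numeric(r_grid),
                 cv_folds = if (is.null(cv_folds)) NULL else as.integer(cv_folds),
                 seed = as.integer(seed),
                 fgda_components = as.integer(fgda_components),
                 shrinkage = shrinkage, covariance_mode = covariance_mode,
                 zero_phase = isTRUE(zero_phase)),
            class = "pipeline_config")
}

# run expr, prefixing any error with the pipeline stage name
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

# evaluate expr with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Bandpass-filter and epoch EEG trials
#'
#' Applies the configured Butterworth bandpass to every channel of every
#' trial (forward-backward by default, so the net filter has zero phase and
#' double the nominal order) and then extracts the epoch window relative to
#' the cue. For a `trial_set`, each trial is assumed cue-aligned with the cue
#' at its first sample; for a continuous recording (channels x samples
#' matrix), `cues` gives cue onset times in seconds and the whole recording
#' is filtered before epochs are cut.
#'
#' Epochs are half-open `[start, end)`: at 100 Hz the default 0.5-2.5 s
#' window yields exactly 200 samples.
#'
#' @param x a [trial_set()] of cue-aligned raw trials, or a channels x
#'   samples numeric matrix of continuous data.
#' @param cfg a [pipeline_config()].
#' @param cues cue onset times in seconds (continuous input only).
#' @param sfreq sampling rate in Hz (continuous input only).
#' @param labels optional labels for continuous input epochs.
#' @return a [trial_set()] of bandpassed, epoched trials.
#' @export
preprocess <- function(x, cfg = pipeline_config(), cues = NULL, sfreq = NULL,
                       labels = NULL) {
  if (is.matrix(x)) {
    if (is.null(cues) || is.null(sfreq)) {
      stop("continuous input needs 'cues' and 'sfreq'", call. = FALSE)
    }
    return(.preprocess_continuous(x, cues, sfreq, cfg, labels))
  }
  stopifnot(inherits(x, "trial_set"))
  fs <- x$sfreq
  bf <- .design_bandpass(cfg, fs)
  d <- dim(x$data)
  i0 <- round(cfg$epoch[1] * fs) + 1L
  n_ep <- round((cfg$epoch[2] - cfg$epoch[1]) * fs)
  if (i0 + n_ep - 1L > d[3]) {
    stop(sprintf("epoch [%g, %g) s needs %d samples but trials have only %d",
                 cfg$epoch[1], cfg$epoch[2], i0 + n_ep - 1L, d[3]), call. = FALSE)
  }
  out <- array(0, dim = c(d[1], d[2], n_ep))
  for (i in seq_len(d[1])) {
    X <- trial_matrix(x, i)
    Xf <- t(apply(X, 1, .apply_bandpass, bf = bf, zero_phase = cfg$zero_phase))
    out[i, , ] <- Xf[, i0:(i0 + n_ep - 1L), drop = FALSE]
  }
  trial_set(out, labels = x$labels, sfreq = fs, channels = x$channels,
            metadata = x$metadata)
}

.design_bandpass <- function(cfg, fs) {
  nyq <- fs / 2
  if (cfg$band[2] >= nyq) {
    stop(sprintf("band edge %g Hz is at or above Nyquist (%g Hz)",
                 cfg$band[2], nyq), call. = FALSE)
  }
  signal::butter(cfg$filter_order, cfg$band / nyq, type = "pass")
}

.apply_bandpass <- function(v, bf, zero_phase) {
  if (zero_phase) signal::filtfilt(bf, v) else as.numeric(signal::filter(bf, v))
}

.preprocess_continuous <- function(x, cues, sfreq, cfg, labels) {
  bf <- .design_bandpass(cfg, sfreq)
  xf <- t(apply(x, 1, .apply_bandpass, bf = bf, zero_phase = cfg$zero_phase))
  n_ep <- round((cfg$epoch[2] - cfg$epoch[1]) * sfreq)
  out <- array(0, dim = c(length(cues), nrow(x), n_ep))
  for (i in seq_along(cues)) {
    i0 <- round((cues[i] + cfg$epoch[1]) * sfreq) + 1L
    if (i0 < 1 || i0 + n_ep - 1L > ncol(x)) {
      stop(sprintf("epoch for cue %d (t = %g s) exceeds recording bounds",
                   i, cues[i]), call. = FALSE)
    }
    out[i, , ] <- xf[, i0:(i0 + n_ep - 1L)]
  }
  trial_set(out, labels = labels, sfreq = sfreq, channels = rownames(x))
}

# Filtered SCM directly from a full-dimension unit-trace SCM:
# Z Z' = W X X' W' is proportional to W C W', and trace normalization
# removes the proportionality constant.
.project_scm <- function(W, C) {
  M <- symmetrize(W %*% C %*% t(W))
  M / sum(diag(M))
}

# Core fit from precomputed full-dimension trial SCMs; shared by
# fit_srmdrm() and the cross-validation loop so both take the same path.
.fit_core <- function(scms, labels, C1, C2, K, alpha, cfg) {
  fb <- .stage("srcsp", srcsp_filters(C1, C2, K, alpha, k = cfg$k))
  covs <- .stage("covariance", lapply(scms, .project_scm, W = fb$W))
  fgda <- .stage("fgda", fit_fgda(covs, labels,
                                  n_components = cfg$fgda_components,
                                  shrinkage = cfg$shrinkage))
  filtered <- .stage("geodesic_filter", lapply(covs, geodesic_filter, fgda = fgda))
  model <- .stage("mdrm", fit_mdrm(filtered, labels))
  list(filters = fb, fgda = fgda, model = model)
}

#' Fit the spatially regularized Riemannian pipeline
#'
#' End-to-end training at a fixed `(alpha, r)`: per-class composite
#' covariances, SRCSP filter learning with the montage-derived smoothness
#' penalty, projection of every trial to `2k` virtual channels, unit-trace
#' covariances of the projected trials, FGDA fitting plus geodesic filtering
#' of the training covariances, and per-class Riemannian means for MDRM.
#' Trials are expected preprocessed (see [preprocess()]).
#'
#' @param train a labeled, preprocessed [trial_set()].
#' @param montage an [electrode_montage()] matching the channel count.
#' @param alpha smoothness weight (>= 0).
#' @param r Gaussian kernel width (> 0).
#' @param cfg a [pipeline_config()].
#' @return object of class `fitted_pipeline` with fields `filters`, `fgda`,
#'   `model`, `alpha`, `r`, `config`, `classes`.
#' @export
fit_srmdrm <- function(train, montage, alpha, r, cfg = pipeline_config()) {
  stopifnot(inherits(train, "trial_set"), inherits(montage, "electrode_montage"))
  if (is.null(train$labels)) stop("training set must be labeled", call. = FALSE)
  if (length(montage$labels) != dim(train$data)[2]) {
    stop("montage channel count does not match trial set", call. = FALSE)
  }
  classes <- sort(unique(train$labels))
  if (length(classes) != 2) stop("exactly 2 classes required", call. = FALSE)
  scms <- .stage("covariance", trial_covariances(train))
  agg <- function(cl) {
    acc <- Reduce(`+`, scms[train$labels == cl])
    if (cfg$covariance_mode == "mean") acc / sum(train$labels == cl) else acc
  }
  C1 <- agg(classes[1]); C2 <- agg(classes[2])
  K <- .stage("penalty", spatial_penalty(montage, r))
  parts <- .fit_core(scms, train$labels, C1, C2, K, alpha, cfg)
  structure(c(parts, list(alpha = alpha, r = r, config = cfg,
                          classes = classes)),
            class = "fitted_pipeline")
}

#' @export
print.fitted_pipeline <- function(x, ...) {
  cat(sprintf("<fitted_pipeline> srcsp(alpha = %g, r = %g, k = %d) + fgda(%d) + mdrm\n",
              x$alpha, x$r, x$config$k, x$fgda$n_components))
  invisible(x)
}

#' Predict labels for preprocessed test trials
#'
#' Projects each test trial through the fitted spatial filters, computes its
#' unit-trace covariance, applies the fitted geodesic filter, and assigns the
#' class of the nearest Riemannian mean.
#'
#' @param fp a [fit_srmdrm()] fit.
#' @param test a preprocessed [trial_set()] (labels ignored if present).
#' @return list with `labels` and per-class `distances` (one row per trial).
#' @export
predict_srmdrm <- function(fp, test) {
  stopifnot(inherits(fp, "fitted_pipeline"), inherits(test, "trial_set"))
  if (ncol(fp$filters$W) != dim(test$data)[2]) {
    stop("test trial set channel count does not match fitted filters", call. = FALSE)
  }
  scms <- .stage("covariance", trial_covariances(test))
  covs <- lapply(scms, .project_scm, W = fp$filters$W)
  filtered <- .stage("geodesic_filter", lapply(covs, geodesic_filter, fgda = fp$fgda))
  .stage("mdrm", predict_mdrm(fp$model, filtered))
}

# stratified fold assignment; LOO when the smallest class has < 10 trials
.assign_folds <- function(labels, cv_folds, seed) {
  min_class <- min(table(labels))
  folds <- if (is.null(cv_folds)) {
    if (min_class < 10) length(labels) else 5L
  } else cv_folds
  if (folds == length(labels)) {           # leave-one-out
    return(list(assign = seq_along(labels), n_folds = length(labels)))
  }
  if (folds > min_class) {
    stop(sprintf("%d folds but smallest class has %d trials; use fewer folds",
                 folds, min_class), call. = FALSE)
  }
  assign <- integer(length(labels))
  .with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  list(assign = assign, n_folds = folds)
}

#' Select (alpha, r) by stratified cross-validation on the training set
#'
#' Evaluates every pair in `cfg$alpha_grid` x `cfg$r_grid` by stratified
#' k-fold cross-validation (leave-one-out for very small classes), using only
#' the training trials. Ties in mean CV accuracy are broken toward larger
#' `alpha`, then larger `r` — preferring the smoothest filters among equally
#' accurate settings.
#'
#' @inheritParams fit_srmdrm
#' @return list with `alpha`, `r`, `cv_table` (data frame: alpha, r,
#'   accuracy) and `n_folds`.
#' @export
grid_search <- function(train, montage, cfg = pipeline_config()) {
  stopifnot(inherits(train, "trial_set"))
  if (is.null(train$labels)) stop("training set must be labeled", call. = FALSE)
  classes <- sort(unique(train$labels))
  if (length(classes) != 2) stop("exactly 2 classes required", call. = FALSE)
  labels <- train$labels
  fa <- .assign_folds(labels, cfg$cv_folds, cfg$seed)

  scms <- trial_covariances(train)
  Ks <- lapply(cfg$r_grid, function(r) spatial_penalty(montage, r))
  # per-fold class covariances from the fold's training part
  fold_cov <- lapply(seq_len(fa$n_folds), function(f) {
    tr <- fa$assign != f
    if (length(unique(labels[tr])) < 2) {
      stop("a CV fold is missing a class; use fewer folds", call. = FALSE)
    }
    agg <- function(cl) {
      sel <- tr & labels == cl
      acc <- Reduce(`+`, scms[sel])
      if (cfg$covariance_mode == "mean") acc / sum(sel) else acc
    }
    list(C1 = agg(classes[1]), C2 = agg(classes[2]), train = tr)
  })

  grid <- expand.grid(alpha = cfg$alpha_grid, r = cfg$r_grid,
                      KEEP.OUT.ATTRS = FALSE)
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    K <- Ks[[match(grid$r[g], cfg$r_grid)]]
    correct <- 0L
    for (f in seq_len(fa$n_folds)) {
      fc <- fold_cov[[f]]
      te <- which(!fc$train)
      fit <- .fit_core(scms[fc$train], labels[fc$train],
                       fc$C1, fc$C2, K, grid$alpha[g], cfg)
      covs <- lapply(scms[te], .project_scm, W = fit$filters$W)
      filt <- lapply(covs, geodesic_filter, fgda = fit$fgda)
      pred <- predict_mdrm(fit$model, filt)$labels
      correct <- correct + sum(pred == labels[te])
    }
    acc[g] <- correct / length(labels)
  }
  cv_table <- data.frame(alpha = grid$alpha, r = grid$r, accuracy = acc)
  # argmax; ties broken toward larger alpha, then larger r
  best <- order(-cv_table$accuracy, -cv_table$alpha, -cv_table$r)[1]
  list(alpha = cv_table$alpha[best], r = cv_table$r[best],
       cv_table = cv_table, n_folds = fa$n_folds)
}

#' CSP and plain-MDRM baselines
#'
#' Runs the two conventional references under identical preprocessing:
#' (i) CSP filters plus a Fisher linear discriminant on log-variance features
#' of the projected trials, and (ii) MDRM on the full-dimension trial
#' covariances (no spatial filtering, no FGDA).
#'
#' @param train,test labeled, preprocessed [trial_set()]s.
#' @param montage an [electrode_montage()] (interface symmetry with
#'   [fit_srmdrm()]; the baselines use no spatial prior).
#' @param cfg a [pipeline_config()].
#' @return named list of `mi_evaluation` objects (`csp`, `mdrm`), each with a
#'   `predictions` attribute.
#' @export
run_baselines <- function(train, test, montage = NULL, cfg = pipeline_config()) {
  stopifnot(inherits(train, "trial_set"), inherits(test, "trial_set"))
  if (is.null(train$labels) || is.null(test$labels)) {
    stop("baselines need labeled train and test sets", call. = FALSE)
  }
  classes <- sort(unique(train$labels))
  C1 <- class_covariance(train, classes[1], mode = cfg$covariance_mode)
  C2 <- class_covariance(train, classes[2], mode = cfg$covariance_mode)

  # CSP + LDA on log-variance features
  fb <- csp_filters(C1, C2, k = cfg$k)
  logvar <- function(ts) {
    t(vapply(seq_len(n_trials(ts)), function(i) {
      Z <- fb$W %*% trial_matrix(ts, i)
      log(rowSums(Z^2) / ncol(Z))
    }, numeric(2 * cfg$k)))
  }
  ftr <- logvar(train); fte <- logvar(test)
  lda <- MASS::lda(ftr, grouping = factor(train$labels))
  csp_pred <- as.integer(as.character(stats::predict(lda, fte)$class))
  csp_eval <- evaluate_predictions(csp_pred, test$labels)
  attr(csp_eval, "predictions") <- csp_pred

  # full-dimension MDRM
  m <- fit_mdrm(trial_covariances(train), train$labels)
  mdrm_pred <- predict_mdrm(m, trial_covariances(test))$labels
  mdrm_eval <- evaluate_predictions(mdrm_pred, test$labels)
  attr(mdrm_eval, "predictions") <- mdrm_pred

  list(csp = csp_eval, mdrm = mdrm_eval)
}
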