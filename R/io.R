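#' Write a trial set to a container file
#'
#' Serializes the named arrays `data` (trials x channels x samples), `labels`,
#' `sfreq`, `channels` and `metadata` as an RDS file — R's native lossless
#' array container. Round-trips are bit-identical.
#'
#' @param ts a [trial_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(ts, path) {
  stopifnot(inherits(ts, "trial_set"))
  saveRDS(list(data = ts$data, labels = ts$labels, sfreq = ts$sfreq,
               channels = ts$channels, metadata = ts$metadata),
          path, version = 2)
  invisible(path)
}

#' Read a trial set from a container file
#'
#' Validates the layout written by [write_trials()]: `data` and `sfreq` are
#' required; `labels` may be absent (unlabeled test sets) but, when present,
#' must match the trial count.
#'
#' @param path file written by [write_trials()].
#' @return a [trial_set()].
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  obj <- readRDS(path)
  for (field in c("data", "sfreq")) {
    if (is.null(obj[[field]])) {
      stop(sprintf("malformed trial container: missing field '%s'", field),
           call. = FALSE)
    }
  }
  trial_set(obj$data, labels = obj$labels, sfreq = obj$sfreq,
            channels = obj$channels,
            metadata = if (is.null(obj$metadata)) list() else obj$metadata)
}

#' Read an electrode montage from a text file
#'
#' One channel per line, whitespace-separated `label x y z` (the common
#' .sfp-style electrode position layout); lines starting with `#` and blank
#' lines are skipped. Duplicate labels and non-numeric coordinates are
#' rejected with the offending line number.
#'
#' @param path montage text file.
#' @return an [electrode_montage()].
#' @export
read_montage <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  labels <- character(0)
  coords <- matrix(numeric(0), ncol = 3)
  for (ln in seq_along(lines)) {
    s <- trimws(lines[ln])
    if (s == "" || startsWith(s, "#")) next
    parts <- strsplit(s, "[[:space:]]+")[[1]]
    if (length(parts) != 4) {
      stop(sprintf("montage parse error at line %d: expected 'label x y z'", ln),
           call. = FALSE)
    }
    xyz <- suppressWarnings(as.numeric(parts[2:4]))
    if (any(is.na(xyz))) {
      stop(sprintf("montage parse error at line %d: non-numeric coordinate", ln),
           call. = FALSE)
    }
    if (parts[1] %in% labels) {
      stop(sprintf("montage parse error at line %d: duplicate label '%s'",
                   ln, parts[1]), call. = FALSE)
    }
    labels <- c(labels, parts[1])
    coords <- rbind(coords, xyz)
  }
  if (length(labels) == 0) stop("montage file contains no channels", call. = FALSE)
  electrode_montage(labels, coords)
}

#' Write an electrode montage to a text file
#'
#' @param montage an [electrode_montage()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_montage <- function(montage, path) {
  stopifnot(inherits(montage, "electrode_montage"))
  lines <- sprintf("%s %.17g %.17g %.17g", montage$labels,
                   montage$coords[, 1], montage$coords[, 2], montage$coords[, 3])
  writeLines(c("# label x y z", lines), path)
  invisible(path)
}

#' Write per-trial predictions to CSV
#'
#' One row per trial: index, predicted label, and the Riemannian distance to
#' each class mean.
#'
#' @param pred prediction list from [predict_srmdrm()] or [predict_mdrm()].
#' @param path output CSV path.
#' @return the written data frame, invisibly.
#' @export
write_predictions <- function(pred, path) {
  D <- pred$distances
  df <- data.frame(trial = seq_along(pred$labels), predicted = pred$labels)
  for (j in seq_len(ncol(D))) df[[paste0("dist_class_", colnames(D)[j])]] <- D[, j]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
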