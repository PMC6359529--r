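#' Fit a minimum-distance-to-Riemannian-mean (MDRM) classifier
#'
#' Computes the Riemannian mean of the training covariance matrices of each
#' class. Prediction assigns a test covariance to the class whose mean is
#' geodesically closest, so the whole classifier is a set of per-class means.
#'
#' @param train list of SPD matrices (training covariances).
#' @param labels class labels, one per matrix; every class needs at least one.
#' @param tol,max_iter convergence controls passed to [riemannian_mean()].
#' @return object of class `mdrm_model` with fields `class_means` (named list
#'   of SPD matrices) and `classes` (sorted class labels).
#' @export
fit_mdrm <- function(train, labels, tol = 1e-8, max_iter = 50L) {
  stopifnot(is.list(train), length(train) == length(labels))
  if (length(train) == 0) stop("empty training set", call. = FALSE)
  classes <- sort(unique(labels))
  if (length(classes) < 2) {
    stop("training set must contain at least 2 classes", call. = FALSE)
  }
  means <- lapply(classes, function(cl) {
    riemannian_mean(train[labels == cl], tol = tol, max_iter = max_iter)
  })
  names(means) <- as.character(classes)
  structure(list(class_means = means, classes = classes), class = "mdrm_model")
}

#' @export
print.mdrm_model <- function(x, ...) {
  cat(sprintf("<mdrm_model> %d classes, %d x %d covariance means\n",
              length(x$classes), nrow(x$class_means[[1]]), ncol(x$class_means[[1]])))
  invisible(x)
}

#' Predict class labels by minimum Riemannian distance
#'
#' For each covariance matrix, computes the geodesic distance to every class
#' mean and returns the closest class. Exact ties are broken toward the
#' lowest class index with a warning.
#'
#' @param model a fitted [fit_mdrm()] model.
#' @param C a single SPD matrix or a list of them.
#' @return list with `labels` (predicted classes) and `distances`
#'   (matrix, one row per input, one column per class).
#' @export
predict_mdrm <- function(model, C) {
  stopifnot(inherits(model, "mdrm_model"))
  if (is.matrix(C)) C <- list(C)
  n <- nrow(model$class_means[[1]])
  D <- t(vapply(C, function(Ci) {
    if (!identical(dim(Ci), c(n, n))) {
      stop(sprintf("covariance dimension %d does not match model dimension %d",
                   nrow(Ci), n), call. = FALSE)
    }
    vapply(model$class_means, function(M) riemannian_distance(Ci, M), numeric(1))
  }, numeric(length(model$classes))))
  D <- matrix(D, ncol = length(model$classes),
              dimnames = list(NULL, as.character(model$classes)))
  labs <- vapply(seq_len(nrow(D)), function(i) {
    d <- D[i, ]
    j <- which(d <= min(d) * (1 + 1e-12))
    if (length(j) > 1) {
      warning(sprintf("trial %d equidistant from %d class means; choosing lowest class",
                      i, length(j)), call. = FALSE)
    }
    model$classes[j[1]]
  }, model$classes[1])
  list(labels = labs, distances = D)
}

#' Binary classification accuracy and kappa
#'
#' Builds the binary confusion counts and reports accuracy, the
#' chance-corrected kappa coefficient and the counts themselves. With `a`
#' true positives, `b` true negatives, `c` false positives and `d` false
#' negatives: `accuracy = (a + b) / (a + b + c + d)`, the accuracy of a
#' random system with the same marginals is
#' `((b + c)(b + d) + (d + a)(c + a)) / (a + b + c + d)^2`, and
#' `kappa = (accuracy - random) / (1 - random)`. When the random accuracy is
#' exactly 1 (a single outcome on both sides) kappa is undefined and reported
#' as `NA`.
#'
#' @param pred predicted labels.
#' @param truth true labels (same length, exactly 2 distinct classes between
#'   them).
#' @param positive_class which label counts as positive (default: the lowest).
#' @return object of class `mi_evaluation`: list with `accuracy`, `kappa`,
#'   `random_accuracy` and `counts` (named a, b, c, d).
#' @export
evaluate_predictions <- function(pred, truth, positive_class = NULL) {
  if (length(pred) != length(truth) || length(pred) == 0) {
    stop("'pred' and 'truth' must be nonempty and of equal length", call. = FALSE)
  }
  classes <- sort(unique(c(pred, truth)))
  if (length(classes) > 2) stop("binary evaluation only", call. = FALSE)
  if (is.null(positive_class)) positive_class <- classes[1]
  pos <- truth == positive_class
  ppos <- pred == positive_class
  a <- sum(pos & ppos)       # positives correctly identified
  b <- sum(!pos & !ppos)     # negatives correctly identified
  c_ <- sum(!pos & ppos)     # negatives called positive
  d <- sum(pos & !ppos)      # positives called negative
  n <- a + b + c_ + d
  acc <- (a + b) / n
  rand <- ((b + c_) * (b + d) + (d + a) * (c_ + a)) / n^2
  kappa <- if (rand >= 1) NA_real_ else (acc - rand) / (1 - rand)
  structure(list(accuracy = acc, kappa = kappa, random_accuracy = rand,
                 counts = c(a = a, b = b, c = c_, d = d)),
            class = "mi_evaluation")
}

#' @export
print.mi_evaluation <- function(x, ...) {
  cat(sprintf("<mi_evaluation> accuracy %.4f, kappa %s (a=%d b=%d c=%d d=%d)\n",
              x$accuracy,
              if (is.na(x$kappa)) "undefined" else sprintf("%.4f", x$kappa),
              x$counts["a"], x$counts["b"], x$counts["c"], x$counts["d"]))
  invisible(x)
}
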