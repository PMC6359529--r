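#' Tangent-space vectorization of an SPD matrix
#'
#' Maps `Ci` to the tangent space at `C_ref` via [log_map()] and flattens the
#' resulting symmetric matrix to a vector of length `n(n+1)/2`: upper triangle
#' in column-major order, off-diagonal entries weighted by `sqrt(2)` so that
#' the Euclidean norm of the vector equals the Frobenius norm of the tangent
#' matrix.
#'
#' @param C_ref SPD reference point.
#' @param Ci SPD matrix to vectorize.
#' @return numeric vector of length `n(n+1)/2`.
#' @export
tangent_vectorize <- function(C_ref, Ci) {
  S <- log_map(C_ref, Ci)
  .vec_sym(S)
}

.vec_sym <- function(S) {
  n <- nrow(S)
  w <- matrix(sqrt(2), n, n)
  diag(w) <- 1
  (S * w)[upper.tri(S, diag = TRUE)]
}

.unvec_sym <- function(v) {
  n <- (sqrt(8 * length(v) + 1) - 1) / 2
  if (abs(n - round(n)) > 1e-8) stop("vector length is not n(n+1)/2", call. = FALSE)
  n <- round(n)
  S <- matrix(0, n, n)
  S[upper.tri(S, diag = TRUE)] <- v
  S <- S + t(S)
  diag(S) <- diag(S) / 2
  w <- matrix(sqrt(2), n, n)
  diag(w) <- 1
  S / w
}

#' Fit a Fisher geodesic discriminant (FGDA) filter
#'
#' Anchors the tangent space at the Riemannian mean of the training
#' covariances, vectorizes every covariance there, and computes Fisher linear
#' discriminant directions of the tangent vectors: the directions maximizing
#' between-class scatter relative to (shrinkage-regularized) within-class
#' scatter. The fitted filter is the orthogonal projection onto the span of
#' the top `n_components` discriminant directions, assembled as
#' `W (W'W)^{-1} W'`. Applied through [geodesic_filter()] it denoises SPD
#' matrices by discarding tangent directions that carry no class information,
#' without changing their dimension.
#'
#' The within-class scatter is shrunk toward a scaled identity,
#' `(1 - s) Sw + s (tr(Sw)/d) I`: the tangent dimension `n(n+1)/2` routinely
#' exceeds the number of training trials in small calibration sets, so the raw
#' scatter can be singular.
#'
#' @param train list of SPD matrices (training covariances).
#' @param labels class labels, one per matrix; at least 2 classes with at
#'   least 2 matrices each.
#' @param n_components number of discriminant directions kept (default 1, the
#'   full Fisher spectrum of a binary problem). Values at or above the
#'   tangent dimension give the identity projector (a no-op filter).
#' @param shrinkage within-scatter shrinkage in `[0, 1]` (default 0.05).
#' @return object of class `fgda_filter` with fields `reference` (tangent
#'   anchor), `projector`, `directions`, `fisher_ratios`, `n_components`,
#'   `shrinkage`.
#' @export
fit_fgda <- function(train, labels, n_components = 1L, shrinkage = 0.05) {
  stopifnot(is.list(train), length(train) == length(labels))
  if (!is.numeric(shrinkage) || shrinkage < 0 || shrinkage > 1) {
    stop("'shrinkage' must be in [0, 1]", call. = FALSE)
  }
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes", call. = FALSE)
  if (any(table(labels) < 2)) stop("need at least 2 samples per class", call. = FALSE)

  ref <- riemannian_mean(train)
  V <- t(vapply(train, function(C) tangent_vectorize(ref, C),
                numeric(nrow(ref) * (nrow(ref) + 1) / 2)))
  d <- ncol(V)
  n_components <- min(as.integer(n_components), d)
  if (n_components < 1) stop("'n_components' must be >= 1", call. = FALSE)
  if (n_components == d) {
    P <- diag(d)
    return(structure(list(reference = ref, projector = P, directions = diag(d),
                          fisher_ratios = rep(NA_real_, d),
                          n_components = d, shrinkage = shrinkage),
                     class = "fgda_filter"))
  }

  mu <- colMeans(V)
  Sw <- matrix(0, d, d)
  Sb <- matrix(0, d, d)
  for (cl in classes) {
    Vc <- V[labels == cl, , drop = FALSE]
    mc <- colMeans(Vc)
    Sw <- Sw + crossprod(sweep(Vc, 2, mc))
    Sb <- Sb + nrow(Vc) * tcrossprod(mc - mu)
  }
  Sw <- (1 - shrinkage) * Sw + shrinkage * (sum(diag(Sw)) / d) * diag(d)
  ew <- eigen(symmetrize(Sw), symmetric = TRUE, only.values = TRUE)$values
  if (min(ew) <= 1e-12 * max(ew)) {
    stop("within-class scatter is singular; use shrinkage > 0", call. = FALSE)
  }
  # whiten by Sw^{-1/2}: symmetric problem with real eigenpairs
  Wih <- matrix_power(Sw, -0.5)
  eb <- eigen(symmetrize(Wih %*% Sb %*% Wih), symmetric = TRUE)
  dirs <- Wih %*% eb$vectors[, seq_len(n_components), drop = FALSE]
  dirs <- apply(dirs, 2, function(u) u / sqrt(sum(u^2)))
  dirs <- matrix(dirs, nrow = d)
  P <- dirs %*% solve(crossprod(dirs), t(dirs))
  structure(list(reference = ref, projector = symmetrize(P), directions = dirs,
                 fisher_ratios = eb$values[seq_len(n_components)],
                 n_components = n_components, shrinkage = shrinkage),
            class = "fgda_filter")
}

#' @export
print.fgda_filter <- function(x, ...) {
  cat(sprintf("<fgda_filter> %d component(s) on %d-dim tangent space (shrinkage %.3g)\n",
              x$n_components, nrow(x$projector), x$shrinkage))
  invisible(x)
}

#' Geodesic filtering of an SPD matrix
#'
#' Vectorizes `C` in the tangent space at the filter's reference point,
#' applies the discriminant projector, and maps the result back to the
#' manifold. The output is SPD with the same dimension as the input, and the
#' operation is idempotent: filtering twice equals filtering once.
#'
#' @param fgda a fitted [fit_fgda()] filter.
#' @param C SPD matrix (dimension matching the filter's reference).
#' @return SPD matrix of the same dimension.
#' @export
geodesic_filter <- function(fgda, C) {
  stopifnot(inherits(fgda, "fgda_filter"))
  if (!identical(dim(C), dim(fgda$reference))) {
    stop("dimension mismatch with filter reference", call. = FALSE)
  }
  v <- tangent_vectorize(fgda$reference, C)
  exp_map(fgda$reference, .unvec_sym(as.numeric(fgda$projector %*% v)))
}
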