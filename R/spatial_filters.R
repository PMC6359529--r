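#' Electrode montages
#'
#' An `electrode_montage` pairs unique channel labels with 3D electrode
#' positions (consistent length units; the synthetic generator uses a unit
#' head radius). The positions are the prior knowledge behind the spatial
#' smoothness penalty: nearby electrodes measure similar cortical activity,
#' so a good spatial filter should assign them similar weights.
#'
#' @param labels character vector of unique channel names.
#' @param coords numeric matrix N x 3 of electrode positions.
#' @return object of class `electrode_montage`.
#' @export
electrode_montage <- function(labels, coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3 || nrow(coords) != length(labels)) {
    stop("'coords' must be an N x 3 matrix matching 'labels'", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop(sprintf("duplicate channel label: %s",
                 labels[duplicated(labels)][1]), call. = FALSE)
  }
  if (!all(is.finite(coords))) stop("electrode coordinates must be finite", call. = FALSE)
  storage.mode(coords) <- "double"
  rownames(coords) <- labels
  structure(list(labels = as.character(labels), coords = coords),
            class = "electrode_montage")
}

#' @export
print.electrode_montage <- function(x, ...) {
  cat(sprintf("<electrode_montage> %d channels\n", length(x$labels)))
  invisible(x)
}

#' Gaussian adjacency over an electrode montage
#'
#' `G[i, j] = exp(-||v_i - v_j||^2 / (2 r^2))`, where `v_i` is the 3D position
#' of electrode `i`. The kernel width `r` (same units as the coordinates) sets
#' how far apart two electrodes can be while still counting as neighbours.
#'
#' @param montage an [electrode_montage()].
#' @param r positive kernel width.
#' @return symmetric N x N matrix with unit diagonal and entries in (0, 1].
#' @export
gaussian_adjacency <- function(montage, r) {
  stopifnot(inherits(montage, "electrode_montage"))
  if (!is.numeric(r) || length(r) != 1 || r <= 0) {
    stop("'r' must be a positive scalar", call. = FALSE)
  }
  d2 <- as.matrix(stats::dist(montage$coords))^2
  G <- exp(-d2 / (2 * r^2))
  dimnames(G) <- list(montage$labels, montage$labels)
  G
}

#' Graph-Laplacian smoothness penalty
#'
#' `K = D - G` with `D[i, i] = sum_j G[i, j]` (self-adjacency included).
#' The quadratic form `w' K w = (1/2) sum_{i,j} G[i, j] (w_i - w_j)^2`
#' measures the spatial roughness of a filter `w`: it is zero for a constant
#' filter and large when neighbouring electrodes get very different weights.
#' `K` is positive semidefinite with zero row sums.
#'
#' @param G symmetric nonnegative adjacency matrix, e.g. from
#'   [gaussian_adjacency()].
#' @return object of class `penalty_matrix` (a symmetric PSD matrix with
#'   attribute `r` when built via [spatial_penalty()]).
#' @export
laplacian_penalty <- function(G) {
  if (!is.matrix(G) || max(abs(G - t(G))) > 1e-10 * max(abs(G), 1e-300)) {
    stop("'G' must be a symmetric matrix", call. = FALSE)
  }
  if (any(G < 0)) stop("'G' must have nonnegative entries", call. = FALSE)
  K <- diag(rowSums(G)) - G
  dimnames(K) <- dimnames(G)
  structure(symmetrize(K), class = c("penalty_matrix", "matrix"))
}

#' Spatial smoothness penalty from a montage
#'
#' Convenience composition of [gaussian_adjacency()] and
#' [laplacian_penalty()].
#'
#' @inheritParams gaussian_adjacency
#' @return a `penalty_matrix` with attribute `r`.
#' @export
spatial_penalty <- function(montage, r) {
  K <- laplacian_penalty(gaussian_adjacency(montage, r))
  attr(K, "r") <- r
  K
}

# Fix sign (first coefficient of nonnegligible magnitude made positive) and
# scale to unit Euclidean norm, per filter; keeps the bank deterministic.
.canonicalize_filters <- function(W) {
  t(apply(W, 1, function(w) {
    nrm <- sqrt(sum(w^2))
    if (nrm == 0) stop("degenerate zero filter", call. = FALSE)
    w <- w / nrm
    j <- which(abs(w) > 1e-10)[1]
    if (!is.na(j) && w[j] < 0) w <- -w
    w
  }))
}

.filter_bank <- function(W, eigenvalues, k, alpha, provenance) {
  structure(list(W = W, eigenvalues = eigenvalues, k = k, alpha = alpha,
                 provenance = provenance),
            class = "spatial_filter_bank")
}

#' @export
print.spatial_filter_bank <- function(x, ...) {
  cat(sprintf("<spatial_filter_bank> %s: %d filters on %d channels (k = %d, alpha = %g)\n",
              x$provenance, nrow(x$W), ncol(x$W), x$k, x$alpha))
  invisible(x)
}

# Leading k generalized eigenpairs of C w = lambda B w, solved via the
# symmetric whitened problem B^{-1/2} C B^{-1/2} u = lambda u, w = B^{-1/2} u.
.leading_gev <- function(C, B, k, what = "C + alpha*K") {
  P <- tryCatch(matrix_power(B, -0.5),
                error = function(e) stop(sprintf(
                  "'%s' is singular; consider a larger eigenvalue clip or alpha",
                  what), call. = FALSE))
  e <- eigen(symmetrize(P %*% C %*% P), symmetric = TRUE)
  W <- t(P %*% e$vectors[, seq_len(k), drop = FALSE])
  list(W = W, values = e$values[seq_len(k)])
}

#' Common spatial pattern (CSP) filters
#'
#' Solves the generalized eigenproblem `C1 w = lambda C2 w` (equivalently the
#' standard problem on `C2^{-1} C1`) and returns the `k` eigenvectors of
#' largest eigenvalue followed by the `k` of smallest eigenvalue, as rows.
#' The leading filters maximize class-1 variance relative to class-2 variance
#' and the trailing ones the reverse; together they extremize the variance
#' ratio between the two motor-imagery classes. Filters are unit-norm with a
#' deterministic sign convention.
#'
#' @param C1,C2 class covariance matrices (same dimension N).
#' @param k number of filter pairs; `2k <= N`.
#' @return a `spatial_filter_bank` with `2k` rows; field `eigenvalues` holds
#'   the generalized eigenvalue of each row (descending in the leading block,
#'   ascending in the trailing block).
#' @export
csp_filters <- function(C1, C2, k = 3L) {
  stopifnot(identical(dim(C1), dim(C2)))
  N <- nrow(C1)
  k <- as.integer(k)
  if (k < 1 || 2 * k > N) stop("'k' must satisfy 1 <= 2k <= N", call. = FALSE)
  P <- tryCatch(matrix_power(C2, -0.5),
                error = function(e) stop("'C2' is singular beyond clipping", call. = FALSE))
  e <- eigen(symmetrize(P %*% C1 %*% P), symmetric = TRUE)
  sel <- c(seq_len(k), N - seq_len(k) + 1L)
  W <- .canonicalize_filters(t(P %*% e$vectors[, sel, drop = FALSE]))
  .filter_bank(W, e$values[sel], k, alpha = 0, provenance = "csp")
}

#' Spatially regularized CSP (SRCSP) filters
#'
#' Adds the smoothness penalty `alpha * w' K w` to the denominator of each CSP
#' Rayleigh quotient. The two penalized objectives lead to the matrices
#' `M1 = (C2 + alpha K)^{-1} C1` and `M2 = (C1 + alpha K)^{-1} C2`; the bank
#' stacks the `k` leading eigenvectors of `M1` (class-1 filters) then the `k`
#' leading eigenvectors of `M2` (class-2 filters), each block descending by
#' eigenvalue. With `alpha = 0` the filter subspace coincides with plain CSP.
#' The non-symmetric eigenproblems are solved through their symmetric
#' whitened equivalents so eigenpairs are always real.
#'
#' @param C1,C2 class covariance matrices.
#' @param K penalty matrix from [spatial_penalty()] / [laplacian_penalty()].
#' @param alpha nonnegative regularization weight.
#' @param k filter pairs; `2k <= N`.
#' @return a `spatial_filter_bank` with `2k` rows.
#' @export
srcsp_filters <- function(C1, C2, K, alpha, k = 3L) {
  stopifnot(identical(dim(C1), dim(C2)), identical(dim(C1), dim(unclass(K))))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0) {
    stop("'alpha' must be a nonnegative scalar", call. = FALSE)
  }
  N <- nrow(C1)
  k <- as.integer(k)
  if (k < 1 || 2 * k > N) stop("'k' must satisfy 1 <= 2k <= N", call. = FALSE)
  K <- unclass(K)
  g1 <- .leading_gev(C1, symmetrize(C2 + alpha * K), k, "C2 + alpha*K")
  g2 <- .leading_gev(C2, symmetrize(C1 + alpha * K), k, "C1 + alpha*K")
  W <- .canonicalize_filters(rbind(g1$W, g2$W))
  .filter_bank(W, c(g1$values, g2$values), k, alpha = alpha, provenance = "srcsp")
}

#' Project trials through a spatial filter bank
#'
#' Computes `Z = W X` for each trial, reducing N channels to `2k` virtual
#' channels; labels and sampling rate are carried through.
#'
#' @param fb a `spatial_filter_bank`.
#' @param x a channels x samples matrix or a [trial_set()].
#' @return object of the same kind as `x`, with `2k` channels.
#' @export
apply_filters <- function(fb, x) {
  stopifnot(inherits(fb, "spatial_filter_bank"))
  W <- fb$W
  if (is.matrix(x)) {
    if (ncol(W) != nrow(x)) {
      stop(sprintf("filter bank expects %d channels, trial has %d",
                   ncol(W), nrow(x)), call. = FALSE)
    }
    return(W %*% x)
  }
  if (!inherits(x, "trial_set")) stop("'x' must be a matrix or trial_set", call. = FALSE)
  d <- dim(x$data)
  if (ncol(W) != d[2]) {
    stop(sprintf("filter bank expects %d channels, trial set has %d",
                 ncol(W), d[2]), call. = FALSE)
  }
  out <- array(0, dim = c(d[1], nrow(W), d[3]))
  for (i in seq_len(d[1])) out[i, , ] <- W %*% trial_matrix(x, i)
  trial_set(out, labels = x$labels, sfreq = x$sfreq,
            channels = sprintf("csp%02d", seq_len(nrow(W))),
            metadata = x$metadata)
}
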