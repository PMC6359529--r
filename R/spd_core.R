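#' Affine-invariant Riemannian geometry on the SPD manifold
#'
#' EEG trial covariance matrices are symmetric positive-definite (SPD) and
#' live on a curved Riemannian manifold rather than in a flat vector space.
#' These primitives implement the affine-invariant geometry used throughout
#' the package: matrix powers/log/exp via the symmetric eigendecomposition,
#' the logarithmic and exponential maps between the manifold and its tangent
#' space at a reference point, the geodesic (Riemannian) distance, and the
#' Frechet (geometric) mean computed by iterative tangent-space averaging.
#'
#' @name spd-geometry
NULL

# Relative floor applied to eigenvalues before log / negative powers; real
# covariance estimates can be numerically rank-deficient.
.SPD_EIG_CLIP <- 1e-12

#' Symmetrize a square matrix
#'
#' Replaces `C` by `(C + t(C)) / 2`. Floating-point asymmetry otherwise
#' produces complex eigenpairs from non-symmetric solvers.
#'
#' @param C square numeric matrix.
#' @return symmetric matrix of the same dimension.
#' @keywords internal
symmetrize <- function(C) (C + t(C)) / 2

#' Validate an SPD matrix
#'
#' Checks symmetry (max|C - t(C)| <= 1e-10 * max|C|) and strict positive
#' definiteness (smallest eigenvalue > 0).
#'
#' @param C numeric matrix to check.
#' @param name label used in error messages.
#' @return invisibly, the eigenvalues of `symmetrize(C)` (decreasing).
#' @export
assert_spd <- function(C, name = deparse(substitute(C))) {
  if (!is.matrix(C) || !is.numeric(C) || nrow(C) != ncol(C)) {
    stop(sprintf("'%s' must be a square numeric matrix", name), call. = FALSE)
  }
  scale <- max(abs(C), 1e-300)
  if (max(abs(C - t(C))) > 1e-10 * scale) {
    stop(sprintf("'%s' is not symmetric within tolerance", name), call. = FALSE)
  }
  ev <- eigen(symmetrize(C), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop(sprintf("'%s' is not positive definite: smallest eigenvalue %.3e <= 0",
                 name, min(ev)), call. = FALSE)
  }
  invisible(ev)
}

# Eigendecomposition with relative clipping of small/negative eigenvalues.
# strict = TRUE refuses non-positive eigenvalues instead of clipping.
.spd_eigen <- function(C, strict = FALSE, name = "C") {
  e <- eigen(symmetrize(C), symmetric = TRUE)
  lam <- e$values
  if (strict && min(lam) <= 0) {
    stop(sprintf("'%s' is not SPD: eigenvalue %.3e <= 0", name, min(lam)),
         call. = FALSE)
  }
  floor_val <- .SPD_EIG_CLIP * max(lam, .SPD_EIG_CLIP)
  if (min(lam) < floor_val) {
    warning(sprintf("clipping %d eigenvalue(s) of '%s' below %.3e",
                    sum(lam < floor_val), name, floor_val), call. = FALSE)
    lam <- pmax(lam, floor_val)
  }
  list(values = lam, vectors = e$vectors)
}

# U diag(f(lambda)) U^T
.spd_fun <- function(C, f, strict = FALSE, name = "C") {
  e <- .spd_eigen(C, strict = strict, name = name)
  symmetrize(e$vectors %*% (f(e$values) * t(e$vectors)))
}

#' Matrix power of an SPD matrix
#'
#' Computes `C^p = U diag(lambda_i^p) U^T` from the symmetric
#' eigendecomposition; the result is SPD for any real `p`.
#'
#' @param C SPD matrix.
#' @param p real exponent.
#' @return SPD matrix `C^p`.
#' @examples
#' matrix_power(diag(c(4, 9)), 0.5)   # diag(2, 3)
#' @export
matrix_power <- function(C, p) {
  stopifnot(is.numeric(p), length(p) == 1)
  .spd_fun(C, function(l) l^p, strict = p < 0 || (p %% 1 != 0),
           name = deparse(substitute(C)))
}

#' Matrix logarithm of an SPD matrix
#'
#' `logm(C) = U diag(log lambda_i) U^T`; the result is symmetric and lives in
#' the tangent space at the identity.
#'
#' @param C SPD matrix.
#' @return symmetric matrix.
#' @export
matrix_log <- function(C) {
  .spd_fun(C, log, strict = TRUE, name = deparse(substitute(C)))
}

#' Matrix exponential of a symmetric matrix
#'
#' `expm(S) = U diag(exp lambda_i) U^T`; inverse of [matrix_log()]. The result
#' is always SPD.
#'
#' @param S symmetric matrix.
#' @return SPD matrix.
#' @export
matrix_exp <- function(S) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) stop("'S' must be square", call. = FALSE)
  scale <- max(abs(S), 1e-300)
  if (max(abs(S - t(S))) > 1e-10 * scale) {
    stop("'S' must be symmetric", call. = FALSE)
  }
  e <- eigen(symmetrize(S), symmetric = TRUE)
  symmetrize(e$vectors %*% (exp(e$values) * t(e$vectors)))
}

#' Logarithmic map: manifold point to tangent vector
#'
#' Projects `Ci` to the tangent space anchored at `C_ref`:
#' `S = C^{1/2} logm(C^{-1/2} Ci C^{-1/2}) C^{1/2}`.
#'
#' @param C_ref SPD reference (tangent anchor).
#' @param Ci SPD matrix to project.
#' @return symmetric matrix (tangent vector at `C_ref`).
#' @seealso [exp_map()] for the inverse.
#' @export
log_map <- function(C_ref, Ci) {
  if (!identical(dim(C_ref), dim(Ci))) {
    stop("dimension mismatch between 'C_ref' and 'Ci'", call. = FALSE)
  }
  Chalf <- matrix_power(C_ref, 0.5)
  Cihalf <- matrix_power(C_ref, -0.5)
  symmetrize(Chalf %*% matrix_log(symmetrize(Cihalf %*% Ci %*% Cihalf)) %*% Chalf)
}

#' Exponential map: tangent vector back to the manifold
#'
#' `C^{1/2} expm(C^{-1/2} S C^{-1/2}) C^{1/2}`; inverse of [log_map()] at the
#' same reference.
#'
#' @param C_ref SPD reference (tangent anchor).
#' @param S symmetric tangent vector at `C_ref`.
#' @return SPD matrix.
#' @export
exp_map <- function(C_ref, S) {
  if (!identical(dim(C_ref), dim(S))) {
    stop("dimension mismatch between 'C_ref' and 'S'", call. = FALSE)
  }
  Chalf <- matrix_power(C_ref, 0.5)
  Cihalf <- matrix_power(C_ref, -0.5)
  symmetrize(Chalf %*% matrix_exp(symmetrize(Cihalf %*% S %*% Cihalf)) %*% Chalf)
}

#' Riemannian (geodesic) distance between SPD matrices
#'
#' Affine-invariant distance
#' `Rd(C1, C2) = ||logm(C1^{-1/2} C2 C1^{-1/2})||_F = sqrt(sum log^2 lambda_i)`
#' with `lambda_i` the eigenvalues of the whitened product. Invariant under
#' any common congruence `C -> A^T C A` with invertible `A`.
#'
#' @param C1,C2 SPD matrices of identical dimension.
#' @return nonnegative scalar; zero iff `C1 == C2`.
#' @export
riemannian_distance <- function(C1, C2) {
  if (!identical(dim(C1), dim(C2))) {
    stop("dimension mismatch between 'C1' and 'C2'", call. = FALSE)
  }
  W <- matrix_power(C1, -0.5)
  lam <- .spd_eigen(symmetrize(W %*% C2 %*% W), strict = TRUE, name = "C1^-1/2 C2 C1^-1/2")$values
  sqrt(sum(log(lam)^2))
}

#' Riemannian (Frechet / geometric) mean of a set of SPD matrices
#'
#' The unique SPD matrix minimizing the sum of squared geodesic distances to
#' the set. Computed by the standard fixed-point iteration: map all members to
#' the tangent space at the current estimate, take the arithmetic mean there,
#' map back, and repeat until the Frobenius norm of the tangent mean falls
#' below `tol`. Initialization is the arithmetic (Euclidean) mean.
#'
#' @param S list of SPD matrices of identical dimension.
#' @param tol convergence tolerance on the Frobenius norm of the tangent-space
#'   mean update (default `1e-8`).
#' @param max_iter maximum number of iterations (default 50). Non-convergence
#'   raises a warning with the final update norm; the last iterate is still
#'   returned.
#' @return SPD matrix, the Riemannian mean.
#' @examples
#' A <- diag(c(1, 4)); B <- diag(c(4, 1))
#' riemannian_mean(list(A, B))  # diag(2, 2): elementwise geometric mean
#' @export
riemannian_mean <- function(S, tol = 1e-8, max_iter = 50L) {
  if (!is.list(S) || length(S) == 0) {
    stop("'S' must be a nonempty list of SPD matrices", call. = FALSE)
  }
  n <- nrow(S[[1]])
  if (!all(vapply(S, function(C) identical(dim(C), c(n, n)), logical(1)))) {
    stop("all members of 'S' must share the same dimension", call. = FALSE)
  }
  if (length(S) == 1) return(symmetrize(S[[1]]))
  M <- symmetrize(Reduce(`+`, S) / length(S))
  upd <- Inf
  for (it in seq_len(max_iter)) {
    Mh <- matrix_power(M, 0.5)
    Mih <- matrix_power(M, -0.5)
    # tangent mean at M, computed in whitened coordinates
    Tm <- matrix(0, n, n)
    for (C in S) Tm <- Tm + matrix_log(symmetrize(Mih %*% C %*% Mih))
    Tm <- symmetrize(Tm / length(S))
    upd <- norm(Tm, "F")
    M <- symmetrize(Mh %*% matrix_exp(Tm) %*% Mh)
    if (upd <= tol) break
  }
  if (upd > tol) {
    warning(sprintf("Riemannian mean did not converge in %d iterations (update norm %.3e)",
                    max_iter, upd), call. = FALSE)
  }
  M
}
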