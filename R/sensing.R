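# Sensing operators A = K Psi acting on sparse coefficients.
#
# A sensing_op bundles forward/adjoint actions with a cached Gram matrix
# G = A A^T (and its eigendecomposition), which the solvers' projection
# steps reuse across iterations. Because Psi is unitary, G equals
# K_r K_r^T and is independent of the basis.

new_sensing_op <- function(forward, adjoint, gram_fn, M, N,
                           basis = NULL, grid = NULL, dense = NULL) {
  cache <- new.env(parent = emptyenv())
  structure(
    list(forward = forward, adjoint = adjoint, gram_fn = gram_fn,
         M = as.integer(M), N = as.integer(N),
         basis = basis, grid = grid, dense = dense, cache = cache),
    class = "sensing_op"
  )
}

#' Wrap a plain matrix as a sensing operator
#'
#' @param A real matrix (rows = measurements).
#' @return a `sensing_op`.
#' @export
as_sensing_op <- function(A) {
  if (inherits(A, "sensing_op")) return(A)
  stopifnot(is.matrix(A), is.numeric(A))
  new_sensing_op(
    forward = function(v) as.vector(A %*% v),
    adjoint = function(v) as.vector(crossprod(A, v)),
    gram_fn = function() tcrossprod(A),
    M = nrow(A), N = ncol(A), dense = A
  )
}

#' Compose the sensing operator A = K Psi
#'
#' Combines a measurement model (real-lifted, see [real_matrix()]) with a
#' wavelet synthesis basis: the forward action is `A theta =
#' K_r synthesize(theta)` and the adjoint is `A^T v =
#' analyze(K_r^T v)`. With `dense = TRUE` the explicit 2M x N matrix is
#' also materialized (small problems; mainly for cross-checks).
#'
#' @param model a `measurement_model`.
#' @param basis a [wavelet_basis()] on the model's grid side.
#' @param dense also build the explicit matrix.
#' @return a `sensing_op` of size 2M x N.
#' @export
compose_sensing <- function(model, basis, dense = FALSE) {
  stopifnot(inherits(model, "measurement_model"),
            inherits(basis, "wavelet_basis"))
  if (basis$side_px != model$grid$side_px) {
    stop_invalid("basis side (%d) does not match model grid (%d)",
                 basis$side_px, model$grid$side_px)
  }
  Kr <- real_matrix(model)
  side <- basis$side_px
  dense_A <- NULL
  if (dense) {
    dense_A <- t(apply(Kr, 1, function(row) {
      analyze(unflatten_image(row, side), basis)
    }))
  }
  new_sensing_op(
    forward = function(v) as.vector(Kr %*% flatten_image(synthesize(v, basis))),
    adjoint = function(v) analyze(unflatten_image(as.vector(crossprod(Kr, v)),
                                                  side), basis),
    gram_fn = function() tcrossprod(Kr),   # = A A^T since Psi is unitary
    M = nrow(Kr), N = ncol(Kr),
    basis = basis, grid = model$grid, dense = dense_A
  )
}

# Eigendecomposition of G = A A^T, computed once per operator and cached.
# All projections with any regularization lambda reduce to diagonal solves
# in this eigenbasis.
op_gram_eigen <- function(op) {
  if (is.null(op$cache$eig)) {
    G <- op$gram_fn()
    op$cache$eig <- eigen(G, symmetric = TRUE)
  }
  op$cache$eig
}

# Solve (G + shift * I) z = r via the cached eigendecomposition,
# restricted to the identifiable range of G: eigenvalues below
# 1e-12 * max are numerical noise of the Gram computation (the physical
# operator is band-limited, so near-null directions are expected) and
# their components of r are unservable by any correction A^T z, so they
# are dropped. With shift = 0 this is the pseudo-inverse; with shift > 0
# it keeps the Tikhonov-regularized correction consistent with its
# lambda -> Inf (shift -> 0) limit. A Gram with fewer than half its
# directions identifiable signals a configuration error.
op_gram_solve <- function(op, r, shift = 0) {
  eig <- op_gram_eigen(op)
  keep <- eig$values > max(eig$values) * 1e-12
  if (sum(keep) < length(keep) / 2) {
    stop_invalid("A A^T is numerically rank-deficient (rank %d of %d)",
                 sum(keep), length(keep))
  }
  if (all(keep)) {
    V <- eig$vectors
    d <- eig$values + shift
  } else {
    V <- eig$vectors[, keep, drop = FALSE]
    d <- eig$values[keep] + shift
  }
  solve_eig <- function(b) as.vector(V %*% (crossprod(V, b) / d))
  z <- solve_eig(r)
  # two refinement passes against the true operator (G z computed as
  # A (A^T z)) recover the accuracy the factorization loses when the
  # Gram matrix is severely ill-conditioned
  r_id <- as.vector(V %*% crossprod(V, r))  # r restricted to kept range
  for (pass in 1:2) {
    resid <- r_id - (op$forward(op$adjoint(z)) + shift * z)
    if (sqrt(sum(resid^2)) <= 1e-12 * max(sqrt(sum(r_id^2)), 1e-300)) break
    z <- z + solve_eig(resid)
  }
  z
}

# Scaled view of a sensing operator: A' = A / s with s^2 the mean Gram
# eigenvalue, sharing the cached eigendecomposition. The adaptive
# regularization of the ReSL0 solver is calibrated on this unit-scale
# system, which makes the solver invariant to the overall scale of A.
op_unit_scaled <- function(op) {
  eig <- op_gram_eigen(op)
  s2 <- mean(pmax(eig$values, 0))
  if (s2 == 0) s2 <- 1
  s <- sqrt(s2)
  view <- new_sensing_op(
    forward = function(v) op$forward(v) / s,
    adjoint = function(v) op$adjoint(v) / s,
    gram_fn = function() op$gram_fn() / s2,
    M = op$M, N = op$N, basis = op$basis, grid = op$grid
  )
  view$cache$eig <- list(values = eig$values / s2, vectors = eig$vectors)
  list(op = view, scale = s)
}
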