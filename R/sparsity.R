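# Orthonormal wavelet sparsity basis Psi with X = Psi theta.
#
# The transform is the separable 2-D periodized DWT built from an
# orthonormal filter pair, applied level by level to the low-pass block
# (Mallat layout). Periodization keeps every level an orthogonal map, so
# Psi is unitary: analysis is both the inverse and the adjoint of
# synthesis, which the solvers rely on when moving between the coefficient
# and image domains.

.wavelet_filters <- list(
  haar = c(1, 1) / sqrt(2),
  # 4-tap Daubechies (D4), the default sparsifying filter
  d4 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
)

# cache of one-level orthonormal DWT matrices, keyed by "family:n"
.dwt_cache <- new.env(parent = emptyenv())

# n x n matrix of the one-level periodized DWT: first n/2 rows low-pass,
# last n/2 rows high-pass (quadrature mirror of h).
dwt_step_matrix <- function(n, family) {
  key <- paste0(family, ":", n)
  if (!is.null(.dwt_cache[[key]])) return(.dwt_cache[[key]])
  h <- .wavelet_filters[[family]]
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)  # (h_L, -h_{L-1}, ...)
  W <- matrix(0, n, n)
  for (k in seq_len(n / 2)) {
    idx <- ((2 * (k - 1) + seq_len(L) - 1) %% n) + 1
    for (m in seq_len(L)) {
      W[k, idx[m]] <- W[k, idx[m]] + h[m]
      W[n / 2 + k, idx[m]] <- W[n / 2 + k, idx[m]] + g[m]
    }
  }
  .dwt_cache[[key]] <- W
  W
}

#' Wavelet basis descriptor
#'
#' Describes the orthonormal synthesis basis Psi used to sparsify images:
#' `X = synthesize(theta)`, `theta = analyze(X)`. Families: `"d4"`
#' (4-tap Daubechies, default), `"haar"`, and `"identity"` (Psi = I, for
#' solver tests on synthetic sparse vectors).
#'
#' @param side_px image side the basis applies to.
#' @param family `"d4"`, `"haar"` or `"identity"`.
#' @param levels decomposition depth; default is the maximum depth at
#'   which the low-pass block stays divisible by 2 and at least as long as
#'   the filter.
#' @return object of class `wavelet_basis`.
#' @export
wavelet_basis <- function(side_px, family = "d4", levels = NULL) {
  stopifnot(side_px >= 2)
  if (family == "identity") {
    return(structure(list(side_px = as.integer(side_px), family = "identity",
                          levels = 0L, boundary = "periodic"),
                     class = "wavelet_basis"))
  }
  if (!family %in% names(.wavelet_filters)) {
    stop_invalid("unknown wavelet family '%s' (have: %s, identity)",
                 family, paste(names(.wavelet_filters), collapse = ", "))
  }
  flen <- length(.wavelet_filters[[family]])
  max_lev <- 0L
  n <- side_px
  while (n %% 2 == 0 && n / 2 >= flen) {
    max_lev <- max_lev + 1L
    n <- n / 2
  }
  if (is.null(levels)) levels <- max_lev
  if (levels < 1L || levels > max_lev) {
    stop_invalid("levels must be in 1..%d for side %d and family '%s'",
                 max_lev, side_px, family)
  }
  structure(
    list(side_px = as.integer(side_px), family = family,
         levels = as.integer(levels), boundary = "periodic"),
    class = "wavelet_basis"
  )
}

#' Analyze: image to sparse coefficients
#'
#' Applies the orthonormal analysis transform (the inverse, and adjoint,
#' of Psi) to a phantom image or square matrix and returns the flattened
#' coefficient vector theta of length N.
#'
#' @param image a [phantom_image()] or square numeric matrix.
#' @param basis a [wavelet_basis()] with matching side.
#' @return numeric vector theta with `length(theta) == side^2`.
#' @export
analyze <- function(image, basis) {
  m <- if (inherits(image, "phantom_image")) image$pixels else image
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop_invalid("image must be square")
  if (nrow(m) != basis$side_px) {
    stop_invalid("image side (%d) does not match basis side (%d)",
                 nrow(m), basis$side_px)
  }
  if (basis$family == "identity") return(flatten_image(m))
  for (l in seq_len(basis$levels)) {
    n <- basis$side_px / 2^(l - 1)
    W <- dwt_step_matrix(n, basis$family)
    m[1:n, 1:n] <- W %*% m[1:n, 1:n] %*% t(W)
  }
  flatten_image(m)
}

#' Synthesize: sparse coefficients to image
#'
#' Applies Psi to a coefficient vector, exactly inverting [analyze()].
#'
#' @param theta numeric coefficient vector of length `side^2`.
#' @param basis a [wavelet_basis()].
#' @return square numeric matrix of side `basis$side_px`.
#' @export
synthesize <- function(theta, basis) {
  if (length(theta) != basis$side_px^2) {
    stop_invalid("coefficient length (%d) does not match basis (%d pixels)",
                 length(theta), basis$side_px^2)
  }
  m <- unflatten_image(theta, basis$side_px)
  if (basis$family == "identity") return(m)
  for (l in rev(seq_len(basis$levels))) {
    n <- basis$side_px / 2^(l - 1)
    W <- dwt_step_matrix(n, basis$family)
    m[1:n, 1:n] <- t(W) %*% m[1:n, 1:n] %*% W
  }
  m
}
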