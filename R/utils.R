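# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so seeded constructors never clobber the global stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Flatten a square image to a vector (row-major)
#'
#' The package-wide flattening convention maps pixel (i, j) of a square
#' image to flat index `(i - 1) * side + j`, i.e. rows are traversed in
#' order and columns cycle fastest. [unflatten_image()] is its inverse.
#'
#' @param m square numeric matrix.
#' @return numeric vector of length `nrow(m)^2`.
#' @export
flatten_image <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  as.vector(t(m))
}

#' @rdname flatten_image
#' @param v numeric vector of length `side^2`.
#' @param side image side in pixels.
#' @export
unflatten_image <- function(v, side) {
  stopifnot(length(v) == side * side)
  matrix(v, side, side, byrow = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)
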