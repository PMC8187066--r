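# Procedural test phantoms: ground-truth absorbed-energy maps on [0, 1].

#' Construct a phantom image
#'
#' A `phantom_image` is a square map of absorbed optical energy density,
#' dimensionless and scaled to lie in \[0, 1\], together with its physical
#' side length. It is the ground truth `X` that the forward model projects
#' into pressure data and that reconstructions are scored against.
#'
#' @param pixels square numeric matrix with values in \[0, 1\].
#' @param extent_mm physical side length of the imaged square, in mm.
#' @return object of class `phantom_image` with fields `pixels`,
#'   `side_px`, `extent_mm`.
#' @export
phantom_image <- function(pixels, extent_mm = 30) {
  if (!is.matrix(pixels) || nrow(pixels) != ncol(pixels)) {
    stop_invalid("phantom pixels must be a square matrix")
  }
  if (nrow(pixels) < 8L) stop_invalid("phantom side must be at least 8 px")
  if (!all(is.finite(pixels))) stop_invalid("phantom pixels must be finite")
  if (min(pixels) < -1e-12 || max(pixels) > 1 + 1e-12) {
    stop_invalid("phantom pixel values must lie in [0, 1]")
  }
  structure(
    list(
      pixels = pmin(pmax(pixels, 0), 1),
      side_px = nrow(pixels),
      extent_mm = extent_mm
    ),
    class = "phantom_image"
  )
}

#' @export
print.phantom_image <- function(x, ...) {
  cat(sprintf(
    "<phantom_image> %d x %d px, %.1f mm, values in [%.3g, %.3g], %.1f%% nonzero\n",
    x$side_px, x$side_px, x$extent_mm, min(x$pixels), max(x$pixels),
    100 * mean(x$pixels != 0)
  ))
  invisible(x)
}

# Classical Shepp-Logan ellipse set: additive intensity, semi-axes and
# centres on the unit square [-1, 1]^2, rotation in degrees.
.shepp_logan_ellipses <- data.frame(
  value   = c(2, -0.98, -0.02, -0.02, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01),
  a       = c(0.69, 0.6624, 0.11, 0.16, 0.21, 0.046, 0.046, 0.046, 0.023, 0.023),
  b       = c(0.92, 0.8740, 0.31, 0.41, 0.25, 0.046, 0.046, 0.023, 0.023, 0.046),
  x0      = c(0, 0, 0.22, -0.22, 0, 0, 0, -0.08, 0, 0.06),
  y0      = c(0, -0.0184, 0, 0, 0.35, 0.1, -0.1, -0.605, -0.606, -0.605),
  phi_deg = c(0, 0, -18, 18, 0, 0, 0, 0, 0, 0)
)

# Sum of ellipse intensities at arbitrary points of [-1, 1]^2.
# A pixel belongs to an ellipse iff its centre coordinate satisfies the
# ellipse inequality (no anti-aliasing).
shepp_logan_value_at <- function(x, y, ellipses = .shepp_logan_ellipses) {
  val <- numeric(length(x))
  for (e in seq_len(nrow(ellipses))) {
    phi <- ellipses$phi_deg[e] * pi / 180
    dx <- x - ellipses$x0[e]
    dy <- y - ellipses$y0[e]
    u <- cos(phi) * dx + sin(phi) * dy
    v <- -sin(phi) * dx + cos(phi) * dy
    inside <- (u / ellipses$a[e])^2 + (v / ellipses$b[e])^2 <= 1
    val <- val + ellipses$value[e] * inside
  }
  val
}

#' Shepp-Logan head phantom
#'
#' Rasterizes the classical ten-ellipse Shepp-Logan phantom at
#' `side_px` x `side_px`. Each pixel takes the summed intensity of the
#' ellipses whose region contains the pixel-centre coordinate; the result
#' is then min-max rescaled to \[0, 1\].
#'
#' @param side_px image side in pixels (>= 8).
#' @param extent_mm physical side length in mm.
#' @param rescale rescale min-max to \[0, 1\] (default). `FALSE` returns the
#'   raw summed intensities (useful for cross-checks against the ellipse
#'   table).
#' @return a [phantom_image()] (or a bare matrix when `rescale = FALSE`).
#' @export
generate_shepp_logan <- function(side_px, extent_mm = 30, rescale = TRUE) {
  if (side_px < 8L) stop_invalid("side_px must be >= 8")
  # pixel-centre coordinates on [-1, 1], y increasing upwards
  cs <- (2 * (seq_len(side_px) - 0.5) / side_px) - 1
  x <- rep(cs, times = side_px)
  y <- rep(rev(cs), each = side_px)
  raw <- unflatten_image(shepp_logan_value_at(x, y), side_px)
  if (!rescale) return(raw)
  rng <- range(raw)
  phantom_image((raw - rng[1]) / (rng[2] - rng[1]), extent_mm)
}

#' Vessel-like phantom
#'
#' Draws `n_branches` smooth curvilinear absorbers (random-walk centrelines
#' of width 1-3 px) on a zero background, emulating the sparse vascular
#' structures photoacoustic imaging targets. Deterministic for a fixed
#' seed; the result is sparse (few nonzero pixels), which is the premise
#' of compressed-sensing recovery.
#'
#' @param side_px image side in pixels (>= 8).
#' @param n_branches number of vessel branches (>= 1).
#' @param seed RNG seed; identical seeds give bit-identical images.
#' @param extent_mm physical side length in mm.
#' @return a [phantom_image()].
#' @export
generate_vessel_phantom <- function(side_px, n_branches = 5, seed = 1,
                                    extent_mm = 30) {
  if (side_px < 8L) stop_invalid("side_px must be >= 8")
  if (n_branches < 1L) stop_invalid("n_branches must be >= 1")
  px <- with_seed(seed, {
    img <- matrix(0, side_px, side_px)
    for (b in seq_len(n_branches)) {
      # start inside the central region, walk with slowly drifting heading
      pos <- stats::runif(2, 0.25 * side_px, 0.75 * side_px)
      ang <- stats::runif(1, 0, 2 * pi)
      width <- sample(1:3, 1)
      level <- stats::runif(1, 0.5, 1)
      n_steps <- round(stats::runif(1, 0.6, 1.3) * side_px)
      half <- (width - 1) / 2
      for (s in seq_len(n_steps)) {
        ang <- ang + stats::rnorm(1, 0, 0.15)
        pos <- pos + 0.7 * c(cos(ang), sin(ang))
        if (any(pos < 2) || any(pos > side_px - 1)) break
        i0 <- max(1L, floor(pos[1] - half)); i1 <- min(side_px, ceiling(pos[1] + half))
        j0 <- max(1L, floor(pos[2] - half)); j1 <- min(side_px, ceiling(pos[2] + half))
        for (ii in i0:i1) for (jj in j0:j1) {
          if ((ii - pos[1])^2 + (jj - pos[2])^2 <= (half + 0.5)^2) {
            img[ii, jj] <- max(img[ii, jj], level)
          }
        }
      }
    }
    img
  })
  phantom_image(px, extent_mm)
}

#' Resolution-bar phantom
#'
#' Deterministic resolution test pattern: four groups of parallel bars at
#' decreasing pitch placed in the image quadrants, plus a trio of disks.
#' Foreground values lie in \[0.5, 1\] on a zero background.
#'
#' @param side_px image side in pixels (>= 32).
#' @param extent_mm physical side length in mm.
#' @return a [phantom_image()].
#' @export
generate_resolution_phantom <- function(side_px, extent_mm = 30) {
  if (side_px < 32L) stop_invalid("side_px must be >= 32")
  img <- matrix(0, side_px, side_px)
  box <- side_px %/% 4
  margin <- side_px %/% 10
  pitches <- pmax(2L, round(side_px / c(12, 18, 26, 42)))
  corners <- list(
    c(margin, margin),
    c(margin, side_px - margin - box),
    c(side_px - margin - box, margin),
    c(side_px - margin - box, side_px - margin - box)
  )
  for (g in seq_along(pitches)) {
    p <- pitches[g]
    bar <- max(1L, p %/% 2)
    ori <- corners[[g]]
    n_bars <- max(3L, min(5L, (box + (p - bar)) %/% p))
    for (k in seq_len(n_bars)) {
      j0 <- ori[2] + (k - 1L) * p
      img[ori[1]:(ori[1] + box - 1L), j0:(j0 + bar - 1L)] <- 1
    }
  }
  # central disks at three radii, mid-grey
  ctr <- (side_px + 1) / 2
  radii <- c(box / 3, box / 5, box / 8)
  offs <- c(-1.2, 0, 1.2) * box / 2
  ij <- expand.grid(i = seq_len(side_px), j = seq_len(side_px))
  for (d in seq_along(radii)) {
    sel <- (ij$i - ctr)^2 + (ij$j - (ctr + offs[d]))^2 <= radii[d]^2
    img[cbind(ij$i[sel], ij$j[sel])] <- 0.75
  }
  phantom_image(img, extent_mm)
}

#' Read and write phantom images
#'
#' `write_phantom_png()` stores the pixel map as 8-bit grayscale PNG;
#' `read_phantom_png()` loads any grayscale (or RGB, averaged) PNG and
#' min-max rescales it to \[0, 1\]. `write_phantom_array()` /
#' `read_phantom_array()` use a lossless plain-text matrix format.
#'
#' @param phantom a [phantom_image()].
#' @param path file path.
#' @param extent_mm physical side length assigned on read, in mm.
#' @name phantom_io
#' @export
write_phantom_png <- function(phantom, path) {
  png::writePNG(phantom$pixels, target = path)
  invisible(path)
}

#' @rdname phantom_io
#' @export
read_phantom_png <- function(path, extent_mm = 30) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- apply(arr[, , 1:3, drop = FALSE], c(1, 2), mean)
  rng <- range(arr)
  if (rng[2] > rng[1]) arr <- (arr - rng[1]) / (rng[2] - rng[1])
  phantom_image(arr, extent_mm)
}

#' @rdname phantom_io
#' @export
write_phantom_array <- function(phantom, path) {
  utils::write.table(
    format(phantom$pixels, digits = 17),
    file = path, row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname phantom_io
#' @export
read_phantom_array <- function(path, extent_mm = 30) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  phantom_image(m, extent_mm)
}
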