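# Frequency-domain forward model for circular-scan photoacoustic tomography.
#
# A single transducer is rotated around the object; at each of p positions
# the pressure spectrum is sampled at q temporal frequencies, giving
# M = p*q complex measurements of the N = side^2 pixel absorptions:
#   K[(m,n), (i,j)] = i c k_n exp(-i k_n |r_m - r_ij|) / |r_m - r_ij|
# (global physical constants folded into a unit scale factor, which cancels
# because simulation and inversion share the same operator).

#' Pixel lattice of the imaged region
#'
#' Square grid of `side_px` x `side_px` pixel centres spanning
#' `extent_mm` x `extent_mm`, centred on the origin. The flat ordering of
#' pixels is row-major (see [flatten_image()]); `coords_mm` holds the
#' centre coordinates, in mm, in that order.
#'
#' @param side_px image side in pixels.
#' @param extent_mm physical side length in mm.
#' @return object of class `image_grid` with fields `side_px`, `extent_mm`,
#'   `n_pixels`, `coords_mm` (N x 2 matrix).
#' @export
image_grid <- function(side_px, extent_mm = 30) {
  stopifnot(side_px >= 2, extent_mm > 0)
  delta <- extent_mm / side_px
  cs <- -extent_mm / 2 + (seq_len(side_px) - 0.5) * delta
  structure(
    list(
      side_px = as.integer(side_px),
      extent_mm = extent_mm,
      n_pixels = as.integer(side_px)^2,
      pixel_size_mm = delta,
      coords_mm = cbind(
        x = rep(cs, times = side_px),        # column index cycles fastest
        y = rep(rev(cs), each = side_px)     # row 1 at the top
      )
    ),
    class = "image_grid"
  )
}

#' Circular scan geometry
#'
#' `n_positions` transducer positions uniformly spaced over 360 degrees on
#' a circle of radius `radius_mm` centred on the image.
#'
#' @param n_positions number of detector positions p.
#' @param radius_mm scan circle radius in mm; must leave all detectors
#'   strictly outside the image support of any grid it is paired with.
#' @return object of class `scan_geometry` with `angles_rad` and
#'   `positions_mm` (p x 2).
#' @export
scan_geometry <- function(n_positions, radius_mm = 40) {
  stopifnot(n_positions >= 1, radius_mm > 0)
  angles <- 2 * pi * (seq_len(n_positions) - 1) / n_positions
  structure(
    list(
      n_positions = as.integer(n_positions),
      radius_mm = radius_mm,
      angles_rad = angles,
      positions_mm = cbind(x = radius_mm * cos(angles),
                           y = radius_mm * sin(angles))
    ),
    class = "scan_geometry"
  )
}

#' Random temporal-frequency sampling
#'
#' Draws `n_freqs` i.i.d. uniform frequencies inside the open band
#' `band_mhz` for each detector position (independently per position by
#' default, or one shared draw with `share = TRUE`). Deterministic for a
#' fixed seed.
#'
#' @param n_positions detector position count p.
#' @param n_freqs frequencies per position q.
#' @param band_mhz length-2 frequency window in MHz.
#' @param seed RNG seed for the draw.
#' @param share reuse a single frequency set across all positions.
#' @return object of class `frequency_sampling` with `freqs_hz`
#'   (p x q matrix, Hz).
#' @export
frequency_sampling <- function(n_positions, n_freqs, band_mhz = c(0.2, 3),
                               seed = 1, share = FALSE) {
  stopifnot(n_freqs >= 1, length(band_mhz) == 2, band_mhz[1] > 0,
            band_mhz[2] > band_mhz[1])
  f <- with_seed(seed, {
    if (share) {
      row <- stats::runif(n_freqs, band_mhz[1], band_mhz[2])
      matrix(row, n_positions, n_freqs, byrow = TRUE)
    } else {
      matrix(stats::runif(n_positions * n_freqs, band_mhz[1], band_mhz[2]),
             n_positions, n_freqs, byrow = TRUE)
    }
  })
  structure(
    list(
      n_positions = as.integer(n_positions),
      n_freqs = as.integer(n_freqs),
      band_mhz = band_mhz,
      seed = seed,
      share = share,
      freqs_hz = f * 1e6
    ),
    class = "frequency_sampling"
  )
}

#' Build the frequency-domain measurement matrix
#'
#' Assembles the complex M x N operator K mapping the flattened absorption
#' map to pressure spectra, with M = p*q rows grouped by detector position
#' (outer) then frequency (inner). Entry for detector `r_m`, wavenumber
#' `k_n = 2 pi f_n / c` and pixel `r_ij` is
#' `i c k_n exp(-i k_n d) / d` with `d = |r_m - r_ij|` (metres).
#'
#' @param grid an [image_grid()].
#' @param geometry a [scan_geometry()]; every detector must lie strictly
#'   outside the grid's bounding circle.
#' @param freqs a [frequency_sampling()] with matching position count.
#' @param sound_speed speed of sound in m/s.
#' @return object of class `measurement_model` with the complex matrix `K`
#'   and its inputs.
#' @export
build_measurement_matrix <- function(grid, geometry, freqs,
                                     sound_speed = 1500) {
  stopifnot(inherits(grid, "image_grid"), inherits(geometry, "scan_geometry"),
            inherits(freqs, "frequency_sampling"))
  if (sound_speed <= 0) stop_invalid("sound_speed must be positive")
  if (freqs$n_positions != geometry$n_positions) {
    stop_invalid("frequency sampling and geometry disagree on position count")
  }
  bound <- max(sqrt(rowSums(grid$coords_mm^2))) + grid$pixel_size_mm / 2
  if (geometry$radius_mm <= bound) {
    stop_invalid("scan radius %.2f mm does not clear the image support (%.2f mm)",
                 geometry$radius_mm, bound)
  }
  p <- geometry$n_positions
  q <- freqs$n_freqs
  n <- grid$n_pixels
  K <- matrix(0i, p * q, n)
  for (m in seq_len(p)) {
    d_mm <- sqrt((grid$coords_mm[, 1] - geometry$positions_mm[m, 1])^2 +
                 (grid$coords_mm[, 2] - geometry$positions_mm[m, 2])^2)
    d <- d_mm / 1000
    if (any(d < 1e-6)) stop_invalid("detector %d within 1 um of a pixel centre", m)
    k_n <- 2 * pi * freqs$freqs_hz[m, ] / sound_speed
    # q x N block: (i c k_n) * exp(-i k_n d) / d
    phase <- exp(-1i * outer(k_n, d))
    block <- (1i * sound_speed * k_n) * phase /
      matrix(d, q, n, byrow = TRUE)
    K[((m - 1) * q + 1):(m * q), ] <- block
  }
  # The physical constants of the pressure equation enter only as one
  # global factor, which cancels between simulation and inversion; it is
  # chosen so rows have unit RMS norm, keeping measurement magnitudes,
  # Gram eigenvalues and the adaptive regularization parameter on O(1)
  # scales.
  scale_factor <- sqrt(sum(Mod(K)^2) / (p * q))
  K <- K / scale_factor
  structure(
    list(K = K, sound_speed_m_s = sound_speed, grid = grid,
         geometry = geometry, freqs = freqs, scale_factor = scale_factor,
         n_measurements = p * q, n_pixels = n),
    class = "measurement_model"
  )
}

#' Real lifting of the complex system
#'
#' The unknown absorption map is real, so the complex M x N system
#' `Y = K X` is solved as the real 2M x N system stacking real and
#' imaginary parts. `real_matrix()` returns the stacked operator;
#' `real_measurements()` stacks a complex pressure vector the same way.
#'
#' @param model a `measurement_model`.
#' @return 2M x N real matrix.
#' @export
real_matrix <- function(model) {
  stopifnot(inherits(model, "measurement_model"))
  rbind(Re(model$K), Im(model$K))
}

#' @rdname real_matrix
#' @param data a `pressure_data` object (or complex vector).
#' @export
real_measurements <- function(data) {
  y <- if (inherits(data, "pressure_data")) data$Y else data
  c(Re(y), Im(y))
}

#' Simulate noiseless pressure data
#'
#' Computes `Y = K X` for a phantom on the model's grid.
#'
#' @param model a `measurement_model`.
#' @param phantom a [phantom_image()] on the same grid.
#' @return object of class `pressure_data` with complex vector `Y`,
#'   `snr_db = Inf`.
#' @export
simulate_pressure <- function(model, phantom) {
  stopifnot(inherits(model, "measurement_model"),
            inherits(phantom, "phantom_image"))
  if (phantom$side_px != model$grid$side_px) {
    stop_invalid("phantom side (%d) does not match model grid (%d)",
                 phantom$side_px, model$grid$side_px)
  }
  y <- as.vector(model$K %*% flatten_image(phantom$pixels))
  structure(
    list(Y = y, snr_db = Inf, noise_seed = NA_integer_,
         n_measurements = model$n_measurements),
    class = "pressure_data"
  )
}

#' Add measurement noise at an exact SNR
#'
#' Adds circularly-symmetric white Gaussian noise `e`, rescaled after
#' drawing so that `10 log10(||Y||^2 / ||e||^2)` equals `snr_db` exactly.
#' Deterministic per seed.
#'
#' @param data a `pressure_data` object with nonzero `Y`.
#' @param snr_db target signal-to-noise ratio in dB (finite).
#' @param seed RNG seed for the noise draw.
#' @return a new `pressure_data` with noisy `Y`.
#' @export
add_noise <- function(data, snr_db, seed = 1) {
  stopifnot(inherits(data, "pressure_data"))
  if (!is.finite(snr_db)) stop_invalid("snr_db must be finite")
  y <- data$Y
  ny2 <- sum(Mod(y)^2)
  if (ny2 == 0) stop_invalid("SNR undefined for zero measurements")
  e <- with_seed(seed, {
    complex(real = stats::rnorm(length(y)), imaginary = stats::rnorm(length(y)))
  })
  e <- e * sqrt(ny2 / 10^(snr_db / 10) / sum(Mod(e)^2))
  structure(
    list(Y = y + e, snr_db = snr_db, noise_seed = as.integer(seed),
         n_measurements = data$n_measurements),
    class = "pressure_data"
  )
}
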