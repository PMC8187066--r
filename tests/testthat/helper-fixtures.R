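# Shared fixtures: small imaging instances and random sparse-recovery
# problems, all built in code under fixed seeds.

# Small end-to-end imaging instance (model + sensing operator + data).
small_instance <- function(side = 16, p = 6, q = 8, extent = 30,
                           radius = 40, freq_seed = 7, family = "d4") {
  grid <- image_grid(side, extent)
  geom <- scan_geometry(p, radius)
  fs <- frequency_sampling(p, q, c(0.2, 3), seed = freq_seed)
  model <- build_measurement_matrix(grid, geom, fs, 1500)
  basis <- wavelet_basis(side, family)
  list(grid = grid, geom = geom, fs = fs, model = model, basis = basis,
       A = compose_sensing(model, basis))
}

# Random Gaussian sparse-recovery instance.
gaussian_instance <- function(n = 64, m = 32, k = 4, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(m * n), m, n)
  theta <- numeric(n)
  theta[sample(n, k)] <- rnorm(k, 0, 2)
  list(A = A, theta = theta, y = as.vector(A %*% theta))
}

rel_err <- function(x, ref) sqrt(sum((x - ref)^2)) / sqrt(sum(ref^2))
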