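test_that("measurement matrix matches an element-wise oracle", {
  grid <- image_grid(3, 6)
  geom <- scan_geometry(2, 40)
  fs <- frequency_sampling(2, 2, c(0.2, 3), seed = 7)
  model <- build_measurement_matrix(grid, geom, fs, 1500)
  K <- model$K * model$scale_factor   # undo the global normalization
  c0 <- 1500
  for (m in 1:2) {
    pos <- geom$positions_mm[m, ]
    for (n in 1:2) {
      k_n <- 2 * pi * fs$freqs_hz[m, n] / c0
      for (j in 1:9) {
        d <- sqrt(sum((grid$coords_mm[j, ] - pos)^2)) / 1000
        expected <- 1i * c0 * k_n * exp(-1i * k_n * d) / d
        expect_equal(K[(m - 1) * 2 + n, j], expected, tolerance = 1e-12)
      }
    }
  }
  # modulus depends on distance and frequency only: |entry| = c k / d
  j <- 5
  d <- sqrt(sum((grid$coords_mm[j, ] - geom$positions_mm[1, ])^2)) / 1000
  k1 <- 2 * pi * fs$freqs_hz[1, 1] / c0
  expect_equal(Mod(K[1, j]), c0 * k1 / d, tolerance = 1e-12)
})

test_that("row modulus decays as 1/distance at fixed frequency", {
  inst <- small_instance(side = 8, p = 1, q = 1, extent = 10, radius = 40)
  K <- inst$model$K
  d <- sqrt((inst$grid$coords_mm[, 1] - inst$geom$positions_mm[1, 1])^2 +
            (inst$grid$coords_mm[, 2] - inst$geom$positions_mm[1, 2])^2)
  prod <- Mod(K[1, ]) * d
  expect_equal(max(prod) / min(prod), 1, tolerance = 1e-12)
  # equidistant pixels share a modulus: symmetric pair about the x-axis
  expect_equal(Mod(K[1, 1]), Mod(K[1, 57]), tolerance = 1e-12)
})

test_that("matrix construction is deterministic and validated", {
  a <- small_instance(side = 8, p = 3, q = 4)
  b <- small_instance(side = 8, p = 3, q = 4)
  expect_identical(a$model$K, b$model$K)
  # detectors must clear the image support
  expect_error(
    build_measurement_matrix(image_grid(8, 30), scan_geometry(4, 10),
                             frequency_sampling(4, 2, seed = 1)),
    "does not clear"
  )
  expect_error(
    build_measurement_matrix(image_grid(8, 30), scan_geometry(4, 40),
                             frequency_sampling(3, 2, seed = 1)),
    "position count"
  )
})

test_that("frequency sampling is seeded, banded, and optionally shared", {
  fs <- frequency_sampling(5, 16, c(0.2, 3), seed = 3)
  expect_identical(fs$freqs_hz, frequency_sampling(5, 16, c(0.2, 3), seed = 3)$freqs_hz)
  expect_true(all(fs$freqs_hz > 0.2e6 & fs$freqs_hz < 3e6))
  expect_gt(length(unique(as.vector(fs$freqs_hz))), 16)  # per-position redraw
  sh <- frequency_sampling(5, 16, c(0.2, 3), seed = 3, share = TRUE)
  expect_true(all(sh$freqs_hz[1, ] == t(sh$freqs_hz)))
})

test_that("pressure simulation is the linear forward map", {
  inst <- small_instance(side = 8, p = 4, q = 4)
  zero <- phantom_image(matrix(0, 8, 8))
  expect_true(all(simulate_pressure(inst$model, zero)$Y == 0))

  px <- matrix(0, 8, 8); px[3, 5] <- 1
  one <- phantom_image(px)
  j <- flatten_image(px) == 1
  expect_equal(simulate_pressure(inst$model, one)$Y, inst$model$K[, j],
               tolerance = 1e-15)

  ph <- generate_vessel_phantom(8, 2, seed = 1)
  y1 <- simulate_pressure(inst$model, ph)$Y
  scaled <- phantom_image(ph$pixels * 0.4)   # 2.5 * 0.4 = 1 keeps range
  expect_equal(2.5 * simulate_pressure(inst$model, scaled)$Y, y1,
               tolerance = 1e-12)

  expect_error(simulate_pressure(inst$model, generate_shepp_logan(16)),
               "does not match")
})

test_that("noise injection hits the requested SNR exactly and is seeded", {
  inst <- small_instance(side = 8, p = 4, q = 4)
  data <- simulate_pressure(inst$model, generate_shepp_logan(8))
  noisy <- add_noise(data, 20, seed = 5)
  e <- noisy$Y - data$Y
  achieved <- 10 * log10(sum(Mod(data$Y)^2) / sum(Mod(e)^2))
  expect_equal(achieved, 20, tolerance = 1e-9)
  expect_identical(noisy$Y, add_noise(data, 20, seed = 5)$Y)
  expect_false(identical(noisy$Y, add_noise(data, 20, seed = 6)$Y))

  zero <- simulate_pressure(inst$model, phantom_image(matrix(0, 8, 8)))
  expect_error(add_noise(zero, 20), "SNR undefined")
  expect_error(add_noise(data, Inf), "finite")
})

test_that("very high SNR is indistinguishable from noiseless downstream", {
  inst <- small_instance(side = 16, p = 10, q = 16)
  ph <- generate_shepp_logan(16)
  clean <- simulate_pressure(inst$model, ph)
  nearly <- add_noise(clean, 300, seed = 2)
  r1 <- resl0_solve(inst$A, real_measurements(clean))
  r2 <- resl0_solve(inst$A, real_measurements(nearly))
  x1 <- synthesize(r1$theta_hat, inst$basis)
  x2 <- synthesize(r2$theta_hat, inst$basis)
  expect_lt(100 * sqrt(sum((x1 - x2)^2) / sum(ph$pixels^2)), 1e-6)
})

test_that("real lifting stacks real and imaginary parts consistently", {
  inst <- small_instance(side = 8, p = 3, q = 4)
  Kr <- real_matrix(inst$model)
  expect_equal(dim(Kr), c(2 * 12, 64))
  data <- simulate_pressure(inst$model, generate_shepp_logan(8))
  yr <- real_measurements(data)
  x <- flatten_image(generate_shepp_logan(8)$pixels)
  expect_equal(yr, as.vector(Kr %*% x), tolerance = 1e-12)
})
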