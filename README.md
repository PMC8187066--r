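# resl0

Sparse-view photoacoustic tomography reconstruction by smoothed-L0
minimization, in R.

Photoacoustic imaging recovers a map of absorbed optical energy from
ultrasound recorded outside the tissue. With few detector positions
(sparse view) the discretized problem `Y = K X` is underdetermined:
`K` is the temporal-frequency measurement operator for a circular scan,
with entries `i c k_n exp(-i k_n |r_m - r_ij|) / |r_m - r_ij|` for
detector `r_m`, wavenumber `k_n = 2 pi f_n / c` and pixel `r_ij`.
Compressed sensing restores well-posedness through wavelet sparsity
`X = Psi theta`, and the package solves

```
min ||theta||_0   subject to   Y ≈ (K Psi) theta
```

via the Gaussian surrogate `F_sigma(theta) = sum_i exp(-theta_i^2 / sigma^2)`
(whose complement `N - F_sigma` approaches the L0 norm as `sigma -> 0`)
annealed over a geometric sigma schedule. Two solvers are provided:

* **SL0** — gradient steps on `F_sigma`, each followed by the exact
  projection onto `{A theta = y}`;
* **ReSL0** — the error-tolerant variant: the projection is replaced by
  the Tikhonov-regularized correction
  `theta - A^T (A A^T + lambda^-1 I)^-1 (A theta - y)`, with `lambda`
  chosen adaptively each outer iteration as
  `||theta_grad - theta_prev||^2 / ||A^T (A theta_prev - y)||^2`,
  so the projection hardens on clean data and stays damped under
  measurement noise.

The package also ships the forward model (with exact-SNR noise
injection), an orthonormal periodized Daubechies/Haar wavelet basis,
procedural test phantoms (Shepp-Logan, vessel-like, resolution bars),
PSNR/NMAE quality metrics, and a seeded experiment runner for
view-count and noise sweeps with CSV output. A thin command-line
wrapper lives in `inst/cli/resl0-cli.R`. See the methods vignette
(`vignettes/resl0-methods.Rmd`) for the model, parameter defaults and
numerical design choices.

## Worked example

Reconstruct a 64-px Shepp-Logan phantom from 40 detector positions with
64 random frequencies per position in [0.2, 3] MHz (noiseless):

```r
library(resl0)
ph    <- generate_shepp_logan(64)
grid  <- image_grid(64, extent_mm = 30)
geom  <- scan_geometry(n_positions = 40, radius_mm = 40)
freqs <- frequency_sampling(40, n_freqs = 64, band_mhz = c(0.2, 3), seed = 1)
model <- build_measurement_matrix(grid, geom, freqs, sound_speed = 1500)
y     <- real_measurements(simulate_pressure(model, ph))
A     <- compose_sensing(model, wavelet_basis(64))

fit <- resl0_solve(A, y)
fit
#> <solver_result> resl0: 7 outer iterations, converged, final residual 7.34e-13
psnr(ph, fit$image_hat)
#> [1] 192.66
```

A PSNR of 192.7 dB means the reconstruction is exact to numerical
precision — at this sampling level the instance is in the
near-exact-recovery regime. Under noise the regularized solver
consistently scores above the equality-constrained baseline:

```r
plan <- experiment_plan(side_px = 64, positions = c(35, 40), n_freqs = 32,
                        snr_db = 30, methods = c("sl0", "resl0"),
                        n_repetitions = 3, freq_seed = 1, noise_seed = 1)
summarize_sweep(run_noise_sweep(plan))
#>   method n_positions snr_db   psnr_db     nmae
#> 1  resl0          35     30 -16.11758 1586.522
#> 3  resl0          40     30 -19.41888 2320.123
#> 2    sl0          35     30 -18.46652 2079.187
#> 4    sl0          40     30 -21.74959 3034.219
```

ReSL0 sits 2–3 dB above SL0 in every cell; the low absolute fidelity at
this reduced scale reflects the severe ill-conditioning of the
band-limited acoustic operator, which amplifies measurement noise (see
the vignette's limitations section).

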