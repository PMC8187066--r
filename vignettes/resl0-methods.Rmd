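---
title: "Sparse-view photoacoustic reconstruction with smoothed-L0 solvers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse-view photoacoustic reconstruction with smoothed-L0 solvers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resl0)
```

## The imaging problem

Photoacoustic tomography illuminates tissue with a nanosecond laser
pulse; optical absorbers convert the deposited energy into a pressure
transient that ultrasound transducers record outside the object. The
image of interest is the absorbed-energy map $A(\mathbf r)$ on a pixel
grid, flattened into $X \in \mathbb{R}^N$. In the temporal-frequency
domain, the pressure spectrum recorded by a point detector at
$\mathbf r_m$ for wavenumber $k_n = 2\pi f_n / c$ is a linear
functional of $X$ with kernel

$$K_{(m,n),(i,j)} \;=\; i\,c\,k_n\,
  \frac{e^{-i k_n \lVert \mathbf r_m - \mathbf r_{ij}\rVert}}
       {\lVert \mathbf r_m - \mathbf r_{ij}\rVert},$$

so that $Y = KX$ with $M = p\,q$ rows for $p$ detector positions and
$q$ sampled frequencies per position. All physical prefactors
(Grueneisen coefficient, $1/4\pi c$, detector response) enter as one
global constant that cancels between simulation and inversion; the
package fixes it by normalizing $K$ to unit RMS row norm, which also
keeps measurement norms, Gram eigenvalues and the adaptive
regularization parameter on order-one scales. Because $X$ is real, the
complex $M \times N$ system is solved as the real $2M \times N$ system
that stacks real and imaginary parts.

In sparse-view imaging $p$ is small (a single rotating transducer, few
stops), so $2M < N$ and the system is underdetermined. Compressed
sensing restores well-posedness through sparsity: $X = \Psi\theta$ with
$\Psi$ an orthonormal wavelet synthesis basis and $\theta$
compressible. Writing $A = K\Psi$, reconstruction becomes sparse
recovery from $Y = A\theta$.

## The solvers

Both solvers replace the combinatorial $\lVert\theta\rVert_0$ with the
Gaussian surrogate $F_\sigma(\theta) = \sum_i e^{-\theta_i^2/\sigma^2}$,
for which $N - F_\sigma(\theta) \to \lVert\theta\rVert_0$ as
$\sigma \to 0$. A graduated non-convexity schedule
$\sigma_j = \rho\,\sigma_{j-1}$ maximizes $F_\sigma$ over the data
constraint for a decreasing sequence of widths, each outer iteration
running $L$ inner steps of the gradient ascent
$\theta \leftarrow \theta + \mu\sigma^2\nabla F_\sigma(\theta)$
followed by a projection toward the data:

* **SL0** enforces $A\theta = y$ exactly:
  $\theta \leftarrow \theta - A^{T}(AA^{T})^{-1}(A\theta - y)$.
* **ReSL0** tolerates measurement error through the Tikhonov-regularized
  correction
  $\theta_p = \hat\theta - A^{T}\!\left(AA^{T} + \lambda^{-1} I\right)^{-1}
  (A\hat\theta - y)$, the closed-form minimizer of
  $\lVert\theta_p-\hat\theta\rVert^2 + \lambda\lVert A\theta_p - y\rVert^2$.
  The weight is chosen adaptively once per outer iteration,
  $\lambda_j = \lVert\theta_\nabla - \hat\theta_{j-1}\rVert^2 /
  \lVert A^{T}(A\hat\theta_{j-1} - y)\rVert^2$, where $\theta_\nabla$ is
  the first inner gradient step at $\sigma_j$, and then held fixed for
  the inner loop. The ratio grows as the iterates approach feasibility,
  so the damping relaxes toward the exact projection on clean data,
  while noise keeps the residual — and hence the damping — finite.

Both initialize the $\sigma$ schedule at $\sigma_0 = 4\max_i|\hat\theta_0|$
and stop when the relative image change between outer iterations falls
below `stop_tol` or $\sigma$ reaches its floor.

### Design choices the published description leaves open

Several elements of the iteration are not pinned down by the usual
presentations of these algorithms; the package resolves them as follows
and exposes every one through `solver_config()`.

* **Inner step size `mu = 1`.** With this package's surrogate
  convention ($e^{-\theta^2/\sigma^2}$, no $1/2$ in the exponent) the
  inner update is $\theta_i(1 - 2\mu e^{-\theta_i^2/\sigma^2})$. The
  classical SL0 step size of 2 applies to the $e^{-\theta^2/2\sigma^2}$
  convention; its equivalent here is $\mu = 1$, giving the same
  small-coefficient multiplier of $-1$. Larger $\mu$ makes that
  multiplier exceed 1 in magnitude and the null-space components of the
  iterate diverge.
* **Annealing rate `rho = 0.55`, floor `sigma_min_ratio = 1e-6`.** The
  stopping rule compares successive outer iterates, so the anneal must
  move enough per iteration that the rule only engages at convergence;
  at $\rho \ge 0.8$ the per-iteration change falls below a 0.005
  threshold while $\sigma$ is still large and the solver stops with
  order $10^{-2}$ relative error. The floor is deep enough that the
  final coefficient error, which scales with the last $\sigma$, reaches
  the $10^{-5}$ relative-error regime that near-exact recoveries
  exhibit.
* **Adaptive-$\lambda$ scale invariance.** The $\lambda$ ratio is not
  invariant to the overall scale of $A$ (its denominator grows as
  $\lVert A\rVert^4$ while a Tikhonov weight should track
  $\lVert A\rVert^2$), so ReSL0 runs internally on the row-normalized
  system $A/s$, $s^2$ the mean Gram eigenvalue; the constraint set and
  hence the solution are unchanged. Clip bounds default to
  $[10^{-16}, 10^{16}]$: on severely ill-conditioned operators a
  tighter cap turns the clean-data $\lambda \to \infty$ limit into real
  damping of the weakest identifiable directions.
* **ReSL0 initialization.** SL0 starts from the minimum-norm solution,
  which is exactly feasible. For ReSL0 an exactly-interpolating start
  zeroes the $\lambda$ denominator, and the degenerate-case cap would
  then lock the solver into equality-like projections — i.e. into SL0 —
  permanently. ReSL0 therefore starts from the Tikhonov-damped
  minimum-norm solution (unit shift on the normalized system), which
  carries the residual the adaptive rule reads the error level from.
* **Numerical rank.** The band-limited acoustic operator is
  intrinsically near-rank-deficient: at sampling ratios near one, a
  fraction of the Gram eigenvalues sits at the numerical-noise floor.
  All Gram solves (minimum-norm start, both projections) restrict to
  the identifiable range (eigenvalues above $10^{-12}$ of the largest),
  refine against the true operator, and only abort when fewer than half
  the directions are identifiable, which indicates a configuration
  error rather than physics.

The Gram matrix $AA^{T} = K_r K_r^{T}$ does not depend on the wavelet
basis (orthonormality) or on $\lambda$, so its eigendecomposition is
computed once per operator and reused by every projection at any
regularization level — the factorization-reuse that keeps the per-
iteration cost at a few matrix-vector products.

## The wavelet basis

The sparsifying transform is a separable 2-D periodized orthonormal
wavelet transform (Mallat layout), default family the 4-tap Daubechies
filter at maximum depth, with Haar and the identity basis as options.
Periodization keeps every level exactly orthogonal, so analysis is both
the inverse and the adjoint of synthesis — the property the solvers use
when moving between coefficient and image domains, and the reason the
Gram matrix is basis-independent. The transform is implemented
in-package as per-level orthonormal transform matrices; Parseval
equality and exact invertibility are asserted to $10^{-10}$ in the test
suite.

## Synthetic phantoms

Three procedural phantoms emulate the standard absorbed-energy test
images, each min–max scaled to $[0,1]$:

* `generate_shepp_logan()` — the classical ten-ellipse head phantom
  (a pixel takes the summed intensity of the ellipses containing its
  centre; no anti-aliasing). The classical, not contrast-modified,
  intensity set is used, since the subsequent rescale to $[0,1]$ sets
  the usable dynamic range anyway.
* `generate_vessel_phantom()` — seeded random-walk centrelines of
  width 1–3 px, emulating sparse vascular absorbers. Deterministic per
  seed, sparse by construction (the compressed-sensing premise).
* `generate_resolution_phantom()` — deterministic bar groups at four
  decreasing pitches plus disks, for resolution assessment.

These are stand-ins with the right qualitative structure, not copies of
any specific published bitmap; quantitative results on the vessel and
resolution phantoms are therefore comparable only in trend. The
simulated data they generate is *inverse-crime* data: the same operator
is used for simulation and inversion, there is no transducer impulse
response, no heterogeneous sound speed, no 3-D effects. Passing tests
demonstrate the solver chain, not clinical performance.

## Study conditions and problem sizes

The experiment runner reproduces the two studies a practitioner runs on
this pipeline: a **view sweep** (reconstruction quality versus the
number of detector positions, noiseless) and a **noise sweep** (quality
versus SNR at fixed geometry; noise is circular white Gaussian,
renormalized so the realized SNR is exact, seeded per repetition).

The full-size study uses a $128\times128$ grid on $30\times30$ mm,
$c = 1500$ m/s, detectors on a 40 mm circle, and $q = 128$ frequencies
per position drawn uniformly from $[0.2, 3]$ MHz — the grid resolution
then sits exactly at the acoustic diffraction limit of the band
($\lambda_{\min}/2 \approx 0.25$ mm per 0.23 mm pixel). The package's
own studies, including `scripts/acceptance.R` and the acceptance tests,
run a reduced-scale rendition at $64$ px with $q = 64$, keeping the
$q = \text{side}$ convention of the full-size study and every physical
condition unchanged; per-cell medians are taken over 5 independent
frequency draws. This size keeps the densest Gram eigendecomposition at
$6400^2$, which a single CPU core handles in under a minute.

Scale reduction changes the problem in one unavoidable way: the wavelet
representation of the Shepp-Logan phantom becomes relatively less
sparse as resolution falls (the significant-coefficient fraction roughly
doubles from 128 px to 64 px), while at fixed $M/N$ the physical
operator supplies no extra information. In consequence the reduced
study's recovery transition sits at a different *relative* sampling
ratio than the full-size one: at 64 px the 45- and 50-position cells are
(numerically rank-truncated) overdetermined systems and both solvers
reach near-exact recovery there, whereas the full-size study keeps
those cells underdetermined with partial-recovery scores. Medians at
the reduced scale therefore land in the near-exact regime
(PSNR well above 100 dB at 45–50 positions) rather than at the
full-size study's intermediate values; the view-sweep *shape* — flat
low-quality scores, then a sharp transition to the high-quality band
within the 5–50 position range — is preserved. Keeping the full-size
$M/N$ ratio instead (e.g. $q = 32$ at 64 px) does not restore the
full-size behaviour: the heavier sparsity fraction pushes those cells
below the recovery transition altogether, an information limit of the
reduced instance rather than a solver property.

For the noise-robustness comparison the underdetermined regime is the
scientifically relevant one (on overdetermined cells both solvers
converge to the same truncated least-squares point), so the acceptance
check runs 64 px, 40 positions, $q = 32$, 20 dB SNR, 10 noise seeds; the
regularized solver beats the equality-constrained one on every seed in
our runs.

## Metrics

`psnr()` implements $10\log_{10}\!\left(N\,\mathrm{MAX}_I^2 /
\lVert X - \hat X\rVert_2^2\right)$ with $\mathrm{MAX}_I$ the maximum
of the ground-truth image (identical to the conventional
$10\log_{10}(\mathrm{MAX}_I^2/\mathrm{MSE})$; identical images return
`Inf`). `nmae()` implements the percent-scale relative 2-norm error
$100\,\lVert\hat X - X\rVert_2 / \lVert X\rVert_2$ — despite the
"mean absolute error" reading of the acronym, the 2-norm formula is
what the field's quality tables print, and it is implemented verbatim.
The two are monotone transforms of each other at fixed $N$,
$\mathrm{MAX}_I$ and $\lVert X\rVert$; the test suite asserts the
implied identity.

## A small worked example

```{r example, eval = FALSE}
ph <- generate_shepp_logan(64)
grid <- image_grid(64, extent_mm = 30)
geom <- scan_geometry(n_positions = 40, radius_mm = 40)
freqs <- frequency_sampling(40, n_freqs = 64, band_mhz = c(0.2, 3), seed = 1)
model <- build_measurement_matrix(grid, geom, freqs, sound_speed = 1500)
y <- real_measurements(simulate_pressure(model, ph))
A <- compose_sensing(model, wavelet_basis(64))
fit <- resl0_solve(A, y)
psnr(ph, fit$image_hat)
```

## Known limitations

* The forward model is the ideal point-detector, homogeneous-medium,
  2-D frequency-domain operator; no time-domain simulation, impulse
  response, or 3-D geometry.
* Dense-matrix linear algebra bounds practical problem sizes to roughly
  $128$ px grids with a few thousand measurements on a single machine;
  the sweep runner refuses plans beyond its memory budget rather than
  swapping.
* On noisy data both smoothed-L0 solvers remain local ascent methods;
  at low SNR the reconstructions degrade substantially and the
  regularized variant's advantage is in degree, not kind.
* L1 (basis-pursuit) and total-variation reconstruction are deliberately
  out of scope; third-party solvers can be attached to the experiment
  runner through `register_solver()`.
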