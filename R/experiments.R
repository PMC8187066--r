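# Experiment orchestration: seeded view-count and noise sweeps producing
# tidy results tables, plus measurement export/import for offline
# reconstruction.

.solver_registry <- new.env(parent = emptyenv())

#' Register a reconstruction solver
#'
#' Built-in solvers `"sl0"` and `"resl0"` are pre-registered; third-party
#' solvers plug into the sweep runners through this adapter interface.
#'
#' @param name solver name used in experiment plans.
#' @param fn function `(A, y, cfg) -> solver_result`-like list containing
#'   at least `theta_hat` and `converged`.
#' @export
register_solver <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1, is.function(fn))
  .solver_registry[[name]] <- fn
  invisible(name)
}

get_solver <- function(name) {
  fn <- .solver_registry[[name]]
  if (is.null(fn)) {
    stop_invalid("unknown solver '%s' (registered: %s)", name,
                 paste(sort(ls(.solver_registry)), collapse = ", "))
  }
  fn
}

registered_solvers <- function() sort(ls(.solver_registry))

.phantom_generators <- list(
  shepp_logan = function(side, extent, seed) generate_shepp_logan(side, extent),
  vessel = function(side, extent, seed) {
    generate_vessel_phantom(side, seed = seed, extent_mm = extent)
  },
  resolution = function(side, extent, seed) {
    generate_resolution_phantom(side, extent)
  }
)

#' Define an experiment plan
#'
#' Bundles every knob of a simulation study: phantom, grid, geometry,
#' frequency sampling, noise levels, solvers, seeds and solver settings.
#' Together with its seeds a plan determines every output bit of
#' [run_view_sweep()] / [run_noise_sweep()] (timing columns aside).
#'
#' @param phantom `"shepp_logan"`, `"vessel"`, `"resolution"`, or a
#'   [phantom_image()] supplied directly.
#' @param side_px,extent_mm image raster and physical size.
#' @param sound_speed speed of sound in m/s.
#' @param radius_mm scan circle radius in mm.
#' @param positions increasing vector of detector position counts.
#' @param n_freqs frequencies per position.
#' @param band_mhz frequency window in MHz.
#' @param snr_db SNR levels in dB for noise sweeps (`Inf` = noiseless).
#' @param methods registered solver names to compare.
#' @param freq_seed,noise_seed base seeds; repetition r uses seed + r - 1.
#' @param n_repetitions repeated draws per cell (frequency draws for view
#'   sweeps, noise draws for noise sweeps).
#' @param wavelet_family,levels sparsity basis settings.
#' @param solver a [solver_config()].
#' @return object of class `experiment_plan`.
#' @export
experiment_plan <- function(phantom = "shepp_logan", side_px = 128,
                            extent_mm = 30, sound_speed = 1500,
                            radius_mm = 40, positions = seq(5, 50, by = 5),
                            n_freqs = 128, band_mhz = c(0.2, 3),
                            snr_db = Inf, methods = c("sl0", "resl0"),
                            freq_seed = 1, noise_seed = 1,
                            n_repetitions = 1, wavelet_family = "d4",
                            levels = NULL, solver = solver_config()) {
  if (is.unsorted(positions, strictly = TRUE) || any(positions < 1)) {
    stop_invalid("positions must be strictly increasing positive integers")
  }
  for (m in methods) get_solver(m)  # fail fast on unknown names
  if (is.character(phantom) && !phantom %in% names(.phantom_generators)) {
    stop_invalid("unknown phantom '%s' (have: %s)", phantom,
                 paste(names(.phantom_generators), collapse = ", "))
  }
  structure(
    list(phantom = phantom, side_px = side_px, extent_mm = extent_mm,
         sound_speed = sound_speed, radius_mm = radius_mm,
         positions = as.integer(positions), n_freqs = as.integer(n_freqs),
         band_mhz = band_mhz, snr_db = snr_db, methods = methods,
         freq_seed = as.integer(freq_seed), noise_seed = as.integer(noise_seed),
         n_repetitions = as.integer(n_repetitions),
         wavelet_family = wavelet_family, levels = levels, solver = solver),
    class = "experiment_plan"
  )
}

# Dense K, its real lift and the Gram eigendecomposition dominate memory;
# refuse plans whose largest cell would exceed the budget.
check_memory_budget <- function(plan, budget_gb = 6) {
  p <- max(plan$positions)
  m2 <- 2 * p * plan$n_freqs
  bytes <- 8 * (2 * m2 * plan$side_px^2 +  # complex K + real lift
                2 * m2^2)                  # Gram + eigenvectors
  if (bytes > budget_gb * 1e9) {
    stop_invalid("largest sweep cell needs ~%.1f GB (> %.0f GB budget): %d positions x %d frequencies on a %d px grid",
                 bytes / 1e9, budget_gb, p, plan$n_freqs, plan$side_px)
  }
  invisible(bytes)
}

plan_phantom <- function(plan) {
  if (inherits(plan$phantom, "phantom_image")) return(plan$phantom)
  .phantom_generators[[plan$phantom]](plan$side_px, plan$extent_mm,
                                      plan$freq_seed)
}

# Run every method on one simulated cell, returning result-table rows.
run_cell <- function(plan, phantom, basis, n_pos, freq_seed, noise_seed,
                     snr, rep) {
  grid <- image_grid(plan$side_px, plan$extent_mm)
  geom <- scan_geometry(n_pos, plan$radius_mm)
  fs <- frequency_sampling(n_pos, plan$n_freqs, plan$band_mhz, seed = freq_seed)
  model <- build_measurement_matrix(grid, geom, fs, plan$sound_speed)
  data <- simulate_pressure(model, phantom)
  if (is.finite(snr)) data <- add_noise(data, snr, seed = noise_seed)
  y <- real_measurements(data)
  A <- compose_sensing(model, basis)
  rows <- lapply(plan$methods, function(m) {
    solver <- get_solver(m)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(solver(A, y, plan$solver), error = function(e) e)
    cpu <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      return(data.frame(method = m, n_positions = n_pos, snr_db = snr,
                        repetition = rep, freq_seed = freq_seed,
                        noise_seed = noise_seed, psnr_db = NA_real_,
                        nmae = NA_real_, cpu_seconds = cpu,
                        n_outer = NA_integer_, converged = FALSE,
                        failed = TRUE))
    }
    x_hat <- if (!is.null(res$image_hat)) res$image_hat else {
      synthesize(res$theta_hat, basis)
    }
    data.frame(method = m, n_positions = n_pos, snr_db = snr,
               repetition = rep, freq_seed = freq_seed,
               noise_seed = noise_seed,
               psnr_db = psnr(phantom, x_hat), nmae = nmae(phantom, x_hat),
               cpu_seconds = cpu, n_outer = res$n_outer,
               converged = isTRUE(res$converged), failed = FALSE)
  })
  do.call(rbind, rows)
}

#' Run a view-count sweep
#'
#' For each detector position count in the plan: draws frequencies
#' (seeded, one independent draw per repetition), builds the measurement
#' matrix, simulates noiseless pressure data (plus noise if the plan's
#' `snr_db` is finite), reconstructs with each method, and scores PSNR and
#' NMAE against the phantom. Deterministic given the plan's seeds.
#'
#' @param plan an [experiment_plan()].
#' @param verbose print one line per cell.
#' @return `data.frame` with one row per
#'   (method x positions x repetition): columns `method`, `n_positions`,
#'   `snr_db`, `repetition`, `freq_seed`, `noise_seed`, `psnr_db`, `nmae`,
#'   `cpu_seconds`, `n_outer`, `converged`, `failed`.
#' @export
run_view_sweep <- function(plan, verbose = FALSE) {
  stopifnot(inherits(plan, "experiment_plan"))
  check_memory_budget(plan)
  phantom <- plan_phantom(plan)
  basis <- wavelet_basis(plan$side_px, plan$wavelet_family, plan$levels)
  snr <- plan$snr_db[1]
  out <- list()
  for (n_pos in plan$positions) {
    for (r in seq_len(plan$n_repetitions)) {
      rows <- run_cell(plan, phantom, basis, n_pos,
                       freq_seed = plan$freq_seed + r - 1L,
                       noise_seed = plan$noise_seed + r - 1L,
                       snr = snr, rep = r)
      if (verbose) {
        message(sprintf("positions=%d rep=%d: %s", n_pos, r,
                        paste(sprintf("%s %.1f dB", rows$method, rows$psnr_db),
                              collapse = ", ")))
      }
      out[[length(out) + 1L]] <- rows
    }
  }
  do.call(rbind, out)
}

#' Run a noise sweep
#'
#' As [run_view_sweep()], but iterating over the plan's `snr_db` levels.
#' The frequency draw (hence the measurement matrix) is fixed per position
#' count while each repetition redraws the noise, so all SNR curves share
#' one geometry.
#'
#' @inheritParams run_view_sweep
#' @return `data.frame` as in [run_view_sweep()].
#' @export
run_noise_sweep <- function(plan, verbose = FALSE) {
  stopifnot(inherits(plan, "experiment_plan"))
  check_memory_budget(plan)
  if (length(plan$snr_db) < 1) stop_invalid("plan has no SNR levels")
  phantom <- plan_phantom(plan)
  basis <- wavelet_basis(plan$side_px, plan$wavelet_family, plan$levels)
  out <- list()
  for (n_pos in plan$positions) {
    grid <- image_grid(plan$side_px, plan$extent_mm)
    geom <- scan_geometry(n_pos, plan$radius_mm)
    fs <- frequency_sampling(n_pos, plan$n_freqs, plan$band_mhz,
                             seed = plan$freq_seed)
    model <- build_measurement_matrix(grid, geom, fs, plan$sound_speed)
    clean <- simulate_pressure(model, phantom)
    A <- compose_sensing(model, basis)
    for (snr in plan$snr_db) {
      for (r in seq_len(plan$n_repetitions)) {
        nseed <- plan$noise_seed + r - 1L
        data <- if (is.finite(snr)) add_noise(clean, snr, seed = nseed) else clean
        y <- real_measurements(data)
        for (m in plan$methods) {
          t0 <- proc.time()[["elapsed"]]
          res <- tryCatch(get_solver(m)(A, y, plan$solver),
                          error = function(e) e)
          cpu <- proc.time()[["elapsed"]] - t0
          if (inherits(res, "error")) {
            out[[length(out) + 1L]] <- data.frame(
              method = m, n_positions = n_pos, snr_db = snr, repetition = r,
              freq_seed = plan$freq_seed, noise_seed = nseed,
              psnr_db = NA_real_, nmae = NA_real_, cpu_seconds = cpu,
              n_outer = NA_integer_, converged = FALSE, failed = TRUE)
            next
          }
          x_hat <- if (!is.null(res$image_hat)) res$image_hat else {
            synthesize(res$theta_hat, basis)
          }
          out[[length(out) + 1L]] <- data.frame(
            method = m, n_positions = n_pos, snr_db = snr, repetition = r,
            freq_seed = plan$freq_seed, noise_seed = nseed,
            psnr_db = psnr(phantom, x_hat), nmae = nmae(phantom, x_hat),
            cpu_seconds = cpu, n_outer = res$n_outer,
            converged = isTRUE(res$converged), failed = FALSE)
          if (verbose) {
            message(sprintf("positions=%d snr=%s rep=%d %s: %.1f dB",
                            n_pos, format(snr), r, m,
                            out[[length(out)]]$psnr_db))
          }
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Aggregate sweep results
#'
#' Median (or mean) PSNR/NMAE per (method, positions, SNR) cell.
#'
#' @param results table from a sweep runner.
#' @param stat `"median"` or `"mean"`.
#' @return aggregated `data.frame`.
#' @export
summarize_sweep <- function(results, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  f <- if (stat == "median") stats::median else mean
  agg <- stats::aggregate(
    cbind(psnr_db, nmae) ~ method + n_positions + snr_db,
    data = results, FUN = f
  )
  agg[order(agg$method, agg$n_positions, agg$snr_db), ]
}

.sidecar_keys <- c("side_px", "extent_mm", "sound_speed", "n_positions",
                   "radius_mm", "n_freqs", "band_mhz", "freq_seed",
                   "freq_share", "snr_db", "noise_seed")

#' Export and re-import simulated measurements
#'
#' `export_measurement()` writes a pressure vector as a two-column text
#' file (`<basename>.yvec`: real, imaginary) plus a JSON sidecar
#' (`<basename>.json`) holding every parameter needed to rebuild the
#' measurement matrix, so a reconstruction can be rerun from disk.
#' `reconstruct_from_file()` validates the sidecar, rebuilds the
#' operator, runs the named solver and (optionally) writes the
#' reconstructed image as PNG and text array.
#'
#' @param model a `measurement_model`.
#' @param data a `pressure_data` from that model.
#' @param basename output path prefix.
#' @export
export_measurement <- function(model, data, basename) {
  stopifnot(inherits(model, "measurement_model"),
            inherits(data, "pressure_data"))
  meta <- list(
    side_px = model$grid$side_px, extent_mm = model$grid$extent_mm,
    sound_speed = model$sound_speed_m_s,
    n_positions = model$geometry$n_positions,
    radius_mm = model$geometry$radius_mm,
    n_freqs = model$freqs$n_freqs, band_mhz = model$freqs$band_mhz,
    freq_seed = model$freqs$seed, freq_share = model$freqs$share,
    snr_db = if (is.finite(data$snr_db)) data$snr_db else "noiseless",
    noise_seed = data$noise_seed
  )
  jsonlite::write_json(meta, paste0(basename, ".json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.table(
    data.frame(re = Re(data$Y), im = Im(data$Y)),
    file = paste0(basename, ".yvec"), row.names = FALSE, quote = FALSE
  )
  invisible(basename)
}

#' @rdname export_measurement
#' @param solver_name a registered solver name.
#' @param cfg a [solver_config()].
#' @param wavelet_family sparsity basis family.
#' @param output_prefix if non-NULL, write `<prefix>.png` and
#'   `<prefix>.txt` of the reconstruction.
#' @return list with `image` (matrix) and `result` (`solver_result`).
#' @export
reconstruct_from_file <- function(basename, solver_name = "resl0",
                                  cfg = solver_config(),
                                  wavelet_family = "d4",
                                  output_prefix = NULL) {
  solver <- get_solver(solver_name)
  json_path <- paste0(basename, ".json")
  if (!file.exists(json_path)) stop_invalid("missing sidecar '%s'", json_path)
  meta <- tryCatch(jsonlite::read_json(json_path, simplifyVector = TRUE),
                   error = function(e) {
                     stop_invalid("unreadable sidecar '%s': %s", json_path,
                                  conditionMessage(e))
                   })
  missing <- setdiff(.sidecar_keys, names(meta))
  if (length(missing) > 0) {
    stop_invalid("sidecar is missing required keys: %s",
                 paste(missing, collapse = ", "))
  }
  yv <- utils::read.table(paste0(basename, ".yvec"), header = TRUE)
  y <- complex(real = yv$re, imaginary = yv$im)
  grid <- image_grid(meta$side_px, meta$extent_mm)
  geom <- scan_geometry(meta$n_positions, meta$radius_mm)
  fs <- frequency_sampling(meta$n_positions, meta$n_freqs, meta$band_mhz,
                           seed = meta$freq_seed, share = isTRUE(meta$freq_share))
  model <- build_measurement_matrix(grid, geom, fs, meta$sound_speed)
  if (length(y) != model$n_measurements) {
    stop_invalid("measurement length %d does not match sidecar geometry (%d)",
                 length(y), model$n_measurements)
  }
  basis <- wavelet_basis(meta$side_px, wavelet_family)
  A <- compose_sensing(model, basis)
  res <- solver(A, real_measurements(y), cfg)
  img <- if (!is.null(res$image_hat)) res$image_hat else {
    synthesize(res$theta_hat, basis)
  }
  if (!is.null(output_prefix)) {
    clipped <- pmin(pmax(img, 0), 1)
    png::writePNG(clipped, target = paste0(output_prefix, ".png"))
    utils::write.table(format(img, digits = 17),
                       file = paste0(output_prefix, ".txt"),
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  list(image = img, result = res)
}

# nocov start
.onLoad <- function(libname, pkgname) {
  register_solver("sl0", function(A, y, cfg) sl0_solve(A, y, cfg))
  register_solver("resl0", function(A, y, cfg) resl0_solve(A, y, cfg))
}
# nocov end
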