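# Scenario runner: reproduces each canonical experiment of the reed-bank
# study at configurable scale and writes a deterministic output bundle
# (config echo, per-stage CSVs, derived-statistics JSON, run log).

scenario_names <- c("fig3", "fig4", "fig5_6", "fig7", "fig8", "fig9",
                    "fig10", "fig11", "fig12", "fig13", "fig14", "fig15")

# internal: nearest reed to a target natural frequency
nearest_reed <- function(bank, f_hz) which.min(abs(bank$natural_freq_hz - f_hz))

# internal: steady-state waterfall reconstructed from phasors
phasor_waterfall <- function(resp, n_cycles = 2, samples_per_cycle = 40) {
  w <- 2 * pi * resp$drive_freq_hz
  tt <- seq(0, n_cycles / resp$drive_freq_hz,
            length.out = n_cycles * samples_per_cycle + 1)
  x <- t(sapply(resp$phasor, function(X) Im(X * exp(1i * w * tt))))
  data.frame(time_s = rep(tt, each = length(resp$phasor)),
             reed_index = rep(seq_along(resp$phasor), times = length(tt)),
             displacement = as.vector(x))
}

# internal: ripple statistics of a transect: first peak ratio and the mean of
# the subsequent ones, from peaks at/above the main peak location
transect_peak_stats <- function(series, axis, min_prominence_db = 1) {
  pk <- find_peaks(series, axis, min_prominence_db)
  main <- pk$location[which.max(pk$height)]
  pk <- pk[pk$location >= main, , drop = FALSE]
  r <- peak_ratios(pk)
  list(n_peaks = nrow(pk),
       main_to_secondary = if (length(r)) r[1] else NA_real_,
       mean_subsequent = if (length(r) > 1) mean(r[-1]) else NA_real_)
}

#' Run a canonical reed-bank scenario
#'
#' Reproduces one of the package's standard experiments end to end and writes
#' a deterministic output bundle under `out_dir/<name>/`: `config.json` (the
#' resolved parameters), per-stage CSV tables, `stats.json` with the derived
#' statistics (peak ratios, slopes, periodicities, plateau ratios, settling
#' times), and `run.log` (the only file carrying timestamps).  Re-running
#' with identical parameters reproduces the CSV payloads byte for byte.
#'
#' Scenarios: `fig3` switch-on transients and settling of the 21-reed Wilson
#' bank; `fig4` travelling-wave waterfalls (coupled vs uncoupled); `fig5_6`
#' the 51-combination coupling/damping sweep of amplitude and phase profiles;
#' `fig7` single-reed frequency responses; `fig8` spatial ripples of the
#' 201-oscillator bank as coupling grows; `fig9` the full response map and its
#' transect peak ratios; `fig10` ripples and phase transitions; `fig11`
#' uniform versus boundary-tapered coupling; `fig12` single-reed forcing and
#' attenuation slopes; `fig13` phase-band periodicity from forced time-domain
#' runs; `fig14` impulse responses and their spectra; `fig15` frequency
#' plateaus and clustering.
#'
#' @param name scenario name, one of
#'   `"fig3", "fig4", "fig5_6", "fig7", "fig8", "fig9", "fig10", "fig11",
#'   "fig12", "fig13", "fig14", "fig15"`.
#' @param out_dir output directory (created if needed).
#' @param overrides named list of parameter overrides for the scenario
#'   (unknown names are rejected); e.g. `list(kappa = 300)`.
#' @param scale scale factor in `(0, 1]` shrinking run durations and grid
#'   resolutions proportionally for quick runs.
#' @param quiet suppress per-stage console output?
#' @return invisibly, a list with `stats`, `tables` (data frames) and `files`.
#' @examples
#' \donttest{
#' res <- run_scenario("fig5_6", out_dir = tempdir())
#' res$stats$max_phase_lag_cycles_kappa4600
#' }
#' @export
run_scenario <- function(name, out_dir, overrides = list(), scale = 1,
                         quiet = TRUE) {
  if (!is.character(name) || length(name) != 1 || !(name %in% scenario_names))
    stop("unknown scenario '", paste(name, collapse = ","), "'; valid names: ",
         paste(scenario_names, collapse = ", "), call. = FALSE)
  if (!is.finite(scale) || scale <= 0 || scale > 1)
    stop("'scale' must be in (0, 1]", call. = FALSE)
  dir <- file.path(out_dir, name)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(dir, "run.log")
  cat(sprintf("[%s] scenario %s start (scale=%g)\n",
              format(Sys.time(), "%Y-%m-%d %H:%M:%S"), name, scale),
      file = logfile)
  stage <- function(label, expr) {
    t0 <- proc.time()[3]
    val <- tryCatch(expr, error = function(e)
      stop(sprintf("scenario %s failed at stage '%s': %s", name, label,
                   conditionMessage(e)), call. = FALSE))
    msg <- sprintf("[%s] stage=%s wall_s=%.2f",
                   format(Sys.time(), "%Y-%m-%d %H:%M:%S"), label,
                   proc.time()[3] - t0)
    cat(msg, "\n", file = logfile, append = TRUE)
    if (!quiet) message(msg)
    val
  }

  fn <- get(paste0("scenario_", sub("fig", "fig_", name)), mode = "function")
  res <- fn(overrides, scale, stage)

  cfg <- c(list(scenario = name, scale = scale,
                package_version = as.character(utils::packageVersion("frahm")),
                solver = list(rtol = 1e-8, atol = 1e-10, method = "lsoda")),
           res$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  for (nm in names(res$tables))
    write.csv(res$tables[[nm]], file.path(dir, paste0(nm, ".csv")),
              row.names = FALSE)
  jsonlite::write_json(res$stats, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cat(sprintf("[%s] scenario %s done\n",
              format(Sys.time(), "%Y-%m-%d %H:%M:%S"), name),
      file = logfile, append = TRUE)
  invisible(list(stats = res$stats, tables = res$tables,
                 files = list.files(dir, full.names = TRUE)))
}

# internal: merge overrides into scenario defaults, rejecting unknown keys
scenario_params <- function(defaults, overrides) {
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad))
    stop("unknown override(s): ", paste(bad, collapse = ", "), call. = FALSE)
  modifyList(defaults, overrides)
}

scenario_fig_3 <- function(overrides, scale, stage) {
  p <- scenario_params(list(kappa = 2500, gamma = 0.014, drive_hz = 50,
                            duration_s = 5, tol_fraction = 0.02), overrides)
  bank <- build_wilson_bank(p$kappa, p$gamma)
  traj <- stage("integrate", simulate_forced(
    bank, drive_spec(p$drive_hz, p$duration_s * scale)))
  st <- stage("settling", settling_time(traj, p$tol_fraction))
  keep <- c(1, 11, 21)
  tr <- data.frame(time_s = rep(traj$time_s, each = 3),
                   reed_index = rep(keep, times = length(traj$time_s)),
                   natural_freq_hz = rep(bank$natural_freq_hz[keep],
                                         times = length(traj$time_s)),
                   displacement = as.vector(traj$displacement[keep, ]))
  list(config = p,
       tables = list(transients = tr,
                     settling = data.frame(reed_index = seq_len(bank$n),
                                           settling_time_s = st)),
       stats = list(max_settling_time_s = max(st),
                    all_settled_by_2s = all(!is.na(st) & st <= 2)))
}

scenario_fig_4 <- function(overrides, scale, stage) {
  p <- scenario_params(list(kappa = 2500, gamma = 0.014, drive_hz = 50,
                            n_cycles = 2), overrides)
  coupled <- stage("phasors_coupled",
                   solve_phasors(build_wilson_bank(p$kappa, p$gamma),
                                 p$drive_hz))
  uncoupled <- stage("phasors_uncoupled",
                     solve_phasors(build_wilson_bank(0, p$gamma), p$drive_hz))
  list(config = p,
       tables = list(waterfall_coupled = phasor_waterfall(coupled, p$n_cycles),
                     waterfall_uncoupled = phasor_waterfall(uncoupled,
                                                            p$n_cycles)),
       stats = list(peak_reed_coupled = which.max(Mod(coupled$phasor)),
                    peak_reed_uncoupled = which.max(Mod(uncoupled$phasor))))
}

scenario_fig_5_6 <- function(overrides, scale, stage) {
  p <- scenario_params(list(kappa_max = 5000, kappa_step = 100,
                            drive_hz = 50), overrides)
  kappas <- seq(0, p$kappa_max, by = p$kappa_step)
  rows <- stage("sweep", lapply(kappas, function(k) {
    prof <- steady_state_profile(
      solve_phasors(build_wilson_bank(k, gamma_for_kappa(k)), p$drive_hz),
      phase_ref = "highest_freq_reed")
    data.frame(kappa = k, reed_index = seq_along(prof$amplitude),
               natural_freq_hz = prof$natural_freq_hz,
               amplitude_norm = prof$amplitude / max(prof$amplitude),
               phase_cycles = prof$phase_cycles)
  }))
  tab <- do.call(rbind, rows)
  lag4600 <- if (4600 <= p$kappa_max) {
    prof <- steady_state_profile(
      solve_phasors(build_wilson_bank(4600, gamma_for_kappa(4600)),
                    p$drive_hz), phase_ref = "highest_freq_reed")
    max(prof$phase_cycles)
  } else NA_real_
  list(config = p,
       tables = list(profiles = tab),
       stats = list(n_combinations = length(kappas),
                    max_phase_lag_cycles_kappa4600 = lag4600))
}

scenario_fig_7 <- function(overrides, scale, stage) {
  p <- scenario_params(list(kappa = 2200, gamma = 0.013, f_lo = 40, f_hi = 60,
                            step_hz = 0.1), overrides)
  bank <- build_wilson_bank(p$kappa, p$gamma)
  grid <- seq(p$f_lo, p$f_hi, by = p$step_hz / scale)
  m <- stage("response_map", response_map(bank, grid))
  best <- grid[apply(m$amplitude, 2, which.max)]
  list(config = p,
       tables = list(frequency_responses = as.data.frame(m),
                     peak_drive = data.frame(
                       reed_index = seq_len(bank$n),
                       natural_freq_hz = bank$natural_freq_hz,
                       peak_drive_hz = best)),
       stats = list(mean_peak_shift_hz = mean(best - bank$natural_freq_hz),
                    all_peaks_above_natural = all(
                      best > bank$natural_freq_hz)))
}

scenario_fig_8 <- function(overrides, scale, stage) {
  p <- scenario_params(list(kappa_max = 400, kappa_step = 10, gamma = 0.025,
                            drive_hz = 1750), overrides)
  kappas <- seq(0, p$kappa_max, by = p$kappa_step)
  rows <- stage("sweep", lapply(kappas, function(k) {
    b <- build_greenwood_bank(k, p$gamma)
    amp <- Mod(solve_phasors(b, p$drive_hz)$phasor)
    data.frame(kappa = k, reed_index = seq_len(b$n),
               natural_freq_hz = b$natural_freq_hz, amplitude = amp)
  }))
  tab <- do.call(rbind, rows)
  pk <- vapply(rows, function(df)
    df$natural_freq_hz[which.max(df$amplitude)], 0)
  list(config = p,
       tables = list(profiles = tab),
       stats = list(peak_natural_freq_by_kappa = setNames(
         as.list(pk), paste0("kappa_", kappas)),
         peak_shift_monotone = all(diff(pk) <= 1e-9)))
}

scenario_fig_9 <- function(overrides, scale, stage) {
  p <- scenario_params(list(kappa = 200, gamma = 0.025, grid_lo = 1000,
                            grid_hi = 2500, grid_step = 2.5,
                            transect_hz = 1750), overrides)
  bank <- build_greenwood_bank(p$kappa, p$gamma)
  grid <- seq(p$grid_lo, p$grid_hi, by = p$grid_step / scale)
  m <- stage("response_map", response_map(bank, grid))
  j <- nearest_reed(bank, p$transect_hz)
  r <- which.min(abs(grid - p$transect_hz))
  vert <- stage("transects",
                transect_peak_stats(m$amplitude[, j], grid))
  # the spatial transect runs toward lower natural frequency: keep peaks at
  # or below the main one and invert the descending ratio train
  spatial <- {
    amp <- m$amplitude[r, ]
    pks <- find_peaks(amp, bank$natural_freq_hz)
    main <- pks$location[which.max(pks$height)]
    pks <- pks[pks$location <= main, , drop = FALSE]
    rr <- rev(peak_ratios(pks))       # reorder outward from the main peak
    list(n_peaks = nrow(pks),
         main_to_secondary = if (length(rr)) rr[1] else NA_real_,
         mean_subsequent = if (length(rr) > 1) mean(rr[-1]) else NA_real_)
  }
  list(config = p,
       tables = list(response_map = as.data.frame(m)),
       stats = list(drive_transect = vert, spatial_transect = spatial))
}

scenario_fig_10 <- function(overrides, scale, stage) {
  p <- scenario_params(list(kappas = c(200, 500), gamma = 0.025,
                            drive_hz = 1800), overrides)
  tabs <- list()
  stats <- list()
  for (k in p$kappas) {
    bank <- build_greenwood_bank(k, p$gamma)
    prof <- stage(paste0("profile_kappa", k),
                  steady_state_profile(solve_phasors(bank, p$drive_hz)))
    tabs[[paste0("profile_kappa", k)]] <- as.data.frame(prof)
    mins <- find_minima(prof$amplitude, prof$natural_freq_hz)
    stats[[paste0("n_minima_kappa", k)]] <- nrow(mins)
  }
  list(config = p, tables = tabs, stats = stats)
}

scenario_fig_11 <- function(overrides, scale, stage) {
  p <- scenario_params(list(kappas = c(200, 400), gamma = 0.025,
                            drive_hz = 1750, ramp_len = 10, margin = 20),
                       overrides)
  tabs <- list()
  stats <- list()
  for (k in p$kappas) {
    uni <- build_greenwood_bank(k, p$gamma)
    tap <- uni
    tap$coupling <- tapered_coupling_profile(uni$n, max(uni$coupling),
                                             p$ramp_len)
    a_u <- Mod(stage(paste0("uniform_kappa", k),
                     solve_phasors(uni, p$drive_hz))$phasor)
    a_t <- Mod(stage(paste0("tapered_kappa", k),
                     solve_phasors(tap, p$drive_hz))$phasor)
    dd <- 20 * log10(a_t / a_u)
    tabs[[paste0("taper_kappa", k)]] <- data.frame(
      reed_index = seq_len(uni$n), natural_freq_hz = uni$natural_freq_hz,
      amplitude_uniform = a_u, amplitude_tapered = a_t, diff_db = dd)
    mid <- seq.int(p$margin + 1, uni$n - p$margin)
    stats[[paste0("max_mid_array_diff_db_kappa", k)]] <- max(abs(dd[mid]))
  }
  list(config = p, tables = tabs, stats = stats)
}

scenario_fig_12 <- function(overrides, scale, stage) {
  p <- scenario_params(list(kappa = 200, gamma = 0.025, drive_hz = 1750,
                            fit_range_db = c(3, 23)), overrides)
  bank <- build_greenwood_bank(p$kappa, p$gamma)
  all_driven <- stage("all_reeds", solve_phasors(bank, p$drive_hz))
  j <- nearest_reed(bank, p$drive_hz)
  one <- stage("single_reed", single_reed_drive(bank, j, p$drive_hz))
  slopes <- stage("slopes",
                  attenuation_slopes(one, fit_range_db = p$fit_range_db))
  list(config = p,
       tables = list(all_driven = as.data.frame(all_driven),
                     single_reed = as.data.frame(one)),
       stats = list(driven_reed = j,
                    low_side_db_per_oct = unname(slopes["low_side"]),
                    high_side_db_per_oct = unname(slopes["high_side"])))
}

scenario_fig_13 <- function(overrides, scale, stage) {
  p <- scenario_params(list(kappas = c(0, 200, 400), gamma = 0.025,
                            drive_hz = 1750, duration_s = 0.1), overrides)
  tabs <- list()
  stats <- list()
  for (k in p$kappas) {
    bank <- build_greenwood_bank(k, p$gamma)
    traj <- stage(paste0("integrate_kappa", k), simulate_forced(
      bank, drive_spec(p$drive_hz, p$duration_s * scale)))
    prof <- steady_state_profile(traj)
    tabs[[paste0("profile_kappa", k)]] <- as.data.frame(prof)
    if (k > 0)
      stats[[paste0("band_period_hz_kappa", k)]] <-
        phase_band_period(prof)
  }
  list(config = p, tables = tabs, stats = stats)
}

scenario_fig_14 <- function(overrides, scale, stage) {
  p <- scenario_params(list(kappa = 200, gamma = 0.025, duration_s = 0.05,
                            pad_factor = 8, band_hz = c(1000, 3000),
                            mid_reeds = seq(81, 121, by = 5)), overrides)
  bank <- build_greenwood_bank(p$kappa, p$gamma)
  traj <- stage("integrate",
                simulate_impulse(bank, p$duration_s * scale))
  spec <- stage("fft", impulse_spectrum(traj, p$pad_factor))
  sel <- spec$freq_hz >= p$band_hz[1] & spec$freq_hz <= p$band_hz[2]
  ratios <- vapply(p$mid_reeds, function(j) {
    pk <- find_peaks(spec$magnitude[j, sel], spec$freq_hz[sel])
    r <- peak_ratios(pk)
    if (length(r)) mean(r) else NA_real_
  }, 0)
  show <- unique(round(seq(1, bank$n, length.out = 11)))
  spec_tab <- data.frame(
    reed_index = rep(show, each = sum(sel)),
    freq_hz = rep(spec$freq_hz[sel], times = length(show)),
    magnitude = as.vector(t(spec$magnitude[show, sel])))
  list(config = p,
       tables = list(spectra = spec_tab),
       stats = list(mean_peak_ratio = mean(ratios, na.rm = TRUE),
                    per_reed_ratio = setNames(as.list(ratios),
                                              paste0("reed_", p$mid_reeds))))
}

scenario_fig_15 <- function(overrides, scale, stage) {
  p <- scenario_params(list(kappas = c(0, 1000), gamma = 0.025,
                            f_lo = 1000, f_hi = 2000, n = 201,
                            duration_s = 0.05, pad_factor = 8), overrides)
  tabs <- list()
  stats <- list()
  for (k in p$kappas) {
    bank <- build_linear_bank(p$f_lo, p$f_hi, p$n, k, p$gamma)
    traj <- stage(paste0("integrate_kappa", k),
                  simulate_impulse(bank, p$duration_s * scale))
    map <- dominant_frequency_map(
      stage(paste0("fft_kappa", k), impulse_spectrum(traj, p$pad_factor)))
    tabs[[paste0("dominant_kappa", k)]] <- as.data.frame(map)
    r <- plateau_ratios(map)
    stats[[paste0("n_plateau_ratios_kappa", k)]] <- length(r)
    if (length(r))
      stats[[paste0("first_plateau_ratio_kappa", k)]] <- r[1]
  }
  list(config = p, tables = tabs, stats = stats)
}
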