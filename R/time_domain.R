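#' Sinusoidal drive specification
#'
#' @param freq_hz drive frequency in Hz (positive).
#' @param duration_s simulated time in seconds (positive).
#' @param samples_per_cycle output sampling density, in samples per cycle of
#'   the *highest natural frequency in the bank* (the output grid must resolve
#'   the fastest oscillation present, not just the drive).
#' @return an object of class `"drive_spec"`.
#' @export
drive_spec <- function(freq_hz, duration_s, samples_per_cycle = 40) {
  if (!is.finite(freq_hz) || freq_hz <= 0)
    stop("'freq_hz' must be positive", call. = FALSE)
  if (!is.finite(duration_s) || duration_s <= 0)
    stop("'duration_s' must be positive", call. = FALSE)
  if (!is.finite(samples_per_cycle) || samples_per_cycle < 4)
    stop("'samples_per_cycle' must be at least 4", call. = FALSE)
  structure(list(freq_hz = freq_hz, duration_s = duration_s,
                 samples_per_cycle = samples_per_cycle),
            class = "drive_spec")
}

#' @export
print.drive_spec <- function(x, ...) {
  cat(sprintf("Sinusoidal drive: %.6g Hz for %.4g s (%g samples/cycle at top f_j)\n",
              x$freq_hz, x$duration_s, x$samples_per_cycle))
  invisible(x)
}

# internal: output time grid; dt resolves the fastest natural oscillation
reed_times <- function(bank, duration_s, samples_per_cycle) {
  dt <- 1 / (samples_per_cycle * max(bank$natural_freq_hz))
  seq(0, duration_s, by = dt)
}

# internal: padded parameter block matching the layout in src/reed_deriv.c
REED_PARMS_MAX <- 4224L

reed_parms <- function(bank, omega_drive, famp) {
  p <- c(bank$n, omega_drive, omega_j(bank)^2, bank$gamma * omega_j(bank),
         famp, bank$coupling)
  if (length(p) > REED_PARMS_MAX)
    stop(sprintf("time-domain engine supports at most %d reeds",
                 (REED_PARMS_MAX - 1) %/% 4), call. = FALSE)
  c(p, rep(0, REED_PARMS_MAX - length(p)))
}

reed_ode <- function(bank, y0, times, omega_drive, famp, rtol, atol, method) {
  out <- deSolve::ode(y = y0, times = times, func = "reed_deriv",
                      parms = reed_parms(bank, omega_drive, famp),
                      dllname = "frahm", initfunc = "reed_init",
                      rtol = rtol, atol = atol, method = method)
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0)
    stop(sprintf("integration failed (istate = %d); try looser tolerances or a different method",
                 istate[1]), call. = FALSE)
  if (nrow(out) < length(times))
    stop("integration stopped early", call. = FALSE)
  out
}

traj_matrix <- function(out, n, offset) {
  m <- t(out[, 1 + offset + seq_len(n), drop = FALSE])
  dimnames(m) <- NULL
  m
}

new_trajectory <- function(time_s, displacement, velocity, bank, drive) {
  structure(list(time_s = time_s, displacement = displacement,
                 velocity = velocity, bank = bank, drive = drive),
            class = "reed_trajectory")
}

#' Integrate the forced reed bank in the time domain
#'
#' Solves the `2n`-dimensional first-order form of the equations of motion
#' with an adaptive solver, from quiescent initial conditions
#' (`x_j(0) = x_j'(0) = 0`), under parallel (or masked) sinusoidal forcing
#' `f0 * mask_j * sin(omega t)`.  Reed `j` feels the per-link coupling force
#' `k_{j-1,j}(x_{j-1}-x_j) + k_{j,j+1}(x_{j+1}-x_j)`; absent links at the ends
#' contribute nothing, which for uniform coupling is exactly the classic
#' free-end boundary prescription (`x_2 - x_1` and `x_{n-1} - x_n`).
#'
#' @param bank a [reed_bank()].
#' @param drive a [drive_spec()].
#' @param rtol,atol solver tolerances.
#' @param method a [deSolve::ode()] method; the default `"lsoda"` switches
#'   automatically between stiff and non-stiff steppers.
#' @return an object of class `"reed_trajectory"` holding the sample times,
#'   an `n x T` displacement matrix, an `n x T` velocity matrix, and
#'   references to the bank and drive.
#' @seealso [simulate_impulse()], [steady_state_profile()], [solve_phasors()]
#' @examples
#' bank <- build_wilson_bank(kappa = 2500, gamma = 0.014)
#' traj <- simulate_forced(bank, drive_spec(50, 0.5))
#' traj
#' @export
simulate_forced <- function(bank, drive, rtol = 1e-8, atol = 1e-10,
                            method = "lsoda") {
  stopifnot(inherits(bank, "reed_bank"), inherits(drive, "drive_spec"))
  times <- reed_times(bank, drive$duration_s, drive$samples_per_cycle)
  out <- reed_ode(bank, y0 = rep(0, 2 * bank$n), times = times,
                  omega_drive = 2 * pi * drive$freq_hz,
                  famp = bank$f0 * bank$forcing_mask,
                  rtol = rtol, atol = atol, method = method)
  new_trajectory(unname(out[, 1]), traj_matrix(out, bank$n, 0),
                 traj_matrix(out, bank$n, bank$n), bank, drive)
}

#' Impulse response of the reed bank
#'
#' Unforced evolution from a global velocity impulse: `x_j(0) = 0` and
#' `x_j'(0) = 1` on every reed (forcing switched off).  Coupled banks respond
#' with beating ("waxing and waning") envelopes whose spectra carry multiple
#' closely spaced peaks.
#'
#' @param bank a [reed_bank()].
#' @param duration_s simulated time in seconds.
#' @param samples_per_cycle output sampling density per cycle of the highest
#'   natural frequency.
#' @param rtol,atol,method as in [simulate_forced()].
#' @return a `"reed_trajectory"` with a `NULL` drive.
#' @examples
#' bank <- build_wilson_bank(kappa = 0, gamma = 0.014)
#' traj <- simulate_impulse(bank, duration_s = 0.5)
#' @export
simulate_impulse <- function(bank, duration_s, samples_per_cycle = 40,
                             rtol = 1e-8, atol = 1e-10, method = "lsoda") {
  stopifnot(inherits(bank, "reed_bank"))
  if (!is.finite(duration_s) || duration_s <= 0)
    stop("'duration_s' must be positive", call. = FALSE)
  times <- reed_times(bank, duration_s, samples_per_cycle)
  out <- reed_ode(bank, y0 = c(rep(0, bank$n), rep(1, bank$n)), times = times,
                  omega_drive = 0, famp = rep(0, bank$n),
                  rtol = rtol, atol = atol, method = method)
  new_trajectory(unname(out[, 1]), traj_matrix(out, bank$n, 0),
                 traj_matrix(out, bank$n, bank$n), bank, NULL)
}

#' @export
print.reed_trajectory <- function(x, ...) {
  cat(sprintf("Reed trajectory: %d reeds x %d samples over %.4g s (%s)\n",
              nrow(x$displacement), ncol(x$displacement), max(x$time_s),
              if (is.null(x$drive)) "impulse protocol"
              else sprintf("forced at %.6g Hz", x$drive$freq_hz)))
  invisible(x)
}

#' @export
as.data.frame.reed_trajectory <- function(x, ...) {
  n <- nrow(x$displacement)
  data.frame(time_s = rep(x$time_s, each = n),
             reed_index = rep(seq_len(n), times = length(x$time_s)),
             displacement = as.vector(x$displacement))
}

#' Waterfall plot of a trajectory
#'
#' Offsets each reed's displacement trace vertically so the travelling wave
#' is visible as a diagonal ridge running toward the low-frequency reeds.
#'
#' @param x a `"reed_trajectory"`.
#' @param n_cycles how many final drive cycles to show (ignored for impulse
#'   runs, where the full record is shown).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.reed_trajectory <- function(x, n_cycles = 2, ...) {
  keep <- if (is.null(x$drive)) rep(TRUE, length(x$time_s)) else
    x$time_s >= max(x$time_s) - n_cycles / x$drive$freq_hz
  xx <- x$displacement[, keep, drop = FALSE]
  amp <- max(abs(xx))
  if (amp == 0) amp <- 1
  off <- outer(seq_len(nrow(xx)), rep(1, ncol(xx))) * 2 * amp
  matplot(x$time_s[keep], t(xx + off), type = "l", lty = 1, col = 1,
          xlab = "time (s)", ylab = "reed (offset displacement)",
          yaxt = "n", ...)
  invisible(x)
}

#' Steady-state amplitude and phase profile
#'
#' Generic measurement of the per-reed steady-state response at the drive
#' frequency.  For a forced trajectory the amplitude is the peak absolute
#' displacement over the final `n_cycles` drive cycles (the classic
#' "amplitude reached during the last 3 cycles" measure) and the phase is the
#' argument of the single-frequency Fourier component of `x_j(t)` over that
#' window.  For a phasor solution ([solve_phasors()]) both are read off the
#' complex amplitudes directly.  Phase lags are unwrapped along the array
#' (adjacent-difference unwrap with a pi jump threshold) and re-referenced to
#' either the driving force or the reed with the highest natural frequency.
#'
#' @param x a `"reed_trajectory"` (with a drive) or a `"reed_response"`.
#' @param n_cycles number of final drive cycles in the measurement window.
#' @param phase_ref `"force"` (phase lag behind the driving force) or
#'   `"highest_freq_reed"` (lag relative to the fastest reed, the convention
#'   used when comparing against the analogue measurements).
#' @param ... unused.
#' @return an object of class `"steady_state_profile"` with per-reed
#'   `amplitude`, `phase_cycles` (lag, in cycles, increasing toward more
#'   delayed reeds), `natural_freq_hz`, the drive frequency and the phase
#'   reference.
#' @examples
#' bank <- build_wilson_bank(kappa = 4600, gamma = 0.021)
#' prof <- steady_state_profile(solve_phasors(bank, 50),
#'                              phase_ref = "highest_freq_reed")
#' max(prof$phase_cycles)  # about 2.5 cycles at the apex end
#' @export
steady_state_profile <- function(x, ...) UseMethod("steady_state_profile")

#' @rdname steady_state_profile
#' @export
steady_state_profile.reed_trajectory <- function(x, n_cycles = 3,
                                                 phase_ref = c("force", "highest_freq_reed"),
                                                 ...) {
  phase_ref <- match.arg(phase_ref)
  if (is.null(x$drive))
    stop("steady-state profile needs a forced trajectory", call. = FALSE)
  period <- 1 / x$drive$freq_hz
  t_end <- max(x$time_s)
  t0 <- t_end - n_cycles * period
  if (t0 < min(x$time_s) - 1e-12)
    stop("measurement window of ", n_cycles,
         " cycles is longer than the trajectory", call. = FALSE)
  keep <- x$time_s >= t0 - 1e-12
  if (sum(keep) < 8)
    stop("too few samples in the measurement window", call. = FALSE)
  tt <- x$time_s[keep]
  xx <- x$displacement[, keep, drop = FALSE]
  amplitude <- unname(apply(abs(xx), 1, max))

  # single-frequency Fourier component by least squares on the window:
  # x ~ a sin(wt) + b cos(wt); exact for a pure sinusoid at any sampling
  w <- 2 * pi * x$drive$freq_hz
  basis <- cbind(sin(w * tt), cos(w * tt))
  ab <- t(qr.solve(basis, t(xx)))            # n x 2
  lag_rad <- atan2(-ab[, 2], ab[, 1])        # x = C sin(wt - lag)
  finish_profile(amplitude, lag_rad, x$bank, x$drive$freq_hz, phase_ref,
                 source = "time_domain")
}

# internal: unwrap the phase-lag sequence along the array.
#
# The travelling wave makes the lag accumulate monotonically toward the
# lower-natural-frequency reeds, and at amplitude minima the transition
# between phase plateaus can exceed pi between adjacent reeds -- a symmetric
# (-pi, pi] unwrap then drops whole turns.  Unwrapping along the direction of
# accumulating lag with the branch window [-pi/2, 3*pi/2) admits those rapid
# forward transitions while still tolerating small backward wiggles.
unwrap_lag <- function(lag_rad, natural_freq_hz) {
  ord <- order(natural_freq_hz, decreasing = TRUE)
  lag <- lag_rad[ord]
  d <- diff(lag)
  d <- (d + pi / 2) %% (2 * pi) - pi / 2
  out <- cumsum(c(lag[1], d))
  out[order(ord)]
}

# internal: unwrap along the array, re-reference, assemble the object
finish_profile <- function(amplitude, lag_rad, bank, drive_freq_hz,
                           phase_ref, source) {
  lag <- unname(unwrap_lag(lag_rad, bank$natural_freq_hz))
  amplitude <- unname(amplitude)
  if (phase_ref == "highest_freq_reed")
    lag <- lag - lag[which.max(bank$natural_freq_hz)]
  structure(list(amplitude = amplitude,
                 phase_cycles = lag / (2 * pi),
                 natural_freq_hz = bank$natural_freq_hz,
                 drive_freq_hz = drive_freq_hz,
                 phase_ref = phase_ref,
                 source = source,
                 bank = bank),
            class = "steady_state_profile")
}

#' @export
print.steady_state_profile <- function(x, ...) {
  pk <- which.max(x$amplitude)
  cat(sprintf("Steady-state profile at %.6g Hz (%s): %d reeds\n",
              x$drive_freq_hz, x$source, length(x$amplitude)))
  cat(sprintf("  peak amplitude %.4g at reed %d (f_j = %.5g Hz)\n",
              x$amplitude[pk], pk, x$natural_freq_hz[pk]))
  cat(sprintf("  phase lag span %.3g cycles (re %s)\n",
              diff(range(x$phase_cycles)), x$phase_ref))
  invisible(x)
}

#' @export
as.data.frame.steady_state_profile <- function(x, ...) {
  data.frame(reed_index = seq_along(x$amplitude),
             natural_freq_hz = x$natural_freq_hz,
             amplitude = x$amplitude,
             phase_cycles = x$phase_cycles)
}

#' @export
plot.steady_state_profile <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(x$natural_freq_hz, x$amplitude / max(x$amplitude), type = "l",
       log = "y", xlab = "natural frequency (Hz)",
       ylab = "normalised amplitude",
       main = sprintf("drive %.5g Hz", x$drive_freq_hz), ...)
  abline(v = x$drive_freq_hz, lty = 3)
  plot(x$natural_freq_hz, x$phase_cycles, type = "l",
       xlab = "natural frequency (Hz)",
       ylab = sprintf("phase lag (cycles re %s)", x$phase_ref))
  invisible(x)
}

#' Per-reed settling time
#'
#' Operationalises "settled into steady state": for each reed, the
#' cycle-by-cycle peak amplitude is compared with the final steady-state
#' amplitude (measured over the last 3 cycles), and the settling time is the
#' earliest cycle boundary after which every subsequent cycle peak stays
#' within `tol_fraction` of it.
#'
#' @param traj a forced `"reed_trajectory"`.
#' @param tol_fraction relative tolerance on the cycle peak (default 2%).
#' @return numeric vector of per-reed settling times in seconds; `NA` marks a
#'   reed that never settles within the simulated span.
#' @examples
#' bank <- build_wilson_bank(kappa = 2500, gamma = 0.014)
#' traj <- simulate_forced(bank, drive_spec(50, 3))
#' max(settling_time(traj))  # below 2 s
#' @export
settling_time <- function(traj, tol_fraction = 0.02) {
  stopifnot(inherits(traj, "reed_trajectory"))
  if (is.null(traj$drive))
    stop("settling time needs a forced trajectory", call. = FALSE)
  period <- 1 / traj$drive$freq_hz
  n_cyc <- floor(max(traj$time_s) / period)
  if (n_cyc < 4)
    stop("trajectory shorter than 4 drive cycles", call. = FALSE)
  cyc <- pmin(floor(traj$time_s / period), n_cyc - 1)  # 0-based cycle index
  steady <- steady_state_profile(traj, n_cycles = 3)$amplitude
  vapply(seq_len(nrow(traj$displacement)), function(j) {
    peaks <- vapply(split(abs(traj$displacement[j, ]), cyc), max, 0)
    ok <- abs(peaks - steady[j]) <= tol_fraction * steady[j]
    if (!all(ok[length(ok)])) return(NA_real_)
    bad <- which(!ok)
    if (length(bad) == 0) 0 else {
      if (max(bad) == length(ok)) NA_real_ else max(bad) * period
    }
  }, 0)
}
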