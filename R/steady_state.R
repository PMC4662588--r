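#' Frequency-domain steady-state solution
#'
#' Solves the steady state of the driven coupled reed bank directly, without
#' time integration.  Writing `x_j(t) = Im(X_j e^{i w t})` with sinusoidal
#' forcing `f0 * mask_j * sin(w t)` turns the equations of motion into a
#' complex tridiagonal linear system `A X = f0 * mask` with
#' `A_jj = w_j^2 - w^2 + i gamma w_j w + k_left(j) + k_right(j)` and
#' off-diagonal entries `-k_link`; missing links at the ends contribute
#' nothing.  `|X_j|` is the steady-state amplitude and `-Arg(X_j)` the phase
#' lag behind the force.  This solver is the exact oracle for the time-domain
#' engine and is fast enough for dense response maps.
#'
#' @param bank a [reed_bank()].
#' @param drive_freq_hz drive frequency in Hz (positive).
#' @param engine `"tridiagonal"` (Thomas algorithm, default) or `"dense"`
#'   (full complex solve, retained as a cross-check path).
#' @return an object of class `"reed_response"`: the complex `phasor` vector,
#'   the drive frequency and the bank.
#' @seealso [steady_state_profile()], [response_map()], [single_reed_drive()]
#' @examples
#' bank <- build_wilson_bank(kappa = 2200, gamma = 0.013)
#' resp <- solve_phasors(bank, 50)
#' which.max(Mod(resp$phasor))  # spatial peak below the 50 Hz reed
#' @export
solve_phasors <- function(bank, drive_freq_hz,
                          engine = c("tridiagonal", "dense")) {
  stopifnot(inherits(bank, "reed_bank"))
  engine <- match.arg(engine)
  if (!is.finite(drive_freq_hz) || drive_freq_hz <= 0)
    stop("'drive_freq_hz' must be positive", call. = FALSE)
  w <- 2 * pi * drive_freq_hz
  wj <- omega_j(bank)
  kl <- c(0, bank$coupling)            # link to the left of reed j
  kr <- c(bank$coupling, 0)            # link to the right of reed j
  d <- complex(real = wj^2 - w^2 + kl + kr, imaginary = bank$gamma * wj * w)
  rhs <- complex(real = bank$f0 * bank$forcing_mask)
  X <- if (engine == "tridiagonal") {
    solve_tridiag(d, -bank$coupling, rhs)
  } else {
    A <- diag(d)
    idx <- seq_len(bank$n - 1)
    A[cbind(idx, idx + 1)] <- -bank$coupling
    A[cbind(idx + 1, idx)] <- -bank$coupling
    solve(A, rhs)
  }
  if (any(!is.finite(Re(X))) || any(!is.finite(Im(X))))
    stop("singular steady-state system (undamped exact resonance?)",
         call. = FALSE)
  structure(list(phasor = X, drive_freq_hz = drive_freq_hz, bank = bank),
            class = "reed_response")
}

# internal: Thomas algorithm for a symmetric complex tridiagonal system
solve_tridiag <- function(diag_, off, rhs) {
  n <- length(diag_)
  if (n == 1) return(rhs / diag_)
  cp <- complex(length.out = n - 1)
  dp <- complex(length.out = n)
  cp[1] <- off[1] / diag_[1]
  dp[1] <- rhs[1] / diag_[1]
  for (j in 2:n) {
    m <- diag_[j] - off[j - 1] * cp[j - 1]
    if (j < n) cp[j] <- off[j] / m
    dp[j] <- (rhs[j] - off[j - 1] * dp[j - 1]) / m
  }
  x <- complex(length.out = n)
  x[n] <- dp[n]
  for (j in (n - 1):1) x[j] <- dp[j] - cp[j] * x[j + 1]
  x
}

#' @export
print.reed_response <- function(x, ...) {
  amp <- Mod(x$phasor)
  pk <- which.max(amp)
  cat(sprintf("Steady-state phasor response at %.6g Hz: %d reeds\n",
              x$drive_freq_hz, length(amp)))
  cat(sprintf("  peak |X| = %.4g at reed %d (f_j = %.5g Hz)\n",
              amp[pk], pk, x$bank$natural_freq_hz[pk]))
  invisible(x)
}

#' @export
as.data.frame.reed_response <- function(x, ...) {
  lag <- unwrap_lag(-Arg(x$phasor), x$bank$natural_freq_hz) / (2 * pi)
  data.frame(reed_index = seq_along(x$phasor),
             natural_freq_hz = x$bank$natural_freq_hz,
             amplitude = Mod(x$phasor),
             phase_cycles = lag,
             re = Re(x$phasor), im = Im(x$phasor))
}

#' @rdname steady_state_profile
#' @export
steady_state_profile.reed_response <- function(x,
                                               phase_ref = c("force", "highest_freq_reed"),
                                               ...) {
  phase_ref <- match.arg(phase_ref)
  finish_profile(Mod(x$phasor), -Arg(x$phasor), x$bank, x$drive_freq_hz,
                 phase_ref, source = "phasor")
}

#' Closed-form amplitude of an uncoupled driven reed
#'
#' The textbook driven damped harmonic oscillator,
#' `f0 / sqrt((w_j^2 - w^2)^2 + (gamma w_j w)^2)`: the `kappa = 0` limit of
#' the bank, used as reference ("uncoupled") curves and for half-power
#' bandwidth (Q) checks.
#'
#' @param f_j natural frequency of the reed in Hz.
#' @param gamma damping ratio.
#' @param drive_freq_hz drive frequency (or vector of frequencies) in Hz.
#' @param f0 forcing amplitude.
#' @return amplitude(s), same length as `drive_freq_hz`.
#' @examples
#' uncoupled_amplitude(50, 0.014, 50)          # resonance: f0/(gamma w_j^2)
#' uncoupled_amplitude(50, 0.014, 1e-6) * (2 * pi * 50)^2  # static limit f0
#' @export
uncoupled_amplitude <- function(f_j, gamma, drive_freq_hz, f0 = 1000) {
  wj <- 2 * pi * f_j
  w <- 2 * pi * drive_freq_hz
  f0 / sqrt((wj^2 - w^2)^2 + (gamma * wj * w)^2)
}

#' Response map over a grid of drive frequencies
#'
#' Runs [solve_phasors()] at each drive frequency and stacks the amplitude
#' and (array-unwrapped) phase-lag profiles into matrices: rows are drive
#' frequencies, columns are reeds.  A vertical transect (fixed reed) gives a
#' frequency-response curve with ripples above the reed's natural frequency;
#' a horizontal transect (fixed drive) gives the spatial profile with ripples
#' below the drive frequency.
#'
#' @param bank a [reed_bank()].
#' @param drive_grid_hz ascending vector of drive frequencies in Hz.
#' @return an object of class `"response_map"` with `drive_freq_hz`,
#'   `natural_freq_hz`, and `amplitude` / `phase_cycles` matrices.
#' @examples
#' bank <- build_greenwood_bank(kappa = 200)
#' m <- response_map(bank, seq(1600, 2000, by = 10))
#' @export
response_map <- function(bank, drive_grid_hz) {
  stopifnot(inherits(bank, "reed_bank"))
  if (length(drive_grid_hz) < 1 || is.unsorted(drive_grid_hz, strictly = TRUE))
    stop("'drive_grid_hz' must be non-empty and strictly ascending",
         call. = FALSE)
  amp <- matrix(0, length(drive_grid_hz), bank$n)
  ph <- matrix(0, length(drive_grid_hz), bank$n)
  for (r in seq_along(drive_grid_hz)) {
    X <- solve_phasors(bank, drive_grid_hz[r])$phasor
    amp[r, ] <- Mod(X)
    ph[r, ] <- unwrap_lag(-Arg(X), bank$natural_freq_hz) / (2 * pi)
  }
  structure(list(drive_freq_hz = drive_grid_hz,
                 natural_freq_hz = bank$natural_freq_hz,
                 amplitude = amp, phase_cycles = ph, bank = bank),
            class = "response_map")
}

#' @export
print.response_map <- function(x, ...) {
  cat(sprintf("Response map: %d drive frequencies (%.5g-%.5g Hz) x %d reeds\n",
              length(x$drive_freq_hz), min(x$drive_freq_hz),
              max(x$drive_freq_hz), length(x$natural_freq_hz)))
  invisible(x)
}

#' @export
plot.response_map <- function(x, ...) {
  image(x$drive_freq_hz, x$natural_freq_hz, log10(x$amplitude),
        col = hcl.colors(64, "viridis"),
        xlab = "drive frequency (Hz)", ylab = "natural frequency (Hz)",
        main = "log10 amplitude", ...)
  invisible(x)
}

#' Drive a single reed
#'
#' Applies the sinusoidal force to one reed only (one-hot forcing mask) and
#' solves the steady state.  The decay of `|X|` away from the driven reed
#' measures how far energy propagates along the chain; it is markedly slower
#' toward lower-frequency reeds (the travelling-wave direction) than toward
#' higher-frequency ones.
#'
#' @param bank a [reed_bank()].
#' @param j index of the driven reed.
#' @param drive_freq_hz drive frequency in Hz.
#' @return a `"reed_response"` with attribute `driven_reed = j`.
#' @seealso [attenuation_slopes()]
#' @examples
#' bank <- build_greenwood_bank(kappa = 200)
#' j <- which.min(abs(bank$natural_freq_hz - 1750))
#' resp <- single_reed_drive(bank, j, 1750)
#' @export
single_reed_drive <- function(bank, j, drive_freq_hz) {
  stopifnot(inherits(bank, "reed_bank"))
  if (!is.finite(j) || j < 1 || j > bank$n || j != round(j))
    stop("'j' must be a reed index in 1..n", call. = FALSE)
  mask <- rep(0, bank$n)
  mask[j] <- 1
  b <- bank
  b$forcing_mask <- mask
  resp <- solve_phasors(b, drive_freq_hz)
  attr(resp, "driven_reed") <- as.integer(j)
  resp
}
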