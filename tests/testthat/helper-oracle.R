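# Shared oracles and fixtures, all built in code.

# closed-form steady state of a single driven damped oscillator:
# x'' + gamma*wj*x' + wj^2*x = f0*sin(w*t)
single_oscillator_phasor <- function(f_j, gamma, drive_hz, f0 = 1000) {
  wj <- 2 * pi * f_j
  w <- 2 * pi * drive_hz
  f0 / complex(real = wj^2 - w^2, imaginary = gamma * wj * w)
}

# duration after which the switch-on transient has decayed to 1/margin of its
# initial size for the slowest-decaying reed (decay rate gamma*omega_j/2)
transient_duration <- function(bank, margin = 400) {
  2 * log(margin) / (bank$gamma * 2 * pi * min(bank$natural_freq_hz))
}

# literal reference integration of the uniform-coupling equations of motion
# (kappa*(x[j-1] - 2 x[j] + x[j+1]), end terms x2 - x1 and x[n-1] - x[n]),
# written directly in R against deSolve -- independent of the package's
# compiled per-link right-hand side
reference_forced_trajectory <- function(bank, drive, rtol = 1e-8,
                                        atol = 1e-10) {
  stopifnot(length(unique(bank$coupling)) == 1)
  kappa <- bank$coupling[1]
  n <- bank$n
  wj <- 2 * pi * bank$natural_freq_hz
  w <- 2 * pi * drive$freq_hz
  famp <- bank$f0 * bank$forcing_mask
  rhs <- function(t, y, parms) {
    x <- y[1:n]; v <- y[(n + 1):(2 * n)]
    coup <- kappa * (c(x[-1], 0) + c(0, x[-n]) - 2 * x)
    coup[1] <- kappa * (x[2] - x[1])
    coup[n] <- kappa * (x[n - 1] - x[n])
    acc <- -bank$gamma * wj * v - wj^2 * x + famp * sin(w * t) + coup
    list(c(v, acc))
  }
  times <- seq(0, drive$duration_s,
               by = 1 / (drive$samples_per_cycle * max(bank$natural_freq_hz)))
  deSolve::ode(y = rep(0, 2 * n), times = times, func = rhs, parms = NULL,
               rtol = rtol, atol = atol)
}

# a synthetic forced trajectory with known per-reed amplitude and phase lag
synthetic_trajectory <- function(amps, lags_rad, drive_hz, duration_s,
                                 fs_hz, f_natural = NULL) {
  tt <- seq(0, duration_s, by = 1 / fs_hz)
  x <- t(sapply(seq_along(amps), function(j)
    amps[j] * sin(2 * pi * drive_hz * tt - lags_rad[j])))
  n <- length(amps)
  if (is.null(f_natural)) f_natural <- seq(55, 45, length.out = n)
  bank <- reed_bank(f_natural, gamma = 0.01, coupling = 0)
  structure(list(time_s = tt, displacement = x, velocity = 0 * x, bank = bank,
                 drive = drive_spec(drive_hz, duration_s)),
            class = "reed_trajectory")
}
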