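#' Construct a reed bank
#'
#' A reed bank is the physical model: `n` passive damped harmonic oscillators
#' ("reeds") with natural frequencies `natural_freq_hz`, a common dimensionless
#' damping ratio `gamma` (quality factor `Q = 1/gamma`), elastic
#' nearest-neighbour coupling stored *per link* (`n - 1` values, link `j`
#' joining reeds `j` and `j + 1`), a forcing amplitude `f0` and a per-reed
#' forcing mask.  An all-ones mask is the standard parallel forcing (every reed
#' feels the same field, as hair cells feel sound through the fluid); a one-hot
#' mask drives a single reed.
#'
#' The forcing amplitude is arbitrary: the system is linear, so `f0` only sets
#' an overall scale.
#'
#' @param natural_freq_hz numeric vector of natural frequencies \eqn{f_j} in
#'   Hz, length at least 2, all positive.
#' @param gamma dimensionless damping ratio \eqn{\gamma \ge 0}.
#' @param coupling per-link coupling constants in (rad/s)^2: either a single
#'   value recycled to all `n - 1` links or a vector of length `n - 1`.
#' @param f0 forcing amplitude (arbitrary units).
#' @param forcing_mask per-reed weights in `[0, 1]` multiplying `f0`.
#' @return An object of class `"reed_bank"`.
#' @seealso [build_wilson_bank()], [build_greenwood_bank()],
#'   [build_linear_bank()], [tapered_coupling_profile()]
#' @examples
#' bank <- reed_bank(seq(55, 45, by = -0.5), gamma = 0.014, coupling = 2500)
#' bank
#' @export
reed_bank <- function(natural_freq_hz, gamma, coupling, f0 = 1000,
                      forcing_mask = rep(1, length(natural_freq_hz))) {
  n <- length(natural_freq_hz)
  if (n < 2)
    stop("a reed bank needs at least 2 oscillators", call. = FALSE)
  if (!is.numeric(natural_freq_hz) || any(!is.finite(natural_freq_hz)) ||
      any(natural_freq_hz <= 0))
    stop("'natural_freq_hz' must be finite and positive", call. = FALSE)
  if (!is.numeric(gamma) || length(gamma) != 1 || !is.finite(gamma) ||
      gamma < 0)
    stop("'gamma' must be a single non-negative number", call. = FALSE)
  if (length(coupling) == 1) coupling <- rep(coupling, n - 1)
  if (length(coupling) != n - 1)
    stop("'coupling' must have exactly n - 1 entries (one per link)",
         call. = FALSE)
  if (any(!is.finite(coupling)) || any(coupling < 0))
    stop("'coupling' must be finite and non-negative", call. = FALSE)
  if (!is.numeric(f0) || length(f0) != 1 || !is.finite(f0))
    stop("'f0' must be a single finite number", call. = FALSE)
  if (length(forcing_mask) != n || any(!is.finite(forcing_mask)) ||
      any(forcing_mask < 0) || any(forcing_mask > 1))
    stop("'forcing_mask' must be n values in [0, 1]", call. = FALSE)

  structure(
    list(n = n,
         natural_freq_hz = as.numeric(natural_freq_hz),
         gamma = as.numeric(gamma),
         coupling = as.numeric(coupling),
         f0 = as.numeric(f0),
         forcing_mask = as.numeric(forcing_mask)),
    class = "reed_bank")
}

#' Damping calibrated to coupling strength
#'
#' A rubber band threaded between the reeds supplies both elastic coupling and
#' damping, so the two are not independent: combinations that best reproduce
#' the analogue measurements follow the affine rule
#' \deqn{\gamma = 3.37\times 10^{-6}\,\kappa + 0.00553.}
#'
#' @param kappa coupling constant(s), non-negative; vectorised.
#' @return damping ratio(s) \eqn{\gamma}.
#' @examples
#' gamma_for_kappa(c(0, 150, 2200, 4600))
#' @export
gamma_for_kappa <- function(kappa) {
  if (any(!is.finite(kappa)) || any(kappa < 0))
    stop("'kappa' must be finite and non-negative", call. = FALSE)
  3.37e-6 * kappa + 0.00553
}

#' The 21-reed Wilson bank
#'
#' Builds the classic vibrating-reed frequency meter configuration: 21 reeds
#' with natural frequencies descending from 55 Hz (reed 1) to 45 Hz (reed 21)
#' in 0.5 Hz steps, uniform coupling, parallel forcing with `f0 = 1000`.
#'
#' @param kappa uniform per-link coupling constant, non-negative.
#' @param gamma damping ratio, or `"auto"` to apply the rubber-band
#'   calibration [gamma_for_kappa()].
#' @param f0 forcing amplitude.
#' @return a [reed_bank()].
#' @examples
#' build_wilson_bank(kappa = 2500, gamma = 0.014)
#' build_wilson_bank(kappa = 4600)  # gamma = "auto" gives about 0.021
#' @export
build_wilson_bank <- function(kappa, gamma = "auto", f0 = 1000) {
  if (identical(gamma, "auto")) gamma <- gamma_for_kappa(kappa)
  reed_bank(seq(55, 45, by = -0.5), gamma = gamma, coupling = kappa, f0 = f0)
}

#' Greenwood frequency-position map
#'
#' Characteristic frequency at distance `x_mm` from the cochlear apex under
#' the exponential place-frequency map
#' \deqn{F = A\,(10^{a x} - k).}
#' The default constants are the standard human map (`A = 165.4` Hz,
#' `a = 0.06` per mm, `k = 0.88`).
#'
#' @param x_mm distance from the apex in mm; vectorised.
#' @param params a [greenwood_params()] list.
#' @return frequency in Hz.
#' @examples
#' greenwood_frequency(c(16.5, 18.5))  # about 1.47 and 1.99 kHz
#' @export
greenwood_frequency <- function(x_mm, params = greenwood_params()) {
  f <- params$A * (10^(params$a * x_mm) - params$k)
  if (any(!is.finite(f)) || any(f <= 0))
    stop("Greenwood map yields non-positive frequency over the requested range",
         call. = FALSE)
  f
}

#' @rdname greenwood_frequency
#' @param A scale in Hz (`A > 0`).
#' @param a exponent rate per mm (`a > 0`).
#' @param k dimensionless offset (`k >= 0`).
#' @export
greenwood_params <- function(A = 165.4, a = 0.06, k = 0.88) {
  if (A <= 0 || a <= 0 || k < 0)
    stop("need A > 0, a > 0, k >= 0", call. = FALSE)
  list(A = A, a = a, k = k)
}

#' The 201-oscillator Greenwood bank
#'
#' Natural frequencies follow the human Greenwood map over a stretch of
#' cochlea `x_start`--`x_end` mm from the apex sampled every `dx` mm (0.01 mm,
#' the width of a hair cell, gives 201 oscillators spanning roughly 1.5--2 kHz
#' in nearly equal steps of about 2.5 Hz).  Oscillator 1 has the lowest
#' natural frequency.  The default damping `gamma = 0.025` corresponds to
#' Q of 40.
#'
#' @section Coupling units for kilohertz banks:
#' The coupling constants conventionally quoted for the kilohertz banks
#' (kappa of a few hundred) follow the millisecond time convention of the
#' original calculations, i.e. they are in (rad/ms)^2.  At kilohertz natural
#' frequencies a coupling of a few hundred (rad/s)^2 would be utterly
#' negligible against \eqn{\omega_j^2 \approx 10^8}: the chain would behave
#' as uncoupled, which contradicts every published kilohertz-bank result.
#' `kappa_unit = "rad2_per_ms2"` (the default) therefore converts the given
#' value by the factor \eqn{10^6} into the (rad/s)^2 stored in the bank;
#' pass `"rad2_per_s2"` to supply SI values directly.
#'
#' @param kappa uniform per-link coupling constant, in `kappa_unit`.
#' @param gamma damping ratio.
#' @param x_start,x_end,dx apex distances in mm defining the sampled stretch.
#' @param params Greenwood map constants, see [greenwood_params()].
#' @param f0 forcing amplitude.
#' @param kappa_unit unit of `kappa`: `"rad2_per_ms2"` (historical
#'   kilohertz-bank convention, default) or `"rad2_per_s2"` (SI).
#' @return a [reed_bank()] (coupling stored in (rad/s)^2).
#' @examples
#' bank <- build_greenwood_bank(kappa = 200)
#' range(bank$natural_freq_hz)
#' mean(diff(bank$natural_freq_hz))  # about 2.5 Hz
#' @export
build_greenwood_bank <- function(kappa, gamma = 0.025, x_start = 16.5,
                                 x_end = 18.5, dx = 0.01,
                                 params = greenwood_params(), f0 = 1000,
                                 kappa_unit = c("rad2_per_ms2", "rad2_per_s2")) {
  kappa <- kappa * kappa_unit_factor(kappa_unit)
  if (!is.finite(x_start) || !is.finite(x_end) || x_end <= x_start)
    stop("'x_end' must exceed 'x_start'", call. = FALSE)
  if (!is.finite(dx) || dx <= 0)
    stop("'dx' must be positive", call. = FALSE)
  x <- seq(x_start, x_end, by = dx)
  if (length(x) < 2)
    stop("fewer than 2 positions in the requested range", call. = FALSE)
  reed_bank(greenwood_frequency(x, params), gamma = gamma, coupling = kappa,
            f0 = f0)
}

#' A bank with equally spaced natural frequencies
#'
#' Used for the kilohertz clustering experiments (201 oscillators equally
#' spaced from 1 to 2 kHz), so `kappa` defaults to the same millisecond
#' coupling convention as [build_greenwood_bank()]; pass
#' `kappa_unit = "rad2_per_s2"` for SI values (e.g. to rebuild a Wilson-like
#' bank, whose coupling constants are quoted in (rad/s)^2).
#'
#' @param f_start,f_end first and last natural frequencies in Hz
#'   (`f_start < f_end`); both endpoints are included.
#' @param n number of oscillators.
#' @param kappa uniform per-link coupling constant, in `kappa_unit`.
#' @param gamma damping ratio.
#' @param f0 forcing amplitude.
#' @inheritParams build_greenwood_bank
#' @return a [reed_bank()] (coupling stored in (rad/s)^2).
#' @examples
#' build_linear_bank(1000, 2000, 201, kappa = 1000, gamma = 0.025)
#' @export
build_linear_bank <- function(f_start, f_end, n, kappa, gamma, f0 = 1000,
                              kappa_unit = c("rad2_per_ms2", "rad2_per_s2")) {
  if (!is.finite(n) || n < 2)
    stop("'n' must be at least 2", call. = FALSE)
  if (!is.finite(f_start) || !is.finite(f_end) || f_start >= f_end)
    stop("'f_start' must be below 'f_end'", call. = FALSE)
  reed_bank(seq(f_start, f_end, length.out = n), gamma = gamma,
            coupling = kappa * kappa_unit_factor(kappa_unit), f0 = f0)
}

# internal: conversion to the (rad/s)^2 stored in a bank
kappa_unit_factor <- function(kappa_unit) {
  switch(match.arg(kappa_unit, c("rad2_per_ms2", "rad2_per_s2")),
         rad2_per_ms2 = 1e6, rad2_per_s2 = 1)
}

#' Boundary-tapered coupling profile
#'
#' Per-link coupling vector in which coupling vanishes at the chain ends and
#' rises linearly over `ramp_len` links to a fixed interior maximum, mirrored
#' at the far end.  Used to test whether the response ripples depend on the
#' boundary conditions: swapping this profile for a uniform one leaves the
#' mid-array response nearly unchanged.
#'
#' @param n number of reeds in the bank the profile is for (the returned
#'   vector has `n - 1` entries).
#' @param kappa_max interior coupling value.
#' @param ramp_len number of links over which the ramp rises; `0` gives a
#'   uniform profile.
#' @return numeric vector of `n - 1` per-link coupling constants.
#' @examples
#' k <- tapered_coupling_profile(201, 200)
#' k[c(1, 11, 100, 200)]
#' @export
tapered_coupling_profile <- function(n, kappa_max, ramp_len = 10) {
  if (!is.finite(n) || n < 2) stop("'n' must be at least 2", call. = FALSE)
  if (!is.finite(kappa_max) || kappa_max < 0)
    stop("'kappa_max' must be non-negative", call. = FALSE)
  if (ramp_len < 0) stop("'ramp_len' must be non-negative", call. = FALSE)
  if (ramp_len > 0 && n <= 2 * ramp_len)
    stop("ramp too long for this bank: need n > 2 * ramp_len", call. = FALSE)
  k <- rep(kappa_max, n - 1)
  if (ramp_len > 0) {
    ramp <- kappa_max * (0:ramp_len) / ramp_len
    k[1:(ramp_len + 1)] <- ramp
    k[(n - 1):(n - 1 - ramp_len)] <- ramp
  }
  k
}

#' @export
print.reed_bank <- function(x, ...) {
  f <- x$natural_freq_hz
  dir <- if (f[1] > f[x$n]) "descending" else "ascending"
  cat(sprintf("Reed bank: %d oscillators, %.4g-%.4g Hz (%s)\n",
              x$n, min(f), max(f), dir))
  kr <- range(x$coupling)
  kdesc <- if (diff(kr) == 0) sprintf("uniform %.4g", kr[1]) else
    sprintf("%.4g-%.4g (tapered/profile)", kr[1], kr[2])
  cat(sprintf("  coupling kappa: %s (rad/s)^2 per link\n", kdesc))
  cat(sprintf("  damping gamma: %.4g (Q = %.3g)\n", x$gamma,
              if (x$gamma > 0) 1 / x$gamma else Inf))
  driven <- sum(x$forcing_mask > 0)
  cat(sprintf("  forcing: f0 = %.4g on %d of %d reeds\n",
              x$f0, driven, x$n))
  invisible(x)
}

#' @export
summary.reed_bank <- function(object, ...) {
  df <- as.data.frame(object)
  cat(sprintf("Reed bank with %d oscillators\n", object$n))
  print(utils::head(df, 3))
  if (object$n > 3) cat(sprintf("  ... %d more reeds\n", object$n - 3))
  invisible(df)
}

#' @export
as.data.frame.reed_bank <- function(x, ...) {
  data.frame(index = seq_len(x$n),
             natural_freq_hz = x$natural_freq_hz,
             kappa_left = c(NA_real_, x$coupling),
             kappa_right = c(x$coupling, NA_real_),
             forcing_mask = x$forcing_mask)
}

#' @export
plot.reed_bank <- function(x, ...) {
  plot(seq_len(x$n), x$natural_freq_hz, type = "b", pch = 20,
       xlab = "reed index", ylab = "natural frequency (Hz)",
       main = "Reed bank tuning", ...)
  invisible(x)
}

# internal: angular frequencies
omega_j <- function(bank) 2 * pi * bank$natural_freq_hz
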