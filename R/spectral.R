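#' Magnitude spectra of an impulse run
#'
#' Fourier-transforms every reed's impulse response.  The records are
#' transient-complete (the response has decayed essentially to zero by the end
#' of the run), so no taper window is applied; zero-padding by `pad_factor`
#' refines the frequency grid enough to resolve peak spacings at ratios near
#' 1.05, and peak locations are further refined by quadratic interpolation
#' when the spectrum is searched ([find_peaks()], [dominant_frequency_map()]).
#'
#' @param traj an unforced `"reed_trajectory"` from [simulate_impulse()], on a
#'   uniform time grid.
#' @param pad_factor zero-padding factor (FFT length = `pad_factor` times the
#'   record length).
#' @return an object of class `"reed_spectrum"`: ascending `freq_hz` grid
#'   (one-sided, DC to Nyquist), an `n x F` `magnitude` matrix, and provenance
#'   (sampling rate, padding, window).
#' @examples
#' bank <- build_wilson_bank(kappa = 0, gamma = 0.014)
#' spec <- impulse_spectrum(simulate_impulse(bank, 2))
#' @export
impulse_spectrum <- function(traj, pad_factor = 8) {
  stopifnot(inherits(traj, "reed_trajectory"))
  if (!is.null(traj$drive))
    stop("impulse spectra are defined for unforced trajectories", call. = FALSE)
  dt <- diff(traj$time_s)
  if (any(abs(dt - dt[1]) > 1e-9 * dt[1]))
    stop("time grid is not uniform", call. = FALSE)
  if (!is.finite(pad_factor) || pad_factor < 1)
    stop("'pad_factor' must be at least 1", call. = FALSE)
  fs <- 1 / dt[1]
  T_ <- ncol(traj$displacement)
  nfft <- as.integer(round(pad_factor * T_))
  padded <- matrix(0, nfft, nrow(traj$displacement))
  padded[seq_len(T_), ] <- t(traj$displacement)
  ft <- mvfft(padded)
  keep <- seq_len(nfft %/% 2 + 1)          # DC .. Nyquist
  structure(list(freq_hz = (keep - 1) * fs / nfft,
                 magnitude = t(Mod(ft[keep, , drop = FALSE])),
                 natural_freq_hz = traj$bank$natural_freq_hz,
                 provenance = list(fs_hz = fs, pad_factor = pad_factor,
                                   nfft = nfft, record_len = T_,
                                   window = "none")),
            class = "reed_spectrum")
}

#' @export
print.reed_spectrum <- function(x, ...) {
  cat(sprintf("Impulse spectra: %d reeds x %d bins (0-%.5g Hz, step %.4g Hz)\n",
              nrow(x$magnitude), ncol(x$magnitude), max(x$freq_hz),
              x$freq_hz[2] - x$freq_hz[1]))
  invisible(x)
}

#' @export
plot.reed_spectrum <- function(x, reeds = unique(round(seq(1, nrow(x$magnitude),
                                                           length.out = 11))),
                               xlim = NULL, ...) {
  mag <- x$magnitude[reeds, , drop = FALSE]
  matplot(x$freq_hz, t(mag), type = "l", lty = 1, log = "y",
          xlab = "frequency (Hz)", ylab = "magnitude", xlim = xlim, ...)
  invisible(x)
}

#' Dominant frequency of each reed's impulse spectrum
#'
#' Picks, for every oscillator, the frequency of the globally highest peak of
#' its magnitude spectrum (quadratic-interpolated on the dB scale, DC bin
#' excluded).  Uncoupled oscillators each peak at their own natural frequency;
#' coupled banks cluster into runs of oscillators sharing one dominant
#' frequency -- the frequency plateaus.
#'
#' @param spectra a `"reed_spectrum"`.
#' @return an object of class `"plateau_map"`: per-reed `dominant_hz` (`NA`
#'   flags a flat spectrum), the natural-frequency axis and the spectral grid
#'   step.
#' @seealso [plateau_ratios()]
#' @export
dominant_frequency_map <- function(spectra) {
  stopifnot(inherits(spectra, "reed_spectrum"))
  freq <- spectra$freq_hz
  dom <- apply(spectra$magnitude, 1, function(m) {
    m <- m[-1]; f <- freq[-1]               # drop DC
    if (diff(range(m)) == 0) return(NA_real_)
    i <- which.max(m)
    if (i == 1 || i == length(m) || any(m[(i - 1):(i + 1)] <= 0))
      return(f[i])
    quad_vertex(f[(i - 1):(i + 1)], 20 * log10(m[(i - 1):(i + 1)]))[1]
  })
  structure(list(dominant_hz = dom,
                 natural_freq_hz = spectra$natural_freq_hz,
                 grid_step_hz = freq[2] - freq[1],
                 native_res_hz = spectra$provenance$fs_hz /
                   spectra$provenance$record_len),
            class = "plateau_map")
}

#' @export
print.plateau_map <- function(x, ...) {
  cat(sprintf("Dominant-frequency map: %d reeds, %.5g-%.5g Hz\n",
              length(x$dominant_hz), min(x$dominant_hz, na.rm = TRUE),
              max(x$dominant_hz, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.plateau_map <- function(x, ...) {
  plot(x$natural_freq_hz, x$dominant_hz, type = "s",
       xlab = "natural frequency (Hz)", ylab = "dominant frequency (Hz)", ...)
  abline(0, 1, lty = 3)
  invisible(x)
}

#' Ratios between successive frequency plateaus
#'
#' Collapses runs of at least `min_run` adjacent oscillators whose dominant
#' frequencies agree within `tol` into plateau values and returns the ratios
#' between successive plateaus.  A strictly graded map (e.g. the uncoupled
#' case) contains no runs and yields an empty result.
#'
#' Adjacent oscillators count as members of one plateau when their dominant
#' frequencies differ by less than the tolerance.  By default the tolerance is
#' half the *local tonotopic step* (the natural-frequency spacing between the
#' two oscillators): synchronised neighbours in a cluster differ by far less
#' than the gradient would demand, while an unclustered (uncoupled) map steps
#' by exactly the gradient and never merges -- regardless of record length or
#' padding.
#'
#' @param map a `"plateau_map"`.
#' @param min_run minimum run length counting as a plateau (3 avoids
#'   single-oscillator "plateaus").
#' @param tol frequency agreement tolerance in Hz; `NULL` (default) uses half
#'   the local natural-frequency step.
#' @return numeric vector of successive plateau-value ratios (possibly empty).
#' @examples
#' m <- structure(list(dominant_hz = rep(c(1000, 1100), each = 5),
#'                     natural_freq_hz = seq(990, 1110, length.out = 10),
#'                     grid_step_hz = 2, native_res_hz = 20),
#'                class = "plateau_map")
#' plateau_ratios(m)  # 1.1
#' @export
plateau_ratios <- function(map, min_run = 3, tol = NULL) {
  stopifnot(inherits(map, "plateau_map"))
  dom <- map$dominant_hz
  if (any(is.na(dom)))
    stop("dominant-frequency map contains undefined entries", call. = FALSE)
  steps <- abs(diff(map$natural_freq_hz))
  tol_i <- if (is.null(tol)) steps / 2 else rep(tol, length(dom) - 1)
  same <- abs(diff(dom)) <= tol_i
  run_id <- cumsum(c(1L, !same))
  runs <- split(dom, run_id)
  v <- vapply(runs[lengths(runs) >= min_run], mean, 0)
  if (length(v) < 2) return(numeric(0))
  unname(v[-1] / v[-length(v)])
}

#' Amplitude envelope of an oscillatory series
#'
#' Magnitude of the analytic signal (positive-frequency reconstruction via
#' FFT).  Beating between closely spaced spectral components shows up as
#' waxing and waning of this envelope; for a single damped mode the envelope
#' decays as a plain exponential with rate `gamma * w_j / 2`.
#'
#' @param x numeric series (one reed's displacement record), at least a few
#'   cycles long.
#' @return numeric envelope, same length as `x`.
#' @examples
#' t <- seq(0, 1, by = 1e-4)
#' env <- envelope(sin(2 * pi * 100 * t) + sin(2 * pi * 105 * t))
#' @export
envelope <- function(x) {
  n <- length(x)
  if (n < 16)
    stop("series too short for envelope extraction", call. = FALSE)
  h <- rep(0, n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(fft(x) * h, inverse = TRUE) / n)
}
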