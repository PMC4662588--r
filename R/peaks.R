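# Peak detection and derived ripple statistics.
#
# All detection happens on a log-magnitude (dB) scale: the ripples riding on
# the skirt of the main response peak are tiny on a linear scale but regular
# and prominent in dB.

# internal: local maxima of a numeric series y over axis, with topographic
# prominence.  Ties (flat tops) resolve to the lowest axis value.  Returns
# integer indices and prominences in the units of y.
local_maxima <- function(y, min_prominence) {
  m <- length(y)
  idx <- which(vapply(2:(m - 1), function(i)
    is.finite(y[i]) && y[i] > y[i - 1] && y[i] >= y[i + 1], NA)) + 1L
  if (length(idx) == 0)
    return(list(idx = integer(0), prominence = numeric(0)))
  prom <- vapply(idx, function(i) {
    left <- y[seq_len(i - 1)]
    higher <- which(left > y[i])
    lbase <- min(left[seq.int(if (length(higher)) max(higher) else 1, i - 1)],
                 na.rm = TRUE)
    right <- y[seq.int(i + 1, m)]
    higher <- which(right > y[i])
    rbase <- min(right[seq_len(if (length(higher)) min(higher) else m - i)],
                 na.rm = TRUE)
    y[i] - max(lbase, rbase)
  }, 0)
  keep <- prom >= min_prominence
  list(idx = idx[keep], prominence = prom[keep])
}

# internal: vertex of the parabola through three (x, y) points; falls back to
# the middle point when the points are collinear or the curvature is wrong
quad_vertex <- function(x, y) {
  A <- cbind(1, x, x^2)
  cf <- solve(A, y)
  if (!is.finite(cf[3]) || cf[3] >= 0)
    return(c(x[2], y[2]))
  h <- -cf[2] / (2 * cf[3])
  if (h < min(x) || h > max(x)) return(c(x[2], y[2]))
  c(h, cf[1] + cf[2] * h + cf[3] * h^2)
}

#' Detect peaks in a magnitude series
#'
#' Local maxima of `20*log10(series)` with topographic prominence of at least
#' `min_prominence_db`, located along `axis` (a frequency grid or the reeds'
#' natural-frequency axis).  Peak positions and heights are refined by local
#' quadratic interpolation through the three dB samples around each maximum.
#' Ties on flat tops resolve toward the lower axis value.
#'
#' @param series non-negative magnitudes (linear units).
#' @param axis ascending axis values, same length as `series`.
#' @param min_prominence_db prominence threshold in dB (default 1 dB).
#' @return an object of classes `"peak_set"` and `"data.frame"` with columns
#'   `location` (axis units), `height` (linear units) and `prominence_db`,
#'   ordered by location.  An all-zero series yields an empty peak set.
#' @examples
#' x <- seq(0, 10, by = 0.01)
#' s <- exp(-(x - 3)^2) + 0.5 * exp(-(x - 7)^2 / 0.5)
#' find_peaks(s, x)
#' @export
find_peaks <- function(series, axis = seq_along(series),
                       min_prominence_db = 1.0) {
  if (length(series) < 3)
    stop("'series' must have at least 3 points", call. = FALSE)
  if (length(axis) != length(series) || is.unsorted(axis, strictly = TRUE))
    stop("'axis' must be strictly ascending and match 'series'", call. = FALSE)
  if (any(!is.finite(series)) || any(series < 0))
    stop("'series' must be finite and non-negative", call. = FALSE)
  empty <- data.frame(location = numeric(0), height = numeric(0),
                      prominence_db = numeric(0))
  class(empty) <- c("peak_set", "data.frame")
  if (all(series == 0)) return(empty)
  db <- ifelse(series > 0, 20 * log10(series), -Inf)
  found <- local_maxima(db, min_prominence_db)
  if (length(found$idx) == 0) return(empty)
  ref <- t(vapply(found$idx, function(i) {
    if (is.finite(db[i - 1]) && is.finite(db[i + 1]))
      quad_vertex(axis[(i - 1):(i + 1)], db[(i - 1):(i + 1)])
    else c(axis[i], db[i])
  }, c(0, 0)))
  out <- data.frame(location = ref[, 1],
                    height = 10^(ref[, 2] / 20),
                    prominence_db = found$prominence)
  out <- out[order(out$location), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_set", "data.frame")
  out
}

# internal: amplitude minima = maxima of the negated dB series
find_minima <- function(series, axis = seq_along(series),
                        min_prominence_db = 1.0) {
  db <- ifelse(series > 0, 20 * log10(series), -Inf)
  found <- local_maxima(-db, min_prominence_db)
  if (length(found$idx) == 0)
    return(data.frame(location = numeric(0), prominence_db = numeric(0)))
  loc <- vapply(found$idx, function(i) {
    if (is.finite(db[i - 1]) && is.finite(db[i + 1]))
      quad_vertex(axis[(i - 1):(i + 1)], -db[(i - 1):(i + 1)])[1]
    else axis[i]
  }, 0)
  data.frame(location = sort(loc), prominence_db = found$prominence)
}

#' Successive peak-location ratios
#'
#' @param peaks a `"peak_set"` from [find_peaks()] (or any data frame with a
#'   `location` column ordered ascending).
#' @return numeric vector of successive ratios, each greater than 1; empty if
#'   fewer than two peaks.
#' @examples
#' peak_ratios(data.frame(location = c(1750, 1855, 1911)))
#' @export
peak_ratios <- function(peaks) {
  loc <- peaks$location
  if (length(loc) < 2) return(numeric(0))
  loc[-1] / loc[-length(loc)]
}

#' Attenuation slopes around a singly driven reed
#'
#' When only one reed is driven, the response decays on both sides; the decay
#' rate measures how strongly vibration is attenuated as it propagates along
#' the chain.  On each side of the driven reed the responses falling between
#' `fit_range_db[1]` and `fit_range_db[2]` dB below the peak are fitted by
#' least squares as `20*log10(amplitude)` versus `log2(natural frequency)`,
#' and the slope magnitude is returned in dB/octave.  The fit window stops at
#' the first reed dropping below the lower bound, so ripples further out do
#' not re-enter the fit.
#'
#' @param response a `"reed_response"` from [single_reed_drive()].
#' @param driven_reed index of the driven reed; defaults to the
#'   `driven_reed` attribute of `response`.
#' @param fit_range_db two dB values (below the peak) bounding the fit region.
#' @return named numeric vector `c(low_side = ..., high_side = ...)` in
#'   dB/octave (low natural-frequency side first).
#' @examples
#' bank <- build_greenwood_bank(kappa = 200)
#' j <- which.min(abs(bank$natural_freq_hz - 1750))
#' attenuation_slopes(single_reed_drive(bank, j, 1750))
#' @export
attenuation_slopes <- function(response, driven_reed = attr(response, "driven_reed"),
                               fit_range_db = c(3, 23)) {
  stopifnot(inherits(response, "reed_response"))
  if (is.null(driven_reed))
    stop("'response' does not record a driven reed; pass 'driven_reed'",
         call. = FALSE)
  n <- length(response$phasor)
  if (driven_reed <= 1 || driven_reed >= n)
    stop("driven reed must be interior to the array", call. = FALSE)
  f <- response$bank$natural_freq_hz
  db <- 20 * log10(Mod(response$phasor))
  rel <- db[driven_reed] - db          # dB below the peak, positive outward

  fit_side <- function(ord) {
    below <- rel[ord]
    start <- which(below >= fit_range_db[1])
    if (length(start) == 0)
      stop("no reeds fall below the upper fit bound on one side",
           call. = FALSE)
    start <- start[1]
    stop_at <- which(below > fit_range_db[2])
    stop_at <- if (length(stop_at)) stop_at[1] - 1 else length(ord)
    sel <- ord[seq.int(start, stop_at)]
    sel <- sel[rel[sel] >= fit_range_db[1] & rel[sel] <= fit_range_db[2]]
    if (length(sel) < 3)
      stop("fewer than 3 reeds in the attenuation fit window", call. = FALSE)
    abs(unname(coef(lm(db[sel] ~ log2(f[sel])))[2]))
  }

  c(low_side = fit_side(seq.int(driven_reed - 1, 1)),
    high_side = fit_side(seq.int(driven_reed + 1, n)))
}

#' Periodicity of the phase/amplitude bands along the array
#'
#' Coupled banks under parallel forcing develop regular bands along the array:
#' amplitude minima accompanied by rapid phase transitions.  This measures
#' their spatial periodicity in natural-frequency units, as the mean spacing
#' between successive amplitude minima on the low-natural-frequency side of
#' the main peak (amplitude minima are used rather than the phase derivative
#' because the two coincide and the minima are numerically robust).
#'
#' The band spacing shrinks roughly geometrically with distance from the peak
#' (successive ripple ratios of about 1.03), so a mean over *every* minimum in
#' the array depends on how far the array happens to extend.  The default
#' therefore measures the period where the bands are fully developed: the
#' spacing(s) between the `n_bands + 1` minima nearest the main peak
#' (`n_bands = 1` gives the single spacing adjacent to the peak, the
#' extent-independent choice).  Set `n_bands = Inf` for the whole-array mean.
#'
#' @param profile a `"steady_state_profile"`.
#' @param n_bands how many inter-minima spacings, counted from the main peak
#'   outward, enter the mean; `Inf` averages over all detected minima.
#' @param min_prominence_db prominence threshold for minima detection, in dB.
#' @return mean spacing between successive minima, in Hz of natural frequency.
#' @examples
#' bank <- build_greenwood_bank(kappa = 200)
#' prof <- steady_state_profile(solve_phasors(bank, 1750))
#' phase_band_period(prof)  # about 60 Hz
#' @export
phase_band_period <- function(profile, n_bands = 1, min_prominence_db = 1.0) {
  stopifnot(inherits(profile, "steady_state_profile"))
  f <- profile$natural_freq_hz
  amp <- profile$amplitude
  ord <- order(f)
  f <- f[ord]; amp <- amp[ord]
  pk <- which.max(amp)
  if (pk < 5)
    stop("main peak too close to the low-frequency end", call. = FALSE)
  side <- seq_len(pk)
  mins <- find_minima(amp[side], f[side], min_prominence_db)
  if (nrow(mins) < 2)
    stop("fewer than 2 amplitude minima on the low-frequency side",
         call. = FALSE)
  gaps <- diff(mins$location)            # ascending: last gap is nearest peak
  mean(tail(gaps, min(n_bands, length(gaps))))
}
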