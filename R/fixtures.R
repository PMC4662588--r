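#' Random small reed bank for property tests
#'
#' Draws a reproducible random bank: a uniform random oscillator count, a
#' monotone natural-frequency profile (random direction), one uniform random
#' coupling constant and damping ratio.  Intended for property-style tests;
#' the RNG state of the caller is left untouched.
#'
#' @param seed integer seed; the same seed always yields the same bank.
#' @param n_range integer range for the number of oscillators.
#' @param f_range natural-frequency range in Hz.
#' @param kappa_range coupling range.
#' @param gamma_range damping range.
#' @return a [reed_bank()].
#' @examples
#' identical(generate_fixture_bank(1), generate_fixture_bank(1))
#' @export
generate_fixture_bank <- function(seed, n_range = c(3, 12),
                                  f_range = c(40, 60),
                                  kappa_range = c(0, 5000),
                                  gamma_range = c(0.005, 0.05)) {
  if (n_range[1] < 2 || n_range[2] < n_range[1])
    stop("degenerate 'n_range'", call. = FALSE)
  if (f_range[2] <= f_range[1] || f_range[1] <= 0)
    stop("degenerate 'f_range'", call. = FALSE)
  if (kappa_range[2] < kappa_range[1] || kappa_range[1] < 0)
    stop("degenerate 'kappa_range'", call. = FALSE)
  if (gamma_range[2] < gamma_range[1] || gamma_range[1] < 0)
    stop("degenerate 'gamma_range'", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ns <- seq.int(n_range[1], n_range[2])
  n <- ns[sample.int(length(ns), 1)]
  f <- sort(stats::runif(n, f_range[1], f_range[2]))
  if (stats::runif(1) < 0.5) f <- rev(f)
  reed_bank(f,
            gamma = stats::runif(1, gamma_range[1], gamma_range[2]),
            coupling = stats::runif(1, kappa_range[1], kappa_range[2]))
}
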