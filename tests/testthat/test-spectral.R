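# helper: wrap a bare matrix of records as an unforced trajectory
as_impulse_traj <- function(x, fs_hz, f_natural) {
  structure(list(time_s = (seq_len(ncol(x)) - 1) / fs_hz,
                 displacement = x, velocity = 0 * x,
                 bank = reed_bank(f_natural, gamma = 0.01, coupling = 0),
                 drive = NULL),
            class = "reed_trajectory")
}

test_that("a pure tone lands on its frequency within grid resolution", {
  fs <- 40000
  tt <- seq(0, 0.1, by = 1 / fs)
  x <- rbind(sin(2 * pi * 1000 * tt), sin(2 * pi * 1234.5 * tt))
  spec <- impulse_spectrum(as_impulse_traj(x, fs, c(1000, 1234.5)),
                           pad_factor = 8)
  res <- spec$freq_hz[2] - spec$freq_hz[1]
  for (j in 1:2) {
    pk <- spec$freq_hz[-1][which.max(spec$magnitude[j, -1])]
    expect_equal(pk, c(1000, 1234.5)[j], tolerance = res / 1000)
  }
})

test_that("uncoupled impulse spectrum is a resonance line of width gamma*f", {
  gamma <- 0.02
  bank <- reed_bank(c(50, 40), gamma = gamma, coupling = 0)
  spec <- impulse_spectrum(simulate_impulse(bank, 8, samples_per_cycle = 40))
  m <- spec$magnitude[1, ]
  pk <- which.max(m)
  expect_equal(spec$freq_hz[pk], 50 * sqrt(1 - gamma^2 / 4), tolerance = 2e-3)
  half <- m[pk] / sqrt(2)
  lo <- spec$freq_hz[max(which(m[1:pk] < half))]
  hi <- spec$freq_hz[pk + min(which(m[(pk + 1):length(m)] < half))]
  expect_equal(hi - lo, gamma * 50, tolerance = 0.1)
})

test_that("spectral energy matches time-domain energy (Parseval)", {
  bank <- generate_fixture_bank(17)
  traj <- simulate_impulse(bank, 2)
  spec <- impulse_spectrum(traj, pad_factor = 1)
  nfft <- spec$provenance$nfft
  for (j in c(1, bank$n)) {
    e_time <- sum(traj$displacement[j, ]^2)
    mag <- spec$magnitude[j, ]
    k <- length(mag)
    nyq <- if (nfft %% 2 == 0) mag[k]^2 else 0
    interior <- if (nfft %% 2 == 0) mag[2:(k - 1)] else mag[2:k]
    e_spec <- (mag[1]^2 + 2 * sum(interior^2) + nyq) / nfft
    expect_equal(e_spec / e_time, 1, tolerance = 0.01)
  }
})

test_that("impulse spectra demand unforced uniform-grid trajectories", {
  bank <- build_wilson_bank(0, 0.014)
  forced <- simulate_forced(bank, drive_spec(50, 0.2))
  expect_error(impulse_spectrum(forced), "unforced")
  traj <- simulate_impulse(bank, 0.2)
  traj$time_s <- traj$time_s^1.01
  expect_error(impulse_spectrum(traj), "uniform")
})

test_that("coupled kilohertz impulse spectra carry peak trains near ratio 1.05", {
  bank <- build_greenwood_bank(200)
  spec <- impulse_spectrum(simulate_impulse(bank, 0.05))
  sel <- spec$freq_hz >= 1000 & spec$freq_hz <= 3000
  pk <- find_peaks(spec$magnitude[101, sel], spec$freq_hz[sel])
  expect_gt(nrow(pk), 2)
  r <- peak_ratios(pk)
  expect_equal(r[1], 1.05, tolerance = 0.01)
  expect_true(all(r[-1] < r[1]))   # subsequent spacings are tighter
  # lower-frequency reeds wax and wane: beating envelopes are non-monotone
  env <- envelope(traj_row <- simulate_impulse(bank, 0.02)$displacement[30, ])
  core <- env[seq(0.2 * length(env), 0.9 * length(env))]
  expect_gt(nrow(find_peaks(core, min_prominence_db = 1)), 1)
})

test_that("dominant-frequency map follows natural frequencies when uncoupled", {
  bank <- build_linear_bank(1000, 2000, 201, 0, 0.025)
  map <- dominant_frequency_map(impulse_spectrum(simulate_impulse(bank, 0.05)))
  expect_equal(map$dominant_hz,
               bank$natural_freq_hz * sqrt(1 - 0.025^2 / 4), tolerance = 1e-3)
  # strictly graded: no plateaus at all
  expect_length(plateau_ratios(map), 0)
})

test_that("two identical uncoupled oscillators share a dominant frequency", {
  fs <- 8000
  tt <- seq(0, 0.5, by = 1 / fs)
  x <- exp(-20 * tt) * sin(2 * pi * 200 * tt)
  map <- dominant_frequency_map(
    impulse_spectrum(as_impulse_traj(rbind(x, x), fs, c(200, 200))))
  expect_equal(map$dominant_hz[1], map$dominant_hz[2])
})

test_that("plateau collapsing handles staircases, single plateaus and gaps", {
  mk <- function(dom) structure(
    list(dominant_hz = dom,
         natural_freq_hz = seq_along(dom),
         grid_step_hz = 1, native_res_hz = 4),
    class = "plateau_map")
  expect_equal(plateau_ratios(mk(rep(c(1000, 1100), each = 5))), 1.1)
  expect_length(plateau_ratios(mk(rep(1000, 9))), 0)
  expect_length(plateau_ratios(mk(seq(1000, 1400, by = 10))), 0)
  # runs shorter than min_run do not count
  expect_length(plateau_ratios(mk(c(rep(1000, 5), 1100, 1100, rep(1200, 5)))),
                1)
  expect_error(plateau_ratios(mk(c(1000, NA, 1100))), "undefined")
})

test_that("envelope captures beats and exponential decay", {
  fs <- 10000
  tt <- seq(0, 1, by = 1 / fs)
  f0 <- 100
  beat <- sin(2 * pi * f0 * tt) + sin(2 * pi * 1.05 * f0 * tt)
  env <- envelope(beat)
  pk <- find_peaks(env[100:(length(env) - 100)], tt[100:(length(env) - 100)],
                   min_prominence_db = 3)
  expect_equal(mean(diff(pk$location)), 1 / (0.05 * f0), tolerance = 0.01)

  dec <- exp(-3 * tt) * sin(2 * pi * 50 * tt)
  env2 <- envelope(dec)
  mid <- seq(1000, 8000)
  fit <- coef(lm(log(env2[mid]) ~ tt[mid]))
  expect_equal(unname(fit[2]), -3, tolerance = 0.01)

  expect_error(envelope(1:5), "short")
})
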