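test_that("Wilson bank reproduces the historical 21-reed configuration", {
  bank <- build_wilson_bank(kappa = 2500, gamma = 0.014)
  expect_s3_class(bank, "reed_bank")
  expect_equal(bank$n, 21)
  expect_equal(bank$natural_freq_hz[1], 55)
  expect_equal(bank$natural_freq_hz[21], 45)
  expect_equal(diff(bank$natural_freq_hz), rep(-0.5, 20))
  expect_equal(bank$coupling, rep(2500, 20))
  expect_equal(bank$f0, 1000)
  expect_equal(bank$forcing_mask, rep(1, 21))
  expect_equal(bank$gamma, 0.014)

  uncoupled <- build_wilson_bank(kappa = 0, gamma = 0.014)
  expect_equal(uncoupled$coupling, rep(0, 20))

  auto <- build_wilson_bank(kappa = 4600)
  expect_equal(auto$gamma, gamma_for_kappa(4600))
  expect_equal(round(auto$gamma, 3), 0.021)
})

test_that("damping calibration is the published affine rule", {
  expect_equal(gamma_for_kappa(0), 0.00553)
  expect_equal(round(gamma_for_kappa(150), 3), 0.006)
  expect_equal(round(gamma_for_kappa(2200), 3), 0.013)
  expect_equal(round(gamma_for_kappa(4600), 3), 0.021)
  # affinity: g(k1) + g(k2) - g(0) == g(k1 + k2)
  for (k in list(c(0, 0), c(150, 4450), c(17.5, 2500), c(1234.5, 3333))) {
    expect_equal(gamma_for_kappa(k[1]) + gamma_for_kappa(k[2]) -
                   gamma_for_kappa(0),
                 gamma_for_kappa(k[1] + k[2]), tolerance = 1e-12)
  }
  expect_error(gamma_for_kappa(-1), "non-negative")
})

test_that("Greenwood map matches its closed form and is strictly increasing", {
  # F = 165.4 * (10^(0.06 x) - 0.88), evaluated by hand at the endpoints
  expect_equal(greenwood_frequency(16.5), 165.4 * (10^0.99 - 0.88))
  expect_equal(greenwood_frequency(16.5), 1470.80, tolerance = 1e-4)
  expect_equal(greenwood_frequency(18.5), 1985.21, tolerance = 1e-4)
  # degenerate map: k = 0 collapses to the pure exponential
  expect_equal(greenwood_frequency(0, greenwood_params(k = 0)), 165.4)
  x <- seq(0, 30, by = 0.1)
  expect_true(all(diff(greenwood_frequency(x)) > 0))
  expect_error(greenwood_frequency(-40), "non-positive")
  expect_error(greenwood_params(A = -1), "A > 0")
})

test_that("Greenwood bank spans 1.5-2 kHz in near-uniform 2.5 Hz steps", {
  bank <- build_greenwood_bank(kappa = 200)
  expect_equal(bank$n, 201)
  f <- bank$natural_freq_hz
  expect_true(f[1] > 1400 && f[1] < 1600)
  expect_true(f[201] > 1900 && f[201] < 2100)
  expect_true(all(diff(f) > 0))
  expect_equal(mean(diff(f)), 2.5, tolerance = 0.1)
  # near-linearity: every increment within 15% of the mean step (the
  # exponential map stretches the steps by about a third across the 2 mm span)
  expect_lt(max(abs(diff(f) / mean(diff(f)) - 1)), 0.15)
  expect_equal(bank$gamma, 0.025)
  expect_equal(1 / bank$gamma, 40)
  expect_error(build_greenwood_bank(200, x_start = 17, x_end = 17), "exceed")
})

test_that("kilohertz-bank coupling follows the millisecond unit convention", {
  expect_equal(build_greenwood_bank(kappa = 200)$coupling[1], 2e8)
  expect_equal(build_greenwood_bank(kappa = 2e8,
                                    kappa_unit = "rad2_per_s2")$coupling[1],
               2e8)
  expect_equal(build_linear_bank(1000, 2000, 201, 1000, 0.025)$coupling[1],
               1e9)
})

test_that("linear bank hits both endpoints with exact spacing", {
  bank <- build_linear_bank(1000, 2000, 201, 1000, 0.025)
  expect_equal(bank$n, 201)
  expect_equal(diff(bank$natural_freq_hz), rep(5, 200))
  expect_equal(range(bank$natural_freq_hz), c(1000, 2000))

  two <- build_linear_bank(45, 55, 2, 0, 0.014, kappa_unit = "rad2_per_s2")
  expect_equal(two$natural_freq_hz, c(45, 55))

  wil <- build_linear_bank(45, 55, 21, 2500, 0.014,
                           kappa_unit = "rad2_per_s2")
  expect_equal(rev(wil$natural_freq_hz),
               build_wilson_bank(2500, 0.014)$natural_freq_hz)
})

test_that("tapered coupling profile ramps linearly and mirrors at both ends", {
  k <- tapered_coupling_profile(201, 200, ramp_len = 10)
  expect_length(k, 200)
  expect_equal(k[1], 0)
  expect_equal(k[11], 200)
  expect_equal(k[100], 200)
  expect_equal(k[200], 0)
  expect_equal(k[1:11], seq(0, 200, by = 20))
  expect_equal(k[200:190], seq(0, 200, by = 20))

  expect_equal(tapered_coupling_profile(21, 150, ramp_len = 0), rep(150, 20))
  expect_equal(tapered_coupling_profile(201, 0), rep(0, 200))
  expect_error(tapered_coupling_profile(15, 100, ramp_len = 10), "ramp")
})

test_that("bank construction enforces the physical invariants", {
  expect_error(reed_bank(50, gamma = 0.01, coupling = numeric(0)),
               "at least 2")
  expect_error(reed_bank(c(50, -45), gamma = 0.01, coupling = 0), "positive")
  expect_error(reed_bank(c(50, 45), gamma = -0.1, coupling = 0),
               "non-negative")
  expect_error(reed_bank(c(50, 45), gamma = 0.01, coupling = c(1, 2)),
               "n - 1")
  expect_error(reed_bank(c(50, 45), gamma = 0.01, coupling = -5),
               "non-negative")
  expect_error(reed_bank(c(50, 45), gamma = 0.01, coupling = 0,
                         forcing_mask = c(0.5, 1.5)), "\\[0, 1\\]")
  expect_error(build_wilson_bank(-10), "non-negative")
  # fixture generator output always passes the same validation
  for (s in 1:20) expect_s3_class(generate_fixture_bank(s), "reed_bank")
})

test_that("fixture banks are reproducible and seed-sensitive", {
  expect_identical(generate_fixture_bank(1), generate_fixture_bank(1))
  expect_false(identical(generate_fixture_bank(1), generate_fixture_bank(2)))
  b <- generate_fixture_bank(7, f_range = c(40, 60), kappa_range = c(0, 0))
  expect_true(all(b$coupling == 0))
  expect_true(all(b$natural_freq_hz >= 40 & b$natural_freq_hz <= 60))
  expect_error(generate_fixture_bank(1, n_range = c(5, 3)), "degenerate")
})

test_that("bank config round-trips through YAML and exports to CSV", {
  bank <- build_greenwood_bank(kappa = 200)
  bank$coupling <- tapered_coupling_profile(201, 2e8)
  path <- tempfile(fileext = ".yaml")
  write_bank_config(bank, path)
  back <- read_bank_config(path)
  expect_equal(back$natural_freq_hz, bank$natural_freq_hz)
  expect_equal(back$coupling, bank$coupling)
  expect_equal(back$gamma, bank$gamma)

  csv <- tempfile(fileext = ".csv")
  write_result_csv(bank, csv, meta = list(kind = "bank"))
  df <- read.csv(csv)
  expect_equal(nrow(df), 201)
  expect_equal(df$kappa_right[1], bank$coupling[1])
  expect_true(is.na(df$kappa_left[1]))
  expect_true(file.exists(paste0(csv, ".json")))
})
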