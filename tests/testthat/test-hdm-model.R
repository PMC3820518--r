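bank <- tuning_bank()

test_that("spectral response is Gaussian tuning scaled by loudness", {
  nu17 <- bank$preferred_log_frequencies[17]
  L <- 2.3
  r <- spectral_response(nu17, L, bank)
  expect_equal(r[17], L, tolerance = 1e-12)       # tuning factor 1 at preference
  expect_equal(which.max(r), 17L)
  expect_equal(spectral_response(nu17, 0, bank), rep(0, 50))
  ## symmetry: input equidistant from two preferred frequencies
  mid <- mean(bank$preferred_log_frequencies[25:26])
  r <- spectral_response(mid, 1, bank)
  expect_equal(r[25], r[26], tolerance = 1e-12)
  expect_true(all(spectral_response(6.9, 1.5, bank) >= 0))
  expect_error(spectral_response(Inf, 1, bank), "non-finite")
})

test_that("channel tuning integrates to a loudness-proportional Gaussian area", {
  L <- 1.7
  sw <- bank$tuning_width
  for (i in c(1, 25, 50)) {
    area <- stats::integrate(function(nu)
      sapply(nu, function(n) spectral_response(n, L, bank)[i]),
      lower = bank$preferred_log_frequencies[i] - 8 * sw,
      upper = bank$preferred_log_frequencies[i] + 8 * sw,
      rel.tol = 1e-9)$value
    expect_equal(area, L * sw * sqrt(2 * pi), tolerance = 1e-6)
  }
})

test_that("hidden-state flow has the stated fixed points", {
  model <- auditory_hdm()
  ## frequency at its target: no frequency flow
  f <- hdm_flow(c(0.4, -0.1, 7.1), c(0.5, 7.1), model)
  expect_equal(f[3], 0, tolerance = 1e-12)
  ## origin is the attractor of the undriven loudness subsystem
  f <- hdm_flow(c(0, 0, 6.9), c(0, 7.0), model)
  expect_equal(f[1:2], c(0, 0), tolerance = 1e-12)
  ## frequency relaxes at rate kappa
  f <- hdm_flow(c(0, 0, 6.9), c(0, 7.0), model)
  expect_equal(hdm_flow(c(0, 0, 6.8), c(0, 7.0), model)[3],
               model$kappa_freq * 0.2, tolerance = 1e-12)
})

test_that("loudness subsystem spirals to zero and decays below 1% within 48 units", {
  model <- auditory_hdm()
  ev <- eigen(model$loudness_matrix)$values
  expect_true(all(Re(ev) < 0))
  expect_true(all(abs(Im(ev)) > 0))
  ## closed-form impulse response of the damped oscillator (independent of
  ## hdm_flow): x_l(t) = (omega^2 / omega_d) exp(-zeta omega t) sin(omega_d t)
  omega <- mmn_config()$dynamics$omega
  zeta <- mmn_config()$dynamics$zeta
  omega_d <- omega * sqrt(1 - zeta^2)
  xl <- function(t) (omega^2 / omega_d) * exp(-zeta * omega * t) * sin(omega_d * t)
  t <- seq(0, 200, by = 0.01)
  peak <- max(abs(xl(t)))
  expect_true(all(abs(xl(t[t >= 48])) < 0.01 * peak))
  ## and hdm_flow integrates to the same trajectory (fine Euler cross-check)
  x <- c(0, omega^2); h <- 0.001
  for (i in seq_len(10000)) x <- x + h * (model$loudness_matrix %*% x)[, 1]
  expect_equal(x[1], xl(10), tolerance = 1e-2)
})

test_that("prior precision is strictly decreasing and matches its mapping", {
  p <- c(0.01, 0.05, 0.1, 0.3, 0.6, 0.9, 0.99)
  prec <- prior_precision_from_probability(p)
  expect_true(all(diff(prec) < 0))
  expect_true(all(prec > 0 & is.finite(prec)))
  ## independent recomputation of the documented mapping at p = 0.05
  expect_equal(prior_precision_from_probability(0.05),
               0.5 + 1.5 * log(1 / 0.05), tolerance = 1e-12)
  ## approaches the floor as p -> 1
  expect_equal(prior_precision_from_probability(1 - 1e-12), 0.5,
               tolerance = 1e-9)
  expect_error(prior_precision_from_probability(0), "strictly inside")
  expect_error(prior_precision_from_probability(1), "strictly inside")
})

test_that("sensory prediction composes loudness read-out with the tuning bank", {
  model <- auditory_hdm()
  expect_equal(generate_observation(c(0, 0.5, 7.0), model), rep(0, 50))
  x <- c(0.8, -0.2, 6.95)
  expect_equal(generate_observation(x, model),
               spectral_response(6.95, 0.8, model$tuning), tolerance = 1e-12)
  expect_true(all(is.finite(generate_observation(c(1e3, -1e3, 20), model))))
})

test_that("model construction enforces the spiral-decay and rate invariants", {
  expect_error(auditory_hdm(config = list(dynamics = list(zeta = 1.5))),
               "spiral")
  expect_error(auditory_hdm(config = list(dynamics = list(kappa_freq = -1))))
  expect_error(oddball_condition(deviant_probability = 0), "")
})

test_that("configuration round-trips through YAML", {
  cf <- mmn_config()
  cf$dynamics$kappa_freq <- 0.33
  path <- tempfile(fileext = ".yaml")
  write_mmn_config(cf, path)
  cf2 <- read_mmn_config(path)
  expect_equal(cf2$dynamics$kappa_freq, 0.33)
  expect_equal(cf2$erp$lead_field, cf$erp$lead_field)
  expect_equal(cf2$tuning$sigma_tune, cf$tuning$sigma_tune)
})
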