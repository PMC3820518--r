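## tiny error trajectory for forward-model tests
toy_errors <- function(n = 64, dt = 1) {
  structure(list(times = (seq_len(n) - 1) * dt,
                 xi_sensory = matrix(0.1, n, 5),
                 xi_states = matrix(-0.2, n, 3),
                 xi_causes = matrix(0.3, n, 2),
                 native_dt = dt),
            class = "error_trajectory")
}

test_that("the time warp is the stated affine map and composes affinely", {
  err <- toy_errors()
  id <- observation_params(conduction_shift_ms = 0, time_scale = 1)
  w <- timewarp(err, id, onset_native = 0)
  expect_equal(w$times, err$times)
  expect_identical(w$xi_sensory, err$xi_sensory)   # values unchanged
  ## native duration D maps onto 70 ms: scale = 70 / D per native unit
  env <- mmn_config()$envelope
  D <- 2 * sqrt(2 * log(2)) * env$sd
  p <- observation_params()
  expect_equal(p$time_scale, 70 / D, tolerance = 1e-12)
  w2 <- timewarp(err, p, onset_native = 10)
  expect_equal(w2$times, p$conduction_shift_ms + p$time_scale * (err$times - 10))
  ## two successive warps equal the composed affine warp
  pa <- observation_params(conduction_shift_ms = 3, time_scale = 2)
  pb <- observation_params(conduction_shift_ms = -1, time_scale = 0.5)
  wa <- timewarp(err, pa, onset_native = 4)
  wab <- timewarp(wa, pb, onset_native = 1)
  composed <- -1 + 0.5 * ((3 + 2 * (err$times - 4)) - 1)
  expect_equal(wab$times, composed, tolerance = 1e-12)
})

test_that("source LFP is a summed logistic with the stated limits", {
  n <- 20; k <- 7
  xi0 <- matrix(0, n, k)
  expect_equal(source_lfp(xi0, 1.3), rep(k / 2, n))
  ## saturation
  expect_equal(source_lfp(matrix(1e3, n, k), 5), rep(k, n), tolerance = 1e-10)
  ## near-linear regime: LFP ~ k/2 + (lambda/4) * sum(xi)
  lam <- 0.7
  xi <- matrix(stats::rnorm(n * k, sd = 1e-3), n, k)
  approx_lfp <- k / 2 + (lam / 4) * rowSums(xi)
  expect_equal(source_lfp(xi, lam), approx_lfp, tolerance = 1e-7)
  expect_error(source_lfp(xi, -1), "slope")
})

test_that("scalp potential is the lead-field superposition plus offset", {
  lfps <- cbind(sin(1:30), cos(1:30), (1:30) / 30)
  p0 <- observation_params(lead_field = c(0, 0, 0), offset = 1.25)
  expect_equal(scalp_potential(lfps, p0), rep(1.25, 30))
  p <- observation_params(lead_field = c(2, -1, 0.5), offset = 0.3)
  manual <- 2 * lfps[, 1] - 1 * lfps[, 2] + 0.5 * lfps[, 3] + 0.3
  expect_equal(scalp_potential(lfps, p), manual, tolerance = 1e-12)
  ## doubling the lead field doubles the deflection about the offset
  p2 <- observation_params(lead_field = c(4, -2, 1), offset = 0.3)
  expect_equal(scalp_potential(lfps, p2) - 0.3, 2 * (scalp_potential(lfps, p) - 0.3),
               tolerance = 1e-12)
})

test_that("post-processing passes DC, attenuates 40 Hz by 3 dB and crushes 80 Hz", {
  tt <- seq(0, 1000, by = 1)    # 1 kHz sampling, ms axis
  dc <- postprocess(erp_waveform(tt, rep(2.5, length(tt))))
  expect_equal(range(dc$filtered$voltages), c(2.5, 2.5), tolerance = 1e-9)
  expect_equal(dc$filtered$sampling_rate, 200)
  amp_at <- function(f_hz) {
    out <- postprocess(erp_waveform(tt, sin(2 * pi * f_hz * tt / 1000)))
    sel <- out$filtered$times >= 300 & out$filtered$times <= 900
    ts <- out$filtered$times[sel] / 1000
    fit <- stats::lm(out$filtered$voltages[sel] ~ sin(2 * pi * f_hz * ts) +
                       cos(2 * pi * f_hz * ts))
    sqrt(sum(stats::coef(fit)[2:3]^2))
  }
  expect_lt(abs(amp_at(40) - 10^(-3 / 20)), 0.05 * 10^(-3 / 20))
  expect_lt(amp_at(80), 10^(-18 / 20))
  expect_error(postprocess(erp_waveform(seq(0, 100, by = 5), rnorm(21))),
               "400")
})

test_that("the forward map is deterministic and unit-order invariant", {
  err <- toy_errors(128)
  err$xi_sensory <- matrix(stats::rnorm(128 * 5, sd = 0.5), 128, 5)
  p <- observation_params()
  a <- erp_forward(err, p, onset_native = 30)
  b <- erp_forward(err, p, onset_native = 30)
  expect_identical(a$filtered$voltages, b$filtered$voltages)
  ## permuting units within a source leaves the waveform unchanged
  err_perm <- err
  err_perm$xi_sensory <- err$xi_sensory[, c(3, 1, 5, 2, 4)]
  c_ <- erp_forward(err_perm, p, onset_native = 30)
  expect_equal(a$filtered$voltages, c_$filtered$voltages, tolerance = 1e-12)
})

test_that("waveforms round-trip through delimited text", {
  w <- erp_waveform(seq(0, 100, by = 5), sin(seq(0, 100, by = 5) / 10))
  path <- tempfile(fileext = ".tsv")
  write_waveform(w, path)
  w2 <- read_waveform(path)
  expect_equal(w2$times, w$times)
  expect_equal(w2$voltages, w$voltages, tolerance = 1e-12)
  expect_equal(w2$sampling_rate, w$sampling_rate)
})
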