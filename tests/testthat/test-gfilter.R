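## small static model: one cause observed directly, no hidden states
static_model <- function(py = 3, pv = 2, eta = 1.5, order = 2L, dt = 0.5) {
  gf_model(g = function(x, v) v, gx = function(x, v) matrix(0, 1, 0),
           gv = function(x, v) matrix(1, 1, 1),
           n_x = 0L, n_v = 1L, n_y = 1L, Pi_y = py, Pi_v = pv,
           eta = function(t) matrix(c(eta, 0, 0), order + 1L, 1),
           order_states = order, order_causes = order, smoothness = 2, dt = dt)
}
const_data <- function(y, order = 2L)
  generalized_vector(matrix(c(y, rep(0, order)), order + 1L, 1))
belief_pack_test <- function(b) c(b$mu_x, b$mu_v)

test_that("prediction errors match a hand-computed 1-D linear example", {
  ## g = 2x, f = -x + v, embedding order 1, smoothness 1 (identity derivative
  ## correlations), Pi_y = 2, Pi_x = 3, Pi_v = 1.5; all expected values below
  ## were computed by hand from the definitions.
  gfm <- gf_model(g = function(x, v) 2 * x, gx = function(x, v) matrix(2, 1, 1),
                  gv = function(x, v) matrix(0, 1, 1),
                  f = function(x, v) -x + v, fx = function(x, v) matrix(-1, 1, 1),
                  fv = function(x, v) matrix(1, 1, 1),
                  n_x = 1L, n_v = 1L, n_y = 1L,
                  Pi_y = 2, Pi_x = 3, Pi_v = 1.5,
                  eta = function(t) matrix(c(0.2, 0), 2, 1),
                  order_states = 1L, order_causes = 1L, smoothness = 1, dt = 1)
  belief <- structure(list(mu_x = matrix(c(0.5, 0.2), 2, 1),
                           mu_v = matrix(c(0.3, 0.1), 2, 1)),
                      class = "belief_state")
  y <- generalized_vector(matrix(c(1.4, -0.3), 2, 1))
  pe <- prediction_errors(belief, y, gfm, t = 0)
  expect_equal(as.numeric(pe$eps$y), c(0.4, -0.7), tolerance = 1e-12)
  expect_equal(as.numeric(pe$eps$x), c(0.4, 0.1), tolerance = 1e-12)
  expect_equal(as.numeric(pe$eps$v), c(0.1, 0.1), tolerance = 1e-12)
  expect_equal(as.numeric(pe$xi$y), c(0.8, -1.4), tolerance = 1e-12)
  expect_equal(as.numeric(pe$xi$x), c(1.2, 0.3), tolerance = 1e-12)
  expect_equal(as.numeric(pe$xi$v), c(0.15, 0.15), tolerance = 1e-12)
})

test_that("a belief that exactly generates the data yields zero errors", {
  gfm <- static_model()
  b <- belief_init(gfm)
  b$mu_v[1, 1] <- 1.5                      # prior mean = data below
  pe <- prediction_errors(b, const_data(1.5), gfm)
  expect_lt(max(abs(pe$xi$y)), 1e-12)
  expect_lt(max(abs(pe$xi$v)), 1e-12)
})

test_that("precision weighting is linear: doubling Pi doubles xi", {
  gfm1 <- static_model(py = 3, pv = 2)
  gfm2 <- static_model(py = 6, pv = 4)
  b <- belief_init(gfm1); b$mu_v[1, 1] <- 0.9
  y <- const_data(2)
  pe1 <- prediction_errors(b, y, gfm1)
  pe2 <- prediction_errors(b, y, gfm2)
  expect_equal(pe2$xi$y, 2 * pe1$xi$y, tolerance = 1e-12)
  expect_equal(pe2$xi$v, 2 * pe1$xi$v, tolerance = 1e-12)
  expect_equal(pe1$eps$y, pe2$eps$y, tolerance = 1e-12)
})

test_that("the static fixed point is the conjugate-Gaussian posterior mean", {
  py <- 3; pv <- 2; eta <- 1.5; yval <- 4
  gfm <- static_model(py, pv, eta)
  b <- belief_init(gfm)
  y <- const_data(yval)
  for (i in 1:200) b <- gf_step(b, y, gfm, dt = 0.5)
  truth <- (py * yval + pv * eta) / (py + pv)
  expect_lt(abs(b$mu_v[1, 1] - truth) / abs(truth), 1e-6)
  ## at the fixed point the update vanishes (pure prior prediction of a
  ## static belief): one more step does not move the belief
  b2 <- gf_step(b, y, gfm, dt = 0.5)
  expect_lt(max(abs(belief_pack_test(b2) - belief_pack_test(b))), 1e-8)
})

test_that("small steps descend the precision-weighted squared error", {
  gfm <- static_model()
  y <- const_data(4)
  E <- function(b) {
    pe <- prediction_errors(b, y, gfm)
    sum(pe$eps$y * pe$xi$y) + sum(pe$eps$v * pe$xi$v)
  }
  b <- belief_init(gfm)           # prior mean far from the data
  for (dt in c(0.001, 0.01, 0.05)) {
    expect_lt(E(gf_step(b, y, gfm, dt = dt)), E(b))
  }
})

test_that("divergence raises an informative error", {
  gfm <- static_model()
  gfm$divergence_bound <- 1e-3
  b <- belief_init(gfm)
  expect_error(gf_step(b, const_data(100), gfm, dt = 0.5), "diverged")
})

## cached noiseless deviant runs for trajectory-level properties
run_cache <- local({
  cache <- list()
  function(mag, p = 0.05, prior_hz = 1000) {
    key <- paste(mag, p, prior_hz)
    if (is.null(cache[[key]])) {
      cnd <- oddball_condition(1000, mag, p)
      gen <- auditory_hdm(cnd)
      stim <- generate_stimulus(cnd, gen, noiseless = TRUE)
      model <- auditory_hdm(cnd, prior_mean_hz = prior_hz)
      cache[[key]] <<- list(stim = stim, run = filter_run(stim, model),
                            model = model)
    }
    cache[[key]]
  }
})

test_that("an expected standard evokes far smaller cause errors than a deviant", {
  std <- run_cache(0, 0.05, prior_hz = 1000)   # expected tone presented
  dev <- run_cache(0.32, 0.05, prior_hz = 1000)
  expect_lt(max(abs(std$run$errors$xi_causes[, 2])),
            0.2 * max(abs(dev$run$errors$xi_causes[, 2])))
})

test_that("the deviant's frequency is inferred and released after offset", {
  r <- run_cache(0.32, 0.05)
  stim <- r$stim
  plateau <- stim$times >= 83 & stim$times <= 109
  mu <- r$run$mu_v[, 2]
  spacing <- log(1.32)
  expect_lt(abs(mean(mu[plateau]) - stim$truth$target_log_freq), 0.05 * spacing)
  ## after stimulus offset the inferred target returns toward the prior mean
  eta <- r$model$prior_mean_freq
  expect_lt(abs(mu[length(mu)] - eta), 0.25 * abs(mean(mu[plateau]) - eta))
})

test_that("raising prior precision strictly deepens the cause errors", {
  stim <- run_cache(0.32, 0.05)$stim          # fixed deviant stimulus
  peaks <- sapply(c(0.4, 0.2, 0.1, 0.05), function(p) {
    m <- auditory_hdm(oddball_condition(1000, 0.32, p))
    max(abs(filter_run(stim, m)$errors$xi_causes))
  })
  expect_true(all(diff(peaks) > 0))
})

test_that("error peaks are nondecreasing in deviance magnitude", {
  peaks <- t(sapply(c(0.02, 0.04, 0.27, 0.32), function(mag) {
    r <- run_cache(mag, 0.05)
    c(y = max(abs(r$run$errors$xi_sensory)),
      v = max(abs(r$run$errors$xi_causes)))
  }))
  expect_true(all(diff(peaks[, "y"]) >= 0))
  expect_true(all(diff(peaks[, "v"]) >= 0))
})

test_that("filtering identical inputs gives identical trajectories", {
  cnd <- oddball_condition(1000, 0.127, 0.1)
  stim <- generate_stimulus(cnd, auditory_hdm(cnd), rng_seed = 3)
  r1 <- filter_run(stim, auditory_hdm(cnd))
  r2 <- filter_run(stim, auditory_hdm(cnd))
  expect_identical(r1$mu_v, r2$mu_v)
  expect_identical(r1$errors$xi_sensory, r2$errors$xi_sensory)
})
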