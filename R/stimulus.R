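#' Loudness cause envelope
#'
#' The hidden cause driving the loudness subsystem: a Gaussian bump in native
#' simulation time.  After the ERP time warp its peak falls roughly 70 ms
#' after stimulus onset with a standard deviation of about 30 ms.
#'
#' @param t native simulation time (vector allowed).
#' @param envelope list with \code{peak_time}, \code{sd}, \code{amplitude}.
#' @return envelope value(s) v_l(t).
#' @export
loudness_cause <- function(t, envelope) {
  envelope$amplitude * exp(-(t - envelope$peak_time)^2 / (2 * envelope$sd^2))
}

## analytic time derivatives of the envelope, for generalized prior means
loudness_cause_deriv <- function(t, envelope, order) {
  s2 <- envelope$sd^2
  u <- (t - envelope$peak_time)
  g <- loudness_cause(t, envelope)
  switch(as.character(order),
         "0" = g,
         "1" = -u / s2 * g,
         "2" = (u^2 / s2^2 - 1 / s2) * g,
         stop("envelope derivatives implemented up to order 2"))
}

#' Sample the target log-frequency for one trial
#'
#' The trial's target log-frequency is drawn from a normal distribution
#' centred on the standard frequency (standard trials) or on the standard
#' frequency raised by the deviance magnitude (deviant trials), with a small
#' trial-to-trial jitter \code{sigma_draw}.
#'
#' @param condition an \code{\link{oddball_condition}}.
#' @param rng_seed integer seed (NULL leaves the RNG stream alone).
#' @param sigma_draw jitter SD in log-frequency units.
#' @return sampled target log-frequency.
#' @export
sample_target_frequency <- function(condition, rng_seed = NULL,
                                    sigma_draw = mmn_config()$generation$sigma_draw) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  mu <- target_log_frequency(condition)
  stats::rnorm(1, mean = mu, sd = sigma_draw)
}

## deterministic centre of the target-frequency distribution
target_log_frequency <- function(condition) {
  f <- condition$standard_hz
  if (condition$trial_type == "deviant") f <- f * (1 + condition$deviance_magnitude)
  log(f)
}

#' Smooth Gaussian-process noise
#'
#' Stationary Gaussian noise with Gaussian-shaped autocorrelation of width
#' \code{smoothness} and marginal variance \code{exp(-logprec)}, synthesized
#' by convolving white Gaussian noise with a Gaussian kernel (of width
#' \code{smoothness / sqrt(2)}, so the output autocorrelation has the stated
#' width) and rescaling analytically to the target marginal variance.
#'
#' @param n_steps number of samples (>= 2).
#' @param dt sampling interval (native units).
#' @param logprec log-precision of each stream; \code{Inf} yields zeros.
#' @param smoothness autocorrelation width (native time units).
#' @param n_streams number of independent streams (columns).
#' @param rng_seed integer seed.
#' @return n_steps x n_streams matrix.
#' @export
smooth_noise <- function(n_steps, dt, logprec, smoothness, n_streams = 1L,
                         rng_seed = NULL) {
  stopifnot(n_steps >= 2, smoothness > 0)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (is.infinite(logprec)) return(matrix(0, n_steps, n_streams))
  sk <- smoothness / sqrt(2)
  m <- max(1L, ceiling(4 * sk / dt))
  k <- exp(-((-m:m) * dt)^2 / (2 * sk^2))
  e <- matrix(stats::rnorm((n_steps + 2L * m) * n_streams), ncol = n_streams)
  sm <- apply(e, 2, function(col) {
    as.numeric(stats::convolve(col, rev(k), type = "open"))[(2L * m + 1L):(2L * m + n_steps)]
  })
  sm <- matrix(sm, nrow = n_steps)
  sd_target <- exp(-logprec / 2)
  sm * (sd_target / sqrt(sum(k^2)))
}

#' Generate a spectrogram stimulus from the hierarchical dynamic model
#'
#' Samples the trial's target log-frequency, then integrates the stochastic
#' hidden-state dynamics forward (fourth-order Runge-Kutta on the
#' deterministic flow, smooth noise held constant within a step) and reads
#' the states out through the tonotopic bank with smooth observation noise.
#' Generation-side precisions are high, so the stimulus is a near-noiseless
#' realization of the model.
#'
#' @param condition an \code{\link{oddball_condition}}.
#' @param model an \code{\link{auditory_hdm}} (generation side).
#' @param rng_seed integer seed controlling all randomness of the trial.
#' @param noiseless logical; TRUE integrates the purely deterministic model
#'   with the target frequency at the distribution centre.
#' @return object of class \code{spectrogram}: \code{times},
#'   \code{channels} (times x 50), and \code{truth} (hidden trajectories,
#'   causes and the sampled target) for diagnostics.
#' @export
generate_stimulus <- function(condition, model = auditory_hdm(condition),
                              rng_seed = NULL, noiseless = FALSE) {
  cf <- model$config
  n <- cf$grid$n_steps
  dt <- cf$grid$dt
  times <- (seq_len(n) - 1L) * dt
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (noiseless) {
    v_nu <- target_log_frequency(condition)
    wx <- matrix(0, n, model$n_x)
    wy <- matrix(0, n, model$n_y)
  } else {
    v_nu <- sample_target_frequency(condition, rng_seed = NULL,
                                    sigma_draw = cf$generation$sigma_draw)
    wx <- smooth_noise(n, dt, cf$generation$state_logprec, model$smoothness,
                       n_streams = model$n_x)
    wy <- smooth_noise(n, dt, cf$generation$obs_logprec, model$smoothness,
                       n_streams = model$n_y)
  }
  v_l <- loudness_cause(times, model$loudness_cause_envelope)
  X <- matrix(0, n, model$n_x)
  Y <- matrix(0, n, model$n_y)
  x <- c(0, 0, v_nu)
  for (i in seq_len(n)) {
    X[i, ] <- x
    Y[i, ] <- generate_observation(x, model) + wy[i, ]
    if (any(!is.finite(x)))
      stop(sprintf("stimulus integration diverged at step %d", i))
    v_mid <- c(loudness_cause(times[i] + dt / 2, model$loudness_cause_envelope), v_nu)
    v_end <- c(loudness_cause(times[i] + dt, model$loudness_cause_envelope), v_nu)
    drift <- function(x, v) hdm_flow(x, v, model) + wx[i, ]
    k1 <- drift(x, c(v_l[i], v_nu))
    k2 <- drift(x + dt / 2 * k1, v_mid)
    k3 <- drift(x + dt / 2 * k2, v_mid)
    k4 <- drift(x + dt * k3, v_end)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  structure(list(times = times, channels = Y,
                 truth = list(x = X, v_l = v_l, target_log_freq = v_nu),
                 dt = dt),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("Spectrogram: %d time steps x %d channels (dt = %g)\n",
              nrow(x$channels), ncol(x$channels), x$dt))
  cat(sprintf("  target log-frequency %.4f (%.1f Hz); peak channel activity %.3f\n",
              x$truth$target_log_freq, exp(x$truth$target_log_freq),
              max(x$channels)))
  invisible(x)
}

#' @export
plot.spectrogram <- function(x, ...) {
  graphics::image(x$times, seq_len(ncol(x$channels)), x$channels,
                  xlab = "native time", ylab = "frequency channel",
                  main = "Spectrogram", ...)
  invisible(x)
}

#' Simulate stimuli from an auditory model
#'
#' \code{simulate} method: draws \code{nsim} independent spectrogram trials
#' from the generative model under its condition.
#'
#' @param object an \code{\link{auditory_hdm}}.
#' @param nsim number of trials.
#' @param seed integer seed for the first trial; subsequent trials increment it.
#' @param ... unused.
#' @return list of \code{spectrogram} objects.
#' @export
simulate.auditory_hdm <- function(object, nsim = 1, seed = NULL, ...) {
  seeds <- if (is.null(seed)) rep(list(NULL), nsim) else as.list(seed + seq_len(nsim) - 1L)
  lapply(seeds, function(s) generate_stimulus(object$condition, object, rng_seed = s))
}
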