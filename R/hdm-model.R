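#' Tonotopic tuning bank
#'
#' A bank of 50 frequency channels with Gaussian tuning in log-frequency,
#' emulating the tonotopic organization of primary auditory cortex: channel i
#' responds maximally when the instantaneous log-frequency equals its
#' preferred log-frequency \code{nu[i]}, falling off with Gaussian width
#' \code{sigma_tune}.
#'
#' @param center_log_freq log-frequency at the centre of the bank (natural
#'   log of Hz); defaults to log(1000).
#' @param sigma_tune tuning width in log-frequency units.
#' @param span_widths half-span of the bank in multiples of the tuning width.
#' @param n_channels number of channels (fixed at 50 by the cortical model).
#' @return object of class \code{tuning_bank}.
#' @export
tuning_bank <- function(center_log_freq = log(1000), sigma_tune = 0.1,
                        span_widths = 4, n_channels = 50L) {
  stopifnot(sigma_tune > 0, span_widths > 0, n_channels == 50L)
  nu <- seq(center_log_freq - span_widths * sigma_tune,
            center_log_freq + span_widths * sigma_tune,
            length.out = n_channels)
  structure(list(preferred_log_frequencies = nu, tuning_width = sigma_tune),
            class = "tuning_bank")
}

#' Spectral response of the tonotopic bank
#'
#' Loudness-modulated Gaussian tuning: channel i responds with
#' \code{loudness * exp(-(nu - nu_i)^2 / (2 sigma_tune^2))}.
#'
#' @param log_frequency instantaneous log-frequency.
#' @param loudness instantaneous loudness (multiplicative gain).
#' @param tuning a \code{\link{tuning_bank}}.
#' @return numeric vector of 50 channel activities.
#' @export
spectral_response <- function(log_frequency, loudness, tuning) {
  if (!is.finite(log_frequency) || !is.finite(loudness))
    stop("non-finite input to spectral_response")
  d <- log_frequency - tuning$preferred_log_frequencies
  loudness * exp(-d^2 / (2 * tuning$tuning_width^2))
}

## derivative of the channel response with respect to log-frequency
spectral_response_dnu <- function(log_frequency, loudness, tuning) {
  d <- log_frequency - tuning$preferred_log_frequencies
  -(d / tuning$tuning_width^2) * loudness * exp(-d^2 / (2 * tuning$tuning_width^2))
}

#' Map deviant probability to prior precision
#'
#' The confidence of the listener's prediction about the target frequency is
#' set by how rare deviants are: \code{precision = pi_floor +
#' pi_scale * (-log(p))}.  Rarer deviants (small p) imply a more precise
#' prior; the mapping is continuous, strictly decreasing in p, and approaches
#' the floor \code{pi_floor} as p approaches 1.
#'
#' @param p deviant probability, strictly inside (0, 1).
#' @param pi_floor,pi_scale mapping constants (log-frequency precision units).
#' @return prior precision of the target log-frequency belief.
#' @export
prior_precision_from_probability <- function(p, pi_floor = 0.5, pi_scale = 1.5) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("deviant probability must lie strictly inside (0, 1)")
  pi_floor + pi_scale * (-log(p))
}

#' Oddball condition descriptor
#'
#' @param standard_hz standard-tone frequency in Hz.
#' @param deviance_magnitude proportional frequency difference between the
#'   deviant and the standard (e.g. 0.127 for a 1270 Hz deviant on a 1000 Hz
#'   standard).
#' @param deviant_probability relative frequency of deviants in the stream,
#'   in (0, 1).
#' @param trial_type "standard" or "deviant".
#' @return object of class \code{oddball_condition}.
#' @export
oddball_condition <- function(standard_hz = 1000, deviance_magnitude = 0.127,
                              deviant_probability = 0.05,
                              trial_type = c("deviant", "standard")) {
  trial_type <- match.arg(trial_type)
  stopifnot(standard_hz > 0, deviance_magnitude >= 0,
            deviant_probability > 0, deviant_probability < 1)
  structure(list(standard_hz = standard_hz,
                 deviance_magnitude = deviance_magnitude,
                 deviant_probability = deviant_probability,
                 trial_type = trial_type),
            class = "oddball_condition")
}

#' Default model configuration
#'
#' All constants of the auditory hierarchical dynamic model, on the native
#' simulation grid (dimensionless time units, one unit per integration step).
#' Returned as a nested list; any entry can be overridden and the list passed
#' to \code{\link{auditory_hdm}} or written to / read from YAML with
#' \code{\link{write_mmn_config}} / \code{\link{read_mmn_config}}.
#'
#' @return nested list of configuration values.
#' @export
mmn_config <- function() {
  list(
    grid = list(n_steps = 256L, dt = 1),
    tuning = list(sigma_tune = 0.1, span_widths = 4, n_channels = 50L),
    dynamics = list(kappa_freq = 0.5, omega = 0.25, zeta = 0.5),
    envelope = list(peak_time = 96, sd = 28, amplitude = 1),
    priors = list(pi_floor = 0.5, pi_scale = 1.5, cause_loudness_logprec = 2),
    recognition = list(obs_logprec = 2, state_logprec = 7),
    generation = list(obs_logprec = 16, state_logprec = 16,
                      sigma_draw = 0.005),
    smoothness = 2,
    embedding = list(order_states = 4L, order_causes = 2L),
    erp = list(conduction_shift_ms = 10,
               slopes = c(1, 0.2, 3),
               lead_field = c(-2, -0.5, -2),
               offset = 0)
  )
}

## merge user overrides into the default configuration (shallow, per section)
merge_config <- function(config) {
  base <- mmn_config()
  if (is.null(config)) return(base)
  for (s in names(config)) {
    if (is.list(base[[s]]) && is.list(config[[s]])) {
      for (k in names(config[[s]])) base[[s]][[k]] <- config[[s]][[k]]
    } else base[[s]] <- config[[s]]
  }
  base
}

#' Write / read a model configuration
#'
#' @param config nested configuration list (see \code{\link{mmn_config}}).
#' @param path file path for the YAML configuration.
#' @return \code{read_mmn_config} returns the configuration list merged over
#'   the defaults.
#' @export
write_mmn_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_mmn_config
#' @export
read_mmn_config <- function(path) {
  merge_config(yaml::read_yaml(path))
}

#' The three-level auditory generative model
#'
#' Builds the hierarchical dynamic model of a single tone: hidden states are
#' the instantaneous loudness and its velocity (a damped oscillatory
#' subsystem driven by the loudness cause) and the instantaneous
#' log-frequency (which relaxes towards the target log-frequency at rate
#' \code{kappa_freq}); the observation function reads the states out through
#' a 50-channel tonotopic tuning bank.  The prior on the target log-frequency
#' encodes the listener's expectation: its mean is the expected tone and its
#' precision is set by the deviant probability.
#'
#' @param condition an \code{\link{oddball_condition}}; fixes the standard
#'   frequency, the prior precision (via deviant probability) and, through
#'   \code{prior_mean_hz}, what tone the listener expects.
#' @param config nested configuration list; entries override
#'   \code{\link{mmn_config}} defaults.
#' @param prior_mean_hz expected tone frequency (Hz).  Defaults to the
#'   standard frequency (the "expected standard" listener).
#' @return object of class \code{auditory_hdm}.
#' @export
auditory_hdm <- function(condition = oddball_condition(), config = NULL,
                         prior_mean_hz = condition$standard_hz) {
  cf <- merge_config(config)
  tun <- tuning_bank(center_log_freq = log(condition$standard_hz),
                     sigma_tune = cf$tuning$sigma_tune,
                     span_widths = cf$tuning$span_widths,
                     n_channels = cf$tuning$n_channels)
  omega <- cf$dynamics$omega; zeta <- cf$dynamics$zeta
  A <- matrix(c(0, -omega^2, 1, -2 * zeta * omega), 2, 2)
  ev <- eigen(A, only.values = TRUE)$values
  if (any(Re(ev) >= 0) || all(Im(ev) == 0))
    stop("loudness dynamics must spiral (decay) towards zero: need a stable complex pair")
  kappa <- cf$dynamics$kappa_freq
  stopifnot(kappa > 0)
  prior_prec <- prior_precision_from_probability(
    condition$deviant_probability, cf$priors$pi_floor, cf$priors$pi_scale)
  model <- list(
    condition = condition,
    config = cf,
    tuning = tun,
    kappa_freq = kappa,
    loudness_matrix = A,
    loudness_drive = c(0, omega^2),
    smoothness = cf$smoothness,
    prior_mean_freq = log(prior_mean_hz),
    prior_precision_freq = prior_prec,
    n_x = 3L, n_v = 2L, n_y = cf$tuning$n_channels,
    log_precisions = list(
      recognition = list(obs = cf$recognition$obs_logprec,
                         state = cf$recognition$state_logprec),
      generation = list(obs = cf$generation$obs_logprec,
                        state = cf$generation$state_logprec)),
    loudness_cause_envelope = cf$envelope
  )
  class(model) <- "auditory_hdm"
  model
}

#' @export
print.auditory_hdm <- function(x, ...) {
  cnd <- x$condition
  cat("Auditory hierarchical dynamic model (3 levels)\n")
  cat(sprintf("  standard: %g Hz; deviant: %+.1f%% (p = %g); trial: %s\n",
              cnd$standard_hz, 100 * cnd$deviance_magnitude,
              cnd$deviant_probability, cnd$trial_type))
  cat(sprintf("  listener expects %g Hz with prior precision %.2f\n",
              exp(x$prior_mean_freq), x$prior_precision_freq))
  cat(sprintf("  50 tonotopic channels, tuning width %g log-units; kappa = %g\n",
              x$tuning$tuning_width, x$kappa_freq))
  invisible(x)
}

## loudness read-out l(x): first loudness state.  Isolated so alternative
## nonnegative read-outs (softplus, exponential) are one-line swaps.
loudness_readout <- function(x) x[1]

#' Deterministic flow of the hidden states
#'
#' \code{dx/dt} for the hidden-state 3-vector \code{(x_l, x_l', x_nu)} given
#' causes \code{(v_l, v_nu)}: the loudness pair follows the damped
#' oscillator driven by \code{v_l}; the log-frequency relaxes towards the
#' target \code{v_nu} at rate \code{kappa_freq}.
#'
#' @param x hidden states (loudness, loudness velocity, log-frequency).
#' @param v hidden causes (loudness cause, target log-frequency).
#' @param model an \code{\link{auditory_hdm}}.
#' @return 3-vector dx/dt.
#' @export
hdm_flow <- function(x, v, model) {
  if (any(!is.finite(x)) || any(!is.finite(v))) stop("non-finite state or cause")
  c(model$loudness_matrix %*% x[1:2] + model$loudness_drive * v[1],
    model$kappa_freq * (v[2] - x[3]))
}

## constant Jacobians of the flow
hdm_flow_jacobian <- function(model) {
  fx <- rbind(cbind(model$loudness_matrix, c(0, 0)),
              c(0, 0, -model$kappa_freq))
  fv <- rbind(c(0, 0), c(model$loudness_drive[2], 0), c(0, model$kappa_freq))
  list(fx = fx, fv = fv)
}

#' Sensory prediction g(x)
#'
#' Composes the loudness read-out with the tonotopic spectral response:
#' the predicted 50-channel activity for hidden states \code{x}.
#'
#' @inheritParams hdm_flow
#' @return 50-vector of predicted channel activities.
#' @export
generate_observation <- function(x, model) {
  spectral_response(x[3], loudness_readout(x), model$tuning)
}

## Jacobian of g with respect to the hidden states (50 x 3)
hdm_obs_jacobian <- function(x, model) {
  phi <- spectral_response(x[3], 1, model$tuning)
  cbind(phi, 0, spectral_response_dnu(x[3], loudness_readout(x), model$tuning))
}
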