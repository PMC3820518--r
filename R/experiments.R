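## Seeds for individual rows of a sweep, derived from one base seed and kept
## inside the 32-bit integer range.
condition_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + 104729 * i) %% 2147483647)
}

#' Simulate one oddball condition
#'
#' Runs the canonical pair of simulations: the deviant simulation presents
#' tone B to a listener expecting tone A (the standard), and the standard
#' simulation presents the same tone B to a listener expecting B.  Both runs
#' share the same stimulus realization (seed), so the difference wave
#' isolates the effect of expectation.  Perception is simulated by
#' generalized filtering; precision-weighted prediction errors are mapped to
#' scalp ERPs; the MMN is the deviant-minus-standard difference wave, with
#' fractional-area latency (unfiltered) and windowed amplitude (filtered).
#'
#' @param condition an \code{\link{oddball_condition}}.
#' @param config model configuration overrides (see \code{\link{mmn_config}}).
#' @param obs_params \code{\link{observation_params}}.
#' @param rng_seed integer seed for the stimulus realization.
#' @param noiseless logical: integrate the generator without noise.
#' @return list of class \code{mmn_condition_run}: standard and deviant ERPs,
#'   MMN waves (unfiltered + filtered), latency (ms), amplitude and peak
#'   depth (microvolt), and the two filtering runs.
#' @export
run_condition <- function(condition, config = NULL,
                          obs_params = observation_params(),
                          rng_seed = NULL, noiseless = FALSE) {
  cnd <- oddball_condition(condition$standard_hz, condition$deviance_magnitude,
                           condition$deviant_probability, "deviant")
  deviant_hz <- cnd$standard_hz * (1 + cnd$deviance_magnitude)
  ## expected-A / presented-B listener (deviant ERP)
  model_dev <- auditory_hdm(cnd, config)
  ## expected-B / presented-B listener (standard ERP), same prior precision
  model_std <- auditory_hdm(cnd, config, prior_mean_hz = deviant_hz)
  gen_model <- model_dev  # generation side is condition-defined, prior-free
  stim <- generate_stimulus(cnd, gen_model, rng_seed = rng_seed,
                            noiseless = noiseless)
  run_dev <- filter_run(stim, model_dev)
  run_std <- filter_run(stim, model_std)
  onset <- native_stimulus_onset(model_dev$loudness_cause_envelope)
  erp_dev <- erp_forward(run_dev$errors, obs_params, onset)
  erp_std <- erp_forward(run_std$errors, obs_params, onset)
  mmn_unf <- difference_wave(erp_dev$unfiltered, erp_std$unfiltered)
  mmn_fil <- difference_wave(erp_dev$filtered, erp_std$filtered)
  latency <- fractional_area_latency(mmn_unf)
  amplitude <- if (is.na(latency)) NA_real_ else
    tryCatch(mmn_amplitude(mmn_fil, latency), error = function(e) NA_real_)
  structure(list(condition = cnd, stimulus = stim,
                 run_deviant = run_dev, run_standard = run_std,
                 erp_deviant = erp_dev, erp_standard = erp_std,
                 mmn_unfiltered = mmn_unf, mmn_filtered = mmn_fil,
                 latency_ms = latency, amplitude_uV = amplitude,
                 peak_uV = min(mmn_fil$voltages),
                 obs_params = obs_params, seed = rng_seed),
            class = "mmn_condition_run")
}

#' @export
print.mmn_condition_run <- function(x, ...) {
  cat(sprintf("Oddball condition: %g Hz standard, %+.1f%% deviant, p = %g\n",
              x$condition$standard_hz, 100 * x$condition$deviance_magnitude,
              x$condition$deviant_probability))
  cat(sprintf("  MMN latency %.1f ms (fractional area, + %g ms conduction shift included)\n",
              x$latency_ms, x$obs_params$conduction_shift_ms))
  cat(sprintf("  MMN amplitude %.3f uV (windowed mean), peak %.3f uV\n",
              x$amplitude_uV, x$peak_uV))
  invisible(x)
}

#' @export
plot.mmn_condition_run <- function(x, ...) {
  f <- x$mmn_filtered
  graphics::plot(x$erp_standard$filtered$times, x$erp_standard$filtered$voltages,
                 type = "l", col = "blue", xlab = "peristimulus time (ms)",
                 ylab = "uV",
                 ylim = range(x$erp_standard$filtered$voltages,
                              x$erp_deviant$filtered$voltages, f$voltages), ...)
  graphics::lines(x$erp_deviant$filtered$times, x$erp_deviant$filtered$voltages,
                  col = "red")
  graphics::lines(f$times, f$voltages, col = "black", lwd = 2)
  if (!is.na(x$latency_ms)) graphics::abline(v = x$latency_ms, lty = 3)
  graphics::legend("bottomright", c("standard", "deviant", "MMN"),
                   col = c("blue", "red", "black"), lty = 1, cex = 0.7)
  invisible(x)
}

#' Default sweep grids
#'
#' Deviance magnitudes 2, 4, 12.7, 27 and 32 percent and deviant
#' probabilities 0.05 to 0.4, matching the simulated oddball experiments
#' (1020, 1040, 1270 and 1320 Hz deviants on a 1000 Hz standard at p = 0.05;
#' probability varied at 12.7\% deviance).
#'
#' @return list with \code{magnitudes} and \code{probabilities}.
#' @export
default_sweep_grid <- function() {
  list(magnitudes = c(0.02, 0.04, 0.127, 0.27, 0.32),
       probabilities = c(0.05, 0.1, 0.2, 0.3, 0.4))
}

#' Deviance-magnitude by deviant-probability sweep
#'
#' Runs \code{\link{run_condition}} over the cross product of the grids (one
#' row per condition and seed) and returns a tidy results table.  Failures in
#' individual rows are recorded in the \code{error} column and the sweep
#' continues.
#'
#' @param magnitudes deviance magnitudes (fractions).
#' @param probabilities deviant probabilities (fractions in (0,1)).
#' @param config,obs_params forwarded to \code{\link{run_condition}}.
#' @param seeds integer vector of base seeds (one replicate per seed).
#'   Deviant probability manipulates only the listener's prior precision, so
#'   rows sharing a magnitude and seed reuse the same stimulus realization;
#'   the probability effect is then isolated from stimulus jitter.
#' @param standard_hz standard frequency.
#' @param noiseless logical; TRUE for deterministic sweeps.
#' @return data.frame with magnitude, probability, seed, latency_ms,
#'   amplitude_uV, peak_uV and error columns, with the condition-mean
#'   qualitative contrasts as attribute \code{"contrasts"}.
#' @export
mmn_sweep <- function(magnitudes = default_sweep_grid()$magnitudes,
                      probabilities = default_sweep_grid()$probabilities,
                      config = NULL, obs_params = observation_params(),
                      seeds = 1L, standard_hz = 1000, noiseless = FALSE) {
  stopifnot(length(magnitudes) >= 1L, length(probabilities) >= 1L)
  grid <- expand.grid(magnitude = magnitudes, probability = probabilities,
                      seed = seeds, KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  out <- data.frame(grid, latency_ms = NA_real_, amplitude_uV = NA_real_,
                    peak_uV = NA_real_, error = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    res <- tryCatch({
      cnd <- oddball_condition(standard_hz, grid$magnitude[i],
                               grid$probability[i], "deviant")
      mag_idx <- match(grid$magnitude[i], magnitudes)
      run_condition(cnd, config, obs_params,
                    rng_seed = condition_seed(grid$seed[i], mag_idx),
                    noiseless = noiseless)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$error[i] <- conditionMessage(res)
    } else {
      out$latency_ms[i] <- res$latency_ms
      out$amplitude_uV[i] <- res$amplitude_uV
      out$peak_uV[i] <- res$peak_uV
    }
  }
  attr(out, "contrasts") <- mmn_contrasts(out)
  out
}

#' Qualitative MMN contrasts from a sweep table
#'
#' Summarizes the four phenomenological patterns on condition means:
#' (a) deeper MMN peak with larger deviance magnitude at p = 0.05;
#' (b) deeper MMN peak with lower deviant probability at 12.7\% deviance;
#' (c) shorter latency at 32\% than at 12.7\% deviance (p = 0.05);
#' (d) latency spread across probabilities (magnitude <= 12.7\%) small
#' relative to the (c) latency difference.
#'
#' @param table a \code{\link{mmn_sweep}} results table.
#' @return list with the four contrasts (logical \code{holds} plus the
#'   numbers behind each).
#' @export
mmn_contrasts <- function(table) {
  ok <- is.na(table$error)
  tb <- table[ok, , drop = FALSE]
  cond_mean <- function(sub, col)
    tapply(sub[[col]], list(sub$magnitude, sub$probability), mean, na.rm = TRUE)
  a <- b <- c_ <- d <- NULL
  ## (a) |peak| increasing in magnitude at p = 0.05
  s <- tb[tb$probability == 0.05, ]
  if (nrow(s)) {
    m <- tapply(abs(s$peak_uV), s$magnitude, mean)
    a <- list(magnitudes = as.numeric(names(m)), abs_peak = as.numeric(m),
              holds = all(diff(m) > 0))
  }
  ## (b) |peak| increasing as p decreases at magnitude 12.7%
  s <- tb[abs(tb$magnitude - 0.127) < 1e-9, ]
  if (nrow(s)) {
    m <- tapply(abs(s$peak_uV), s$probability, mean)   # ordered by p increasing
    b <- list(probabilities = as.numeric(names(m)), abs_peak = as.numeric(m),
              holds = all(diff(m) < 0))
  }
  ## (c) latency shorter at 32% than 12.7% (p = 0.05)
  s <- tb[tb$probability == 0.05 & tb$magnitude %in% c(0.127, 0.32), ]
  if (nrow(s)) {
    m <- tapply(s$latency_ms, s$magnitude, mean)
    if (all(c("0.127", "0.32") %in% names(m)))
      c_ <- list(latency_127 = m[["0.127"]], latency_320 = m[["0.32"]],
                 holds = m[["0.32"]] < m[["0.127"]])
  }
  ## (d) latency ~ unaffected by p at moderate magnitude
  s <- tb[tb$magnitude <= 0.127 + 1e-9, ]
  if (nrow(s) && !is.null(c_)) {
    spread <- max(tapply(s$latency_ms, list(s$magnitude, s$probability), mean,
                         na.rm = TRUE) |>
                    apply(1, function(r) diff(range(r, na.rm = TRUE))),
                  na.rm = TRUE)
    d <- list(latency_spread_over_p = spread,
              magnitude_latency_difference = c_$latency_127 - c_$latency_320,
              holds = spread < (c_$latency_127 - c_$latency_320))
  }
  list(amplitude_vs_magnitude = a, amplitude_vs_probability = b,
       latency_vs_magnitude = c_, latency_vs_probability = d)
}
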