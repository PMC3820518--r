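#' Observation (forward-model) parameters
#'
#' Parameters mapping precision-weighted prediction errors to the scalp:
#' sigmoid slopes per source (A1, lateral Heschl's gyrus, inferior frontal
#' gyrus), a 3-component lead field, a constant offset, the conduction delay
#' from the ear, and the native-time to milliseconds scale.
#'
#' @param slopes positive sigmoid gains, length 3 (A1, Heschl, IFG).
#' @param lead_field lead-field weights in microvolt per unit LFP, length 3.
#' @param offset constant scalp term (microvolt).
#' @param conduction_shift_ms conduction delay from the ear (ms).  It trades
#'   off exactly against latency, so it is reported alongside all latencies.
#' @param time_scale ms of peristimulus time per native time unit.
#' @return object of class \code{observation_params}.
#' @export
observation_params <- function(slopes = mmn_config()$erp$slopes,
                               lead_field = mmn_config()$erp$lead_field,
                               offset = mmn_config()$erp$offset,
                               conduction_shift_ms = mmn_config()$erp$conduction_shift_ms,
                               time_scale = NULL) {
  stopifnot(length(slopes) == 3L, all(slopes > 0), length(lead_field) == 3L,
            is.null(time_scale) || time_scale > 0)
  if (is.null(time_scale)) time_scale <- default_time_scale()
  structure(list(slopes = as.numeric(slopes),
                 lead_field = as.numeric(lead_field),
                 offset = as.numeric(offset),
                 conduction_shift_ms = conduction_shift_ms,
                 time_scale = time_scale),
            class = "observation_params")
}

## The warp scale maps the native stimulus duration onto 70 ms.  Duration is
## read as the loudness envelope's full width at half maximum (2.3548 sd),
## which also places the warped envelope SD near 30 ms.
native_stimulus_duration <- function(envelope = mmn_config()$envelope) {
  2 * sqrt(2 * log(2)) * envelope$sd
}

default_time_scale <- function(envelope = mmn_config()$envelope,
                               target_ms = 70) {
  target_ms / native_stimulus_duration(envelope)
}

## native time of stimulus onset: one FWHM before the envelope peak
native_stimulus_onset <- function(envelope = mmn_config()$envelope) {
  envelope$peak_time - native_stimulus_duration(envelope)
}

#' Warp the error time axis to peristimulus milliseconds
#'
#' Affine map of the native time axis: shifted by the conduction delay and
#' scaled so the native stimulus duration becomes 70 ms; peristimulus zero is
#' the stimulus onset at the ear.  Values are unchanged.
#'
#' @param errors an \code{error_trajectory}.
#' @param params \code{\link{observation_params}}.
#' @param onset_native native time of stimulus onset (maps to the conduction
#'   delay on the warped axis).
#' @return the same trajectory with \code{times} in ms.
#' @export
timewarp <- function(errors, params, onset_native = native_stimulus_onset()) {
  errors$times <- params$conduction_shift_ms +
    params$time_scale * (errors$times - onset_native)
  errors$native_dt <- NULL
  errors$dt_ms <- diff(errors$times[1:2])
  errors
}

#' Local field potential of one source
#'
#' Each prediction-error unit is passed through a logistic activation
#' \code{1 / (1 + exp(-slope * xi))} (firing cannot be negative and saturates
#' for large errors) and the unit responses are summed within the source.
#'
#' @param xi times x units matrix of precision-weighted errors for one source.
#' @param slope positive sigmoid gain.
#' @return numeric LFP time series.
#' @export
source_lfp <- function(xi, slope) {
  stopifnot(slope > 0)
  xi <- as.matrix(xi)
  rowSums(stats::plogis(slope * xi))
}

#' Scalp potential from three source LFPs
#'
#' Linear superposition of the local field potentials plus a constant:
#' \code{v(t) = sum_i w_i LFP_i(t) + offset}.
#'
#' @param lfps times x 3 matrix (A1, Heschl, IFG) on a common time axis.
#' @param params \code{\link{observation_params}}.
#' @return numeric scalp potential (microvolt).
#' @export
scalp_potential <- function(lfps, params) {
  lfps <- as.matrix(lfps)
  if (ncol(lfps) != 3L) stop("expected three aligned source LFPs")
  as.numeric(lfps %*% params$lead_field) + params$offset
}

#' ERP waveform container
#'
#' @param times_ms peristimulus time axis (ms), uniformly sampled.
#' @param voltages scalp potential (microvolt).
#' @param sampling_rate sampling rate in Hz; inferred from the axis if NULL.
#' @return object of class \code{erp_waveform}.
#' @export
erp_waveform <- function(times_ms, voltages, sampling_rate = NULL) {
  stopifnot(length(times_ms) == length(voltages), length(times_ms) >= 2L)
  dts <- diff(times_ms)
  if (max(abs(dts - dts[1])) > 1e-6 * abs(dts[1]))
    stop("ERP waveform must be uniformly sampled")
  if (is.null(sampling_rate)) sampling_rate <- 1000 / dts[1]
  structure(list(times = as.numeric(times_ms), voltages = as.numeric(voltages),
                 sampling_rate = sampling_rate),
            class = "erp_waveform")
}

#' @export
print.erp_waveform <- function(x, ...) {
  cat(sprintf("ERP waveform: %d samples at %.1f Hz, %.1f..%.1f ms\n",
              length(x$times), x$sampling_rate, min(x$times), max(x$times)))
  cat(sprintf("  range [%.3f, %.3f] uV\n", min(x$voltages), max(x$voltages)))
  invisible(x)
}

#' @export
plot.erp_waveform <- function(x, ...) {
  graphics::plot(x$times, x$voltages, type = "l", xlab = "peristimulus time (ms)",
                 ylab = "potential (uV)", ...)
  graphics::abline(h = 0, v = 0, col = "grey70", lty = 3)
  invisible(x)
}

#' Simulated data processing: downsample and low-pass
#'
#' Resamples the waveform to 200 Hz (linear interpolation onto a uniform
#' 5 ms grid) and applies a single-pass 3rd-order Butterworth low-pass with a
#' 40 Hz cut-off.  Both the unfiltered (resampled) and filtered waveforms are
#' returned: latency estimation uses the unfiltered waveform, amplitude the
#' filtered one.  The filter is primed with the first sample value so a
#' constant passes with unit DC gain.
#'
#' @param wave an \code{\link{erp_waveform}} sampled at >= 400 Hz.
#' @param fs_out output rate (Hz).
#' @param cutoff_hz low-pass cut-off (Hz).
#' @return list with \code{unfiltered} and \code{filtered}
#'   \code{erp_waveform}s at \code{fs_out}.
#' @export
postprocess <- function(wave, fs_out = 200, cutoff_hz = 40) {
  if (wave$sampling_rate < 400)
    stop("input sampling rate must be at least 400 Hz")
  if (fs_out < 2 * cutoff_hz)
    stop("output rate below twice the filter cut-off")
  dt_out <- 1000 / fs_out
  t_out <- seq(ceiling(min(wave$times) / dt_out) * dt_out, max(wave$times),
               by = dt_out)
  v_out <- stats::approx(wave$times, wave$voltages, xout = t_out)$y
  bw <- signal::butter(3, cutoff_hz / (fs_out / 2), type = "low")
  pad <- 64L
  v_pad <- c(rep(v_out[1L], pad), v_out)
  v_f <- as.numeric(signal::filter(bw, v_pad))[-(seq_len(pad))]
  list(unfiltered = erp_waveform(t_out, v_out, fs_out),
       filtered = erp_waveform(t_out, v_f, fs_out))
}

#' Full forward model: prediction errors to scalp ERP
#'
#' Composes the time warp, per-source sigmoid transformation, lead-field
#' superposition, baseline correction over the pre-stimulus interval, and
#' the simulated data processing chain.
#'
#' @param errors an \code{error_trajectory} from \code{\link{filter_run}}.
#' @param params \code{\link{observation_params}}.
#' @param onset_native native time of stimulus onset.
#' @return list of class \code{mmn_erp}: \code{native} (full-rate waveform),
#'   \code{unfiltered} and \code{filtered} (200 Hz) waveforms.
#' @export
erp_forward <- function(errors, params = observation_params(),
                        onset_native = native_stimulus_onset()) {
  warped <- timewarp(errors, params, onset_native)
  lfps <- cbind(source_lfp(warped$xi_sensory, params$slopes[1L]),
                if (!is.null(warped$xi_states))
                  source_lfp(warped$xi_states, params$slopes[2L]) else 0,
                source_lfp(warped$xi_causes, params$slopes[3L]))
  v <- scalp_potential(lfps, params)
  pre <- warped$times < 0
  if (any(pre)) v <- v - mean(v[pre])
  native <- erp_waveform(warped$times, v)
  post <- postprocess(native)
  structure(list(native = native, unfiltered = post$unfiltered,
                 filtered = post$filtered, params = params),
            class = "mmn_erp")
}

#' Write / read an ERP waveform as delimited text
#'
#' Two tab-separated columns: \code{time_ms}, \code{voltage_uV}.
#'
#' @param wave an \code{\link{erp_waveform}}.
#' @param path output file path.
#' @return \code{read_waveform} returns an \code{erp_waveform}.
#' @export
write_waveform <- function(wave, path) {
  utils::write.table(data.frame(time_ms = wave$times, voltage_uV = wave$voltages),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  erp_waveform(d[[1L]], d[[2L]])
}
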