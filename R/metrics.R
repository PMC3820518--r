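#' MMN difference wave
#'
#' Pointwise deviant-minus-standard subtraction on identical time axes.
#'
#' @param deviant_erp,standard_erp \code{\link{erp_waveform}}s on the same
#'   axis.
#' @return \code{erp_waveform} of the difference.
#' @export
difference_wave <- function(deviant_erp, standard_erp) {
  if (length(deviant_erp$times) != length(standard_erp$times) ||
      max(abs(deviant_erp$times - standard_erp$times)) > 1e-9)
    stop("deviant and standard ERPs must share a time axis")
  erp_waveform(deviant_erp$times,
               deviant_erp$voltages - standard_erp$voltages,
               deviant_erp$sampling_rate)
}

#' Fractional-area latency of the MMN trough
#'
#' Finds the most negative point of the waveform, delimits the trough by the
#' first and last (linearly interpolated) points at which the amplitude is at
#' least half the trough depth, and returns the time that splits the negative
#' area inside that window into the stated fractions.  Area is accumulated by
#' trapezoidal integration of the rectified-negative part, with linear
#' interpolation between samples, so the latency is sub-sample accurate.
#' Intended for unfiltered difference waves.
#'
#' @param wave an \code{\link{erp_waveform}} with a negative trough.
#' @param fraction area fraction to the left of the returned time (0.5 =
#'   classic 50\% area latency).
#' @return latency in ms, or \code{NA} with class \code{"no_mmn"} attribute
#'   message if the waveform has no negative deflection.
#' @export
fractional_area_latency <- function(wave, fraction = 0.5) {
  stopifnot(fraction > 0, fraction < 1)
  t <- wave$times; v <- wave$voltages
  i_min <- which.min(v)
  depth <- v[i_min]
  if (depth >= 0) {
    out <- NA_real_
    attr(out, "no_mmn") <- "no negative deflection: no MMN detected"
    return(out)
  }
  thr <- depth / 2
  below <- v <= thr
  ## first and last crossings of the half-depth level, interpolated
  first_idx <- which(below)[1L]
  last_idx <- which(below)[sum(below)]
  t_first <- if (first_idx == 1L) t[1L] else {
    i <- first_idx
    t[i - 1L] + (thr - v[i - 1L]) / (v[i] - v[i - 1L]) * (t[i] - t[i - 1L])
  }
  t_last <- if (last_idx == length(v)) t[length(t)] else {
    i <- last_idx
    t[i] + (thr - v[i]) / (v[i + 1L] - v[i]) * (t[i + 1L] - t[i])
  }
  ## rectified-negative waveform on a grid including the window edges
  tt <- sort(unique(c(t[t >= t_first & t <= t_last], t_first, t_last)))
  vv <- stats::approx(t, v, xout = tt)$y
  vv <- pmin(vv, 0)
  seg <- -(vv[-length(vv)] + vv[-1L]) / 2 * diff(tt)   # positive areas
  total <- sum(seg)
  target <- fraction * total
  cum <- cumsum(seg)
  j <- which(cum >= target - 1e-12)[1L]
  prev <- if (j == 1L) 0 else cum[j - 1L]
  need <- target - prev
  ## invert the trapezoid on segment j: area(s) is quadratic in s
  a <- -vv[j]; b <- -vv[j + 1L]; h <- tt[j + 1L] - tt[j]
  if (abs(b - a) < 1e-12 * max(abs(a), abs(b), 1)) {
    s <- if (a > 0) need / a else 0
  } else {
    ## solve a*s + (b - a) s^2 / (2h) = need for s in [0, h]
    A <- (b - a) / (2 * h); B <- a; C <- -need
    disc <- max(B^2 - 4 * A * C, 0)
    s <- (-B + sqrt(disc)) / (2 * A)
    if (s < 0 || s > h) s <- (-B - sqrt(disc)) / (2 * A)
    s <- min(max(s, 0), h)
  }
  tt[j] + s
}

#' Windowed MMN amplitude
#'
#' Mean voltage of the (low-pass filtered) difference wave within a +/-10 ms
#' window around the estimated latency.
#'
#' @param filtered_wave low-pass filtered \code{\link{erp_waveform}}.
#' @param latency latency estimate in ms.
#' @param half_window half window width in ms.
#' @return amplitude in microvolt.
#' @export
mmn_amplitude <- function(filtered_wave, latency, half_window = 10) {
  t <- filtered_wave$times
  if (is.na(latency)) stop("latency is NA: no MMN detected")
  if (latency - half_window < min(t) || latency + half_window > max(t))
    stop("amplitude window truncated by the trial edge")
  sel <- t >= latency - half_window & t <= latency + half_window
  mean(filtered_wave$voltages[sel])
}
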