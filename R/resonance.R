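#' Chirp (ZAP) stimulus specification
#'
#' Describes the subthreshold frequency-sweep stimulus: a sinusoidal
#' current of fixed amplitude whose instantaneous frequency increases
#' linearly from `f_start` to `f_end` over `duration`. Defaults match the
#' standard protocol of +/-50 pA swept 0 to 15 Hz over 15 s.
#'
#' @param amplitude Peak current in pA (> 0).
#' @param f_start Start frequency in Hz (>= 0).
#' @param f_end End frequency in Hz (> f_start).
#' @param duration Sweep duration in s (> 0).
#' @return Object of class `"chirp_spec"`.
#' @export
chirp_spec <- function(amplitude = 50, f_start = 0, f_end = 15,
                       duration = 15) {
  if (!is.finite(amplitude) || amplitude <= 0)
    stop("chirp_spec: amplitude must be > 0")
  if (!is.finite(f_start) || f_start < 0 || f_end <= f_start)
    stop("chirp_spec: need 0 <= f_start < f_end")
  if (!is.finite(duration) || duration <= 0)
    stop("chirp_spec: duration must be > 0")
  structure(list(amplitude = amplitude, f_start = f_start, f_end = f_end,
                 duration = duration), class = "chirp_spec")
}

#' Generate a linear chirp current trace
#'
#' Builds `I(t) = A * sin(theta(t))` with phase
#' `theta(t) = 2*pi*(f_start*t + (f_end - f_start)*t^2/(2*T))`, the
#' standard linear ZAP. The sample interval must resolve the top
#' frequency (`dt <= 1/(2*f_end)`).
#'
#' @param spec A [chirp_spec()].
#' @param dt Sample interval in ms.
#' @return Current [trace()] in pA.
#' @export
make_chirp <- function(spec, dt) {
  stopifnot(inherits(spec, "chirp_spec"))
  if (dt * 1e-3 > 1 / (2 * spec$f_end))
    stop("make_chirp: dt = ", dt, " ms cannot resolve f_end = ",
         spec$f_end, " Hz (Nyquist)")
  t_s <- seq(0, spec$duration, by = dt * 1e-3)
  phase <- 2 * pi * (spec$f_start * t_s +
    (spec$f_end - spec$f_start) * t_s^2 / (2 * spec$duration))
  trace(spec$amplitude * sin(phase), dt = dt, unit = "pA")
}

#' Impedance amplitude profile from a chirp response
#'
#' Transforms the mean-subtracted voltage response and the current
#' stimulus into the frequency domain with an FFT and evaluates the
#' impedance on `band`. The default `"magnitude"` mode reports
#' `|V(f)/I(f)|`; `"real_ratio"` reports `Re(V(f))/Re(I(f))`, the
#' literal ratio of real parts, kept for comparability but numerically
#' fragile near zeros of `Re(I)`. With voltage in mV and current in pA
#' the ratio is in gigaohms and is reported as MOhm. Frequencies where
#' the stimulus has negligible power (|I(f)| below `floor_frac` of its
#' band maximum) are not evaluated.
#'
#' @param voltage Voltage [trace()] in mV.
#' @param current Current [trace()] in pA (same length and dt).
#' @param band Length-2 Hz interval to evaluate (default 0.5-15 Hz; the
#'   lower edge excludes the DC bin and leakage near 0 Hz).
#' @param mode `"magnitude"` (default) or `"real_ratio"`.
#' @param floor_frac Stimulus-power floor as a fraction of the band
#'   maximum of |I(f)|.
#' @return Object of class `"impedance_profile"`: list with `freqs` (Hz),
#'   `z` (MOhm), `band`, `mode`.
#' @export
impedance_profile <- function(voltage, current, band = c(0.5, 15),
                              mode = c("magnitude", "real_ratio"),
                              floor_frac = 0.01) {
  mode <- match.arg(mode)
  check_unit(voltage, "mV")
  check_unit(current, "pA")
  if (length(voltage$samples) != length(current$samples) ||
      abs(voltage$dt - current$dt) > 1e-12 * voltage$dt)
    stop("impedance_profile: voltage and current must share length and dt")
  n <- length(voltage$samples)
  fs <- 1000 / voltage$dt
  freqs <- (seq_len(n) - 1) * fs / n
  vf <- stats::fft(voltage$samples - mean(voltage$samples))
  cf <- stats::fft(current$samples)
  in_band <- which(freqs >= band[1] & freqs <= band[2])
  if (length(in_band) == 0L)
    stop("impedance_profile: no FFT bins on the requested band")
  # the floor guards the actual denominator: |I(f)| for the magnitude
  # ratio, |Re(I(f))| for the literal real-part ratio
  denom <- if (mode == "magnitude") Mod(cf) else abs(Re(cf))
  if (max(denom[in_band]) <= 0)
    stop("impedance_profile: stimulus has no power in band")
  floor_amp <- floor_frac * max(denom[in_band])
  keep <- in_band[denom[in_band] >= floor_amp]
  if (length(keep) == 0L)
    stop("impedance_profile: stimulus has no power in band")
  z <- if (mode == "magnitude") {
    1000 * Mod(vf[keep] / cf[keep])
  } else {
    1000 * Re(vf[keep]) / Re(cf[keep])
  }
  structure(list(freqs = freqs[keep], z = z, band = band, mode = mode),
            class = "impedance_profile")
}

#' @export
print.impedance_profile <- function(x, ...) {
  cat(sprintf(
    "<impedance_profile> %d points on [%.3g, %.3g] Hz, mode=%s\n",
    length(x$freqs), min(x$freqs), max(x$freqs), x$mode))
  invisible(x)
}

#' Peak resonance frequency of an impedance profile
#'
#' Fits a polynomial (default order 6) to impedance versus frequency on
#' `[band_low, max(freqs)]` and reports the frequency at which the
#' fitted curve is maximal, located on a dense grid; ties break toward
#' the lower frequency. A profile whose fitted maximum sits at the lower
#' band edge is monotone-decreasing over the band (a low-pass membrane)
#' and is flagged non-resonant.
#'
#' @param profile An [impedance_profile()].
#' @param poly_order Polynomial order for the fit.
#' @param band_low Lower edge of the evaluation band in Hz.
#' @param grid_step Spacing of the argmax search grid in Hz.
#' @return List with `peak_freq` (Hz), `resonant` (logical), `fit` (the
#'   `lm` object), and `grid` (data.frame of the fitted curve).
#' @export
peak_resonance_frequency <- function(profile, poly_order = 6,
                                     band_low = 0.5, grid_step = 0.01) {
  stopifnot(inherits(profile, "impedance_profile"))
  sel <- profile$freqs >= band_low
  f <- profile$freqs[sel]
  z <- profile$z[sel]
  if (length(f) < poly_order + 1)
    stop("peak_resonance_frequency: need at least ", poly_order + 1,
         " points for a degree-", poly_order, " fit, have ", length(f))
  fit <- stats::lm(z ~ stats::poly(f, degree = poly_order, raw = FALSE))
  grid_f <- seq(band_low, max(f), by = grid_step)
  pred <- stats::predict(fit, newdata = data.frame(f = grid_f))
  peak_i <- which.max(pred)           # which.max returns the first maximum
  peak_freq <- grid_f[peak_i]
  resonant <- peak_i > 1L
  list(peak_freq = peak_freq, resonant = resonant, fit = fit,
       grid = data.frame(freq = grid_f, z_fit = as.numeric(pred)))
}

#' Chirp resonance analysis of a voltage response
#'
#' Convenience wrapper: impedance profile plus peak resonance frequency.
#'
#' @inheritParams impedance_profile
#' @inheritParams peak_resonance_frequency
#' @return List with `profile`, `peak_freq`, `resonant`.
#' @export
resonance_analysis <- function(voltage, current, band = c(0.5, 15),
                               mode = c("magnitude", "real_ratio"),
                               poly_order = 6) {
  mode <- match.arg(mode)
  prof <- impedance_profile(voltage, current, band = band, mode = mode)
  pk <- peak_resonance_frequency(prof, poly_order = poly_order,
                                 band_low = band[1])
  list(profile = prof, peak_freq = pk$peak_freq, resonant = pk$resonant)
}
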