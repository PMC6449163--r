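# Internal: central-difference derivative of a voltage trace in mV/ms.
# Endpoints use one-sided differences so the vector keeps the trace length.
trace_dvdt <- function(tr) {
  v <- tr$samples
  n <- length(v)
  d <- numeric(n)
  if (n >= 3) d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * tr$dt)
  d[1] <- (v[2] - v[1]) / tr$dt
  d[n] <- (v[n] - v[n - 1]) / tr$dt
  d
}

#' Detect action potentials by level crossing
#'
#' Spikes are counted at upward crossings of `level` (default -20 mV);
#' each spike time is the local voltage maximum between the upward and
#' the following downward crossing. Detections closer together than
#' `min_isi` are merged, keeping the larger peak, which prevents double
#' counting on noisy repolarizations.
#'
#' @param tr Voltage [trace()] in mV.
#' @param level Detection level in mV.
#' @param min_isi Merge distance in ms.
#' @return Numeric vector of spike times (ms), possibly empty.
#' @export
detect_spikes <- function(tr, level = -20, min_isi = 2) {
  check_unit(tr, "mV")
  v <- tr$samples
  above <- v >= level
  up <- which(!above[-length(above)] & above[-1]) + 1L
  if (length(up) == 0L) return(numeric(0))
  times <- numeric(0)
  peaks <- numeric(0)
  tt <- trace_times(tr)
  for (s in up) {
    e <- s
    while (e < length(v) && above[e + 1L]) e <- e + 1L
    pk <- s - 1L + which.max(v[s:e])
    times <- c(times, tt[pk])
    peaks <- c(peaks, v[pk])
  }
  # merge detections closer than min_isi, keeping the taller peak
  out_t <- times[1]
  out_p <- peaks[1]
  for (k in seq_along(times)[-1]) {
    last <- length(out_t)
    if (times[k] - out_t[last] < min_isi) {
      if (peaks[k] > out_p[last]) {
        out_t[last] <- times[k]
        out_p[last] <- peaks[k]
      }
    } else {
      out_t <- c(out_t, times[k])
      out_p <- c(out_p, peaks[k])
    }
  }
  out_t
}

#' Action-potential waveform features
#'
#' Extracts the standard single-spike landmarks for a detected spike:
#'
#' * `threshold`: the membrane potential at the first sample, searching
#'   forward from `pre_search` ms before the -20 mV detection crossing,
#'   where the central-difference dV/dt reaches `dvdt_criterion`
#'   (default 20 mV/ms);
#' * `max_dvdt`: the maximum dV/dt between threshold and the peak;
#' * `amplitude`: peak voltage minus the resting membrane potential;
#' * `fahp`: the fast afterhyperpolarization, measured by scanning dV/dt
#'   from the threshold time: its first zero-crossing (+ to -) is the
#'   spike peak and the second (- to +) is the trough; the fAHP
#'   amplitude is threshold voltage minus trough voltage (positive when
#'   the trough undershoots threshold). If no second crossing occurs
#'   within `fahp_window` ms after the peak, the fAHP is reported absent
#'   (`NA`).
#'
#' @param tr Voltage [trace()] in mV.
#' @param peak_time A spike time from [detect_spikes()] (ms).
#' @param rmp Resting membrane potential in mV (amplitude reference).
#' @param dvdt_criterion Threshold slope criterion in mV/ms.
#' @param fahp_window Maximum peak-to-trough delay in ms.
#' @param level Detection level used to find the crossing (mV).
#' @param pre_search How far before the crossing the threshold search
#'   starts (ms).
#' @return List with `peak_time`, `threshold`, `max_dvdt`, `amplitude`,
#'   `fahp`, `fahp_time` (the last two `NA` when absent).
#' @export
ap_waveform_features <- function(tr, peak_time, rmp, dvdt_criterion = 20,
                                 fahp_window = 1.5, level = -20,
                                 pre_search = 3) {
  check_unit(tr, "mV")
  tt <- trace_times(tr)
  dv <- trace_dvdt(tr)
  pk <- which.min(abs(tt - peak_time))
  # locate the upward level crossing that precedes this peak
  before <- which(tr$samples[seq_len(pk - 1L)] < level)
  cross <- if (length(before) > 0L) max(before) + 1L else 1L
  start <- max(1L, cross - round(pre_search / tr$dt))
  seg <- start:pk
  hit <- seg[dv[seg] >= dvdt_criterion]
  if (length(hit) == 0L)
    stop("ap_waveform_features: dV/dt never reached ", dvdt_criterion,
         " mV/ms before the spike at ", peak_time, " ms")
  thr_i <- hit[1]
  max_dvdt <- max(dv[thr_i:pk])
  # scan from threshold for the two dV/dt zero-crossings
  s <- sign(dv)
  peak_i <- NA_integer_
  trough_i <- NA_integer_
  i <- thr_i
  while (i < length(dv)) {
    if (is.na(peak_i) && s[i] > 0 && s[i + 1L] <= 0) {
      peak_i <- i + 1L
    } else if (!is.na(peak_i) && s[i] < 0 && s[i + 1L] >= 0) {
      trough_i <- i + 1L
      break
    }
    i <- i + 1L
  }
  fahp <- NA_real_
  fahp_time <- NA_real_
  if (!is.na(peak_i) && !is.na(trough_i) &&
      tt[trough_i] - tt[peak_i] <= fahp_window) {
    fahp <- tr$samples[thr_i] - tr$samples[trough_i]
    fahp_time <- tt[trough_i]
  }
  list(peak_time = tt[pk], threshold = tr$samples[thr_i],
       max_dvdt = max_dvdt, amplitude = tr$samples[pk] - rmp,
       fahp = fahp, fahp_time = fahp_time)
}

#' Spike-train features: ISIs and accommodation ratio
#'
#' Interspike intervals are successive differences of the spike times.
#' The spike-frequency accommodation (SFA) ratio compares the sixth
#' interval to the first; it is reported only for trains with at least
#' seven spikes (six intervals). Published descriptions of this ratio
#' disagree on its direction, so the reciprocal is available via
#' `convention = "isi1_over_isi6"` rather than chosen silently.
#'
#' @param spike_times Sorted spike times in ms.
#' @param convention `"isi6_over_isi1"` (default) or `"isi1_over_isi6"`.
#' @return List with `spike_times`, `isis`, `sfa` (`NA` when < 7 spikes),
#'   `count`, `convention`.
#' @export
train_features <- function(spike_times,
                           convention = c("isi6_over_isi1",
                                          "isi1_over_isi6")) {
  convention <- match.arg(convention)
  if (is.unsorted(spike_times, strictly = TRUE))
    stop("train_features: spike_times must be strictly increasing")
  isis <- diff(spike_times)
  sfa <- NA_real_
  if (length(spike_times) >= 7L) {
    sfa <- if (convention == "isi6_over_isi1") isis[6] / isis[1]
           else isis[1] / isis[6]
  }
  list(spike_times = spike_times, isis = isis, sfa = sfa,
       count = length(spike_times), convention = convention)
}

# Internal: spike count inside the step window of one sweep.
sweep_spike_count <- function(sw, level = -20) {
  st <- detect_spikes(sw$voltage, level = level)
  ep <- sw$epoch
  sum(st >= ep$onset & st <= ep$onset + ep$duration)
}

#' FI curve: spike count versus injected current
#'
#' For each requested step amplitude, counts the action potentials fired
#' within the step window of the matching sweep.
#'
#' @param ss A [sweep_set()] of suprathreshold steps.
#' @param amplitudes pA amplitudes to report (default 100 to 500 in
#'   50-pA increments).
#' @param level Spike detection level (mV).
#' @return List with `amplitudes` and `counts` (class `"fi_curve"`).
#' @export
fi_curve <- function(ss, amplitudes = seq(100, 500, by = 50),
                     level = -20) {
  stopifnot(inherits(ss, "sweep_set"))
  amps <- sweep_amplitudes(ss)
  idx <- vapply(amplitudes, function(a) {
    hit <- which(abs(amps - a) < 1e-6)
    if (length(hit) == 0L) NA_integer_ else hit[1]
  }, integer(1))
  if (anyNA(idx))
    stop("fi_curve: no sweep at amplitude(s) ",
         paste(amplitudes[is.na(idx)], collapse = ", "), " pA")
  counts <- vapply(idx, function(i) sweep_spike_count(ss$sweeps[[i]],
                                                      level = level),
                   numeric(1))
  structure(list(amplitudes = amplitudes, counts = as.integer(counts)),
            class = "fi_curve")
}

#' Select sweeps with a spike count in a given range
#'
#' Returns the (1-based) indices of sweeps whose in-step spike count
#' falls inside `count_range` inclusive; the 8-11-spike default selects
#' trains from the middle of the response curve for waveform analysis.
#'
#' @param ss A [sweep_set()].
#' @param count_range Length-2 inclusive integer interval.
#' @param level Spike detection level (mV).
#' @return Integer vector of sweep indices (possibly empty).
#' @export
select_trains <- function(ss, count_range = c(8, 11), level = -20) {
  stopifnot(inherits(ss, "sweep_set"))
  counts <- vapply(ss$sweeps, sweep_spike_count, numeric(1), level = level)
  which(counts >= count_range[1] & counts <= count_range[2])
}
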