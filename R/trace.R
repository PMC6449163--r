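#' Uniformly sampled signal with a unit tag
#'
#' A `trace` is the package's elementary signal container: a uniformly
#' sampled scalar time series with a start time, a sample interval, and a
#' declared physical unit. Time is carried as `(t0, dt, n)` rather than an
#' explicit time column so resampling inconsistencies cannot arise; times
#' are reconstructed on demand with [trace_times()].
#'
#' Canonical units throughout the package are millivolts (`"mV"`) for
#' membrane voltage, picoamperes (`"pA"`) for injected current, and
#' microvolts (`"uV"`) for EEG. Operations that require a particular unit
#' check the tag and fail before computing anything.
#'
#' @param samples Numeric vector of sample values (non-empty, finite or NA).
#' @param dt Sample interval in milliseconds (> 0).
#' @param t0 Time of the first sample in milliseconds.
#' @param unit One of `"mV"`, `"pA"`, `"uV"`.
#' @return An object of class `"trace"`.
#' @examples
#' tr <- trace(rep(-65, 1000), dt = 0.1, unit = "mV")
#' trace_duration(tr)
#' @export
trace <- function(samples, dt, t0 = 0, unit = c("mV", "pA", "uV")) {
  unit <- match.arg(unit)
  if (!is.numeric(samples) || length(samples) == 0L)
    stop("trace: `samples` must be a non-empty numeric vector")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("trace: `dt` must be a single positive number (ms)")
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0))
    stop("trace: `t0` must be a single finite number (ms)")
  structure(
    list(samples = as.numeric(samples), dt = as.numeric(dt),
         t0 = as.numeric(t0), unit = unit),
    class = "trace"
  )
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %d samples @ dt=%g ms, t0=%g ms, unit=%s\n",
              length(x$samples), x$dt, x$t0, x$unit))
  invisible(x)
}

#' Sample times of a trace
#' @param tr A [trace()].
#' @return Numeric vector of sample times in ms.
#' @export
trace_times <- function(tr) {
  stopifnot(inherits(tr, "trace"))
  tr$t0 + (seq_along(tr$samples) - 1) * tr$dt
}

#' Trace duration in milliseconds
#' @param tr A [trace()].
#' @export
trace_duration <- function(tr) {
  stopifnot(inherits(tr, "trace"))
  (length(tr$samples) - 1) * tr$dt
}

# Internal: demand a unit tag before any computation touches the samples.
check_unit <- function(tr, unit, what = deparse(substitute(tr))) {
  if (!inherits(tr, "trace"))
    stop(sprintf("%s: expected a trace object", what))
  if (tr$unit != unit)
    stop(sprintf("%s: expected unit '%s' but trace is tagged '%s'",
                 what, unit, tr$unit))
  invisible(tr)
}

# Internal: indices of samples whose time lies in [from, to] (ms).
window_index <- function(tr, from, to) {
  tt <- trace_times(tr)
  which(tt >= from & tt <= to)
}

#' Square current-step epoch
#'
#' Describes the command step of one sweep: onset and duration in ms and
#' amplitude in pA (relative to the holding current).
#'
#' @param onset Step onset in ms (>= 0).
#' @param duration Step duration in ms (> 0).
#' @param amplitude Step amplitude in pA.
#' @return An object of class `"step_epoch"`.
#' @export
step_epoch <- function(onset, duration, amplitude) {
  if (!is.finite(onset) || onset < 0) stop("step_epoch: onset must be >= 0")
  if (!is.finite(duration) || duration <= 0)
    stop("step_epoch: duration must be > 0")
  if (!is.finite(amplitude)) stop("step_epoch: amplitude must be finite")
  structure(list(onset = as.numeric(onset), duration = as.numeric(duration),
                 amplitude = as.numeric(amplitude)),
            class = "step_epoch")
}

#' Family of paired voltage/command sweeps
#'
#' A `sweep_set` bundles the sweeps of one protocol run: each sweep is a
#' voltage trace (mV), the matching command trace (pA), and a
#' [step_epoch()] describing the injected step. All sweeps must share the
#' sampling interval and length. Free-form metadata (e.g. `protocol`,
#' `fs_hz`, a recorded-but-uncorrected liquid junction potential) rides
#' along in `metadata`.
#'
#' @param sweeps List of sweeps; each a list with elements `voltage`
#'   (trace, mV), `command` (trace, pA), `epoch` ([step_epoch()]).
#' @param metadata Named list of free-form metadata.
#' @return An object of class `"sweep_set"`.
#' @export
sweep_set <- function(sweeps, metadata = list()) {
  if (!is.list(sweeps) || length(sweeps) == 0L)
    stop("sweep_set: need at least one sweep")
  for (i in seq_along(sweeps)) {
    sw <- sweeps[[i]]
    if (!all(c("voltage", "command", "epoch") %in% names(sw)))
      stop(sprintf("sweep_set: sweep %d lacks voltage/command/epoch", i))
    check_unit(sw$voltage, "mV", sprintf("sweep %d voltage", i))
    check_unit(sw$command, "pA", sprintf("sweep %d command", i))
    if (!inherits(sw$epoch, "step_epoch"))
      stop(sprintf("sweep_set: sweep %d epoch is not a step_epoch", i))
    if (length(sw$voltage$samples) != length(sw$command$samples))
      stop(sprintf("sweep_set: sweep %d voltage/command length mismatch", i))
    ep <- sw$epoch
    if (ep$onset + ep$duration >
        trace_duration(sw$voltage) + sw$voltage$dt / 2)
      stop(sprintf("sweep_set: sweep %d epoch extends past the trace", i))
  }
  dts <- vapply(sweeps, function(s) s$voltage$dt, numeric(1))
  lens <- vapply(sweeps, function(s) length(s$voltage$samples), integer(1))
  if (max(dts) - min(dts) > 1e-12 * max(dts))
    stop("sweep_set: mixed sampling rates across sweeps (dt differs)")
  if (length(unique(lens)) != 1L)
    stop("sweep_set: sweeps differ in length")
  structure(list(sweeps = sweeps, metadata = metadata), class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  amps <- vapply(x$sweeps, function(s) s$epoch$amplitude, numeric(1))
  cat(sprintf("<sweep_set> %d sweeps, dt=%g ms, amplitudes [%s] pA\n",
              length(x$sweeps), x$sweeps[[1]]$voltage$dt,
              paste(format(amps), collapse = ", ")))
  invisible(x)
}

#' Sweep step amplitudes
#' @param ss A [sweep_set()].
#' @return Numeric vector of step amplitudes (pA), one per sweep.
#' @export
sweep_amplitudes <- function(ss) {
  stopifnot(inherits(ss, "sweep_set"))
  vapply(ss$sweeps, function(s) s$epoch$amplitude, numeric(1))
}

#' Multi-channel EEG record
#'
#' Named EEG channels in microvolts sharing one sampling rate.
#'
#' @param channels Named list of [trace()] objects tagged `"uV"`, all of
#'   equal length.
#' @param fs Sampling rate in Hz (> 0).
#' @return An object of class `"eeg_record"`.
#' @export
eeg_record <- function(channels, fs) {
  if (!is.list(channels) || length(channels) == 0L)
    stop("eeg_record: need at least one channel")
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("eeg_record: channels must be named")
  if (!is.finite(fs) || fs <= 0) stop("eeg_record: fs must be > 0")
  for (nm in names(channels))
    check_unit(channels[[nm]], "uV", sprintf("channel '%s'", nm))
  lens <- vapply(channels, function(ch) length(ch$samples), integer(1))
  if (length(unique(lens)) != 1L)
    stop("eeg_record: channels differ in length")
  structure(list(channels = channels, fs = as.numeric(fs)),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  n <- length(x$channels[[1]]$samples)
  cat(sprintf("<eeg_record> %d channel(s) [%s], %g s @ %g Hz\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              n / x$fs, x$fs))
  invisible(x)
}
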