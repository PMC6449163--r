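#' Sliding-window power of an EEG channel
#'
#' Computes the signal power in a sliding window (default 3 s, stepped
#' by 15 ms — exactly 12 samples at 800 Hz). Power is defined as the
#' within-window variance (mean squared deviation from the window mean,
#' in microvolts squared), which makes the measure insensitive to
#' electrode DC drift. Windows are left-aligned; a trailing partial
#' window is dropped.
#'
#' @param channel EEG [trace()] in uV.
#' @param window Window length in s.
#' @param step Step size in s.
#' @return Object of class `"power_series"`: list with `window_starts`
#'   (s), `power` (uV^2), `window`, `step`.
#' @export
sliding_window_power <- function(channel, window = 3, step = 0.015) {
  check_unit(channel, "uV")
  fs <- 1000 / channel$dt
  x <- channel$samples
  n <- length(x)
  wlen <- round(window * fs)
  slen <- max(1L, round(step * fs))
  if (wlen > n)
    stop("sliding_window_power: record (", n / fs,
         " s) shorter than the window (", window, " s)")
  starts <- seq(1L, n - wlen + 1L, by = slen)
  # O(n) rolling moments via cumulative sums
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  sum1 <- cs[starts + wlen] - cs[starts]
  sum2 <- cs2[starts + wlen] - cs2[starts]
  pw <- sum2 / wlen - (sum1 / wlen)^2
  pw[pw < 0] <- 0  # guard against cumsum round-off on constant signals
  structure(list(window_starts = (starts - 1L) / fs, power = pw,
                 window = window, step = step),
            class = "power_series")
}

#' Flag seizure-candidate intervals by power threshold
#'
#' Maximal runs of windows whose power is strictly above `threshold`
#' (a window sitting exactly at the threshold never flags) become
#' candidate intervals spanning the union of their member windows;
#' intervals that overlap in time are merged. These are candidates for
#' inspection — confirming an electrographic seizure (and its
#' behavioral correlate) is outside the detector's scope.
#'
#' @param power A [sliding_window_power()] result.
#' @param threshold Power threshold in uV^2 (default 100).
#' @return data.frame with columns `start` (s), `end` (s),
#'   `peak_power` (uV^2); zero rows when nothing flags.
#' @export
flag_candidates <- function(power, threshold = 100) {
  stopifnot(inherits(power, "power_series"))
  hot <- power$power > threshold
  if (!any(hot))
    return(data.frame(start = numeric(0), end = numeric(0),
                      peak_power = numeric(0)))
  r <- rle(hot)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  hot_runs <- which(r$values)
  iv <- data.frame(
    start = power$window_starts[run_start[hot_runs]],
    end = power$window_starts[run_end[hot_runs]] + power$window,
    peak_power = vapply(hot_runs, function(k) {
      max(power$power[run_start[k]:run_end[k]])
    }, numeric(1))
  )
  # merge intervals that overlap (window length exceeds the run gap)
  merged <- iv[1, ]
  for (k in seq_len(nrow(iv))[-1]) {
    last <- nrow(merged)
    if (iv$start[k] <= merged$end[last]) {
      merged$end[last] <- max(merged$end[last], iv$end[k])
      merged$peak_power[last] <- max(merged$peak_power[last],
                                     iv$peak_power[k])
    } else {
      merged <- rbind(merged, iv[k, ])
    }
  }
  rownames(merged) <- NULL
  merged
}

#' Detect seizure candidates across all channels of a record
#'
#' Runs [sliding_window_power()] and [flag_candidates()] per channel.
#'
#' @param rec An [eeg_record()].
#' @param window,step,threshold Passed through to the two stages.
#' @return data.frame with columns `channel`, `start`, `end`,
#'   `peak_power`.
#' @export
detect_seizure_candidates <- function(rec, window = 3, step = 0.015,
                                      threshold = 100) {
  stopifnot(inherits(rec, "eeg_record"))
  out <- lapply(names(rec$channels), function(nm) {
    pw <- sliding_window_power(rec$channels[[nm]], window = window,
                               step = step)
    iv <- flag_candidates(pw, threshold = threshold)
    if (nrow(iv) == 0L) return(NULL)
    cbind(channel = nm, iv)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L)
    return(data.frame(channel = character(0), start = numeric(0),
                      end = numeric(0), peak_power = numeric(0)))
  do.call(rbind, out)
}
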