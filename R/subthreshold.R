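#' Resting membrane potential from a baseline window
#'
#' Mean membrane voltage over a pre-stimulus window. The recordings this
#' targets hold the cell near rest before the step, so an averaged
#' baseline is the natural estimator; it is robust to sample noise with
#' standard error sigma/sqrt(n).
#'
#' @param tr Voltage [trace()] in mV.
#' @param baseline Length-2 numeric, window `c(from, to)` in ms.
#' @return RMP in mV.
#' @export
resting_membrane_potential <- function(tr, baseline) {
  check_unit(tr, "mV")
  if (length(baseline) != 2L || baseline[2] <= baseline[1])
    stop("resting_membrane_potential: baseline must be c(from, to), to > from")
  idx <- window_index(tr, baseline[1], baseline[2])
  if (length(idx) == 0L)
    stop("resting_membrane_potential: baseline window contains no samples")
  mean(tr$samples[idx])
}

# Internal: coefficient of determination, computed directly (avoids
# summary.lm's perfect-fit warning on exact synthetic data).
ols_r_squared <- function(fit, y) {
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(1)
  1 - sum(stats::residuals(fit)^2) / tss
}

# Internal: baseline mean (last `width` ms before the step onset) and
# steady-state mean (last `width` ms of the step) for one sweep.
sweep_step_levels <- function(sw, width = 100) {
  ep <- sw$epoch
  v <- sw$voltage
  b0 <- max(v$t0, ep$onset - width)
  base_idx <- window_index(v, b0, ep$onset - v$dt / 2)
  off <- ep$onset + ep$duration
  ss_idx <- window_index(v, off - width, off - v$dt / 2)
  if (length(base_idx) == 0L || length(ss_idx) == 0L)
    stop("sweep has no samples in the baseline or steady-state window")
  list(baseline = mean(v$samples[base_idx]),
       steady = mean(v$samples[ss_idx]))
}

# Internal: sweeps whose voltage contains action potentials (any detected
# spike at the given level). Used by the exclusion rule shared by the
# subthreshold measurements.
spiking_sweeps <- function(ss, level = -20) {
  which(vapply(ss$sweeps, function(sw) {
    length(detect_spikes(sw$voltage, level = level)) > 0L
  }, logical(1)))
}

#' Input resistance from a step family
#'
#' The steady-state voltage deflection of each sweep (mean over the last
#' 100 ms of the step minus the pre-step baseline mean) is plotted
#' against the injected current amplitude over `current_range`
#' (default -70 to 10 pA), and the slope of an ordinary least-squares fit
#' is reported as the input resistance. A slope in mV/pA is a resistance
#' in gigaohms, so the reported value is `1000 * slope` megaohms.
#' Sweeps in which action potentials were generated are excluded before
#' fitting and reported.
#'
#' @param ss A [sweep_set()] of current steps.
#' @param current_range Length-2 pA interval of amplitudes to use.
#' @param steady_window Averaging window width in ms for baseline and
#'   steady state.
#' @param spike_level Detection level (mV) for the spike-exclusion screen.
#' @return List with `rin_mohm`, `r_squared`, `slope_mv_per_pa`,
#'   `sweeps_used`, `sweeps_excluded`, and the per-sweep `delta_v` table.
#' @export
input_resistance <- function(ss, current_range = c(-70, 10),
                             steady_window = 100, spike_level = -20) {
  stopifnot(inherits(ss, "sweep_set"))
  amps <- sweep_amplitudes(ss)
  in_range <- which(amps >= current_range[1] & amps <= current_range[2])
  spikers <- intersect(spiking_sweeps(ss, level = spike_level), in_range)
  used <- setdiff(in_range, spikers)
  if (length(used) < 2L)
    stop("input_resistance: fewer than 2 usable sweeps in range [",
         current_range[1], ", ", current_range[2], "] pA (excluded: ",
         if (length(spikers)) paste(spikers, collapse = ", ") else "none",
         ")")
  dv <- vapply(used, function(i) {
    lv <- sweep_step_levels(ss$sweeps[[i]], width = steady_window)
    lv$steady - lv$baseline
  }, numeric(1))
  fit <- stats::lm(dv ~ amps[used])
  slope <- unname(stats::coef(fit)[2])
  r2 <- ols_r_squared(fit, dv)
  list(rin_mohm = 1000 * slope, r_squared = r2, slope_mv_per_pa = slope,
       sweeps_used = used, sweeps_excluded = spikers,
       delta_v = data.frame(sweep = used, amplitude_pa = amps[used],
                            delta_v_mv = dv))
}

#' Rebound slope from hyperpolarizing steps
#'
#' For each hyperpolarizing, spike-free sweep, the rebound depolarization
#' amplitude (peak of voltage minus baseline in a window after step
#' offset) is plotted against the membrane potential at the end of the
#' step (mean over its last `end_window` ms), and the slope of a linear
#' fit is the rebound slope (mV/mV). A memoryless membrane rebounds to
#' baseline and gives slope 0; hyperpolarization-activated (sag/rebound)
#' machinery makes deeper steps rebound further, giving a negative slope.
#'
#' @param ss A [sweep_set()] of current steps.
#' @param post_window Window after step offset in which the rebound peak
#'   is sought (ms).
#' @param end_window Averaging window for the end-of-step potential (ms).
#' @param baseline_window Pre-step baseline averaging width (ms).
#' @param spike_level Detection level (mV) for the spike screen.
#' @return List with `slope_mv_per_mv`, `r_squared`, `sweeps_used`,
#'   `sweeps_excluded`, and the per-sweep `points` table.
#' @export
rebound_slope <- function(ss, post_window = 400, end_window = 10,
                          baseline_window = 100, spike_level = -20) {
  stopifnot(inherits(ss, "sweep_set"))
  amps <- sweep_amplitudes(ss)
  hyper <- which(amps < 0)
  spikers <- intersect(spiking_sweeps(ss, level = spike_level), hyper)
  used <- setdiff(hyper, spikers)
  if (length(used) < 2L)
    stop("rebound_slope: fewer than 2 usable hyperpolarizing sweeps")
  pts <- lapply(used, function(i) {
    sw <- ss$sweeps[[i]]
    ep <- sw$epoch
    v <- sw$voltage
    base <- sweep_step_levels(sw, width = baseline_window)$baseline
    off <- ep$onset + ep$duration
    end_idx <- window_index(v, off - end_window, off - v$dt / 2)
    post_idx <- window_index(v, off + v$dt / 2, off + post_window)
    if (length(post_idx) == 0L)
      stop("rebound_slope: sweep ", i, " has no samples after step offset")
    c(end_v = mean(v$samples[end_idx]),
      rebound = max(v$samples[post_idx] - base))
  })
  pts <- do.call(rbind, pts)
  fit <- stats::lm(pts[, "rebound"] ~ pts[, "end_v"])
  list(slope_mv_per_mv = unname(stats::coef(fit)[2]),
       r_squared = ols_r_squared(fit, pts[, "rebound"]),
       sweeps_used = used, sweeps_excluded = spikers,
       points = data.frame(sweep = used, end_v_mv = pts[, "end_v"],
                           rebound_mv = pts[, "rebound"]))
}

#' Combined subthreshold feature set for one cell
#'
#' Convenience wrapper running [resting_membrane_potential()] (on the
#' pre-step baseline of the first sweep), [input_resistance()], and
#' [rebound_slope()] on one step family.
#'
#' @param ss A [sweep_set()] of current steps.
#' @param current_range pA interval for the Rin fit.
#' @param post_window Rebound search window (ms).
#' @return List with `rmp_mv`, `rin_mohm`, `rin_r_squared`,
#'   `rebound_slope_mv_per_mv`, `sweeps_used`, `sweeps_excluded`.
#' @export
subthreshold_features <- function(ss, current_range = c(-70, 10),
                                  post_window = 400) {
  stopifnot(inherits(ss, "sweep_set"))
  sw1 <- ss$sweeps[[1]]
  rmp <- resting_membrane_potential(
    sw1$voltage, c(max(sw1$voltage$t0, sw1$epoch$onset - 100),
                   sw1$epoch$onset - sw1$voltage$dt / 2))
  rin <- input_resistance(ss, current_range = current_range)
  reb <- tryCatch(rebound_slope(ss, post_window = post_window),
                  error = function(e) NULL)
  list(rmp_mv = rmp,
       rin_mohm = rin$rin_mohm,
       rin_r_squared = rin$r_squared,
       rebound_slope_mv_per_mv =
         if (is.null(reb)) NA_real_ else reb$slope_mv_per_mv,
       sweeps_used = rin$sweeps_used,
       sweeps_excluded = rin$sweeps_excluded)
}
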