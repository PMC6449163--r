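# Internal: evaluate `code` under a fixed RNG seed, restoring the
# caller's RNG state afterwards so generators are pure in (params, seed).
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Parameters of the resonant model neuron
#'
#' The synthetic membrane is a generalized (resonant) integrate-and-fire
#' model: a leaky capacitor coupled to one slow feedback current,
#'
#' `C dV/dt = -g_L (V - E_L) - g_1 w + I(t)`,
#' `tau_1 dw/dt = (V - E_L) - w`,
#'
#' the simplest model whose impedance has a closed form with an interior
#' resonance peak (see [closed_form_impedance()]). Its DC input
#' resistance is `1/(g_L + g_1)`. Optional threshold/reset spiking with
#' adaptation turns it into a spiking model with an exact spike log.
#'
#' @param C Capacitance in pF (> 0).
#' @param g_L Leak conductance in nS (> 0).
#' @param g_1 Feedback (resonant) conductance in nS (>= 0).
#' @param tau_1 Feedback time constant in ms (>= 0).
#' @param E_L Resting potential in mV.
#' @param spike Optional list enabling spiking: `V_T` (threshold mV),
#'   `V_reset` (reset mV), `b` (adaptation increment added to the
#'   feedback variable per spike, mV-equivalent), `refractory` (ms).
#' @return Object of class `"resonant_neuron_params"`.
#' @export
resonant_neuron_params <- function(C = 200, g_L = 15, g_1 = 25,
                                   tau_1 = 50, E_L = -68, spike = NULL) {
  if (C <= 0 || g_L <= 0) stop("resonant_neuron_params: need C, g_L > 0")
  if (g_1 < 0 || tau_1 < 0)
    stop("resonant_neuron_params: need g_1, tau_1 >= 0")
  if (!is.null(spike)) {
    spike <- utils::modifyList(
      list(V_T = -50, V_reset = -65, b = 0, refractory = 2), spike)
    if (spike$V_T <= E_L)
      stop("resonant_neuron_params: spike threshold must exceed E_L")
  }
  structure(list(C = C, g_L = g_L, g_1 = g_1, tau_1 = tau_1, E_L = E_L,
                 spike = spike), class = "resonant_neuron_params")
}

#' Demonstration parameter presets
#'
#' `"dorsal-like"` has the stronger feedback conductance (resonance in
#' the 4-Hz region), `"ventral-like"` the weaker one (nearer 3 Hz).
#' These are illustrative presets for demos and carry no quantitative
#' claim about any recorded population.
#'
#' @param name `"dorsal-like"` or `"ventral-like"`.
#' @return A [resonant_neuron_params()].
#' @export
neuron_preset <- function(name = c("dorsal-like", "ventral-like")) {
  name <- match.arg(name)
  switch(name,
    "dorsal-like" = resonant_neuron_params(C = 180, g_L = 14, g_1 = 32,
                                           tau_1 = 42, E_L = -68),
    "ventral-like" = resonant_neuron_params(C = 200, g_L = 12, g_1 = 14,
                                            tau_1 = 60, E_L = -64))
}

#' Closed-form impedance of the resonant model neuron
#'
#' The subthreshold system is linear, so its impedance is
#' `Z(w) = 1 / (g_L + i*w*C + g_1 / (1 + i*w*tau_1))` with `w = 2*pi*f`.
#' Returned as a magnitude in MOhm. This is the analytic oracle the
#' chirp-based measurement is tested against: at f = 0 it reduces to
#' the DC resistance `1/(g_L + g_1)`, and with `g_1 = 0` to the RC
#' low-pass form `1/|g_L + i*w*C|`.
#'
#' @param p A [resonant_neuron_params()].
#' @param f Frequency (Hz), vectorized.
#' @return |Z(f)| in MOhm.
#' @export
closed_form_impedance <- function(p, f) {
  stopifnot(inherits(p, "resonant_neuron_params"))
  w_ms <- 2 * pi * f * 1e-3  # rad per ms
  y <- p$g_L + 1i * w_ms * p$C +
    if (p$tau_1 > 0) p$g_1 / (1 + 1i * w_ms * p$tau_1) else p$g_1
  1000 / Mod(y)
}

# Internal: frequency (Hz) maximizing |Z| on [f_lo, f_hi], dense grid.
impedance_argmax <- function(p, f_lo = 0.5, f_hi = 15, step = 0.001) {
  f <- seq(f_lo, f_hi, by = step)
  f[which.max(closed_form_impedance(p, f))]
}

# Internal: 2x2 matrix exponential by scaling-and-squaring Taylor.
expm_2x2 <- function(A) {
  nrm <- max(abs(A))
  s <- if (nrm > 0.5) ceiling(log2(nrm / 0.5)) else 0L
  As <- A / 2^s
  E <- diag(2)
  term <- diag(2)
  for (k in 1:16) {
    term <- term %*% As / k
    E <- E + term
  }
  for (k in seq_len(s)) E <- E %*% E
  E
}

# Fixed stereotyped action-potential waveform pasted by the spiking
# simulator: rise V_T -> AP_PEAK at AP_RISE mV/ms, fall to V_reset at
# AP_FALL mV/ms. Keeps spikes visible to a -20 mV detector while the
# subthreshold dynamics stay linear.
AP_PEAK <- 30
AP_RISE <- 150
AP_FALL <- 100

# Internal: per-spike dead time (template + refractory) in ms.
spike_dead_time <- function(p, dt) {
  sp <- p$spike
  n_rise <- ceiling((AP_PEAK - sp$V_T) / (AP_RISE * dt))
  n_fall <- ceiling((AP_PEAK - sp$V_reset) / (AP_FALL * dt))
  n_ref <- round(sp$refractory / dt)
  (n_rise + n_fall + n_ref) * dt
}

#' Simulate the resonant model neuron under an arbitrary current
#'
#' Integrates the two-variable linear subthreshold system with an
#' exact-exponential update per sample (the input is held constant over
#' each step), which is unconditionally stable for stiff parameter
#' draws. When spiking is enabled, a threshold crossing is logged, a
#' stereotyped spike waveform is pasted into the voltage trace, and
#' integration resumes from the reset potential after the refractory
#' period (with the adaptation increment added to the feedback
#' variable). Optional Gaussian observation noise is added to the
#' returned voltage only; it does not feed back into the dynamics or
#' the spike log. Identical (parameters, stimulus, seed) give identical
#' output.
#'
#' @param p A [resonant_neuron_params()].
#' @param stim Current [trace()] in pA.
#' @param seed Integer RNG seed (used only for observation noise).
#' @param noise_sd Observation noise SD in mV (default 0).
#' @param v0 Initial voltage (default `E_L`).
#' @return List with `voltage` (mV [trace()]), `spike_times` (ms),
#'   `dead_ms` (per-spike dead time, ms; `NA` when not spiking).
#' @export
simulate_neuron <- function(p, stim, seed = 1, noise_sd = 0,
                            v0 = p$E_L) {
  stopifnot(inherits(p, "resonant_neuron_params"))
  check_unit(stim, "pA")
  dt <- stim$dt
  tau_m <- p$C / p$g_L
  if (dt > tau_m / 10 || (p$tau_1 > 0 && dt > p$tau_1 / 10))
    stop("simulate_neuron: dt = ", dt, " ms too coarse for tau_m = ",
         signif(tau_m, 3), " ms / tau_1 = ", p$tau_1,
         " ms (need dt <= tau/10)")
  I <- stim$samples
  n <- length(I)
  tau1 <- if (p$tau_1 > 0) p$tau_1 else NA_real_
  if (is.na(tau1)) {
    # instantaneous feedback: w == V - E_L, a single-state leak g_L + g_1
    g_eff <- p$g_L + p$g_1
    a <- exp(-dt * g_eff / p$C)
    V <- numeric(n)
    V[1] <- v0
    vss_gain <- (1 - a) / g_eff
    for (i in seq_len(n - 1))
      V[i + 1] <- p$E_L + a * (V[i] - p$E_L) + vss_gain * I[i]
    W <- V - p$E_L
  } else {
    A <- matrix(c(-p$g_L / p$C, 1 / tau1, -p$g_1 / p$C, -1 / tau1), 2, 2)
    E <- expm_2x2(A * dt)
    M <- solve(A, E - diag(2))
    b0 <- c(p$g_L * p$E_L / p$C, -p$E_L / tau1)
    Mb0 <- as.numeric(M %*% b0)
    m1 <- M[, 1] / p$C
    V <- numeric(n)
    W <- numeric(n)
    V[1] <- v0
    W[1] <- 0
    e11 <- E[1, 1]; e12 <- E[1, 2]; e21 <- E[2, 1]; e22 <- E[2, 2]
    for (i in seq_len(n - 1)) {
      V[i + 1] <- e11 * V[i] + e12 * W[i] + Mb0[1] + m1[1] * I[i]
      W[i + 1] <- e21 * V[i] + e22 * W[i] + Mb0[2] + m1[2] * I[i]
    }
  }
  spike_times <- numeric(0)
  dead_ms <- NA_real_
  if (!is.null(p$spike)) {
    sp <- p$spike
    dead_ms <- spike_dead_time(p, dt)
    n_rise <- ceiling((AP_PEAK - sp$V_T) / (AP_RISE * dt))
    n_fall <- ceiling((AP_PEAK - sp$V_reset) / (AP_FALL * dt))
    n_ref <- round(sp$refractory / dt)
    rise <- sp$V_T + (AP_PEAK - sp$V_T) * seq_len(n_rise) / n_rise
    fall <- AP_PEAK - (AP_PEAK - sp$V_reset) * seq_len(n_fall) / n_fall
    template <- c(rise, fall, rep(sp$V_reset, n_ref))
    i <- 1L
    tt0 <- stim$t0
    while (i <= n) {
      if (V[i] >= sp$V_T) {
        spike_times <- c(spike_times, tt0 + (i - 1L) * dt)
        j <- min(n, i + length(template))
        if (j > i) V[(i + 1L):j] <- template[seq_len(j - i)]
        # resume integration from reset with the adaptation kick
        vi <- sp$V_reset
        wi <- if (is.na(tau1)) vi - p$E_L else W[i] + sp$b
        if (j < n) {
          V[j] <- vi
          W[j] <- wi
          for (k in j:(n - 1L)) {
            if (is.na(tau1)) {
              V[k + 1] <- p$E_L + a * (V[k] - p$E_L) + vss_gain * I[k]
              W[k + 1] <- V[k + 1] - p$E_L
            } else {
              V[k + 1] <- e11 * V[k] + e12 * W[k] + Mb0[1] + m1[1] * I[k]
              W[k + 1] <- e21 * V[k] + e22 * W[k] + Mb0[2] + m1[2] * I[k]
            }
            if (V[k + 1] >= sp$V_T) break
          }
        }
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  if (noise_sd > 0)
    V <- V + with_seed(seed, stats::rnorm(n, sd = noise_sd))
  list(voltage = trace(V, dt = dt, t0 = stim$t0, unit = "mV"),
       spike_times = spike_times, dead_ms = dead_ms)
}

#' Simulate a current-step sweep family
#'
#' Convenience wrapper building a [sweep_set()] from the model neuron:
#' one sweep per amplitude, each a baseline / 800-ms step / tail
#' protocol.
#'
#' @param p A [resonant_neuron_params()].
#' @param amplitudes Step amplitudes in pA.
#' @param onset,duration,tail Step timing in ms.
#' @param dt Sample interval in ms.
#' @param seed Seed for observation noise.
#' @param noise_sd Observation noise SD in mV.
#' @return A [sweep_set()] with metadata `protocol = "step"` and the
#'   ground-truth spike log per sweep in `metadata$spike_log`.
#' @export
synth_step_sweeps <- function(p, amplitudes, onset = 100,
                              duration = 800, tail = 500, dt = 0.25,
                              seed = 1, noise_sd = 0) {
  n <- round((onset + duration + tail) / dt) + 1L
  tt <- (seq_len(n) - 1) * dt
  spike_log <- vector("list", length(amplitudes))
  sweeps <- vector("list", length(amplitudes))
  for (k in seq_along(amplitudes)) {
    I <- ifelse(tt >= onset & tt < onset + duration, amplitudes[k], 0)
    stim <- trace(I, dt = dt, unit = "pA")
    sim <- simulate_neuron(p, stim, seed = seed + k,
                           noise_sd = noise_sd)
    spike_log[[k]] <- sim$spike_times
    sweeps[[k]] <- list(voltage = sim$voltage, command = stim,
                       epoch = step_epoch(onset, duration, amplitudes[k]))
  }
  sweep_set(sweeps, metadata = list(protocol = "step",
                                    spike_log = spike_log,
                                    dead_ms = if (is.null(p$spike))
                                      NA_real_ else spike_dead_time(p, dt)))
}

#' Simulate a chirp sweep
#'
#' Drives the model neuron with [make_chirp()] and wraps the result as a
#' one-sweep [sweep_set()] tagged `protocol = "chirp"`.
#'
#' @param p A [resonant_neuron_params()].
#' @param spec A [chirp_spec()].
#' @param dt Sample interval in ms.
#' @param seed Seed for observation noise.
#' @param noise_sd Observation noise SD in mV.
#' @return A [sweep_set()] with one sweep.
#' @export
synth_chirp_sweep <- function(p, spec = chirp_spec(), dt = 0.5,
                              seed = 1, noise_sd = 0) {
  stim <- make_chirp(spec, dt = dt)
  sim <- simulate_neuron(p, stim, seed = seed, noise_sd = noise_sd)
  sweep_set(list(list(voltage = sim$voltage, command = stim,
                      epoch = step_epoch(0, trace_duration(stim),
                                         spec$amplitude))),
            metadata = list(protocol = "chirp"))
}

#' Stylized action-potential template with programmed landmarks
#'
#' Builds a piecewise waveform whose landmarks equal the arguments by
#' construction, for exercising the waveform extractor against known
#' truth: a resting baseline, a quadratic depolarizing foot whose slope
#' reaches `foot_end_slope` exactly when the voltage reaches
#' `threshold`, a linear rise at `rise_slope` to `peak`, a linear fall
#' to `trough` over `trough_delay` ms, a small zero-initial-slope
#' afterdepolarization bump, and an exponential relaxation back to
#' `rmp`.
#'
#' @param threshold Programmed threshold in mV.
#' @param peak Peak voltage in mV (> threshold).
#' @param trough fAHP trough voltage in mV (< threshold).
#' @param rmp Resting potential in mV (< threshold).
#' @param rise_slope Rise slope in mV/ms.
#' @param trough_delay Peak-to-trough delay in ms.
#' @param foot_end_slope Foot slope at threshold in mV/ms (the
#'   conventional 20 mV/ms threshold criterion).
#' @param dt Sample interval in ms.
#' @param baseline Pre-foot baseline duration in ms.
#' @return List with `trace` (mV), `peak_time` (ms), and the programmed
#'   landmark values.
#' @export
synth_ap_template <- function(threshold = -50, peak = 30, trough = -58,
                              rmp = -65, rise_slope = 150,
                              trough_delay = 0.8, foot_end_slope = 20,
                              dt = 0.025, baseline = 5) {
  if (peak <= threshold)
    stop("synth_ap_template: peak must exceed threshold")
  if (trough >= threshold)
    stop("synth_ap_template: trough must be below threshold")
  if (rmp >= threshold)
    stop("synth_ap_template: rmp must be below threshold")
  if (rise_slope <= foot_end_slope)
    stop("synth_ap_template: rise_slope must exceed foot_end_slope")
  n_base <- round(baseline / dt)
  t_foot <- 2 * (threshold - rmp) / foot_end_slope
  n_foot <- max(2L, round(t_foot / dt))
  foot <- rmp + (threshold - rmp) * (seq_len(n_foot) / n_foot)^2
  n_rise <- max(2L, round((peak - threshold) / (rise_slope * dt)))
  rise <- threshold + (peak - threshold) * seq_len(n_rise) / n_rise
  n_fall <- max(2L, round(trough_delay / dt))
  fall <- peak - (peak - trough) * seq_len(n_fall) / n_fall
  n_adp <- max(2L, round(3 / dt))
  adp_amp <- min(3, (threshold - trough) / 2)
  adp <- trough + adp_amp * (seq_len(n_adp) / n_adp)^2
  n_rec <- round(10 / dt)
  rec_start <- trough + adp_amp
  rec <- rmp + (rec_start - rmp) * exp(-(seq_len(n_rec) * dt) / 4)
  v <- c(rep(rmp, n_base), foot, rise, fall, adp, rec)
  peak_time <- (n_base + n_foot + n_rise - 1) * dt
  list(trace = trace(v, dt = dt, unit = "mV"), peak_time = peak_time,
       threshold = threshold, peak = peak, trough = trough, rmp = rmp,
       rise_slope = rise_slope)
}

#' Seizure epoch specification for synthetic EEG
#'
#' @param start Epoch start in s.
#' @param duration Epoch duration in s (> 0).
#' @param rms Epoch RMS amplitude in uV (> 0).
#' @param carrier Carrier frequency in Hz.
#' @return Object of class `"seizure_epoch"`.
#' @export
seizure_epoch <- function(start, duration, rms, carrier = 8) {
  if (duration <= 0 || rms <= 0)
    stop("seizure_epoch: duration and rms must be > 0")
  structure(list(start = start, duration = duration, rms = rms,
                 carrier = carrier), class = "seizure_epoch")
}

#' Synthesize an EEG record with known seizure epochs
#'
#' The background is low-pass-filtered Gaussian noise (2nd-order
#' Butterworth, 30-Hz corner) rescaled to exactly `background_rms`;
#' each epoch adds an amplitude-modulated sinusoid (modulation depth
#' 0.5 at 0.7 Hz, normalized so the epoch RMS equals the requested
#' value on average). Ground-truth epoch intervals are returned with
#' the record. Identical seeds give identical samples.
#'
#' @param duration Record length in s.
#' @param fs Sampling rate in Hz (default 800).
#' @param background_rms Background RMS in uV.
#' @param epochs List of [seizure_epoch()] (non-overlapping).
#' @param seed Integer RNG seed.
#' @param channel Channel name.
#' @return List with `record` ([eeg_record()]) and `intervals`
#'   (data.frame `start`, `end` in s).
#' @export
synth_eeg <- function(duration, fs = 800, background_rms = 3,
                      epochs = list(), seed = 1, channel = "eeg1") {
  n <- round(duration * fs)
  if (length(epochs) > 1L) {
    ord <- order(vapply(epochs, `[[`, numeric(1), "start"))
    epochs <- epochs[ord]
    for (k in seq_len(length(epochs) - 1L)) {
      if (epochs[[k]]$start + epochs[[k]]$duration >
          epochs[[k + 1L]]$start)
        stop("synth_eeg: overlapping epochs")
    }
  }
  x <- with_seed(seed, {
    white <- stats::rnorm(n)
    bf <- signal::butter(2, 30 / (fs / 2), type = "low")
    bg <- signal::filtfilt(bf, white)
    bg * (background_rms / sqrt(mean(bg^2)))
  })
  tt <- (seq_len(n) - 1) / fs
  iv <- data.frame(start = numeric(0), end = numeric(0))
  for (ep in epochs) {
    if (!inherits(ep, "seizure_epoch"))
      stop("synth_eeg: epochs must be seizure_epoch objects")
    sel <- tt >= ep$start & tt < ep$start + ep$duration
    if (!any(sel)) next
    te <- tt[sel] - ep$start
    m <- 0.5
    env <- (1 + m * sin(2 * pi * 0.7 * te)) / sqrt(1 + m^2 / 2)
    x[sel] <- x[sel] +
      sqrt(2) * ep$rms * env * sin(2 * pi * ep$carrier * te)
    iv <- rbind(iv, data.frame(start = ep$start,
                               end = ep$start + ep$duration))
  }
  ch <- list(trace(x, dt = 1000 / fs, unit = "uV"))
  names(ch) <- channel
  list(record = eeg_record(ch, fs = fs), intervals = iv)
}

#' Random dendritic morphology
#'
#' Grows a random binary tree rooted at a soma node at the origin:
#' `depth` bifurcation levels, segment lengths drawn around
#' `mean_segment`, directions jittered around the parent direction, and
#' radii tapering with depth. One stem is typed apical (4), the other
#' basal (3). `depth = 0` yields a soma-only morphology.
#'
#' @param depth Number of bifurcation levels (>= 0).
#' @param mean_segment Mean segment length in um.
#' @param seed Integer RNG seed.
#' @return A [morphology()].
#' @export
synth_morphology <- function(depth, mean_segment = 40, seed = 1) {
  if (depth < 0) stop("synth_morphology: depth must be >= 0")
  with_seed(seed, {
    rows <- list(c(1, 1, 0, 0, 0, 6, -1))
    next_id <- 2L
    grow <- function(parent_id, pos, dir, level, type, radius) {
      if (level > depth) return(invisible(NULL))
      n_branch <- if (level == 1L) 1L else 2L
      for (b in seq_len(n_branch)) {
        d <- dir + 0.45 * stats::rnorm(3)
        d <- d / sqrt(sum(d^2))
        len <- mean_segment * stats::runif(1, 0.7, 1.3)
        # two SWC nodes per edge so chords are shorter than a shell gap
        mid <- pos + d * len / 2
        tip <- pos + d * len
        id_mid <- next_id; id_tip <- next_id + 1L
        next_id <<- next_id + 2L
        rows[[length(rows) + 1L]] <<-
          c(id_mid, type, mid, radius, parent_id)
        rows[[length(rows) + 1L]] <<-
          c(id_tip, type, tip, radius * 0.9, id_mid)
        grow(id_tip, tip, d, level + 1L, type, radius * 0.8)
      }
    }
    if (depth >= 1) {
      grow(1L, c(0, 0, 0), c(0, 1, 0), 1L, 4L, 1.5)   # apical stem
      grow(1L, c(0, 0, 0), c(0, -1, 0), 1L, 3L, 1.2)  # basal stem
    }
    m <- do.call(rbind, rows)
    morphology(data.frame(id = as.integer(m[, 1]),
                          type = as.integer(m[, 2]),
                          x = m[, 3], y = m[, 4], z = m[, 5],
                          radius = m[, 6],
                          parent = as.integer(m[, 7])))
  })
}

#' Axis-aligned layered test image
#'
#' A banded 16-bit image whose value depends only on the normalized
#' horizontal position: band `k` spans normalized x in
#' `[edges[k-1], edges[k])` and has value `band_values[k]`. A profile
#' path along +x recovers the bands; a single band gives a uniform
#' image.
#'
#' @param shape `c(rows, cols)` in pixels.
#' @param band_edges Strictly increasing interior edges in (0, 1).
#' @param band_values One value per band (`length(band_edges) + 1`),
#'   each in \[0, 65535\].
#' @return A [gray_image()].
#' @export
synth_layer_image <- function(shape, band_edges, band_values) {
  if (length(band_values) != length(band_edges) + 1L)
    stop("synth_layer_image: need one more value than interior edges")
  if (any(band_values < 0 | band_values > 65535))
    stop("synth_layer_image: band values must lie in [0, 65535]")
  if (is.unsorted(band_edges, strictly = TRUE) ||
      any(band_edges <= 0 | band_edges >= 1))
    stop("synth_layer_image: edges must be strictly increasing in (0,1)")
  nr <- shape[1]; nc <- shape[2]
  u <- (seq_len(nc) - 0.5) / nc
  vals <- band_values[findInterval(u, band_edges) + 1L]
  gray_image(matrix(rep(vals, each = nr), nrow = nr))
}

#' Anatomical shape ratios consistent with a target position
#'
#' Inverts the longitudinal position model: draws the CA1 and CA3
#' ratios uniformly from a feasible box and solves the DG ratio so that
#' [longitudinal_position()] returns `position` exactly. Positions the
#' model cannot reach with non-negative ratios raise an error.
#'
#' @param position Target position in mm.
#' @param seed Integer RNG seed.
#' @return List with `ca1`, `ca3`, `dg`.
#' @export
synth_anatomical_ratios <- function(position, seed = 1) {
  u <- position - POSITION_COEF[["intercept"]]
  if (!is.finite(u) || u < 0)
    stop("synth_anatomical_ratios: position ", position,
         " mm is infeasible with non-negative ratios")
  with_seed(seed, {
    ca1 <- stats::runif(1, 0, 0.4 * u / POSITION_COEF[["ca1"]])
    ca3 <- stats::runif(1, 0, 0.4 * u / POSITION_COEF[["ca3"]])
    dg <- (u - POSITION_COEF[["ca1"]] * ca1 -
             POSITION_COEF[["ca3"]] * ca3) / POSITION_COEF[["dg"]]
    list(ca1 = ca1, ca3 = ca3, dg = dg)
  })
}
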