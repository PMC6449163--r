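# Paste AP template waveforms into a resting trace with peaks at the
# requested times (ms); returns the composite trace.
paste_templates <- function(peak_times, rmp = -65, dt = 0.025,
                            total = 400, ...) {
  tp <- synth_ap_template(rmp = rmp, dt = dt, ...)
  v <- rep(rmp, round(total / dt))
  for (pt in peak_times) {
    i0 <- round((pt - tp$peak_time) / dt)
    idx <- i0 + seq_along(tp$trace$samples)
    v[idx] <- tp$trace$samples
  }
  trace(v, dt = dt, unit = "mV")
}

test_that("spike detection counts level crossings and ignores
           subthreshold traces", {
  sub <- trace(seq(-65, -40, length.out = 1000), dt = 0.1, unit = "mV")
  expect_equal(detect_spikes(sub), numeric(0))

  tr <- paste_templates(c(100, 200, 300))
  st <- detect_spikes(tr)
  expect_length(st, 3)
  expect_true(all(abs(st - c(100, 200, 300)) <= 0.1))

  # invariant to a DC offset that stays below the detection level
  tr2 <- tr
  tr2$samples <- tr2$samples + 5
  expect_equal(detect_spikes(tr2), st)
})

test_that("detected spike count equals the simulator's log", {
  p <- resonant_neuron_params(
    C = 400, g_L = 20, g_1 = 0, tau_1 = 0, E_L = -65,
    spike = list(V_T = -50, V_reset = -65, b = 0, refractory = 2))
  ss <- synth_step_sweeps(p, amplitudes = 300, dt = 0.1, seed = 6)
  det <- detect_spikes(ss$sweeps[[1]]$voltage)
  expect_length(det, length(ss$metadata$spike_log[[1]]))
})

test_that("AP landmark extraction recovers programmed template values", {
  tp <- synth_ap_template(threshold = -50, peak = 30, trough = -58,
                          rmp = -65, rise_slope = 150)
  st <- detect_spikes(tp$trace)
  f <- ap_waveform_features(tp$trace, st[1], rmp = -65)
  expect_lt(abs(f$threshold - (-50)), 0.5)
  expect_lt(abs(f$amplitude - 95), 0.5)
  expect_lt(abs(f$fahp - 8), 0.5)
})

test_that("max dV/dt reports the programmed rise slope", {
  tp <- synth_ap_template(rise_slope = 100, dt = 0.025)
  st <- detect_spikes(tp$trace)
  f <- ap_waveform_features(tp$trace, st[1], rmp = -65)
  expect_equal(f$max_dvdt, 100, tolerance = 0.02)
})

test_that("a trough later than the fAHP window is reported absent", {
  tp <- synth_ap_template(trough_delay = 2.5)
  st <- detect_spikes(tp$trace)
  f <- ap_waveform_features(tp$trace, st[1], rmp = -65)
  expect_true(is.na(f$fahp))
  expect_true(is.na(f$fahp_time))
})

test_that("waveform features equal a brute-force derivative-scan oracle
           across varied templates", {
  cases <- list(
    list(threshold = -50, peak = 30, trough = -58, rise_slope = 150),
    list(threshold = -45, peak = 20, trough = -55, rise_slope = 220),
    list(threshold = -55, peak = 35, trough = -60, rise_slope = 120,
         trough_delay = 1.2))
  for (cs in cases) {
    tp <- do.call(synth_ap_template, c(cs, list(rmp = -70, dt = 0.025)))
    st <- detect_spikes(tp$trace)
    f <- ap_waveform_features(tp$trace, st[1], rmp = -70)
    o <- oracle_ap_landmarks(tp$trace$samples, 0.025)
    expect_equal(f$threshold, o$threshold, tolerance = 1e-9)
    expect_equal(f$max_dvdt, o$max_dvdt, tolerance = 1e-9)
    expect_equal(f$amplitude, o$peak_v - (-70), tolerance = 1e-9)
    expect_equal(f$fahp, o$fahp, tolerance = 1e-9)
  }
})

test_that("threshold extraction fails when the criterion is never met", {
  slow <- trace(c(seq(-65, -10, length.out = 8000),
                  seq(-10, -65, length.out = 8000)),
                dt = 0.025, unit = "mV")  # max slope ~ 0.275 mV/ms
  st <- detect_spikes(slow)
  expect_length(st, 1)
  expect_error(ap_waveform_features(slow, st[1], rmp = -65),
               "never reached")
})

test_that("train features implement the ISI-ratio conventions", {
  reg <- seq(0, by = 50, length.out = 10)
  expect_equal(train_features(reg)$sfa, 1.0)
  tr <- cumsum(c(0, c(50, 60, 70, 80, 90, 100)))
  expect_equal(train_features(tr)$sfa, 2.0)
  expect_equal(train_features(tr, convention = "isi1_over_isi6")$sfa,
               0.5)
  five <- seq(0, by = 40, length.out = 5)
  expect_true(is.na(train_features(five)$sfa))
  expect_equal(train_features(five)$isis, rep(40, 4))
  expect_error(train_features(c(10, 5, 20)), "increasing")
})

test_that("FI curve matches the closed-form LIF rate within one spike
           and is monotone", {
  p <- resonant_neuron_params(
    C = 400, g_L = 20, g_1 = 0, tau_1 = 0, E_L = -65,
    spike = list(V_T = -50, V_reset = -65, b = 0, refractory = 2))
  amps <- seq(100, 500, by = 50)
  ss <- synth_step_sweeps(p, amplitudes = amps, dt = 0.1, seed = 9)
  fic <- fi_curve(ss)
  ref <- vapply(amps, function(I) {
    oracle_lif_count(R_gohm = 1 / 20, tau_ms = 400 / 20, dv_thr = 15,
                     I_pa = I, duration_ms = 800,
                     dead_ms = ss$metadata$dead_ms)
  }, integer(1))
  expect_true(all(abs(fic$counts - ref) <= 1))
  expect_true(all(diff(fic$counts) >= 0))
})

test_that("FI curve of a passive membrane is zero and missing
           amplitudes are reported", {
  p <- resonant_neuron_params(C = 200, g_L = 15, g_1 = 5, tau_1 = 50)
  ss <- synth_step_sweeps(p, amplitudes = seq(100, 500, 50), dt = 0.25)
  expect_equal(fi_curve(ss)$counts, rep(0L, 9))
  expect_error(fi_curve(ss, amplitudes = c(100, 600)), "600")
})

test_that("train selection uses inclusive count bounds", {
  # sweeps with exactly 3, 8, 9, 11, and 12 spikes inside the step
  mk_sweep <- function(n_spikes) {
    v <- paste_templates(seq(150, by = 60, length.out = n_spikes),
                         dt = 0.05, total = 1000)
    I <- ifelse(trace_times(v) >= 100 & trace_times(v) < 900, 250, 0)
    list(voltage = v, command = trace(I, dt = 0.05, unit = "pA"),
         epoch = step_epoch(100, 800, 250))
  }
  ss <- sweep_set(lapply(c(3, 8, 9, 11, 12), mk_sweep))
  expect_equal(select_trains(ss, count_range = c(8, 11)), c(2L, 3L, 4L))
  expect_equal(select_trains(ss, count_range = c(9, 12)),
               c(3L, 4L, 5L))
  expect_length(select_trains(ss, count_range = c(100, 200)), 0)
})
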