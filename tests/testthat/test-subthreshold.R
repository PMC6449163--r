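test_that("resting membrane potential is the baseline-window mean", {
  tr <- trace(rep(-65, 1000), dt = 1, unit = "mV")
  expect_equal(resting_membrane_potential(tr, c(0, 500)), -65)
  set.seed(42)
  noisy <- trace(-68 + rnorm(1000, sd = 0.5), dt = 1, unit = "mV")
  expect_lt(abs(resting_membrane_potential(noisy, c(0, 999)) + 68), 0.05)
  expect_error(resting_membrane_potential(tr, c(2000, 3000)),
               "no samples")
  expect_error(resting_membrane_potential(tr, c(50, 50)), "to > from")
})

test_that("RMP of the simulated neuron at rest recovers E_L", {
  p <- resonant_neuron_params(E_L = -68)
  stim <- trace(rep(0, 4000), dt = 0.5, unit = "pA")
  sim <- simulate_neuron(p, stim, seed = 5, noise_sd = 0.2)
  expect_lt(abs(resting_membrane_potential(sim$voltage, c(0, 1999)) + 68),
            0.1)
})

test_that("input resistance recovers an ideal resistor exactly", {
  ss <- make_resistor_sweeps(c(-70, -50, -30, -10, 10),
                             gain_mv_per_pa = 0.05)
  fit <- input_resistance(ss)
  expect_equal(fit$rin_mohm, 50, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$sweeps_excluded, integer(0))
})

test_that("sweeps containing action potentials are excluded from Rin", {
  ss <- make_resistor_sweeps(c(-70, -50, -30, -10, 10),
                             gain_mv_per_pa = 0.05)
  # insert a spike into the +10 pA sweep during the step
  v <- ss$sweeps[[5]]$voltage$samples
  v[500:504] <- c(-30, 10, 35, 0, -40)
  ss$sweeps[[5]]$voltage$samples <- v
  fit <- input_resistance(ss)
  expect_equal(fit$sweeps_excluded, 5L)
  expect_equal(fit$sweeps_used, 1:4)
  expect_equal(fit$rin_mohm, 50, tolerance = 1e-9)
  # with only one spike-free sweep left, the fit must refuse
  ss2 <- make_resistor_sweeps(c(-70, 10), gain_mv_per_pa = 0.05)
  v2 <- ss2$sweeps[[2]]$voltage$samples
  v2[500:504] <- c(-30, 10, 35, 0, -40)
  ss2$sweeps[[2]]$voltage$samples <- v2
  expect_error(input_resistance(ss2), "fewer than 2")
})

test_that("Rin of the model neuron matches the DC closed form", {
  p <- resonant_neuron_params(C = 200, g_L = 15, g_1 = 5, tau_1 = 50)
  ss <- synth_step_sweeps(p, amplitudes = c(-70, -50, -30, -10, 10),
                          dt = 0.25, seed = 2)
  fit <- input_resistance(ss)
  expect_equal(fit$rin_mohm, 1000 / (15 + 5), tolerance = 0.02)
})

test_that("noise-free passive Rin converges to 1/g_L within 1%", {
  p <- resonant_neuron_params(C = 200, g_L = 20, g_1 = 0, tau_1 = 0)
  ss <- synth_step_sweeps(p, amplitudes = c(-70, -50, -30, -10, 10),
                          dt = 0.25, noise_sd = 0)
  expect_equal(input_resistance(ss)$rin_mohm, 50, tolerance = 0.01)
})

test_that("Rin is invariant to voltage offsets and sweep order", {
  p <- resonant_neuron_params(C = 200, g_L = 15, g_1 = 10, tau_1 = 50)
  ss <- synth_step_sweeps(p, amplitudes = c(-70, -50, -30, -10, 10),
                          dt = 0.25, seed = 3, noise_sd = 0.1)
  base <- input_resistance(ss)$rin_mohm
  for (offset in c(-12, 5)) {
    shifted <- ss
    for (i in seq_along(shifted$sweeps))
      shifted$sweeps[[i]]$voltage$samples <-
        shifted$sweeps[[i]]$voltage$samples + offset
    expect_equal(input_resistance(shifted)$rin_mohm, base,
                 tolerance = 1e-9)
  }
  reord <- sweep_set(ss$sweeps[c(3, 1, 5, 2, 4)], ss$metadata)
  expect_equal(input_resistance(reord)$rin_mohm, base, tolerance = 1e-9)
})

test_that("a memoryless membrane has rebound slope 0", {
  ss <- make_resistor_sweeps(c(-150, -110, -70, -30),
                             gain_mv_per_pa = 0.05)
  expect_lt(abs(rebound_slope(ss)$slope_mv_per_mv), 0.01)
  p <- resonant_neuron_params(C = 200, g_L = 20, g_1 = 0, tau_1 = 0)
  ssp <- synth_step_sweeps(p, amplitudes = c(-150, -110, -70, -30),
                           dt = 0.25)
  expect_lt(abs(rebound_slope(ssp)$slope_mv_per_mv), 0.01)
})

test_that("resonant-membrane rebound slope is negative and matches an
           independent re-measurement", {
  p <- resonant_neuron_params(C = 200, g_L = 15, g_1 = 25, tau_1 = 50)
  ss <- synth_step_sweeps(p, amplitudes = c(-150, -110, -70, -30),
                          dt = 0.25, seed = 8)
  got <- rebound_slope(ss)
  expect_lt(got$slope_mv_per_mv, 0)
  # oracle: measure each sweep with explicit index arithmetic, fit by hand
  ends <- numeric(0); rebs <- numeric(0)
  for (sw in ss$sweeps) {
    v <- sw$voltage$samples; dt <- sw$voltage$dt; ep <- sw$epoch
    idx_of <- function(t) round(t / dt) + 1
    base <- mean(v[idx_of(ep$onset - 100):(idx_of(ep$onset) - 1)])
    off <- ep$onset + ep$duration
    ends <- c(ends, mean(v[idx_of(off - 10):(idx_of(off) - 1)]))
    rebs <- c(rebs, max(v[(idx_of(off) + 1):idx_of(off + 400)] - base))
  }
  expect_equal(got$slope_mv_per_mv, oracle_ols_slope(ends, rebs),
               tolerance = 0.05)
  # a single usable sweep is a degenerate input
  one <- sweep_set(ss$sweeps[1], ss$metadata)
  expect_error(rebound_slope(one), "fewer than 2")
})

test_that("subthreshold_features composes the three measurements", {
  p <- resonant_neuron_params(C = 200, g_L = 15, g_1 = 10, tau_1 = 50,
                              E_L = -66)
  ss <- synth_step_sweeps(p, amplitudes = c(-150, -110, -70, -30, 10),
                          dt = 0.25, seed = 4)
  feats <- subthreshold_features(ss)
  expect_equal(feats$rmp_mv, -66, tolerance = 0.05)
  expect_equal(feats$rin_mohm, input_resistance(ss)$rin_mohm)
  expect_equal(feats$rebound_slope_mv_per_mv,
               rebound_slope(ss)$slope_mv_per_mv)
})
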