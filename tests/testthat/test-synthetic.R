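test_that("the model neuron sits at its fixed point with zero input", {
  p <- resonant_neuron_params(E_L = -68)
  stim <- trace(rep(0, 2000), dt = 0.5, unit = "pA")
  sim <- simulate_neuron(p, stim)
  expect_true(all(abs(sim$voltage$samples + 68) < 1e-9))
})

test_that("the DC step response matches I/(g_L + g_1)", {
  p <- resonant_neuron_params(C = 200, g_L = 15, g_1 = 5, tau_1 = 50,
                              E_L = -68)
  n <- 4000
  I <- c(rep(0, 400), rep(-50, n - 400))
  sim <- simulate_neuron(p, trace(I, dt = 0.5, unit = "pA"))
  dv <- mean(utils::tail(sim$voltage$samples, 200)) - (-68)
  expect_equal(dv, -50 / (15 + 5), tolerance = 0.01)
})

test_that("subthreshold integration matches the analytic matrix
           exponential solution at two step sizes", {
  p <- resonant_neuron_params(C = 200, g_L = 15, g_1 = 25, tau_1 = 50,
                              E_L = -68)
  # analytic step response via an eigen-decomposition done in the test
  A <- matrix(c(-p$g_L / p$C, 1 / p$tau_1, -p$g_1 / p$C, -1 / p$tau_1),
              2, 2)
  b <- c((p$g_L * p$E_L - 60) / p$C, -p$E_L / p$tau_1)  # I = -60 pA
  xss <- solve(A, -b)
  ev <- eigen(A)
  analytic_v <- function(t_ms) {
    x0 <- c(p$E_L, 0)
    co <- solve(ev$vectors, x0 - xss)
    Re((ev$vectors %*% (co * exp(ev$values * t_ms)))[1]) + xss[1]
  }
  for (dt in c(0.5, 0.25)) {
    n <- round(400 / dt) + 1
    sim <- simulate_neuron(p, trace(rep(-60, n), dt = dt, unit = "pA"))
    for (t_ms in c(25, 100, 400)) {
      v_ref <- analytic_v(t_ms)
      v_got <- sim$voltage$samples[round(t_ms / dt) + 1]
      expect_equal(v_got - p$E_L, v_ref - p$E_L, tolerance = 0.01)
    }
  }
})

test_that("generators are pure functions of parameters and seed", {
  p <- resonant_neuron_params()
  stim <- make_chirp(chirp_spec(), dt = 0.5)
  a <- simulate_neuron(p, stim, seed = 7, noise_sd = 0.2)
  b <- simulate_neuron(p, stim, seed = 7, noise_sd = 0.2)
  expect_identical(a$voltage$samples, b$voltage$samples)
  e1 <- synth_eeg(10, epochs = list(seizure_epoch(3, 2, 30)), seed = 9)
  e2 <- synth_eeg(10, epochs = list(seizure_epoch(3, 2, 30)), seed = 9)
  expect_identical(e1$record$channels[[1]]$samples,
                   e2$record$channels[[1]]$samples)
  expect_identical(synth_morphology(4, seed = 5)$nodes,
                   synth_morphology(4, seed = 5)$nodes)
})

test_that("unstable integration steps are rejected", {
  p <- resonant_neuron_params(C = 100, g_L = 20, g_1 = 10, tau_1 = 5)
  stim <- trace(rep(0, 100), dt = 2, unit = "pA")
  expect_error(simulate_neuron(p, stim), "too coarse")
})

test_that("the closed-form impedance has the stated limits", {
  p <- resonant_neuron_params(C = 200, g_L = 15, g_1 = 5, tau_1 = 50)
  expect_equal(closed_form_impedance(p, 0), 50)
  rc <- resonant_neuron_params(C = 200, g_L = 20, g_1 = 0, tau_1 = 0)
  f <- c(1, 5, 10)
  w <- 2 * pi * f * 1e-3
  expect_equal(closed_form_impedance(rc, f),
               1000 / Mod(20 + 1i * w * 200), tolerance = 1e-12)
  res <- resonant_neuron_params(C = 200, g_L = 15, g_1 = 25, tau_1 = 50)
  grid <- seq(0.5, 15, 0.001)
  z <- closed_form_impedance(res, grid)
  expect_gt(grid[which.max(z)], 0.5)  # interior maximum exists
})

test_that("AP templates reject inconsistent landmarks", {
  expect_error(synth_ap_template(threshold = -50, peak = -55),
               "peak must exceed")
  expect_error(synth_ap_template(threshold = -50, trough = -45),
               "trough")
  expect_error(synth_ap_template(threshold = -50, rmp = -45), "rmp")
})

test_that("synthetic EEG epochs carry their designed power", {
  sim <- synth_eeg(30, background_rms = 3,
                   epochs = list(seizure_epoch(10, 10, rms = 30)),
                   seed = 41)
  pw <- sliding_window_power(sim$record$channels[[1]])
  inside <- pw$window_starts >= 10 & pw$window_starts + 3 <= 20
  expect_lt(abs(mean(pw$power[inside]) - 900) / 900, 0.10)
  expect_error(synth_eeg(30, epochs = list(seizure_epoch(5, 10, 30),
                                           seizure_epoch(8, 5, 30))),
               "overlap")
})

test_that("random morphologies satisfy SWC invariants and grow with
           depth", {
  m0 <- synth_morphology(0, seed = 1)
  expect_equal(nrow(m0$nodes), 1)
  mean_len <- vapply(c(2, 4), function(d) {
    mean(vapply(1:20, function(s)
      total_dendritic_length(synth_morphology(d, seed = s)), numeric(1)))
  }, numeric(1))
  expect_gt(mean_len[2], mean_len[1])
})

test_that("layered images validate their band specification", {
  uni <- synth_layer_image(c(10, 50), band_edges = numeric(0),
                           band_values = 700)
  expect_true(all(uni$pixels == 700))
  expect_error(synth_layer_image(c(10, 50), 0.5, c(100, 70000)),
               "65535")
  expect_error(synth_layer_image(c(10, 50), c(0.6, 0.4), c(1, 2, 3)),
               "increasing")
})
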