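# Independent brute-force oracles used to check the package's
# implementations. These deliberately share no code with R/: plain
# loops and closed forms only.

# OLS slope/intercept from the textbook normal equations.
oracle_ols_slope <- function(x, y) {
  xb <- sum(x) / length(x)
  yb <- sum(y) / length(y)
  sum((x - xb) * (y - yb)) / sum((x - xb)^2)
}

# Textbook Holm-Sidak step-down, written as an explicit loop.
oracle_holm_sidak <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    raw <- 1 - (1 - p[ord[i]])^(m - i + 1)
    running <- max(running, raw)
    adj[ord[i]] <- min(running, 1)
  }
  adj
}

# Dendritic segments of a morphology, re-derived by explicit loops.
oracle_segments <- function(m) {
  nd <- m$nodes
  soma <- nd[nd$type == 1, ]
  ctr <- c(mean(soma$x), mean(soma$y), mean(soma$z))
  segs <- list()
  for (i in seq_len(nrow(nd))) {
    if (!(nd$type[i] %in% c(3, 4)) || nd$parent[i] == -1) next
    pi <- which(nd$id == nd$parent[i])
    p1 <- if (nd$type[pi] == 1) ctr else c(nd$x[pi], nd$y[pi], nd$z[pi])
    segs[[length(segs) + 1]] <- list(
      a = p1, b = c(nd$x[i], nd$y[i], nd$z[i]),
      r1 = nd$radius[pi], r2 = nd$radius[i])
  }
  list(center = ctr, segs = segs)
}

# Sholl counts by testing every (segment, radius) pair independently.
oracle_sholl <- function(m, radii) {
  o <- oracle_segments(m)
  counts <- integer(length(radii))
  for (k in seq_along(radii)) {
    r <- radii[k]
    for (sg in o$segs) {
      d1 <- sqrt(sum((sg$a - o$center)^2))
      d2 <- sqrt(sum((sg$b - o$center)^2))
      if (min(d1, d2) < r && max(d1, d2) >= r)
        counts[k] <- counts[k] + 1L
    }
  }
  counts
}

oracle_dendritic_length <- function(m) {
  o <- oracle_segments(m)
  tot <- 0
  for (sg in o$segs) tot <- tot + sqrt(sum((sg$b - sg$a)^2))
  tot
}

oracle_surface_area <- function(m) {
  o <- oracle_segments(m)
  tot <- 0
  for (sg in o$segs) {
    L <- sqrt(sum((sg$b - sg$a)^2))
    tot <- tot + pi * (sg$r1 + sg$r2) * sqrt(L^2 + (sg$r1 - sg$r2)^2)
  }
  tot
}

# Brute-force AP landmark scan: recompute the central-difference
# derivative by loop and walk the samples literally.
oracle_ap_landmarks <- function(v, dt, level = -20, criterion = 20,
                                fahp_window = 1.5, pre_search = 3) {
  n <- length(v)
  dv <- numeric(n)
  for (i in 2:(n - 1)) dv[i] <- (v[i + 1] - v[i - 1]) / (2 * dt)
  dv[1] <- (v[2] - v[1]) / dt
  dv[n] <- (v[n] - v[n - 1]) / dt
  cross <- NA
  for (i in 2:n) if (v[i] >= level && v[i - 1] < level) { cross <- i; break }
  start <- max(1, cross - round(pre_search / dt))
  # spike peak: maximum while above level
  e <- cross
  while (e < n && v[e + 1] >= level) e <- e + 1
  pk <- (cross:e)[which.max(v[cross:e])]
  thr <- NA
  for (i in start:pk) if (dv[i] >= criterion) { thr <- i; break }
  maxd <- max(dv[thr:pk])
  peak_i <- NA; trough_i <- NA
  for (i in thr:(n - 1)) {
    if (is.na(peak_i) && dv[i] > 0 && dv[i + 1] <= 0) peak_i <- i + 1
    else if (!is.na(peak_i) && dv[i] < 0 && dv[i + 1] >= 0) {
      trough_i <- i + 1; break
    }
  }
  fahp <- NA
  if (!is.na(trough_i) && (trough_i - peak_i) * dt <= fahp_window)
    fahp <- v[thr] - v[trough_i]
  list(threshold = v[thr], max_dvdt = maxd, peak_v = v[pk], fahp = fahp)
}

# Closed-form spike count of a leaky integrate-and-fire neuron with
# reset to E_L and per-spike dead time, over a step of given duration.
oracle_lif_count <- function(R_gohm, tau_ms, dv_thr, I_pa, duration_ms,
                             dead_ms) {
  dv_inf <- 1000 * R_gohm * I_pa / 1000  # mV (R in GOhm, I in pA)
  if (dv_inf <= dv_thr) return(0L)
  t_lat <- tau_ms * log(dv_inf / (dv_inf - dv_thr))
  period <- t_lat + dead_ms
  if (t_lat > duration_ms) return(0L)
  as.integer(floor((duration_ms - t_lat) / period) + 1)
}

# Random 3D rotation matrix (QR of a Gaussian matrix, det +1).
oracle_rotation <- function(seed) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Apply a rigid motion to a morphology's coordinates.
transform_morphology <- function(m, Q, shift = c(0, 0, 0)) {
  nd <- m$nodes
  xyz <- t(Q %*% t(as.matrix(nd[, c("x", "y", "z")]))) +
    matrix(shift, nrow(nd), 3, byrow = TRUE)
  nd$x <- xyz[, 1]; nd$y <- xyz[, 2]; nd$z <- xyz[, 3]
  morphology(nd)
}

# Build a sweep set analytically: voltage = baseline + gain * I during
# the step (instantaneous membrane), for resistor-style fixtures.
make_resistor_sweeps <- function(amplitudes, gain_mv_per_pa,
                                 baseline = -65, onset = 100,
                                 duration = 800, tail = 100, dt = 1) {
  n <- round((onset + duration + tail) / dt) + 1
  tt <- (seq_len(n) - 1) * dt
  sweeps <- lapply(amplitudes, function(a) {
    I <- ifelse(tt >= onset & tt < onset + duration, a, 0)
    v <- baseline + gain_mv_per_pa * I
    list(voltage = trace(v, dt = dt, unit = "mV"),
         command = trace(I, dt = dt, unit = "pA"),
         epoch = step_epoch(onset, duration, a))
  })
  sweep_set(sweeps, metadata = list(protocol = "step"))
}

# Resonant parameter draw with a guaranteed interior resonance peak.
draw_resonant_params <- function(seed, f_min = 1) {
  set.seed(seed)
  repeat {
    p <- resonant_neuron_params(C = runif(1, 150, 250),
                                g_L = runif(1, 10, 20),
                                g_1 = runif(1, 15, 35),
                                tau_1 = runif(1, 40, 80), E_L = -68)
    f <- seq(0.5, 15, by = 0.001)
    fres <- f[which.max(closed_form_impedance(p, f))]
    if (fres >= f_min) return(list(params = p, f_res = fres))
  }
}
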