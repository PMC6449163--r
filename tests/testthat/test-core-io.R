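test_that("trace construction validates samples, dt, and unit", {
  expect_error(trace(numeric(0), dt = 0.1), "non-empty")
  expect_error(trace(1:10, dt = 0), "positive")
  expect_error(trace(1:10, dt = 0.1, unit = "volts"))
  tr <- trace(rep(-65, 5), dt = 0.5, t0 = 10, unit = "mV")
  expect_equal(trace_times(tr), c(10, 10.5, 11, 11.5, 12))
  expect_equal(trace_duration(tr), 2)
})

test_that("operations reject traces with the wrong unit tag", {
  current <- trace(rep(0, 100), dt = 1, unit = "pA")
  expect_error(resting_membrane_potential(current, c(0, 50)), "unit")
  expect_error(detect_spikes(current), "unit")
  expect_error(sliding_window_power(current), "unit")
})

test_that("sweep_set enforces shared dt, shared length, and units", {
  mk <- function(dt, n = 100) list(
    voltage = trace(rep(-65, n), dt = dt, unit = "mV"),
    command = trace(rep(0, n), dt = dt, unit = "pA"),
    epoch = step_epoch(10, 50, -50))
  expect_error(sweep_set(list(mk(1), mk(2))), "mixed sampling")
  expect_error(sweep_set(list(mk(1, 100), mk(1, 90))), "length")
  bad <- mk(1)
  bad$voltage$unit <- "uV"
  expect_error(sweep_set(list(bad)), "unit")
  expect_error(sweep_set(list()), "at least one")
  ok <- sweep_set(list(mk(1), mk(1)))
  expect_s3_class(ok, "sweep_set")
  expect_equal(sweep_amplitudes(ok), c(-50, -50))
})

test_that("sweep-table write-then-read is the identity on samples", {
  ss <- make_resistor_sweeps(c(-70, -30, 10), gain_mv_per_pa = 0.05,
                             dt = 0.5)
  path <- tempfile(fileext = ".csv")
  write_sweep_table(ss, path)
  back <- read_sweep_table(path)
  expect_length(back$sweeps, 3)
  for (i in 1:3) {
    expect_equal(back$sweeps[[i]]$voltage$samples,
                 ss$sweeps[[i]]$voltage$samples, tolerance = 1e-9)
    expect_equal(back$sweeps[[i]]$command$samples,
                 ss$sweeps[[i]]$command$samples, tolerance = 1e-9)
    expect_equal(back$sweeps[[i]]$epoch$amplitude,
                 ss$sweeps[[i]]$epoch$amplitude)
  }
  expect_equal(back$sweeps[[1]]$voltage$dt, 0.5)
})

test_that("sweep-table reader rejects malformed files with named fields", {
  empty <- tempfile(fileext = ".csv")
  writeLines(character(0), empty)
  expect_error(read_sweep_table(empty), "empty")

  ss <- make_resistor_sweeps(c(-70, 10), gain_mv_per_pa = 0.05)
  path <- tempfile(fileext = ".csv")
  write_sweep_table(ss, path)

  lines <- readLines(path)
  no_hdr <- tempfile(fileext = ".csv")
  writeLines(lines[-1], no_hdr)
  expect_error(read_sweep_table(no_hdr), "fs_hz")

  dropped <- tempfile(fileext = ".csv")
  writeLines(sub("voltage_mv", "volts", lines), dropped)
  expect_error(read_sweep_table(dropped), "voltage_mv")

  # truncate the second sweep: lengths differ -> mixed-sampling error
  body <- grep("^#", lines, invert = TRUE)
  ragged <- tempfile(fileext = ".csv")
  writeLines(lines[-utils::tail(body, 5)], ragged)
  expect_error(read_sweep_table(ragged), "mixed sampling")
})

test_that("SWC round-trips and computes path length for a line", {
  f <- tempfile(fileext = ".swc")
  writeLines("1 1 0 0 0 5 -1", f)
  m <- read_swc(f)
  expect_equal(nrow(m$nodes), 1)
  expect_equal(m$soma_id, 1)

  # soma + 5 collinear dendrite nodes spaced 20 um: path length 100
  writeLines(c("# comment", "1 1 0 0 0 5 -1",
               sprintf("%d 3 %d 0 0 1 %d", 2:6, seq(20, 100, 20), 1:5)),
             f)
  m <- read_swc(f)
  expect_equal(nrow(m$nodes), 6)
  expect_equal(total_dendritic_length(m), 100)

  m2 <- synth_morphology(depth = 3, seed = 7)
  f2 <- tempfile(fileext = ".swc")
  write_swc(m2, f2)
  back <- read_swc(f2)
  expect_equal(back$nodes$x, m2$nodes$x, tolerance = 1e-9)
  expect_equal(back$nodes$parent, m2$nodes$parent)
})

test_that("SWC parser reports structural errors with line numbers", {
  f <- tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 5 -1", "2 3 10 0 0 1 99"), f)
  expect_error(read_swc(f), "dangling parent id 99")
  writeLines(c("1 1 0 0 0 5 -1", "2 3 10 0 0"), f)
  expect_error(read_swc(f), "line 2")
  writeLines(c("1 1 0 0 0 5 -1", "1 3 10 0 0 1 1"), f)
  expect_error(read_swc(f), "duplicate")
  writeLines(c("1 1 0 0 0 5 -1", "2 3 10 0 0 1 -1"), f)
  expect_error(read_swc(f), "root")
})

test_that("EEG CSV reader preserves channels and rejects bad bodies", {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(ch1 = rep(0, 2400)), f, row.names = FALSE)
  rec <- read_eeg_record(f, fs = 800)
  expect_equal(length(rec$channels$ch1$samples) / rec$fs, 3.0)

  df <- data.frame(frontal = rnorm(10), parietal = rnorm(10),
                   temporal = rnorm(10))
  utils::write.csv(df, f, row.names = FALSE)
  rec <- read_eeg_record(f, fs = 800)
  expect_equal(names(rec$channels), c("frontal", "parietal", "temporal"))

  writeLines(c("a,b", "1,2", "3"), f)
  expect_error(read_eeg_record(f, fs = 800), "row 3")
  writeLines(c("a,b", "1,2", "3,oops"), f)
  expect_error(read_eeg_record(f, fs = 800), "non-numeric")
})

test_that("EEG write-then-read reproduces samples", {
  sim <- synth_eeg(2, background_rms = 3, seed = 11)
  f <- tempfile(fileext = ".csv")
  write_eeg_record(sim$record, f)
  back <- read_eeg_record(f, fs = 800)
  expect_equal(back$channels[[1]]$samples,
               sim$record$channels[[1]]$samples, tolerance = 1e-9)
})

test_that("16-bit images round-trip through TIFF and PNG exactly", {
  set.seed(3)
  img <- gray_image(matrix(sample(0:65535, 400), 20, 20))
  for (ext in c(".tif", ".png")) {
    f <- tempfile(fileext = ext)
    write_gray_image(img, f)
    back <- read_gray_image(f)
    expect_equal(back$pixels, img$pixels)
  }
  expect_error(gray_image(matrix(-1, 2, 2)), "65535")
  expect_error(gray_image(matrix(70000, 2, 2)), "65535")
})
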