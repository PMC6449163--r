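#' Write a sweep set to the package's sweep-table CSV format
#'
#' One CSV per sweep set. Three comment header lines carry the shared
#' protocol metadata (`# fs_hz=`, `# step_onset_ms=`, `# step_duration_ms=`),
#' followed by a long table with columns
#' `sweep, amplitude_pa, sample_index, voltage_mv, command_pa`.
#' Sample times are reconstructed on read from `fs_hz`; no time column is
#' stored.
#'
#' @param ss A [sweep_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_sweep_table()]
#' @export
write_sweep_table <- function(ss, path) {
  stopifnot(inherits(ss, "sweep_set"))
  dt <- ss$sweeps[[1]]$voltage$dt
  ep1 <- ss$sweeps[[1]]$epoch
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# fs_hz=%.10g", 1000 / dt),
    sprintf("# step_onset_ms=%.10g", ep1$onset),
    sprintf("# step_duration_ms=%.10g", ep1$duration),
    "sweep,amplitude_pa,sample_index,voltage_mv,command_pa"
  ), con)
  for (i in seq_along(ss$sweeps)) {
    sw <- ss$sweeps[[i]]
    n <- length(sw$voltage$samples)
    writeLines(sprintf("%d,%.10g,%d,%.10g,%.10g",
                       i, sw$epoch$amplitude, seq_len(n) - 1L,
                       sw$voltage$samples, sw$command$samples), con)
  }
  invisible(path)
}

# Internal: pull `key=value` out of a `# key=value` comment header.
sweep_header_value <- function(lines, key, path) {
  pat <- paste0("^#\\s*", key, "\\s*=\\s*")
  hit <- grep(pat, lines)
  if (length(hit) == 0L)
    stop(sprintf("read_sweep_table: missing header '# %s=' in %s",
                 key, path))
  val <- suppressWarnings(as.numeric(sub(pat, "", lines[hit[1]])))
  if (is.na(val))
    stop(sprintf("read_sweep_table: non-numeric value for header '%s'", key))
  val
}

#' Read a sweep-table CSV into a sweep set
#'
#' Counterpart of [write_sweep_table()]; write-then-read reproduces the
#' sample values up to numeric formatting. Malformed files (missing
#' headers or columns, non-numeric cells, sweeps of unequal length) fail
#' with an error naming the offending field.
#'
#' @param path Path to a sweep-table CSV.
#' @return A [sweep_set()].
#' @export
read_sweep_table <- function(path) {
  if (!file.exists(path)) stop("read_sweep_table: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(trimws(lines))))
    stop("read_sweep_table: empty file: ", path)
  fs <- sweep_header_value(lines, "fs_hz", path)
  onset <- sweep_header_value(lines, "step_onset_ms", path)
  duration <- sweep_header_value(lines, "step_duration_ms", path)
  if (fs <= 0) stop("read_sweep_table: fs_hz must be > 0")
  body <- lines[!grepl("^\\s*#", lines)]
  tab <- utils::read.csv(text = paste(body, collapse = "\n"))
  req <- c("sweep", "amplitude_pa", "sample_index", "voltage_mv",
           "command_pa")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols) > 0L)
    stop("read_sweep_table: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  for (cc in req) {
    if (!is.numeric(tab[[cc]]) || anyNA(tab[[cc]]))
      stop("read_sweep_table: non-numeric value in column '", cc, "'")
  }
  dt <- 1000 / fs
  ids <- unique(tab$sweep)
  sweeps <- lapply(ids, function(id) {
    sub <- tab[tab$sweep == id, ]
    sub <- sub[order(sub$sample_index), ]
    amp <- unique(sub$amplitude_pa)
    if (length(amp) != 1L)
      stop("read_sweep_table: sweep ", id,
           " has multiple amplitude_pa values")
    list(voltage = trace(sub$voltage_mv, dt = dt, unit = "mV"),
         command = trace(sub$command_pa, dt = dt, unit = "pA"),
         epoch = step_epoch(onset, duration, amp))
  })
  lens <- vapply(sweeps, function(s) length(s$voltage$samples), integer(1))
  if (length(unique(lens)) != 1L)
    stop("read_sweep_table: mixed sampling: sweeps differ in length (",
         paste(lens, collapse = ", "), ")")
  sweep_set(sweeps, metadata = list(fs_hz = fs, source = path))
}

#' Write an EEG record as CSV
#'
#' Plain CSV, header row = channel names, body in microvolts.
#'
#' @param rec An [eeg_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eeg_record <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_record"))
  df <- as.data.frame(lapply(rec$channels, function(ch) ch$samples))
  names(df) <- names(rec$channels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an EEG CSV into an EEG record
#'
#' Expects a header row naming the channels and a numeric body in
#' microvolts; the sampling rate is supplied by the caller (it is a
#' property of the acquisition system, not the file). Ragged rows and
#' non-numeric cells fail with the offending row index.
#'
#' @param path Path to the CSV.
#' @param fs Sampling rate in Hz.
#' @return An [eeg_record()].
#' @export
read_eeg_record <- function(path, fs) {
  if (!file.exists(path)) stop("read_eeg_record: file not found: ", path)
  nf <- utils::count.fields(path, sep = ",")
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1])[1]
    stop("read_eeg_record: ragged row ", bad, " (", nf[bad],
         " field(s), expected ", nf[1], ")")
  }
  tab <- utils::read.csv(path, check.names = FALSE)
  if (ncol(tab) == 0L || nrow(tab) == 0L)
    stop("read_eeg_record: no data in ", path)
  for (cc in names(tab)) {
    vals <- tab[[cc]]
    if (!is.numeric(vals) || anyNA(vals)) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(vals))))[1]
      stop("read_eeg_record: non-numeric cell in column '", cc,
           "', row ", bad)
    }
  }
  dt <- 1000 / fs
  channels <- lapply(tab, function(v) trace(v, dt = dt, unit = "uV"))
  names(channels) <- names(tab)
  eeg_record(channels, fs = fs)
}
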