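#' Holm-Sidak step-down multiple-comparison adjustment
#'
#' Adjusts a family of p-values by the step-down Sidak procedure: sort
#' ascending, compute `1 - (1 - p_(j))^(m - j + 1)` for the j-th
#' smallest of m p-values, enforce monotonicity by the running maximum,
#' clip at 1, and return in the original order. This is the correction
#' applied to families of repeated t tests (spike-by-spike or
#' bin-by-bin comparisons); it is slightly more powerful than Holm's
#' Bonferroni-based step-down. (Not available via [stats::p.adjust()],
#' which offers only the Bonferroni-flavored Holm procedure.)
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @examples
#' holm_sidak_adjust(c(0.01, 0.04))  # 1-(1-0.01)^2 = 0.0199, then 0.04
#' @export
holm_sidak_adjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("holm_sidak_adjust: p-values must lie in [0, 1]")
  m <- length(pvals)
  ord <- order(pvals)
  raw <- 1 - (1 - pvals[ord])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(raw), 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Analysis configuration for a per-cell report
#'
#' A flat list of every tunable parameter of the pipeline, each
#' defaulting to the protocol's published value where one exists:
#' spike detection at -20 mV, threshold criterion 20 mV/ms, fAHP window
#' 1.5 ms, Rin fit over \[-70, 10\] pA, FI family 100-500 pA, 8-11-spike
#' train selection, chirp band 0.5-15 Hz with a degree-6 polynomial
#' peak fit, and a 400-ms rebound window. Unknown parameter names are
#' rejected before any computation runs.
#'
#' @param ... Name-value overrides of the defaults.
#' @return Named list of class `"cell_config"`.
#' @export
cell_config <- function(...) {
  defaults <- list(
    spike_level_mv = -20,
    dvdt_criterion_mv_per_ms = 20,
    fahp_window_ms = 1.5,
    min_isi_ms = 2,
    rin_range_pa = c(-70, 10),
    rebound_window_ms = 400,
    fi_amplitudes_pa = seq(100, 500, by = 50),
    train_count_range = c(8, 11),
    sfa_convention = "isi6_over_isi1",
    resonance_band_hz = c(0.5, 15),
    impedance_mode = "magnitude",
    poly_order = 6
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0L)
    stop("cell_config: unknown parameter(s): ",
         paste(unknown, collapse = ", "))
  structure(utils::modifyList(defaults, over), class = "cell_config")
}

# Internal: protocol tag of a sweep set ("step" unless declared chirp).
sweep_protocol <- function(ss) {
  p <- ss$metadata$protocol
  if (is.null(p)) "step" else p
}

#' Assemble a per-cell report
#'
#' Deterministically composes the analysis stages on the protocols
#' present: the step family feeds the subthreshold features, the FI
#' curve, and the train/spike features of the selected 8-11-spike
#' trains; the chirp sweep feeds the impedance profile and peak
#' resonance frequency. A missing protocol yields an explicitly `NULL`
#' section, never a silent default. The configuration is echoed
#' verbatim into the report, and identical inputs and configuration
#' produce byte-identical serialized reports (see [report_json()]).
#'
#' @param sweeps A [sweep_set()], or a list of sweep sets whose
#'   `metadata$protocol` is `"step"` or `"chirp"`.
#' @param config A [cell_config()].
#' @param cell_id Identifier echoed into the report.
#' @return List of class `"cell_report"` with sections `subthreshold`,
#'   `fi`, `trains`, `resonance`, plus `parameters` and `provenance`.
#' @export
run_cell_report <- function(sweeps, config = cell_config(),
                            cell_id = "cell") {
  if (!inherits(config, "cell_config"))
    stop("run_cell_report: config must be a cell_config()")
  if (inherits(sweeps, "sweep_set")) sweeps <- list(sweeps)
  if (length(sweeps) == 0L)
    stop("run_cell_report: no sweep sets supplied")
  for (ss in sweeps) stopifnot(inherits(ss, "sweep_set"))
  prot <- vapply(sweeps, sweep_protocol, character(1))
  step_ss <- if (any(prot == "step")) sweeps[[which(prot == "step")[1]]]
  chirp_ss <- if (any(prot == "chirp")) sweeps[[which(prot == "chirp")[1]]]

  sub <- NULL
  fi <- NULL
  trains <- NULL
  if (!is.null(step_ss)) {
    sub <- tryCatch(
      subthreshold_features(step_ss, current_range = config$rin_range_pa,
                            post_window = config$rebound_window_ms),
      error = function(e) list(error = conditionMessage(e)))
    fi <- tryCatch(
      fi_curve(step_ss, amplitudes = config$fi_amplitudes_pa,
               level = config$spike_level_mv),
      error = function(e) list(error = conditionMessage(e)))
    sel <- select_trains(step_ss, count_range = config$train_count_range,
                         level = config$spike_level_mv)
    rmp <- if (!is.null(sub$rmp_mv)) sub$rmp_mv else NA_real_
    trains <- lapply(sel, function(i) {
      sw <- step_ss$sweeps[[i]]
      st <- detect_spikes(sw$voltage, level = config$spike_level_mv,
                          min_isi = config$min_isi_ms)
      tf <- train_features(st, convention = config$sfa_convention)
      aps <- lapply(st, function(pt) {
        tryCatch(
          ap_waveform_features(sw$voltage, pt, rmp = rmp,
                               dvdt_criterion =
                                 config$dvdt_criterion_mv_per_ms,
                               fahp_window = config$fahp_window_ms,
                               level = config$spike_level_mv),
          error = function(e) list(error = conditionMessage(e)))
      })
      list(sweep = i, amplitude_pa = sw$epoch$amplitude,
           train = tf, spikes = aps)
    })
  }

  res <- NULL
  if (!is.null(chirp_ss)) {
    sw <- chirp_ss$sweeps[[1]]
    res <- tryCatch({
      ra <- resonance_analysis(sw$voltage, sw$command,
                               band = config$resonance_band_hz,
                               mode = config$impedance_mode,
                               poly_order = config$poly_order)
      list(peak_freq_hz = ra$peak_freq, resonant = ra$resonant,
           n_points = length(ra$profile$freqs))
    }, error = function(e) list(error = conditionMessage(e)))
  }

  structure(list(
    cell_id = cell_id,
    subthreshold = sub,
    fi = fi,
    trains = trains,
    resonance = res,
    parameters = unclass(config),
    provenance = list(package = "dvca1",
                      version = as.character(utils::packageVersion("dvca1")),
                      protocols = prot)
  ), class = "cell_report")
}

#' Serialize a cell report to canonical JSON
#'
#' Deterministic serialization (fixed 10-digit numeric precision, no
#' timestamps): the same report object always yields byte-identical
#' JSON.
#'
#' @param report A [run_cell_report()] result.
#' @return A JSON string.
#' @export
report_json <- function(report) {
  stopifnot(inherits(report, "cell_report"))
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  as.character(jsonlite::toJSON(strip(report), auto_unbox = TRUE,
                                digits = 10, null = "null", na = "null"))
}
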