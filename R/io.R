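# Tabular I/O, configuration and end-to-end workflows.

TRACE_COLUMNS <- c("molecule_id", "frame", "time_s", "donor", "acceptor")

#' Read a long-format trace table
#'
#' Reads the canonical interchange format for intensity trajectories: one
#' tab-separated table with a header and columns `molecule_id`, `frame`,
#' `time_s`, `donor`, `acceptor`. Malformed numeric cells are reported with
#' their row number; an empty file yields an empty table with a warning.
#'
#' @param path File path.
#' @return data.frame with the trace schema.
#' @export
read_trace_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (file.size(path) == 0) {
    warning("empty trace file; returning an empty collection")
    return(stats::setNames(
      data.frame(character(), integer(), numeric(), numeric(), numeric()),
      TRACE_COLUMNS))
  }
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = TRUE)
  miss <- setdiff(TRACE_COLUMNS, names(raw))
  if (length(miss)) {
    stop(sprintf("trace table schema error: missing column(s) %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (!nrow(raw)) {
    warning("trace file has a header but no rows; returning an empty collection")
  }
  for (col in c("frame", "time_s", "donor", "acceptor")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad)) {
      stop(sprintf("non-numeric value in column `%s` at data row %d ('%s')",
                   col, bad[1], raw[[col]][bad[1]]), call. = FALSE)
    }
    raw[[col]] <- v
  }
  raw$frame <- as.integer(raw$frame)
  raw
}

#' Write a long-format trace table
#'
#' @param traces Trace data.frame (or an `smfret_ensemble`, whose `traces`
#'   element is written).
#' @param path Output path; written atomically (temp file + rename).
#' @return `path`, invisibly.
#' @export
write_trace_table <- function(traces, path) {
  if (inherits(traces, "smfret_ensemble")) traces <- traces$traces
  miss <- setdiff(TRACE_COLUMNS, names(traces))
  if (length(miss)) {
    stop(sprintf("trace table schema error: missing column(s) %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  tmp <- paste0(path, ".tmp")
  utils::write.table(traces[TRACE_COLUMNS], tmp, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Analysis configuration
#'
#' Central collection of the pipeline tunables with their defaults. Unknown
#' keys are rejected. A short hash of the configuration is embedded in
#' workflow reports for provenance.
#'
#' @param ... Named overrides of the defaults: `bin_width` (E, 0.02),
#'   `hist_range` (`c(-0.1, 1.1)`), `first_frames` (15), `min_total_frac`
#'   (fraction of median total intensity below which a frame is invalid,
#'   0.1), `median_filter` (TRUE), `components` (`"auto"`, 1 or 2),
#'   `rate_method` (`"survival"`), `dwell_bin_frames` (2), `alpha` (model
#'   selection level, 0.01), `sg_window` (11), `sg_order` (3),
#'   `temperature_K` (293.15).
#' @return Named list of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  defaults <- list(
    bin_width = 0.02, hist_range = c(-0.1, 1.1), first_frames = 15,
    min_total_frac = 0.1, median_filter = TRUE, components = "auto",
    rate_method = "survival", dwell_bin_frames = 2, alpha = 0.01,
    sg_window = 11, sg_order = 3, temperature_K = 293.15
  )
  user <- list(...)
  if (length(user) && is.null(names(user))) {
    stop("configuration overrides must be named", call. = FALSE)
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown configuration key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  structure(utils::modifyList(defaults, user), class = "analysis_config")
}

# Deterministic short hash of an R object (Adler-32 over its serialization);
# used only for provenance stamps in reports.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  a <- 1
  b <- 0
  for (byte in bytes) {
    a <- (a + byte) %% 65521
    b <- (b + a) %% 65521
  }
  sprintf("%04x%04x", b, a)
}

#' Run the full smFRET analysis workflow
#'
#' Traces to report: preprocessing ([process_traces()]), per-molecule FRET
#' values and histogram, Gaussian-mixture population fit, state assignment,
#' dwell extraction, transition-rate estimation and equilibrium energetics.
#' Fully deterministic given a seed and configuration.
#'
#' @param traces Long-format trajectory table, or `NULL` to simulate.
#' @param model A [two_state_model()] used when `traces` is `NULL` (its
#'   background values are then also used for correction).
#' @param n_molecules Ensemble size when simulating.
#' @param config An [analysis_config()].
#' @param seed RNG seed used for simulation.
#' @param bg_donor,bg_acceptor Backgrounds for correction when supplying
#'   real traces.
#' @return Object of class `smfret_report`: list with `provenance`,
#'   `histogram`, `mixture`, `fractions`, `rates` (when two populations are
#'   present), `dwells`, `energetics`.
#' @export
run_smfret_workflow <- function(traces = NULL, model = NULL, n_molecules = 200,
                                config = analysis_config(), seed = NULL,
                                bg_donor = NULL, bg_acceptor = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(traces)) {
    if (is.null(model)) stop("supply `traces` or a simulation `model`", call. = FALSE)
    ens <- simulate_ensemble(model, n_molecules, seed = seed)
    traces <- ens$traces
    bg_donor <- bg_donor %||% model$bg_donor
    bg_acceptor <- bg_acceptor %||% model$bg_acceptor
  }
  frame_interval <- {
    one <- traces[traces$molecule_id == traces$molecule_id[1], "time_s"]
    min(diff(one))
  }
  fret <- process_traces(traces, bg_donor = bg_donor, bg_acceptor = bg_acceptor)
  values <- molecule_fret_values(fret, n_first_frames = config$first_frames)
  hist <- build_histogram(values, bin_width = config$bin_width,
                          range = config$hist_range)
  ncomp <- if (identical(config$components, "auto")) {
    select_n_components(hist, alpha = config$alpha)
  } else {
    as.integer(config$components)
  }
  mixture <- fit_gaussian_mixture(hist, ncomp)

  rates <- NULL
  dwells <- NULL
  energetics <- NULL
  if (mixture$n_components == 2L) {
    states <- assign_states(fret, mixture = mixture,
                            median_filter = config$median_filter)
    dwells <- extract_dwells(states, frame_interval = frame_interval)
    rates <- tryCatch(
      fit_dwell_rates(dwells, method = config$rate_method,
                      bin_width_s = config$dwell_bin_frames * frame_interval),
      error = function(e) {
        warning("rate estimation skipped: ", conditionMessage(e))
        NULL
      })
    energetics <- folding_energetics(
      fractions = mixture$fractions,
      rates = if (!is.null(rates)) rates else NULL,
      temperature_K = config$temperature_K)
  }

  structure(
    list(provenance = list(package_version = as.character(utils::packageVersion("g4fold")),
                           config_hash = config_hash(config), seed = seed,
                           n_molecules = length(unique(traces$molecule_id))),
         histogram = hist, mixture = mixture, fractions = mixture$fractions,
         dwells = dwells, rates = rates, energetics = energetics,
         config = config),
    class = "smfret_report"
  )
}

#' @export
print.smfret_report <- function(x, ...) {
  cat(sprintf("smFRET workflow report (%d molecules, config %s)\n",
              x$provenance$n_molecules, x$provenance$config_hash))
  print(x$mixture)
  if (!is.null(x$rates)) {
    print(x$rates$low_to_high)
    print(x$rates$high_to_low)
  }
  if (!is.null(x$energetics)) print(x$energetics)
  invisible(x)
}

#' Run the CD analysis workflow
#'
#' Combines whichever CD inputs are available into one report: topology
#' classification of a spectrum, exponential fit of a kinetic trace and
#' sigmoidal fits of one or more melting curves (reporting the midpoint
#' difference when exactly two are given, e.g. with and without a
#' stabilizing protein).
#'
#' @param spectrum Optional CD spectrum (`wavelength_nm`, `signal`).
#' @param kinetic Optional kinetic trace (`time`, `signal`).
#' @param melting Optional melting curve or list of melting curves
#'   (`temperature_C`, `signal`).
#' @param config An [analysis_config()].
#' @return Object of class `cd_report`: list with `provenance` and the
#'   sections that were computed (`topology`, `kinetics`, `melting`,
#'   `delta_tm_C`).
#' @export
run_cd_workflow <- function(spectrum = NULL, kinetic = NULL, melting = NULL,
                            config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(spectrum) && is.null(kinetic) && is.null(melting)) {
    stop("supply at least one of `spectrum`, `kinetic`, `melting`", call. = FALSE)
  }
  out <- list(provenance = list(
    package_version = as.character(utils::packageVersion("g4fold")),
    config_hash = config_hash(config)))
  if (!is.null(spectrum)) {
    sm <- smooth_spectrum(spectrum, config$sg_window, config$sg_order)
    out$topology <- classify_topology(sm, smooth = FALSE)
  }
  if (!is.null(kinetic)) {
    out$kinetics <- fit_exponential(kinetic, model = "auto", alpha = config$alpha)
  }
  if (!is.null(melting)) {
    if (is.data.frame(melting)) melting <- list(melting)
    out$melting <- lapply(melting, fit_melting)
    if (length(out$melting) == 2 &&
        all(vapply(out$melting, `[[`, logical(1), "converged"))) {
      out$delta_tm_C <- out$melting[[2]]$tm - out$melting[[1]]$tm
    }
  }
  structure(out, class = "cd_report")
}

#' @export
print.cd_report <- function(x, ...) {
  cat("CD workflow report\n")
  if (!is.null(x$topology)) print(x$topology)
  if (!is.null(x$kinetics)) print(x$kinetics)
  if (!is.null(x$melting)) for (m in x$melting) print(m)
  if (!is.null(x$delta_tm_C)) cat(sprintf("  delta Tm = %+.2f C\n", x$delta_tm_C))
  invisible(x)
}
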