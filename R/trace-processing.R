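#' Background-correct an intensity trajectory
#'
#' Subtracts constant background levels channel-wise. Backgrounds are either
#' supplied, or estimated from the post-bleach segment of the trace (median
#' of each channel after its detected bleach) when `NULL`. Negative corrected
#' counts are permitted: they are noise and clipping them would bias
#' downstream Gaussian fits.
#'
#' @param traj Single-molecule trajectory data.frame with columns
#'   `molecule_id`, `frame`, `time_s`, `donor`, `acceptor`.
#' @param bg_donor,bg_acceptor Background counts; `NULL` requests estimation
#'   from the post-bleach median (0 is used, with a warning, when no bleach
#'   is detectable).
#' @return The trajectory with corrected channels; attributes `bg_donor`,
#'   `bg_acceptor` record the values used. A warning is issued when a
#'   background exceeds the 95th percentile of its channel.
#' @export
background_correct <- function(traj, bg_donor = NULL, bg_acceptor = NULL) {
  check_trajectory(traj)
  if (is.null(bg_donor) || is.null(bg_acceptor)) {
    bl <- detect_photobleach(traj)
    if (is.null(bg_acceptor)) {
      bg_acceptor <- if (!is.na(bl$acceptor_bleach_frame)) {
        median(traj$acceptor[bl$acceptor_bleach_frame:nrow(traj)])
      } else {
        warning("no acceptor bleach detected; using background 0")
        0
      }
    }
    if (is.null(bg_donor)) {
      bg_donor <- if (!is.na(bl$donor_bleach_frame)) {
        median(traj$donor[bl$donor_bleach_frame:nrow(traj)])
      } else {
        warning("no donor bleach detected; using background 0")
        0
      }
    }
  }
  if (!is.finite(bg_donor) || !is.finite(bg_acceptor)) {
    stop_field("bg_donor/bg_acceptor", "must be finite")
  }
  if (bg_donor > quantile(traj$donor, 0.95)) {
    warning("donor background exceeds the 95th percentile of the channel")
  }
  if (bg_acceptor > quantile(traj$acceptor, 0.95)) {
    warning("acceptor background exceeds the 95th percentile of the channel")
  }
  traj$donor <- traj$donor - bg_donor
  traj$acceptor <- traj$acceptor - bg_acceptor
  attr(traj, "bg_donor") <- bg_donor
  attr(traj, "bg_acceptor") <- bg_acceptor
  traj
}

check_trajectory <- function(traj) {
  need <- c("molecule_id", "frame", "time_s", "donor", "acceptor")
  miss <- setdiff(need, names(traj))
  if (length(miss)) {
    stop(sprintf("trajectory is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (nrow(traj) > 1) {
    dt <- diff(traj$time_s)
    if (any(dt <= 0) || diff(range(dt)) > 1e-6) {
      stop("`time_s` must be strictly increasing with constant spacing", call. = FALSE)
    }
  }
  invisible(traj)
}

#' Detect single-step photobleaching in a trajectory
#'
#' Locates acceptor and donor photobleach events from their single-step
#' signatures. An acceptor bleach is the largest single-frame acceptor drop
#' exceeding `n_sigma` times the robust frame-to-frame noise SD, accompanied
#' by a donor rise of at least half that magnitude within one frame, after
#' which the acceptor-channel share of the signal stays collapsed (post-step
#' raw FRET ratio below `max_post_e`, which separates a bleach from a
#' high-to-low FRET transition of the molecule itself). A donor bleach is a
#' donor drop of the same significance with no anticorrelated acceptor rise
#' and the summed intensity collapsing to background.
#'
#' @param traj Raw (uncorrected) trajectory; at least 10 frames.
#' @param n_sigma Step significance threshold in robust noise SDs.
#' @param max_post_e Maximum post-step raw ratio `acceptor / (acceptor +
#'   donor)` for a step to qualify as an acceptor bleach.
#' @return list with `acceptor_bleach_frame` and `donor_bleach_frame`: the
#'   first bleached frame index, or `NA` when no step qualifies.
#' @export
detect_photobleach <- function(traj, n_sigma = 5, max_post_e = 0.25) {
  check_trajectory(traj)
  n <- nrow(traj)
  if (n < 10) stop("photobleach detection needs at least 10 frames", call. = FALSE)
  a <- traj$acceptor
  d <- traj$donor
  s_a <- robust_step_sd(a)
  s_d <- robust_step_sd(d)
  da <- diff(a)
  dd <- diff(d)

  acc_bleach <- NA_integer_
  # candidate acceptor steps, largest drop first
  cand <- which(da < -n_sigma * max(s_a, 1e-12))
  cand <- cand[order(da[cand])]
  for (i in cand) {
    rise <- max(dd[max(1, i - 1):min(n - 1, i + 1)])
    if (rise < -da[i] / 2) next
    post_a <- median(a[(i + 1):n])
    post_d <- median(d[(i + 1):n])
    tot <- post_a + post_d
    post_e <- if (tot > 0) post_a / tot else 0
    if (post_e > max_post_e) next
    # collapsed for good: acceptor never recovers above half the step
    if (quantile(a[(i + 1):n], 0.9) > a[i] - 0.5 * abs(da[i])) next
    acc_bleach <- i + 1L
    break
  }

  don_bleach <- NA_integer_
  cand <- which(dd < -n_sigma * max(s_d, 1e-12))
  cand <- cand[order(dd[cand])]
  tot_trace <- a + d
  for (i in cand) {
    # anticorrelated acceptor rise means FRET transition or acceptor event
    if (max(da[max(1, i - 1):min(n - 1, i + 1)]) > -dd[i] / 4) next
    pre_tot <- median(tot_trace[max(1, i - 9):i])
    post_tot <- median(tot_trace[(i + 1):n])
    if (post_tot > 0.3 * pre_tot) next
    don_bleach <- i + 1L
    break
  }
  list(acceptor_bleach_frame = acc_bleach, donor_bleach_frame = don_bleach)
}

#' Compute an apparent-FRET trace from a corrected trajectory
#'
#' Computes `E = acceptor / (acceptor + donor)` per frame of a
#' background-corrected trajectory. Frames with total intensity below
#' `min_total` are marked invalid; frames at or after `valid_until` (e.g. a
#' detected photobleach) are invalid as well.
#'
#' @param traj Background-corrected trajectory.
#' @param min_total Validity threshold on the summed corrected intensity;
#'   default is 10% of the trace median total.
#' @param valid_until Index of the last analyzable frame (e.g. frame before
#'   the earliest bleach); default the whole trace.
#' @return data.frame (class `fret_trace`) with columns `molecule_id`,
#'   `frame`, `time_s`, `efficiency`, `valid`; attribute `valid_until`.
#' @export
compute_fret <- function(traj, min_total = NULL, valid_until = nrow(traj)) {
  check_trajectory(traj)
  total <- traj$donor + traj$acceptor
  if (is.null(min_total)) min_total <- 0.1 * median(total)
  valid <- total >= min_total & seq_len(nrow(traj)) <= valid_until
  if (!any(valid)) {
    stop("all frames fall below the intensity threshold; empty FRET trace", call. = FALSE)
  }
  eff <- ifelse(valid, traj$acceptor / total, NA_real_)
  out <- data.frame(molecule_id = traj$molecule_id, frame = traj$frame,
                    time_s = traj$time_s, efficiency = eff, valid = valid)
  attr(out, "valid_until") <- as.integer(valid_until)
  class(out) <- c("fret_trace", "data.frame")
  out
}

#' Process an ensemble of trajectories into FRET traces
#'
#' Full per-molecule preprocessing: photobleach detection on the raw trace,
#' background correction, truncation at the earliest bleach, and FRET
#' computation with a shared validity threshold (10% of the ensemble-median
#' total intensity by default).
#'
#' @param traces Long-format trajectory table (columns `molecule_id`,
#'   `frame`, `time_s`, `donor`, `acceptor`), e.g. from
#'   [simulate_ensemble()]`$traces` or [read_trace_table()].
#' @param bg_donor,bg_acceptor Constant backgrounds applied to every
#'   molecule; `NULL` estimates them per molecule from post-bleach medians
#'   (molecules without a detected bleach fall back to 0, silently here,
#'   since many never bleach within the observation window).
#' @param min_total Validity threshold; `NULL` for the ensemble default.
#' @param detect_bleach Whether to run photobleach detection and truncate.
#' @return Long-format data.frame of per-frame efficiencies (columns
#'   `molecule_id`, `frame`, `time_s`, `efficiency`, `valid`).
#' @export
process_traces <- function(traces, bg_donor = NULL, bg_acceptor = NULL,
                           min_total = NULL, detect_bleach = TRUE) {
  per_mol <- split_by_molecule(traces)
  if (is.null(min_total)) {
    bg_d0 <- bg_donor %||% 0
    bg_a0 <- bg_acceptor %||% 0
    min_total <- 0.1 * median(traces$donor + traces$acceptor - bg_d0 - bg_a0)
  }
  out <- lapply(per_mol, function(traj) {
    valid_until <- nrow(traj)
    bgd <- bg_donor
    bga <- bg_acceptor
    if (detect_bleach && nrow(traj) >= 10) {
      bl <- detect_photobleach(traj)
      if (!is.na(bl$acceptor_bleach_frame)) {
        valid_until <- min(valid_until, bl$acceptor_bleach_frame - 1L)
        if (is.null(bga)) bga <- median(traj$acceptor[bl$acceptor_bleach_frame:nrow(traj)])
      }
      if (!is.na(bl$donor_bleach_frame)) {
        valid_until <- min(valid_until, bl$donor_bleach_frame - 1L)
        if (is.null(bgd)) bgd <- median(traj$donor[bl$donor_bleach_frame:nrow(traj)])
      }
    }
    traj$donor <- traj$donor - (bgd %||% 0)
    traj$acceptor <- traj$acceptor - (bga %||% 0)
    if (valid_until < 1) return(NULL)
    ft <- tryCatch(compute_fret(traj, min_total = min_total, valid_until = valid_until),
                   error = function(e) NULL)
    ft
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) stop("no analyzable molecules after preprocessing", call. = FALSE)
  res <- do.call(rbind, lapply(out, as.data.frame))
  rownames(res) <- NULL
  res
}

#' Per-molecule FRET value from the first valid frames
#'
#' The population-histogram statistic: the arithmetic mean of the first
#' `n_first_frames` valid FRET efficiencies of a molecule. Molecules with
#' fewer valid frames are excluded (signalled by `NA`, not an error).
#'
#' @param trace A `fret_trace` (or any data.frame with `efficiency` and
#'   `valid` columns) for one molecule.
#' @param n_first_frames Number of initial valid frames averaged (default
#'   15).
#' @return The mean efficiency, or `NA_real_` when the molecule has fewer
#'   than `n_first_frames` valid frames.
#' @export
molecule_fret_value <- function(trace, n_first_frames = 15) {
  e <- trace$efficiency[trace$valid]
  if (length(e) < n_first_frames) return(NA_real_)
  mean(e[seq_len(n_first_frames)])
}

#' Per-molecule FRET values for an ensemble
#'
#' Applies [molecule_fret_value()] to every molecule of a long-format FRET
#' table; excluded molecules (fewer than `n_first_frames` valid frames) are
#' dropped and counted.
#'
#' @param fret Long-format FRET table from [process_traces()].
#' @inheritParams molecule_fret_value
#' @return data.frame with columns `molecule_id`, `e_value`; attribute
#'   `n_excluded`.
#' @export
molecule_fret_values <- function(fret, n_first_frames = 15) {
  per_mol <- split_by_molecule(fret)
  vals <- vapply(per_mol, molecule_fret_value, numeric(1),
                 n_first_frames = n_first_frames)
  keep <- !is.na(vals)
  if (any(!keep)) {
    message(sprintf("%d molecule(s) excluded: fewer than %d valid frames",
                    sum(!keep), n_first_frames))
  }
  out <- data.frame(molecule_id = names(per_mol)[keep], e_value = vals[keep],
                    row.names = NULL)
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Build a FRET population histogram
#'
#' Bins one-value-per-molecule FRET efficiencies. The range is extended in
#' whole bins to cover any values outside it, so counts always conserve the
#' number of molecules; the underlying values are retained for value-space
#' fitting.
#'
#' @param values Numeric vector of per-molecule FRET values (>= 10), or the
#'   data.frame returned by [molecule_fret_values()].
#' @param bin_width Bin width in E units (default 0.02).
#' @param range Minimum E-axis coverage (default `c(-0.1, 1.1)`).
#' @return Object of class `fret_histogram`: list with `breaks`, `mids`,
#'   `counts`, `bin_width`, `values`.
#' @export
build_histogram <- function(values, bin_width = 0.02, range = c(-0.1, 1.1)) {
  if (is.data.frame(values)) values <- values$e_value
  values <- values[!is.na(values)]
  if (length(values) < 10) {
    stop("need at least 10 molecules to build a population histogram; collect more data",
         call. = FALSE)
  }
  lo <- min(range[1], floor(min(values) / bin_width) * bin_width)
  hi <- max(range[2], ceiling(max(values) / bin_width) * bin_width)
  breaks <- seq(lo, hi + bin_width / 2, by = bin_width)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  structure(list(breaks = h$breaks, mids = h$mids, counts = h$counts,
                 bin_width = bin_width, values = values),
            class = "fret_histogram")
}

#' @export
print.fret_histogram <- function(x, ...) {
  cat(sprintf("FRET histogram: %d molecules, %d bins of width %.3g on [%.2f, %.2f]\n",
              length(x$values), length(x$counts), x$bin_width,
              min(x$breaks), max(x$breaks)))
  invisible(x)
}
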