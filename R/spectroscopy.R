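# CD spectroscopy: smoothing, topology classification, exponential folding
# kinetics and thermal melting fits.

check_spectrum <- function(spec) {
  need <- c("wavelength_nm", "signal")
  if (!all(need %in% names(spec))) {
    stop("spectrum needs columns `wavelength_nm` and `signal`", call. = FALSE)
  }
  if (any(diff(spec$wavelength_nm) <= 0)) {
    stop("`wavelength_nm` must be strictly increasing", call. = FALSE)
  }
  invisible(spec)
}

#' Savitzky-Golay smoothing of a CD spectrum
#'
#' @param spec data.frame with columns `wavelength_nm`, `signal`.
#' @param window_points Filter window length (odd, > `poly_order`).
#' @param poly_order Polynomial order (default 3). Polynomials up to this
#'   order pass through the filter unchanged.
#' @return The spectrum with smoothed `signal`.
#' @export
smooth_spectrum <- function(spec, window_points = 11, poly_order = 3) {
  check_spectrum(spec)
  if (window_points %% 2 == 0 || window_points <= poly_order) {
    stop_field("window_points", "must be odd and greater than `poly_order`")
  }
  if (window_points >= nrow(spec)) {
    stop_field("window_points", "must be smaller than the series length")
  }
  spec$signal <- as.numeric(signal::sgolayfilt(spec$signal, p = poly_order,
                                               n = window_points))
  spec
}

# positions of local maxima/minima of a vector (interior points)
local_extrema <- function(y) {
  n <- length(y)
  if (n < 3) return(list(max = integer(0), min = integer(0)))
  i <- 2:(n - 1)
  list(max = i[y[i] > y[i - 1] & y[i] >= y[i + 1]],
       min = i[y[i] < y[i - 1] & y[i] <= y[i + 1]])
}

#' Classify G-quadruplex topology from a CD spectrum
#'
#' Rule-based call from the extrema of the (smoothed) spectrum, using the
#' canonical G4 signatures: \emph{parallel} - positive maximum in 255-270 nm
#' and negative minimum in 235-248 nm, with no positive band at or beyond
#' 285 nm; \emph{antiparallel} - positive maximum in 285-300 nm with a
#' negative signal in 255-270 nm; \emph{hybrid_or_mixture} - positive bands
#' in both 255-270 and 285-300 nm. Anything else, or a spectrum whose band
#' amplitudes stay below the noise floor, is \emph{undetermined}.
#'
#' @param spec data.frame with columns `wavelength_nm`, `signal` covering at
#'   least 230-310 nm.
#' @param smooth Smooth with [smooth_spectrum()] first (default TRUE).
#' @param noise_floor Minimum |amplitude| for a band to count; default 3x
#'   the robust SD of the smoothing residual (0 if `smooth = FALSE`).
#' @return Object of class `topology_call`: list with `label`, `evidence`
#'   (data.frame of band extrema) and `ratio_295_265`.
#' @export
classify_topology <- function(spec, smooth = TRUE, noise_floor = NULL) {
  check_spectrum(spec)
  wl <- spec$wavelength_nm
  if (min(wl) > 230 || max(wl) < 310) {
    stop("spectrum must cover 230-310 nm for topology classification", call. = FALSE)
  }
  raw <- spec$signal
  sm <- if (smooth && nrow(spec) > 11) smooth_spectrum(spec)$signal else raw
  if (is.null(noise_floor)) {
    noise_floor <- if (smooth) 3 * stats::mad(raw - sm) else 0
  }

  ex <- local_extrema(sm)
  band_max <- function(lo, hi) {
    i <- ex$max[wl[ex$max] >= lo & wl[ex$max] <= hi]
    i <- i[sm[i] > noise_floor]
    if (length(i)) i[which.max(sm[i])] else NA_integer_
  }
  band_min <- function(lo, hi) {
    i <- ex$min[wl[ex$min] >= lo & wl[ex$min] <= hi]
    i <- i[sm[i] < -noise_floor]
    if (length(i)) i[which.min(sm[i])] else NA_integer_
  }

  p_260 <- band_max(255, 270)   # parallel-type positive band
  n_240 <- band_min(235, 248)
  p_290 <- band_max(285, 300)   # antiparallel-type positive band
  n_260 <- band_min(255, 270)

  label <- if (!is.na(p_290) && !is.na(n_260)) {
    "antiparallel"
  } else if (!is.na(p_260) && !is.na(p_290)) {
    "hybrid_or_mixture"
  } else if (!is.na(p_260) && !is.na(n_240)) {
    "parallel"
  } else {
    "undetermined"
  }

  ev_idx <- c(pos_255_270 = p_260, neg_235_248 = n_240,
              pos_285_300 = p_290, neg_255_270 = n_260)
  evidence <- data.frame(
    band = names(ev_idx),
    wavelength_nm = ifelse(is.na(ev_idx), NA_real_, wl[ev_idx]),
    amplitude = ifelse(is.na(ev_idx), NA_real_, sm[ev_idx]),
    row.names = NULL
  )
  at <- function(nm) sm[which.min(abs(wl - nm))]
  ratio <- if (abs(at(265)) > 0) at(295) / at(265) else NA_real_
  structure(list(label = label, evidence = evidence,
                 ratio_295_265 = ratio, noise_floor = noise_floor),
            class = "topology_call")
}

#' @export
print.topology_call <- function(x, ...) {
  cat(sprintf("G4 topology call: %s (theta295/theta265 = %.3g)\n",
              x$label, x$ratio_295_265))
  invisible(x)
}

#' Fit exponential folding kinetics to a CD trace
#'
#' Fits `f(t) = a (1 - exp(-b t))` (mono) or
#' `f(t) = a (1 - exp(-b t)) + c (1 - exp(-d t))` (bi) by least squares.
#' With `model = "auto"` the biphasic model is selected only when it reduces
#' the residual sum of squares per an F-test at `alpha` \emph{and} the two
#' rates are identifiable (`b / d >= rate_ratio_min`); the printed bi form
#' degenerates when `b = d`. By convention `b >= d` (fast phase first).
#'
#' @param trace data.frame with columns `time`, `signal` (>= 10 points); the
#'   attribute `time_unit` ("s" or "min"), if present, sets the rate unit.
#' @param model `"auto"`, `"mono"` or `"bi"`.
#' @param alpha F-test level for model selection (default 0.01).
#' @param rate_ratio_min Identifiability guard on `b / d` (default 3).
#' @return Object of class `exp_fit`: list with `model`, `coefficients`
#'   (`a`, `b` and for bi `c`, `d`), `se`, `rss`, `n`, `converged`,
#'   `time_unit`, and the rate(s) expressed in both `per_s` and `per_min`.
#' @export
fit_exponential <- function(trace, model = c("auto", "mono", "bi"),
                            alpha = 0.01, rate_ratio_min = 3) {
  model <- match.arg(model)
  if (!all(c("time", "signal") %in% names(trace))) {
    stop("kinetic trace needs columns `time` and `signal`", call. = FALSE)
  }
  if (nrow(trace) < 10) stop("need at least 10 points", call. = FALSE)
  t <- trace$time
  y <- trace$signal
  unit <- attr(trace, "time_unit") %||% "s"

  fit_mono <- function() {
    a0 <- mean(tail(y, max(3, length(y) %/% 10)))
    if (a0 == 0) a0 <- max(abs(y)) * sign(y[which.max(abs(y))])
    half <- t[which.min(abs(y - 0.5 * a0))]
    b0 <- if (half > 0) log(2) / half else 1 / mean(t)
    tryCatch(
      minpack.lm::nlsLM(y ~ a * (1 - exp(-b * t)),
                        data = data.frame(t = t, y = y),
                        start = list(a = a0, b = b0), lower = c(-Inf, 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
  }
  fit_bi <- function(mono_fit) {
    st <- if (!is.null(mono_fit)) coef(mono_fit) else c(a = max(y), b = 1 / mean(t))
    tryCatch(
      minpack.lm::nlsLM(y ~ a * (1 - exp(-b * t)) + cc * (1 - exp(-d * t)),
                        data = data.frame(t = t, y = y),
                        start = list(a = st[["a"]] / 2, b = st[["b"]] * 4,
                                     cc = st[["a"]] / 2, d = st[["b"]] / 2),
                        lower = c(-Inf, 1e-12, -Inf, 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
  }

  m1 <- fit_mono()
  pick <- model
  m2 <- NULL
  if (model != "mono") {
    m2 <- fit_bi(m1)
    if (model == "auto") {
      pick <- "mono"
      if (!is.null(m1) && !is.null(m2)) {
        rss1 <- sum(residuals(m1)^2)
        rss2 <- sum(residuals(m2)^2)
        df2 <- length(y) - 4
        co2 <- coef(m2)
        rates <- sort(c(co2[["b"]], co2[["d"]]), decreasing = TRUE)
        identifiable <- rates[2] > 0 && rates[1] / rates[2] >= rate_ratio_min
        if (df2 > 0 && rss2 < rss1 && identifiable) {
          p <- if (rss2 <= 0) 0 else
            pf(((rss1 - rss2) / 2) / (rss2 / df2), 2, df2, lower.tail = FALSE)
          if (p < alpha) pick <- "bi"
        }
      } else if (is.null(m1) && !is.null(m2)) {
        pick <- "bi"
      }
    }
  }

  if (pick == "mono") {
    if (is.null(m1)) {
      return(structure(list(model = "mono", coefficients = NULL, se = NULL,
                            rss = NA_real_, n = length(y), converged = FALSE,
                            time_unit = unit, diagnostics = "mono fit failed"),
                       class = "exp_fit"))
    }
    co <- coef(m1)
    se <- sqrt(diag(vcov(m1)))
    fit <- m1
    co_out <- c(a = unname(co[["a"]]), b = unname(co[["b"]]))
  } else {
    if (is.null(m2)) {
      return(structure(list(model = "bi", coefficients = NULL, se = NULL,
                            rss = NA_real_, n = length(y), converged = FALSE,
                            time_unit = unit, diagnostics = "bi fit failed"),
                       class = "exp_fit"))
    }
    co <- coef(m2)
    se <- sqrt(diag(vcov(m2)))
    # fast phase first: b >= d
    if (co[["b"]] < co[["d"]]) {
      co <- c(a = co[["cc"]], b = co[["d"]], cc = co[["a"]], d = co[["b"]])
      se <- se[c("cc", "d", "a", "b")]
      names(se) <- c("a", "b", "cc", "d")
    }
    fit <- m2
    co_out <- c(a = unname(co[["a"]]), b = unname(co[["b"]]),
                c = unname(co[["cc"]]), d = unname(co[["d"]]))
  }
  to_per_s <- if (unit == "min") 1 / 60 else 1
  rates <- co_out[names(co_out) %in% c("b", "d")]
  structure(
    list(model = pick, coefficients = co_out,
         se = setNames(as.numeric(se), sub("cc", "c", names(se))),
         rss = sum(residuals(fit)^2), n = length(y), converged = TRUE,
         time_unit = unit,
         rates_per_s = rates * to_per_s,
         rates_per_min = rates * to_per_s * 60),
    class = "exp_fit"
  )
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("%s-exponential fit (%s)\n", x$model,
              if (x$converged) "converged" else "NOT converged"))
  if (x$converged) {
    cat("  ", paste(sprintf("%s = %.4g", names(x$coefficients), x$coefficients),
                    collapse = ", "), "\n", sep = "")
    cat(sprintf("  rate(s): %s min^-1\n",
                paste(signif(x$rates_per_min, 4), collapse = ", ")))
  }
  invisible(x)
}

#' Fit a sigmoidal thermal melting curve
#'
#' Boltzmann fit `theta(T) = theta_f + (theta_u - theta_f) /
#' (1 + exp((tm - T) / width))`; at the midpoint `tm` the signal is exactly
#' between the folded and unfolded baselines.
#'
#' @param curve data.frame with columns `temperature_C`, `signal` (>= 20
#'   points spanning both baselines).
#' @return Object of class `melting_fit`: list with `tm`, `tm_se`, `width`,
#'   `theta_folded`, `theta_unfolded`, `rss`, `converged`.
#' @export
fit_melting <- function(curve) {
  if (!all(c("temperature_C", "signal") %in% names(curve))) {
    stop("melting curve needs columns `temperature_C` and `signal`", call. = FALSE)
  }
  if (nrow(curve) < 20) stop("need at least 20 points", call. = FALSE)
  o <- order(curve$temperature_C)
  tt <- curve$temperature_C[o]
  y <- curve$signal[o]
  nb <- max(5, length(y) %/% 15)
  tf0 <- mean(head(y, nb))
  tu0 <- mean(tail(y, nb))
  if (abs(tu0 - tf0) < 1e-12) {
    return(structure(list(tm = NA_real_, tm_se = NA_real_, width = NA_real_,
                          theta_folded = tf0, theta_unfolded = tu0,
                          rss = NA_real_, converged = FALSE,
                          diagnostics = "flat curve: no transition to fit"),
                     class = "melting_fit"))
  }
  tm0 <- tt[which.min(abs(y - (tf0 + tu0) / 2))]
  resid_fn <- function(p) {
    y - (p[["tf"]] + (p[["tu"]] - p[["tf"]]) / (1 + exp((p[["tm"]] - tt) / p[["w"]])))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(tf = tf0, tu = tu0, tm = tm0, w = 3),
                       lower = c(-Inf, -Inf, min(tt), 1e-3),
                       upper = c(Inf, Inf, max(tt), diff(range(tt))),
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) {
    return(structure(list(tm = NA_real_, tm_se = NA_real_, width = NA_real_,
                          theta_folded = tf0, theta_unfolded = tu0,
                          rss = NA_real_, converged = FALSE,
                          diagnostics = "optimizer failed"),
                     class = "melting_fit"))
  }
  co <- fit$par
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 4))
  structure(
    list(tm = unname(co[["tm"]]), tm_se = unname(se[3]),
         width = unname(co[["w"]]),
         theta_folded = unname(co[["tf"]]), theta_unfolded = unname(co[["tu"]]),
         rss = sum(fit$fvec^2), converged = TRUE),
    class = "melting_fit"
  )
}

#' @export
print.melting_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("Melting fit: Tm = %.2f +/- %.2f C (width %.2f C)\n",
                x$tm, x$tm_se, x$width))
  } else {
    cat("Melting fit did not converge:", x$diagnostics, "\n")
  }
  invisible(x)
}
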