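# Binding-affinity estimation and NMR chemical-shift perturbations.

#' Bound fraction under the single-site depletion model
#'
#' Exact 1:1 binding with ligand depletion: for total protein `P`, total
#' labeled DNA `D` and dissociation constant `K_D` (all in the same
#' concentration unit),
#' `f = ((P + D + K_D) - sqrt((P + D + K_D)^2 - 4 P D)) / (2 D)`.
#' Reduces to the hyperbola `P / (P + K_D)` when `D << K_D`.
#'
#' @param protein_total Total titrant concentration(s), >= 0 (vectorized).
#' @param dna_total Total labeled-species concentration, > 0.
#' @param k_d Dissociation constant, > 0.
#' @return Bound fraction(s) in `[0, 1]`.
#' @export
#' @examples
#' fraction_bound(4.9, 0.02, 4.9)  # ~0.4995 at P = K_D with trace DNA
fraction_bound <- function(protein_total, dna_total, k_d) {
  if (any(protein_total < 0)) stop_field("protein_total", "must be >= 0")
  if (dna_total <= 0) stop_field("dna_total", "must be > 0")
  if (k_d <= 0) stop_field("k_d", "must be > 0")
  s <- protein_total + dna_total + k_d
  disc <- pmax(s^2 - 4 * protein_total * dna_total, 0)
  pmin(pmax((s - sqrt(disc)) / (2 * dna_total), 0), 1)
}

#' Fit a single-site binding isotherm to a titration series
#'
#' Least-squares fit of `response = r_free + (r_bound - r_free) * f_bound`
#' to a (serial-dilution) titration, with the bound fraction from the
#' ligand-depletion quadratic ([fraction_bound()]) or, optionally, the
#' hyperbolic approximation. The fit flags titrations that do not reach
#' saturation: `saturation_reached` is `FALSE` when the fitted `r_bound`
#' overshoots the maximum observed response by more than 20% of the fitted
#' amplitude.
#'
#' @param series data.frame with columns `concentration_uM` (strictly
#'   descending), `response`; attribute `dna_total_uM` (or argument
#'   `dna_total`). At least 8 points, and the response must vary by more
#'   than 3x its noise level.
#' @param model `"depletion"` (default) or `"hyperbolic"`.
#' @param dna_total Labeled-species concentration (uM); default from the
#'   series attribute, else 0.02.
#' @return Object of class `binding_fit`: list with `k_d`, `k_d_se`,
#'   `r_free`, `r_bound`, `saturation_reached`, `rss`, `model`.
#' @export
fit_binding_isotherm <- function(series, model = c("depletion", "hyperbolic"),
                                 dna_total = NULL) {
  model <- match.arg(model)
  if (!all(c("concentration_uM", "response") %in% names(series))) {
    stop("titration needs columns `concentration_uM` and `response`", call. = FALSE)
  }
  conc <- series$concentration_uM
  y <- series$response
  if (any(conc <= 0)) stop_field("concentration_uM", "must be > 0")
  if (any(diff(conc) >= 0)) stop_field("concentration_uM", "must be strictly descending")
  if (length(conc) < 8) stop("need at least 8 titration points", call. = FALSE)
  if (is.null(dna_total)) dna_total <- attr(series, "dna_total_uM") %||% 0.02

  # noise level from second differences of the (smooth) isotherm
  noise <- sd(diff(diff(y))) / sqrt(6)
  if (!is.finite(noise)) noise <- 0
  if (diff(range(y)) <= 3 * noise || diff(range(y)) == 0) {
    stop("response is flat relative to its noise; no binding transition to fit",
         call. = FALSE)
  }

  o <- order(conc)
  half <- (min(y) + max(y)) / 2
  kd0 <- approx(y[o], conc[o], xout = half, ties = mean)$y
  if (is.na(kd0) || kd0 <= 0) kd0 <- stats::median(conc)
  rf0 <- y[which.min(conc)]
  rb0 <- y[which.max(conc)]

  f_model <- if (model == "depletion") {
    function(kd) fraction_bound(conc, dna_total, kd)
  } else {
    function(kd) conc / (conc + kd)
  }
  fit <- minpack.lm::nls.lm(
    par = c(kd = kd0, rf = rf0, rb = rb0),
    lower = c(1e-9, -Inf, -Inf),
    fn = function(p) y - (p[["rf"]] + (p[["rb"]] - p[["rf"]]) * f_model(p[["kd"]])),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  p <- fit$par
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 3))
  amp <- abs(p[["rb"]] - p[["rf"]])
  overshoot <- (p[["rb"]] - max(y)) * sign(p[["rb"]] - p[["rf"]])
  structure(
    list(k_d = unname(p[["kd"]]), k_d_se = unname(se[1]),
         r_free = unname(p[["rf"]]), r_bound = unname(p[["rb"]]),
         saturation_reached = overshoot <= 0.2 * amp,
         rss = sum(fit$fvec^2), model = model,
         dna_total_uM = dna_total,
         converged = fit$info %in% 1:4),
    class = "binding_fit"
  )
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Binding isotherm fit (%s): K_D = %.3g +/- %.2g uM%s\n",
              x$model, x$k_d, x$k_d_se,
              if (x$saturation_reached) "" else "  [saturation NOT reached]"))
  invisible(x)
}

#' Chemical shift perturbation
#'
#' Combined amide 1H/15N perturbation
#' `CSP = sqrt((0.102 * delta_n)^2 + delta_h^2)` (ppm), symmetric in the
#' sign of both inputs. Vectorized.
#'
#' @param delta_h 1H chemical-shift change (ppm).
#' @param delta_n 15N chemical-shift change (ppm).
#' @return CSP values (ppm, >= 0).
#' @export
compute_csp <- function(delta_h, delta_n) {
  if (any(!is.finite(delta_h)) || any(!is.finite(delta_n))) {
    stop_field("delta_h/delta_n", "must be finite")
  }
  sqrt((0.102 * delta_n)^2 + delta_h^2)
}

#' Rank residues by chemical shift perturbation
#'
#' Sorts a peak-shift table by CSP and flags residues whose CSP exceeds the
#' conventional mean + 1 SD cutoff (the "maximal CSP" residues of a
#' titration).
#'
#' @param shifts data.frame with columns `residue`, `delta_h_ppm`,
#'   `delta_n_ppm` (>= 5 residues).
#' @return The table with added `csp_ppm` and `outlier` columns, sorted by
#'   decreasing CSP; attribute `cutoff_ppm`.
#' @export
csp_rank <- function(shifts) {
  need <- c("residue", "delta_h_ppm", "delta_n_ppm")
  if (!all(need %in% names(shifts))) {
    stop(sprintf("peak-shift table needs columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(shifts) < 5) stop("need at least 5 residues", call. = FALSE)
  shifts$csp_ppm <- compute_csp(shifts$delta_h_ppm, shifts$delta_n_ppm)
  cutoff <- mean(shifts$csp_ppm) + sd(shifts$csp_ppm)
  shifts$outlier <- shifts$csp_ppm > cutoff
  out <- shifts[order(-shifts$csp_ppm), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cutoff_ppm") <- cutoff
  out
}
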