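# Gaussian decomposition of FRET population histograms.

gaussian_sum <- function(x, means, sds, amps) {
  y <- rep(0, length(x))
  for (i in seq_along(means)) {
    y <- y + amps[i] * exp(-(x - means[i])^2 / (2 * sds[i]^2))
  }
  y
}

# Local maxima of a count vector (after light median smoothing), returned as
# bin indices sorted by height.
find_peaks <- function(counts, min_sep_bins = 5) {
  y <- if (length(counts) >= 5) stats::runmed(counts, 3) else counts
  n <- length(y)
  idx <- which(y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf) & y > 0)
  idx <- idx[order(-y[idx])]
  picked <- integer(0)
  for (i in idx) {
    if (all(abs(i - picked) >= min_sep_bins)) picked <- c(picked, i)
  }
  picked
}

# Component means from a fixed-bandwidth kernel density of the values:
# robust to the histogram bin width, and sensitive to minority populations
# down to a few percent. Returns a sorted vector of 1 or 2 candidate means.
density_modes <- function(values, n_components, bw = 0.025,
                          min_sep = 0.1, min_height = 0.02) {
  d <- stats::density(values, bw = bw, n = 512)
  n <- length(d$y)
  ex <- which(d$y > c(-Inf, d$y[-n]) & d$y >= c(d$y[-1], -Inf))
  ex <- ex[d$y[ex] > min_height * max(d$y)]
  ex <- ex[order(-d$y[ex])]
  picked <- integer(0)
  for (i in ex) {
    if (all(abs(d$x[i] - d$x[picked]) >= min_sep)) picked <- c(picked, i)
    if (length(picked) == n_components) break
  }
  modes <- d$x[picked]
  if (length(modes) < n_components) {
    # unresolved minority component: pair the mode with the mean of the
    # values on the far side of it
    mode <- modes[1] %||% stats::median(values)
    far <- values[abs(values - mode) > 1.5 * min_sep]
    other <- if (length(far) >= 3) mean(far) else mode + 0.3
    modes <- c(mode, other)[seq_len(n_components)]
  }
  sort(modes)
}

# Initial (amps, means, sds) from candidate means by nearest-mean clustering.
cluster_init <- function(values, means0, bin_width) {
  k <- length(means0)
  assign <- vapply(values, function(v) which.min(abs(v - means0)), integer(1))
  sds <- vapply(seq_len(k), function(i) {
    x <- values[assign == i]
    if (length(x) >= 3) max(sd(x), bin_width) else 0.05
  }, numeric(1))
  counts <- tabulate(assign, k)
  amps <- pmax(counts * bin_width / (sds * sqrt(2 * pi)), 1)
  list(means = means0, sds = sds, amps = amps)
}

#' Fit a 1- or 2-Gaussian population model to a FRET histogram
#'
#' Least-squares fit of a sum of Gaussians
#' `sum_i a_i * exp(-(x - mu_i)^2 / (2 sigma_i^2))` to the histogram bin
#' counts at bin centers, as used for smFRET population decomposition.
#' Relative population contributions are the areas under each component,
#' `fraction_i = 100 * a_i * sigma_i / sum_j a_j * sigma_j`. Initialization
#' is from the largest well-separated local maxima of the histogram (or from
#' value quantiles when fewer peaks are visible than components requested);
#' given data and initialization the fit is deterministic.
#'
#' @param hist A [build_histogram()] object (>= 5 occupied bins).
#' @param n_components 1 or 2; `NULL` selects automatically via
#'   [select_n_components()].
#' @param init Optional list with numeric `means`, `sds`, `amps` overriding
#'   the automatic initialization.
#' @return Object of class `gmix_fit`: list with `n_components`, `means`
#'   (ascending), `sds`, `amplitudes`, `fractions` (percent, summing to 100),
#'   `rss`, `converged`, `fitted`, and the data used. Component SDs are
#'   bounded below by half the bin width. Non-convergence yields a flagged
#'   fit (`converged = FALSE`) carrying the initialization.
#' @export
fit_gaussian_mixture <- function(hist, n_components = NULL, init = NULL) {
  stopifnot(inherits(hist, "fret_histogram"))
  if (is.null(n_components)) {
    n_components <- select_n_components(hist)
  }
  if (!n_components %in% c(1L, 2L)) {
    stop_field("n_components", "must be 1 or 2")
  }
  if (sum(hist$counts > 0) < 5) {
    stop("histogram has fewer than 5 occupied bins", call. = FALSE)
  }
  x <- hist$mids
  y <- hist$counts
  k <- n_components

  inits <- if (!is.null(init)) {
    list(init)
  } else {
    # multi-start: kernel-density modes (bin-width independent) and, when
    # visible, raw histogram peaks; best residual wins
    cand <- list(cluster_init(hist$values,
                              density_modes(hist$values, k), hist$bin_width))
    peaks <- find_peaks(y)
    if (length(peaks) >= k) {
      pk <- sort(peaks[seq_len(k)])
      cand <- c(cand, list(list(means = x[pk], sds = rep(0.05, k),
                                amps = pmax(y[pk], 1))))
    }
    cand
  }

  sd_floor <- hist$bin_width / 2
  lower <- c(rep(0, k), rep(min(x), k), rep(sd_floor, k))
  upper <- c(rep(Inf, k), rep(max(x), k), rep(diff(range(x)) / 2, k))
  resid_fn <- function(p) {
    y - gaussian_sum(x, means = p[(k + 1):(2 * k)], sds = p[(2 * k + 1):(3 * k)],
                     amps = p[1:k])
  }

  best <- NULL
  par_fallback <- NULL
  for (ini in inits) {
    par0 <- pmin(pmax(c(ini$amps, ini$means, pmax(ini$sds, sd_floor)), lower), upper)
    if (is.null(par_fallback)) par_fallback <- par0
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || sum(fit$fvec^2) < sum(best$fvec^2))) {
      best <- fit
    }
  }
  fit <- best
  converged <- !is.null(fit) && fit$info %in% 1:4
  p <- if (is.null(fit)) par_fallback else fit$par
  amps <- p[1:k]
  means <- p[(k + 1):(2 * k)]
  sds <- p[(2 * k + 1):(3 * k)]
  ord <- order(means)
  amps <- amps[ord]; means <- means[ord]; sds <- sds[ord]
  areas <- amps * sds
  fractions <- if (sum(areas) > 0) 100 * areas / sum(areas) else rep(100 / k, k)
  fitted <- gaussian_sum(x, means, sds, amps)

  structure(
    list(n_components = k, means = means, sds = sds, amplitudes = amps,
         fractions = fractions, rss = sum((y - fitted)^2),
         converged = converged, fitted = fitted, mids = x, counts = y,
         bin_width = hist$bin_width, n_molecules = length(hist$values),
         info = if (is.null(fit)) "optimizer error" else fit$message),
    class = "gmix_fit"
  )
}

#' @export
print.gmix_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit (%d component%s, %s)\n", x$n_components,
              if (x$n_components > 1) "s" else "",
              if (x$converged) "converged" else "NOT converged"))
  for (i in seq_len(x$n_components)) {
    cat(sprintf("  component %d: mean E = %.3f, sd = %.3f, area fraction = %.1f%%\n",
                i, x$means[i], x$sds[i], x$fractions[i]))
  }
  invisible(x)
}

#' Choose between one and two Gaussian populations
#'
#' Fits both models and picks two components when the extra component is
#' statistically justified (F-test on the residual sum of squares at
#' `alpha`), the fitted means are separated by more than the larger
#' component SD, and both components hold at least `min_fraction` percent of
#' the area (a sliver below that is indistinguishable from counting noise at
#' typical ensemble sizes); otherwise one.
#'
#' @param hist A [build_histogram()] object.
#' @param alpha Significance level of the F-test (default 0.01).
#' @param min_fraction Minimum percent area per component (default 5).
#' @return 1 or 2 (integer).
#' @export
select_n_components <- function(hist, alpha = 0.01, min_fraction = 5) {
  f1 <- fit_gaussian_mixture(hist, 1L)
  f2 <- fit_gaussian_mixture(hist, 2L)
  if (!f2$converged) return(1L)
  n <- length(hist$mids)
  df2 <- n - 6
  if (df2 <= 0) return(1L)
  if (f2$rss <= 0) {
    p <- 0
  } else {
    fstat <- ((f1$rss - f2$rss) / 3) / (f2$rss / df2)
    if (!is.finite(fstat) || fstat < 0) return(1L)
    p <- pf(fstat, 3, df2, lower.tail = FALSE)
  }
  sep <- abs(diff(f2$means)) > max(f2$sds)
  substantial <- min(f2$fractions) >= min_fraction
  if (p < alpha && sep && substantial) 2L else 1L
}

#' Maximum-likelihood Gaussian mixture fit in value space
#'
#' Direct EM fit (via \pkg{mclust}) of a Gaussian mixture to the
#' per-molecule FRET values themselves, bypassing the histogram. Serves as
#' the internal cross-check for [fit_gaussian_mixture()]: area fractions
#' from the histogram fit and mixing weights from the likelihood fit should
#' agree within a few percentage points.
#'
#' @param values Numeric per-molecule FRET values (or a [build_histogram()]
#'   object, whose stored values are used).
#' @param n_components 1 or 2.
#' @return Object of class `gmix_fit` with weights as `fractions` (percent).
#' @export
fit_gaussian_mixture_values <- function(values, n_components = 2L) {
  if (inherits(values, "fret_histogram")) values <- values$values
  if (!n_components %in% c(1L, 2L)) stop_field("n_components", "must be 1 or 2")
  fit <- mclust::Mclust(values, G = n_components, modelNames = "V",
                        verbose = FALSE)
  if (is.null(fit)) stop("value-space mixture fit failed", call. = FALSE)
  means <- as.numeric(fit$parameters$mean)
  sds <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sds) == 1L) sds <- rep(sds, n_components)
  w <- as.numeric(fit$parameters$pro)
  ord <- order(means)
  structure(
    list(n_components = n_components, means = means[ord], sds = sds[ord],
         amplitudes = w[ord] * length(values),
         fractions = 100 * w[ord] / sum(w), rss = NA_real_,
         converged = TRUE, fitted = NULL, mids = NULL, counts = NULL,
         bin_width = NA_real_, n_molecules = length(values),
         info = "value-space ML (EM)"),
    class = "gmix_fit"
  )
}

#' Population shift between two conditions
#'
#' Compares two mixture fits (e.g. before/after adding a G4-binding
#' protein), matching components by nearest mean, and reports per-component
#' fraction deltas and mean shifts. A change in the number of components is
#' reported as a refolding of the conformational landscape rather than an
#' error.
#'
#' @param fit_before,fit_after Converged [fit_gaussian_mixture()] objects.
#' @return list with `landscape_change` (logical) and, when the component
#'   counts match, a data.frame `components` with columns `mean_before`,
#'   `mean_after`, `mean_shift`, `fraction_before`, `fraction_after`,
#'   `fraction_delta` (percentage points).
#' @export
population_shift <- function(fit_before, fit_after) {
  stopifnot(inherits(fit_before, "gmix_fit"), inherits(fit_after, "gmix_fit"))
  if (!fit_before$converged || !fit_after$converged) {
    stop("both fits must have converged", call. = FALSE)
  }
  if (fit_before$n_components != fit_after$n_components) {
    return(list(landscape_change = TRUE,
                n_components = c(before = fit_before$n_components,
                                 after = fit_after$n_components)))
  }
  k <- fit_before$n_components
  # nearest-mean matching; with components sorted ascending, the identity
  # assignment minimizes total |mean shift| unless the landscape reordered
  perm <- seq_len(k)
  if (k == 2L) {
    straight <- sum(abs(fit_after$means - fit_before$means))
    crossed <- sum(abs(rev(fit_after$means) - fit_before$means))
    if (crossed < straight) perm <- c(2L, 1L)
  }
  comp <- data.frame(
    mean_before = fit_before$means,
    mean_after = fit_after$means[perm],
    fraction_before = fit_before$fractions,
    fraction_after = fit_after$fractions[perm]
  )
  comp$mean_shift <- comp$mean_after - comp$mean_before
  comp$fraction_delta <- comp$fraction_after - comp$fraction_before
  list(landscape_change = FALSE, components = comp)
}
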