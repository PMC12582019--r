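#' Simulate a CD kinetic trace
#'
#' Generates a folding kinetic trace at a fixed wavelength from the
#' mono-exponential model `f(t) = a * (1 - exp(-b t))` or, when `c` and `d`
#' are supplied, the bi-exponential model
#' `f(t) = a * (1 - exp(-b t)) + c * (1 - exp(-d t))`, plus additive Gaussian
#' noise. The time unit of `t_grid` is carried through unchanged (the
#' matching rates `b`, `d` are in its reciprocal unit).
#'
#' @param a,b Amplitude and rate of the first phase (`b > 0`).
#' @param c,d Optional amplitude and rate of a second phase (`d > 0`).
#' @param t_grid Strictly increasing time grid.
#' @param noise_sd SD of additive Gaussian noise, in signal units.
#' @param seed RNG seed.
#' @param time_unit Label recorded on the output ("s" or "min").
#' @param wavelength_nm Wavelength label recorded on the output (265 or 295
#'   by convention).
#' @return data.frame with columns `time`, `signal` and attributes
#'   `time_unit`, `wavelength_nm`.
#' @export
simulate_cd_kinetics <- function(a, b, c = NULL, d = NULL, t_grid,
                                 noise_sd = 0, seed = NULL,
                                 time_unit = "min", wavelength_nm = 295) {
  check_scalar(a, "a"); check_scalar(b, "b")
  if (b <= 0) stop_field("b", "rate must be > 0")
  if (!is.null(c)) {
    check_scalar(c, "c")
    if (is.null(d)) stop_field("d", "required when `c` is given")
    check_scalar(d, "d")
    if (d <= 0) stop_field("d", "rate must be > 0")
  }
  if (any(diff(t_grid) <= 0)) stop_field("t_grid", "must be strictly increasing")
  y <- a * (1 - exp(-b * t_grid))
  if (!is.null(c)) y <- y + c * (1 - exp(-d * t_grid))
  y <- with_preserved_seed(seed, y + rnorm(length(t_grid), 0, noise_sd))
  structure(data.frame(time = t_grid, signal = y),
            time_unit = time_unit, wavelength_nm = wavelength_nm)
}

#' Simulate a thermal melting curve
#'
#' Boltzmann sigmoid
#' `theta(T) = theta_folded + (theta_unfolded - theta_folded) /
#' (1 + exp((tm - T) / width))`, sampled on a regular temperature grid with
#' additive Gaussian noise. At `T = tm` the noiseless signal is exactly
#' midway between the baselines.
#'
#' @param tm Melting midpoint in degrees C, inside `t_range`.
#' @param width Transition width in degrees C (> 0).
#' @param theta_folded,theta_unfolded Low- and high-temperature baselines
#'   (ellipticity, mdeg).
#' @param t_range Temperature range scanned, within `[0, 110]` degrees C.
#' @param step Grid step in degrees C.
#' @param noise_sd SD of additive Gaussian noise (mdeg).
#' @param seed RNG seed.
#' @return data.frame with columns `temperature_C`, `signal`.
#' @export
simulate_melting_curve <- function(tm, width = 4, theta_folded = 10,
                                   theta_unfolded = 0, t_range = c(25, 95),
                                   step = 0.5, noise_sd = 0, seed = NULL) {
  check_scalar(tm, "tm"); check_scalar(width, "width")
  if (width <= 0) stop_field("width", "must be > 0")
  if (t_range[1] < 0 || t_range[2] > 110 || t_range[1] >= t_range[2]) {
    stop_field("t_range", "must be increasing and within [0, 110] degrees C")
  }
  temp <- seq(t_range[1], t_range[2], by = step)
  y <- theta_folded + (theta_unfolded - theta_folded) / (1 + exp((tm - temp) / width))
  y <- with_preserved_seed(seed, y + rnorm(length(temp), 0, noise_sd))
  data.frame(temperature_C = temp, signal = y)
}

#' Simulate a binding titration series
#'
#' Generates an MST-style 1:1 serial-dilution titration. Responses follow
#' `r_free + (r_bound - r_free) * f_bound`, with the bound fraction from the
#' single-site ligand-depletion quadratic ([fraction_bound()]). The default
#' design follows a 16-point 1:1 dilution from 200 uM with 20 nM labeled
#' DNA.
#'
#' @param k_d Dissociation constant (uM, > 0).
#' @param dna_total Labeled DNA concentration (uM, > 0).
#' @param top_conc Highest titrant (protein) concentration (uM).
#' @param n_points Number of dilution points.
#' @param dilution_factor Serial dilution factor (> 1).
#' @param r_free,r_bound Response of free and fully bound DNA.
#' @param noise_frac Gaussian noise SD as a fraction of the response
#'   amplitude `|r_bound - r_free|`.
#' @param seed RNG seed.
#' @return data.frame with columns `concentration_uM` (descending),
#'   `response`; attribute `dna_total_uM`.
#' @export
simulate_titration <- function(k_d, dna_total = 0.02, top_conc = 200,
                               n_points = 16, dilution_factor = 2,
                               r_free = 0, r_bound = 1, noise_frac = 0,
                               seed = NULL) {
  check_scalar(k_d, "k_d")
  if (k_d <= 0) stop_field("k_d", "must be > 0")
  if (dna_total <= 0) stop_field("dna_total", "must be > 0")
  if (top_conc <= 0) stop_field("top_conc", "must be > 0")
  if (dilution_factor <= 1) stop_field("dilution_factor", "must be > 1")
  conc <- top_conc / dilution_factor^(seq_len(n_points) - 1)
  f <- fraction_bound(conc, dna_total, k_d)
  y <- r_free + (r_bound - r_free) * f
  y <- with_preserved_seed(
    seed, y + rnorm(n_points, 0, noise_frac * abs(r_bound - r_free)))
  structure(data.frame(concentration_uM = conc, response = y),
            dna_total_uM = dna_total)
}

# Gaussian band sets realizing the canonical G4 CD signatures:
# parallel: +264 / -240; antiparallel: +295, +240 / -260;
# hybrid: positive bands at both 264 and 290.
cd_band_table <- function(topology) {
  switch(topology,
    parallel = data.frame(center = c(264, 240), height = c(1, -0.55), width = c(9, 7)),
    antiparallel = data.frame(center = c(295, 240, 262), height = c(1, 0.5, -0.6), width = c(9, 7, 8)),
    hybrid = data.frame(center = c(264, 290, 240), height = c(0.8, 0.7, -0.4), width = c(9, 8, 7)),
    stop_field("topology_label", "must be one of 'parallel', 'antiparallel', 'hybrid'")
  )
}

#' Simulate a CD spectrum of a G-quadruplex topology
#'
#' Builds a 200-320 nm spectrum as a sum of Gaussian bands realizing the
#' canonical topology signatures: parallel structures show a positive band
#' near 264 nm and a negative band near 240 nm; antiparallel structures show
#' positive bands near 295 and 240 nm with a negative band near 260 nm;
#' hybrid (or mixed) structures show positive bands near both 264 and
#' 290 nm.
#'
#' @param topology_label One of `"parallel"`, `"antiparallel"`, `"hybrid"`.
#' @param amplitude Peak amplitude scale (mdeg); 0 gives a flat spectrum.
#' @param noise_sd SD of additive Gaussian noise (mdeg).
#' @param seed RNG seed.
#' @param wavelength Wavelength grid (nm), default 200-320 at 1 nm.
#' @return data.frame with columns `wavelength_nm`, `signal`.
#' @export
simulate_cd_spectrum <- function(topology_label, amplitude = 10, noise_sd = 0,
                                 seed = NULL, wavelength = seq(200, 320, by = 1)) {
  bands <- cd_band_table(topology_label)
  y <- rep(0, length(wavelength))
  for (i in seq_len(nrow(bands))) {
    y <- y + amplitude * bands$height[i] *
      exp(-(wavelength - bands$center[i])^2 / (2 * bands$width[i]^2))
  }
  y <- with_preserved_seed(seed, y + rnorm(length(wavelength), 0, noise_sd))
  data.frame(wavelength_nm = wavelength, signal = y)
}
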