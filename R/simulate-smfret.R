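#' Two-state FRET dynamics model
#'
#' Ground-truth parameter set for simulating surface-immobilized
#' single-molecule FRET trajectories of a molecule interconverting between a
#' compacted low-FRET conformer and a folded (G-quadruplex) high-FRET
#' conformer. Transitions follow a discrete-time embedding of a two-state
#' Markov chain: within a frame the state is constant, and the probability of
#' switching at a frame boundary is `1 - exp(-k * frame_interval)`.
#'
#' @param e_low,e_high Mean apparent FRET efficiency of the low (compacted)
#'   and high (folded) state. Must satisfy `0 <= e_low < e_high <= 1`.
#' @param sigma_e_low,sigma_e_high Per-frame FRET noise SD of each state.
#' @param k_lh,k_hl Low-to-high and high-to-low transition rates (s^-1),
#'   strictly positive.
#' @param i_total Mean total photon counts per frame shared between donor and
#'   acceptor channels.
#' @param sigma_channel Additive Gaussian read-noise SD per channel (counts).
#' @param bg_donor,bg_acceptor Mean background counts per channel.
#' @param frame_interval Frame integration time in seconds (typically 0.1 or
#'   0.3).
#' @param n_frames Number of frames per molecule.
#' @param tau_bleach_acceptor,tau_bleach_donor Exponential photobleach
#'   lifetimes in seconds; `Inf` disables bleaching of that fluorophore.
#' @param p_init_high Probability that a molecule starts in the high-FRET
#'   state. Defaults to the stationary occupancy `k_lh / (k_lh + k_hl)`; it is
#'   exposed separately because refolded samples can start far from
#'   equilibrium.
#' @param seed Default RNG seed used by the simulators when no per-call seed
#'   is given; `NULL` uses the session stream.
#'
#' @return An object of class `two_state_model` (a validated list of the
#'   parameters above).
#' @seealso [simulate_trajectory()], [simulate_ensemble()]
#' @export
#' @examples
#' m <- two_state_model(k_lh = 0.011, k_hl = 0.050, seed = 1)
#' m$p_init_high  # stationary occupancy ~0.18
two_state_model <- function(e_low = 0.49, e_high = 0.81,
                            sigma_e_low = 0.06, sigma_e_high = 0.06,
                            k_lh, k_hl,
                            i_total = 500, sigma_channel = 15,
                            bg_donor = 50, bg_acceptor = 50,
                            frame_interval = 0.3, n_frames = 300,
                            tau_bleach_acceptor = Inf, tau_bleach_donor = Inf,
                            p_init_high = NULL, seed = NULL) {
  for (f in c("e_low", "e_high", "sigma_e_low", "sigma_e_high", "k_lh", "k_hl",
              "i_total", "sigma_channel", "bg_donor", "bg_acceptor",
              "frame_interval", "n_frames")) {
    check_scalar(get(f), f)
  }
  if (k_lh <= 0) stop_field("k_lh", "transition rate must be > 0")
  if (k_hl <= 0) stop_field("k_hl", "transition rate must be > 0")
  if (e_low < 0 || e_high > 1 || e_low >= e_high) {
    stop_field("e_low/e_high", "must satisfy 0 <= e_low < e_high <= 1")
  }
  if (sigma_e_low < 0) stop_field("sigma_e_low", "must be >= 0")
  if (sigma_e_high < 0) stop_field("sigma_e_high", "must be >= 0")
  if (frame_interval <= 0) stop_field("frame_interval", "must be > 0")
  if (n_frames < 1) stop_field("n_frames", "must be >= 1")
  if (sigma_channel < 0) stop_field("sigma_channel", "must be >= 0")
  if (tau_bleach_acceptor <= 0) stop_field("tau_bleach_acceptor", "must be > 0 (Inf allowed)")
  if (tau_bleach_donor <= 0) stop_field("tau_bleach_donor", "must be > 0 (Inf allowed)")
  if (is.null(p_init_high)) p_init_high <- k_lh / (k_lh + k_hl)
  check_scalar(p_init_high, "p_init_high")
  if (p_init_high < 0 || p_init_high > 1) stop_field("p_init_high", "must lie in [0, 1]")

  structure(
    list(e_low = e_low, e_high = e_high,
         sigma_e_low = sigma_e_low, sigma_e_high = sigma_e_high,
         k_lh = k_lh, k_hl = k_hl,
         i_total = i_total, sigma_channel = sigma_channel,
         bg_donor = bg_donor, bg_acceptor = bg_acceptor,
         frame_interval = frame_interval, n_frames = as.integer(n_frames),
         tau_bleach_acceptor = tau_bleach_acceptor,
         tau_bleach_donor = tau_bleach_donor,
         p_init_high = p_init_high, seed = seed),
    class = "two_state_model"
  )
}

#' @export
print.two_state_model <- function(x, ...) {
  cat("Two-state FRET model\n")
  cat(sprintf("  E_low  = %.3f (sd %.3f)   E_high = %.3f (sd %.3f)\n",
              x$e_low, x$sigma_e_low, x$e_high, x$sigma_e_high))
  cat(sprintf("  k_lh = %.4g s^-1   k_hl = %.4g s^-1   stationary p_high = %.3f\n",
              x$k_lh, x$k_hl, x$k_lh / (x$k_lh + x$k_hl)))
  cat(sprintf("  %d frames x %.3g s, I_total = %g, channel sd = %g, bg = %g/%g\n",
              x$n_frames, x$frame_interval, x$i_total, x$sigma_channel,
              x$bg_donor, x$bg_acceptor))
  invisible(x)
}

# Sample a state path (0 = low, 1 = high) of length n by alternating
# geometric dwells; numerically safe for switching probabilities down to ~0.
sample_state_path <- function(n, p_lh, p_hl, p_init_high) {
  state <- integer(n)
  cur <- if (runif(1) < p_init_high) 1L else 0L
  i <- 1L
  while (i <= n) {
    p <- if (cur == 1L) p_hl else p_lh
    len <- if (p >= 1) 1 else 1 + floor(log(runif(1)) / log1p(-p))
    len <- min(len, n - i + 1)
    state[i:(i + len - 1L)] <- cur
    i <- i + as.integer(len)
    cur <- 1L - cur
  }
  state
}

#' Simulate one donor/acceptor intensity trajectory
#'
#' Generates a per-frame intensity trajectory for a single immobilized
#' molecule under a [two_state_model()], together with the ground truth used
#' to generate it. Before any photobleach, `donor = bg_donor +
#' (1 - E) * i_total + noise` and `acceptor = bg_acceptor + E * i_total +
#' noise`, where `E` is the per-frame state mean plus state noise. After the
#' acceptor bleaches, the acceptor collapses to background and the donor
#' gains the acceptor's share of `i_total` (the anticorrelated single-step
#' signature); after the donor bleaches, both channels collapse to
#' background.
#'
#' @param model A [two_state_model()].
#' @param molecule_id Identifier stored in the output table.
#' @param seed RNG seed for this call; defaults to the model's seed.
#' @return A list with elements `trajectory` (data.frame with columns
#'   `molecule_id`, `frame`, `time_s`, `donor`, `acceptor`) and `truth` (list
#'   with the integer state path `state`, 0 = low / 1 = high, bleach frame
#'   indices `bleach_frame_acceptor` / `bleach_frame_donor` (`NA` if the
#'   fluorophore survives the trace), and the generating `model`).
#' @export
#' @examples
#' m <- two_state_model(k_lh = 0.02, k_hl = 0.05, n_frames = 50, seed = 7)
#' sim <- simulate_trajectory(m)
#' head(sim$trajectory)
simulate_trajectory <- function(model, molecule_id = 1L, seed = model$seed) {
  stopifnot(inherits(model, "two_state_model"))
  with_preserved_seed(seed, simulate_trajectory_impl(model, molecule_id))
}

simulate_trajectory_impl <- function(model, molecule_id) {
  n <- model$n_frames
  dt <- model$frame_interval
  p_lh <- -expm1(-model$k_lh * dt)
  p_hl <- -expm1(-model$k_hl * dt)
  state <- sample_state_path(n, p_lh, p_hl, model$p_init_high)

  bleach_frame <- function(tau) {
    if (!is.finite(tau)) return(NA_integer_)
    fr <- floor(rexp(1L, rate = 1 / tau) / dt) + 1L
    if (fr > n) NA_integer_ else as.integer(fr)
  }
  bl_a <- bleach_frame(model$tau_bleach_acceptor)
  bl_d <- bleach_frame(model$tau_bleach_donor)

  e_mean <- ifelse(state == 1L, model$e_high, model$e_low)
  e_sd <- ifelse(state == 1L, model$sigma_e_high, model$sigma_e_low)
  e_frame <- e_mean + rnorm(n, 0, 1) * e_sd
  donor <- model$bg_donor + (1 - e_frame) * model$i_total +
    rnorm(n, 0, model$sigma_channel)
  acceptor <- model$bg_acceptor + e_frame * model$i_total +
    rnorm(n, 0, model$sigma_channel)

  if (!is.na(bl_a) && (is.na(bl_d) || bl_a <= bl_d)) {
    idx <- bl_a:n
    if (!is.na(bl_d)) idx <- bl_a:max(bl_a, bl_d - 1L)
    acceptor[idx] <- model$bg_acceptor + rnorm(length(idx), 0, model$sigma_channel)
    donor[idx] <- model$bg_donor + model$i_total + rnorm(length(idx), 0, model$sigma_channel)
  }
  if (!is.na(bl_d)) {
    idx <- bl_d:n
    acceptor[idx] <- model$bg_acceptor + rnorm(length(idx), 0, model$sigma_channel)
    donor[idx] <- model$bg_donor + rnorm(length(idx), 0, model$sigma_channel)
  }

  list(
    trajectory = data.frame(
      molecule_id = molecule_id,
      frame = seq_len(n),
      time_s = (seq_len(n) - 1) * dt,
      donor = donor,
      acceptor = acceptor
    ),
    truth = list(state = state,
                 bleach_frame_acceptor = bl_a,
                 bleach_frame_donor = bl_d,
                 model = model)
  )
}

#' Simulate an ensemble of single-molecule trajectories
#'
#' Independent molecules are drawn from one seeded RNG stream, so a fixed
#' seed reproduces the whole ensemble bit-identically.
#'
#' @inheritParams simulate_trajectory
#' @param n_molecules Number of molecules (>= 1).
#' @return An object of class `smfret_ensemble`: a list with `traces` (one
#'   long-format data.frame, columns `molecule_id`, `frame`, `time_s`,
#'   `donor`, `acceptor`), `truth` (list per molecule as in
#'   [simulate_trajectory()]) and `model`.
#' @export
simulate_ensemble <- function(model, n_molecules, seed = model$seed) {
  stopifnot(inherits(model, "two_state_model"))
  if (!is.numeric(n_molecules) || length(n_molecules) != 1L || n_molecules < 1) {
    stop_field("n_molecules", "must be >= 1")
  }
  n_molecules <- as.integer(n_molecules)
  with_preserved_seed(seed, {
    sims <- lapply(seq_len(n_molecules), function(i) simulate_trajectory_impl(model, i))
    structure(
      list(traces = do.call(rbind, lapply(sims, `[[`, "trajectory")),
           truth = lapply(sims, `[[`, "truth"),
           model = model),
      class = "smfret_ensemble"
    )
  })
}

#' @export
print.smfret_ensemble <- function(x, ...) {
  cat(sprintf("smFRET ensemble: %d molecules x %d frames (dt = %.3g s)\n",
              length(x$truth), x$model$n_frames, x$model$frame_interval))
  invisible(x)
}

#' Simulate per-molecule FRET values from a Gaussian population mixture
#'
#' Draws one apparent-FRET value per molecule from a 1- or 2-component
#' Gaussian population, emulating the per-molecule values that enter smFRET
#' population histograms (each value being the mean E over the first frames
#' of a trajectory).
#'
#' @param n Number of molecules.
#' @param means,sds Component means and SDs (E units), equal length.
#' @param weights Component weights (normalized internally).
#' @param seed RNG seed.
#' @return Numeric vector of length `n`.
#' @export
simulate_fret_population <- function(n, means, sds, weights = rep(1, length(means)),
                                     seed = NULL) {
  if (length(means) != length(sds) || length(means) != length(weights)) {
    stop("`means`, `sds` and `weights` must have equal length", call. = FALSE)
  }
  if (any(sds < 0)) stop_field("sds", "must be >= 0")
  if (any(weights < 0) || sum(weights) <= 0) stop_field("weights", "must be non-negative, not all zero")
  weights <- weights / sum(weights)
  with_preserved_seed(seed, {
    comp <- sample.int(length(means), n, replace = TRUE, prob = weights)
    rnorm(n, means[comp], sds[comp])
  })
}
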