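# Shared fixture builders. Everything is generated in code; seeds are fixed
# so all expectations are deterministic.

kinetic_model <- function(condition = c("no_protein", "with_protein"), ...) {
  condition <- match.arg(condition)
  kin <- g4ix_conditions()$fret_kinetics
  two_state_model(e_low = kin$e_low, e_high = kin$e_high,
                  sigma_e_low = kin$sigma_e, sigma_e_high = kin$sigma_e,
                  k_lh = kin[[condition]]$k_lh, k_hl = kin[[condition]]$k_hl,
                  frame_interval = kin$frame_interval, n_frames = kin$n_frames,
                  ...)
}

# A clean constructed trajectory with optional step changes.
step_trajectory <- function(donor_levels, acceptor_levels, lengths,
                            noise_sd = 5, dt = 0.1, seed = 99) {
  n <- sum(lengths)
  d <- rep(donor_levels, lengths)
  a <- rep(acceptor_levels, lengths)
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    data.frame(molecule_id = 1L, frame = seq_len(n), time_s = (seq_len(n) - 1) * dt,
               donor = d + rnorm(n, 0, noise_sd),
               acceptor = a + rnorm(n, 0, noise_sd))
  })
}

# FRET trace data.frame straight from per-frame efficiencies.
fret_trace_from_e <- function(e, dt = 0.3, molecule_id = 1L, valid = TRUE) {
  data.frame(molecule_id = molecule_id, frame = seq_along(e),
             time_s = (seq_along(e) - 1) * dt, efficiency = e,
             valid = rep_len(valid, length(e)))
}

# Dwell table from explicit durations (all uncensored, non-terminal by default).
dwell_table_from_durations <- function(durations_s, state = "high",
                                       frame_interval = 0.3,
                                       censored = FALSE, terminal = FALSE) {
  out <- data.frame(molecule_id = seq_along(durations_s), state = state,
                    n_frames = round(durations_s / frame_interval),
                    duration_s = durations_s,
                    censored = rep_len(censored, length(durations_s)),
                    terminal = rep_len(terminal, length(durations_s)))
  attr(out, "frame_interval") <- frame_interval
  class(out) <- c("dwell_table", "data.frame")
  out
}

expect_within <- function(object, target, tol) {
  expect_lt(abs(object - target), tol)
}
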