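test_that("thresholding assigns states as constructed", {
  e <- c(rep(0.4, 10), rep(0.85, 5), rep(0.4, 10))
  st <- assign_states(fret_trace_from_e(e), threshold = 0.6, median_filter = FALSE)
  expect_equal(st$state, c(rep("low", 10), rep("high", 5), rep("low", 10)))
  all_high <- assign_states(fret_trace_from_e(rep(0.9, 8)), threshold = 0.6)
  expect_equal(unique(all_high$state), "high")
  one_comp <- fit_gaussian_mixture(build_histogram(
    simulate_fret_population(100, 0.5, 0.05, seed = 1)), 1)
  expect_error(assign_states(fret_trace_from_e(e), mixture = one_comp),
               "two-component")
})

test_that("dwell extraction turns runs into durations with censored edges", {
  e <- c(rep(0.4, 10), rep(0.85, 5), rep(0.4, 10))
  st <- assign_states(fret_trace_from_e(e, dt = 0.3), threshold = 0.6,
                      median_filter = FALSE)
  dw <- extract_dwells(st, frame_interval = 0.3)
  expect_equal(nrow(dw), 3)
  expect_equal(dw$censored, c(TRUE, FALSE, TRUE))
  unc <- dw[!dw$censored, ]
  expect_equal(unc$state, "high")
  expect_equal(unc$duration_s, 1.5)
  # constant-state trace: a single dwell, censored at both ends
  st2 <- assign_states(fret_trace_from_e(rep(0.4, 20)), threshold = 0.6)
  dw2 <- extract_dwells(st2, frame_interval = 0.3)
  expect_equal(nrow(dw2), 1)
  expect_true(all(dw2$censored))
  expect_error(extract_dwells(st[0, ]), "empty")
})

test_that("noiseless traces reproduce the ground-truth state path and dwells", {
  m <- two_state_model(e_low = 0.49, e_high = 0.81, sigma_e_low = 0,
                       sigma_e_high = 0, sigma_channel = 0,
                       k_lh = 0.05, k_hl = 0.1, n_frames = 500,
                       frame_interval = 0.3)
  ens <- simulate_ensemble(m, 5, seed = 8)
  fret <- process_traces(ens$traces, bg_donor = 50, bg_acceptor = 50,
                         detect_bleach = FALSE)
  st <- assign_states(fret, threshold = 0.65, median_filter = FALSE)
  truth <- unlist(lapply(ens$truth, `[[`, "state"))
  expect_equal(st$state, ifelse(truth == 1L, "high", "low"))
  dw <- extract_dwells(st, frame_interval = 0.3)
  truth_runs <- unlist(lapply(ens$truth, function(tr) rle(tr$state)$lengths))
  expect_equal(sort(dw$n_frames), sort(truth_runs))
})

test_that("with realistic noise and the median filter, misassignment stays below 1%", {
  m <- kinetic_model("no_protein")
  ens <- simulate_ensemble(m, 50, seed = 9)
  fret <- process_traces(ens$traces, bg_donor = 50, bg_acceptor = 50,
                         detect_bleach = FALSE)
  st <- assign_states(fret, threshold = 0.65, median_filter = TRUE)
  truth <- unlist(lapply(ens$truth, `[[`, "state"))
  expect_lt(mean((st$state == "high") != (truth == 1L)), 0.01)
})

test_that("per-molecule mean dwells average uncensored dwells only", {
  dw <- dwell_table_from_durations(c(1.5, 2.5))
  dw$molecule_id <- c(1, 1)
  pm <- per_molecule_mean_dwells(dw)
  expect_equal(pm$mean_high_s, 2.0)
  expect_true(is.na(pm$mean_low_s))
  all_cens <- dwell_table_from_durations(3, censored = TRUE, terminal = TRUE)
  expect_message(out <- per_molecule_mean_dwells(all_cens), "no uncensored")
  expect_equal(nrow(out), 0)
})

test_that("per-molecule high-dwell means center on 1/k_hl in long traces", {
  m <- two_state_model(e_low = 0.49, e_high = 0.81, sigma_e_low = 0.06,
                       sigma_e_high = 0.06, k_lh = 0.011, k_hl = 0.05,
                       n_frames = 2000, frame_interval = 0.3)
  ens <- simulate_ensemble(m, 100, seed = 10)
  fret <- process_traces(ens$traces, bg_donor = 50, bg_acceptor = 50,
                         detect_bleach = FALSE)
  st <- assign_states(fret, threshold = 0.65)
  pm <- suppressMessages(per_molecule_mean_dwells(extract_dwells(st, 0.3)))
  expect_within(mean(pm$mean_high_s, na.rm = TRUE), 20, 3)
})

test_that("the exponential MLE recovers the rate of iid dwell samples", {
  set.seed(40)
  dw <- dwell_table_from_durations(rexp(500, 0.05))
  est <- fit_dwell_rate(dw, "high_to_low", method = "mle")
  expect_within(est$rate, 0.05, 0.005)
  expect_equal(est$se, est$rate / sqrt(500))
  one <- dwell_table_from_durations(10)
  expect_equal(fit_dwell_rate(one, "high_to_low", method = "mle",
                              min_dwells = 1)$rate, 0.1)
  expect_error(fit_dwell_rate(dwell_table_from_durations(rexp(5, 1)),
                              "high_to_low", method = "mle"), "5 uncensored")
})

test_that("histogram-exponential and MLE rates agree on untruncated dwells", {
  set.seed(41)
  dw <- dwell_table_from_durations(0.3 * (1 + rgeom(400, -expm1(-0.05 * 0.3))))
  mle <- fit_dwell_rate(dw, "high_to_low", method = "mle")
  hst <- fit_dwell_rate(dw, "high_to_low", method = "histogram")
  comb_se <- sqrt(mle$se^2 + max(hst$se, mle$se, na.rm = TRUE)^2)
  expect_within(hst$rate, mle$rate, 2 * comb_se)
})

test_that("the censoring-aware estimator is calibrated on the discrete chain", {
  # geometric dwells with known switching probability, cut into windows
  m <- two_state_model(k_lh = 0.011, k_hl = 0.050, frame_interval = 0.3,
                       n_frames = 300)
  ens <- simulate_ensemble(m, 200, seed = 30)
  states <- do.call(rbind, lapply(seq_along(ens$truth), function(i) {
    data.frame(molecule_id = i, frame = 1:300, time_s = (0:299) * 0.3,
               state = ifelse(ens$truth[[i]]$state == 1L, "high", "low"))
  }))
  dw <- extract_dwells(states, frame_interval = 0.3)
  r <- fit_dwell_rates(dw, method = "survival")
  expect_within(r$low_to_high$rate, 0.011, 3 * r$low_to_high$se)
  expect_within(r$high_to_low$rate, 0.050, 3 * r$high_to_low$se)
})

test_that("pipeline rate recovery at the study regime is accurate across seeds", {
  errs <- sapply(1:20, function(s) {
    rep <- suppressWarnings(run_smfret_workflow(model = kinetic_model("no_protein"),
                                                n_molecules = 200, seed = 200 + s))
    c(abs(rep$rates$low_to_high$rate / 0.011 - 1),
      abs(rep$rates$high_to_low$rate / 0.050 - 1))
  })
  expect_lte(median(errs[1, ]), 0.2)
  expect_lte(median(errs[2, ]), 0.2)
})

test_that("folding energetics follow -RT ln K with a rates/fractions cross-check", {
  expect_equal(folding_energetics(fractions = c(50, 50))$dg_fractions_kj_mol, 0)
  expect_equal(folding_energetics(rates = c(0.02, 0.02))$dg_rates_kj_mol, 0)
  fe <- folding_energetics(fractions = c(37, 63), temperature_K = 293.15)
  expect_equal(fe$dg_fractions_kj_mol, -1.2972, tolerance = 1e-4)
  # consistent two-state system: both routes agree
  both <- folding_energetics(fractions = c(82, 18), rates = c(0.011, 0.050))
  expect_within(both$consistency_ratio, 1, 0.03)
  # boundary fractions flag an infinite free energy instead of erroring
  inf_case <- folding_energetics(fractions = c(0, 100))
  expect_true(inf_case$boundary_fraction)
  expect_true(is.infinite(inf_case$dg_fractions_kj_mol))
})
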