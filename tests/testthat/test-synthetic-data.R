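test_that("model validation rejects invalid parameters, naming the field", {
  expect_error(two_state_model(k_lh = 0, k_hl = 0.05), "k_lh")
  expect_error(two_state_model(k_lh = 0.01, k_hl = -1), "k_hl")
  expect_error(two_state_model(k_lh = 0.01, k_hl = 0.05, e_low = 0.9, e_high = 0.5),
               "e_low/e_high")
  expect_error(two_state_model(k_lh = 0.01, k_hl = 0.05, frame_interval = 0),
               "frame_interval")
  expect_error(two_state_model(k_lh = 0.01, k_hl = 0.05, p_init_high = 1.5),
               "p_init_high")
  expect_error(simulate_ensemble(two_state_model(k_lh = 0.01, k_hl = 0.05), 0),
               "n_molecules")
})

test_that("stationary occupancy of simulated chains matches k_lh/(k_lh+k_hl)", {
  m <- two_state_model(k_lh = 0.011, k_hl = 0.050, frame_interval = 0.3,
                       n_frames = 1e5)
  ens <- simulate_ensemble(m, 10, seed = 42)
  occ <- mean(unlist(lapply(ens$truth, `[[`, "state")))
  # band: 3 sigma with the effective sample size reduced by the chain's
  # autocorrelation time 2/((k_lh+k_hl) dt) ~ 110 frames
  expect_within(occ, 0.011 / 0.061, 0.012)
})

test_that("ground-truth dwell durations are exponential with the generating rate", {
  m <- two_state_model(k_lh = 0.02, k_hl = 0.05, frame_interval = 0.1,
                       n_frames = 7e5)
  sim <- simulate_trajectory(m, seed = 7)
  r <- rle(sim$truth$state)
  k <- length(r$lengths)
  interior <- seq_len(k)[-c(1, k)]
  low_d <- r$lengths[interior][r$values[interior] == 0L] * 0.1
  expect_gte(length(low_d), 1000)
  ks <- suppressWarnings(stats::ks.test(low_d[1:1000], "pexp", 0.02))
  expect_gt(ks$p.value, 0.01)
})

test_that("simulation is bit-reproducible under a fixed seed", {
  m <- two_state_model(k_lh = 0.02, k_hl = 0.05, n_frames = 200,
                       tau_bleach_acceptor = 40)
  a <- simulate_ensemble(m, 20, seed = 5)
  b <- simulate_ensemble(m, 20, seed = 5)
  expect_identical(a$traces, b$traces)
  expect_identical(a$truth, b$truth)
  c <- simulate_ensemble(m, 20, seed = 6)
  expect_false(identical(a$traces, c$traces))
})

test_that("changing only the seed changes the noise, not the noiseless signal", {
  t1 <- simulate_cd_kinetics(1, 0.5, t_grid = 0:20, noise_sd = 0, seed = 1)
  t2 <- simulate_cd_kinetics(1, 0.5, t_grid = 0:20, noise_sd = 0, seed = 2)
  expect_identical(t1$signal, t2$signal)
  n1 <- simulate_melting_curve(50, 4, noise_sd = 0.5, seed = 1)
  n2 <- simulate_melting_curve(50, 4, noise_sd = 0.5, seed = 2)
  expect_false(identical(n1$signal, n2$signal))
  expect_identical(simulate_melting_curve(50, 4, noise_sd = 0, seed = 1)$signal,
                   simulate_melting_curve(50, 4, noise_sd = 0, seed = 2)$signal)
})

test_that("noiseless frames give E exactly equal to the state mean", {
  m <- two_state_model(e_low = 0.2, e_high = 0.85, sigma_e_low = 0,
                       sigma_e_high = 0, k_lh = 0.5, k_hl = 1e-9,
                       sigma_channel = 0, bg_donor = 0, bg_acceptor = 0,
                       p_init_high = 1, n_frames = 50)
  sim <- simulate_trajectory(m, seed = 3)
  e <- sim$trajectory$acceptor / (sim$trajectory$acceptor + sim$trajectory$donor)
  expect_equal(e, rep(0.85, 50))
})

test_that("initial-state probability is honored across an ensemble", {
  m <- two_state_model(k_lh = 0.011, k_hl = 0.050, n_frames = 2,
                       p_init_high = 0.07)
  ens <- simulate_ensemble(m, 2000, seed = 17)
  started_high <- vapply(ens$truth, function(tr) tr$state[1] == 1L, logical(1))
  # binomial 3 sigma at n = 2000
  expect_within(mean(started_high), 0.07, 3 * sqrt(0.07 * 0.93 / 2000))
})

test_that("acceptor bleach produces the anticorrelated single-step signature", {
  m <- two_state_model(e_low = 0.4, e_high = 0.8, sigma_e_low = 0, sigma_e_high = 0,
                       k_lh = 1e-9, k_hl = 1e-9, sigma_channel = 0,
                       p_init_high = 0, n_frames = 100, tau_bleach_acceptor = 10,
                       frame_interval = 0.3)
  sim <- simulate_trajectory(m, seed = 11)
  bf <- sim$truth$bleach_frame_acceptor
  expect_false(is.na(bf))
  tr <- sim$trajectory
  expect_equal(tr$acceptor[bf], m$bg_acceptor)
  expect_equal(tr$donor[bf], m$bg_donor + m$i_total)
  expect_equal(tr$donor[bf] - tr$donor[bf - 1], tr$acceptor[bf - 1] - tr$acceptor[bf])
})

test_that("kinetic-trace generator follows the printed exponential equations", {
  expect_equal(simulate_cd_kinetics(1, 0.5, t_grid = c(1e-12, 1))$signal[1], 0,
               tolerance = 1e-9)
  long <- simulate_cd_kinetics(1, 0.5, t_grid = c(1, 1000))$signal[2]
  expect_equal(long, 1, tolerance = 1e-9)
  # hand evaluation of the bi-exponential at t = 1
  y <- simulate_cd_kinetics(1, 2, c = 0.5, d = 0.2, t_grid = c(0.5, 1))$signal[2]
  expect_equal(y, 0.9552993, tolerance = 1e-6)
  expect_error(simulate_cd_kinetics(1, -2, t_grid = 0:5), "b")
  expect_error(simulate_cd_kinetics(1, 1, t_grid = c(0, 0, 1)), "t_grid")
})

test_that("melting generator hits the inflection identity and grid arithmetic", {
  mc <- simulate_melting_curve(41.2, 4, theta_folded = 10, theta_unfolded = 0,
                               t_range = c(25, 95), step = 0.5)
  expect_equal(nrow(mc), 141)
  sig_at_tm <- approx(mc$temperature_C, mc$signal, xout = 41.2)$y
  expect_equal(sig_at_tm, 5, tolerance = 1e-3)
  expect_error(simulate_melting_curve(50, width = 0), "width")
})

test_that("titration generator obeys the depletion isotherm limits", {
  tt <- simulate_titration(4.9)
  expect_equal(nrow(tt), 16)
  expect_equal(min(tt$concentration_uM), 200 / 2^15, tolerance = 1e-9)
  # hyperbolic limit: P = K_D >> D gives half saturation
  f <- fraction_bound(4.9, 0.0001, 4.9)
  expect_within(f, 0.5, 0.005)
  expect_error(simulate_titration(-1), "k_d")
})

test_that("synthetic spectra realize the topology signatures they are labeled with", {
  sp <- simulate_cd_spectrum("parallel", 10)
  peak <- sp$wavelength_nm[which.max(sp$signal)]
  expect_true(peak >= 255 && peak <= 270)
  expect_equal(classify_topology(simulate_cd_spectrum("antiparallel", 10))$label,
               "antiparallel")
  flat <- simulate_cd_spectrum("parallel", amplitude = 0, noise_sd = 0.05, seed = 2)
  expect_equal(classify_topology(flat)$label, "undetermined")
  expect_error(simulate_cd_spectrum("sideways"), "topology_label")
})

test_that("noiseless generator output is exactly recovered by the matching fit", {
  tr <- simulate_cd_kinetics(2.5, 0.8, t_grid = seq(0.05, 10, 0.05))
  f <- fit_exponential(tr, "mono")
  expect_within(abs(f$coefficients[["a"]] / 2.5 - 1), 0, 1e-6)
  expect_within(abs(f$coefficients[["b"]] / 0.8 - 1), 0, 1e-6)

  mc <- simulate_melting_curve(52.8, 4)
  expect_within(fit_melting(mc)$tm, 52.8, 4 / 50)

  tt <- simulate_titration(4.9)
  expect_within(fit_binding_isotherm(tt)$k_d, 4.9, 1e-3)
})
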