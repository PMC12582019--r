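test_that("background correction is channel-wise subtraction, not clipping", {
  traj <- data.frame(molecule_id = 1L, frame = 1:12, time_s = (0:11) * 0.1,
                     donor = rep(300, 12), acceptor = rep(120, 12))
  out <- suppressWarnings(background_correct(traj, bg_donor = 100, bg_acceptor = 150))
  expect_equal(out$donor, rep(200, 12))
  expect_equal(out$acceptor, rep(-30, 12))  # negative values kept
  ident <- background_correct(traj, bg_donor = 0, bg_acceptor = 0)
  expect_equal(ident$donor, traj$donor)
  expect_warning(background_correct(traj, bg_donor = 400, bg_acceptor = 0),
                 "95th percentile")
})

test_that("background is recoverable from the post-bleach channel median", {
  m <- two_state_model(k_lh = 0.02, k_hl = 0.05, n_frames = 400,
                       bg_donor = 50, bg_acceptor = 50,
                       tau_bleach_acceptor = 20, tau_bleach_donor = 40,
                       frame_interval = 0.1)
  ens <- simulate_ensemble(m, 40, seed = 12)
  ests <- sapply(seq_len(40), function(i) {
    tr <- ens$traces[ens$traces$molecule_id == i, ]
    bl <- detect_photobleach(tr)
    if (is.na(bl$acceptor_bleach_frame)) return(NA_real_)
    attr(suppressWarnings(background_correct(tr, bg_donor = 50)), "bg_acceptor")
  })
  expect_within(median(ests, na.rm = TRUE), 50, 2)
})

test_that("FRET efficiency is the acceptor fraction of total intensity", {
  traj <- data.frame(molecule_id = 1L, frame = 1:3, time_s = (0:2) * 0.1,
                     donor = c(50, 100, 15), acceptor = c(50, 0, 85))
  ft <- compute_fret(traj, min_total = 0)
  expect_equal(ft$efficiency, c(0.5, 0, 0.85))
  expect_error(compute_fret(traj, min_total = 1e6), "threshold")
})

test_that("constructed photobleach steps are located at the right frame", {
  # acceptor bleach: acceptor 500 -> 50 at frame 120 with donor 300 -> 750
  tr <- step_trajectory(donor_levels = c(300, 750), acceptor_levels = c(500, 50),
                        lengths = c(119, 81))
  bl <- detect_photobleach(tr)
  expect_equal(bl$acceptor_bleach_frame, 120L)
  expect_true(is.na(bl$donor_bleach_frame))

  # flat noisy trace: nothing to find
  flat <- step_trajectory(300, 400, lengths = c(200))
  bl2 <- detect_photobleach(flat)
  expect_true(is.na(bl2$acceptor_bleach_frame) && is.na(bl2$donor_bleach_frame))

  # donor bleach: both channels collapse to background
  tr3 <- step_trajectory(donor_levels = c(300, 20), acceptor_levels = c(500, 20),
                         lengths = c(150, 50))
  bl3 <- detect_photobleach(tr3)
  expect_equal(bl3$donor_bleach_frame, 151L)
  expect_error(detect_photobleach(flat[1:5, ]), "10 frames")
})

test_that("a FRET transition is not mistaken for an acceptor bleach", {
  # high -> low transition: anticorrelated but acceptor stays well above bg
  tr <- step_trajectory(donor_levels = c(145, 305), acceptor_levels = c(455, 295),
                        lengths = c(100, 100))
  bl <- detect_photobleach(tr)
  expect_true(is.na(bl$acceptor_bleach_frame))
})

test_that("detected bleach times recover the generating lifetime", {
  m <- two_state_model(k_lh = 0.011, k_hl = 0.050, frame_interval = 0.3,
                       n_frames = 1000, tau_bleach_acceptor = 30)
  ens <- simulate_ensemble(m, 300, seed = 21)
  det <- vapply(seq_len(300), function(i) {
    tr <- ens$traces[ens$traces$molecule_id == i, ]
    detect_photobleach(tr)$acceptor_bleach_frame
  }, integer(1))
  truth <- vapply(ens$truth, `[[`, integer(1), "bleach_frame_acceptor")
  both <- !is.na(det) & !is.na(truth)
  expect_gt(sum(both) / sum(!is.na(truth) & truth > 1), 0.95)
  expect_gt(mean(det[both] == truth[both]), 0.95)
  det_t <- (det[!is.na(det)] - 1) * 0.3
  true_t <- (truth[!is.na(truth)] - 1) * 0.3
  expect_within(mean(det_t), mean(true_t), 1)
  # exponential lifetime: sample mean within ~3 SE of tau = 30 s
  expect_within(mean(det_t), 30, 3 * 30 / sqrt(length(det_t)) + 1)
})

test_that("truncation at a detected bleach is idempotent", {
  tr <- step_trajectory(donor_levels = c(300, 750), acceptor_levels = c(500, 50),
                        lengths = c(119, 81))
  bl <- detect_photobleach(tr)
  trunc <- tr[seq_len(bl$acceptor_bleach_frame - 1L), ]
  bl2 <- detect_photobleach(trunc)
  expect_true(is.na(bl2$acceptor_bleach_frame))
})

test_that("per-molecule value averages the first 15 valid frames only", {
  ft <- fret_trace_from_e(rep(0.41, 40))
  expect_equal(molecule_fret_value(ft), 0.41)
  # boundary: 14 valid frames -> excluded
  ft14 <- fret_trace_from_e(rep(0.41, 14))
  expect_true(is.na(molecule_fret_value(ft14)))
  # later frames must not contribute
  ft2 <- fret_trace_from_e(c(rep(0.4, 15), rep(0.9, 25)))
  expect_equal(molecule_fret_value(ft2), 0.4)
})

test_that("per-molecule values from a single-population ensemble center on the state mean", {
  m <- two_state_model(e_low = 0.41, e_high = 0.9, sigma_e_low = 0.05,
                       sigma_e_high = 0.05, k_lh = 1e-9, k_hl = 1,
                       p_init_high = 0, n_frames = 20, frame_interval = 0.1)
  ens <- simulate_ensemble(m, 150, seed = 14)
  fret <- process_traces(ens$traces, bg_donor = 50, bg_acceptor = 50,
                         detect_bleach = FALSE)
  vals <- suppressMessages(molecule_fret_values(fret))
  expect_equal(nrow(vals), 150)
  expect_within(mean(vals$e_value), 0.41, 0.01)
})

test_that("histogram counts conserve the number of molecules for any bin width", {
  v <- simulate_fret_population(250, c(0.45, 0.8), c(0.06, 0.05), c(0.5, 0.5),
                                seed = 4)
  for (bw in c(0.01, 0.02, 0.04)) {
    h <- build_histogram(v, bin_width = bw)
    expect_equal(sum(h$counts), 250)
  }
  # values outside the nominal range are still counted
  h2 <- build_histogram(c(v, 1.4, -0.3), bin_width = 0.02)
  expect_equal(sum(h2$counts), 252)
  # degenerate: all values identical occupy a single bin
  h3 <- build_histogram(rep(0.5, 30))
  expect_equal(sum(h3$counts > 0), 1)
  expect_error(build_histogram(rep(0.5, 9)), "at least 10")
})

test_that("bimodal histograms place their modes at the generating means", {
  v <- simulate_fret_population(600, c(0.45, 0.8), c(0.05, 0.05), c(0.5, 0.5),
                                seed = 15)
  h <- build_histogram(v, bin_width = 0.02)
  lo <- h$mids[h$mids < 0.6][which.max(h$counts[h$mids < 0.6])]
  hi <- h$mids[h$mids > 0.6][which.max(h$counts[h$mids > 0.6])]
  expect_within(lo, 0.45, 0.021)
  expect_within(hi, 0.80, 0.021)
})
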