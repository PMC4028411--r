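test_that("simulate_coupled_phases honours its limiting cases", {
  set.seed(31)
  tight <- simulate_coupled_phases(1e6, 0, 5000)
  expect_equal(plv(tight$phase_a, tight$phase_b), 1, tolerance = 1e-3)
  loose <- simulate_coupled_phases(0, 0, 2e4)
  expect_lt(plv(loose$phase_a, loose$phase_b), 0.02)
  expect_error(simulate_coupled_phases(-1, 0, 100), "nonnegative")
})

test_that("kappa = 2 sample PLV matches the Bessel-ratio oracle at n = 1e5", {
  set.seed(32)
  p <- simulate_coupled_phases(2, pi / 3, 1e5)
  # oracle frozen from besselI: I1(2)/I0(2)
  expect_equal(bessel_ratio(2), 0.6977747, tolerance = 1e-6)
  expect_equal(plv(p$phase_a, p$phase_b), 0.6977747,
               tolerance = 3 * plv_mc_se(2, 1e5) / 0.6977747)
})

test_that("rvonmises concentration matches theory across kappa", {
  set.seed(33)
  for (kappa in c(0.5, 1, 4)) {
    th <- rvonmises(5e4, kappa)
    expect_true(all(th > -pi & th <= pi))
    expect_equal(Mod(mean(exp(1i * th))), bessel_ratio(kappa),
                 tolerance = 4 * plv_mc_se(kappa, 5e4))
  }
})

test_that("simulate_pac_source respects depth limits and returns usable truth", {
  set.seed(34)
  fs <- 480; n <- fs * 3
  theta <- band_definition("theta", 4, 8)
  gamma <- band_definition("high_gamma", 65, 85)
  expect_error(simulate_pac_source(6, 75, 1.2, n, fs), "\\[0, 1\\]")
  expect_error(simulate_pac_source(6, 300, 0.5, n, fs), "fs/2")
  s0 <- simulate_pac_source(6, 75, 0, n, fs, noise_sd = 0.5)
  # no modulation: envelope-phase PLV sits near the finite-sample null level
  v0 <- mean(replicate(20, {
    s <- simulate_pac_source(6, 75, 0, n, fs, noise_sd = 0.5)
    pac_envelope_phase(wrap_phase(s$theta_phase), s$series, gamma, theta, fs,
                       window_idx = 241:(n - 240))
  }))
  v1 <- mean(replicate(20, {
    s <- simulate_pac_source(6, 75, 0.8, n, fs, noise_sd = 0.5)
    pac_envelope_phase(wrap_phase(s$theta_phase), s$series, gamma, theta, fs,
                       window_idx = 241:(n - 240))
  }))
  expect_gt(v1, v0 + 0.2)
})

test_that("planted envelope modulation depth is recovered from the raw series", {
  set.seed(35)
  fs <- 480; n <- fs * 40
  m <- 0.5
  s <- simulate_pac_source(6, 75, m, n, fs)
  # analysis band wider than the carrier wander so the modulation
  # sidebands are not clipped
  env <- instantaneous_amplitude(
    analytic(bandpass(s$series, band_definition("hg", 55, 95), fs)))
  # envelope = A (1 + m cos(phi)): regress envelope on cos(theta phase)
  fit <- lm(env[500:(n - 500)] ~ cos(s$theta_phase[500:(n - 500)]))
  expect_equal(unname(coef(fit)[2] / coef(fit)[1]), m, tolerance = 0.05)
})

test_that("sim_config validates its invariants", {
  expect_error(sim_config(power_ratio = 0.5), ">= 1")
  expect_error(sim_config(kappa_baseline = -1), "nonnegative")
  expect_error(sim_config(pac_depth_cue = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(theta_band = band_definition("t", 4, 40)),
               "non-overlapping")
  expect_error(sim_config(source_positions = c(seed = 1, coupled = 2,
                                               pac = 1e5)),
               "on the grid")
})

test_that("simulate_subject is bit-reproducible and shaped as configured", {
  cfg <- sim_config(n_subjects = 2, n_trials_per_condition = 4,
                    grid_dims = c(3, 3, 2), n_sensors = 12,
                    trial_window = c(-1.25, 1.75), rng_seed = 99)
  s1 <- simulate_subject(cfg, 1)
  s2 <- simulate_subject(cfg, 1)
  expect_identical(s1$epochs$data, s2$epochs$data)
  expect_identical(s1$truth, s2$truth)
  s_other <- simulate_subject(cfg, 2)
  expect_false(identical(s1$epochs$data, s_other$epochs$data))
  expect_equal(dim(s1$epochs$data), c(12L, 1440L, 4L))
  expect_equal(nrow(s1$truth$eye_covariate), 8L)
  # seed displaced at most 20 mm from the reference voxel
  d <- sqrt(sum((cfg$grid_coords[s1$truth$seed_voxel, ] -
                   cfg$grid_coords[s1$truth$reference_seed_voxel, ])^2))
  expect_lte(d, 20)
})

test_that("ground truth records every planted value", {
  cfg <- sim_config(n_subjects = 3, n_trials_per_condition = 3,
                    grid_dims = c(3, 3, 2), n_sensors = 8,
                    trial_window = c(-1.25, 1.75))
  study <- simulate_study(cfg)
  gt <- study$ground_truth
  expect_equal(nrow(gt), 3L)
  expect_true(all(gt$kappa_cue == cfg$kappa_cue))
  expect_true(all(gt$power_ratio == cfg$power_ratio))
  av <- study$subjects[[1]]$truth$artifact_variance
  expect_length(av, 3L)
  expect_true(all(av >= cfg$artifact_variance_range[1] &
                    av <= cfg$artifact_variance_range[2]))
})

test_that("save_simulation writes data, CSV ground truth and DCF config", {
  cfg <- sim_config(n_subjects = 1, n_trials_per_condition = 2,
                    grid_dims = c(2, 2, 2), n_sensors = 6,
                    trial_window = c(-1.25, 1.75))
  study <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  paths <- save_simulation(study, dir)
  expect_true(all(file.exists(paths)))
  gt <- read.csv(paths[["ground_truth"]])
  expect_equal(gt$kappa_cue, cfg$kappa_cue)
  dcf <- read.dcf(paths[["config"]])
  expect_equal(as.numeric(dcf[1, "fs"]), 480)
})
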