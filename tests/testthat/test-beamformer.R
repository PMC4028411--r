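random_psd <- function(n) {
  A <- matrix(rnorm(n * n), n)
  crossprod(A) + 0.1 * diag(n)
}

test_that("identity covariance with a canonical lead field returns that basis vector", {
  model <- source_model(matrix(c(0, 0, 0), 1), leadfield = diag(3)[, 1, drop = FALSE])
  w <- compute_weights(diag(3), model, reg_fraction = 0)
  expect_equal(as.numeric(w$W), c(1, 0, 0), tolerance = 1e-12)
})

test_that("unit-gain identity holds for arbitrary covariances and lead fields", {
  set.seed(41)
  for (i in 1:20) {
    ns <- sample(4:12, 1); nv <- sample(2:8, 1)
    L <- matrix(rnorm(ns * nv), ns)
    model <- source_model(matrix(rnorm(nv * 3), nv) * 10, L)
    w <- compute_weights(random_psd(ns), model,
                         reg_fraction = runif(1, 0, 0.2))
    gains <- rowSums(w$W * t(L))
    expect_true(all(abs(gains - 1) < 1e-6))
  }
})

test_that("invalid covariances are rejected", {
  model <- source_model(matrix(rnorm(6), 2) * 10, matrix(rnorm(8), 4))
  asym <- matrix(rnorm(16), 4)
  expect_error(compute_weights(asym, model), "symmetric")
  notpsd <- diag(c(1, 1, 1, -2))
  expect_error(compute_weights(notpsd, model), "positive semi-definite")
  expect_error(compute_weights(diag(3), model), "sensor count")
})

test_that("beamformer output is minimum-variance among unit-gain filters", {
  set.seed(42)
  C <- random_psd(3)
  l <- rnorm(3)
  model <- source_model(matrix(0, 1, 3), matrix(l, 3))
  w <- compute_weights(C, model, reg_fraction = 0.05)
  Cr <- C + 0.05 * mean(diag(C)) * diag(3)
  # brute force: optimize over the 2-dim affine space {w : w'l = 1}
  w0 <- l / sum(l^2)
  NS <- svd(matrix(l, 1), nu = 0, nv = 3)$v[, 2:3]
  obj <- function(ab) {
    wv <- w0 + NS %*% ab
    t(wv) %*% Cr %*% wv
  }
  opt <- optim(c(0, 0), obj, method = "BFGS")
  w_brute <- w0 + NS %*% opt$par
  expect_equal(as.numeric(w$W), as.numeric(w_brute), tolerance = 1e-4)
})

test_that("virtual electrodes pass dimensions and recover a noiseless source exactly", {
  set.seed(43)
  ns <- 6
  l <- rnorm(ns)
  model <- source_model(matrix(0, 1, 3), matrix(l, ns))
  s <- sin(2 * pi * 6 * (0:479) / 480)
  X <- array(outer(l, s), c(ns, 480, 1))
  ep <- trial_epochs(X, 480, onset = 0)
  C <- tcrossprod(matrix(X, ns)) / 479 + 1e-9 * diag(ns)
  w <- compute_weights(C, model, reg_fraction = 0)
  src <- virtual_electrode(w, ep)
  expect_equal(drop(src$data), s, tolerance = 1e-6)
  expect_error(virtual_electrode(w, trial_epochs(array(0, c(3, 10, 1)), 480,
                                                 onset = 0)),
               "sensors")
})

test_that("weights with identity rows return the sensor series unchanged", {
  ns <- 4
  model <- source_model(matrix(rnorm(ns * 3), ns) * 10, diag(ns))
  w <- compute_weights(diag(ns), model, reg_fraction = 0)
  X <- array(rnorm(ns * 100 * 2), c(ns, 100, 2))
  ep <- trial_epochs(X, 480, onset = 0)
  src <- virtual_electrode(w, ep)
  expect_equal(src$data, X, tolerance = 1e-10)
})

test_that("two well-separated planted sources are each recovered at their own voxel", {
  set.seed(44)
  fs <- 480; nt <- fs * 2; ntr <- 8; ns <- 24
  coords <- rbind(c(-40, 0, 0), c(40, 0, 0))
  # smooth, well-separated synthetic lead fields
  L <- megcoupling:::synth_leadfield(coords, ns)
  model <- source_model(coords, L)
  s1 <- matrix(rnorm(nt * ntr), nt); s2 <- matrix(rnorm(nt * ntr), nt)
  s1 <- apply(s1, 2, function(v) bandpass(v, band_definition("theta", 4, 8), fs))
  s2 <- apply(s2, 2, function(v) bandpass(v, band_definition("lg", 30, 45), fs))
  X <- array(0, c(ns, nt, ntr))
  for (tr in 1:ntr) {
    X[, , tr] <- L %*% rbind(s1[, tr], s2[, tr]) +
      matrix(rnorm(ns * nt, sd = 0.02), ns, nt)
  }
  ep <- trial_epochs(X, fs, onset = -1)
  C <- tcrossprod(matrix(X, ns) - rowMeans(matrix(X, ns))) / (nt * ntr - 1)
  w <- compute_weights(C, model, reg_fraction = 0.01)
  src <- virtual_electrode(w, ep)
  r11 <- cor(as.numeric(src$data[1, , ]), as.numeric(s1))
  r22 <- cor(as.numeric(src$data[2, , ]), as.numeric(s2))
  r12 <- cor(as.numeric(src$data[1, , ]), as.numeric(s2))
  expect_gt(abs(r11), 0.95)
  expect_gt(abs(r22), 0.95)
  expect_lt(abs(r12), 0.2)
})

test_that("identical cue and baseline windows give a zero contrast map", {
  set.seed(45)
  cfg <- sim_config(n_subjects = 1, n_trials_per_condition = 4,
                    grid_dims = c(3, 3, 2), n_sensors = 12,
                    trial_window = c(-1.25, 1.75))
  su <- simulate_subject(cfg, 1)
  # both conditions read the same samples -> contrast must vanish exactly
  same <- condition_windows(baseline = c(0.5, 1.5), cue = c(0.5, 1.5))
  C <- subject_covariance(su$epochs, cfg$windows)
  w <- compute_weights(C, su$model)
  pm <- power_contrast_map(w, su$epochs, cfg$theta_band, same)
  expect_lt(max(abs(pm$contrast)) / max(pm$power_baseline), 1e-12)
})

test_that("the normalized contrast's argmax is invariant to a global sensor gain", {
  set.seed(46)
  cfg <- sim_config(n_subjects = 1, n_trials_per_condition = 8,
                    grid_dims = c(3, 3, 2), n_sensors = 16,
                    trial_window = c(-1.25, 1.75))
  su <- simulate_subject(cfg, 1)
  run <- function(gain) {
    ep <- su$epochs
    ep$data <- ep$data * gain
    model <- source_model(su$model$coords, su$model$leadfield * gain)
    C <- subject_covariance(ep, cfg$windows)
    w <- compute_weights(C, model)
    pm <- power_contrast_map(w, ep, cfg$theta_band, cfg$windows)
    pm$voxel[which.max(pm$contrast)]
  }
  expect_equal(run(1), run(2))
})

test_that("zero noise power is rejected", {
  model <- source_model(matrix(rnorm(6), 2) * 10, matrix(rnorm(8), 4))
  w <- compute_weights(diag(4), model)
  ep <- trial_epochs(array(rnorm(4 * 1680), c(4, 1680, 1)), 480, onset = -1.5)
  expect_error(power_contrast_map(w, ep, band_definition("theta", 4, 8),
                                  condition_windows(), noise_power = 0),
               "positive")
})
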