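# Independent oracles and small scenario builders shared across tests.

# brute-force resultant vector length: explicit running sums, no complex
# shortcuts shared with the implementation
plv_brute <- function(a, b) {
  cs <- 0; ss <- 0
  for (i in seq_along(a)) {
    d <- a[i] - b[i]
    cs <- cs + cos(d)
    ss <- ss + sin(d)
  }
  sqrt(cs^2 + ss^2) / length(a)
}

pli_brute <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) {
    d <- a[i] - b[i]
    d <- d - 2 * pi * floor((d + pi) / (2 * pi))  # into [-pi, pi)
    if (d == -pi) d <- pi
    s <- s + sign(d)
  }
  abs(s / length(a))
}

# textbook one-sample t
t_brute <- function(x) mean(x) / (sd(x) / sqrt(length(x)))

# asymptotic SE of the sample mean resultant length of von Mises draws
# (delta method: Var(Rhat) ~ Var(cos theta)/n around the mean direction)
plv_mc_se <- function(kappa, n) {
  rho <- besselI(kappa, 1, TRUE) / besselI(kappa, 0, TRUE)
  alpha2 <- besselI(kappa, 2, TRUE) / besselI(kappa, 0, TRUE)
  sqrt(((1 + alpha2) / 2 - rho^2) / n)
}

# Source-level epochs where every voxel is an instantaneous (zero-lag)
# mixture of one common theta source plus independent noise; the common
# source's amplitude rises in the cue window when snr_ratio > 1.
make_zero_lag_epochs <- function(n_voxels, n_trials, fs = 480,
                                 trial_window = c(-1.25, 1.75),
                                 snr_ratio = 1, noise_sd = 1,
                                 mix_lo = 0.5, mix_hi = 1.5) {
  time <- seq(trial_window[1], trial_window[2] - 1 / fs, by = 1 / fs)
  nt <- length(time)
  theta <- band_definition("theta", 4, 8)
  prof <- megcoupling:::window_profile(time, c(0.5, 1.5))
  mix <- runif(n_voxels, mix_lo, mix_hi)
  X <- array(0, c(n_voxels, nt, n_trials))
  for (tr in seq_len(n_trials)) {
    phi <- megcoupling:::oscillator_phase(nt, fs, theta)
    s <- (1 + (sqrt(snr_ratio) - 1) * prof) * cos(phi)
    X[, , tr] <- outer(mix, s) +
      matrix(rnorm(n_voxels * nt, sd = noise_sd), n_voxels, nt)
  }
  trial_epochs(X, fs, time = time, space = "source")
}

# toy grid coordinates for source-level group stats (10-mm lattice)
toy_coords <- function(dims) megcoupling:::make_grid(dims, 10)

# condition difference of per-trial coupling values at each voxel
coupling_diff_by_voxel <- function(map) {
  cm <- coupling_condition_means(map)
  cm$difference
}
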