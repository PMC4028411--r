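# Synthetic multi-subject MEG study generator. Plants a frontal-midline
# theta power increase, a second source theta-phase-coupled to it (von Mises
# phase jitter with configurable concentration and lag), a third source whose
# high-gamma amplitude is modulated by the seed's theta phase, a trial-varying
# low-frequency eye-movement artifact, and additive sensor noise, all mixed
# to sensors through smooth synthetic lead fields on a 10-mm grid. Every
# planted value is returned as ground truth so the pipeline can be validated
# by parameter recovery.

#' Ratio of modified Bessel functions I1(kappa)/I0(kappa)
#'
#' The population mean resultant length (and hence expected PLV) of von
#' Mises-distributed phase differences with concentration `kappa`.
#'
#' @param kappa Nonnegative concentration parameter(s).
#' @return Values in `[0, 1)`.
#' @export
bessel_ratio <- function(kappa) {
  stopifnot(all(kappa >= 0))
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

#' Draw von Mises random angles
#'
#' Best-Fisher (1979) rejection sampler; reduces to the uniform circular
#' distribution as `kappa` approaches 0.
#'
#' @param n Number of draws.
#' @param kappa Concentration (>= 0).
#' @param mu Mean direction in radians.
#' @return Angles in (-pi, pi].
#' @export
rvonmises <- function(n, kappa, mu = 0) {
  if (kappa < 0) stop("kappa must be nonnegative", call. = FALSE)
  if (kappa < 1e-8) return(wrap_phase(stats::runif(n, -pi, pi) + mu))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling((n - length(out)) * 1.3))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    keep <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    out <- c(out, sign(u3[keep] - 0.5) * acos(pmin(1, pmax(-1, f[keep]))))
  }
  wrap_phase(out[seq_len(n)] + mu)
}

# Ornstein-Uhlenbeck unit-variance noise, used for frequency drift and the
# eye-movement artifact time course
ou_noise <- function(n, fs, tau) {
  a <- exp(-1 / (fs * tau))
  innov_sd <- sqrt(1 - a^2)
  as.numeric(stats::filter(stats::rnorm(n, sd = innov_sd), a,
                           method = "recursive", init = stats::rnorm(1)))
}

# Wandering-frequency oscillator phase: instantaneous frequency is an OU
# process around the band centre, clipped inside the band, so that phase
# decorrelates across trials like a physiological rhythm
oscillator_phase <- function(n, fs, band, freq_sd = NULL, tau = 0.5) {
  f0 <- (band$low + band$high) / 2
  if (is.null(freq_sd)) freq_sd <- (band$high - band$low) / 6
  f <- f0 + freq_sd * ou_noise(n, fs, tau)
  f <- pmin(band$high, pmax(band$low, f))
  phi0 <- stats::runif(1, -pi, pi)
  phi0 + 2 * pi * cumsum(f) / fs
}

# Smooth 0..1 indicator of a time window with raised-cosine ramps
window_profile <- function(time, window, ramp = 0.1) {
  p <- numeric(length(time))
  up <- (time - (window[1] - ramp / 2)) / ramp
  dn <- ((window[2] + ramp / 2) - time) / ramp
  p <- pmin(pmax(up, 0), 1) * pmin(pmax(dn, 0), 1)
  0.5 * (1 - cos(pi * pmin(pmax(p, 0), 1)))
}

# Von Mises phase jitter sampled once per oscillation cycle and interpolated
# through unit vectors, so the jitter survives band-pass filtering while its
# per-cycle concentration matches the requested kappa
cycle_jitter <- function(time, fs, f_cycle, kappa_of_t) {
  knots <- seq(time[1], time[length(time)] + 1 / f_cycle, by = 1 / f_cycle)
  kap <- kappa_of_t(knots)
  eps <- vapply(seq_along(knots), function(i) rvonmises(1L, kap[i]), numeric(1))
  ce <- stats::approx(knots, cos(eps), xout = time, rule = 2)$y
  se <- stats::approx(knots, sin(eps), xout = time, rule = 2)$y
  atan2(se, ce)
}

#' Simulation configuration
#'
#' Collects every constant of the emulated experiment: 17 subjects, 36
#' retrieval trials per subject each containing a 1-s baseline fixation
#' window and a 1-s cue window, 480 Hz sampling, theta 4--8 Hz and low/high
#' gamma 30--45 / 65--85 Hz bands, and the planted effect sizes. Defaults
#' give a cue/baseline theta power ratio of 2 at the seed, seed-to-coupled
#' von Mises concentration rising from 0.8 (baseline) to 1.6 (cue) at a
#' pi/4 phase lag, and theta-phase gamma-amplitude modulation depth rising
#' from 0.2 to 0.7 at the PAC source.
#'
#' @param n_subjects Number of subjects (default 17).
#' @param n_trials_per_condition Trials per subject; each trial contributes
#'   one baseline and one cue window (default 36).
#' @param fs Sampling rate in Hz (default 480).
#' @param trial_window Epoch extent in seconds relative to cue onset
#'   (default `c(-1.5, 2)`, covering both analysis windows with >= 0.5 s of
#'   filter context).
#' @param windows A [condition_windows()] object.
#' @param n_sensors Number of simulated sensors (default 32).
#' @param grid_dims Voxel grid dimensions (default `c(5, 5, 4)`).
#' @param grid_spacing Grid spacing in mm (default 10).
#' @param source_positions Named integer vector/list with voxel indices for
#'   `seed`, `coupled` and `pac` sources; NULL picks three well-separated
#'   default voxels.
#' @param theta_band,low_gamma_band,high_gamma_band [band_definition()]s.
#' @param power_ratio Cue/baseline theta power at the seed source (>= 1).
#' @param coupled_power_ratio Cue/baseline theta power at the coupled source
#'   (default 1; set > 1 with equal kappas for a pure-SNR scenario).
#' @param kappa_baseline,kappa_cue Von Mises concentration of the
#'   seed-to-coupled phase difference per condition (>= 0).
#' @param coupling_lag Phase lag of the coupled source in radians.
#' @param pac_depth_baseline,pac_depth_cue Gamma amplitude modulation depth
#'   m in [0, 1] per condition at the PAC source.
#' @param gamma_power_ratio Cue/baseline gamma amplitude scaling at the PAC
#'   source (emulating the perceptual gamma response; default 1.5).
#' @param artifact_variance_range Per-trial uniform range of eye-artifact
#'   variance (default `c(0.5, 1.5)`).
#' @param artifact_condition_gain Multiplier on the artifact inside the cue
#'   window (1 = artifact independent of condition; > 1 couples the
#'   confound to condition for testing the regression control).
#' @param artifact_amplitude Overall artifact topography scale.
#' @param sensor_noise_sd Additive white sensor noise SD (broadband; with
#'   the defaults the in-band SNR at source level is about 10).
#' @param source_noise_sd Broadband noise added to each source series.
#' @param trial_gain_sd SD of the per-trial, per-window log-normal source
#'   gain (trial-to-trial physiological amplitude variability).
#' @param seed_jitter_mm Maximum displacement of each subject's true seed
#'   source from the group reference voxel (default 20 mm).
#' @param rng_seed Integer master seed; per-subject streams are derived
#'   deterministically from it.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(n_subjects = 17L,
                       n_trials_per_condition = 36L,
                       fs = 480,
                       trial_window = c(-1.5, 2),
                       windows = condition_windows(),
                       n_sensors = 32L,
                       grid_dims = c(5L, 5L, 4L),
                       grid_spacing = 10,
                       source_positions = NULL,
                       theta_band = band_definition("theta", 4, 8),
                       low_gamma_band = band_definition("low_gamma", 30, 45),
                       high_gamma_band = band_definition("high_gamma", 65, 85),
                       power_ratio = 2,
                       coupled_power_ratio = 1,
                       kappa_baseline = 0.8,
                       kappa_cue = 1.6,
                       coupling_lag = pi / 4,
                       pac_depth_baseline = 0.2,
                       pac_depth_cue = 0.7,
                       gamma_power_ratio = 1.5,
                       artifact_variance_range = c(0.5, 1.5),
                       artifact_condition_gain = 1,
                       artifact_amplitude = 0.6,
                       sensor_noise_sd = 0.3,
                       source_noise_sd = 0.15,
                       trial_gain_sd = 0.2,
                       seed_jitter_mm = 20,
                       rng_seed = 1L) {
  bands <- list(theta_band, low_gamma_band, high_gamma_band)
  for (b in bands) check_band_feasible(b, fs)
  ord <- order(vapply(bands, `[[`, numeric(1), "low"))
  bands <- bands[ord]
  for (i in 1:2) {
    if (bands[[i]]$high > bands[[i + 1]]$low) {
      stop("bands must be ordered and non-overlapping", call. = FALSE)
    }
  }
  if (kappa_baseline < 0 || kappa_cue < 0) {
    stop("kappa must be nonnegative", call. = FALSE)
  }
  for (m in c(pac_depth_baseline, pac_depth_cue)) {
    if (m < 0 || m > 1) stop("pac depth m must lie in [0, 1]", call. = FALSE)
  }
  if (power_ratio < 1) stop("power_ratio must be >= 1", call. = FALSE)
  if (coupled_power_ratio < 1) {
    stop("coupled_power_ratio must be >= 1", call. = FALSE)
  }
  stopifnot(length(trial_window) == 2L, trial_window[2] > trial_window[1],
            length(artifact_variance_range) == 2L,
            artifact_variance_range[1] > 0,
            artifact_variance_range[2] >= artifact_variance_range[1])
  grid_dims <- as.integer(grid_dims)
  n_voxels <- prod(grid_dims)
  coords <- make_grid(grid_dims, grid_spacing)
  if (is.null(source_positions)) {
    source_positions <- default_source_positions(coords)
  }
  source_positions <- unlist(source_positions)[c("seed", "coupled", "pac")]
  if (anyNA(source_positions) ||
      any(source_positions < 1L | source_positions > n_voxels)) {
    stop("source_positions must name seed/coupled/pac voxel indices on the grid",
         call. = FALSE)
  }
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    n_trials_per_condition = as.integer(n_trials_per_condition),
    fs = fs, trial_window = trial_window, windows = windows,
    n_sensors = as.integer(n_sensors), grid_dims = grid_dims,
    grid_spacing = grid_spacing, n_voxels = n_voxels, grid_coords = coords,
    source_positions = source_positions,
    theta_band = bands[[1]], low_gamma_band = bands[[2]],
    high_gamma_band = bands[[3]],
    power_ratio = power_ratio, coupled_power_ratio = coupled_power_ratio,
    kappa_baseline = kappa_baseline, kappa_cue = kappa_cue,
    coupling_lag = coupling_lag,
    pac_depth_baseline = pac_depth_baseline, pac_depth_cue = pac_depth_cue,
    gamma_power_ratio = gamma_power_ratio,
    artifact_variance_range = artifact_variance_range,
    artifact_condition_gain = artifact_condition_gain,
    artifact_amplitude = artifact_amplitude,
    sensor_noise_sd = sensor_noise_sd, source_noise_sd = source_noise_sd,
    trial_gain_sd = trial_gain_sd, seed_jitter_mm = seed_jitter_mm,
    rng_seed = as.integer(rng_seed)
  )
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d subjects x %d trials @ %g Hz, %d sensors, %d voxels (%s grid)\n",
    x$n_subjects, x$n_trials_per_condition, x$fs, x$n_sensors, x$n_voxels,
    paste(x$grid_dims, collapse = "x")))
  cat(sprintf("  power ratio %g | kappa %g -> %g (lag %.2f) | pac m %g -> %g\n",
              x$power_ratio, x$kappa_baseline, x$kappa_cue, x$coupling_lag,
              x$pac_depth_baseline, x$pac_depth_cue))
  invisible(x)
}

# Centered 10-mm lattice, MNI-like mm coordinates
make_grid <- function(dims, spacing) {
  ax <- lapply(dims, function(k) (seq_len(k) - (k + 1) / 2) * spacing)
  g <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  rownames(g) <- NULL
  g
}

# three mutually well-separated voxels: seed frontal-top, coupled at the
# opposite lower corner, pac at a lateral posterior position
default_source_positions <- function(coords) {
  pick <- function(target) which.min(colSums((t(coords) - target)^2))
  span <- apply(coords, 2, range)
  c(seed    = pick(c(0, span[2, 2], span[2, 3])),
    coupled = pick(c(0, span[1, 2], span[1, 3])),
    pac     = pick(c(span[2, 1], span[1, 2], span[2, 3])))
}

# Smooth synthetic lead fields: sensors on a hemispherical cap above the
# grid, Gaussian falloff with 30-mm width so neighbouring voxels mix
# (emulating volume conduction); columns unit-normalized
synth_leadfield <- function(coords, n_sensors, jitter_sd = 0) {
  c0 <- colMeans(coords)
  i <- seq_len(n_sensors)
  golden <- pi * (3 - sqrt(5))
  zs <- 0.15 + 0.85 * (i - 0.5) / n_sensors   # upper cap
  th <- golden * i
  r <- 110
  sens <- cbind(r * sqrt(1 - zs^2) * cos(th),
                r * sqrt(1 - zs^2) * sin(th),
                r * zs)
  sens <- sweep(sens, 2, c0, `+`)
  if (jitter_sd > 0) sens <- sens + matrix(stats::rnorm(length(sens), sd = jitter_sd), ncol = 3)
  d2 <- outer(rowSums(sens^2), rowSums(coords^2), `+`) - 2 * sens %*% t(coords)
  L <- exp(-d2 / (2 * 30^2))
  # mild fixed asymmetry so no two columns are exactly proportional
  L <- L * (1 + 0.05 * sin(outer(seq_len(nrow(L)), seq_len(ncol(L)))))
  sweep(L, 2, sqrt(colSums(L^2)), `/`)
}

#' Simulate a pair of coupled phase series
#'
#' Produces a theta-like wandering phase and a second phase lagged by `lag`
#' plus independent von Mises jitter of concentration `kappa` at every
#' sample, emulating two phase-coupled oscillators. The expected PLV of the
#' pair is the Bessel ratio `I1(kappa)/I0(kappa)`.
#'
#' @param kappa Von Mises concentration (>= 0) of the phase jitter.
#' @param lag Phase lag in radians added to the second series.
#' @param n Number of samples.
#' @param fs Sampling rate in Hz used for the underlying phase track.
#' @param band Frequency band of the underlying oscillator.
#' @return List with wrapped phase vectors `phase_a` and `phase_b`.
#' @export
simulate_coupled_phases <- function(kappa, lag, n,
                                    fs = 480,
                                    band = band_definition("theta", 4, 8)) {
  if (kappa < 0) stop("kappa must be nonnegative", call. = FALSE)
  phi <- oscillator_phase(n, fs, band)
  eps <- rvonmises(n, kappa)
  list(phase_a = wrap_phase(phi),
       phase_b = wrap_phase(phi + lag + eps))
}

#' Simulate a phase-amplitude-coupled source
#'
#' Generates `s(t) = A (1 + m cos(phi_theta(t))) cos(phi_gamma(t)) + noise`:
#' a gamma oscillation whose amplitude is modulated by theta phase with
#' depth `m`, the standard amplitude-modulation model of theta-gamma
#' coupling. The theta phase actually used is returned as ground truth.
#'
#' @param f_theta,f_gamma Centre frequencies in Hz of the modulating and
#'   carrier rhythms.
#' @param m Modulation depth in [0, 1].
#' @param n Number of samples.
#' @param fs Sampling rate in Hz (`f_gamma < fs/2` required).
#' @param amplitude Carrier amplitude A.
#' @param noise_sd SD of additive broadband noise.
#' @return List with the `series` and the modulating `theta_phase`
#'   (unwrapped radians).
#' @export
simulate_pac_source <- function(f_theta, f_gamma, m, n, fs,
                                amplitude = 1, noise_sd = 0) {
  if (m < 0 || m > 1) stop("modulation depth m must lie in [0, 1]", call. = FALSE)
  if (f_gamma >= fs / 2) stop("f_gamma must be below fs/2", call. = FALSE)
  bw_t <- band_definition("mod", max(f_theta * 0.7, 0.5), f_theta * 1.3)
  bw_g <- band_definition("carrier", f_gamma * 0.9, min(f_gamma * 1.1, fs / 2 - 1))
  phi_t <- oscillator_phase(n, fs, bw_t)
  phi_g <- oscillator_phase(n, fs, bw_g)
  s <- amplitude * (1 + m * cos(phi_t)) * cos(phi_g)
  if (noise_sd > 0) s <- s + stats::rnorm(n, sd = noise_sd)
  list(series = s, theta_phase = phi_t)
}

# deterministic per-subject seed derived from (master seed, subject id)
subject_seed <- function(rng_seed, subject_id) {
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(rng_seed)
  pool <- sample.int(.Machine$integer.max - 1L, 1024L)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  pool[((subject_id - 1L) %% 1024L) + 1L]
}

#' Simulate one subject's sensor recordings
#'
#' Generates `n_trials_per_condition` epochs of sensor data as a lead-field
#' mixture of three planted sources (seed theta, theta-coupled, PAC), plus a
#' per-trial-scaled eye-movement artifact component and white sensor noise.
#' Cue-condition parameters apply inside the cue window only; each epoch
#' also contains the baseline fixation window. The subject's true seed
#' source is displaced up to `seed_jitter_mm` from the group reference
#' voxel, emulating between-subject variance in frontal-midline theta
#' source location.
#'
#' @param config A [sim_config()] object.
#' @param subject_id Integer subject index (determines the RNG stream).
#' @return List with `epochs` ([trial_epochs()], sensor space), `model`
#'   ([source_model()]), and `truth` (planted values, per-trial artifact
#'   variances and the eye-movement covariate table).
#' @export
simulate_subject <- function(config, subject_id) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(subject_seed(config$rng_seed, subject_id))
  fs <- config$fs
  time <- seq(config$trial_window[1], config$trial_window[2] - 1 / fs, by = 1 / fs)
  nt <- length(time)
  ntr <- config$n_trials_per_condition
  coords <- config$grid_coords
  L <- synth_leadfield(coords, config$n_sensors, jitter_sd = 2)
  model <- source_model(coords, L, spacing = config$grid_spacing)

  # subject's true seed: uniform draw among voxels within seed_jitter_mm
  ref_seed <- config$source_positions[["seed"]]
  d <- sqrt(colSums((t(coords) - coords[ref_seed, ])^2))
  cand <- which(d <= config$seed_jitter_mm + 1e-9)
  seed_vox <- if (length(cand) > 1L) sample(cand, 1L) else cand
  coupled_vox <- config$source_positions[["coupled"]]
  pac_vox <- config$source_positions[["pac"]]

  cue_prof <- window_profile(time, config$windows$cue)
  kappa_of_t <- function(tt) {
    ifelse(tt >= config$windows$cue[1] & tt < config$windows$cue[2],
           config$kappa_cue, config$kappa_baseline)
  }
  m_of_t <- config$pac_depth_baseline +
    (config$pac_depth_cue - config$pac_depth_baseline) * cue_prof

  art_topo <- artifact_topography(coords, config) * config$artifact_amplitude
  art_var <- stats::runif(ntr, config$artifact_variance_range[1],
                          config$artifact_variance_range[2])

  X <- array(0, c(config$n_sensors, nt, ntr))
  eye_rows <- vector("list", ntr)
  ib <- window_indices(time, config$windows$baseline, fs)
  ic <- window_indices(time, config$windows$cue, fs)
  gains <- array(exp(stats::rnorm(ntr * 3 * 2, sd = config$trial_gain_sd)),
                 c(ntr, 3, 2))  # trial x source x window(baseline, cue)

  for (tr in seq_len(ntr)) {
    phi_theta <- oscillator_phase(nt, fs, config$theta_band)
    # seed source: theta with planted cue power increase
    amp_seed <- gains[tr, 1, 1] * (1 - cue_prof) +
      gains[tr, 1, 2] * sqrt(config$power_ratio) * cue_prof
    s_seed <- amp_seed * cos(phi_theta) +
      stats::rnorm(nt, sd = config$source_noise_sd)
    # coupled source: seed theta phase + lag + per-cycle von Mises jitter
    eps <- cycle_jitter(time, fs, (config$theta_band$low + config$theta_band$high) / 2,
                        kappa_of_t)
    amp_cpl <- gains[tr, 2, 1] * (1 - cue_prof) +
      gains[tr, 2, 2] * sqrt(config$coupled_power_ratio) * cue_prof
    s_cpl <- amp_cpl * cos(phi_theta + config$coupling_lag + eps) +
      stats::rnorm(nt, sd = config$source_noise_sd)
    # PAC source: high-gamma carrier amplitude-modulated by the seed's theta
    phi_gamma <- oscillator_phase(nt, fs, config$high_gamma_band)
    amp_pac <- gains[tr, 3, 1] * (1 - cue_prof) +
      gains[tr, 3, 2] * sqrt(config$gamma_power_ratio) * cue_prof
    s_pac <- amp_pac * (1 + m_of_t * cos(phi_theta)) * cos(phi_gamma) +
      stats::rnorm(nt, sd = config$source_noise_sd)
    # eye-movement artifact: slow OU course, per-trial variance scale,
    # optionally inflated inside the cue window
    art <- ou_noise(nt, fs, tau = 0.15) * sqrt(art_var[tr])
    if (config$artifact_condition_gain != 1) {
      art <- art * (1 + (config$artifact_condition_gain - 1) * cue_prof)
    }
    S <- rbind(s_seed, s_cpl, s_pac)
    X[, , tr] <- L[, c(seed_vox, coupled_vox, pac_vox)] %*% S +
      outer(art_topo, art) +
      matrix(stats::rnorm(config$n_sensors * nt, sd = config$sensor_noise_sd),
             config$n_sensors, nt)
    eye_rows[[tr]] <- tibble::tibble(
      trial = tr, condition = c("baseline", "cue"),
      eye_variance = c(stats::var(art[ib]), stats::var(art[ic])))
  }

  truth <- list(
    subject_id = subject_id,
    seed_voxel = seed_vox,
    reference_seed_voxel = ref_seed,
    coupled_voxel = coupled_vox,
    pac_voxel = pac_vox,
    power_ratio = config$power_ratio,
    coupled_power_ratio = config$coupled_power_ratio,
    kappa = c(baseline = config$kappa_baseline, cue = config$kappa_cue),
    coupling_lag = config$coupling_lag,
    pac_depth = c(baseline = config$pac_depth_baseline,
                  cue = config$pac_depth_cue),
    artifact_variance = art_var,
    eye_covariate = dplyr::bind_rows(eye_rows)
  )
  list(epochs = trial_epochs(X, fs, time = time, space = "sensor"),
       model = model, truth = truth)
}

artifact_topography <- function(coords, config) {
  # ocular source in front of and below the grid
  span <- apply(coords, 2, range)
  eye_pos <- c(0, span[2, 2] + 60, span[1, 3] - 30)
  c0 <- colMeans(coords)
  i <- seq_len(config$n_sensors)
  golden <- pi * (3 - sqrt(5))
  zs <- 0.15 + 0.85 * (i - 0.5) / config$n_sensors
  th <- golden * i
  sens <- cbind(110 * sqrt(1 - zs^2) * cos(th),
                110 * sqrt(1 - zs^2) * sin(th), 110 * zs)
  sens <- sweep(sens, 2, c0, `+`)
  v <- exp(-rowSums(sweep(sens, 2, eye_pos)^2) / (2 * 50^2))
  v / sqrt(sum(v^2))
}

#' Simulate a full multi-subject study
#'
#' @param config A [sim_config()] object.
#' @return A `meg_study` object: list with `subjects` (each as returned by
#'   [simulate_subject()]), the `config`, and `ground_truth`, a tibble of
#'   the planted per-subject values.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  subjects <- lapply(seq_len(config$n_subjects),
                     function(s) simulate_subject(config, s))
  gt <- dplyr::bind_rows(lapply(subjects, function(su) {
    tibble::tibble(
      subject = su$truth$subject_id,
      seed_voxel = su$truth$seed_voxel,
      coupled_voxel = su$truth$coupled_voxel,
      pac_voxel = su$truth$pac_voxel,
      power_ratio = su$truth$power_ratio,
      kappa_baseline = su$truth$kappa[["baseline"]],
      kappa_cue = su$truth$kappa[["cue"]],
      pac_depth_baseline = su$truth$pac_depth[["baseline"]],
      pac_depth_cue = su$truth$pac_depth[["cue"]])
  }))
  structure(list(subjects = subjects, config = config, ground_truth = gt),
            class = "meg_study")
}

#' @export
print.meg_study <- function(x, ...) {
  cat(sprintf("<meg_study> %d subjects, %d trials each\n",
              length(x$subjects), x$config$n_trials_per_condition))
  print(x$config)
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Epochs and lead fields are serialized with R's native format, the ground
#' truth table as CSV, and the configuration as a plain-text key-value (DCF)
#' file.
#'
#' @param study A `meg_study` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
save_simulation <- function(study, dir) {
  stopifnot(inherits(study, "meg_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    data = file.path(dir, "study.rds"),
    ground_truth = file.path(dir, "ground_truth.csv"),
    config = file.path(dir, "config.dcf"))
  saveRDS(study, paths[["data"]])
  utils::write.csv(study$ground_truth, paths[["ground_truth"]],
                   row.names = FALSE)
  cfg <- study$config
  flat <- lapply(cfg[!vapply(cfg, is.object, logical(1)) &
                       !names(cfg) %in% c("grid_coords")],
                 function(v) paste(format(v, digits = 12), collapse = " "))
  write.dcf(as.data.frame(flat, check.names = FALSE), paths[["config"]])
  invisible(paths)
}
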