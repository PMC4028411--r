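# Seed-based coupling statistics: phase locking value (PLV), phase lag
# index (PLI), and the envelope-phase PLV used for theta-phase to
# gamma-amplitude coupling (PAC).

#' Phase locking value
#'
#' The resultant vector length of the phase differences over time,
#' `PLV = |mean_t exp(i (a_t - b_t))|`: 1 for a perfectly consistent phase
#' relation, tending to 0 for uniformly distributed phase differences.
#' Note that the sample PLV over a finite window is positively biased;
#' condition contrasts with equal window lengths cancel this bias.
#'
#' @param phase_a,phase_b Phase series in radians, equal length (n >= 2).
#' @return A value in [0, 1].
#' @examples
#' plv(c(0, pi / 2), c(0, 0))  # sqrt(2)/2
#' @export
plv <- function(phase_a, phase_b) {
  check_phase_pair(phase_a, phase_b)
  Mod(mean(exp(1i * (phase_a - phase_b))))
}

#' Phase lag index
#'
#' The absolute mean sign of the wrapped phase difference,
#' `PLI = |mean_t sign(wrap(a_t - b_t))|`. It is 1 for a consistent nonzero
#' phase lag, tends to 0 for randomly distributed phase differences, and is
#' insensitive to zero-lag (volume-conducted) coupling because symmetric
#' phase differences around zero cancel. `sign(0)` counts as 0.
#'
#' @inheritParams plv
#' @return A value in [0, 1].
#' @export
pli <- function(phase_a, phase_b) {
  check_phase_pair(phase_a, phase_b)
  abs(mean(sign(wrap_phase(phase_a - phase_b))))
}

check_phase_pair <- function(a, b) {
  if (length(a) != length(b)) {
    stop("phase series must have equal length", call. = FALSE)
  }
  if (length(a) < 2L) stop("need at least 2 samples", call. = FALSE)
  invisible(TRUE)
}

#' Theta-phase to gamma-amplitude coupling (envelope-phase PLV)
#'
#' The double-Hilbert PAC metric: the target series is band-pass filtered
#' in the gamma band and its analytic amplitude (envelope) extracted; the
#' envelope is then band-pass filtered in the theta band and the Hilbert
#' transform applied a second time to obtain the envelope's instantaneous
#' phase; the PLV between that phase and the seed's theta phase is
#' returned. Filtering runs over the full series and the analysis window is
#' cropped last, so both filtering passes see enough context.
#'
#' @param seed_theta_phase Seed theta phase series (radians) over the full
#'   series extent (same length as `target_series`).
#' @param target_series Raw target voxel series.
#' @param gamma_band,theta_band [band_definition()]s.
#' @param fs Sampling rate in Hz.
#' @param window_idx Optional sample indices of the analysis window; the
#'   PLV is computed over these samples only (default: all).
#' @return A value in [0, 1].
#' @export
pac_envelope_phase <- function(seed_theta_phase, target_series,
                               gamma_band, theta_band, fs,
                               window_idx = NULL) {
  if (length(seed_theta_phase) != length(target_series)) {
    stop("seed phase and target series must have equal length", call. = FALSE)
  }
  env <- instantaneous_amplitude(analytic(bandpass(target_series, gamma_band, fs)))
  env_phase <- instantaneous_phase(analytic(bandpass(env, theta_band, fs)))
  if (is.null(window_idx)) window_idx <- seq_along(env_phase)
  if (length(window_idx) < 2L) {
    stop("analysis window too short after transient trimming", call. = FALSE)
  }
  plv(seed_theta_phase[window_idx], env_phase[window_idx])
}

#' Seed-to-all-voxels coupling map
#'
#' Computes one coupling value per voxel, trial and condition window
#' between a seed voxel and every voxel of a source-space epoch set. For
#' `"plv"` and `"pli"` both series are theta-band analytic phases; for
#' `"pac"` the seed's theta phase is compared against the theta-filtered
#' gamma-envelope phase of each target voxel (double Hilbert). Filtering and
#' both Hilbert transforms use the full epoch; the condition windows are
#' cropped last. Per-trial values are kept so that condition means and
#' confound regressions operate on the trial level.
#'
#' @param source_epochs Source-space [trial_epochs()] (voxels as channels).
#' @param seed_voxel Seed voxel index.
#' @param metric `"plv"`, `"pli"` or `"pac"`.
#' @param windows [condition_windows()].
#' @param theta_band,gamma_band [band_definition()]s (`gamma_band` used by
#'   `"pac"` only).
#' @return A `coupling_map` tibble with columns `voxel`, `trial`,
#'   `condition`, `value`, and attributes `metric` and `seed_voxel`.
#' @export
seed_coupling_map <- function(source_epochs, seed_voxel,
                              metric = c("plv", "pli", "pac"),
                              windows = condition_windows(),
                              theta_band = band_definition("theta", 4, 8),
                              gamma_band = band_definition("high_gamma", 65, 85)) {
  metric <- match.arg(metric)
  stopifnot(inherits(source_epochs, "trial_epochs"))
  d <- dim(source_epochs$data)
  if (seed_voxel < 1L || seed_voxel > d[1]) {
    stop("seed voxel index out of range", call. = FALSE)
  }
  fs <- source_epochs$fs
  idx <- list(baseline = window_indices(source_epochs$time, windows$baseline, fs),
              cue      = window_indices(source_epochs$time, windows$cue, fs))

  theta_phase <- Arg(band_analytic_epochs(source_epochs, theta_band))
  if (metric == "pac") {
    genv <- Mod(band_analytic_epochs(source_epochs, gamma_band))
    env_ep <- trial_epochs(genv, fs, time = source_epochs$time, space = "source")
    target_phase <- Arg(band_analytic_epochs(env_ep, theta_band))
  } else {
    target_phase <- theta_phase
  }
  coupling_map_from_phase(target_phase, theta_phase[seed_voxel, , , drop = FALSE],
                          seed_voxel, metric, idx)
}

# phase-level worker shared by seed_coupling_map and the pipeline drivers;
# seed_phase is 1 x time x trials
coupling_map_from_phase <- function(target_phase, seed_phase, seed_voxel,
                                    metric, idx) {
  d <- dim(target_phase)
  vals <- array(NA_real_, c(d[1], 2L, d[3]))
  for (tr in seq_len(d[3])) {
    seed_ph <- seed_phase[1, , tr]
    for (w in 1:2) {
      ii <- idx[[w]]
      dphi <- sweep(matrix(target_phase[, ii, tr], nrow = d[1]),
                    2, seed_ph[ii], `-`)
      vals[, w, tr] <- switch(metric,
        plv = Mod(rowMeans(exp(1i * dphi))),
        pli = abs(rowMeans(sign(wrap_phase(dphi)))),
        pac = Mod(rowMeans(exp(1i * dphi))))
    }
  }
  out <- tibble::tibble(
    voxel = rep(seq_len(d[1]), 2L * d[3]),
    trial = rep(seq_len(d[3]), each = 2L * d[1]),
    condition = rep(rep(c("baseline", "cue"), each = d[1]), d[3]),
    value = as.numeric(vals))
  attr(out, "metric") <- metric
  attr(out, "seed_voxel") <- as.integer(seed_voxel)
  class(out) <- c("coupling_map", class(out))
  out
}

#' Condition means of a coupling map
#'
#' Averages per-trial coupling values within each condition, per voxel --
#' the summary entered into second-level statistics.
#'
#' @param map A `coupling_map` tibble.
#' @return Tibble with `voxel`, `mean_baseline`, `mean_cue`, `difference`.
#' @export
coupling_condition_means <- function(map) {
  map |>
    dplyr::group_by(.data$voxel, .data$condition) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "value",
                       names_prefix = "mean_") |>
    dplyr::mutate(difference = .data$mean_cue - .data$mean_baseline)
}
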