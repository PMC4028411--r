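# End-to-end drivers: sensor epochs -> beamformer -> band power or coupling
# maps -> confound residualization -> second-level cluster statistics.
# These compose the module-level functions exactly as a user would at the
# console; each stage reports errors under its own name.

#' Sensor covariance for beamformer weights
#'
#' Covariance of the sensor channels over the concatenated baseline and cue
#' windows of all trials (a common spatial filter across conditions, so
#' condition differences cannot be artifacts of different weights).
#'
#' @param epochs Sensor-space [trial_epochs()].
#' @param windows [condition_windows()].
#' @return Sensors x sensors covariance matrix.
#' @export
subject_covariance <- function(epochs, windows) {
  seg <- extract_windows(epochs, windows)
  d1 <- dim(seg$baseline); d2 <- dim(seg$cue)
  X <- cbind(matrix(seg$baseline, d1[1]), matrix(seg$cue, d2[1]))
  Xc <- X - rowMeans(X)
  tcrossprod(Xc) / (ncol(X) - 1)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Group power analysis
#'
#' For every subject: LCMV weights from the subject's own covariance,
#' white-noise-normalized per-trial band power at every voxel, linear
#' residualization against the normalized eye-movement variance covariate,
#' then the per-voxel condition difference (cue - baseline) of the
#' residuals. Subject difference maps are entered into a one-sample t test
#' with cluster-extent thresholding and sign-flip permutation FWE control.
#'
#' @param study A [simulate_study()] result (or an equivalently shaped list
#'   of subjects with `epochs`, `model`, `truth$eye_covariate`).
#' @param band A [band_definition()] or one of `"theta"`, `"low_gamma"`,
#'   `"high_gamma"`.
#' @param windows [condition_windows()]; defaults to the study config's.
#' @param reg_fraction Beamformer regularization fraction.
#' @param residualize_eye Regress out the eye-movement variance covariate
#'   (default TRUE).
#' @param p_voxel,min_extent,n_perm Group-statistics settings (defaults
#'   0.001, 10 voxels, 1000 permutations).
#' @return A `power_analysis` list: `group` (a `stat_map` with clusters and
#'   FWE p-values), `group_peak_coord`, `subject_maps` (subjects x voxels),
#'   `subject_power_maps` (per-subject [power_contrast_map()] tibbles), and
#'   the settings used.
#' @export
run_power_analysis <- function(study, band = "theta", windows = NULL,
                               reg_fraction = 0.05, residualize_eye = TRUE,
                               p_voxel = 0.001, min_extent = 10L,
                               n_perm = 1000L) {
  band <- resolve_band(band, study)
  if (is.null(windows)) windows <- study$config$windows
  subjects <- study$subjects
  coords <- subjects[[1]]$model$coords
  maps <- vector("list", length(subjects))
  subj_rows <- matrix(NA_real_, length(subjects), nrow(coords))
  for (s in seq_along(subjects)) {
    su <- subjects[[s]]
    C <- with_stage("covariance", subject_covariance(su$epochs, windows))
    w <- with_stage("beamformer", compute_weights(C, su$model, reg_fraction))
    pm <- with_stage("power", power_contrast_map(w, su$epochs, band, windows))
    trials <- attr(pm, "trials")
    if (residualize_eye) {
      trials <- with_stage("confound",
        residualize_map(trials, su$truth$eye_covariate))
    }
    diffs <- trials |>
      dplyr::group_by(.data$voxel, .data$condition) |>
      dplyr::summarise(power = mean(.data$power), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "condition", values_from = "power")
    subj_rows[s, diffs$voxel] <- diffs$cue - diffs$baseline
    maps[[s]] <- pm
  }
  group <- with_stage("groupstats",
    cluster_fwe_permutation(subj_rows, coords, p_voxel, min_extent, n_perm,
                            spacing = study$config$grid_spacing))
  peak <- coords[which.max(group$table$t), ]
  structure(list(group = group, group_peak_coord = as.numeric(peak),
                 subject_maps = subj_rows, subject_power_maps = maps,
                 band = band, windows = windows, coords = coords,
                 settings = list(p_voxel = p_voxel, min_extent = min_extent,
                                 n_perm = n_perm,
                                 reg_fraction = reg_fraction)),
            class = "power_analysis")
}

resolve_band <- function(band, study = NULL) {
  if (inherits(band, "band_definition")) return(band)
  if (is.character(band) && length(band) == 1L) {
    if (!is.null(study) && !is.null(study$config)) {
      nm <- paste0(band, "_band")
      if (nm %in% names(study$config)) return(study$config[[nm]])
    }
    cb <- canonical_bands()
    if (band %in% names(cb)) return(cb[[band]])
  }
  stop("unknown band", call. = FALSE)
}

#' Group seed-based coupling analysis
#'
#' Implements the seed-connectivity pipeline: each subject's seed voxel is
#' the one with the greatest theta power increase within `seed_radius` mm
#' of the group power peak; per-trial PLV/PLI/PAC maps between that seed
#' and all voxels are computed in both condition windows; the per-trial
#' values are residualized against normalized eye-movement variance, seed
#' theta power, and per-voxel source power (theta for phase coupling,
#' gamma for PAC); the per-voxel condition difference of the residuals
#' enters the one-sample t / permutation cluster stage. Voxels within
#' `seed_radius` of the group peak are flagged `seed_adjacent` in the
#' output, since coupling effects that close to the seed are hard to
#' interpret.
#'
#' @param study A [simulate_study()] result.
#' @param metric `"plv"`, `"pli"` or `"pac"`.
#' @param group_peak_coord Group-level seed region peak (mm); if NULL, a
#'   theta [run_power_analysis()] is run and its peak used.
#' @param seed_radius Seed search radius in mm (default 20).
#' @param residualize_confounds Regress out eye/seed-power/source-power
#'   covariates (default TRUE; FALSE gives the raw contrast).
#' @param reg_fraction,p_voxel,min_extent,n_perm As in
#'   [run_power_analysis()].
#' @return A `coupling_analysis` list: `group` (`stat_map`), `seeds`
#'   (per-subject selected voxel), `subject_maps` (subjects x voxels
#'   difference matrix), `condition_means` (per subject and voxel, tibble),
#'   `seed_adjacent` (logical per voxel), and settings.
#' @export
run_coupling_analysis <- function(study, metric = c("plv", "pli", "pac"),
                                  group_peak_coord = NULL, seed_radius = 20,
                                  residualize_confounds = TRUE,
                                  reg_fraction = 0.05, p_voxel = 0.001,
                                  min_extent = 10L, n_perm = 1000L) {
  metric <- match.arg(metric)
  cfg <- study$config
  windows <- cfg$windows
  theta <- cfg$theta_band
  gamma <- cfg$high_gamma_band
  subjects <- study$subjects
  coords <- subjects[[1]]$model$coords
  if (is.null(group_peak_coord)) {
    pa <- run_power_analysis(study, theta, windows, reg_fraction,
                             p_voxel = p_voxel, min_extent = min_extent,
                             n_perm = min(n_perm, 500L))
    group_peak_coord <- pa$group_peak_coord
  }
  seeds <- integer(length(subjects))
  subj_rows <- matrix(NA_real_, length(subjects), nrow(coords))
  cond_means <- vector("list", length(subjects))
  for (s in seq_along(subjects)) {
    su <- subjects[[s]]
    C <- with_stage("covariance", subject_covariance(su$epochs, windows))
    w <- with_stage("beamformer", compute_weights(C, su$model, reg_fraction))
    src <- with_stage("beamformer", virtual_electrode(w, su$epochs))
    # one fused band-pass + Hilbert pass per band; power comes from the
    # real part, phase from the argument
    z_theta <- with_stage("spectral", band_analytic_epochs(src, theta))
    theta_pm <- with_stage("power",
      power_map_build(Re(z_theta), w, windows, w$noise_power, theta,
                      src$time, src$fs))
    seeds[s] <- with_stage("seed selection",
      select_seed(theta_pm, group_peak_coord, seed_radius))
    idx <- list(
      baseline = window_indices(src$time, windows$baseline, src$fs),
      cue = window_indices(src$time, windows$cue, src$fs))
    theta_phase <- Arg(z_theta)
    gamma_pm <- NULL
    if (metric == "pac") {
      z_gamma <- with_stage("spectral", band_analytic_epochs(src, gamma))
      gamma_pm <- with_stage("power",
        power_map_build(Re(z_gamma), w, windows, w$noise_power, gamma,
                        src$time, src$fs))
      env_ep <- trial_epochs(Mod(z_gamma), src$fs, time = src$time,
                             space = "source")
      target_phase <- Arg(with_stage("spectral",
        band_analytic_epochs(env_ep, theta)))
    } else {
      target_phase <- theta_phase
    }
    cmap <- with_stage("coupling",
      coupling_map_from_phase(target_phase,
                              theta_phase[seeds[s], , , drop = FALSE],
                              seeds[s], metric, idx))
    raw_means <- coupling_condition_means(cmap)
    if (residualize_confounds) {
      theta_trials <- attr(theta_pm, "trials")
      seed_power <- theta_trials[theta_trials$voxel == seeds[s],
                                 c("trial", "condition", "power")]
      names(seed_power)[names(seed_power) == "power"] <- "seed_power"
      shared <- dplyr::left_join(su$truth$eye_covariate, seed_power,
                                 by = c("trial", "condition"))
      source_power <- if (metric == "pac") attr(gamma_pm, "trials") else
        theta_trials
      cmap <- with_stage("confound",
        residualize_map(cmap, shared, source_power = source_power))
    }
    cm <- coupling_condition_means(cmap)
    subj_rows[s, cm$voxel] <- cm$difference
    cond_means[[s]] <- dplyr::mutate(raw_means, subject = s, .before = 1)
  }
  group <- with_stage("groupstats",
    cluster_fwe_permutation(subj_rows, coords, p_voxel, min_extent, n_perm,
                            spacing = cfg$grid_spacing))
  dpk <- sqrt(colSums((t(coords) - group_peak_coord)^2))
  group$table$seed_adjacent <- dpk <= seed_radius + 1e-9
  structure(list(group = group, seeds = seeds, subject_maps = subj_rows,
                 condition_means = dplyr::bind_rows(cond_means),
                 metric = metric, group_peak_coord = group_peak_coord,
                 seed_adjacent = dpk <= seed_radius + 1e-9, coords = coords,
                 settings = list(seed_radius = seed_radius,
                                 residualized = residualize_confounds,
                                 p_voxel = p_voxel, min_extent = min_extent,
                                 n_perm = n_perm)),
            class = "coupling_analysis")
}

#' @export
print.power_analysis <- function(x, ...) {
  cat(sprintf("<power_analysis> band %s, %d subjects, peak at [%s]\n",
              x$band$name, nrow(x$subject_maps),
              paste(x$group_peak_coord, collapse = "; ")))
  print(x$group)
  invisible(x)
}

#' @export
print.coupling_analysis <- function(x, ...) {
  cat(sprintf("<coupling_analysis> metric %s, %d subjects, seed peak at [%s]\n",
              toupper(x$metric), nrow(x$subject_maps),
              paste(round(x$group_peak_coord, 1), collapse = "; ")))
  print(x$group)
  invisible(x)
}

#' Write a stat map as NIfTI
#'
#' Places the per-voxel values of a `stat_map` on its 3-D grid and writes a
#' NIfTI volume whose affine encodes the grid spacing and mm origin.
#'
#' @param stat_map A `stat_map` carrying coordinates.
#' @param file Output path (`.nii` or `.nii.gz`).
#' @param what Which column to write: `"z"` (default), `"t"` or `"p"`.
#' @return Invisibly, the file path.
#' @export
write_stat_map_nifti <- function(stat_map, file, what = c("z", "t", "p")) {
  what <- match.arg(what)
  coords <- stat_map$coords
  if (is.null(coords)) stop("stat map carries no coordinates", call. = FALSE)
  sp <- apply(coords, 2, function(v) {
    u <- sort(unique(v)); if (length(u) > 1) min(diff(u)) else 10
  })
  origin <- apply(coords, 2, min)
  ijk <- round(sweep(coords, 2, origin) / sp) + 1
  dims <- apply(ijk, 2, max)
  vol <- array(NA_real_, dims)
  vol[cbind(ijk[, 1], ijk[, 2], ijk[, 3])] <- stat_map$table[[what]]
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- sp
  affine <- diag(c(sp, 1))
  affine[1:3, 4] <- origin
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Write per-trial coupling values as CSV
#'
#' @param map A `coupling_map` tibble.
#' @param file Output path.
#' @return Invisibly, the file path.
#' @export
write_coupling_csv <- function(map, file) {
  out <- as.data.frame(map)
  out$metric <- attr(map, "metric")
  out$seed_voxel <- attr(map, "seed_voxel")
  utils::write.csv(out, file, row.names = FALSE)
  invisible(file)
}

#' Ground-truth recovery report
#'
#' Compares pipeline results with the planted effects of a simulated study
#' and returns (optionally writes) a plain-text report.
#'
#' @param study A [simulate_study()] result.
#' @param power A theta [run_power_analysis()] result, optional.
#' @param coupling A [run_coupling_analysis()] result, optional.
#' @param file Optional path to write the report to.
#' @return Invisibly, the report lines.
#' @export
recovery_report <- function(study, power = NULL, coupling = NULL, file = NULL) {
  cfg <- study$config
  coords <- cfg$grid_coords
  lines <- c("Ground-truth recovery report",
             sprintf("subjects: %d, trials/condition: %d, fs: %g Hz",
                     cfg$n_subjects, cfg$n_trials_per_condition, cfg$fs))
  ref <- cfg$source_positions
  lines <- c(lines, sprintf(
    "planted sources (voxel): seed %d, coupled %d, pac %d",
    ref[["seed"]], ref[["coupled"]], ref[["pac"]]))
  if (!is.null(power)) {
    pk <- power$group_peak_coord
    dmm <- sqrt(sum((pk - coords[ref[["seed"]], ])^2))
    lines <- c(lines, sprintf(
      "theta power: group peak [%s] mm, %.1f mm from planted seed (ratio planted %.2f)",
      paste(pk, collapse = "; "), dmm, cfg$power_ratio))
    if (!is.null(power$group$clusters) && nrow(power$group$clusters)) {
      lines <- c(lines, sprintf("  clusters: %s",
        paste(sprintf("extent %d (FWE p = %.4g)", power$group$clusters$extent,
                      power$group$clusters$p_fwe), collapse = ", ")))
    } else {
      lines <- c(lines, "  no supra-threshold cluster")
    }
  }
  if (!is.null(coupling)) {
    tgt <- if (coupling$metric == "pac") ref[["pac"]] else ref[["coupled"]]
    peak_vox <- coupling$group$table$voxel[which.max(coupling$group$table$t)]
    dmm <- sqrt(sum((coords[peak_vox, ] - coords[tgt, ])^2))
    cm <- coupling$condition_means
    cm_t <- cm[cm$voxel == tgt, ]
    lines <- c(lines, sprintf(
      "%s coupling: group peak voxel %d, %.1f mm from planted target; baseline %.3f, cue %.3f, increase in %d/%d subjects",
      toupper(coupling$metric), peak_vox, dmm,
      mean(cm_t$mean_baseline), mean(cm_t$mean_cue),
      sum(cm_t$difference > 0), nrow(cm_t)))
    if (!is.null(coupling$group$clusters) && nrow(coupling$group$clusters)) {
      lines <- c(lines, sprintf("  clusters: %s",
        paste(sprintf("extent %d (FWE p = %.4g)",
                      coupling$group$clusters$extent,
                      coupling$group$clusters$p_fwe), collapse = ", ")))
    } else {
      lines <- c(lines, "  no supra-threshold cluster")
    }
  }
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
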