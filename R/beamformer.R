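#' Source model: voxel grid plus lead fields
#'
#' @param coords Voxel coordinates in mm, an `n_voxels x 3` matrix on a
#'   regular grid.
#' @param leadfield `n_sensors x n_voxels` matrix mapping unit activity at
#'   each (fixed-orientation, scalar) source to the sensor array.
#' @param spacing Grid spacing in mm (default 10).
#' @return A `source_model` object.
#' @export
source_model <- function(coords, leadfield, spacing = 10) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L, ncol(leadfield) == nrow(coords))
  if (any(colSums(leadfield^2) == 0)) {
    stop("leadfield columns must be non-zero", call. = FALSE)
  }
  if (anyDuplicated(coords)) stop("voxel coordinates must be unique", call. = FALSE)
  structure(list(coords = coords, leadfield = leadfield, spacing = spacing),
            class = "source_model")
}

#' @export
print.source_model <- function(x, ...) {
  cat(sprintf("<source_model> %d voxels (%g-mm grid), %d sensors\n",
              nrow(x$coords), x$spacing, nrow(x$leadfield)))
  invisible(x)
}

#' LCMV beamformer weights
#'
#' Computes linearly constrained minimum variance spatial filters from the
#' sensor covariance and lead fields: for voxel n,
#' `w_n = (l_n' Cr^-1 l_n)^-1 Cr^-1 l_n` with
#' `Cr = C + reg_fraction * mean(diag(C)) * I`. Each filter passes its own
#' source with unit gain (`w_n' l_n = 1`) while minimizing output variance,
#' i.e. suppressing every other source as far as the data allow.
#'
#' @param covariance Symmetric positive semi-definite sensor covariance.
#' @param model A [source_model()].
#' @param reg_fraction Diagonal-loading fraction of the mean sensor variance
#'   (default 0.05).
#' @return A `beamformer_weights` object: `W` (voxels x sensors), `wtw`
#'   (per-voxel `w_n' w_n`, the white-noise projection factor), the
#'   regularization used, and `noise_power` (smallest eigenvalue of the
#'   covariance, the default white-noise floor for normalization).
#' @export
compute_weights <- function(covariance, model, reg_fraction = 0.05) {
  stopifnot(inherits(model, "source_model"))
  C <- as.matrix(covariance)
  if (nrow(C) != ncol(C) || max(abs(C - t(C))) > 1e-8 * max(abs(C), 1e-300)) {
    stop("covariance must be a symmetric matrix", call. = FALSE)
  }
  if (nrow(C) != nrow(model$leadfield)) {
    stop("covariance dimension does not match the lead field sensor count",
         call. = FALSE)
  }
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    stop("covariance must be positive semi-definite", call. = FALSE)
  }
  Cr <- C + reg_fraction * mean(diag(C)) * diag(nrow(C))
  Ci_L <- tryCatch(solve(Cr, model$leadfield),
                   error = function(e) stop("regularized covariance is singular",
                                            call. = FALSE))
  denom <- colSums(model$leadfield * Ci_L)
  if (any(denom <= 0)) stop("degenerate lead field/covariance pair", call. = FALSE)
  W <- t(Ci_L) / denom
  structure(list(W = W, wtw = rowSums(W^2), reg_fraction = reg_fraction,
                 noise_power = max(min(ev), 0), model = model),
            class = "beamformer_weights")
}

#' @export
print.beamformer_weights <- function(x, ...) {
  cat(sprintf("<beamformer_weights> %d voxels x %d sensors (reg %.3g, noise floor %.3g)\n",
              nrow(x$W), ncol(x$W), x$reg_fraction, x$noise_power))
  invisible(x)
}

#' Virtual-electrode source time series
#'
#' Applies beamformer weights to sensor epochs, producing one source-space
#' series per voxel and trial.
#'
#' @param weights A [compute_weights()] result.
#' @param epochs Sensor-space [trial_epochs()].
#' @return Source-space [trial_epochs()] with one channel per voxel.
#' @export
virtual_electrode <- function(weights, epochs) {
  stopifnot(inherits(weights, "beamformer_weights"),
            inherits(epochs, "trial_epochs"))
  d <- dim(epochs$data)
  if (ncol(weights$W) != d[1]) {
    stop(sprintf("weights expect %d sensors, epochs have %d",
                 ncol(weights$W), d[1]), call. = FALSE)
  }
  src <- array(weights$W %*% matrix(epochs$data, d[1]),
               c(nrow(weights$W), d[2], d[3]))
  trial_epochs(src, epochs$fs, time = epochs$time, space = "source")
}

#' White-noise-normalized band-power contrast map
#'
#' For every voxel, band power is computed per trial in the baseline and cue
#' windows of the virtual-electrode series and divided by the projected
#' sensor white-noise power `noise_power * (w_n' w_n)`; the per-condition
#' values are averaged across trials and the map value is their difference
#' (cue minus baseline). This neural-activity-index-style normalization
#' removes the beamformer's depth-dependent noise amplification, so the map
#' is invariant to overall sensor gain.
#'
#' @param weights A [compute_weights()] result.
#' @param epochs Sensor-space [trial_epochs()]; each trial contains both
#'   condition windows.
#' @param band [band_definition()] for the power estimate.
#' @param windows [condition_windows()].
#' @param noise_power Sensor white-noise power used for normalization;
#'   defaults to the smallest covariance eigenvalue stored in `weights`.
#' @return A `power_map` tibble with one row per voxel (`voxel`, `x`, `y`,
#'   `z`, `power_baseline`, `power_cue`, `contrast`), with the per-trial
#'   normalized powers attached as attribute `"trials"`.
#' @export
power_contrast_map <- function(weights, epochs, band, windows,
                               noise_power = NULL) {
  stopifnot(inherits(weights, "beamformer_weights"))
  if (is.null(noise_power)) noise_power <- weights$noise_power
  if (!is.numeric(noise_power) || length(noise_power) != 1L || noise_power <= 0) {
    stop("noise_power must be a positive scalar", call. = FALSE)
  }
  if (dim(epochs$data)[3] < 1L) stop("need at least one trial", call. = FALSE)
  src <- if (identical(epochs$space, "source")) epochs else
    virtual_electrode(weights, epochs)
  filt <- bandpass_epochs(src, band)
  power_map_build(filt$data, weights, windows, noise_power, band,
                  src$time, src$fs)
}

# builds the normalized power map from an already band-passed source array
power_map_build <- function(filt_data, weights, windows, noise_power, band,
                            time, fs) {
  ib <- window_indices(time, windows$baseline, fs)
  ic <- window_indices(time, windows$cue, fs)
  pb <- apply(filt_data[, ib, , drop = FALSE]^2, c(1, 3), mean)
  pc <- apply(filt_data[, ic, , drop = FALSE]^2, c(1, 3), mean)
  nv <- nrow(pb); nt <- ncol(pb)
  norm <- noise_power * weights$wtw
  tp <- tibble::tibble(
    voxel = rep(rep(seq_len(nv), nt), 2L),
    trial = rep(rep(seq_len(nt), each = nv), 2L),
    condition = rep(c("baseline", "cue"), each = nv * nt),
    power = c(as.numeric(pb), as.numeric(pc)) / rep(norm, nt * 2L))
  coords <- weights$model$coords
  mb <- rowMeans(pb) / norm
  mc <- rowMeans(pc) / norm
  out <- tibble::tibble(
    voxel = seq_len(nv),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    power_baseline = mb, power_cue = mc, contrast = mc - mb)
  attr(out, "trials") <- tp
  attr(out, "band") <- band
  class(out) <- c("power_map", class(out))
  out
}
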