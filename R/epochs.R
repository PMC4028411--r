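#' Multi-trial epoch container
#'
#' Holds one subject's sensor- or source-space trial epochs as a numeric
#' array of dimension channels x time x trials, together with the sampling
#' rate and a time axis in seconds relative to cue onset. Each epoch spans
#' both the baseline fixation window and the cue window; condition is a
#' property of the analysis window, not of the epoch.
#'
#' @param data Numeric array `[n_channels, n_time, n_trials]` (a matrix is
#'   promoted to a single trial).
#' @param fs Sampling rate in Hz.
#' @param time Numeric time axis (seconds, relative to cue onset), length
#'   `n_time`. Alternatively supply `onset`, the time of the first sample.
#' @param onset Time of the first sample in seconds; used when `time` is
#'   missing.
#' @param space `"sensor"` or `"source"`.
#' @return A `trial_epochs` object.
#' @export
trial_epochs <- function(data, fs, time = NULL, onset = NULL,
                         space = c("sensor", "source")) {
  space <- match.arg(space)
  if (is.matrix(data)) data <- array(data, c(nrow(data), ncol(data), 1L))
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a positive scalar (Hz)", call. = FALSE)
  }
  n_time <- dim(data)[2]
  if (is.null(time)) {
    if (is.null(onset)) stop("supply either time or onset", call. = FALSE)
    time <- onset + (seq_len(n_time) - 1L) / fs
  }
  if (length(time) != n_time) {
    stop("time axis length must match dim(data)[2]", call. = FALSE)
  }
  structure(list(data = data, fs = fs, time = as.numeric(time), space = space),
            class = "trial_epochs")
}

#' @export
print.trial_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<trial_epochs> %d %s channel(s) x %d samples x %d trial(s) @ %g Hz, t = [%.3f, %.3f] s\n",
    d[1], x$space, d[2], d[3], x$fs, x$time[1], x$time[length(x$time)]))
  invisible(x)
}

n_trials <- function(epochs) dim(epochs$data)[3]
n_channels <- function(epochs) dim(epochs$data)[1]

#' Sample indices of a time window
#'
#' Converts a `[t0, t1)` window in seconds into half-open sample indices on
#' an epoch's time axis. Times are rounded to the nearest sample; the window
#' contains exactly `round((t1 - t0) * fs)` samples.
#'
#' @param time Epoch time axis in seconds.
#' @param window Length-2 numeric `c(t0, t1)`.
#' @param fs Sampling rate in Hz.
#' @return Integer vector of sample indices into `time`.
#' @export
window_indices <- function(time, window, fs) {
  i0 <- round((window[1] - time[1]) * fs) + 1
  n  <- round((window[2] - window[1]) * fs)
  idx <- seq.int(i0, length.out = n)
  if (idx[1] < 1L || idx[n] > length(time)) {
    stop(sprintf("epoch too short: window [%g, %g) s not covered by [%g, %g] s",
                 window[1], window[2], time[1], time[length(time)]),
         call. = FALSE)
  }
  as.integer(idx)
}

#' Extract baseline and cue segments from epochs
#'
#' Crops each trial to the two condition windows. At 480 Hz with 1-s windows
#' each segment has exactly 480 samples.
#'
#' @param epochs A [trial_epochs()] object.
#' @param windows A [condition_windows()] object.
#' @return A list with elements `baseline` and `cue`, each a channels x
#'   samples x trials array, plus the per-window sample `indices`.
#' @export
extract_windows <- function(epochs, windows) {
  stopifnot(inherits(epochs, "trial_epochs"),
            inherits(windows, "condition_windows"))
  ib <- window_indices(epochs$time, windows$baseline, epochs$fs)
  ic <- window_indices(epochs$time, windows$cue, epochs$fs)
  list(baseline = epochs$data[, ib, , drop = FALSE],
       cue      = epochs$data[, ic, , drop = FALSE],
       indices  = list(baseline = ib, cue = ic))
}
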