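# Spectral primitives: zero-phase band-pass filtering, analytic signal,
# band power. Filtering is a forward-backward pass of a 4th-order Butterworth
# band-pass (8 poles total), giving zero group delay and squared magnitude
# response. The matrix path runs all channels/trials as columns through
# stats::filter (compiled) so whole epoch sets are filtered in one call.

# single forward IIR pass, columnwise; a[1] must be 1 after normalization
iir_filter_mat <- function(x, b, a) {
  b <- b / a[1]
  a <- a / a[1]
  nb <- length(b)
  xp <- rbind(matrix(0, nb - 1L, ncol(x)), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1L)
  v <- v[nb:nrow(xp), , drop = FALSE]
  if (length(a) > 1L) {
    y <- stats::filter(v, -a[-1L], method = "recursive")
  } else {
    y <- v
  }
  matrix(as.numeric(y), nrow(x), ncol(x))
}

# zero-phase forward-backward filtering with odd-reflection end padding;
# npad absorbs the filter transient so interior samples are undistorted
filtfilt_mat <- function(x, b, a, npad = NULL) {
  n <- nrow(x)
  if (is.null(npad)) npad <- min(n - 1L, 3L * (max(length(a), length(b)) - 1L))
  npad <- min(npad, n - 1L)
  if (npad > 0L) {
    head_pad <- 2 * x[rep(1L, npad), , drop = FALSE] -
      x[(npad + 1L):2L, , drop = FALSE]
    tail_pad <- 2 * x[rep(n, npad), , drop = FALSE] -
      x[(n - 1L):(n - npad), , drop = FALSE]
    xp <- rbind(head_pad, x, tail_pad)
  } else {
    xp <- x
  }
  y <- iir_filter_mat(xp, b, a)
  y <- iir_filter_mat(y[nrow(y):1L, , drop = FALSE], b, a)
  y <- y[nrow(y):1L, , drop = FALSE]
  if (npad > 0L) y <- y[(npad + 1L):(npad + n), , drop = FALSE]
  y
}

butter_coefs <- function(band, fs, order = 4L) {
  flt <- signal::butter(order, c(band$low, band$high) / (fs / 2), type = "pass")
  list(b = flt$b, a = flt$a)
}

# |H(omega)|^2 of the Butterworth band-pass on the FFT frequency grid of a
# length-n segment: the transfer function of one forward plus one backward
# pass (zero phase by construction)
butter_mag2 <- function(n, b, a, fs) {
  w <- 2 * pi * (seq_len(n) - 1L) / n
  e <- exp(-1i * outer(w, seq_along(a) - 1L))
  H <- (e[, seq_along(b), drop = FALSE] %*% b) / (e %*% a)
  as.numeric(Mod(H)^2)
}

# Zero-phase filtering via the frequency domain: odd-reflection padding,
# multiply the spectrum by |H|^2, crop. Equivalent to the forward-backward
# time-domain pass away from the (padded-out) edges, but runs all columns
# of a matrix in one vectorized FFT. Columns are chunked to bound memory.
# With analytic = TRUE the one-sided Hilbert mask is applied in the same
# pass, returning the complex analytic signal of the filtered data
# (Re(z) is exactly the filtered series).
fftfilt_mat <- function(x, b, a, fs, npad, analytic = FALSE) {
  n <- nrow(x)
  npad <- min(npad, n - 1L)
  nfft <- stats::nextn(n + 2L * npad, c(2L, 3L, 5L))
  mult <- butter_mag2(nfft, b, a, fs)
  if (analytic) {
    h <- numeric(nfft)
    h[1] <- 1
    if (nfft %% 2 == 0) {
      h[nfft / 2 + 1] <- 1
      h[2:(nfft / 2)] <- 2
    } else {
      h[2:((nfft + 1) / 2)] <- 2
    }
    mult <- mult * h
  }
  out <- if (analytic) matrix(0i, n, ncol(x)) else matrix(0, n, ncol(x))
  chunk <- max(1L, floor(4e6 / nfft))
  for (j0 in seq(1L, ncol(x), by = chunk)) {
    jj <- j0:min(j0 + chunk - 1L, ncol(x))
    xs <- x[, jj, drop = FALSE]
    if (npad > 0L) {
      head_pad <- 2 * xs[rep(1L, npad), , drop = FALSE] -
        xs[(npad + 1L):2L, , drop = FALSE]
      tail_pad <- 2 * xs[rep(n, npad), , drop = FALSE] -
        xs[(n - 1L):(n - npad), , drop = FALSE]
      xs <- rbind(head_pad, xs, tail_pad)
    }
    xs <- rbind(xs, matrix(0, nfft - nrow(xs), length(jj)))
    y <- stats::mvfft(stats::mvfft(xs) * mult, inverse = TRUE) / nfft
    if (!analytic) y <- Re(y)
    out[, jj] <- y[(npad + 1L):(npad + n), , drop = FALSE]
  }
  out
}

#' Zero-phase band-pass filter
#'
#' Filters a series (or the columns of a matrix) with a 4th-order Butterworth
#' band-pass applied forward and backward, so the output has no group delay
#' and unity passband gain. End effects are absorbed by odd-reflection
#' padding of about three cycles of the band's low edge; callers analysing
#' short windows should filter the full epoch and crop afterwards.
#'
#' @param x Numeric vector or matrix (time in rows, channels in columns).
#' @param band A [band_definition()].
#' @param fs Sampling rate in Hz.
#' @return Filtered data with the shape of `x`.
#' @examples
#' fs <- 480
#' t <- seq(0, 4, by = 1 / fs)
#' y <- bandpass(sin(2 * pi * 6 * t), band_definition("theta", 4, 8), fs)
#' @export
bandpass <- function(x, band, fs) {
  stopifnot(inherits(band, "band_definition"))
  check_band_feasible(band, fs)
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  if (nrow(x) < 24L) {
    stop("series too short to band-pass filter (need > 3 filter transients)",
         call. = FALSE)
  }
  cf <- butter_coefs(band, fs)
  npad <- min(nrow(x) - 1L, ceiling(3 * fs / band$low))
  y <- fftfilt_mat(x, cf$b, cf$a, fs, npad = npad)
  if (vec) drop(y) else y
}

# FFT analytic signal, columnwise (the classic one-sided spectrum method)
analytic_mat <- function(x) {
  n <- nrow(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    if (n > 2) h[2:(n / 2)] <- 2
  } else if (n > 1) {
    h[2:((n + 1) / 2)] <- 2
  }
  stats::mvfft(stats::mvfft(x) * h, inverse = TRUE) / n
}

#' Analytic signal (Hilbert transform)
#'
#' Returns the complex analytic extension of a real band-limited series,
#' computed in the frequency domain. Its modulus is the instantaneous
#' amplitude (envelope) and its argument the instantaneous phase.
#'
#' @param x Numeric vector or matrix (time in rows).
#' @return Complex data with the shape of `x`.
#' @seealso [band_analytic()] for the filter-then-transform convenience,
#'   [instantaneous_phase()], [instantaneous_amplitude()].
#' @export
analytic <- function(x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  if (nrow(x) < 2L) stop("series too short for analytic signal", call. = FALSE)
  z <- analytic_mat(x)
  if (vec) drop(z) else z
}

#' Band-limited analytic signal
#'
#' Band-pass filters a series and returns its analytic signal together with
#' the band and sampling rate.
#'
#' @inheritParams bandpass
#' @return An `analytic_band_signal` object: list with complex `z`, `band`,
#'   `fs`.
#' @export
band_analytic <- function(x, band, fs) {
  z <- analytic(bandpass(x, band, fs))
  structure(list(z = z, band = band, fs = fs), class = "analytic_band_signal")
}

#' @export
print.analytic_band_signal <- function(x, ...) {
  d <- if (is.null(dim(x$z))) c(length(x$z), 1L) else dim(x$z)
  cat(sprintf("<analytic_band_signal> %s %g-%g Hz, %d samples x %d series @ %g Hz\n",
              x$band$name, x$band$low, x$band$high, d[1], d[2], x$fs))
  invisible(x)
}

#' Instantaneous phase and amplitude
#'
#' @param z A complex analytic signal or an `analytic_band_signal`.
#' @return Phase in radians wrapped to (-pi, pi], or nonnegative amplitude,
#'   with the shape of the underlying series.
#' @export
instantaneous_phase <- function(z) {
  if (inherits(z, "analytic_band_signal")) z <- z$z
  wrap_phase(Arg(z))
}

#' @rdname instantaneous_phase
#' @export
instantaneous_amplitude <- function(z) {
  if (inherits(z, "analytic_band_signal")) z <- z$z
  Mod(z)
}

#' Wrap phase angles to (-pi, pi]
#'
#' @param x Phase values in radians.
#' @return Values wrapped into the half-open interval (-pi, pi].
#' @export
wrap_phase <- function(x) {
  w <- x %% (2 * pi)
  w[w > pi] <- w[w > pi] - 2 * pi
  w
}

#' Band power of a series over a window
#'
#' Power is the mean squared band-passed signal over the analysis window
#' (so a unit-amplitude in-band sinusoid has power 0.5). The full series is
#' filtered first and the window cropped afterwards, keeping filter edge
#' effects out of the estimate.
#'
#' @inheritParams bandpass
#' @param window Length-2 numeric `c(t0, t1)` in seconds on `time`, or NULL
#'   for the whole series.
#' @param time Time axis in seconds (defaults to samples starting at 0).
#' @return Scalar power (or one value per column of `x`).
#' @export
band_power <- function(x, band, fs, window = NULL, time = NULL) {
  vec <- is.null(dim(x))
  y <- bandpass(x, band, fs)
  if (vec) y <- matrix(y, ncol = 1L)
  if (!is.null(window)) {
    if (is.null(time)) time <- (seq_len(nrow(y)) - 1L) / fs
    idx <- window_indices(time, window, fs)
    if (length(idx) == 0L) stop("empty analysis window", call. = FALSE)
    y <- y[idx, , drop = FALSE]
  }
  p <- colMeans(y^2)
  if (vec) unname(p[1]) else p
}

# Filter a whole epochs array in one matrix pass; returns an array of the
# same shape. Used by the beamformer/coupling layers.
bandpass_epochs <- function(epochs, band) {
  d <- dim(epochs$data)
  # to time x (channel*trial)
  m <- matrix(aperm(epochs$data, c(2, 1, 3)), nrow = d[2])
  mf <- bandpass(m, band, epochs$fs)
  out <- aperm(array(mf, c(d[2], d[1], d[3])), c(2, 1, 3))
  trial_epochs(out, epochs$fs, time = epochs$time, space = epochs$space)
}

# Fused band-pass + Hilbert over a whole epochs array in one FFT pass;
# returns the complex analytic array (channels x time x trials), whose real
# part is exactly the band-passed data.
band_analytic_epochs <- function(epochs, band) {
  check_band_feasible(band, epochs$fs)
  d <- dim(epochs$data)
  m <- matrix(aperm(epochs$data, c(2, 1, 3)), nrow = d[2])
  cf <- butter_coefs(band, epochs$fs)
  npad <- min(d[2] - 1L, ceiling(3 * epochs$fs / band$low))
  z <- fftfilt_mat(m, cf$b, cf$a, epochs$fs, npad = npad, analytic = TRUE)
  aperm(array(z, c(d[2], d[1], d[3])), c(2, 1, 3))
}

#' Per-trial band power in both condition windows
#'
#' Filters every channel of every trial, crops the baseline and cue windows
#' and returns the mean squared signal per channel, trial and window.
#'
#' @param epochs A [trial_epochs()] object.
#' @param band A [band_definition()].
#' @param windows A [condition_windows()] object.
#' @return A tibble with columns `channel`, `trial`, `condition`
#'   (`"baseline"`/`"cue"`) and `power`.
#' @export
trial_band_power <- function(epochs, band, windows) {
  filt <- bandpass_epochs(epochs, band)
  seg <- extract_windows(filt, windows)
  pb <- apply(seg$baseline^2, c(1, 3), mean)
  pc <- apply(seg$cue^2, c(1, 3), mean)
  nc <- nrow(pb); nt <- ncol(pb)
  tibble::tibble(
    channel = rep(rep(seq_len(nc), nt), 2L),
    trial = rep(rep(seq_len(nt), each = nc), 2L),
    condition = rep(c("baseline", "cue"), each = nc * nt),
    power = c(as.numeric(pb), as.numeric(pc))
  )
}
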