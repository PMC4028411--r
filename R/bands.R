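#' Frequency band definition
#'
#' A band is a named half-open frequency interval in Hz. The canonical bands
#' used throughout the package are theta (4--8 Hz), low gamma (30--45 Hz) and
#' high gamma (65--85 Hz).
#'
#' @param name Band label, e.g. `"theta"`.
#' @param low,high Band edges in Hz; `0 < low < high` required.
#' @return A `band_definition` object (named list with `name`, `low`, `high`).
#' @examples
#' band_definition("theta", 4, 8)
#' @export
band_definition <- function(name, low, high) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(low) || !is.numeric(high) || length(low) != 1L ||
      length(high) != 1L || !is.finite(low) || !is.finite(high)) {
    stop("band edges must be finite scalars", call. = FALSE)
  }
  if (!(low > 0 && high > low)) {
    stop("band requires 0 < low < high (Hz)", call. = FALSE)
  }
  structure(list(name = name, low = low, high = high),
            class = "band_definition")
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band> %s: %g-%g Hz\n", x$name, x$low, x$high))
  invisible(x)
}

#' Canonical analysis bands
#'
#' @return A named list of [band_definition()] objects: `theta` 4--8 Hz,
#'   `low_gamma` 30--45 Hz, `high_gamma` 65--85 Hz.
#' @export
canonical_bands <- function() {
  list(
    theta      = band_definition("theta", 4, 8),
    low_gamma  = band_definition("low_gamma", 30, 45),
    high_gamma = band_definition("high_gamma", 65, 85)
  )
}

check_band_feasible <- function(band, fs) {
  if (band$high >= fs / 2) {
    stop(sprintf("band %s (%g-%g Hz) infeasible at fs = %g Hz (Nyquist %g)",
                 band$name, band$low, band$high, fs, fs / 2), call. = FALSE)
  }
  invisible(TRUE)
}

#' Baseline and cue analysis windows
#'
#' The contrast throughout the package is between a baseline fixation window
#' and a post-cue window, both given in seconds relative to cue onset. The
#' defaults are the final 1 s of fixation before cue onset (`[-1, 0)`) and
#' 0.5 to 1.5 s after cue presentation (`[0.5, 1.5)`). Windows are half-open
#' at sample resolution and must have equal duration so that coupling and
#' power estimates are comparable across conditions.
#'
#' @param baseline,cue Length-2 numeric vectors `c(t0, t1)` in seconds.
#' @return A `condition_windows` object.
#' @export
condition_windows <- function(baseline = c(-1, 0), cue = c(0.5, 1.5)) {
  for (w in list(baseline, cue)) {
    if (length(w) != 2L || !all(is.finite(w)) || w[2] <= w[1]) {
      stop("each window must be c(t0, t1) with t1 > t0", call. = FALSE)
    }
  }
  if (abs(diff(baseline) - diff(cue)) > 1e-9) {
    stop("baseline and cue windows must have equal duration", call. = FALSE)
  }
  structure(list(baseline = as.numeric(baseline), cue = as.numeric(cue)),
            class = "condition_windows")
}

#' @export
print.condition_windows <- function(x, ...) {
  cat(sprintf("<windows> baseline [%g, %g) s, cue [%g, %g) s (re cue onset)\n",
              x$baseline[1], x$baseline[2], x$cue[1], x$cue[2]))
  invisible(x)
}
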