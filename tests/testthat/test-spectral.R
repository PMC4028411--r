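fs <- 480
theta <- band_definition("theta", 4, 8)
tt <- seq(0, 5 - 1 / fs, by = 1 / fs)
interior <- 500:1900

test_that("band definitions validate their edges", {
  expect_error(band_definition("bad", 8, 4), "low < high")
  expect_error(band_definition("bad", -1, 4), "low < high")
  expect_error(bandpass(rnorm(480), band_definition("hf", 200, 260), fs),
               "infeasible")
})

test_that("bandpass has unit passband gain and strong stopband attenuation", {
  y <- bandpass(cos(2 * pi * 6 * tt), theta, fs)
  expect_equal(max(abs(y[interior])), 1, tolerance = 0.05)
  y20 <- bandpass(cos(2 * pi * 20 * tt), theta, fs)
  expect_lt(max(abs(y20[interior])), 10^(-20 / 20))
})

test_that("white-noise band power matches the bandwidth fraction (Parseval)", {
  set.seed(11)
  x <- rnorm(fs * 60)
  y <- bandpass(x, theta, fs)
  ratio <- var(y) / var(x)
  expect_equal(ratio, (theta$high - theta$low) / (fs / 2), tolerance = 0.2)
})

test_that("frequency-domain filtering matches the time-domain forward-backward pass", {
  set.seed(12)
  x <- rnorm(2400)
  cf <- megcoupling:::butter_coefs(theta, fs)
  y_fft <- bandpass(x, theta, fs)
  y_td <- drop(megcoupling:::filtfilt_mat(matrix(x), cf$b, cf$a, npad = 360))
  expect_lt(max(abs(y_fft[300:2100] - y_td[300:2100])) / sd(y_td), 0.02)
})

test_that("the single-pass IIR recursion matches signal::filter exactly", {
  set.seed(13)
  x <- rnorm(1000)
  cf <- megcoupling:::butter_coefs(theta, fs)
  mine <- drop(megcoupling:::iir_filter_mat(matrix(x), cf$b, cf$a))
  ref <- as.numeric(signal::filter(cf$b, cf$a, x))
  expect_equal(mine, ref, tolerance = 1e-10)
})

test_that("zero-phase property: output is not delayed relative to input", {
  set.seed(14)
  x <- bandpass(rnorm(fs * 10), theta, fs)  # in-band input
  y <- bandpass(x, theta, fs)
  cc <- ccf(x, y, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("analytic signal recovers amplitude and phase velocity of a tone", {
  a <- 2.5
  z <- analytic(a * cos(2 * pi * 6 * tt))
  expect_equal(mean(Mod(z)[interior]), a, tolerance = 0.01)
  slope <- diff(unwrap_phase <- cumsum(c(Arg(z)[1], wrap_phase(diff(Arg(z))))))
  expect_equal(mean(slope[interior]) * fs / (2 * pi), 6, tolerance = 0.06)
})

test_that("analytic amplitude tracks a constructed chirp envelope", {
  env <- 1 + 0.5 * sin(2 * pi * 0.5 * tt)
  f_inst <- 40 + 5 * tt  # 40 -> 65 Hz chirp, well inside Nyquist
  x <- env * cos(2 * pi * cumsum(f_inst) / fs)
  amp <- instantaneous_amplitude(analytic(x))
  expect_equal(amp[interior], env[interior], tolerance = 0.02)
})

test_that("band_analytic envelope recovers a planted modulation envelope", {
  env <- 1 + 0.4 * cos(2 * pi * 1 * tt)
  x <- env * cos(2 * pi * 37 * tt) + 0.3 * cos(2 * pi * 90 * tt)
  z <- band_analytic(x, band_definition("low_gamma", 30, 45), fs)
  expect_equal(instantaneous_amplitude(z)[interior], env[interior],
               tolerance = 0.05)
})

test_that("band_power follows the mean-square convention", {
  x6 <- cos(2 * pi * 6 * tt)
  expect_equal(band_power(x6, theta, fs, window = c(1, 4)), 0.5,
               tolerance = 0.02)
  x20 <- cos(2 * pi * 20 * tt)
  expect_lt(band_power(x20, theta, fs, window = c(1, 4)), 0.01)
  both <- x6 + x20
  expect_equal(band_power(both, theta, fs, window = c(1, 4)), 0.5,
               tolerance = 0.05 * 0.5)
})

test_that("trial_band_power agrees with band_power channel by channel", {
  set.seed(15)
  ep <- trial_epochs(array(rnorm(2 * 1680 * 2), c(2, 1680, 2)), fs,
                     onset = -1.5)
  w <- condition_windows()
  tp <- trial_band_power(ep, theta, w)
  for (tr in 1:2) {
    for (ch in 1:2) {
      ref <- band_power(ep$data[ch, , tr], theta, fs,
                        window = w$cue, time = ep$time)
      got <- tp$power[tp$channel == ch & tp$trial == tr &
                        tp$condition == "cue"]
      expect_equal(got, ref, tolerance = 1e-10)
    }
  }
})

test_that("wrap_phase maps onto (-pi, pi]", {
  x <- c(-3 * pi, -pi, -1e-9, 0, pi, pi + 1e-9, 7.5 * pi)
  w <- wrap_phase(x)
  expect_true(all(w > -pi & w <= pi))
  expect_equal(wrap_phase(pi), pi)
  expect_equal(wrap_phase(-pi), pi)
  expect_equal(wrap_phase(2.5), 2.5)
})

test_that("extract_windows returns exactly 480-sample half-open segments", {
  ep <- trial_epochs(array(rnorm(2 * 1680 * 3), c(2, 1680, 3)), fs,
                     onset = -1.5)
  w <- condition_windows()
  seg <- extract_windows(ep, w)
  expect_equal(dim(seg$baseline)[2], 480L)
  expect_equal(dim(seg$cue)[2], 480L)
  onset_idx <- which.min(abs(ep$time))  # sample at t = 0
  expect_equal(seg$indices$cue - onset_idx, 240:719)
  expect_equal(seg$indices$baseline - onset_idx, -480:-1)
  short <- trial_epochs(array(rnorm(2 * 200), c(2, 200, 1)), fs, onset = -0.2)
  expect_error(extract_windows(short, w), "too short")
})

test_that("windows must be equal length and well formed", {
  expect_error(condition_windows(baseline = c(0, 1), cue = c(0.5, 2)),
               "equal duration")
  expect_error(condition_windows(baseline = c(1, 0)), "t1 > t0")
})
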