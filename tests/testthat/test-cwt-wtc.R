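fs <- 7.81

test_that("CWT localizes, scales linearly, and vanishes on zero input", {
  t <- seq(0, by = 1 / fs, length.out = 1500)
  f0 <- 0.1
  x <- sin(2 * pi * f0 * t)
  w <- cwt_morlet(x, fs)
  peak <- w$freq[which.max(rowMeans(Mod(w$coef)^2))]
  # nearest-bin localization: within one bin spacing of f0
  expect_lt(abs(log2(peak / f0)), 1.01 / w$plan$voices)

  w0 <- cwt_morlet(rep(0, 300), fs)
  expect_true(all(Mod(w0$coef) == 0))

  wk <- cwt_morlet(3.5 * x, fs)
  expect_equal(Mod(wk$coef), 3.5 * Mod(w$coef), tolerance = 1e-10)
})

test_that("bands at or beyond Nyquist are rejected", {
  expect_error(cwt_plan(256, fs, f_range = c(0.01, 4)), "Nyquist")
  expect_error(cwt_plan(256, fs, f_range = c(0.1, 0.05)))
  expect_error(wtc(rnorm(100), rnorm(101), fs), "lengths differ")
})

test_that("self-coherence is 1 inside the COI and WTC is symmetric", {
  set.seed(42)
  x <- as.numeric(arima.sim(list(ar = 0.8), 1200))
  y <- rnorm(1200)
  w <- wtc(x, x, fs)
  expect_lt(max(abs(w$R2[w$coi_ok] - 1), na.rm = TRUE), 1e-3)

  wxy <- wtc(x, y, fs)
  wyx <- wtc(y, x, fs)
  expect_equal(wxy$R2, wyx$R2, tolerance = 1e-6)
  expect_true(all(wxy$R2 >= 0 & wxy$R2 <= 1, na.rm = TRUE))
})

test_that("FFT-based WTC matches the explicit-convolution oracle", {
  set.seed(7)
  n <- 192
  plan <- cwt_plan(n, fs = 2, voices = 4, f_range = c(0.05, 0.35))
  x <- sin(2 * pi * 0.12 * (1:n) / 2) + rnorm(n, sd = 0.4)
  y <- 0.6 * x + rnorm(n, sd = 0.6)

  W_fft <- dyadsync:::cwt_apply(x, plan)[seq_len(n), ]
  W_brute <- brute_cwt(x, plan)[seq_len(n), ]
  expect_lt(max(Mod(W_fft - W_brute)), 1e-6)

  R2_fft <- dyadsync:::wtc_from_spectra(
    dyadsync:::cwt_apply(x, plan), dyadsync:::cwt_apply(y, plan),
    dyadsync:::auto_spectrum(dyadsync:::cwt_apply(x, plan), plan),
    dyadsync:::auto_spectrum(dyadsync:::cwt_apply(y, plan), plan), plan)
  R2_brute <- brute_wtc(x, y, plan)
  expect_lt(max(abs(R2_fft - R2_brute), na.rm = TRUE), 1e-6)
})

test_that("prescaled and plain spectrum paths agree", {
  set.seed(8)
  n <- 300
  plan <- cwt_plan(n, fs, voices = 6)
  x <- rnorm(n); y <- rnorm(n)
  Wx <- dyadsync:::cwt_apply(x, plan); Wy <- dyadsync:::cwt_apply(y, plan)
  Wxs <- dyadsync:::cwt_apply(x, plan, prescaled = TRUE)
  Wys <- dyadsync:::cwt_apply(y, plan, prescaled = TRUE)
  a <- dyadsync:::wtc_from_spectra(Wx, Wy,
                                   dyadsync:::auto_spectrum(Wx, plan),
                                   dyadsync:::auto_spectrum(Wy, plan), plan)
  b <- dyadsync:::wtc_from_spectra(Wxs, Wys,
                                   dyadsync:::auto_spectrum(Wxs, plan, TRUE),
                                   dyadsync:::auto_spectrum(Wys, plan, TRUE),
                                   plan, prescaled = TRUE)
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("independent noise has low coherence; a delayed copy stays coherent", {
  set.seed(21)
  n <- 1200
  x <- rnorm(n)
  real <- mean(wtc(x, rnorm(n), fs)$R2[wtc(x, x, fs)$coi_ok], na.rm = TRUE)
  nulls <- replicate(12, {
    w <- wtc(x, rnorm(n), fs)
    mean(w$R2[w$coi_ok], na.rm = TRUE)
  })
  expect_lt(real, quantile(nulls, 0.95) + 0.05)

  # quarter-period lag at 0.1 Hz: phase shift must not destroy coherence
  t <- seq(0, by = 1 / fs, length.out = n)
  s <- sin(2 * pi * 0.1 * t) + 0.2 * rnorm(n)
  lag <- round(2.5 * fs)   # 2.5 s = quarter period
  y <- c(rep(0, lag), s[1:(n - lag)]) + 0.2 * rnorm(n)
  w <- wtc(s, y, fs)
  band <- which(abs(log2(w$freq / 0.1)) < 0.25)
  val <- mean(w$R2[band, ][w$coi_ok[band, ]], na.rm = TRUE)
  expect_gt(val, 0.8)
})

test_that("time_average respects window, COI, and degenerate cases", {
  set.seed(3)
  x <- rnorm(800)
  w <- wtc(x, x, fs)
  s <- time_average(w)
  expect_s3_class(s, "wtc_spectrum")
  ok <- !is.na(s$value)
  expect_true(any(ok))
  expect_equal(unname(s$value[ok]), rep(1, sum(ok)), tolerance = 1e-6)
  # bins whose scales never fit the COI are missing, not fabricated
  expect_true(all(s$n_valid[is.na(s$value)] == 0))

  expect_error(time_average(w, c(500, 600)), "empty task window")
  expect_warning(time_average(w, c(0, 0.3)), "cone of influence")
})

test_that("windows discriminate a half-coupled recording", {
  set.seed(9)
  n <- 2400
  half <- n / 2
  shared <- dyadsync:::band_noise(n, fs, 0.05, 0.1)
  nx <- dyadsync:::band_noise(n, fs, 0.05, 0.1)
  ny <- dyadsync:::band_noise(n, fs, 0.05, 0.1)
  # coupled in the first half only
  mix <- c(rep(1, half), rep(0, n - half))
  x <- mix * shared + (1 - mix) * nx + 0.3 * rnorm(n)
  y <- mix * shared + (1 - mix) * ny + 0.3 * rnorm(n)
  w <- wtc(x, y, fs)
  band <- abs(log2(w$freq / 0.075)) < 0.5
  dur <- n / fs
  s1 <- time_average(w, c(0, dur / 2))
  s2 <- time_average(w, c(dur / 2, dur))
  expect_gt(mean(s1$value[band], na.rm = TRUE),
            mean(s2$value[band], na.rm = TRUE))
})
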