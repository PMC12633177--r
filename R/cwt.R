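#' Plan a Morlet continuous wavelet transform
#'
#' Precomputes the scale grid, padded length, wavelet and smoothing kernel
#' spectra, and the cone-of-influence mask for series of a given length.
#' Reusing a plan across channels and dyads avoids recomputing kernels, which
#' dominates the cost of cohort-level coherence analyses.
#'
#' Scales are spaced geometrically with `voices` scales per octave, covering
#' `f_range` (Hz) from high to low frequency. The analytic Morlet wavelet
#' \eqn{\psi_0(\eta) = \pi^{-1/4} e^{i\omega_0\eta} e^{-\eta^2/2}} is sampled
#' in the time domain over the padded circular grid; the transform is then a
#' circular cross-correlation of the zero-padded, demeaned signal with the
#' scaled wavelet. Frequencies are related to scales through the standard
#' Morlet Fourier factor \eqn{(\omega_0 + \sqrt{2+\omega_0^2})/(4\pi)}.
#'
#' @param n series length in samples.
#' @param fs sampling rate in Hz.
#' @param omega0 Morlet center frequency parameter (dimensionless).
#' @param voices scales per octave.
#' @param f_range numeric length-2, analysis band in Hz (low, high). The high
#'   edge must lie below the Nyquist frequency.
#' @param scale_smooth_octaves width (in octaves) of the boxcar used to smooth
#'   spectra across scales when forming coherence.
#' @param trim_coi drop scales so slow that no time point of an `n`-sample
#'   recording lies inside their cone of influence (their bins could only
#'   ever be missing). Useful for cohort-scale batch analyses; the default
#'   keeps the full grid so unusable bins are reported as `NA`.
#' @return an object of class `cwt_plan`.
#' @export
cwt_plan <- function(n, fs, omega0 = 6, voices = 12, f_range = c(0.01, 0.7),
                     scale_smooth_octaves = 0.6, trim_coi = FALSE) {
  stopifnot(length(n) == 1L, n >= 8L, length(fs) == 1L, fs > 0)
  f_lo <- f_range[1]; f_hi <- f_range[2]
  if (!(f_lo > 0 && f_hi > f_lo))
    stop("f_range must satisfy 0 < low < high")
  if (f_hi >= fs / 2)
    stop(sprintf("requested band edge %.4g Hz is at or beyond Nyquist (%.4g Hz)",
                 f_hi, fs / 2))
  dt <- 1 / fs
  ff <- (omega0 + sqrt(2 + omega0^2)) / (4 * pi)  # freq = ff / scale
  n_oct <- log2(f_hi / f_lo)
  j <- 0:floor(voices * n_oct + 1e-9)
  freq <- f_hi * 2^(-j / voices)
  scale <- ff / freq                               # seconds, increasing
  if (trim_coi) {
    # estimability rule: beyond the cone of influence (sqrt(2)*s from each
    # edge), the usable span must still cover at least two scales, so the
    # time average holds more than one effectively independent coherence
    # sample; shorter-span bins have ill-behaved sampling distributions
    dt0 <- 1 / fs
    usable <- (n - 1) * dt0 - 2 * sqrt(2) * scale >= 2 * scale
    if (!any(usable)) stop("no scale has a usable span inside the cone of influence")
    freq <- freq[usable]
    scale <- scale[usable]
  }
  npad <- 2^ceiling(log2(n))

  # circular offsets, tau = 0 at index 1
  m <- 0:(npad - 1)
  off <- ifelse(m <= npad / 2, m, m - npad) * dt   # seconds

  ns <- length(scale)
  wfft <- matrix(0 + 0i, npad, ns)
  sfft <- matrix(0 + 0i, npad, ns)
  for (k in seq_len(ns)) {
    s <- scale[k]
    eta <- off / s
    psi <- pi^(-0.25) * exp(1i * omega0 * eta - eta^2 / 2) * sqrt(dt / s)
    wfft[, k] <- Conj(stats::fft(psi))
    g <- exp(-0.5 * (off / s)^2)
    g <- g / sum(g)
    sfft[, k] <- stats::fft(g)
  }

  # boxcar smoothing across scales, renormalised at the edges
  L <- max(1L, as.integer(round(scale_smooth_octaves * voices)))
  half <- L %/% 2L
  B <- matrix(0, ns, ns)
  for (i in seq_len(ns)) {
    win <- max(1L, i - half):min(ns, i + half)
    B[win, i] <- 1 / length(win)
  }

  # cone of influence: e-folding time sqrt(2) * scale from either edge
  t_edge <- pmin(seq_len(n) - 1L, n - seq_len(n)) * dt
  coi_ok <- outer(t_edge, sqrt(2) * scale, `>=`)   # n x ns logical

  structure(list(n = n, npad = npad, fs = fs, dt = dt, omega0 = omega0,
                 voices = voices, freq = freq, scale = scale, ns = ns,
                 wfft = wfft, sfft = sfft, B = B, coi_ok = coi_ok,
                 coi_scale_max = t_edge / sqrt(2),
                 scale_smooth_octaves = scale_smooth_octaves),
            class = "cwt_plan")
}

#' @export
print.cwt_plan <- function(x, ...) {
  cat(sprintf("Morlet CWT plan: n=%d (pad %d), fs=%.4g Hz, %d scales (%g/octave), %.4g-%.4g Hz\n",
              x$n, x$npad, x$fs, x$ns, x$voices, min(x$freq), max(x$freq)))
  invisible(x)
}

# padded transform, npad x ns complex; x is demeaned then zero-padded.
# prescaled = TRUE folds the 1/sqrt(scale) coherence normalisation into the
# coefficients so later smoothing steps need no per-scale division.
cwt_apply <- function(x, plan, prescaled = FALSE) {
  stopifnot(length(x) == plan$n, all(is.finite(x)))
  xp <- c(x - mean(x), rep(0, plan$npad - plan$n))
  Xf <- stats::fft(xp)
  M <- Xf * plan$wfft
  if (prescaled) M <- M * rep(1 / sqrt(plan$scale), each = plan$npad)
  stats::mvfft(M, inverse = TRUE) / plan$npad
}

# circular time smoothing with the plan's scale-dependent Gaussian kernels
smooth_time <- function(M, plan) {
  stats::mvfft(stats::mvfft(M) * plan$sfft, inverse = TRUE) / plan$npad
}

smooth_scale <- function(M, plan) M %*% plan$B

# smoothed, scale-normalised spectrum: S( M / s ) in time then scale.
# M built from prescaled transforms already carries the 1/s factor.
smooth_spectrum <- function(M, plan, prescaled = FALSE) {
  if (!prescaled) M <- M * rep(1 / plan$scale, each = plan$npad)
  smooth_scale(smooth_time(M, plan), plan)
}

# smoothed autospectrum of a padded transform (real matrix)
auto_spectrum <- function(W, plan, prescaled = FALSE) {
  Re(smooth_spectrum(Mod(W)^2, plan, prescaled = prescaled))
}

#' Continuous wavelet transform with an analytic Morlet wavelet
#'
#' @param x numeric time series, uniformly sampled.
#' @param fs sampling rate in Hz.
#' @param plan optional precomputed [cwt_plan()]; when supplied, `fs` and the
#'   other parameters are taken from it.
#' @inheritParams cwt_plan
#' @return object of class `cwt`: complex coefficients (`coef`, frequency x
#'   time), the frequency and scale grids, the cone-of-influence maximum
#'   period per time point, and the plan used.
#' @examples
#' x <- sin(2 * pi * 0.1 * seq(0, 120, by = 1 / 7.81))
#' w <- cwt_morlet(x, fs = 7.81)
#' w$freq[which.max(rowMeans(Mod(w$coef)^2))]  # ~0.1 Hz
#' @export
cwt_morlet <- function(x, fs, omega0 = 6, voices = 12, f_range = c(0.01, 0.7),
                       plan = NULL) {
  if (is.null(plan))
    plan <- cwt_plan(length(x), fs, omega0 = omega0, voices = voices,
                     f_range = f_range)
  W <- cwt_apply(x, plan)
  structure(list(coef = t(W[seq_len(plan$n), , drop = FALSE]),
                 freq = plan$freq, scale = plan$scale,
                 coi_ok = t(plan$coi_ok), plan = plan, Wpad = W),
            class = "cwt")
}

#' @export
print.cwt <- function(x, ...) {
  cat(sprintf("Morlet CWT: %d scales x %d samples, %.4g-%.4g Hz\n",
              length(x$freq), ncol(x$coef), min(x$freq), max(x$freq)))
  invisible(x)
}

#' Wavelet transform coherence between two signals
#'
#' Squared, smoothed cross-spectrum over the product of smoothed
#' auto-spectra, following the standard formulation for Morlet wavelet
#' coherence: smoothing in time with a Gaussian of standard deviation equal
#' to the scale, and across scales with a boxcar of fixed octave width; all
#' spectra are normalised by scale before smoothing. Values are clipped to
#' [0, 1]. Cells where the smoothed auto-spectra underflow are set to `NA`.
#'
#' @param x,y equal-length numeric series recorded at the same rate (one per
#'   subject of the dyad).
#' @inheritParams cwt_morlet
#' @return object of class `wtc`: coherence matrix (`R2`, frequency x time),
#'   frequency grid, logical cone-of-influence mask (`coi_ok`, TRUE inside
#'   the cone), sampling rate and plan.
#' @examples
#' t <- seq(0, 200, by = 1 / 7.81)
#' x <- sin(2 * pi * 0.1 * t) + rnorm(length(t), sd = 0.3)
#' w <- wtc(x, x, fs = 7.81)
#' all(abs(w$R2[w$coi_ok] - 1) < 1e-6)
#' @export
wtc <- function(x, y, fs, omega0 = 6, voices = 12, f_range = c(0.01, 0.7),
                plan = NULL) {
  if (length(x) != length(y))
    stop(sprintf("series lengths differ: %d vs %d", length(x), length(y)))
  if (is.null(plan))
    plan <- cwt_plan(length(x), fs, omega0 = omega0, voices = voices,
                     f_range = f_range)
  Wx <- cwt_apply(x, plan, prescaled = TRUE)
  Wy <- cwt_apply(y, plan, prescaled = TRUE)
  Sxx <- auto_spectrum(Wx, plan, prescaled = TRUE)
  Syy <- auto_spectrum(Wy, plan, prescaled = TRUE)
  R2 <- wtc_from_spectra(Wx, Wy, Sxx, Syy, plan, prescaled = TRUE)
  structure(list(R2 = t(R2), freq = plan$freq, scale = plan$scale,
                 coi_ok = t(plan$coi_ok), fs = plan$fs, plan = plan),
            class = "wtc")
}

# coherence matrix (n x ns) from padded transforms and smoothed autospectra
wtc_from_spectra <- function(Wx, Wy, Sxx, Syy, plan, prescaled = FALSE) {
  Sxy <- smooth_spectrum(Wx * Conj(Wy), plan, prescaled = prescaled)
  den <- Sxx * Syy
  R2 <- Mod(Sxy)^2 / den
  R2[den < .Machine$double.eps] <- NA_real_
  R2 <- pmin(pmax(R2, 0), 1)
  matrix(R2, plan$npad, plan$ns)[seq_len(plan$n), , drop = FALSE]
}

#' @export
print.wtc <- function(x, ...) {
  cat(sprintf("WTC matrix: %d frequency bins x %d samples, %.4g-%.4g Hz\n",
              length(x$freq), ncol(x$R2), min(x$freq), max(x$freq)))
  inside <- x$R2[x$coi_ok]
  cat(sprintf("  mean in-COI coherence: %.3f\n", mean(inside, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.wtc <- function(x, ...) {
  z <- x$R2
  z[!x$coi_ok] <- NA
  tt <- seq_len(ncol(z)) / x$fs
  graphics::image(tt, rev(seq_along(x$freq)), t(z[rev(seq_len(nrow(z))), ]),
                  xlab = "time (s)", ylab = "frequency bin (low to high)",
                  main = "wavelet transform coherence", zlim = c(0, 1), ...)
  invisible(x)
}

#' Time-average a coherence matrix over a task window
#'
#' Averages coherence per frequency bin across the time samples that fall
#' both inside the task window and inside the cone of influence. Bins with no
#' valid cell are returned as `NA`.
#'
#' @param w a `wtc` object.
#' @param window numeric length-2, task window in seconds from recording
#'   start, half-open `[start, end)`. `NULL` averages the whole recording.
#' @return object of class `wtc_spectrum`: per-bin mean coherence (`value`),
#'   frequency grid, and the number of valid cells per bin.
#' @export
time_average <- function(w, window = NULL) {
  stopifnot(inherits(w, "wtc"))
  n <- ncol(w$R2)
  tt <- (seq_len(n) - 1L) / w$fs
  keep <- if (is.null(window)) rep(TRUE, n) else (tt >= window[1] & tt < window[2])
  if (!any(keep)) stop("empty task window: no samples in [start, end)")
  ok <- w$coi_ok & matrix(keep, nrow(w$R2), n, byrow = TRUE)
  num <- rowSums(ok)
  val <- ifelse(num > 0, rowSums(w$R2 * ok, na.rm = TRUE) / pmax(num, 1L),
                NA_real_)
  if (all(num == 0))
    warning("window entirely outside the cone of influence; all bins missing")
  structure(list(value = val, freq = w$freq, n_valid = num),
            class = "wtc_spectrum")
}

#' @export
print.wtc_spectrum <- function(x, ...) {
  ok <- !is.na(x$value)
  cat(sprintf("WTC spectrum: %d bins (%d valid), mean coherence %.3f\n",
              length(x$value), sum(ok), mean(x$value[ok])))
  invisible(x)
}

# fast per-bin spectrum for a channel pairing, reusing padded transforms and
# smoothed autospectra; win_keep is a logical over the n unpadded samples
pair_bin_means <- function(Wx, Wy, Sxx, Syy, plan, win_keep = NULL,
                           prescaled = TRUE) {
  R2 <- wtc_from_spectra(Wx, Wy, Sxx, Syy, plan, prescaled = prescaled)
  ok <- plan$coi_ok
  if (!is.null(win_keep)) ok <- ok & win_keep
  num <- colSums(ok)
  val <- colSums(R2 * ok, na.rm = TRUE) / pmax(num, 1L)
  val[num == 0] <- NA_real_
  val
}
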