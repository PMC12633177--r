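# Channel QC and signal-correction chain: CV filter -> optical density ->
# TDDR -> wavelet filter -> SCI filter -> modified Beer-Lambert ->
# short-separation regression. The order is fixed; preprocess_dyad()
# enforces it.

#' Coefficient of variation of raw intensity
#'
#' Population standard deviation over mean, per wavelength; the channel
#' value is the maximum across wavelengths. Raw intensity must be strictly
#' positive, so a zero mean is rejected.
#'
#' @param x numeric vector (one wavelength) or n x 2 matrix (both).
#' @return the CV (scalar).
#' @examples
#' compute_cv(c(90, 110))  # population SD 10 / mean 100 = 0.1
#' @export
compute_cv <- function(x) {
  x <- as.matrix(x)
  cv1 <- function(v) {
    m <- mean(v)
    if (abs(m) < .Machine$double.eps)
      stop("zero-mean intensity: CV undefined (intensity must be positive)")
    n <- length(v)
    sqrt(sum((v - m)^2) / n) / m
  }
  max(apply(x, 2L, cv1))
}

#' Exclude channels by coefficient of variation
#'
#' Drops every channel of either subject whose raw-intensity CV exceeds the
#' threshold and reports each exclusion.
#'
#' @param rec a `dyad_recording`.
#' @param threshold CV cutoff (channels with CV strictly above are removed).
#' @return list with the filtered `recording` and a `report` data frame
#'   (subject, channel, cv, pass, reason).
#' @export
filter_channels_cv <- function(rec, threshold = 0.1) {
  stopifnot(inherits(rec, "dyad_recording"))
  report <- list()
  for (s in 1:2) {
    ints <- rec$subjects[[s]]$intensity
    cv <- vapply(seq_len(ncol(ints)),
                 function(ch) compute_cv(ints[, ch, ]), numeric(1))
    pass <- cv <= threshold
    report[[s]] <- data.frame(subject = s,
                              channel = rec$subjects[[s]]$channels$channel,
                              cv = cv, pass = pass,
                              reason = ifelse(pass, "", "cv"))
    rec$subjects[[s]]$intensity <- ints[, pass, , drop = FALSE]
    rec$subjects[[s]]$channels <- rec$subjects[[s]]$channels[pass, , drop = FALSE]
  }
  if (any(vapply(rec$subjects, function(su) nrow(su$channels) == 0, logical(1))))
    stop("no usable channels: all channels of a subject exceeded the CV threshold")
  list(recording = rec, report = do.call(rbind, report))
}

#' Convert raw intensity to optical density
#'
#' `dOD(t) = -log(I(t) / ref)` with the reference chosen as the geometric
#' temporal mean of the intensity, so the converted series has exactly zero
#' mean and the conversion inverts the generator's
#' `I = baseline * exp(-dOD)` intensity model up to an additive constant.
#'
#' @param x strictly positive numeric vector, or matrix with channels /
#'   wavelengths in columns.
#' @return optical density with the same shape as `x`.
#' @export
intensity_to_od <- function(x) {
  if (is.matrix(x)) {
    bad <- which(x <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("non-positive intensity at sample %d, column %d",
                   bad[1, 1], bad[1, 2]))
    lx <- -log(x)
    return(sweep(lx, 2L, colMeans(lx)))
  }
  if (any(x <= 0))
    stop(sprintf("non-positive intensity at sample %d", which(x <= 0)[1]))
  lx <- -log(x)
  lx - mean(lx)
}

#' Scalp coupling index
#'
#' Band-passes both wavelength series of one channel to the cardiac band and
#' returns their zero-lag Pearson correlation. Good optode-scalp contact
#' shows the cardiac pulsation coherently at both wavelengths (SCI near 1).
#'
#' @param od n x 2 matrix of optical density (columns = wavelengths).
#' @param fs sampling rate in Hz.
#' @param band cardiac band in Hz.
#' @return SCI in `[-1, 1]`, or `NA` if a filtered series is constant.
#' @export
compute_sci <- function(od, fs, band = c(0.5, 2.5)) {
  od <- as.matrix(od)
  stopifnot(ncol(od) == 2L)
  if (stats::sd(od[, 1]) < .Machine$double.eps ||
      stats::sd(od[, 2]) < .Machine$double.eps)
    return(NA_real_)                        # constant series: SCI undefined
  hi <- min(band[2], 0.95 * fs / 2)
  bf <- signal::butter(3, c(band[1], hi) * 2 / fs, type = "pass")
  f1 <- signal::filtfilt(bf, od[, 1])
  f2 <- signal::filtfilt(bf, od[, 2])
  tol <- 1e-10 * (stats::sd(od[, 1]) + stats::sd(od[, 2]))
  if (stats::sd(f1) < tol || stats::sd(f2) < tol)
    return(NA_real_)                        # nothing left in the cardiac band
  stats::cor(f1, f2)
}

#' Modified Beer-Lambert conversion to hemoglobin concentrations
#'
#' Solves, per time point, the 2x2 linear system
#' `dOD_lambda = (eps_HbO,lambda * dHbO + eps_HbR,lambda * dHbR) * d * DPF_lambda`
#' for the two chromophores, given extinction coefficients at both
#' wavelengths, the source-detector distance, and the differential
#' pathlength factor.
#'
#' @param od n x 2 matrix of optical density, columns named "760" and "850".
#' @param distance source-detector distance in cm.
#' @param dpf differential pathlength factor per wavelength.
#' @param ext 2 x 2 extinction matrix (rows = wavelengths, cols = HbO/HbR)
#'   in 1/(cm M).
#' @return n x 2 matrix with columns `HbO`, `HbR` in micromolar.
#' @export
beer_lambert <- function(od, distance = 3, dpf = c(`760` = 6, `850` = 6),
                         ext = extinction_defaults()) {
  od <- as.matrix(od)
  stopifnot(ncol(od) == 2L)
  A <- ext * distance * as.numeric(dpf)      # row-wise DPF scaling
  if (abs(det(A)) < 1e-12 * prod(abs(A[, 1]) + abs(A[, 2])))
    stop("singular extinction matrix: wavelength rows are proportional")
  conc <- t(solve(A, t(od))) * 1e6           # M -> uM
  colnames(conc) <- c("HbO", "HbR")
  conc
}

#' Short-separation regression of superficial signals
#'
#' Ordinary least squares of a long-channel hemodynamic series on one or
#' more short-separation regressors (plus intercept); the residual — the
#' component unexplained by superficial physiology — is returned. The
#' residual is orthogonal to every regressor by construction.
#'
#' @param long numeric vector, long-channel series (one chromophore).
#' @param shorts numeric vector or matrix of short-channel regressors; when
#'   `NULL` or empty the input is returned unchanged with a warning.
#' @return residual series (zero mean).
#' @export
short_separation_regression <- function(long, shorts) {
  if (is.null(shorts) || NCOL(shorts) == 0L || NROW(shorts) == 0L) {
    warning("no surviving short channels: returning long channel unregressed")
    return(long - mean(long))
  }
  shorts <- as.matrix(shorts)
  stopifnot(nrow(shorts) == length(long))
  stats::lm.fit(cbind(1, shorts), long)$residuals
}

#' Run the full preprocessing chain on a dyadic recording
#'
#' Applies, in fixed order: CV-based channel exclusion on raw intensity,
#' optical-density conversion, TDDR, wavelet filtering, SCI-based channel
#' exclusion, the modified Beer-Lambert law, and short-separation regression
#' of each long channel on the subject's surviving short channels. All
#' corrections are per channel and never mix subjects.
#'
#' @param rec a `dyad_recording`.
#' @param cv_threshold CV exclusion cutoff.
#' @param sci_threshold SCI exclusion cutoff (channels strictly below fail).
#' @param sci_band cardiac band (Hz) for the SCI.
#' @param tddr_split_hz passed to [tddr()].
#' @param wavelet_k passed to [wavelet_filter()].
#' @return object of class `dyad_hemo`: per subject, HbO and HbR matrices
#'   (time x surviving long channels) after superficial regression, the
#'   surviving channel tables, and the combined `qc` report.
#' @export
preprocess_dyad <- function(rec, cv_threshold = 0.1, sci_threshold = 0.8,
                            sci_band = c(0.5, 2.5), tddr_split_hz = NULL,
                            wavelet_k = 4) {
  stopifnot(inherits(rec, "dyad_recording"))
  cvf <- filter_channels_cv(rec, cv_threshold)
  rec <- cvf$recording
  qc <- cvf$report

  out <- vector("list", 2L)
  for (s in 1:2) {
    ints <- rec$subjects[[s]]$intensity
    chans <- rec$subjects[[s]]$channels
    nch <- nrow(chans)
    od <- array(NA_real_, dim = dim(ints), dimnames = dimnames(ints))
    sci <- numeric(nch)
    for (ch in seq_len(nch)) {
      for (w in 1:2) {
        o <- intensity_to_od(ints[, ch, w])
        o <- tddr(o, rec$fs, split_hz = tddr_split_hz)
        od[, ch, w] <- wavelet_filter(o, k = wavelet_k)
      }
      v <- compute_sci(od[, ch, ], rec$fs, band = sci_band)
      sci[ch] <- if (is.na(v)) -Inf else v
    }
    pass <- sci >= sci_threshold
    qc <- rbind(qc, data.frame(subject = s, channel = chans$channel,
                               cv = NA_real_, pass = pass,
                               reason = ifelse(pass, "", "sci")))
    if (!any(pass & chans$type == "long"))
      stop(sprintf("no usable long channels for subject %d after SCI filter", s))

    keep <- which(pass)
    chans_k <- chans[keep, , drop = FALSE]
    hbo <- matrix(NA_real_, nrow(od), length(keep))
    hbr <- matrix(NA_real_, nrow(od), length(keep))
    geom <- geometry_defaults()
    for (i in seq_along(keep)) {
      dist <- if (chans_k$type[i] == "long") geom$distance_long else geom$distance_short
      conc <- beer_lambert(od[, keep[i], ], distance = dist, dpf = geom$dpf)
      hbo[, i] <- conc[, "HbO"]
      hbr[, i] <- conc[, "HbR"]
    }

    is_long <- chans_k$type == "long"
    shorts_hbo <- hbo[, !is_long, drop = FALSE]
    shorts_hbr <- hbr[, !is_long, drop = FALSE]
    long_idx <- which(is_long)
    hbo_l <- matrix(NA_real_, nrow(hbo), length(long_idx))
    hbr_l <- matrix(NA_real_, nrow(hbo), length(long_idx))
    no_shorts <- ncol(shorts_hbo) == 0L
    if (no_shorts)
      warning(sprintf("subject %d: no surviving short channels; skipping superficial regression", s))
    for (i in seq_along(long_idx)) {
      if (no_shorts) {
        hbo_l[, i] <- hbo[, long_idx[i]] - mean(hbo[, long_idx[i]])
        hbr_l[, i] <- hbr[, long_idx[i]] - mean(hbr[, long_idx[i]])
      } else {
        hbo_l[, i] <- short_separation_regression(hbo[, long_idx[i]], shorts_hbo)
        hbr_l[, i] <- short_separation_regression(hbr[, long_idx[i]], shorts_hbr)
      }
    }
    out[[s]] <- list(HbO = hbo_l, HbR = hbr_l,
                     channels = chans_k[is_long, , drop = FALSE],
                     sci = sci)
  }

  structure(list(subjects = out, fs = rec$fs, n = rec$n,
                 annotations = rec$annotations, qc = qc),
            class = "dyad_hemo")
}

#' @export
print.dyad_hemo <- function(x, ...) {
  cat(sprintf("dyad_hemo: %d / %d surviving long channels (subjects 1 / 2), %d samples @ %.4g Hz\n",
              ncol(x$subjects[[1]]$HbO), ncol(x$subjects[[2]]$HbO), x$n, x$fs))
  excl <- x$qc[!x$qc$pass, ]
  cat(sprintf("  %d channel exclusions (%s)\n", nrow(excl),
              if (nrow(excl)) paste(unique(excl$reason), collapse = ", ") else "none"))
  invisible(x)
}
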