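# Periodic Daubechies-4 (D4, two vanishing moments) discrete wavelet
# transform. Implemented here because the motion-artifact wavelet filter
# needs only this one orthonormal filter bank.

d4_filters <- function() {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  g <- c(h[4], -h[3], h[2], -h[1])
  list(h = h, g = g)
}

# one level of periodic analysis: x (even length) -> list(a, d)
dwt_step <- function(x) {
  f <- d4_filters()
  N <- length(x)
  idx <- outer(seq(0, N - 2L, by = 2L), 0:3, `+`) %% N + 1L  # N/2 x 4
  xm <- matrix(x[idx], nrow = N / 2L)
  list(a = as.numeric(xm %*% f$h), d = as.numeric(xm %*% f$g))
}

# inverse of dwt_step
idwt_step <- function(a, d) {
  f <- d4_filters()
  N <- 2L * length(a)
  x <- numeric(N)
  pos <- outer(seq(0, N - 2L, by = 2L), 0:3, `+`) %% N + 1L
  contrib <- outer(a, f$h) + outer(d, f$g)        # N/2 x 4
  for (m in 1:4) {
    at <- pos[, m]
    x[at] <- x[at] + contrib[, m]
  }
  x
}

# multi-level periodic D4 decomposition; length(x) must be divisible by 2^J
dwt_d4 <- function(x, J) {
  stopifnot(length(x) %% 2^J == 0)
  details <- vector("list", J)
  a <- x
  for (j in seq_len(J)) {
    st <- dwt_step(a)
    details[[j]] <- st$d
    a <- st$a
  }
  list(a = a, d = details)
}

idwt_d4 <- function(dec) {
  a <- dec$a
  for (j in rev(seq_along(dec$d))) a <- idwt_step(a, dec$d[[j]])
  a
}

#' Wavelet-based motion-artifact filter
#'
#' Decomposes an optical-density series with a periodic Daubechies-4
#' discrete wavelet transform and zeroes detail coefficients that are
#' outliers within their own level: coefficients with magnitude above
#' `k * IQR / 1.349` (a robust estimate of `k` standard deviations under a
#' Gaussian bulk) are set to zero before reconstruction. Spikes and steps
#' concentrate in a few large coefficients per level while the hemodynamic
#' signal spreads across many moderate ones, so thresholding attenuates
#' artifacts with little effect on clean signal. Because the transform is
#' orthonormal and coefficients are only zeroed, signal energy never
#' increases.
#'
#' Series whose length is not a multiple of `2^levels` are reflection-padded
#' before the transform and cropped afterwards.
#'
#' @param x numeric series.
#' @param k robust threshold multiplier (in Gaussian-equivalent standard
#'   deviations).
#' @param levels decomposition depth; default `min(6, floor(log2(n)) - 3)`.
#' @return filtered series, same length as `x`.
#' @export
wavelet_filter <- function(x, k = 4, levels = NULL) {
  n <- length(x)
  if (is.null(levels)) levels <- max(1L, min(6L, floor(log2(n)) - 3L))
  if (n < 2^levels * 2L)
    stop(sprintf("series too short (%d samples) for %d decomposition levels",
                 n, levels))
  block <- 2^levels
  m <- ceiling(n / block) * block
  xp <- if (m > n) c(x, rev(x)[seq_len(m - n)]) else x

  dec <- dwt_d4(xp, levels)
  for (j in seq_along(dec$d)) {
    d <- dec$d[[j]]
    tau <- k * stats::IQR(d) / 1.349
    d[abs(d) > tau] <- 0
    dec$d[[j]] <- d
  }
  idwt_d4(dec)[seq_len(n)]
}
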