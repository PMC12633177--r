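# Brute-force oracles, independent of the package's FFT-based paths:
# wavelet transforms and smoothing as explicit convolution sums, BH as the
# literal step-up rule, Kendall tau as O(n^2) pair counting.

# circular offset of index m (0-based) on a ring of length npad, mapped to
# [-npad/2, npad/2)
circ_offset <- function(m, npad) ifelse(m <= npad / 2, m, m - npad)

# direct Morlet CWT: W(s, t) = sum_t' x(t') sqrt(dt/s) conj(psi0((t'-t) dt/s))
# over the zero-padded circular grid (explicit sums, no FFT)
brute_cwt <- function(x, plan) {
  n <- plan$n; npad <- plan$npad; dt <- plan$dt
  xp <- c(x - mean(x), rep(0, npad - n))
  W <- matrix(0 + 0i, npad, plan$ns)
  for (k in seq_len(plan$ns)) {
    s <- plan$scale[k]
    for (t in 0:(npad - 1)) {
      off <- circ_offset((0:(npad - 1) - t) %% npad, npad)
      eta <- off * dt / s
      psi <- pi^(-0.25) * exp(1i * plan$omega0 * eta - eta^2 / 2)
      W[t + 1, k] <- sum(xp * Conj(psi)) * sqrt(dt / s)
    }
  }
  W
}

# direct circular convolution with the normalised Gaussian time-smoothing
# kernel of each scale, then the boxcar across scales
brute_smooth <- function(M, plan) {
  npad <- plan$npad; dt <- plan$dt
  out <- M
  for (k in seq_len(plan$ns)) {
    s <- plan$scale[k]
    off <- circ_offset(0:(npad - 1), npad) * dt
    g <- exp(-0.5 * (off / s)^2)
    g <- g / sum(g)
    col <- M[, k]
    sm <- complex(npad)
    for (t in 0:(npad - 1)) {
      idx <- ((t - (0:(npad - 1))) %% npad) + 1
      sm[t + 1] <- sum(col[idx] * g)
    }
    out[, k] <- sm
  }
  out %*% plan$B
}

brute_wtc <- function(x, y, plan) {
  Wx <- brute_cwt(x, plan)
  Wy <- brute_cwt(y, plan)
  sdiv <- function(M) M * rep(1 / plan$scale, each = plan$npad)
  Sxx <- Re(brute_smooth(sdiv(Mod(Wx)^2 + 0i), plan))
  Syy <- Re(brute_smooth(sdiv(Mod(Wy)^2 + 0i), plan))
  Sxy <- brute_smooth(sdiv(Wx * Conj(Wy)), plan)
  R2 <- Mod(Sxy)^2 / (Sxx * Syy)
  R2 <- pmin(pmax(R2, 0), 1)
  matrix(R2, plan$npad, plan$ns)[seq_len(plan$n), , drop = FALSE]
}

# literal BH step-up: reject the largest k with p_(k) <= k * alpha / m;
# adjusted values by cumulative minimum from the largest rank
brute_bh <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- ps * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  k <- which(ps <= seq_len(m) * alpha / m)
  rej_sorted <- rep(FALSE, m)
  if (length(k)) rej_sorted[seq_len(max(k))] <- TRUE
  qq <- numeric(m); qq[o] <- q
  rr <- logical(m); rr[o] <- rej_sorted
  list(q = qq, reject = rr)
}

# O(n^2) tau-b: concordant/discordant pair counting with tie correction
brute_kendall <- function(x, y) {
  n <- length(x)
  C <- D <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- sign(x[j] - x[i]); b <- sign(y[j] - y[i])
    if (a == 0 && b == 0) next
    if (a == 0) tx <- tx + 1
    else if (b == 0) ty <- ty + 1
    else if (a == b) C <- C + 1
    else D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((C + D + tx) * (C + D + ty))
}
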