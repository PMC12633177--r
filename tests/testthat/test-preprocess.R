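fs <- 7.81

test_that("coefficient of variation follows the population-SD convention", {
  expect_equal(compute_cv(rep(5, 100)), 0)
  expect_equal(compute_cv(c(90, 110)), 0.1)              # pop SD 10 / mean 100
  x <- runif(50, 500, 1500)
  expect_equal(compute_cv(3 * x), compute_cv(x), tolerance = 1e-12)
  expect_error(compute_cv(c(-1, 1)), "zero-mean")
})

test_that("CV filter excludes exactly the channels above threshold", {
  rec <- make_recording(c(0.05, 0.11, 0.09))
  out <- filter_channels_cv(rec, 0.1)
  expect_equal(nrow(out$recording$subjects[[1]]$channels), 2L)
  expect_equal(out$report$reason[!out$report$pass],
               rep("cv", sum(!out$report$pass)))
  expect_equal(sum(!out$report$pass), 2L)   # one channel per subject

  out_inf <- filter_channels_cv(rec, Inf)
  expect_equal(nrow(out_inf$recording$subjects[[1]]$channels), 3L)

  expect_error(filter_channels_cv(make_recording(c(0.2, 0.3)), 0.1),
               "no usable channels")
})

test_that("corrupted channels are caught by the CV filter in simulation", {
  set.seed(31)
  sp <- dyad_spec(n_channels_long = 10, n_channels_short = 2,
                  duration_s = 120, artifact_rate = 0, seed = 31)
  gd <- generate_dyad(sp)
  rec <- gd$recording
  corrupted <- c(2, 7)   # inject detector failure: huge multiplicative noise
  for (ch in corrupted) {
    for (w in 1:2) {
      n <- rec$n
      rec$subjects[[1]]$intensity[, ch, w] <-
        rec$subjects[[1]]$intensity[, ch, w] * exp(0.4 * rnorm(n))
    }
  }
  out <- filter_channels_cv(rec, 0.1)
  excl <- out$report$channel[out$report$subject == 1 & !out$report$pass]
  expect_true(all(corrupted %in% excl))
})

test_that("optical density conversion is the exact inverse of the intensity model", {
  expect_equal(intensity_to_od(rep(123.4, 50)), rep(0, 50))
  set.seed(5)
  x <- 0.03 * rnorm(300)
  I <- 1500 * exp(-x)
  od <- intensity_to_od(I)
  expect_equal(od, x - mean(x), tolerance = 1e-12)

  I2 <- rep(1000, 400); I2[37] <- 500
  od2 <- intensity_to_od(I2)
  expect_equal(od2[37] - od2[38], log(2), tolerance = 1e-12)

  expect_error(intensity_to_od(c(1, -2, 3)), "sample 2")
})

test_that("TDDR removes spikes and steps but passes clean signal through", {
  t <- (0:1199) / fs
  clean <- sin(2 * pi * 0.05 * t) + 0.3 * sin(2 * pi * 1.2 * t) +
    0.1 * rnorm(1200)
  out <- tddr(clean, fs)
  expect_lt(sqrt(mean((out - clean)^2)) / sd(clean), 0.05)

  i0 <- 500
  amp <- 10 * sd(clean)
  spiky <- clean; spiky[i0] <- spiky[i0] + amp
  outs <- tddr(spiky, fs)
  expect_gt(1 - abs(outs[i0] - out[i0]) / amp, 0.9)
  off <- setdiff(seq_along(clean), (i0 - 2):(i0 + 2))
  expect_lt(max(abs(outs[off] - out[off])), 0.1 * sd(clean))

  stepped <- clean; stepped[700:1200] <- stepped[700:1200] + 8 * sd(clean)
  outst <- tddr(stepped, fs)
  resid_off <- mean(outst[700:1200] - clean[700:1200]) -
    mean(outst[1:699] - clean[1:699])
  expect_lt(abs(resid_off), 0.8 * sd(clean))

  const <- rep(2.5, 100)
  expect_equal(tddr(const, fs), const)
  expect_equal(mean(tddr(spiky, fs)), mean(spiky))    # mean level preserved
  expect_error(tddr(1:5, fs), "too short")
})

test_that("the D4 wavelet transform reconstructs perfectly and the filter behaves", {
  set.seed(11)
  x <- rnorm(256)
  dec <- dyadsync:::dwt_d4(x, 4)
  expect_equal(dyadsync:::idwt_d4(dec), x, tolerance = 1e-10)
  # orthonormality: energy preserved across the decomposition
  expect_equal(sum(x^2), sum(dec$a^2) + sum(unlist(dec$d)^2),
               tolerance = 1e-10)

  t <- (0:1023) / fs
  slow <- sin(2 * pi * 0.05 * t) + 0.5 * sin(2 * pi * 0.11 * t + 1)
  wf <- wavelet_filter(slow)
  expect_lt(sqrt(mean((wf - slow)^2)) / sd(slow), 0.05)

  stepped <- slow; stepped[600:1024] <- stepped[600:1024] + 6 * sd(slow)
  wfs <- wavelet_filter(stepped)
  off_in <- mean(stepped[600:1024] - slow[600:1024])
  off_out <- mean(wfs[600:1024] - slow[600:1024]) -
    mean(wfs[1:599] - slow[1:599])
  expect_lt(abs(off_out), abs(off_in))

  expect_equal(wavelet_filter(rep(0, 256)), rep(0, 256))
  # energy never increases (orthonormal transform, coefficients only zeroed)
  y <- rnorm(512) + c(rep(0, 255), 20, rep(0, 256))
  expect_lte(sum(wavelet_filter(y)^2), sum(y^2) + 1e-8)
})

test_that("SCI hits its closed-form cases", {
  t <- (0:799) / fs
  cardiac <- sin(2 * pi * 1.2 * t)
  expect_equal(compute_sci(cbind(cardiac, cardiac), fs), 1, tolerance = 1e-6)
  expect_equal(compute_sci(cbind(cardiac, -cardiac), fs), -1, tolerance = 1e-6)
  set.seed(2)
  scis <- replicate(100, compute_sci(cbind(rnorm(400), rnorm(400)), fs))
  expect_lt(abs(mean(scis)), 0.03)
  expect_true(is.na(compute_sci(cbind(rep(1, 100), rep(2, 100)), fs)))
})

test_that("Beer-Lambert inverts its forward model to machine precision", {
  expect_equal(beer_lambert(cbind(`760` = rep(0, 10), `850` = rep(0, 10))),
               cbind(HbO = rep(0, 10), HbR = rep(0, 10)), tolerance = 1e-12)

  set.seed(9)
  hbo <- rnorm(200); hbr <- rnorm(200)
  ext <- extinction_defaults()
  d <- 3; dpf <- c(`760` = 6, `850` = 6)
  od <- cbind(`760` = (ext["760", "HbO"] * hbo + ext["760", "HbR"] * hbr) * d * dpf[1] * 1e-6,
              `850` = (ext["850", "HbO"] * hbo + ext["850", "HbR"] * hbr) * d * dpf[2] * 1e-6)
  conc <- beer_lambert(od, distance = d, dpf = dpf)
  expect_equal(unname(conc[, "HbO"]), hbo, tolerance = 1e-9)
  expect_equal(unname(conc[, "HbR"]), hbr, tolerance = 1e-9)

  half <- beer_lambert(od, distance = d, dpf = 2 * dpf)
  expect_equal(unname(half), unname(conc) / 2, tolerance = 1e-9)

  bad <- matrix(c(1, 2, 2, 4), 2, byrow = TRUE,
                dimnames = list(c("760", "850"), c("HbO", "HbR")))
  expect_error(beer_lambert(od, ext = bad), "singular")
})

test_that("short-separation regression removes what it should and only that", {
  set.seed(4)
  n <- 500
  short <- rnorm(n)
  expect_lt(max(abs(short_separation_regression(short, short))), 1e-10)

  neural <- as.numeric(arima.sim(list(ar = 0.9), n))
  long <- neural + 0.8 * short
  res <- short_separation_regression(long, short)
  expect_lt(abs(sum(res * short)), 1e-6)               # orthogonal residual
  expect_gt(cor(res, neural), cor(long, neural))

  # orthogonal regressor leaves the signal untouched (up to intercept)
  ortho <- sin(2 * pi * (1:n) / 50)
  lo <- rep(c(1, -1), n / 2)
  expect_gt(cor(short_separation_regression(lo, ortho), lo - mean(lo)), 0.999)

  expect_warning(r <- short_separation_regression(long, NULL), "unregressed")
  expect_equal(r, long - mean(long))
})

test_that("full chain recovers the injected hemodynamics on artifact-free dyads", {
  sp <- dyad_spec(n_channels_long = 3, n_channels_short = 2,
                  duration_s = 120, coupling_strength = 0.3,
                  artifact_rate = 0, seed = 5)
  gd <- generate_dyad(sp)
  h <- preprocess_dyad(gd$recording)
  expect_equal(nrow(h$qc[!h$qc$pass, ]), 0L)
  for (s in 1:2)
    for (ch in 1:3)
      expect_gt(cor(h$subjects[[s]]$HbO[, ch], gd$truth$neural[[s]][, ch]),
                0.95)
})

test_that("lowering a QC threshold never increases the surviving channel count", {
  sp <- dyad_spec(n_channels_long = 4, n_channels_short = 2,
                  duration_s = 120, artifact_rate = 4, seed = 8)
  rec <- generate_dyad(sp)$recording
  survivors <- sapply(c(0.2, 0.1, 0.05, 0.02), function(thr) {
    out <- tryCatch(filter_channels_cv(rec, thr),
                    error = function(e) NULL)
    if (is.null(out)) 0L else sum(out$report$pass)
  })
  expect_true(all(diff(survivors) <= 0))
})
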