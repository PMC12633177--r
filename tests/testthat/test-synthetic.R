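quick_spec <- function(...) {
  args <- utils::modifyList(list(n_channels_long = 2, n_channels_short = 1,
                                 duration_s = 120, artifact_rate = 0),
                            list(...))
  do.call(dyad_spec, args)
}

test_that("spec invariants are enforced with explicit messages", {
  expect_error(quick_spec(coupling_strength = 1.2), "\\[0, 1\\]")
  expect_error(quick_spec(coupling_band = c(0.1, 4)), "Nyquist")
  expect_error(quick_spec(coupling_band = c(0.005, 0.1), duration_s = 120),
               "4 periods")
  expect_error(dyad_spec(n_channels_long = 0), "at least one")
})

test_that("generation is bit-identical under a fixed seed", {
  sp <- quick_spec(seed = 77, artifact_rate = 3)
  a <- generate_dyad(sp)
  b <- generate_dyad(sp)
  expect_identical(a$recording, b$recording)
  expect_identical(a$truth, b$truth)
  c <- generate_dyad(quick_spec(seed = 78, artifact_rate = 3))
  expect_false(identical(a$recording$subjects[[1]]$intensity,
                         c$recording$subjects[[1]]$intensity))
})

test_that("physiological noise shows periodogram peaks at configured frequencies", {
  sp <- quick_spec(seed = 5, duration_s = 240)
  gd <- generate_dyad(sp)
  # short channel is scalp-dominated
  od <- intensity_to_od(gd$recording$subjects[[1]]$intensity[, 3, "850"])
  n <- length(od)
  pw <- Mod(fft(od))^2
  fr <- (0:(n - 1)) * sp$fs / n
  half <- fr <= sp$fs / 2
  pw <- pw[half]; fr <- fr[half]
  bin <- sp$fs / n
  for (cmp in c("cardiac", "resp", "mayer")) {
    f0 <- sp$noise_profile[[cmp]][["freq"]]
    near <- which(abs(fr - f0) <= bin)         # within one bin
    away <- which(abs(fr - f0) > 5 * bin & fr > 0.02)
    expect_gt(max(pw[near]), 10 * stats::median(pw[away]))
  }
})

test_that("artifact inventory is consistent with the recording", {
  sp <- quick_spec(seed = 12, artifact_rate = 6)
  gd <- generate_dyad(sp)
  ev <- gd$truth$artifacts
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$time_s >= 0 & ev$time_s < sp$duration_s))
  expect_true(all(ev$kind %in% c("spike", "shift")))
  expect_true(all(ev$subject %in% 1:2))
})

test_that("stronger injected coupling raises band-averaged coherence", {
  # spec example: strength 0.9 vs uncoupled, 360 s blocks
  sp1 <- dyad_spec(n_channels_long = 1, n_channels_short = 1,
                   duration_s = 360, coupling_strength = 0.9,
                   artifact_rate = 0, seed = 4)
  sp0 <- sp1; sp0$coupling_strength <- 0
  inband <- function(sp) {
    gd <- generate_dyad(sp)
    w <- wtc(gd$truth$neural[[1]][, 1], gd$truth$neural[[2]][, 1], sp$fs)
    band <- w$freq >= 0.05 & w$freq <= 0.1
    mean(w$R2[band, ][w$coi_ok[band, ]], na.rm = TRUE)
  }
  expect_gt(inband(sp1), inband(sp0))
})

test_that("band coherence is monotone in coupling strength over seeds", {
  strengths <- c(0, 0.3, 0.6, 0.9)
  means <- sapply(strengths, function(st) {
    vals <- sapply(1:20, function(s) {
      sp <- dyad_spec(n_channels_long = 1, n_channels_short = 1,
                      duration_s = 240, coupling_strength = st,
                      artifact_rate = 0, seed = 1000 + s)
      gd <- generate_dyad(sp)
      w <- wtc(gd$truth$neural[[1]][, 1], gd$truth$neural[[2]][, 1], sp$fs,
               voices = 6)
      band <- w$freq >= 0.05 & w$freq <= 0.1
      mean(w$R2[band, ][w$coi_ok[band, ]], na.rm = TRUE)
    })
    mean(vals)
  })
  expect_true(all(diff(means) > 0))
})

test_that("long/short channel correlation grows with scalp gain", {
  cors <- sapply(c(0.2, 0.8), function(g) {
    mean(sapply(1:5, function(s) {
      gd <- generate_dyad(quick_spec(scalp_gain = g, seed = 200 + s))
      od_l <- intensity_to_od(gd$recording$subjects[[1]]$intensity[, 1, "850"])
      od_s <- intensity_to_od(gd$recording$subjects[[1]]$intensity[, 3, "850"])
      cor(od_l, od_s)
    }))
  })
  expect_gt(cors[2], cors[1])
})

test_that("cohort generation mirrors the study design", {
  sp <- quick_spec(seed = 1)
  ds <- generate_cohort(c(A = 33, B = 18, C = 12), spec = sp,
                        transcripts = FALSE, seed = 3)
  expect_equal(unname(table(ds$groups)[c("A", "B", "C")]),
               c(33L, 18L, 12L), ignore_attr = TRUE)
  expect_length(ds$dyads, 63)

  expect_error(generate_cohort(c(A = 5, B = 1), spec = sp), "at least 2")
  expect_error(generate_cohort(c(A = 3, B = 3), spec = sp,
                               effect_map = list(A = c("9" = 0.3)), seed = 1),
               "out of range")

  ds2 <- generate_cohort(c(A = 2, B = 2), spec = sp,
                         effect_map = list(A = c("2" = 0.4)), seed = 3,
                         transcripts = FALSE)
  stA <- ds2$dyads[[1]]$strengths
  stB <- ds2$dyads[[3]]$strengths
  expect_equal(stA[2] - stB[2], 0.4, tolerance = 1e-12)
  expect_equal(stA[1], stB[1])
  # identical seed reproduces the cohort
  ds3 <- generate_cohort(c(A = 2, B = 2), spec = sp,
                         effect_map = list(A = c("2" = 0.4)), seed = 3,
                         transcripts = FALSE)
  expect_identical(ds2$dyads[[1]]$signals, ds3$dyads[[1]]$signals)
})

test_that("symptom scores track coupling with the requested Kendall tau", {
  taus <- sapply(1:15, function(s) {
    ds <- generate_cohort(c(A = 40), spec = quick_spec(),
                          coupling_spread = c(0.05, 0.85), symptom_tau = 0.4,
                          transcripts = FALSE, seed = 400 + s)
    st <- sapply(ds$dyads, function(d) d$strengths[1])
    sy <- sapply(ds$dyads, `[[`, "symptom")
    kendall_cor(st, sy)$tau
  })
  expect_lt(abs(mean(taus) - 0.4), 0.1)
})
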