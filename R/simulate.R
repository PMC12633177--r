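# Synthetic dyadic fNIRS generator: two-subject, two-wavelength raw intensity
# with physiological noise, a shared scalp component, motion artifacts, and
# cross-brain coupling injected in a configurable low-frequency band.

# run expr under a temporary RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  force(expr)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Specification of a synthetic dyadic recording
#'
#' Collects the generator parameters for one mother-child dyad. Defaults
#' mirror a NIRSport2-style acquisition: 7.81 Hz sampling, wavelengths
#' 760/850 nm, long (3 cm) plus short-separation (0.8 cm) channels, and a
#' 6-minute task block. Physiological noise is built from cardiac
#' (~1.2 Hz), respiratory (~0.3 Hz) and Mayer-wave (~0.1 Hz) oscillations
#' plus white noise; motion artifacts are spikes and baseline shifts at
#' Poisson-distributed times.
#'
#' @param n_channels_long long channels per subject.
#' @param n_channels_short short-separation channels per subject.
#' @param fs sampling rate in Hz.
#' @param duration_s seconds in the task block.
#' @param coupling_band numeric length-2 (Hz): band carrying the shared
#'   cross-brain oscillation. The high edge must lie below Nyquist.
#' @param coupling_strength target band coherence in `[0, 1]`; scalar or one
#'   value per long channel pair.
#' @param artifact_rate expected motion events per minute per channel.
#' @param scalp_gain amplitude ratio of the shared superficial component in
#'   long channels (short channels carry it at gain 1).
#' @param noise_profile list with elements `cardiac`, `resp`, `mayer` (each
#'   `c(freq =, amp =)` in Hz and uM) and `white` (uM, measurement noise).
#' @param neural_band_sd,neural_out_sd standard deviation (uM) of the
#'   in-coupling-band and out-of-band neural HbO components.
#' @param seed RNG seed for [generate_dyad()].
#' @return object of class `dyad_spec`.
#' @export
dyad_spec <- function(n_channels_long = 8, n_channels_short = 2, fs = 7.81,
                      duration_s = 360, coupling_band = c(0.05, 0.1),
                      coupling_strength = 0.3, artifact_rate = 2,
                      scalp_gain = 0.5,
                      noise_profile = list(cardiac = c(freq = 1.2, amp = 0.30),
                                           resp   = c(freq = 0.3, amp = 0.10),
                                           mayer  = c(freq = 0.1, amp = 0.15),
                                           white  = 0.04),
                      neural_band_sd = 0.20, neural_out_sd = 0.20,
                      seed = 1L) {
  spec <- list(n_channels_long = as.integer(n_channels_long),
               n_channels_short = as.integer(n_channels_short),
               fs = fs, duration_s = duration_s,
               coupling_band = coupling_band,
               coupling_strength = coupling_strength,
               artifact_rate = artifact_rate, scalp_gain = scalp_gain,
               noise_profile = noise_profile,
               neural_band_sd = neural_band_sd, neural_out_sd = neural_out_sd,
               seed = seed)
  validate_dyad_spec(spec)
  structure(spec, class = "dyad_spec")
}

validate_dyad_spec <- function(spec) {
  with(spec, {
    if (any(coupling_strength < 0) || any(coupling_strength > 1))
      stop("coupling_strength must lie in [0, 1]")
    if (!(length(coupling_strength) %in% c(1L, n_channels_long)))
      stop("coupling_strength must be scalar or one value per long channel")
    f_lo <- coupling_band[1]; f_hi <- coupling_band[2]
    if (!(f_lo > 0 && f_hi > f_lo))
      stop("coupling_band must satisfy 0 < low < high")
    if (f_hi >= fs / 2)
      stop(sprintf("coupling band edge %.4g Hz is at or beyond Nyquist (%.4g Hz)",
                   f_hi, fs / 2))
    if (duration_s * fs < 4 / f_lo * fs)
      stop("duration_s must cover at least 4 periods of the coupling band low edge")
    if (n_channels_long < 1L || n_channels_short < 1L)
      stop("need at least one long and one short channel per subject")
  })
  invisible(spec)
}

#' @export
print.dyad_spec <- function(x, ...) {
  cat(sprintf("dyad_spec: %d long + %d short channels, %.4g Hz, %g s\n",
              x$n_channels_long, x$n_channels_short, x$fs, x$duration_s))
  cat(sprintf("  coupling %.2g-%.2g Hz, strength %s; artifacts %g/min; scalp gain %g\n",
              x$coupling_band[1], x$coupling_band[2],
              paste(signif(x$coupling_strength, 2), collapse = "/"),
              x$artifact_rate, x$scalp_gain))
  invisible(x)
}

# unit-variance band-limited Gaussian process built in the frequency
# domain. keep = TRUE retains [f_lo, f_hi] with a raised-cosine power
# envelope over the outer `taper` fraction of the band's log-width on each
# side (a band-pass-filtered process has soft edges; a brick-wall mask
# would ring in time). keep = FALSE notches [f_lo, f_hi] out of [0, f_max].
band_noise <- function(n, fs, f_lo, f_hi, keep = TRUE, f_max = 0.5,
                       taper = 0.3) {
  z <- stats::rnorm(n)
  f <- abs(seq(0, fs, length.out = n + 1L)[seq_len(n)])
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  Z <- stats::fft(z)
  if (keep) {
    amp <- numeric(n)
    inb <- f >= f_lo & f <= f_hi
    if (taper > 0) {
      lw <- log(f_hi / f_lo)
      u <- (log(pmax(f, 1e-12)) - log(f_lo)) / lw      # 0..1 across band
      env <- rep(1, n)
      lo_edge <- inb & u < taper
      hi_edge <- inb & u > 1 - taper
      env[lo_edge] <- 0.5 * (1 - cos(pi * u[lo_edge] / taper))
      env[hi_edge] <- 0.5 * (1 - cos(pi * (1 - u[hi_edge]) / taper))
      amp[inb] <- sqrt(env[inb])
    } else {
      amp[inb] <- 1
    }
    Z <- Z * amp
  } else {
    sel <- f <= f_max & !(f >= f_lo & f <= f_hi) & f > 1e-9
    Z[!sel] <- 0
  }
  x <- Re(stats::fft(Z, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s < .Machine$double.eps) return(rep(0, n))
  x / s
}

#' Default molar extinction coefficients
#'
#' HbO/HbR extinction coefficients (1/(cm M)) at 760 and 850 nm, from a
#' standard published molar absorptivity table; used by [beer_lambert()]
#' and the synthetic generator's forward model.
#'
#' @return 2 x 2 matrix, rows "760"/"850", columns "HbO"/"HbR".
#' @export
extinction_defaults <- function() {
  matrix(c(1486.5865, 3843.707,
           2526.391, 1798.643),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("760", "850"), c("HbO", "HbR")))
}

# geometry defaults: source-detector distance (cm) and DPF per wavelength
geometry_defaults <- function() {
  list(distance_long = 3.0, distance_short = 0.8, dpf = c(`760` = 6, `850` = 6))
}

region_labels <- function(n) {
  base <- c("right FA", "left Broca", "right DLPFC", "left SFG",
            "left STG", "left FEF", "right SMG", "right TPJ",
            "left DLPFC", "right STG", "left SMG", "right Broca")
  rep_len(base, n)
}

# forward model: HbO/HbR (uM) -> delta-OD per wavelength (zero-mean)
hemo_to_od <- function(hbo, hbr, distance, geom = geometry_defaults(),
                       ext = extinction_defaults()) {
  od <- cbind(`760` = (ext["760", "HbO"] * hbo + ext["760", "HbR"] * hbr) *
                distance * geom$dpf[["760"]] * 1e-6,
              `850` = (ext["850", "HbO"] * hbo + ext["850", "HbR"] * hbr) *
                distance * geom$dpf[["850"]] * 1e-6)
  sweep(od, 2L, colMeans(od))
}

#' Generate one synthetic dyadic fNIRS recording
#'
#' Produces raw two-wavelength intensity for both subjects of a dyad, plus
#' the ground truth used downstream in tests: injected neural components,
#' per-channel motion-artifact inventories, and the coupled channel pairs
#' with their target coherences.
#'
#' Homologous long channels of the two subjects share a band-limited
#' Gaussian oscillation mixed with per-subject residual band noise. The
#' shared-variance fraction is set to the square root of the target
#' coherence, which is the closed-form calibration for magnitude-squared
#' coherence of a common signal observed in independent noise of matched
#' band power. Short channels contain only the superficial (scalp) component
#' plus measurement noise; long channels add the scalp component at
#' `scalp_gain`. Raw intensity is `baseline * exp(-dOD)`, so optical-density
#' conversion round-trips exactly.
#'
#' @param spec a [dyad_spec()].
#' @return list with elements `recording` (class `dyad_recording`) and
#'   `truth` (class `dyad_truth`).
#' @export
generate_dyad <- function(spec) {
  validate_dyad_spec(spec)
  with_seed(spec$seed, generate_dyad_impl(spec))
}

generate_dyad_impl <- function(spec) {
  fs <- spec$fs
  n <- round(spec$duration_s * fs)
  nL <- spec$n_channels_long; nS <- spec$n_channels_short
  nc <- nL + nS
  band <- spec$coupling_band
  strength <- rep_len(spec$coupling_strength, nL)
  np <- spec$noise_profile
  geom <- geometry_defaults()
  tt <- (seq_len(n) - 1L) / fs

  # shared in-band components per homologous long-channel pair
  neural <- vector("list", 2L)   # per subject: n x nL injected HbO neural part
  for (s in 1:2) neural[[s]] <- matrix(0, n, nL)
  for (ch in seq_len(nL)) {
    shared <- band_noise(n, fs, band[1], band[2], keep = TRUE)
    f_shared <- sqrt(strength[ch])          # shared variance fraction
    for (s in 1:2) {
      resid <- band_noise(n, fs, band[1], band[2], keep = TRUE)
      inband <- sqrt(f_shared) * shared + sqrt(1 - f_shared) * resid
      outband <- band_noise(n, fs, band[1], band[2], keep = FALSE,
                            f_max = 0.5)    # coupling band notched out
      neural[[s]][, ch] <- spec$neural_band_sd * inband +
        spec$neural_out_sd * outband
    }
  }

  subjects <- vector("list", 2L)
  scalp_store <- vector("list", 2L)
  artifacts <- list()
  for (s in 1:2) {
    # subject-level systemic/scalp component with configured spectral peaks
    phases <- stats::runif(3, 0, 2 * pi)
    scalp <- np$cardiac[["amp"]] * sin(2 * pi * np$cardiac[["freq"]] * tt + phases[1]) +
      np$resp[["amp"]] * sin(2 * pi * np$resp[["freq"]] * tt + phases[2]) +
      np$mayer[["amp"]] * sin(2 * pi * np$mayer[["freq"]] * tt + phases[3]) +
      0.05 * band_noise(n, fs, 0.005, 0.04, keep = TRUE)   # slow drift
    scalp_store[[s]] <- scalp

    intensity <- array(NA_real_, dim = c(n, nc, 2L),
                       dimnames = list(NULL, NULL, c("760", "850")))
    for (ch in seq_len(nc)) {
      long <- ch <= nL
      # functional HbR runs anticorrelated with neural HbO; the systemic
      # (scalp) pulsation is a volume change and enters HbR weakly with
      # positive sign, keeping the cardiac beat in phase at both wavelengths
      if (long) {
        hbo <- neural[[s]][, ch] + spec$scalp_gain * scalp +
          np$white * stats::rnorm(n)
        hbr <- -neural[[s]][, ch] / 3 + 0.1 * spec$scalp_gain * scalp +
          np$white / 2 * stats::rnorm(n)
        dist <- geom$distance_long
      } else {
        hbo <- scalp + np$white * stats::rnorm(n)
        hbr <- 0.1 * scalp + np$white / 2 * stats::rnorm(n)
        dist <- geom$distance_short
      }
      od <- hemo_to_od(hbo, hbr, dist)

      # motion artifacts: spikes (1-3 samples, 5-20x SD) and baseline shifts
      n_ev <- stats::rpois(1, spec$artifact_rate * spec$duration_s / 60)
      if (n_ev > 0) {
        ev_t <- sort(sample.int(n - 4L, n_ev))
        ev_kind <- sample(c("spike", "shift"), n_ev, replace = TRUE)
        ev_amp <- stats::runif(n_ev, 5, 20) * sample(c(-1, 1), n_ev, replace = TRUE)
        ev_wid <- sample(1:3, n_ev, replace = TRUE)
        for (w in c("760", "850")) {
          sdw <- stats::sd(od[, w])
          for (e in seq_len(n_ev)) {
            if (ev_kind[e] == "spike") {
              idx <- ev_t[e]:min(n, ev_t[e] + ev_wid[e] - 1L)
              od[idx, w] <- od[idx, w] + ev_amp[e] * sdw
            } else {
              od[ev_t[e]:n, w] <- od[ev_t[e]:n, w] + ev_amp[e] / 2.5 * sdw
            }
          }
        }
        artifacts[[length(artifacts) + 1L]] <-
          data.frame(subject = s, channel = ch, time_s = (ev_t - 1L) / fs,
                     kind = ev_kind, amplitude_sd = ev_amp, width = ev_wid)
      }

      baseline <- stats::runif(2, 800, 2000)
      intensity[, ch, "760"] <- baseline[1] * exp(-od[, "760"])
      intensity[, ch, "850"] <- baseline[2] * exp(-od[, "850"])
    }

    channels <- data.frame(channel = seq_len(nc), source = seq_len(nc),
                           detector = seq_len(nc),
                           type = c(rep("long", nL), rep("short", nS)),
                           region = c(region_labels(nL), rep("scalp", nS)))
    subjects[[s]] <- list(intensity = intensity, channels = channels)
  }

  rec <- structure(list(subjects = subjects, fs = fs, n = n,
                        duration_s = spec$duration_s,
                        annotations = data.frame(task = "tangram", start = 0,
                                                 end = spec$duration_s)),
                   class = "dyad_recording")
  truth <- structure(list(
    coupled_pairs = data.frame(channel = seq_len(nL), strength = strength),
    coupling_band = band,
    neural = neural,
    scalp = scalp_store,
    artifacts = if (length(artifacts)) do.call(rbind, artifacts) else
      data.frame(subject = integer(), channel = integer(), time_s = numeric(),
                 kind = character(), amplitude_sd = numeric(), width = integer())),
    class = "dyad_truth")
  list(recording = rec, truth = truth)
}

#' @export
print.dyad_recording <- function(x, ...) {
  nc <- ncol(x$subjects[[1]]$intensity)
  cat(sprintf("dyad_recording: 2 subjects x %d channels x 2 wavelengths, %d samples @ %.4g Hz (%g s)\n",
              nc, x$n, x$fs, x$duration_s))
  cat(sprintf("  tasks: %s\n",
              paste(sprintf("%s [%g, %g)", x$annotations$task,
                            x$annotations$start, x$annotations$end),
                    collapse = ", ")))
  invisible(x)
}

#' Generate a synthetic study cohort
#'
#' Builds a multi-group study dataset with known ground truth: per-group
#' coupling deltas on designated channel pairs, per-child latent verbal
#' ability driving CHAT transcripts, and behavioral scores (a symptom total
#' and a task score). Group labels A/B/C mirror a three-group design of an
#' affected group, a matched control group, and typically developing peers;
#' the default sizes are 33/18/12.
#'
#' At the default `level = "hemo"`, dyad signals are generated directly at
#' the artifact-free hemodynamic level (the coupled neural components plus
#' measurement noise), which is what the coherence stage consumes and keeps
#' cohort-scale simulation fast. `level = "raw"` runs [generate_dyad()] per
#' dyad so the full preprocessing chain can be exercised.
#'
#' @param n_per_group integer vector (names optional) of dyads per group;
#'   every group needs at least 2 dyads.
#' @param spec baseline [dyad_spec()] shared by all dyads.
#' @param effect_map named list: group label -> named numeric vector of
#'   coupling-strength deltas indexed by channel pair (e.g.
#'   `list(A = c("3" = 0.3))`).
#' @param coupling_spread optional length-2 numeric: when given, each dyad's
#'   coupling strength at `symptom_pair` is an equiprobable monotone map of
#'   a standard-normal latent into `[lo, hi]`, giving across-dyad variation.
#' @param symptom_tau optional target Kendall correlation between the
#'   symptom score and the latent coupling at `symptom_pair`, realised
#'   through a Gaussian copula (rank correlation is preserved by the
#'   monotone map).
#' @param symptom_pair channel-pair index the symptom score tracks.
#' @param latent_verbal means of per-group child latent verbal ability in
#'   `[0, 1]` (names must cover the groups).
#' @param transcripts generate a CHAT transcript per child (disable to speed
#'   up purely neural simulations).
#' @param seed RNG seed.
#' @return object of class `study_dataset`.
#' @export
generate_cohort <- function(n_per_group = c(A = 33, B = 18, C = 12),
                            spec = dyad_spec(), effect_map = NULL,
                            coupling_spread = NULL, symptom_tau = NA,
                            symptom_pair = 1L,
                            latent_verbal = c(A = 0.35, B = 0.60, C = 0.65),
                            transcripts = TRUE,
                            level = c("hemo", "raw"), seed = 1L) {
  level <- match.arg(level)
  if (is.null(names(n_per_group)))
    names(n_per_group) <- LETTERS[seq_along(n_per_group)]
  if (any(n_per_group < 2))
    stop("every group needs at least 2 dyads")
  validate_dyad_spec(spec)
  if (!all(names(n_per_group) %in% names(latent_verbal)))
    stop("latent_verbal must name every group")
  with_seed(seed, generate_cohort_impl(n_per_group, spec, effect_map,
                                       coupling_spread, symptom_tau,
                                       symptom_pair, latent_verbal,
                                       transcripts, level))
}

# per-group behavioral score parameters (symptom total is SRS-2-like
# T-scores; task score mirrors a tangram score scale)
score_profile <- function() {
  list(symptom = list(A = c(61, 14), B = c(65, 12), C = c(48, 8)),
       task    = list(A = c(14.2, 7.7), B = c(16.1, 4.7), C = c(21.4, 8.3)))
}

generate_cohort_impl <- function(n_per_group, spec, effect_map,
                                 coupling_spread, symptom_tau, symptom_pair,
                                 latent_verbal, transcripts, level) {
  fs <- spec$fs
  n <- round(spec$duration_s * fs)
  nL <- spec$n_channels_long
  base_strength <- rep_len(spec$coupling_strength, nL)
  prof <- score_profile()
  rho <- if (is.na(symptom_tau)) NA_real_ else sin(pi * symptom_tau / 2)

  dyads <- list()
  id <- 0L
  for (g in names(n_per_group)) {
    st_g <- base_strength
    if (!is.null(effect_map[[g]])) {
      idx <- as.integer(names(effect_map[[g]]))
      if (any(is.na(idx)) || any(idx < 1L) || any(idx > nL))
        stop("effect_map channel indices out of range")
      st_g[idx] <- st_g[idx] + as.numeric(effect_map[[g]])
    }
    st_g <- clamp(st_g, 0, 1)
    for (d in seq_len(n_per_group[[g]])) {
      id <- id + 1L
      st <- st_g
      u <- stats::rnorm(1)
      if (!is.null(coupling_spread))
        st[symptom_pair] <- coupling_spread[1] +
          diff(coupling_spread) * stats::pnorm(u)
      symptom <- if (!is.na(rho)) {
        v <- rho * u + sqrt(1 - rho^2) * stats::rnorm(1)
        prof$symptom[[g]][1] + prof$symptom[[g]][2] * v
      } else {
        stats::rnorm(1, prof$symptom[[g]][1], prof$symptom[[g]][2])
      }
      task_score <- stats::rnorm(1, prof$task[[g]][1], prof$task[[g]][2])
      lv <- clamp(stats::rnorm(1, latent_verbal[[g]], 0.12), 0, 1)

      if (level == "hemo") {
        sig <- hemo_pair_signals(n, fs, spec, st)
        dyad <- list(id = id, group = g, signals = sig, strengths = st,
                     recording = NULL, truth = NULL)
      } else {
        spec_d <- spec
        spec_d$coupling_strength <- st
        spec_d$seed <- NULL               # RNG flows from the cohort seed
        gd <- generate_dyad_impl(spec_d)
        dyad <- list(id = id, group = g, signals = NULL, strengths = st,
                     recording = gd$recording, truth = gd$truth)
      }
      dyad$symptom <- symptom
      dyad$task_score <- task_score
      dyad$latent_verbal <- lv
      if (transcripts)
        dyad$transcript <- generate_transcript_impl(lv)
      dyads[[id]] <- dyad
    }
  }

  structure(list(dyads = dyads, groups = vapply(dyads, `[[`, "", "group"),
                 spec = spec, fs = fs, n = n, level = level,
                 n_pairs = nL, symptom_pair = symptom_pair),
            class = "study_dataset")
}

# artifact-free hemodynamic-level signals for one dyad: per subject an
# n x n_pairs matrix of HbO-like series carrying the injected coupling
hemo_pair_signals <- function(n, fs, spec, strengths) {
  band <- spec$coupling_band
  out <- list(matrix(0, n, length(strengths)), matrix(0, n, length(strengths)))
  for (ch in seq_along(strengths)) {
    shared <- band_noise(n, fs, band[1], band[2], keep = TRUE)
    f_shared <- sqrt(strengths[ch])
    for (s in 1:2) {
      resid <- band_noise(n, fs, band[1], band[2], keep = TRUE)
      inband <- sqrt(f_shared) * shared + sqrt(1 - f_shared) * resid
      outband <- band_noise(n, fs, band[1], band[2], keep = FALSE, f_max = 0.5)
      out[[s]][, ch] <- spec$neural_band_sd * inband +
        spec$neural_out_sd * outband +
        spec$noise_profile$white * stats::rnorm(n)
    }
  }
  out
}

#' @export
print.study_dataset <- function(x, ...) {
  tb <- table(x$groups)
  cat(sprintf("study_dataset: %d dyads (%s), %d channel pairs, %d samples @ %.4g Hz, level '%s'\n",
              length(x$dyads),
              paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
              x$n_pairs, x$n, x$fs, x$level))
  invisible(x)
}
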