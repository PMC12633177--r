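# Calibration and power studies for the IBS pipeline. These drive the same
# machinery end to end on synthetic cohorts with known ground truth; the
# package's validation suite and reproduction script are thin wrappers
# around them.

#' Type-I calibration of permutation bin selection
#'
#' Simulates cohorts with zero injected coupling and measures the fraction
#' of frequency bins selected as task-related, which should match the
#' nominal selection level.
#'
#' @param n_cohorts simulated cohorts.
#' @param n_dyads dyads per cohort.
#' @param duration_s recording length per dyad (seconds).
#' @param n_perm permutation samples per cohort.
#' @param voices scales per octave for the coherence analysis.
#' @param alpha selection level.
#' @param seed RNG seed (cohort and permutation seeds are derived from it).
#' @return list: `rate` (mean per-bin selection rate), `per_cohort` rates,
#'   and the settings.
#' @export
study_bin_calibration <- function(n_cohorts = 500, n_dyads = 8,
                                  duration_s = 120, n_perm = 200,
                                  voices = 6, alpha = 0.05, seed = 1L) {
  rates <- numeric(n_cohorts)
  for (k in seq_len(n_cohorts)) {
    sp <- dyad_spec(n_channels_long = 1, n_channels_short = 1,
                    duration_s = duration_s, coupling_strength = 0,
                    artifact_rate = 0)
    ds <- generate_cohort(c(A = n_dyads), spec = sp, transcripts = FALSE,
                          seed = (seed * 7919 + k) %% .Machine$integer.max)
    coh <- cohort_coherence(ds, n_perm = n_perm, voices = voices,
                            seed = (seed * 104729 + k) %% .Machine$integer.max)
    sel <- suppressWarnings(select_bins(coh$real[[1]], coh$null[[1]],
                                        alpha = alpha))
    ok <- !is.na(sel$p_value)
    rates[k] <- mean(sel$mask[ok])
  }
  list(rate = mean(rates), per_cohort = rates, alpha = alpha,
       n_cohorts = n_cohorts, n_dyads = n_dyads)
}

#' Frequency-band recovery of injected coupling
#'
#' Injects coupling in a known band and measures the fraction of in-band
#' and out-of-band frequency bins selected by the permutation test,
#' averaged over seeds.
#'
#' @param n_seeds independent cohorts.
#' @param n_dyads dyads per cohort.
#' @param strength injected band coherence.
#' @param band coupling band (Hz).
#' @inheritParams study_bin_calibration
#' @return list with `in_rate`, `out_rate`, and per-seed values.
#' @export
study_band_recovery <- function(n_seeds = 20, n_dyads = 20, strength = 0.6,
                                band = c(0.05, 0.1), duration_s = 240,
                                n_perm = 200, voices = 12, alpha = 0.05,
                                seed = 1L) {
  inr <- outr <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    sp <- dyad_spec(n_channels_long = 1, n_channels_short = 1,
                    duration_s = duration_s, coupling_strength = strength,
                    coupling_band = band, artifact_rate = 0)
    ds <- generate_cohort(c(A = n_dyads), spec = sp, transcripts = FALSE,
                          seed = (seed * 6007 + s) %% .Machine$integer.max)
    coh <- cohort_coherence(ds, n_perm = n_perm, voices = voices,
                            seed = (seed * 31337 + s) %% .Machine$integer.max)
    sel <- suppressWarnings(select_bins(coh$real[[1]], coh$null[[1]],
                                        alpha = alpha))
    inb <- coh$freq >= band[1] & coh$freq <= band[2]
    ok <- !is.na(sel$p_value)
    inr[s] <- mean(sel$mask[inb & ok])
    outr[s] <- mean(sel$mask[!inb & ok])
  }
  list(in_rate = mean(inr), out_rate = mean(outr),
       in_per_seed = inr, out_per_seed = outr)
}

#' End-to-end group recovery through the full statistical stage
#'
#' Simulates a three-group cohort in which one channel pair carries a
#' coupling delta in group A, runs coherence, bin selection, Fisher-z IBS,
#' one-way ANOVA with post-hoc t-tests and BH-FDR, and reports how often
#' the true pair is flagged and how many other pairs are flagged.
#'
#' @param n_seeds repetitions.
#' @param n_per_group dyads per group (scalar).
#' @param delta coupling increment on the affected pair in group A.
#' @param base baseline coupling of all pairs in all groups.
#' @param n_pairs homologous channel pairs simulated.
#' @param target_pair the pair carrying the delta.
#' @inheritParams study_bin_calibration
#' @return list with `hit_rate`, `false_per_seed` (mean), and per-seed
#'   detail.
#' @export
study_group_recovery <- function(n_seeds = 20, n_per_group = 15, delta = 0.3,
                                 base = 0.15, n_pairs = 6, target_pair = 3,
                                 duration_s = 360, n_perm = 100, voices = 6,
                                 alpha = 0.05, seed = 1L) {
  hits <- logical(n_seeds)
  false_n <- integer(n_seeds)
  for (s in seq_len(n_seeds)) {
    sp <- dyad_spec(n_channels_long = n_pairs, n_channels_short = 1,
                    duration_s = duration_s, coupling_strength = base,
                    artifact_rate = 0)
    em <- list(A = stats::setNames(delta, as.character(target_pair)))
    ds <- generate_cohort(c(A = n_per_group, B = n_per_group, C = n_per_group),
                          spec = sp, effect_map = em, transcripts = FALSE,
                          seed = (seed * 4001 + s) %% .Machine$integer.max)
    ibs <- suppressWarnings(
      ibs_pipeline(ds, n_perm = n_perm, voices = voices, alpha = alpha,
                   seed = (seed * 9001 + s) %% .Machine$integer.max))
    an <- run_full_analysis(ibs$table, alpha = alpha)
    flagged <- an$channel_tests$pair[an$channel_tests$significant]
    hits[s] <- target_pair %in% flagged
    false_n[s] <- length(setdiff(flagged, target_pair))
  }
  list(hit_rate = mean(hits), false_per_seed = mean(false_n),
       hits = hits, false_n = false_n)
}

#' Recovery of a symptom-coupling Kendall correlation at study scale
#'
#' Generates single-group cohorts in which the symptom score has a known
#' Kendall correlation with one channel pair's coupling strength, estimates
#' IBS through the pipeline, and reports the mean estimated tau between IBS
#' and symptom scores.
#'
#' @param n_seeds repetitions.
#' @param n_dyads dyads (children) per cohort.
#' @param tau target Kendall correlation between symptom and coupling.
#' @param coupling_spread range of per-dyad coupling strengths.
#' @inheritParams study_bin_calibration
#' @return list with `tau_hat` (mean over seeds) and per-seed estimates.
#' @export
study_tau_recovery <- function(n_seeds = 50, n_dyads = 33, tau = 0.4,
                               coupling_spread = c(0.05, 0.85),
                               duration_s = 180, n_perm = 100, voices = 6,
                               seed = 1L) {
  taus <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    sp <- dyad_spec(n_channels_long = 1, n_channels_short = 1,
                    duration_s = duration_s, coupling_strength = 0.45,
                    artifact_rate = 0)
    ds <- generate_cohort(c(A = n_dyads), spec = sp,
                          coupling_spread = coupling_spread,
                          symptom_tau = tau, transcripts = FALSE,
                          seed = (seed * 2003 + s) %% .Machine$integer.max)
    ibs <- suppressWarnings(
      ibs_pipeline(ds, n_perm = n_perm, voices = voices,
                   seed = (seed * 5003 + s) %% .Machine$integer.max))
    sy <- vapply(ds$dyads, `[[`, 0, "symptom")
    taus[s] <- kendall_cor(ibs$table$z, sy)$tau
  }
  list(tau_hat = mean(taus), per_seed = taus, target = tau)
}
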