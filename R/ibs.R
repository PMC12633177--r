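# Inter-brain synchrony: wavelet coherence spectra per dyadic channel pair,
# permutation selection of task-related frequency bins, Fisher-z IBS.

# signals for subject s of dyad d (time x channel-pair matrix)
dyad_signal <- function(ds, d, s) {
  sig <- ds$dyads[[d]]$signals
  if (is.null(sig))
    stop("dataset has raw-level recordings; run preprocess_cohort() first")
  sig[[s]]
}

# draw n_perm shuffled non-partner pairings: subject-1 of dyad i with
# subject-2 of dyad j != i, uniform over ordered non-partner pairs; returns
# the distinct pairings with multiplicities so each spectrum is computed once
sample_null_pairings <- function(n_dyads, n_perm) {
  if (n_dyads < 2L)
    stop("permutation null needs at least 2 dyads (no non-partner available)")
  i <- sample.int(n_dyads, n_perm, replace = TRUE)
  j <- sample.int(n_dyads - 1L, n_perm, replace = TRUE)
  j <- ifelse(j >= i, j + 1L, j)            # uniform over j != i
  key <- (i - 1L) * n_dyads + j
  tab <- table(key)
  k <- as.integer(names(tab))
  data.frame(i = (k - 1L) %/% n_dyads + 1L, j = (k - 1L) %% n_dyads + 1L,
             mult = as.integer(tab))
}

#' Wavelet coherence spectra for a study cohort
#'
#' For every dyad and channel pair, computes the time-averaged wavelet
#' coherence spectrum over the task window (real pairings), and optionally a
#' permutation null in which subject-1 signals are re-paired with randomly
#' chosen non-partner subject-2 signals and pushed through the identical
#' coherence path. Transforms and smoothed auto-spectra are computed once
#' per subject channel and shared between the real and null pairings;
#' duplicate null pairings are computed once and weighted by multiplicity.
#'
#' @param ds a `study_dataset` with hemodynamic-level signals.
#' @param pairs channel-pair indices to analyse.
#' @param window task window in seconds (`NULL` = whole recording).
#' @param n_perm permutation samples (0 skips the null).
#' @param seed RNG seed for the pairing draw.
#' @param voices,f_range,omega0 passed to [cwt_plan()]. The cohort path
#'   defaults to `omega0 = 8`: the selection stage resolves individual
#'   bins at `1/voices` octave spacing, and the Morlet spectral width at
#'   the conventional `omega0 = 6` (~0.24 octave) smears band edges across
#'   several bins; `omega0 = 8` trades some time resolution for the
#'   frequency selectivity that per-bin selection requires.
#' @param scale_smooth_octaves smoothing across scales. The cohort path
#'   defaults to 0 (time-only smoothing): the selection stage tests
#'   individual frequency bins, and smoothing across scale blurs exactly
#'   the frequency resolution that the bin mask is meant to capture. The
#'   standalone [wtc()] estimator keeps the conventional 0.6-octave boxcar.
#' @param trim_coi drop frequency bins whose usable in-COI span is too
#'   short to estimate a time-averaged coherence at this recording length
#'   (default here, since such bins carry no usable data).
#' @return object of class `cohort_coherence`: per pair, the real spectra
#'   matrix (dyads x bins) and the null spectra with multiplicities, plus
#'   the frequency grid.
#' @export
cohort_coherence <- function(ds, pairs = seq_len(ds$n_pairs), window = NULL,
                             n_perm = 1000L, seed = 1L, voices = 12,
                             f_range = c(0.01, 0.7), omega0 = 8,
                             scale_smooth_octaves = 0, trim_coi = TRUE) {
  stopifnot(inherits(ds, "study_dataset"))
  n_dyads <- length(ds$dyads)
  plan <- cwt_plan(ds$n, ds$fs, omega0 = omega0, voices = voices,
                   f_range = f_range,
                   scale_smooth_octaves = scale_smooth_octaves,
                   trim_coi = trim_coi)
  win_keep <- NULL
  if (!is.null(window)) {
    tt <- (seq_len(ds$n) - 1L) / ds$fs
    keep <- tt >= window[1] & tt < window[2]
    if (!any(keep)) stop("empty task window: no samples in [start, end)")
    win_keep <- keep
  }
  perm <- if (n_perm > 0L)
    with_seed(seed, sample_null_pairings(n_dyads, n_perm)) else NULL

  real <- vector("list", length(pairs))
  null <- vector("list", length(pairs))
  for (pi in seq_along(pairs)) {
    p <- pairs[pi]
    W1 <- vector("list", n_dyads); S1 <- vector("list", n_dyads)
    W2 <- vector("list", n_dyads); S2 <- vector("list", n_dyads)
    for (d in seq_len(n_dyads)) {
      W1[[d]] <- cwt_apply(dyad_signal(ds, d, 1L)[, p], plan, prescaled = TRUE)
      S1[[d]] <- auto_spectrum(W1[[d]], plan, prescaled = TRUE)
      W2[[d]] <- cwt_apply(dyad_signal(ds, d, 2L)[, p], plan, prescaled = TRUE)
      S2[[d]] <- auto_spectrum(W2[[d]], plan, prescaled = TRUE)
    }
    rmat <- t(vapply(seq_len(n_dyads), function(d)
      pair_bin_means(W1[[d]], W2[[d]], S1[[d]], S2[[d]], plan, win_keep),
      numeric(plan$ns)))
    real[[pi]] <- rmat
    if (!is.null(perm)) {
      nmat <- t(vapply(seq_len(nrow(perm)), function(r)
        pair_bin_means(W1[[perm$i[r]]], W2[[perm$j[r]]],
                       S1[[perm$i[r]]], S2[[perm$j[r]]], plan, win_keep),
        numeric(plan$ns)))
      null[[pi]] <- list(spectra = nmat, mult = perm$mult,
                         pairings = perm[, c("i", "j")])
    }
  }
  structure(list(real = real, null = null, pairs = pairs, freq = plan$freq,
                 window = window, n_perm = n_perm, seed = seed,
                 groups = ds$groups, n_dyads = n_dyads),
            class = "cohort_coherence")
}

#' @export
print.cohort_coherence <- function(x, ...) {
  cat(sprintf("cohort_coherence: %d dyads x %d channel pairs, %d bins (%.3g-%.3g Hz), %d permutations\n",
              x$n_dyads, length(x$pairs), length(x$freq), min(x$freq),
              max(x$freq), x$n_perm))
  invisible(x)
}

#' Permutation null for inter-brain coherence
#'
#' Builds `n_perm` shuffled-pair coherence spectra per channel pair: each
#' null sample pairs a subject-1 signal with a non-partner subject-2 signal
#' (never the true partner) and recomputes the time-averaged coherence
#' spectrum through the identical path as the real dyads. The draw is
#' uniform over ordered non-partner pairings; repeated pairings are recorded
#' with their multiplicity.
#'
#' @inheritParams cohort_coherence
#' @return object of class `permutation_null`: per channel pair, the
#'   distinct null spectra, multiplicities and pairings.
#' @export
build_null <- function(ds, n_perm = 1000L, seed = 1L,
                       pairs = seq_len(ds$n_pairs), window = NULL,
                       voices = 12, f_range = c(0.01, 0.7), omega0 = 8) {
  if (length(ds$dyads) < 2L)
    stop("permutation null needs at least 2 dyads (no non-partner available)")
  coh <- cohort_coherence(ds, pairs = pairs, window = window, n_perm = n_perm,
                          seed = seed, voices = voices, f_range = f_range,
                          omega0 = omega0)
  structure(list(null = coh$null, pairs = pairs, freq = coh$freq,
                 n_perm = n_perm, seed = seed, scheme = "shuffled non-partner pairing"),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("permutation_null: %d samples (%d distinct pairings), %d channel pairs, scheme '%s'\n",
              x$n_perm, nrow(x$null[[1]]$spectra), length(x$pairs), x$scheme))
  invisible(x)
}

# expand a null spectra matrix by pairing multiplicity
expand_null <- function(null_p) {
  null_p$spectra[rep(seq_len(nrow(null_p$spectra)), null_p$mult), , drop = FALSE]
}

#' Select task-related frequency bins against the permutation null
#'
#' Per frequency bin, an independent two-sample t-test (classical pooled
#' variance by default; Welch via `var_equal = FALSE`) compares the real
#' dyads' coherence values with the null sample's; bins where the real
#' coherence is significantly elevated (one-sided, `p < alpha`) are
#' selected as task-related. The test is applied to Fisher-z-transformed
#' coherence by default: `atanh` is the variance-stabilizing transform for
#' coherence, removes the right skew of bounded values that otherwise
#' makes the one-sided t conservative, and matches the scale on which the
#' pipeline's IBS statistic lives. A two-sided test is available for
#' exploratory use. Bins with missing data on either side are never
#' selected.
#'
#' @param real numeric matrix of real spectra (dyads x bins).
#' @param null a per-pair null component (as stored in
#'   [cohort_coherence()] / [build_null()] objects): list with `spectra` and
#'   `mult`.
#' @param alpha selection level.
#' @param alternative `"greater"` (task-related = elevated coherence,
#'   default) or `"two.sided"`.
#' @param var_equal pooled-variance t-test (default) or Welch.
#' @param transform scale on which the t-test runs: Fisher z (default) or
#'   raw coherence.
#' @return object of class `bin_selection`: logical `mask`, per-bin
#'   `p_value`, and the settings used. An empty mask triggers a warning but
#'   is not an error.
#' @export
select_bins <- function(real, null, alpha = 0.05,
                        alternative = c("greater", "two.sided"),
                        var_equal = TRUE,
                        transform = c("fisher_z", "none")) {
  alternative <- match.arg(alternative)
  transform <- match.arg(transform)
  nullmat <- expand_null(null)
  nb <- ncol(real)
  stopifnot(ncol(nullmat) == nb)
  if (transform == "fisher_z") {
    real <- atanh(pmin(real, 1 - 1e-6))
    nullmat <- atanh(pmin(nullmat, 1 - 1e-6))
  }
  p <- rep(NA_real_, nb)
  for (b in seq_len(nb)) {
    rv <- real[, b]; nv <- nullmat[, b]
    rv <- rv[!is.na(rv)]; nv <- nv[!is.na(nv)]
    if (length(rv) < 2L || length(nv) < 2L) next
    if (stats::sd(rv) < 1e-15 && stats::sd(nv) < 1e-15) { p[b] <- 1; next }
    p[b] <- stats::t.test(rv, nv, alternative = alternative,
                          var.equal = var_equal)$p.value
  }
  mask <- !is.na(p) & p < alpha
  if (!any(mask))
    warning("no frequency bin selected at alpha = ", alpha)
  structure(list(mask = mask, p_value = p, alpha = alpha,
                 alternative = alternative, var_equal = var_equal,
                 transform = transform),
            class = "bin_selection")
}

#' @export
print.bin_selection <- function(x, ...) {
  cat(sprintf("bin_selection: %d / %d bins selected (alpha = %g, %s)\n",
              sum(x$mask), length(x$mask), x$alpha, x$alternative))
  invisible(x)
}

#' Fisher-z IBS from a coherence spectrum and a bin mask
#'
#' Averages coherence over the selected frequency bins and applies the
#' Fisher z transform, `z = atanh(mean coherence)`; coherence is clipped at
#' `1 - 1e-6` beforehand so the statistic is always finite.
#'
#' @param spectrum numeric vector of per-bin coherence (e.g. one row of a
#'   [cohort_coherence()] real matrix, or `time_average()$value`).
#' @param mask logical bin mask (e.g. from [select_bins()]).
#' @return IBS z value, or `NA` (with a `reason` attribute) when the mask is
#'   empty or no masked bin has data.
#' @examples
#' compute_ibs(c(0.5, 0.5), c(TRUE, TRUE))  # atanh(0.5) ~ 0.5493
#' @export
compute_ibs <- function(spectrum, mask) {
  if (inherits(spectrum, "wtc_spectrum")) spectrum <- spectrum$value
  if (inherits(mask, "bin_selection")) mask <- mask$mask
  stopifnot(length(mask) == length(spectrum))
  if (!any(mask))
    return(structure(NA_real_, reason = "empty bin mask"))
  v <- spectrum[mask]
  v <- v[!is.na(v)]
  if (!length(v))
    return(structure(NA_real_, reason = "no data in masked bins"))
  atanh(min(mean(v), 1 - 1e-6))
}

#' Full IBS stage for a cohort: coherence, bin selection, Fisher-z table
#'
#' Runs [cohort_coherence()], selects task-related bins against the
#' permutation null (per channel pair by default, or one global mask pooled
#' across pairs), and assembles the tidy IBS table with one Fisher-z value
#' per dyad and channel pair. With `n_perm = 0` the selection stage is
#' skipped and all bins with data are used (logged as a message).
#'
#' @inheritParams cohort_coherence
#' @param alpha bin-selection level.
#' @param scope `"pair"` for per-channel-pair masks (default) or `"global"`
#'   for one mask pooled across all channel pairs.
#' @param task label written into the IBS table.
#' @param alternative passed to [select_bins()].
#' @return object of class `ibs_result`: the `table` (dyad, group, task,
#'   pair, z), per-pair `selection`, and the underlying `coherence`.
#' @export
ibs_pipeline <- function(ds, pairs = seq_len(ds$n_pairs), window = NULL,
                         n_perm = 1000L, alpha = 0.05, seed = 1L,
                         scope = c("pair", "global"), task = "tangram",
                         voices = 12, f_range = c(0.01, 0.7), omega0 = 8,
                         alternative = "greater") {
  scope <- match.arg(scope)
  coh <- cohort_coherence(ds, pairs = pairs, window = window, n_perm = n_perm,
                          seed = seed, voices = voices, f_range = f_range,
                          omega0 = omega0)
  np <- length(pairs)
  selections <- vector("list", np)
  if (n_perm == 0L) {
    message("n_perm = 0: bin selection skipped, using all bins with data")
    for (pi in seq_len(np)) {
      mask <- colSums(!is.na(coh$real[[pi]])) > 0
      selections[[pi]] <- structure(list(mask = mask,
                                         p_value = rep(NA_real_, length(mask)),
                                         alpha = alpha, alternative = "none"),
                                    class = "bin_selection")
    }
  } else if (scope == "global") {
    real_all <- do.call(rbind, coh$real)
    null_all <- list(spectra = do.call(rbind, lapply(coh$null, `[[`, "spectra")),
                     mult = unlist(lapply(coh$null, `[[`, "mult")))
    sel <- select_bins(real_all, null_all, alpha = alpha,
                       alternative = alternative)
    for (pi in seq_len(np)) selections[[pi]] <- sel
  } else {
    for (pi in seq_len(np))
      selections[[pi]] <- select_bins(coh$real[[pi]], coh$null[[pi]],
                                      alpha = alpha, alternative = alternative)
  }

  rows <- list()
  for (pi in seq_len(np)) {
    mask <- selections[[pi]]$mask
    if (!any(mask)) {         # documented fallback: no selected bin
      mask <- colSums(!is.na(coh$real[[pi]])) > 0
    }
    z <- apply(coh$real[[pi]], 1L, compute_ibs, mask = mask)
    rows[[pi]] <- data.frame(dyad = seq_len(coh$n_dyads), group = coh$groups,
                             task = task, pair = pairs[pi], z = as.numeric(z))
  }
  structure(list(table = do.call(rbind, rows), selection = selections,
                 coherence = coh, alpha = alpha, scope = scope),
            class = "ibs_result")
}

#' @export
print.ibs_result <- function(x, ...) {
  cat(sprintf("ibs_result: %d dyads x %d channel pairs (%s-level bin masks)\n",
              x$coherence$n_dyads, length(x$coherence$pairs), x$scope))
  agg <- stats::aggregate(z ~ group + pair, data = x$table, FUN = mean)
  cat("  mean IBS z by group and pair:\n")
  print(utils::head(stats::reshape(agg, idvar = "pair", timevar = "group",
                                   direction = "wide"), 10), row.names = FALSE)
  invisible(x)
}

#' Preprocess every raw recording of a cohort
#'
#' Runs [preprocess_dyad()] on each dyad of a raw-level `study_dataset` and
#' stores the resulting HbO series as the dataset's analysis signals. A
#' homologous channel pair survives only if the channel passed QC for both
#' subjects (a pair with either member excluded is dropped for the dyad's
#' coherence analysis); only channels surviving in every dyad are kept so
#' the cohort shares a common pair set.
#'
#' @param ds a `study_dataset` generated with `level = "raw"`.
#' @param ... passed to [preprocess_dyad()].
#' @return the dataset with hemodynamic signals attached (`level` becomes
#'   `"hemo"`), with a `qc` list per dyad.
#' @export
preprocess_cohort <- function(ds, ...) {
  stopifnot(inherits(ds, "study_dataset"))
  if (ds$level != "raw")
    stop("preprocess_cohort expects a raw-level dataset")
  hemos <- lapply(ds$dyads, function(d) preprocess_dyad(d$recording, ...))
  common <- Reduce(intersect, lapply(hemos, function(h)
    intersect(h$subjects[[1]]$channels$channel, h$subjects[[2]]$channels$channel)))
  if (!length(common))
    stop("no channel pair survived preprocessing in every dyad")
  for (d in seq_along(ds$dyads)) {
    h <- hemos[[d]]
    ds$dyads[[d]]$signals <- lapply(1:2, function(s) {
      idx <- match(common, h$subjects[[s]]$channels$channel)
      h$subjects[[s]]$HbO[, idx, drop = FALSE]
    })
    ds$dyads[[d]]$qc <- h$qc
  }
  ds$level <- "hemo"
  ds$n_pairs <- length(common)
  ds$pair_channels <- common
  ds
}
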