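# Statistical stage: one-way ANOVA across groups, two-tailed post-hoc
# t-tests, Benjamini-Hochberg FDR, Kendall correlations, and the
# orchestrating full analysis.

#' One-way analysis of variance
#'
#' Classical (equal-variance) one-way ANOVA of a response across groups.
#'
#' @param values numeric response.
#' @param groups group labels (factor or character), same length.
#' @return list with `F` and `p`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- as.factor(groups)
  cnt <- table(groups[!is.na(values)])
  if (length(cnt) < 2L || any(cnt < 2L))
    stop("one-way ANOVA needs at least 2 groups with at least 2 values each")
  if (stats::var(values, na.rm = TRUE) < .Machine$double.eps)
    return(list(F = 0, p = 1))
  ft <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(F = unname(ft$statistic), p = unname(ft$p.value))
}

#' Pairwise post-hoc t-tests
#'
#' Two-sample, two-tailed t-tests for the requested group pairs; Welch by
#' default (`pooled = TRUE` gives the equal-variance test).
#'
#' @inheritParams anova_oneway
#' @param pairs list of length-2 character vectors of group labels; default
#'   all pairs.
#' @param pooled use the pooled-variance test instead of Welch.
#' @return data frame with columns `group1`, `group2`, `t`, `p`.
#' @export
posthoc_ttests <- function(values, groups, pairs = NULL, pooled = FALSE) {
  groups <- as.character(groups)
  if (is.null(pairs)) {
    gl <- sort(unique(groups))
    pairs <- utils::combn(gl, 2L, simplify = FALSE)
  }
  rows <- lapply(pairs, function(pr) {
    a <- values[groups == pr[1]]; b <- values[groups == pr[2]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L)
      stop(sprintf("post-hoc t-test needs >= 2 values per group (%s vs %s)",
                   pr[1], pr[2]))
    tt <- stats::t.test(a, b, var.equal = pooled)
    data.frame(group1 = pr[1], group2 = pr[2],
               t = unname(tt$statistic), p = unname(tt$p.value))
  })
  do.call(rbind, rows)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Standard step-up BH adjustment; the adjusted values are monotone by the
#' cumulative-minimum construction, and the rejection mask applies the
#' step-up rule at level `alpha` (reject where `q <= alpha`).
#'
#' @param pvals numeric p-values in `[0, 1]` (`NA` allowed, never rejected).
#' @param alpha FDR level.
#' @return list with `q` (adjusted values) and `reject` (logical mask).
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))$q  # all 0.03
#' @export
bh_fdr <- function(pvals, alpha = 0.05) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(pvals))
  q[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  list(q = q, reject = !is.na(q) & q <= alpha)
}

#' Kendall rank correlation
#'
#' Tie-corrected Kendall tau (tau-b) with its test p-value.
#'
#' @param x,y paired numeric vectors, `n >= 3` complete pairs.
#' @return object of class `correlation_result`: `tau`, `p`, `n`.
#' @examples
#' kendall_cor(c(1, 2, 3, 4), c(1, 3, 2, 4))$tau  # 2/3
#' @export
kendall_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    stop("Kendall correlation needs at least 3 complete pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("Kendall tau undefined: a variable is constant (all values tied)")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
  structure(list(tau = unname(stats::cor(x, y, method = "kendall")),
                 p = unname(ct$p.value), n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Kendall tau = %.3f (p = %.4g, n = %d)\n", x$tau, x$p, x$n))
  invisible(x)
}

#' Full statistical stage: group comparisons and correlations
#'
#' Reproduces the statistics pipeline on a study dataset: per channel pair,
#' one-way ANOVA of IBS across groups with two-tailed post-hoc t-tests and
#' BH-FDR correction across channel pairs; the same comparison chain for
#' each communication metric (FDR across metrics); and, for the channel
#' pairs flagged as showing atypical IBS, Kendall correlations of IBS with
#' each communication metric and with the symptom score within the affected
#' group.
#'
#' @param ibs_table tidy IBS table (columns dyad, group, pair, z), e.g. from
#'   [ibs_pipeline()].
#' @param metrics per-child metrics data frame (dyad, group, MLU, TNW, WPS,
#'   CPS), e.g. from [cohort_metrics()]; `NULL` skips the linguistic stage.
#' @param scores per-dyad behavioral scores (dyad, symptom, task_score), or
#'   `NULL`.
#' @param alpha FDR level.
#' @param fdr_on apply the FDR correction to the ANOVA p-values (default),
#'   the post-hoc p-values, or both.
#' @param correlate_group group whose children enter the correlation stage.
#' @param pooled passed to [posthoc_ttests()].
#' @return object of class `ibs_analysis` with data frames `channel_tests`,
#'   `posthoc`, `metric_tests`, and `correlations`.
#' @export
run_full_analysis <- function(ibs_table, metrics = NULL, scores = NULL,
                              alpha = 0.05,
                              fdr_on = c("anova", "posthoc", "both"),
                              correlate_group = "A", pooled = FALSE) {
  fdr_on <- match.arg(fdr_on)
  pairs <- sort(unique(ibs_table$pair))

  ch <- do.call(rbind, lapply(pairs, function(p) {
    sub <- ibs_table[ibs_table$pair == p, ]
    a <- anova_oneway(sub$z, sub$group)
    data.frame(pair = p, F = a$F, p = a$p)
  }))
  ph <- do.call(rbind, lapply(pairs, function(p) {
    sub <- ibs_table[ibs_table$pair == p, ]
    cbind(pair = p, posthoc_ttests(sub$z, sub$group, pooled = pooled))
  }))
  fa <- bh_fdr(ch$p, alpha)
  ch$q <- fa$q
  fp <- bh_fdr(ph$p, alpha)
  ph$q <- fp$q
  ch$significant <- switch(fdr_on,
    anova = fa$reject,
    posthoc = vapply(ch$pair, function(p) any(fp$reject[ph$pair == p]), TRUE),
    both = fa$reject & vapply(ch$pair, function(p) any(fp$reject[ph$pair == p]), TRUE))

  metric_tests <- NULL
  if (!is.null(metrics)) {
    mnames <- c("MLU", "TNW", "WPS", "CPS")
    metric_tests <- do.call(rbind, lapply(mnames, function(m) {
      a <- anova_oneway(metrics[[m]], metrics$group)
      data.frame(metric = m, F = a$F, p = a$p)
    }))
    fm <- bh_fdr(metric_tests$p, alpha)
    metric_tests$q <- fm$q
    metric_tests$significant <- fm$reject
  }

  correlations <- NULL
  flagged <- ch$pair[ch$significant]
  if (length(flagged) && (!is.null(metrics) || !is.null(scores))) {
    rows <- list()
    for (p in flagged) {
      sub <- ibs_table[ibs_table$pair == p &
                         ibs_table$group == correlate_group, ]
      vars <- list()
      if (!is.null(metrics)) {
        msub <- metrics[metrics$group == correlate_group, ]
        z <- sub$z[match(msub$dyad, sub$dyad)]
        for (m in c("MLU", "TNW", "WPS", "CPS"))
          vars[[m]] <- list(x = z, y = msub[[m]])
      }
      if (!is.null(scores)) {
        ssub <- scores[match(sub$dyad, scores$dyad), ]
        vars[["symptom"]] <- list(x = sub$z, y = ssub$symptom)
        if ("task_score" %in% names(ssub))
          vars[["task_score"]] <- list(x = sub$z, y = ssub$task_score)
      }
      for (vn in names(vars)) {
        k <- tryCatch(kendall_cor(vars[[vn]]$x, vars[[vn]]$y),
                      error = function(e) NULL)
        if (!is.null(k))
          rows[[length(rows) + 1L]] <- data.frame(
            pair = p, variable = vn, tau = k$tau, p = k$p, n = k$n)
      }
    }
    correlations <- if (length(rows)) do.call(rbind, rows) else NULL
  }

  structure(list(channel_tests = ch, posthoc = ph,
                 metric_tests = metric_tests, correlations = correlations,
                 alpha = alpha, fdr_on = fdr_on,
                 correlate_group = correlate_group),
            class = "ibs_analysis")
}

#' @export
print.ibs_analysis <- function(x, ...) {
  cat(sprintf("ibs_analysis: %d channel pairs tested, %d significant after BH-FDR (alpha = %g, on %s p-values)\n",
              nrow(x$channel_tests), sum(x$channel_tests$significant),
              x$alpha, x$fdr_on))
  if (any(x$channel_tests$significant)) {
    print(x$channel_tests[x$channel_tests$significant, ], row.names = FALSE)
  }
  if (!is.null(x$metric_tests)) {
    cat("communication metrics:\n")
    print(x$metric_tests, row.names = FALSE)
  }
  if (!is.null(x$correlations)) {
    cat(sprintf("Kendall correlations (group %s, flagged channels):\n",
                x$correlate_group))
    print(x$correlations, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.ibs_analysis <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
plot.ibs_analysis <- function(x, ibs_table = NULL, ...) {
  if (is.null(ibs_table))
    stop("supply the ibs_table used for the analysis")
  flagged <- x$channel_tests$pair[x$channel_tests$significant]
  p <- if (length(flagged)) flagged[1] else x$channel_tests$pair[1]
  sub <- ibs_table[ibs_table$pair == p, ]
  graphics::boxplot(z ~ group, data = sub,
                    main = sprintf("IBS z by group, channel pair %s", p),
                    xlab = "group", ylab = "IBS (Fisher z)", ...)
  invisible(x)
}
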