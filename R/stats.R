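#' Normality-gated two-group comparison
#'
#' Compares two independent samples of a biomarker the way cohort results
#' are compared: each group is first checked for normality (Shapiro-Wilk at
#' `alpha_normality`); if both pass, an unpaired two-sided t-test is used,
#' otherwise an unpaired Wilcoxon rank-sum (Mann-Whitney) test. Group means
#' and standard deviations are always reported.
#'
#' The nonparametric branch uses the rank-sum test for independent groups
#' (a signed-rank test is a paired procedure and does not apply to unpaired
#' cohorts); the branch taken is recorded in the result.
#'
#' @param a,b Numeric samples (each of size >= 3).
#' @param alpha Significance level for the comparison.
#' @param alpha_normality Level of the per-group Shapiro-Wilk gate.
#' @param labels Group labels, length 2.
#' @return Object of class `group_comparison`: labels, per-group `mean`/`sd`,
#'   `test` ("t" or "wilcoxon"), `normal` (per-group gate results),
#'   `statistic`, `p_value`, `significant`, `alpha`.
#' @export
compare_groups <- function(a, b, alpha = 0.05, alpha_normality = 0.05,
                           labels = c("A", "B")) {
  if (length(a) < 3 || length(b) < 3)
    stop("each sample must contain at least 3 observations")
  norm_ok <- function(x) {
    if (stats::sd(x) == 0) return(FALSE)   # degenerate: not testably normal
    stats::shapiro.test(x)$p.value >= alpha_normality
  }
  na <- norm_ok(a); nb <- norm_ok(b)
  if (identical(a, b)) {
    # identical samples: no evidence of difference by construction
    test <- "t"; stat <- 0; p <- 1
  } else if (na && nb) {
    ht <- stats::t.test(a, b, var.equal = FALSE)
    test <- "t"; stat <- unname(ht$statistic); p <- ht$p.value
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    test <- "wilcoxon"; stat <- unname(ht$statistic); p <- ht$p.value
  }
  structure(list(labels = labels,
                 mean = c(mean(a), mean(b)), sd = c(stats::sd(a), stats::sd(b)),
                 n = c(length(a), length(b)),
                 test = test, normal = c(na, nb),
                 statistic = stat, p_value = p,
                 significant = p < alpha, alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %.4g +/- %.4g (n=%d)  vs  %s: %.4g +/- %.4g (n=%d)\n",
              x$labels[1], x$mean[1], x$sd[1], x$n[1],
              x$labels[2], x$mean[2], x$sd[2], x$n[2]))
  cat(sprintf("  %s test: statistic %.4g, p = %.4g (%ssignificant at alpha = %g)\n",
              ifelse(x$test == "t", "unpaired t", "rank-sum"),
              x$statistic, x$p_value, ifelse(x$significant, "", "not "),
              x$alpha))
  invisible(x)
}

#' Inter-day repeatability of aligned profiles
#'
#' All pairwise Pearson correlation coefficients and root-mean-square
#' deviations between two or more time series on the same time base, with
#' their mean and sd, as used to characterize measurement repeatability.
#'
#' @param profiles List (>= 2) of equal-length numeric vectors, or
#'   [intensity_profile()] objects on one time base.
#' @return Object of class `repeatability_result`: data.frame `pairs`
#'   (`i`, `j`, `pearson`, `rmsd`) and `summary` (mean/sd of each metric).
#' @export
repeatability <- function(profiles) {
  ys <- lapply(profiles, function(p)
    if (inherits(p, "intensity_profile")) p$intensity else as.numeric(p))
  if (length(ys) < 2) stop("repeatability needs at least two profiles")
  n <- unique(vapply(ys, length, integer(1)))
  if (length(n) != 1) stop("profiles must have equal length (aligned time base)")
  idx <- utils::combn(length(ys), 2)
  pairs <- data.frame(i = idx[1, ], j = idx[2, ], pearson = NA_real_,
                      rmsd = NA_real_)
  for (k in seq_len(ncol(idx))) {
    a <- ys[[idx[1, k]]]; b <- ys[[idx[2, k]]]
    pairs$pearson[k] <- stats::cor(a, b)
    pairs$rmsd[k] <- sqrt(mean((a - b)^2))
  }
  structure(list(pairs = pairs,
                 summary = c(pearson_mean = mean(pairs$pearson),
                             pearson_sd = stats::sd(pairs$pearson),
                             rmsd_mean = mean(pairs$rmsd),
                             rmsd_sd = stats::sd(pairs$rmsd))),
            class = "repeatability_result")
}

#' @export
print.repeatability_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("repeatability over %d pairs: Pearson r %.3f +/- %.3f, RMSD %.4g +/- %.4g\n",
              nrow(x$pairs), s["pearson_mean"],
              ifelse(is.na(s["pearson_sd"]), 0, s["pearson_sd"]),
              s["rmsd_mean"], ifelse(is.na(s["rmsd_sd"]), 0, s["rmsd_sd"])))
  invisible(x)
}
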