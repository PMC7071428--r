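# Observed vs estimated per-child time-use comparison: per-child class
# shares, median differences with bootstrap 90% CIs, and nonparametric
# TOST equivalence at a chosen margin.

#' Per-child percentage of time in each intensity class
#'
#' Computes, per child and per source, the percentage of valid epochs in
#' each intensity class. Epochs missing in either source are excluded
#' from both denominators so the shares stay comparable.
#'
#' @param observed data.frame with columns child_id, epoch_index,
#'   intensity (direct observation)
#' @param estimated same layout (classifier output)
#' @return data.frame with columns child_id, class, observed_pct,
#'   estimated_pct; children without valid epochs are excluded with a
#'   warning
#' @export
timeShares <- function(observed, estimated) {
  obs <- as.data.frame(observed); est <- as.data.frame(estimated)
  out <- NULL
  for (ch in unique(obs$child_id)) {
    o <- obs[obs$child_id == ch, ]
    e <- est[est$child_id == ch, ]
    m <- merge(o[, c("epoch_index", "intensity")],
               e[, c("epoch_index", "intensity")],
               by = "epoch_index", suffixes = c("_obs", "_est"))
    m <- m[!is.na(m$intensity_obs) & !is.na(m$intensity_est), ]
    if (nrow(m) == 0L) {
      warning("child ", ch, " has no valid epochs; excluded")
      next
    }
    for (cl in INTENSITY_CLASSES) {
      out <- rbind(out, data.frame(
        child_id = ch, class = cl,
        observed_pct = 100 * mean(m$intensity_obs == cl),
        estimated_pct = 100 * mean(m$intensity_est == cl)))
    }
  }
  rownames(out) <- NULL
  out
}

#' Nonparametric TOST equivalence test on paired differences
#'
#' Two one-sided exact Wilcoxon signed-rank tests of the hypotheses that
#' the median paired difference lies beyond -delta (lower) or +delta
#' (upper); the TOST p-value is the larger of the two one-sided p-values
#' and equivalence is declared when it falls below \code{alpha}. The
#' median difference is reported with a percentile-bootstrap 90\% CI.
#'
#' @param diffs per-child paired differences (estimated - observed, in
#'   percentage points); negative values indicate underestimation
#' @param delta equivalence margin (> 0, percentage points)
#' @param alpha significance level
#' @param nBoot bootstrap replicates for the median CI
#' @param seed integer seed for the bootstrap
#' @param method \code{"wilcoxon"} (signed rank) or \code{"sign"} test
#' @return list with median_difference, ci90 (length 2), p_value,
#'   p_lower, p_upper, equivalent, delta, n
#' @export
tostEquivalence <- function(diffs, delta, alpha = 0.05, nBoot = 2000L,
                            seed = 1L, method = c("wilcoxon", "sign")) {
  method <- match.arg(method)
  d <- diffs[!is.na(diffs)]
  stopifnot(length(d) >= 5L, delta > 0)
  if (method == "wilcoxon") {
    pLower <- suppressWarnings(
      stats::wilcox.test(d + delta, alternative = "greater",
                         mu = 0, exact = NULL)$p.value)
    pUpper <- suppressWarnings(
      stats::wilcox.test(d - delta, alternative = "less",
                         mu = 0, exact = NULL)$p.value)
  } else {
    nL <- sum((d + delta) != 0)
    pLower <- stats::binom.test(sum(d + delta > 0), nL,
                                alternative = "greater")$p.value
    nU <- sum((d - delta) != 0)
    pUpper <- stats::binom.test(sum(d - delta < 0), nU,
                                alternative = "greater")$p.value
  }
  p <- max(pLower, pUpper)
  set.seed(seed)
  if (length(unique(d)) == 1L) {
    ci <- rep(d[1L], 2L)
  } else {
    boots <- replicate(nBoot, stats::median(sample(d, replace = TRUE)))
    ci <- stats::quantile(boots, c(0.05, 0.95), names = FALSE)
  }
  list(median_difference = stats::median(d), ci90 = ci, p_value = p,
       p_lower = pLower, p_upper = pUpper, equivalent = p < alpha,
       delta = delta, n = length(d))
}

#' Full equivalence analysis over intensity classes
#'
#' Runs \code{\link{tostEquivalence}} per intensity class at each margin.
#'
#' @param shares data.frame from \code{\link{timeShares}}
#' @param deltas equivalence margins in percentage points
#' @param alpha significance level
#' @param nBoot,seed bootstrap settings
#' @return data.frame with one row per class x delta
#' @export
equivalenceAnalysis <- function(shares, deltas = c(10, 20), alpha = 0.05,
                                nBoot = 2000L, seed = 1L) {
  out <- NULL
  for (cl in unique(shares$class)) {
    d <- shares$estimated_pct[shares$class == cl] -
      shares$observed_pct[shares$class == cl]
    for (delta in deltas) {
      r <- tostEquivalence(d, delta, alpha = alpha, nBoot = nBoot,
                           seed = seed)
      out <- rbind(out, data.frame(
        class = cl, delta = delta,
        median_difference = r$median_difference,
        ci90_low = r$ci90[1L], ci90_high = r$ci90[2L],
        p_value = r$p_value, equivalent = r$equivalent, n = r$n))
    }
  }
  out
}
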