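# Synthetic "study": epoch-level vector-magnitude data with
# direct-observation labels for a cohort of children, used to exercise
# the classifier and equivalence layers at desk scale.

#' Simulate an epoch-level activity study
#'
#' Generates labelled 5-s epochs for a cohort: per child, intensity
#' labels are drawn with cohort-level proportions (jittered per child via
#' a Dirichlet-like draw) and vector-magnitude values are drawn from
#' class-conditional lognormal distributions with ordered means
#' (SED < LPA < MVPA) and moderate overlap. The default geometric means
#' (15, 60, 200 VM units) and common log-sd 0.5 put the pairwise
#' class confusion (probability mass beyond the midpoint between
#' adjacent class means on the log scale) near 10 percent.
#'
#' A synthetic second rater is derived for reliability checks by
#' re-scoring a fraction of epochs one class up or down.
#'
#' @param nChildren number of children
#' @param epochsPerChild epochs per child (60 = the first 5 min at 5-s
#'   epochs)
#' @param seed integer seed
#' @param classProbs cohort mean class proportions (SED, LPA, MVPA)
#' @param meanlog per-class lognormal location parameters
#' @param sdlog common lognormal scale parameter
#' @param childJitter concentration of the per-child proportion jitter
#'   (larger = children more alike)
#' @return data.frame with columns child_id, epoch_index, vm_value,
#'   intensity, weighted_score (a CARS-consistent score inside the class
#'   interval), rater_b_score
#' @export
simulateStudy <- function(nChildren = 10L, epochsPerChild = 60L, seed = 1L,
                          classProbs = c(SED = 0.28, LPA = 0.41,
                                         MVPA = 0.31),
                          meanlog = c(SED = log(15), LPA = log(60),
                                      MVPA = log(200)),
                          sdlog = 0.5, childJitter = 60) {
  set.seed(seed)
  classes <- INTENSITY_CLASSES
  out <- NULL
  for (ch in seq_len(nChildren)) {
    # per-child proportions: normalized gamma draw (Dirichlet)
    g <- stats::rgamma(3L, shape = classProbs * childJitter)
    p <- g / sum(g)
    lab <- sample(classes, epochsPerChild, replace = TRUE, prob = p)
    vm <- stats::rlnorm(epochsPerChild, meanlog = meanlog[lab],
                        sdlog = sdlog)
    # a CARS-style weighted score consistent with the label
    score <- stats::runif(epochsPerChild,
                          min = c(SED = 1, LPA = 2, MVPA = 3)[lab],
                          max = c(SED = 1.99, LPA = 2.99, MVPA = 4)[lab])
    # second rater: nudge 8% of epochs by +/- 0.3 score units
    nudge <- stats::rbinom(epochsPerChild, 1L, 0.08) *
      sample(c(-0.3, 0.3), epochsPerChild, replace = TRUE)
    raterB <- pmin(4, pmax(1, score + nudge))
    out <- rbind(out, data.frame(
      child_id = ch, epoch_index = seq_len(epochsPerChild),
      vm_value = vm, intensity = lab, weighted_score = score,
      rater_b_score = raterB))
  }
  out
}

#' Pairwise class confusion of the study generator
#'
#' Analytic probability that a draw from one class's lognormal falls
#' beyond the log-scale midpoint toward the adjacent class, for the
#' generator's parameters; a calibration check that the simulated
#' class overlap stays moderate.
#'
#' @param meanlog per-class lognormal locations
#' @param sdlog common lognormal scale
#' @return named vector of adjacent-class confusion probabilities
#' @export
studyClassConfusion <- function(meanlog = c(SED = log(15), LPA = log(60),
                                            MVPA = log(200)),
                                sdlog = 0.5) {
  mid12 <- (meanlog[1L] + meanlog[2L]) / 2
  mid23 <- (meanlog[2L] + meanlog[3L]) / 2
  c(SED_as_LPA = stats::pnorm(mid12, meanlog[1L], sdlog,
                              lower.tail = FALSE),
    LPA_as_SED = stats::pnorm(mid12, meanlog[2L], sdlog),
    LPA_as_MVPA = stats::pnorm(mid23, meanlog[2L], sdlog,
                               lower.tail = FALSE),
    MVPA_as_LPA = stats::pnorm(mid23, meanlog[3L], sdlog))
}
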