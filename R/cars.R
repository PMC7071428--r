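# Direct-observation layer: second-by-second CARS activity codes
# (1 lying/sitting, 2 standing, 3 walking, 4 running/jumping, 5 not in
# frame), frequency-weighted reintegration into 5-s epochs, intensity
# recoding, and inter-rater ICC.

#' Recode a weighted CARS score into an intensity class
#'
#' Cut points: sedentary (SED) < 2; light (LPA) 2 to 2.99;
#' moderate-vigorous (MVPA) >= 3.
#'
#' @param score numeric weighted CARS score(s)
#' @return character vector of \code{"SED"}, \code{"LPA"}, \code{"MVPA"}
#' @export
intensityFromScore <- function(score) {
  ifelse(score < 2, "SED", ifelse(score < 3, "LPA", "MVPA"))
}

#' Reintegrate second-by-second CARS codes into 5-s epochs
#'
#' Within each epoch every activity code is weighted by its frequency of
#' occurrence and the mean taken (equivalently, the arithmetic mean of
#' the scored seconds). Seconds coded 5 (not in frame) are dropped from
#' the mean; an epoch whose seconds are all code 5 is missing.
#'
#' @param records data.frame with columns child_id, second, code
#'   (codes in 1..5); \code{second} is 1-based
#' @param epochS epoch length in seconds
#' @return data.frame with columns child_id, epoch_index, weighted_score,
#'   intensity, n_scored_seconds (score and intensity are \code{NA} for
#'   all-code-5 epochs)
#' @export
reintegrateCars <- function(records, epochS = 5L) {
  rec <- as.data.frame(records)
  stopifnot(all(c("child_id", "second", "code") %in% names(rec)))
  if (nrow(rec) == 0L) return(data.frame())
  if (!all(rec$code %in% 1:5)) stop("CARS codes must be in 1..5")
  rec$epoch_index <- (rec$second - 1L) %/% epochS + 1L
  out <- NULL
  for (ch in unique(rec$child_id)) {
    sub <- rec[rec$child_id == ch, ]
    for (e in sort(unique(sub$epoch_index))) {
      codes <- sub$code[sub$epoch_index == e]
      scored <- codes[codes != 5L]
      n <- length(scored)
      if (n == 0L) {
        score <- NA_real_; intensity <- NA_character_
      } else {
        freq <- table(scored)
        score <- sum(as.numeric(names(freq)) * as.numeric(freq)) /
          sum(freq)
        intensity <- intensityFromScore(score)
      }
      out <- rbind(out, data.frame(
        child_id = ch, epoch_index = e, weighted_score = score,
        intensity = intensity, n_scored_seconds = n))
    }
  }
  rownames(out) <- NULL
  out
}

#' Inter-rater intraclass correlation, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC on
#' paired epoch-level scores, computed from the ANOVA mean squares:
#' rows = epochs (subjects), columns = raters.
#'
#' @param raterA,raterB equal-length numeric score vectors (>= 2 epochs)
#' @return the ICC estimate; \code{NA} with a warning when both raters
#'   have zero variance
#' @export
carsIcc <- function(raterA, raterB) {
  stopifnot(length(raterA) == length(raterB), length(raterA) >= 2L)
  ok <- !is.na(raterA) & !is.na(raterB)
  a <- raterA[ok]; b <- raterB[ok]
  n <- length(a); k <- 2L
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    warning("zero variance in both raters; ICC undefined")
    return(NA_real_)
  }
  dat <- matrix(c(a, b), ncol = k)
  grand <- mean(dat)
  rowM <- rowMeans(dat); colM <- colMeans(dat)
  ssr <- k * sum((rowM - grand)^2)           # between subjects
  ssc <- n * sum((colM - grand)^2)           # between raters
  sse <- sum((dat - outer(rowM, rep(1, k)) -
                outer(rep(1, n), colM) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Read a CARS code CSV
#'
#' @param path CSV with columns child_id, second, code
#' @return data.frame
#' @export
readCarsCsv <- function(path) {
  tab <- utils::read.csv(path)
  stopifnot(all(c("child_id", "second", "code") %in% names(tab)))
  tab
}
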