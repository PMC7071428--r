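# Single-feature CART intensity classifiers and their evaluation.
# The vector magnitude is the sole predictor. "onevsall" trains three
# binary trees (each class against the other two combined); "multiclass"
# trains one tree on all three classes at once.

INTENSITY_CLASSES <- c("SED", "LPA", "MVPA")

#' Train a CART intensity classifier
#'
#' Gini-impurity CART grown on the vector magnitude only (via rpart with
#' cp = 0, no pruning). Leaves carry class posterior proportions.
#' Deterministic given the data and hyperparameters.
#'
#' @param epochs data.frame with columns vm_value and intensity
#'   (\code{"SED"}, \code{"LPA"}, \code{"MVPA"})
#' @param mode \code{"onevsall"} or \code{"multiclass"}
#' @param minLeaf minimum epochs per leaf
#' @param maxDepth maximum tree depth
#' @return an \linkS4class{IntensityModel}
#' @export
trainIntensityModel <- function(epochs, mode = c("onevsall", "multiclass"),
                                minLeaf = 20L, maxDepth = 8L) {
  mode <- match.arg(mode)
  dat <- as.data.frame(epochs)
  stopifnot(all(c("vm_value", "intensity") %in% names(dat)))
  dat <- dat[!is.na(dat$vm_value) & !is.na(dat$intensity), ]
  if (length(unique(dat$intensity)) < 2L)
    stop("training data must contain at least two classes")
  ctl <- rpart::rpart.control(minbucket = minLeaf, minsplit = 2L * minLeaf,
                              cp = 0, maxdepth = maxDepth, xval = 0L)
  present <- intersect(INTENSITY_CLASSES, unique(dat$intensity))
  fits <- list()
  if (mode == "onevsall") {
    for (cl in present) {
      y <- factor(ifelse(dat$intensity == cl, cl, "rest"),
                  levels = c("rest", cl))
      fits[[cl]] <- rpart::rpart(y ~ vm_value,
                                 data = data.frame(y = y,
                                                   vm_value = dat$vm_value),
                                 method = "class", control = ctl,
                                 parms = list(split = "gini"))
    }
  } else {
    y <- factor(dat$intensity, levels = present)
    fits[["multiclass"]] <- rpart::rpart(
      y ~ vm_value, data = data.frame(y = y, vm_value = dat$vm_value),
      method = "class", control = ctl, parms = list(split = "gini"))
  }
  new("IntensityModel", mode = mode, fits = fits, classes = present,
      params = list(min_leaf = minLeaf, max_depth = maxDepth))
}

#' Per-class posterior scores of an intensity model
#'
#' @param model an \linkS4class{IntensityModel}
#' @param vm numeric vector of vector-magnitude values
#' @return matrix (length(vm) x classes) of leaf posterior probabilities
#' @export
predictScores <- function(model, vm) {
  nd <- data.frame(vm_value = vm)
  out <- matrix(NA_real_, length(vm), length(model@classes),
                dimnames = list(NULL, model@classes))
  if (model@mode == "onevsall") {
    for (cl in model@classes)
      out[, cl] <- predict(model@fits[[cl]], nd)[, cl]
  } else {
    p <- predict(model@fits[["multiclass"]], nd)
    out[, colnames(p)] <- p
  }
  out
}

#' Hard class labels of an intensity model
#'
#' One-vs-all models label each epoch with the class of highest binary
#' posterior; multiclass models use the tree's own majority leaf class.
#'
#' @param model an \linkS4class{IntensityModel}
#' @param vm numeric vector of vector-magnitude values
#' @return character vector of class labels
#' @export
predictLabels <- function(model, vm) {
  sc <- predictScores(model, vm)
  model@classes[max.col(sc, ties.method = "first")]
}

#' Rank-statistic AUC
#'
#' Probability that a random positive outranks a random negative, with
#' half-credit for ties (the Mann-Whitney formulation, computed from
#' ranks).
#'
#' @param scores numeric scores, higher = more positive
#' @param positive logical vector marking the positive class
#' @return AUC in [0, 1], \code{NA} if either class is empty
#' @export
aucRank <- function(scores, positive) {
  positive <- as.logical(positive)
  nPos <- sum(positive); nNeg <- sum(!positive)
  if (nPos == 0L || nNeg == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Evaluate an intensity classifier
#'
#' Per class: one-vs-rest AUC from the leaf posterior scores, percentile
#' bootstrap 95\% confidence interval over epoch resampling, and
#' sensitivity/specificity at the model's hard labels. Multiclass models
#' additionally report the confusion matrix.
#'
#' @param model an \linkS4class{IntensityModel}
#' @param epochs data.frame with columns vm_value and intensity
#' @param nBoot bootstrap replicates
#' @param seed integer seed for the bootstrap
#' @return an \linkS4class{EvaluationReport}
#' @export
evaluateIntensityModel <- function(model, epochs, nBoot = 2000L,
                                   seed = 1L) {
  dat <- as.data.frame(epochs)
  dat <- dat[!is.na(dat$vm_value) & !is.na(dat$intensity), ]
  scores <- predictScores(model, dat$vm_value)
  labels <- predictLabels(model, dat$vm_value)
  set.seed(seed)
  per <- NULL
  for (cl in model@classes) {
    pos <- dat$intensity == cl
    if (sum(pos) == 0L || sum(!pos) == 0L) {
      per <- rbind(per, data.frame(
        class = cl, auc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        sensitivity = NA_real_, specificity = NA_real_,
        n_pos = sum(pos), n_neg = sum(!pos)))
      next
    }
    auc <- aucRank(scores[, cl], pos)
    boots <- replicate(nBoot, {
      idx <- sample.int(nrow(dat), replace = TRUE)
      aucRank(scores[idx, cl], pos[idx])
    })
    ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE,
                          names = FALSE)
    predPos <- labels == cl
    sens <- sum(predPos & pos) / sum(pos)
    spec <- sum(!predPos & !pos) / sum(!pos)
    per <- rbind(per, data.frame(
      class = cl, auc = auc, ci_low = ci[1L], ci_high = ci[2L],
      sensitivity = sens, specificity = spec,
      n_pos = sum(pos), n_neg = sum(!pos)))
  }
  conf <- matrix(0L, 0L, 0L)
  if (model@mode == "multiclass") {
    conf <- table(factor(dat$intensity, levels = model@classes),
                  factor(labels, levels = model@classes))
    conf <- unclass(as.matrix(conf))
  }
  new("EvaluationReport", perClass = per, confusion = conf,
      params = list(n_boot = nBoot, seed = seed, n = nrow(dat)))
}

#' Serialize an intensity model to JSON
#'
#' Writes the split structure (variable, threshold, leaf posteriors) of
#' every tree in the model.
#'
#' @param model an \linkS4class{IntensityModel}
#' @param path output JSON file
#' @export
writeIntensityModel <- function(model, path) {
  trees <- lapply(model@fits, function(fit) {
    fr <- fit$frame
    nodes <- data.frame(node = as.integer(rownames(fr)),
                        var = as.character(fr$var), n = fr$n)
    splits <- if (!is.null(fit$splits))
      data.frame(variable = rownames(fit$splits),
                 threshold = fit$splits[, "index"]) else NULL
    list(nodes = nodes, splits = splits,
         text = utils::capture.output(print(fit)))
  })
  out <- list(mode = model@mode, classes = model@classes,
              params = model@params, trees = trees)
  jsonlite::write_json(out, path, auto_unbox = TRUE, force = TRUE)
  invisible(path)
}
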