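test_that("rank AUC equals brute-force pair counting", {
  set.seed(5)
  for (rep in 1:5) {
    n <- sample(20:200, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # with ties
    pos <- runif(n) < 0.4
    if (!any(pos) || all(pos)) next
    expect_equal(aucRank(scores, pos), oracleAuc(scores, pos))
  }
  # 4 vs 4 with exactly one discordant pair -> 15/16
  scores <- c(4, 3, 2.6, 1.5, 2.5, 1.2, 1.1, 1.0)
  pos <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  expect_equal(aucRank(scores, pos), oracleAuc(scores, pos))
  expect_equal(aucRank(scores, pos), 15 / 16)
})

test_that("perfectly separable classes give a single root split and AUC 1", {
  set.seed(1)
  ep <- data.frame(
    vm_value = c(runif(60, 0, 10), runif(60, 20, 40), runif(60, 60, 90)),
    intensity = rep(c("SED", "LPA", "MVPA"), each = 60))
  m <- trainIntensityModel(ep, "onevsall")
  sedFit <- m@fits$SED
  split <- sedFit$splits[1, "index"]
  expect_gt(split, 10); expect_lt(split, 20)
  expect_equal(predictLabels(m, ep$vm_value), ep$intensity)

  ev <- evaluateIntensityModel(m, ep, nBoot = 200, seed = 1)
  pc <- classMetrics(ev)
  expect_equal(pc$auc, rep(1, 3))
  expect_equal(pc$ci_low, rep(1, 3))
  expect_equal(pc$ci_high, rep(1, 3))
  expect_equal(pc$sensitivity, rep(1, 3))
  expect_equal(pc$specificity, rep(1, 3))

  # multiclass on the same data: diagonal confusion matrix
  mm <- trainIntensityModel(ep, "multiclass")
  evm <- evaluateIntensityModel(mm, ep, nBoot = 100, seed = 1)
  cm <- confusionMatrix(evm)
  expect_equal(unname(diag(cm)), rep(60L, 3))
  expect_equal(sum(cm) - sum(diag(cm)), 0L)
})

test_that("single-class training data is rejected", {
  ep <- data.frame(vm_value = runif(50), intensity = "SED")
  expect_error(trainIntensityModel(ep), "two classes")
})

test_that("label-shuffled data scores near-chance AUC", {
  set.seed(9)
  ep <- data.frame(vm_value = rlnorm(600, log(50), 1),
                   intensity = sample(c("SED", "LPA", "MVPA"), 600,
                                      replace = TRUE))
  m <- trainIntensityModel(ep, "onevsall")
  ev <- evaluateIntensityModel(m, ep, nBoot = 300, seed = 2)
  pc <- classMetrics(ev)
  # resubstitution on pure noise stays near 0.5 (mild optimism allowed)
  expect_true(all(pc$auc > 0.45 & pc$auc < 0.65))
})

test_that("evaluation metrics match a printed confusion-table oracle", {
  # 2x2 fixture: TP 40, FN 10, FP 5, TN 45 at the SED-vs-rest boundary
  ep <- data.frame(
    vm_value = c(rep(1, 40), rep(100, 10), rep(2, 5), rep(90, 45)),
    intensity = c(rep("SED", 50), rep("MVPA", 50)))
  m <- trainIntensityModel(ep, "onevsall", minLeaf = 5)
  lab <- predictLabels(m, ep$vm_value)
  tp <- sum(lab == "SED" & ep$intensity == "SED")
  fn <- sum(lab != "SED" & ep$intensity == "SED")
  tn <- sum(lab != "SED" & ep$intensity != "SED")
  fp <- sum(lab == "SED" & ep$intensity != "SED")
  ev <- evaluateIntensityModel(m, ep, nBoot = 100, seed = 1)
  pc <- classMetrics(ev)
  expect_equal(pc$sensitivity[pc$class == "SED"], tp / (tp + fn))
  expect_equal(pc$specificity[pc$class == "SED"], tn / (tn + fp))
})

test_that("bootstrap CIs are reproducible and tighten with more data", {
  set.seed(13)
  mk <- function(n) data.frame(
    vm_value = c(rlnorm(n, log(15), 0.6), rlnorm(n, log(120), 0.6)),
    intensity = rep(c("SED", "MVPA"), each = n))
  small <- mk(40); large <- mk(400)
  ms <- trainIntensityModel(small, "onevsall", minLeaf = 5)
  ml <- trainIntensityModel(large, "onevsall")
  e1 <- evaluateIntensityModel(ms, small, nBoot = 400, seed = 7)
  e2 <- evaluateIntensityModel(ms, small, nBoot = 400, seed = 7)
  expect_identical(classMetrics(e1), classMetrics(e2))
  el <- evaluateIntensityModel(ml, large, nBoot = 400, seed = 7)
  wSmall <- with(classMetrics(e1)[1, ], ci_high - ci_low)
  wLarge <- with(classMetrics(el)[1, ], ci_high - ci_low)
  expect_lt(wLarge, wSmall)
})

test_that("the synthetic study generator is seeded and calibrated", {
  a <- simulateStudy(seed = 99)
  b <- simulateStudy(seed = 99)
  expect_identical(a, b)
  expect_equal(nrow(a), 600L)
  expect_equal(length(unique(a$child_id)), 10L)
  # ordered class means on the VM scale
  mns <- tapply(a$vm_value, a$intensity, stats::median)
  expect_true(mns["SED"] < mns["LPA"] && mns["LPA"] < mns["MVPA"])
  # analytic adjacent-class confusion stays moderate (<= 15%)
  expect_true(all(studyClassConfusion() <= 0.15))
  # scores lie inside their class intervals
  expect_identical(intensityFromScore(a$weighted_score), a$intensity)
})
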