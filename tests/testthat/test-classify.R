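test_that("a separable 1-feature problem is classified with correct signs", {
  v <- matrix(c(1, 2, -1, -2), ncol = 1, dimnames = list(NULL, "F1"))
  model <- trainMarginClassifier(v, c(TRUE, TRUE, FALSE, FALSE))
  sc <- decisionScores(model, v)
  expect_true(all(sc[1:2] > 0))
  expect_true(all(sc[3:4] < 0))
  # boundary lies between -1 and +1 on the feature axis
  grid <- matrix(seq(-2, 2, by = 0.05), ncol = 1, dimnames = list(NULL, "F1"))
  cross <- grid[which.min(abs(decisionScores(model, grid))), 1]
  expect_gt(cross, -1)
  expect_lt(cross, 1)
})

test_that("flipping the labels negates every decision score", {
  set.seed(23)
  v <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("F", 1:4)))
  y <- rep(c(TRUE, FALSE), 5)
  a <- trainMarginClassifier(v, y)
  b <- trainMarginClassifier(v, !y)
  expect_equal(decisionScores(a, v), -decisionScores(b, v), tolerance = 1e-8)
})

test_that("duplicating a training sample keeps separable predictions (retrain oracle)", {
  set.seed(5)
  v <- matrix(c(rnorm(10, 3), rnorm(10, -3)), ncol = 1,
              dimnames = list(NULL, "F1"))
  y <- rep(c(TRUE, FALSE), each = 10)
  test <- matrix(rnorm(20, 0, 4), ncol = 1, dimnames = list(NULL, "F1"))
  a <- trainMarginClassifier(v, y)
  b <- trainMarginClassifier(rbind(v, v[1, , drop = FALSE]), c(y, y[1]))
  expect_equal(decisionScores(a, test) > 0, decisionScores(b, test) > 0)
})

test_that("zero-variance features are dropped with a warning", {
  v <- cbind(F1 = c(1, 2, -1, -2), FLAT = rep(3, 4))
  expect_warning(model <- trainMarginClassifier(v, c(TRUE, TRUE, FALSE, FALSE)),
                 "FLAT")
  expect_equal(model$features, "F1")
})

test_that("feature ranking is deterministic: ties broken by protein id", {
  m <- rbind(zz = c(1, 2, 3, 7, 8, 9),
             aa = c(1, 2, 3, 7, 8, 9),
             noise = c(5, 1, 4, 4, 2, 5))
  colnames(m) <- paste0("S", 1:6)
  x <- ProteomeSet(m, subtype = rep(c("lo", "hi"), each = 3))
  r <- rankFeatures(x, "hi")
  expect_equal(r$protein[1:2], c("aa", "zz"))

  perm <- sample(6)
  x2 <- ProteomeSet(m[, perm], subtype = rep(c("lo", "hi"), each = 3)[perm])
  expect_equal(rankFeatures(x2, "hi")$protein, r$protein)
})

test_that("a perfectly separating protein ranks first in random training subsets", {
  set.seed(66)
  m <- matrix(rnorm(40 * 16), 40, 16,
              dimnames = list(sprintf("P%02d", 1:40), paste0("S", 1:16)))
  m["P07", 1:8] <- m["P07", 1:8] + 6
  st <- rep(c("pos", "neg"), each = 8)
  firsts <- vapply(1:100, function(i) {
    keep <- c(sample(1:8, 6), sample(9:16, 6))
    x <- ProteomeSet(m[, keep], subtype = st[keep])
    rankFeatures(x, "pos")$protein[1]
  }, character(1))
  expect_gte(mean(firsts == "P07"), 0.99)
})

test_that("optimal feature count is the earliest maximum of the curve", {
  mk <- function(acc) new("AccuracyCurve",
    curve = data.frame(class = "A", size = seq_along(acc),
                       mean_accuracy = acc, sd_accuracy = 0,
                       n_runs = 10L),
    classes = "A", featureGrid = seq_along(acc), nRuns = 10L)
  expect_equal(unname(optimalFeatureCounts(mk(c(0.80, 0.90, 0.90, 0.85)))), 2L)
  expect_equal(unname(optimalFeatureCounts(mk(c(0.5, 0.6, 0.7, 0.8)))), 4L)
  expect_equal(unname(optimalFeatureCounts(mk(rep(0.7, 4)))), 1L)
})

test_that("cross-validated feature selection is reproducible from its seed", {
  sim <- generateSynthetic(syntheticConfig(
    nProteins = 80, markersPerClass = 3, markerEffect = 2,
    nEnrichedCategories = 0, nNullCategories = 0,
    missingTargetFraction = 0, seed = 3))
  a <- cvFeatureSelection(sim$matrix, nRuns = 2, featureGrid = c(1, 3), seed = 77)
  b <- cvFeatureSelection(sim$matrix, nRuns = 2, featureGrid = c(1, 3), seed = 77)
  expect_identical(accuracyCurve(a), accuracyCurve(b))
  expect_true(all(accuracyCurve(a)$n_runs == 2))
  expect_error(cvFeatureSelection(makeTinySet(10, 9, missingFraction = 0.2),
                                  nRuns = 2),
               "impute")
})

test_that("more planted markers improve accuracy up the curve", {
  sim <- generateSynthetic(syntheticConfig(
    nProteins = 200, markersPerClass = 5, markerEffect = 2,
    nEnrichedCategories = 0, nNullCategories = 0,
    missingTargetFraction = 0, seed = 10))
  cv <- cvFeatureSelection(sim$matrix, nRuns = 25, featureGrid = c(1, 5),
                           seed = 19)
  curve <- accuracyCurve(cv)
  for (cl in classLevels(sim$matrix)) {
    sub <- curve[curve$class == cl, ]
    expect_gte(sub$mean_accuracy[sub$size == 5],
               sub$mean_accuracy[sub$size == 1] - 0.02)
  }
  expect_gte(max(curve$mean_accuracy), 0.9)
})

test_that("signature extraction records direction by the sign of the mean difference", {
  sim <- generateSynthetic(syntheticConfig(
    nProteins = 100, markersPerClass = 4, markerEffect = 2.5,
    nEnrichedCategories = 0, nNullCategories = 0,
    missingTargetFraction = 0, seed = 21))
  x <- sim$matrix
  sig <- extractSignature(x, setNames(rep(4L, 3), classLevels(x)))
  entries <- signatureEntries(sig)
  truth <- truthMarkers(sim$truth)
  hits <- merge(entries, truth, by = c("class", "protein"))
  expect_gt(nrow(hits), 0)
  expect_equal(hits$direction, ifelse(hits$effect > 0, "positive", "negative"))
  expect_false(anyDuplicated(entries[c("class", "protein")]) > 0)
})

test_that("prediction ties resolve to the earlier class in class order", {
  fakeModel <- function(b) structure(
    list(features = "P1", center = 0, scale = 1, weights = 0,
         intercept = b, cost = 1), class = "marginClassifier")
  sig <- new("SubtypeSignature",
             entries = data.frame(class = c("A", "B", "C"), protein = "P1",
                                  rank = 1L, direction = "positive",
                                  p_value = NA_real_),
             models = list(A = fakeModel(0.2), B = fakeModel(0.2),
                           C = fakeModel(-1)),
             classes = c("A", "B", "C"))
  m <- matrix(0, 1, 1, dimnames = list("P1", "S1"))
  expect_equal(as.character(predict(sig, m)), "A")
})

test_that("prediction errors name an absent or missing signature feature", {
  sim <- generateSynthetic(syntheticConfig(
    nProteins = 50, markersPerClass = 2, markerEffect = 2.5,
    nEnrichedCategories = 0, nNullCategories = 0,
    missingTargetFraction = 0, seed = 8))
  sig <- extractSignature(sim$matrix, setNames(rep(2L, 3), classLevels(sim$matrix)))
  feat <- signatureEntries(sig)$protein[1]
  m <- logRatios(sim$matrix)
  expect_error(predict(sig, m[setdiff(rownames(m), feat), , drop = FALSE]), feat)
  m2 <- m
  m2[feat, 1] <- NA
  expect_error(predict(sig, m2), feat)
})

test_that("prediction is invariant to feature order and recovers training labels", {
  sim <- generateSynthetic(syntheticConfig(
    nProteins = 60, markersPerClass = 3, markerEffect = 3,
    nEnrichedCategories = 0, nNullCategories = 0,
    missingTargetFraction = 0, seed = 30))
  x <- sim$matrix
  sig <- extractSignature(x, setNames(rep(3L, 3), classLevels(x)))
  p1 <- predict(sig, x)
  expect_gte(mean(p1 == subtypes(x)), 0.95)
  m <- logRatios(x)
  p2 <- predict(sig, m[rev(rownames(m)), ])
  expect_identical(p1, p2)
})

test_that("ROC: separation gives 1, constancy 0.5, worked case 8/9", {
  expect_equal(rocCurve(c(3, 2, 1, -1, -2), c(TRUE, TRUE, TRUE, FALSE, FALSE))@auc, 1)
  expect_equal(rocCurve(rep(1, 6), rep(c(TRUE, FALSE), 3))@auc, 0.5)
  r <- rocCurve(c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2),
                c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(r@auc, 8 / 9)
  expect_equal(r@points$fpr[1], 0)
  expect_equal(r@points$tpr[nrow(r@points)], 1)
})

test_that("AUC equals the pairwise oracle and pROC on random small instances", {
  skip_if_not_installed("pROC")
  set.seed(19)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    scores <- round(rnorm(n), sample(c(0, 1, 3), 1))  # rounding makes ties
    r <- rocCurve(scores, labels)
    expect_equal(r@auc, oracleAUC(scores, labels))
    ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores,
                                                direction = "<", quiet = TRUE)))
    expect_equal(r@auc, as.numeric(ref))
  }
})
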