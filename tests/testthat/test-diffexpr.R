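test_that("one-vs-rest t matches the pooled-variance formula and t.test", {
  m <- rbind(p1 = c(1, 2, 3, 4, 5, 6))
  colnames(m) <- paste0("S", 1:6)
  x <- ProteomeSet(m, subtype = c("in", "in", "in", "out", "out", "out"))
  r <- ttestOVR(x, "in")
  # pooled: means 2 and 5, each var 1, se = sqrt(1 * 2/3)
  expect_equal(r$statistic, (2 - 5) / sqrt(2 / 3))
  ref <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(r$statistic, unname(ref$statistic))
  expect_equal(r$p_value, ref$p.value)
  expect_lt(r$statistic, 0)
})

test_that("swapping in/out roles negates t and keeps p", {
  x <- makeTinySet(30, 8, classes = c("A", "B"), seed = 2)
  a <- ttestOVR(x, "A")
  b <- ttestOVR(x, "B")
  expect_equal(a$statistic, -b$statistic)
  expect_equal(a$p_value, b$p_value)
})

test_that("t is zero when the side means are exactly equal", {
  m <- rbind(p = c(1, 3, 2, 2.5, 2, 1.5))
  colnames(m) <- paste0("S", 1:6)
  x <- ProteomeSet(m, subtype = rep(c("A", "B"), each = 3))
  expect_equal(ttestOVR(x, "A")$statistic, 0)
  expect_equal(ttestOVR(x, "A")$p_value, 1)
})

test_that("proteins with < 2 observed values on a side are reported as NA", {
  m <- rbind(ok = rnorm(6), thin = c(1, NA, NA, 2, 3, 4))
  colnames(m) <- paste0("S", 1:6)
  x <- ProteomeSet(m, subtype = rep(c("A", "B"), each = 3))
  r <- ttestOVR(x, "A")
  expect_true(is.na(r[r$protein == "thin", "statistic"]))
  expect_false(is.na(r[r$protein == "ok", "statistic"]))
})

test_that("ANOVA F matches the sums-of-squares oracle (F = 3) and aov", {
  m <- rbind(p = c(1, 2, 3, 2, 3, 4, 3, 4, 5))
  colnames(m) <- paste0("S", 1:9)
  x <- ProteomeSet(m, subtype = rep(c("g1", "g2", "g3"), each = 3))
  r <- anovaF(x)
  expect_equal(r$statistic, 3)
  expect_equal(r$df1, 2)
  expect_equal(r$df2, 6)
  ref <- summary(aov(c(1, 2, 3, 2, 3, 4, 3, 4, 5) ~ rep(c("a", "b", "c"), each = 3)))
  expect_equal(r$statistic, ref[[1]]$`F value`[1])
  expect_equal(r$p_value, ref[[1]]$`Pr(>F)`[1])
})

test_that("identical samples follow the F = 0, p = 1 convention", {
  m <- rbind(flat = rep(2.5, 9))
  colnames(m) <- paste0("S", 1:9)
  x <- ProteomeSet(m, subtype = rep(c("a", "b", "c"), each = 3))
  r <- anovaF(x)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
})

test_that("F is invariant to adding a constant to every sample", {
  x <- makeTinySet(40, 9, seed = 6)
  shifted <- ProteomeSet(logRatios(x) + 7, subtype = subtypes(x))
  expect_equal(anovaF(shifted)$statistic, anovaF(x)$statistic)
})

test_that("with two classes, F equals the squared t", {
  x <- makeTinySet(50, 10, classes = c("A", "B"), seed = 13)
  f <- anovaF(x)$statistic
  t2 <- ttestOVR(x, "A")$statistic^2
  expect_equal(f, t2, tolerance = 1e-10)
})

test_that("permutation FDR is deterministic in the seed and q is monotone", {
  sim <- generateSynthetic(syntheticConfig(
    nProteins = 150, markersPerClass = 4, markerEffect = 2.5,
    nEnrichedCategories = 0, nNullCategories = 0,
    missingTargetFraction = 0, seed = 4))
  x <- sim$matrix
  a <- permutationFDR(x, nPermutations = 40, seed = 9)
  b <- permutationFDR(x, nPermutations = 40, seed = 9)
  expect_identical(a$q_value, b$q_value)
  ord <- order(a$statistic)
  expect_true(all(diff(a$q_value[ord]) <= 1e-12))
  expect_equal(a$significant, a$q_value <= 0.05)
})

test_that("planted effects are detected by permutation FDR, nulls mostly not", {
  sim <- generateSynthetic(syntheticConfig(
    nProteins = 300, markersPerClass = 10, markerEffect = 2.4,
    noiseSd = 0.8, nEnrichedCategories = 0, nNullCategories = 0,
    missingTargetFraction = 0, seed = 42))
  r <- permutationFDR(sim$matrix, nPermutations = 60, level = 0.05, seed = 7)
  planted <- unique(truthMarkers(sim$truth)$protein)
  sigSet <- r$protein[r$significant]
  expect_gte(mean(planted %in% sigSet), 0.9)
  expect_lte(mean(setdiff(r$protein, planted) %in% sigSet), 0.1)
})

test_that("tiny cohorts fall back to all distinct relabelings with a warning", {
  m <- matrix(rnorm(5 * 4), 5, 4,
              dimnames = list(paste0("P", 1:5), paste0("S", 1:4)))
  x <- ProteomeSet(m, subtype = c("A", "A", "B", "B"))
  expect_warning(r <- permutationFDR(x, nPermutations = 25, seed = 1),
                 "distinct")
  expect_true(all(!is.na(r$q_value)))
})

test_that("q-values stabilize with many permutations", {
  # the median-of-counts estimator is quantized in steps of roughly
  # 1 / #{observed >= c}, so q can never agree more tightly than that at
  # mid-range thresholds; the decision (significant set) must be stable
  sim <- generateSynthetic(syntheticConfig(
    nProteins = 1000, markersPerClass = 3, markerEffect = 3,
    nEnrichedCategories = 0, nNullCategories = 0,
    missingTargetFraction = 0, seed = 15))
  a <- permutationFDR(sim$matrix, nPermutations = 1000, seed = 1)
  b <- permutationFDR(sim$matrix, nPermutations = 1000, seed = 2)
  expect_lt(max(abs(a$q_value - b$q_value)), 0.06)
  expect_identical(a$protein[a$significant], b$protein[b$significant])
})
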