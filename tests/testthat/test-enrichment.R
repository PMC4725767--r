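test_that("mean difference: constants give 0, worked case gives 2, order-invariant", {
  m <- rbind(const = rep(5, 5),
             delta = c(2, 4, 1, 1, 1))
  colnames(m) <- paste0("S", 1:5)
  x <- ProteomeSet(m, subtype = c("in", "in", "out", "out", "out"))
  d <- meanDifference(x, "in")
  expect_equal(unname(d["const"]), 0)
  expect_equal(unname(d["delta"]), 2)

  perm <- c(4, 1, 5, 2, 3)
  x2 <- ProteomeSet(m[, perm], subtype = c("in", "in", "out", "out", "out")[perm])
  expect_equal(meanDifference(x2, "in"), d)
})

test_that("proteins lacking data on either side get NA mean difference", {
  m <- rbind(full = rnorm(4), gap = c(NA, NA, 1, 2))
  colnames(m) <- paste0("S", 1:4)
  x <- ProteomeSet(m, subtype = c("A", "A", "B", "B"))
  d <- meanDifference(x, "A")
  expect_true(is.na(d["gap"]))
  expect_false(is.na(d["full"]))
})

test_that("members at the top ranks score exactly +1 and the worked case 0.8095", {
  values <- setNames(1:10, paste0("P", 1:10))
  top <- CategoryMap(list(TOP = paste0("P", 8:10)))
  r <- enrichment1D(values, top, minSize = 3)
  expect_equal(r$score, 1)

  cm <- CategoryMap(list(S = paste0("P", c(6, 9, 10))))
  r2 <- enrichment1D(values, cm, minSize = 3)
  expect_equal(r2$score, 2 * (25 / 3 - 5.5) / 7)
  o <- oracleEnrichment(values, c(6, 9, 10))
  expect_equal(r2$p_value, o$p)
})

test_that("negating values flips every score and preserves every p", {
  set.seed(14)
  values <- setNames(rnorm(60), paste0("P", 1:60))
  cm <- CategoryMap(list(A = paste0("P", 1:10), B = paste0("P", 25:40),
                         C = paste0("P", sample(60, 8))))
  r1 <- enrichment1D(values, cm, minSize = 5)
  r2 <- enrichment1D(-values, cm, minSize = 5)
  r2 <- r2[match(r1$category, r2$category), ]
  expect_equal(r2$score, -r1$score)
  expect_equal(r2$p_value, r1$p_value)
})

test_that("score is bounded and centred at zero under random assignment", {
  set.seed(77)
  scores <- replicate(200, {
    values <- setNames(rnorm(40), paste0("P", 1:40))
    cm <- CategoryMap(list(X = paste0("P", sample(40, 8))))
    enrichment1D(values, cm, minSize = 5)$score
  })
  expect_true(all(abs(scores) <= 1))
  expect_lt(abs(mean(scores)), 3 * sd(scores) / sqrt(length(scores)))
})

test_that("BH significance matches a literal step-up procedure", {
  set.seed(101)
  values <- setNames(c(rnorm(180), rnorm(20, 2)), paste0("P", 1:200))
  sets <- c(lapply(1:8, function(i) paste0("P", sample(180, 15))),
            list(HIT = paste0("P", 181:200)))
  names(sets) <- c(paste0("N", 1:8), "HIT")
  r <- enrichment1D(values, CategoryMap(sets), minSize = 5, fdr = 0.05)
  p <- sort(r$p_value)
  mtests <- length(p)
  below <- which(p <= 0.05 * seq_len(mtests) / mtests)
  stepUp <- if (length(below)) p[max(below)] else -Inf
  expect_setequal(r$category[r$significant], r$category[r$p_value <= stepUp])
  expect_true("HIT" %in% r$category[r$significant])
})

test_that("categories below minSize or spanning all proteins are excluded", {
  values <- setNames(1:10, paste0("P", 1:10))
  cm <- CategoryMap(list(small = paste0("P", 1:3),
                         all = paste0("P", 1:10),
                         ok = paste0("P", 1:5)))
  r <- enrichment1D(values, cm, minSize = 5)
  expect_equal(r$category, "ok")
  none <- enrichment1D(values, CategoryMap(list(tiny = "P1")), minSize = 5)
  expect_equal(nrow(none), 0)
})

test_that("raw p threshold mode drives the significant flag when requested", {
  values <- setNames(1:20, paste0("P", 1:20))
  cm <- CategoryMap(list(TOP = paste0("P", 16:20), MID = paste0("P", 8:12)))
  r <- enrichment1D(values, cm, minSize = 5, pThreshold = 0.5e-2)
  expect_equal(r$significant, r$p_value < 0.5e-2)
})

test_that("hierarchy enrichment labels levels and rolls members up deduplicated", {
  set.seed(55)
  m <- matrix(rnorm(100 * 12), 100, 12,
              dimnames = list(paste0("P", 1:100), paste0("S", 1:12)))
  m[1:10, 1:4] <- m[1:10, 1:4] + 3   # leaf1 up in class A
  m[8:17, 1:4] <- m[8:17, 1:4] + 3   # leaf2 up in class A, overlaps leaf1
  x <- ProteomeSet(m, subtype = rep(c("A", "B", "C"), each = 4))
  cm <- CategoryMap(list(leaf1 = paste0("P", 1:10),
                         leaf2 = paste0("P", 8:17),
                         lonely = paste0("P", 60:75)),
                    parents = c(leaf1 = "par", leaf2 = "par"))
  expect_warning(r <- hierarchyEnrichment(x, cm, minSize = 5), "none")
  expect_setequal(unique(r$level), c("leaf", "parent", "none"))
  parA <- r[r$class == "A" & r$level == "parent", ]
  expect_equal(parA$n_in, 17L)  # union of 1:10 and 8:17, deduplicated
  leafA <- r[r$class == "A" & r$level == "leaf", ]
  expect_true(all(leafA$score > 0))
  expect_gte(parA$score, min(leafA$score))

  # a parent covering every scored protein is excluded (n_in = n)
  cmAll <- CategoryMap(list(l1 = paste0("P", 1:50), l2 = paste0("P", 51:100)),
                       parents = c(l1 = "everything", l2 = "everything"))
  r2 <- hierarchyEnrichment(x, cmAll, minSize = 5)
  expect_false("parent" %in% r2$level)
})

test_that("a planted category shift is recovered as significant with s > 0", {
  hits <- vapply(1:20, function(seed) {
    sim <- generateSynthetic(syntheticConfig(
      nProteins = 300, markersPerClass = 0, nEnrichedCategories = 1,
      nNullCategories = 3, categorySize = 20, categoryShift = 1.6,
      noiseSd = 0.8, missingTargetFraction = 0, seed = seed))
    cl <- truthCategories(sim$truth)$class[1]
    r <- enrichment1D(meanDifference(sim$matrix, cl), sim$categories,
                      minSize = 5, fdr = 0.05)
    row <- r[r$category == "SHIFTED_01", ]
    row$significant && row$score > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
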