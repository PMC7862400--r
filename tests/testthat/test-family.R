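test_that("normalization cubic reproduces its anchors and known values", {
  expect_equal(normalizeDSDR(c(0, 10, 30, 100)), c(0, 1, 2, 3),
               tolerance = 1e-12)
  # 517/315, computed independently by exact rational Lagrange interpolation
  expect_equal(normalizeDSDR(20), 517 / 315, tolerance = 1e-5)
  expect_error(normalizeDSDR(101), "\\[0, 100\\]")
  expect_error(normalizeDSDR(-0.1), "\\[0, 100\\]")
})

test_that("re-derived cubic coefficients match the closed forms", {
  fit <- fitNormalizationCubic()
  expect_equal(fit$a, 1 / 78750, tolerance = 1e-9)
  expect_equal(fit$b, -137 / 63000, tolerance = 1e-9)
  expect_equal(fit$c, 253 / 2100, tolerance = 1e-9)
  expect_equal(fit$d, 0, tolerance = 1e-9)
  x <- seq(0, 100, by = 0.5)
  expect_equal(fit$predict(x), normalizeDSDR(x), tolerance = 1e-9)
})

test_that("the cubic maps into [0, 3], rises to 30, and dips after ~47", {
  x <- seq(0, 100, by = 0.1)
  y <- normalizeDSDR(x)
  expect_true(all(y >= 0 & y <= 3 + 1e-12))
  expect_true(all(diff(normalizeDSDR(seq(0, 30, 0.1))) > 0))
  # documented non-monotonicity: local max near 47.3, local min near 66.9
  expect_gt(normalizeDSDR(47.3), normalizeDSDR(66.9))
  expect_lt(normalizeDSDR(66.9), normalizeDSDR(60))
  expect_gt(normalizeDSDR(100), normalizeDSDR(66.9))
})

test_that("dominant category requires a strict majority", {
  expect_identical(dominantCategory(c("A", "A", "A", "B")), "A")
  expect_identical(dominantCategory(c("A", "A", "B", "B")), NA_character_)
  expect_identical(dominantCategory("A"), "A")
  expect_error(dominantCategory(character(0)), "empty")
  # exhaustive check on all label multisets of sizes 1..5 over 3 labels
  for (n in 1:5) {
    grids <- do.call(expand.grid, rep(list(c("A", "B", "C")), n))
    for (r in seq_len(nrow(grids))) {
      labs <- as.character(unlist(grids[r, ]))
      expected <- {
        tab <- table(labs) / n
        if (max(tab) > 0.5) names(tab)[which.max(tab)] else NA_character_
      }
      expect_identical(dominantCategory(labs), expected)
    }
  }
})

test_that("repetition categories cover the four distribution patterns", {
  expect_identical(repetitionCategory("p1"), "single_copy")
  expect_identical(repetitionCategory(c("p1", "p1", "p1")),
                   "within_protein_only")
  expect_identical(repetitionCategory(c("p1", "p2", "p3")),
                   "across_proteins_only")
  expect_identical(repetitionCategory(c("p1", "p1", "p2", "p2")), "both")
  expect_identical(repetitionCategory(c("p1", "p1", "p2")), "both")
})

test_that("variation values classify into 0 / (0,1] / (1,3]", {
  expect_identical(classifyVariation(c(0, 0.8, 2.5)),
                   c("no_variation", "low_variation", "high_variation"))
  expect_identical(classifyVariation(1), "low_variation")   # closed at 1
  expect_identical(classifyVariation(3), "high_variation")
  expect_error(classifyVariation(3.5), "\\[0, 3\\]")
})

test_that("pairwise variation enumerates unordered pairs within scope", {
  v <- pairwiseVariation(c(2.5, 2.5), c("p1", "p1"), "within_protein")
  expect_true(v$applicable)
  expect_equal(v$pairs$value, 0)
  expect_identical(v$variation_dominant, "no_variation")

  v2 <- pairwiseVariation(c(0, 2.5), c("p1", "p2"), "across_proteins")
  expect_equal(v2$pairs$value, 2.5)
  expect_identical(v2$variation_dominant, "high_variation")

  v3 <- pairwiseVariation(c(1.0, 1.8), c("p1", "p1"), "within_protein")
  expect_equal(v3$pairs$value, 0.8)
  expect_identical(v3$variation_dominant, "low_variation")

  # fewer than two instances in scope -> not applicable
  expect_false(pairwiseVariation(2, "p1", "within_protein")$applicable)
  expect_false(pairwiseVariation(c(1, 2), c("p1", "p2"),
                                 "within_protein")$applicable)
  # three instances on one protein -> three pairs
  v4 <- pairwiseVariation(c(0, 1, 3), rep("p1", 3), "within_protein")
  expect_equal(nrow(v4$pairs), 3L)
  expect_true(all(v4$pairs$value <= 3))
})

test_that("no-variation proportion Fisher test matches exact enumeration", {
  sym <- noVariationProportionTest(matrix(c(5, 5, 5, 5), 2))
  expect_equal(sym$p, 1)
  # fully separated 10/10 table: p = 2 / C(20,10), enumerated independently
  sep <- noVariationProportionTest(matrix(c(10, 0, 0, 10), 2))
  expect_equal(sep$p, 2 / choose(20, 10), tolerance = 1e-12)
  und <- noVariationProportionTest(matrix(c(1, 0, 0, 0), 2))
  expect_false(und$defined)
  expect_true(is.na(und$p))
})

test_that("variation table splits scopes and feeds the Fisher test", {
  metrics <- rbind(
    makeMetricsRow("s1", "PF1", "p1", dsdr = 50, cdrn = 1, 1L, 100L),
    makeMetricsRow("s1", "PF1", "p1", dsdr = 50, cdrn = 1, 201L, 300L),
    makeMetricsRow("s1", "PF2", "p2", dsdr = 0, cdrn = 0),
    makeMetricsRow("s1", "PF2", "p3", dsdr = 80, cdrn = 2),
    makeMetricsRow("s1", "PF3", "p4", dsdr = 10, cdrn = 0))
  vt <- variationTable(metrics)
  expect_setequal(vt$family_id, c("PF1", "PF2"))
  expect_identical(vt$scope[vt$family_id == "PF1"], "within_protein")
  expect_identical(vt$variation_dominant[vt$family_id == "PF1"],
                   "no_variation")
  expect_identical(vt$variation_dominant[vt$family_id == "PF2"],
                   "high_variation")
  pairs <- attr(vt, "pairs")
  expect_equal(nrow(pairs), 2L)
})

test_that("family profiles aggregate instances per species and family", {
  metrics <- rbind(
    makeMetricsRow("s1", "PF1", "p1", dsdr = 50, cdrn = 1),
    makeMetricsRow("s1", "PF1", "p2", dsdr = 60, cdrn = 1),
    makeMetricsRow("s1", "PF1", "p3", dsdr = 55, cdrn = 1),
    makeMetricsRow("s1", "PF2", "p1", dsdr = 0, cdrn = 0),
    makeMetricsRow("s1", "PF2", "p4", dsdr = 20, cdrn = 0))
  fp <- familyProfiles(metrics)
  f1 <- fp[fp$family_id == "PF1", ]
  expect_equal(f1$n_instances, 3L)
  expect_identical(f1$dominant_category, "intrinsically_disordered")
  expect_identical(f1$repetition_category, "across_proteins_only")
  expect_true(f1$family_idd)
  expect_equal(f1$median_norm_dsdr, normalizeDSDR(55))
  f2 <- fp[fp$family_id == "PF2", ]
  expect_true(is.na(f2$dominant_category))  # 1x completely, 1x moderately
  expect_false(f2$family_idd)
  # even count uses the midpoint convention
  expect_equal(f2$median_norm_dsdr,
               mean(normalizeDSDR(c(0, 20))))
})

test_that("clade comparison requires the delta to clear the threshold", {
  r <- compareFamilyDisorderBetweenClades(c(2.5, 1, 0.5), c(1, 1, 1),
                                          deltaThreshold = 1)
  expect_identical(r$call, c("higher_in_A", "similar", "similar"))
  r2 <- compareFamilyDisorderBetweenClades(0, 1.5, 1)
  expect_identical(r2$call, "higher_in_B")
})
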