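test_that("DSDR is the percentage of disordered residues in the interval", {
  calls <- c(rep(TRUE, 30), rep(FALSE, 30))
  expect_equal(computeDSDR(calls), 50)
  expect_equal(computeDSDR(rep(FALSE, 80)), 0)
  expect_equal(computeDSDR(rep(TRUE, 80)), 100)
  expect_equal(computeDSDR(calls, 1, 30), 100)
  expect_error(computeDSDR(calls, 10, 5), "invalid interval")
  expect_error(computeDSDR(calls, 1, 61), "invalid interval")
})

test_that("CDR qualification is strict on both rule branches", {
  mk <- function(L, runlen, at = 10L) {
    v <- rep(FALSE, L); v[at:(at + runlen - 1L)] <- TRUE; v
  }
  expect_equal(nrow(findCDRs(mk(100, 21))), 1L)   # > 20 in a long domain
  expect_equal(nrow(findCDRs(mk(100, 20))), 0L)   # exactly 20 fails
  expect_equal(nrow(findCDRs(mk(40, 16, 5))), 0L) # exactly 40% fails
  expect_equal(nrow(findCDRs(mk(40, 17, 5))), 1L) # > 40% qualifies
  # at exactly 50 residues the short-domain (>40%) rule applies
  expect_equal(nrow(findCDRs(mk(50, 21, 5))), 1L)
  cdr <- findCDRs(mk(100, 25, 30))
  expect_equal(cdr$start, 30L)
  expect_equal(cdr$end, 54L)
})

test_that("findCDRs agrees with the brute-force maximal-run oracle", {
  set.seed(42)
  for (i in 1:500) {
    L <- sample(1:120, 1)
    calls <- runif(L) < runif(1)
    expect_identical(findCDRs(calls), bruteForceCDRs(calls))
  }
})

test_that("DSDR grades use the published bins with closed upper bounds", {
  expect_identical(classifyDSDRGrade(0), "completely_structured")
  expect_identical(classifyDSDRGrade(10), "highly_structured")
  expect_identical(classifyDSDRGrade(30), "moderately_unstructured")
  expect_identical(classifyDSDRGrade(30.1), "intrinsically_disordered")
  expect_identical(classifyDSDRGrade(c(0.01, 100)),
                   c("highly_structured", "intrinsically_disordered"))
  expect_error(classifyDSDRGrade(101), "\\[0, 100\\]")
  expect_error(classifyDSDRGrade(-1), "\\[0, 100\\]")
})

test_that("quadrants follow the DSDR/CDRN class definitions", {
  expect_identical(classifyQuadrant(50, 2), "I")
  expect_identical(classifyQuadrant(10, 1), "II")
  expect_identical(classifyQuadrant(10, 0), "III")
  expect_identical(classifyQuadrant(45, 0), "IV")
  expect_identical(classifyQuadrant(30, 1), "II")  # boundary: 30 is not IDD
  # IDD rule: quadrants I, II, IV
  expect_true(all(isIDD(c(50, 10, 45), c(2, 1, 0))))
  expect_false(isIDD(10, 0))
})

test_that("protein metrics and representative selection behave", {
  profs <- list(pa = rep(TRUE, 10), pb = rep(FALSE, 10),
                pc = c(rep(TRUE, 3), rep(FALSE, 7)))
  pm <- proteinMetrics(profs)
  expect_equal(pm$psdr, c(100, 0, 30))
  expect_identical(pm$is_idp, c(TRUE, FALSE, FALSE))  # strict > 30

  prot <- data.frame(protein_id = c("a2", "a1", "b1", "b2"),
                     gene_id = c("g1", "g1", "g2", "g2"),
                     length = c(100L, 100L, 50L, 80L))
  reps <- selectRepresentatives(prot)
  expect_identical(sort(reps$protein_id), c("a1", "b2"))  # tie -> lexicographic
})

test_that("non-domain regions are the ordered complement of domains", {
  r <- nonDomainRegions(100, 21L, 40L)
  expect_equal(r$start, c(1L, 41L))
  expect_equal(r$end, c(20L, 100L))
  expect_equal(nonDomainRegions(100, integer(0), integer(0)),
               data.frame(start = 1L, end = 100L))
  expect_equal(nrow(nonDomainRegions(100, c(1L, 51L), c(50L, 100L))), 0L)
  # overlapping domains are merged before complementing
  r2 <- nonDomainRegions(60, c(10L, 20L), c(30L, 40L))
  expect_equal(r2$start, c(1L, 41L))
})

test_that("disordered counts are additive over any partition", {
  set.seed(11)
  calls <- runif(200) < 0.4
  cuts <- sort(sample(2:199, 4))
  bounds <- rbind(c(1, cuts[1] - 1),
                  cbind(cuts[-4], cuts[-1] - 1),
                  c(cuts[4], 200))
  parts <- apply(bounds, 1, function(b)
    regionMetrics(calls, b[1], b[2])$n_disordered)
  expect_equal(sum(parts), sum(calls))
})

test_that("flipping a residue to disordered never revokes IDD status", {
  set.seed(13)
  for (i in 1:50) {
    L <- sample(30:90, 1)
    calls <- runif(L) < 0.35
    before <- regionMetrics(calls)$is_idd
    j <- sample(which(!calls), 1)
    calls[j] <- TRUE
    after <- regionMetrics(calls)$is_idd
    expect_false(before && !after)
  }
})

test_that("species summary reports NA percentages for empty species", {
  prot <- data.frame(protein_id = c("s1_p1", "s1_p2", "s2_p1"),
                     gene_id = c("s1_p1", "s1_p2", "s2_p1"),
                     species_id = c("s1", "s1", "s2"),
                     length = c(100L, 100L, 100L))
  metrics <- rbind(
    makeMetricsRow("s1", "PF1", "s1_p1", dsdr = 50, cdrn = 1),
    makeMetricsRow("s1", "PF2", "s1_p2", dsdr = 0, cdrn = 0))
  ss <- speciesSummary(metrics, prot)
  expect_equal(ss$pct_idd[ss$species_id == "s1"], 50)
  expect_true(is.na(ss$pct_idd[ss$species_id == "s2"]))
  expect_equal(ss$n_domains, c(2L, 0L))
})

test_that("domain metrics attach per-instance values from the profiles", {
  calls <- c(rep(FALSE, 10), rep(TRUE, 25), rep(FALSE, 65))
  dom <- data.frame(protein_id = "p1", family_id = "PF1", family_name = "f",
                    start = 6L, end = 60L,
                    full_evalue = 1e-5, c_evalue = 1e-5)
  m <- domainMetrics(dom, list(p1 = calls))
  expect_equal(m$length, 55L)
  expect_equal(m$n_disordered, 25L)
  expect_equal(m$dsdr, 100 * 25 / 55)
  expect_equal(m$cdrn, 1L)          # 25-residue run in a 55-residue domain
  expect_identical(m$quadrant, "I")
  expect_equal(m$norm_dsdr, normalizeDSDR(m$dsdr))
  expect_error(domainMetrics(dom, list(other = calls)), "no disorder profile")
})
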