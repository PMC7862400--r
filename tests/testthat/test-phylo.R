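test_that("distribution width applies the ordered scheme first-match-wins", {
  lin <- makeLineages()
  expect_identical(distributionWidth("human", lin)$category,
                   "species_specific")
  expect_identical(distributionWidth(c("human", "mouse"), lin)$category,
                   "phylum_specific")
  expect_identical(distributionWidth(c("human", "yeast"), lin)$category,
                   "superkingdom_specific")
  expect_identical(distributionWidth(c("human", "ecoli"), lin)$category,
                   "cross_superkingdom")
  expect_error(distributionWidth("martian", lin), "missing from lineage")
})

test_that("scheme refinement does not change assignments on same lineages", {
  lin <- makeLineages()
  full <- defaultDistributionScheme(c("superkingdom", "kingdom", "phylum"))
  again <- defaultDistributionScheme(c("superkingdom", "kingdom", "phylum"))
  sets <- list("human", c("human", "mouse"), c("human", "yeast"),
               c("human", "mouse", "yeast", "ecoli"))
  for (s in sets)
    expect_identical(distributionWidth(s, lin, full)$category,
                     distributionWidth(s, lin, again)$category)
})

test_that("domain age is the LCA depth on the representative lineage", {
  lin <- makeLineages()
  only_rep <- domainAge("human", "human", lin)
  expect_identical(only_rep$grade, "human")    # species-level grade
  expect_equal(only_rep$grade_depth, ncol(lin) - 1L)

  hm <- domainAge(c("human", "mouse"), "human", lin)
  expect_identical(hm$grade, "Chordata")       # shared phylum
  hy <- domainAge(c("human", "yeast"), "human", lin)
  expect_identical(hy$grade, "Eukaryota")
  he <- domainAge(c("human", "ecoli"), "human", lin)
  expect_identical(he$grade, "root")
  expect_equal(he$grade_depth, 0L)
  expect_error(domainAge("mouse", "martian", lin), "missing from lineage")
})

test_that("adding species never makes a domain family younger", {
  lin <- makeLineages()
  sets <- list("human", c("human", "mouse"), c("human", "mouse", "yeast"),
               c("human", "mouse", "yeast", "ecoli"))
  depths <- vapply(sets, function(s) domainAge(s, "human", lin)$grade_depth,
                   integer(1))
  expect_true(all(diff(depths) <= 0))
})

test_that("disordered width is the strict >50% of carrying species", {
  w <- disorderedWidth(c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(w$pct_species_idd, 75)
  expect_true(w$widely_disordered)
  expect_equal(disorderedWidth(rep(FALSE, 5))$pct_species_idd, 0)
  half <- disorderedWidth(c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(half$pct_species_idd, 50)
  expect_false(half$widely_disordered)   # exactly 50% is not "widely"
  expect_error(disorderedWidth(logical(0)), "no species")
})

test_that("young planted families carry a higher IDD fraction", {
  # generator plants a disorder boost on phylum- and species-specific
  # families; pooled over species, young instances must be more often IDD
  cfg <- defaultSimConfig(seed = 5, nSpecies = 12, sequences = FALSE)
  cfg$families <- list(core = 40L, kingdomSpecific = 20L,
                       phylumSpecific = 60L, speciesSpecific = 20L,
                       youngDisorderBoost = 0.25)
  b <- simulateProteome(cfg)
  pr <- runProfile(b)
  phylo <- familyPhyloSummary(pr$families, b$lineages,
                              representative = "sp01")
  m <- merge(pr$metrics,
             phylo[, c("family_id", "distribution_category", "age_depth")],
             by = "family_id")
  young <- m$distribution_category %in% c("phylum_specific",
                                          "species_specific")
  expect_gt(mean(m$is_idd[young]), mean(m$is_idd[!young]))
  # the narrower the distribution, the deeper the age grade (for families
  # the representative carries)
  ok <- !is.na(m$age_depth)
  expect_true(all(m$age_depth[ok & young] >= 3))
})

test_that("idd fraction by age reports one row per grade, oldest first", {
  metrics <- rbind(
    makeMetricsRow("s1", "PF1", "p1", dsdr = 50, cdrn = 1),
    makeMetricsRow("s1", "PF1", "p2", dsdr = 40, cdrn = 1),
    makeMetricsRow("s1", "PF2", "p3", dsdr = 0, cdrn = 0))
  ages <- data.frame(family_id = c("PF1", "PF2"),
                     age_grade = c("s1", "Eukaryota"),
                     age_depth = c(4L, 1L))
  tab <- iddFractionByAge(metrics, ages)
  expect_equal(tab$age_depth, c(1L, 4L))
  expect_equal(tab$frac_idd_instances, c(0, 1))
  # single grade: fraction equals the species-level IDD share
  tab1 <- iddFractionByAge(metrics, transform(ages, age_depth = 2L,
                                              age_grade = "Metazoa"))
  expect_equal(nrow(tab1), 1L)
  expect_equal(tab1$frac_idd_instances, 2 / 3)
  # empty join -> empty table
  none <- iddFractionByAge(metrics,
                           data.frame(family_id = "PFX", age_grade = "g",
                                      age_depth = 1L))
  expect_equal(nrow(none), 0L)
})

test_that("family phylo summary combines width, age and disordered width", {
  lin <- makeLineages()
  fp <- rbind(
    data.frame(species_id = c("human", "mouse"), family_id = "PF1",
               n_instances = 1L, n_proteins = 1L, median_norm_dsdr = 2.5,
               dominant_category = "intrinsically_disordered",
               repetition_category = "single_copy", family_cdrn_flag = TRUE,
               family_idd = TRUE),
    data.frame(species_id = "yeast", family_id = "PF2",
               n_instances = 1L, n_proteins = 1L, median_norm_dsdr = 0,
               dominant_category = "completely_structured",
               repetition_category = "single_copy", family_cdrn_flag = FALSE,
               family_idd = FALSE))
  out <- familyPhyloSummary(fp, lin, representative = "human")
  p1 <- out[out$family_id == "PF1", ]
  expect_identical(p1$distribution_category, "phylum_specific")
  expect_identical(p1$age_grade, "Chordata")
  expect_equal(p1$pct_species_idd, 100)
  p2 <- out[out$family_id == "PF2", ]
  expect_true(is.na(p2$age_grade))   # representative does not carry PF2
  expect_equal(p2$pct_species_idd, 0)
})
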