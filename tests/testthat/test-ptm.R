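ptm_fixture <- function() {
  # two domains on p1: an IDD (1-100, all disordered) and a structured
  # domain (151-250, all ordered); 50 residues of linker between them
  calls <- c(rep(TRUE, 100), rep(FALSE, 50), rep(FALSE, 100))
  dom <- data.frame(protein_id = "p1", family_id = c("PF1", "PF2"),
                    family_name = c("f1", "f2"),
                    start = c(1L, 151L), end = c(100L, 250L),
                    full_evalue = 1e-9, c_evalue = 1e-9)
  metrics <- domainMetrics(dom, list(p1 = calls))
  list(calls = calls, metrics = metrics)
}

test_that("PTM density pools sites per residue within each category", {
  fx <- ptm_fixture()
  sites <- data.frame(protein_id = "p1", position = c(10L, 20L, 160L),
                      residue = "S", mod_type = "Phosphoserine")
  d <- ptmDensityByClass(fx$metrics, sites, "dsdr_grade")
  idd <- d[d$category == "intrinsically_disordered", ]
  expect_equal(idd$n_sites, 2L)
  expect_equal(idd$density, 2 / 100)
  strucd <- d[d$category == "completely_structured", ]
  expect_equal(strucd$density, 1 / 100)
  per_dom <- attr(d, "per_domain")
  expect_equal(sum(per_dom$n_sites), 3L)
})

test_that("sites outside any domain or on unknown proteins are dropped", {
  fx <- ptm_fixture()
  sites <- data.frame(protein_id = c("p1", "p1", "ghost"),
                      position = c(120L, 50L, 10L),
                      residue = "S", mod_type = "Phosphoserine")
  d <- ptmDensityByClass(fx$metrics, sites)
  expect_equal(sum(d$n_sites), 1L)   # only the position-50 site is in a domain
})

test_that("zero sites give zero densities, not errors", {
  fx <- ptm_fixture()
  none <- data.frame(protein_id = character(0), position = integer(0),
                     residue = character(0), mod_type = character(0))
  d <- ptmDensityByClass(fx$metrics, none)
  expect_true(all(d$n_sites == 0L))
  expect_true(all(d$density == 0))
})

test_that("CDR/non-CDR partition conserves the domain's sites", {
  # IDD with one CDR at 31-60 inside a 1-100 domain
  calls <- c(rep(FALSE, 30), rep(TRUE, 30), rep(FALSE, 40),
             rep(TRUE, 5), rep(FALSE, 25))
  dom <- data.frame(protein_id = "p1", family_id = "PF1", family_name = "f",
                    start = 1L, end = 100L,
                    full_evalue = 1e-9, c_evalue = 1e-9)
  metrics <- domainMetrics(dom, list(p1 = calls))
  expect_equal(metrics$cdrn, 1L)
  sites <- data.frame(protein_id = "p1",
                      position = c(35L, 40L, 59L, 5L, 90L),
                      residue = "S", mod_type = "Phosphoserine")
  cd <- cdrVsNoncdrDensity(metrics, list(p1 = calls), sites)
  expect_equal(nrow(cd), 1L)
  expect_equal(cd$cdr_sites, 3L)
  expect_equal(cd$noncdr_sites, 2L)
  expect_equal(cd$cdr_sites + cd$noncdr_sites, 5L)
  expect_equal(cd$cdr_residues, 30L)
  expect_equal(cd$cdr_density, 3 / 30)
  # all sites inside the CDR -> zero non-CDR density
  inside <- sites[1:3, ]
  cd2 <- cdrVsNoncdrDensity(metrics, list(p1 = calls), inside)
  expect_equal(cd2$noncdr_density, 0)
  # domains without a CDR are excluded
  no_cdr <- domainMetrics(dom, list(p1 = rep(FALSE, 130)))
  expect_equal(nrow(cdrVsNoncdrDensity(no_cdr, list(p1 = rep(FALSE, 130)),
                                       sites)), 0L)
})

test_that("density is invariant to row order of sites and domains", {
  fx <- ptm_fixture()
  set.seed(8)
  sites <- data.frame(protein_id = "p1",
                      position = sample(1:250, 40),
                      residue = "S", mod_type = "Phosphoserine")
  d1 <- ptmDensityByClass(fx$metrics, sites)
  d2 <- ptmDensityByClass(fx$metrics, sites[sample(40), ])
  rownames(d2) <- NULL
  expect_equal(d1, d2, ignore_attr = TRUE)
})

test_that("PTM-type enrichment flags a planted phospho excess in IDDs", {
  fx <- ptm_fixture()
  # 60 phospho sites in the IDD, 20 acetyl sites in the structured domain,
  # and a thin shared background of both types
  sites <- rbind(
    data.frame(protein_id = "p1", position = 1:60, residue = "S",
               mod_type = "Phosphoserine"),
    data.frame(protein_id = "p1", position = 151:170, residue = "K",
               mod_type = "N6-acetyllysine"),
    data.frame(protein_id = "p1", position = 61:70, residue = "K",
               mod_type = "N6-acetyllysine"),
    data.frame(protein_id = "p1", position = 171:180, residue = "S",
               mod_type = "Phosphoserine"))
  res <- ptmTypeEnrichment(fx$metrics, sites)
  phos <- res[res$term == "Phosphoserine", ]
  expect_lt(phos$q_over, 0.05)
  expect_gte(phos$grade, 2)
  acet <- res[res$term == "N6-acetyllysine", ]
  expect_lt(acet$grade, 0)
  # a single observed type cannot deviate from its universe share
  one <- ptmTypeEnrichment(fx$metrics,
                           data.frame(protein_id = "p1", position = 1:5,
                                      residue = "S",
                                      mod_type = "Phosphoserine"))
  expect_equal(abs(one$grade), 0.25)
  # no sites at all -> empty result
  empty <- ptmTypeEnrichment(fx$metrics,
                             data.frame(protein_id = "pX", position = 1L,
                                        residue = "S",
                                        mod_type = "Phosphoserine"))
  expect_equal(nrow(empty), 0L)
})
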