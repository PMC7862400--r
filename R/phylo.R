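## Species-distribution width categories, domain age grades, and
## disordered width, all driven by a ranked lineage table
## (see readLineageTable: species_id followed by root-to-leaf rank columns).

.lineage_matrix <- function(lineages, species) {
  miss <- setdiff(species, lineages$species_id)
  if (length(miss))
    stop("species missing from lineage table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  as.matrix(lineages[match(species, lineages$species_id), -1, drop = FALSE])
}

#' Default species-distribution-width scheme
#'
#' Ordered category list evaluated first-match-wins against the ranked
#' lineages of the species carrying a family: species-specific, then
#' specific to one taxon of each rank from leaf-most to root-most
#' (phylum-, kingdom-, superkingdom-specific with the default rank names),
#' and finally a cross-superkingdom fallback for families spanning the
#' root. Users may supply their own ordered scheme in the same shape.
#'
#' @param ranks rank column names of the lineage table, root first
#'   (default superkingdom, kingdom, phylum).
#' @return ordered list of entries \code{list(category, test)} where
#'   \code{test(linmat)} takes the lineage matrix of the family's species.
#' @export
defaultDistributionScheme <- function(ranks = c("superkingdom", "kingdom",
                                                "phylum")) {
  scheme <- list(list(category = "species_specific",
                      test = function(lm) nrow(lm) == 1L))
  for (r in rev(ranks)) {
    local({
      rr <- r
      scheme[[length(scheme) + 1L]] <<- list(
        category = paste0(rr, "_specific"),
        test = function(lm) rr %in% colnames(lm) &&
          length(unique(lm[, rr])) == 1L)
    })
  }
  scheme[[length(scheme) + 1L]] <- list(
    category = "cross_superkingdom", test = function(lm) TRUE)
  scheme
}

#' Distribution width of a domain family
#'
#' Applies an ordered category scheme to the set of lineages of the
#' species containing the family; the first matching category wins.
#'
#' @param species character vector of species carrying the family.
#' @param lineages a lineage table (\code{\link{readLineageTable}}).
#' @param scheme ordered scheme (default
#'   \code{\link{defaultDistributionScheme}} on the table's rank columns).
#' @return list with family n_species and category.
#' @export
distributionWidth <- function(species, lineages, scheme = NULL) {
  species <- unique(species)
  lm <- .lineage_matrix(lineages, species)
  if (is.null(scheme))
    scheme <- defaultDistributionScheme(
      setdiff(colnames(lineages), c("species_id", "species")))
  for (entry in scheme)
    if (isTRUE(entry$test(lm)))
      return(list(n_species = length(species), category = entry$category))
  list(n_species = length(species), category = NA_character_)
}

#' Domain age grade of a family for a representative species
#'
#' The age grade is the oldest (root-most) taxon in which the family first
#' appeared: the lowest common ancestor of the lineages of every species
#' carrying the family, read off the representative species' lineage.
#' Depth 0 is the root (reported as grade "root" when the lineages share
#' no taxon at all); larger depths are younger.
#'
#' @param species species carrying the family (must include the
#'   representative).
#' @param representative the representative species.
#' @param lineages a lineage table.
#' @return list with grade (taxon name), grade_depth (0 = root) and
#'   n_species.
#' @export
domainAge <- function(species, representative, lineages) {
  species <- unique(c(representative, species))
  if (!representative %in% species)
    stop("representative species does not carry the family", call. = FALSE)
  lm <- .lineage_matrix(lineages, species)
  rep_lin <- lm[match(representative, species), ]
  depth <- 0L
  for (j in seq_len(ncol(lm))) {
    if (length(unique(lm[, j])) == 1L && depth == j - 1L) depth <- j
    else break
  }
  list(grade = if (depth == 0L) "root" else unname(rep_lin[depth]),
       grade_depth = depth, n_species = length(species))
}

#' Disordered width of a domain family
#'
#' Percentage of family-carrying species in which the family is called an
#' IDD. A family is widely disordered when this strictly exceeds 50\%.
#'
#' @param iddCalls logical vector: per carrying species, is the family an
#'   IDD there (by the family-dominant rule, the default, or any
#'   instance-level rule chosen upstream).
#' @return list with n_species, pct_species_idd and widely_disordered.
#' @export
disorderedWidth <- function(iddCalls) {
  if (!length(iddCalls)) stop("family carried by no species", call. = FALSE)
  pct <- 100 * mean(iddCalls)
  list(n_species = length(iddCalls), pct_species_idd = pct,
       widely_disordered = pct > 50)
}

#' Family-level phylogenetic summaries across species
#'
#' Per family across all species in a family-profile table: distribution
#' width, disordered width, and (for a chosen representative species) the
#' domain age grade.
#'
#' @param famProfiles output of \code{\link{familyProfiles}} over several
#'   species.
#' @param lineages a lineage table.
#' @param representative species used to read off age grades (families it
#'   does not carry get NA age).
#' @param scheme optional distribution-width scheme.
#' @return data.frame, one row per family.
#' @export
familyPhyloSummary <- function(famProfiles, lineages, representative,
                               scheme = NULL) {
  fams <- split(famProfiles, famProfiles$family_id)
  rows <- lapply(fams, function(fp) {
    dw <- distributionWidth(fp$species_id, lineages, scheme)
    wid <- disorderedWidth(fp$family_idd)
    age <- if (representative %in% fp$species_id)
      domainAge(fp$species_id, representative, lineages)
    else list(grade = NA_character_, grade_depth = NA_integer_)
    data.frame(family_id = fp$family_id[1], n_species = dw$n_species,
               distribution_category = dw$category,
               pct_species_idd = wid$pct_species_idd,
               widely_disordered = wid$widely_disordered,
               age_grade = age$grade, age_depth = age$grade_depth,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' IDD fraction by domain age grade for one species
#'
#' Joins per-instance metrics of one (representative) species with family
#' age depths and reports, per age grade, the fraction of domain instances
#' and of families that are intrinsically disordered (DSDR > 30 or
#' CDRN >= 1).
#'
#' @param metrics per-instance metric table of the representative species.
#' @param familyAges data.frame family_id, age_grade, age_depth (e.g. from
#'   \code{\link{familyPhyloSummary}}).
#' @param familyIdd optional data.frame family_id, family_idd with the
#'   species' family-level IDD calls (from \code{\link{familyProfiles}}).
#' @return data.frame per age grade: counts and IDD fractions, ordered by
#'   depth (oldest first).
#' @export
iddFractionByAge <- function(metrics, familyAges, familyIdd = NULL) {
  m <- merge(metrics, familyAges[, c("family_id", "age_grade", "age_depth")],
             by = "family_id")
  if (!nrow(m))
    return(data.frame(age_grade = character(0), age_depth = integer(0),
                      n_instances = integer(0), frac_idd_instances = numeric(0)))
  parts <- split(m, m$age_depth)
  rows <- lapply(parts, function(g) {
    r <- data.frame(age_grade = g$age_grade[1], age_depth = g$age_depth[1],
                    n_instances = nrow(g),
                    frac_idd_instances = mean(g$is_idd))
    if (!is.null(familyIdd)) {
      fams <- unique(g$family_id)
      calls <- familyIdd$family_idd[match(fams, familyIdd$family_id)]
      r$n_families <- length(fams)
      r$frac_idd_families <- mean(calls, na.rm = TRUE)
    }
    r
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$age_depth), , drop = FALSE]
  rownames(out) <- NULL
  out
}
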