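## PTM-site density by domain disorder class and PTM-type
## over-representation in intrinsically disordered domains.

.match_sites_to_domains <- function(metrics, sites) {
  ## index of the domain row containing each site (first match wins for
  ## overlapping instances); NA when no domain contains the site
  hit <- rep(NA_integer_, nrow(sites))
  byProt <- split(seq_len(nrow(metrics)), metrics$protein_id)
  for (i in seq_len(nrow(sites))) {
    rows <- byProt[[sites$protein_id[i]]]
    if (is.null(rows)) next
    inside <- rows[metrics$start[rows] <= sites$position[i] &
                   metrics$end[rows] >= sites$position[i]]
    if (length(inside)) hit[i] <- inside[1]
  }
  hit
}

#' PTM-site density by domain disorder class
#'
#' Assigns each modification site to the domain instance containing it and
#' pools sites and residues per category of a chosen classifier: the DSDR
#' grade, the CDRN class (0 / 1 / >= 2) or the DSDR-CDRN quadrant. The
#' density is sites per residue within the category, the only unit
#' comparable across categories of different total size. Per-domain
#' densities are returned alongside for rank-based comparisons between
#' categories. Sites on proteins absent from the domain table, or falling
#' between domains, are counted in no category.
#'
#' @param metrics per-instance metric table (\code{\link{domainMetrics}}).
#' @param sites PTM site table (protein_id, position, residue, mod_type).
#' @param classifier one of "dsdr_grade", "cdrn_class", "quadrant".
#' @return data.frame per category (n_domains, n_sites, n_residues,
#'   density) with attribute \code{"per_domain"}: per-domain site counts
#'   and densities.
#' @export
ptmDensityByClass <- function(metrics, sites,
                              classifier = c("dsdr_grade", "cdrn_class",
                                             "quadrant")) {
  classifier <- match.arg(classifier)
  cat <- switch(classifier,
    dsdr_grade = metrics$dsdr_grade,
    cdrn_class = ifelse(metrics$cdrn == 0, "0",
                        ifelse(metrics$cdrn == 1, "1", ">=2")),
    quadrant = metrics$quadrant)
  hit <- .match_sites_to_domains(metrics, sites)
  nsites <- tabulate(hit[!is.na(hit)], nbins = nrow(metrics))
  perDomain <- data.frame(metrics[, c("protein_id", "family_id", "start",
                                      "end", "length")],
                          category = cat, n_sites = nsites,
                          density = nsites / metrics$length,
                          stringsAsFactors = FALSE)
  cats <- sort(unique(cat))
  out <- do.call(rbind, lapply(cats, function(cc) {
    sel <- cat == cc
    data.frame(category = cc, n_domains = sum(sel),
               n_sites = sum(nsites[sel]),
               n_residues = sum(metrics$length[sel]),
               density = sum(nsites[sel]) / sum(metrics$length[sel]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "per_domain") <- perDomain
  out
}

#' PTM density inside vs outside CDRs of disordered domains
#'
#' For every IDD with at least one CDR, partitions its residues into the
#' CDR part and the non-CDR remainder and counts the sites falling in
#' each; sites assigned to the two parts always sum to the sites of the
#' parent domain. Domains without a CDR are excluded.
#'
#' @param metrics per-instance metric table.
#' @param profiles named list of \linkS4class{DisorderProfile} or logical
#'   call vectors (needed to locate the CDR intervals).
#' @param sites PTM site table.
#' @return data.frame per qualifying domain: cdr_residues, noncdr_residues,
#'   cdr_sites, noncdr_sites, cdr_density, noncdr_density.
#' @export
cdrVsNoncdrDensity <- function(metrics, profiles, sites) {
  keep <- which(metrics$is_idd & metrics$cdrn >= 1)
  rows <- lapply(keep, function(i) {
    st <- metrics$start[i]; en <- metrics$end[i]
    cdrs <- findCDRs(profiles[[metrics$protein_id[i]]], st, en)
    cdr_len <- sum(cdrs$length)
    s <- sites[sites$protein_id == metrics$protein_id[i] &
               sites$position >= st & sites$position <= en, , drop = FALSE]
    pos_rel <- s$position - st + 1L
    in_cdr <- vapply(pos_rel, function(p)
      any(p >= cdrs$start & p <= cdrs$end), logical(1))
    data.frame(protein_id = metrics$protein_id[i],
               family_id = metrics$family_id[i],
               start = st, end = en,
               cdr_residues = cdr_len,
               noncdr_residues = metrics$length[i] - cdr_len,
               cdr_sites = sum(in_cdr), noncdr_sites = sum(!in_cdr),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(0), family_id = character(0),
               start = integer(0), end = integer(0),
               cdr_residues = integer(0), noncdr_residues = integer(0),
               cdr_sites = integer(0), noncdr_sites = integer(0))
  out$cdr_density <- ifelse(out$cdr_residues > 0,
                            out$cdr_sites / out$cdr_residues, NA_real_)
  out$noncdr_density <- ifelse(out$noncdr_residues > 0,
                               out$noncdr_sites / out$noncdr_residues,
                               NA_real_)
  rownames(out) <- NULL
  out
}

#' Over-represented PTM types in disordered domains
#'
#' Hypergeometric test per modification type: sites falling in IDDs
#' (selection) against sites falling in any domain (universe), via
#' \code{\link{enrich}}. Types are compared at the description-string
#' level (e.g. "Phosphoserine"), not collapsed to chemistry classes.
#'
#' @param metrics per-instance metric table.
#' @param sites PTM site table.
#' @return \code{\link{enrich}}-style data.frame, one row per mod_type
#'   observed in domains (empty when no site falls in a domain).
#' @export
ptmTypeEnrichment <- function(metrics, sites) {
  hit <- .match_sites_to_domains(metrics, sites)
  in_dom <- !is.na(hit)
  if (!any(in_dom))
    return(enrich(character(0), character(0),
                  data.frame(family_id = character(0), term = character(0))))
  site_id <- paste0("site", seq_len(nrow(sites)))
  universe <- site_id[in_dom]
  selection <- site_id[in_dom & metrics$is_idd[hit]]
  ann <- data.frame(family_id = universe,
                    term = sites$mod_type[in_dom],
                    stringsAsFactors = FALSE)
  enrich(selection, universe, ann)
}
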