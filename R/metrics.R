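## Per-domain and per-region disorder metrics: DSDR, CDR detection, CDRN,
## grade / quadrant / IDD classification, protein-level PSDR, non-domain
## regions and per-species summaries.

.DSDR_GRADES <- c("completely_structured", "highly_structured",
                  "moderately_unstructured", "intrinsically_disordered")

.check_interval <- function(calls, start, end) {
  if (start < 1L || end > length(calls) || start > end)
    stop("invalid interval [", start, ", ", end, "] for a profile of length ",
         length(calls), call. = FALSE)
}

.get_calls <- function(x) if (methods::is(x, "DisorderProfile"))
  disorderCalls(x) else as.logical(x)

#' Domain structural disorder ratio (DSDR)
#'
#' Percentage of disordered residues within an interval of a per-residue
#' call track.
#'
#' @param calls logical call track or a \linkS4class{DisorderProfile}.
#' @param start,end 1-based inclusive interval bounds (default: whole track).
#' @return DSDR in percent, in \[0, 100\].
#' @export
computeDSDR <- function(calls, start = 1L, end = length(.get_calls(calls))) {
  calls <- .get_calls(calls)
  .check_interval(calls, start, end)
  100 * sum(calls[start:end]) / (end - start + 1L)
}

#' Find consecutive disordered regions (CDRs)
#'
#' A CDR is a maximal run of disordered residues that qualifies by length:
#' for regions longer than 50 residues a run must exceed 20 residues; for
#' regions of at most 50 residues a run must exceed 40\% of the region
#' length. Both inequalities are strict, so a 20-residue run in a long
#' domain, or a run of exactly 40\%, does not qualify.
#'
#' @inheritParams computeDSDR
#' @return data.frame with columns start, end, length; coordinates are
#'   1-based within the interval, rows in coordinate order.
#' @export
findCDRs <- function(calls, start = 1L, end = length(.get_calls(calls))) {
  calls <- .get_calls(calls)
  .check_interval(calls, start, end)
  v <- calls[start:end]
  L <- length(v)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (if (L > 50L) r$lengths > 20L else r$lengths > 0.4 * L)
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}

#' Classify DSDR into the four disorder grades
#'
#' Bins: exactly 0 is completely structured; (0, 10\] highly structured;
#' (10, 30\] moderately unstructured; (30, 100\] intrinsically disordered.
#' Boundary values fall to the structured side, consistent with the strict
#' "DSDR > 30\%" rule defining intrinsically disordered domains.
#'
#' @param dsdr numeric vector of DSDR percentages in \[0, 100\].
#' @return character vector of grade labels.
#' @export
classifyDSDRGrade <- function(dsdr) {
  if (any(is.na(dsdr)) || any(dsdr < 0 | dsdr > 100))
    stop("DSDR must lie in [0, 100]", call. = FALSE)
  out <- character(length(dsdr))
  out[dsdr == 0] <- .DSDR_GRADES[1]
  out[dsdr > 0 & dsdr <= 10] <- .DSDR_GRADES[2]
  out[dsdr > 10 & dsdr <= 30] <- .DSDR_GRADES[3]
  out[dsdr > 30] <- .DSDR_GRADES[4]
  out
}

#' Classify a domain into the DSDR/CDRN quadrants
#'
#' I: DSDR > 30 and CDRN >= 1; II: DSDR <= 30 and CDRN >= 1;
#' III: DSDR <= 30 and CDRN = 0; IV: DSDR > 30 and CDRN = 0.
#' Classes I, II and IV are intrinsically disordered domains.
#'
#' @param dsdr numeric DSDR percentages.
#' @param cdrn integer CDR counts.
#' @return character vector in \{"I","II","III","IV"\}.
#' @export
classifyQuadrant <- function(dsdr, cdrn) {
  high <- dsdr > 30
  has <- cdrn >= 1
  ifelse(high & has, "I",
         ifelse(!high & has, "II",
                ifelse(!high, "III", "IV")))
}

#' Is a domain intrinsically disordered?
#'
#' IDD rule: DSDR > 30\% (strict) or at least one CDR.
#' @inheritParams classifyQuadrant
#' @export
isIDD <- function(dsdr, cdrn) dsdr > 30 | cdrn >= 1

#' Metrics for one region of a call track
#'
#' @inheritParams computeDSDR
#' @return list with length, n_disordered, dsdr, cdr_intervals (data.frame),
#'   cdrn, dsdr_grade, quadrant, is_idd.
#' @export
regionMetrics <- function(calls, start = 1L, end = length(.get_calls(calls))) {
  calls <- .get_calls(calls)
  .check_interval(calls, start, end)
  v <- calls[start:end]
  dsdr <- 100 * sum(v) / length(v)
  cdrs <- findCDRs(calls, start, end)
  cdrn <- nrow(cdrs)
  list(length = length(v), n_disordered = sum(v), dsdr = dsdr,
       cdr_intervals = cdrs, cdrn = cdrn,
       dsdr_grade = classifyDSDRGrade(dsdr),
       quadrant = classifyQuadrant(dsdr, cdrn),
       is_idd = isIDD(dsdr, cdrn))
}

#' Per-instance metrics for a domain table
#'
#' Attaches length, n_disordered, dsdr, cdrn, dsdr_grade, quadrant, is_idd
#' and norm_dsdr columns to a domain-instance table, computed on each
#' instance's interval of its protein's call track.
#'
#' @param domains data.frame with protein_id, family_id, start, end (see
#'   \code{\link{readDomtblout}}).
#' @param profiles named list of \linkS4class{DisorderProfile} objects (or
#'   plain logical call vectors), keyed by protein_id.
#' @return the input data.frame with metric columns appended.
#' @export
domainMetrics <- function(domains, profiles) {
  n <- nrow(domains)
  calls_by_prot <- lapply(profiles, .get_calls)
  missing <- setdiff(unique(domains$protein_id), names(calls_by_prot))
  if (length(missing))
    stop("no disorder profile for protein(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  len <- domains$end - domains$start + 1L
  ndis <- integer(n); cdrn <- integer(n)
  for (i in seq_len(n)) {
    v <- calls_by_prot[[domains$protein_id[i]]]
    .check_interval(v, domains$start[i], domains$end[i])
    seg <- v[domains$start[i]:domains$end[i]]
    ndis[i] <- sum(seg)
    r <- rle(seg)
    cdrn[i] <- sum(r$values &
      (if (len[i] > 50L) r$lengths > 20L else r$lengths > 0.4 * len[i]))
  }
  out <- domains
  out$length <- len
  out$n_disordered <- ndis
  out$dsdr <- 100 * ndis / len
  out$cdrn <- cdrn
  out$dsdr_grade <- classifyDSDRGrade(out$dsdr)
  out$quadrant <- classifyQuadrant(out$dsdr, cdrn)
  out$is_idd <- isIDD(out$dsdr, cdrn)
  out$norm_dsdr <- normalizeDSDR(out$dsdr)
  out
}

#' Select representative proteins (longest per gene)
#'
#' Ties on length are broken by the lexicographically smallest protein_id,
#' for determinism.
#'
#' @param proteins data.frame with protein_id, gene_id and length columns.
#' @return the subset of rows kept, one per gene.
#' @export
selectRepresentatives <- function(proteins) {
  o <- order(proteins$gene_id, -proteins$length, proteins$protein_id)
  p <- proteins[o, , drop = FALSE]
  out <- p[!duplicated(p$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Protein-level disorder metrics (PSDR)
#'
#' PSDR is the percentage of disordered residues over the whole protein;
#' proteins with PSDR strictly above 30\% are intrinsically disordered
#' proteins (IDPs). Representative-protein selection (longest per gene) is
#' applied upstream via \code{\link{selectRepresentatives}}.
#'
#' @param profiles named list of \linkS4class{DisorderProfile} (or logical
#'   call vectors).
#' @return data.frame with protein_id, length, psdr, is_idp.
#' @export
proteinMetrics <- function(profiles) {
  calls <- lapply(profiles, .get_calls)
  psdr <- vapply(calls, function(v) 100 * mean(v), numeric(1))
  data.frame(protein_id = names(calls),
             length = lengths(calls),
             psdr = unname(psdr),
             is_idp = unname(psdr > 30),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Complement of the domain intervals on a protein
#'
#' Returns the linkers and N-/C-terminal regions: the complement of the
#' union of the domain intervals, in coordinate order. Metrics on these
#' regions use the same CDR qualification rules with the region length in
#' place of the domain length.
#'
#' @param proteinLength protein length in residues.
#' @param starts,ends 1-based inclusive domain coordinates (may overlap).
#' @return data.frame with columns start, end (possibly zero rows).
#' @export
nonDomainRegions <- function(proteinLength, starts, ends) {
  if (!length(starts))
    return(data.frame(start = 1L, end = as.integer(proteinLength)))
  dom <- IRanges::reduce(IRanges::IRanges(start = starts, end = ends))
  gap <- IRanges::gaps(dom, start = 1L, end = as.integer(proteinLength))
  data.frame(start = IRanges::start(gap), end = IRanges::end(gap))
}

#' Per-species summary of domain and protein disorder
#'
#' For each species: the percentage of domain instances that are IDDs by
#' the DSDR rule (DSDR > 30), by the CDRN rule (CDRN >= 1) and by either
#' rule; the percentage of IDPs; mean PSDR; and counts. The DSDR-rule and
#' CDRN-rule percentages are the X and Y values of the per-species
#' DSDR-vs-CDRN scatter (quadrants I+IV and I+II respectively). Species
#' with zero domains get NA percentages.
#'
#' @param metrics per-instance metrics (\code{\link{domainMetrics}}) with a
#'   species_id column, or without one if \code{proteins} provides the map.
#' @param proteinTable data.frame protein_id, species_id (and optionally
#'   gene_id/length) mapping proteins to species.
#' @param protMetrics optional output of \code{\link{proteinMetrics}} on the
#'   representative proteins.
#' @return data.frame, one row per species.
#' @export
speciesSummary <- function(metrics, proteinTable, protMetrics = NULL) {
  if (!"species_id" %in% names(metrics))
    metrics$species_id <- proteinTable$species_id[
      match(metrics$protein_id, proteinTable$protein_id)]
  species <- sort(unique(proteinTable$species_id))
  rows <- lapply(species, function(s) {
    m <- metrics[metrics$species_id == s, , drop = FALSE]
    nd <- nrow(m)
    pct <- function(x) if (nd) 100 * sum(x) / nd else NA_real_
    r <- data.frame(species_id = s, n_domains = nd,
                    pct_idd_dsdr = pct(m$dsdr > 30),
                    pct_idd_cdrn = pct(m$cdrn >= 1),
                    pct_idd = pct(m$is_idd))
    if (!is.null(protMetrics)) {
      pm <- protMetrics[protMetrics$protein_id %in%
                          proteinTable$protein_id[proteinTable$species_id == s],
                        , drop = FALSE]
      r$n_proteins <- nrow(pm)
      r$mean_psdr <- if (nrow(pm)) mean(pm$psdr) else NA_real_
      r$pct_idp <- if (nrow(pm)) 100 * mean(pm$is_idp) else NA_real_
    }
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
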