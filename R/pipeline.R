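## End-to-end orchestration over a proteome bundle: per-domain profiling,
## complexity correlations, repeat-variation analysis and enrichment.
## A bundle is the in-memory list produced by simulateProteome() or
## readBundle(); all randomness sits in the generator, so reruns on the
## same bundle are deterministic.

.published_defaults <- function() list(
  idd_dsdr_cutoff = 30, cdr_long_run = 20, cdr_short_frac = 0.40,
  dominant_cutoff = 0.5, variation_bins = c(0, 1, 3),
  evalue_cutoff = 0.01)

#' Read a proteome bundle from a directory of standard-format files
#'
#' Counterpart of \code{\link{writeBundle}}: FASTA, IUPred-style scores,
#' domtblout, lineage/cell-type/annotation/PTM TSVs and BLAST tabular
#' alignments (each optional except scores and domains).
#'
#' @param dir directory holding the files written by
#'   \code{\link{writeBundle}}.
#' @param threshold disorder call threshold (default 0.5).
#' @return bundle list in the shape of \code{\link{simulateProteome}}.
#' @export
readBundle <- function(dir, threshold = 0.5) {
  p <- function(f) file.path(dir, f)
  profs <- readDisorderScores(p("disorder_scores.txt"), threshold)
  domains <- readDomtblout(p("domains.domtblout"))
  sequences <- if (file.exists(p("proteome.fasta"))) {
    s <- readFasta(p("proteome.fasta")); stats::setNames(as.character(s),
                                                         names(s))
  } else NULL
  lineages <- if (file.exists(p("lineage.tsv")))
    readLineageTable(p("lineage.tsv")) else NULL
  cellTypes <- if (file.exists(p("cell_types.tsv")))
    readCellTypeTable(p("cell_types.tsv")) else NULL
  annotation <- if (file.exists(p("annotation.tsv")))
    readAnnotationTable(p("annotation.tsv")) else NULL
  ptm <- if (file.exists(p("ptm.tsv"))) readPTMTable(p("ptm.tsv")) else NULL
  alignments <- if (file.exists(p("alignments.tsv")))
    readBlastTabular(p("alignments.tsv")) else NULL
  species_of <- function(pid) sub("_p\\d+$", "", pid)
  prot_ids <- names(profs)
  proteins <- data.frame(protein_id = prot_ids, gene_id = prot_ids,
                         species_id = species_of(prot_ids),
                         length = vapply(profs, length, integer(1)),
                         stringsAsFactors = FALSE, row.names = NULL)
  domains$species_id <- species_of(domains$protein_id)
  list(species = NULL, lineages = lineages, cellTypes = cellTypes,
       proteins = proteins, profiles = profs, domains = domains,
       annotation = annotation, ptm = ptm, alignments = alignments,
       sequences = sequences, groundTruth = NULL)
}

#' Per-domain metrics and per-species summaries for a bundle
#'
#' @param bundle proteome bundle.
#' @return list with \code{metrics} (per-instance), \code{proteins}
#'   (per representative protein), \code{species} (per-species summary)
#'   and \code{families} (per species x family profile).
#' @export
runProfile <- function(bundle) {
  if (!nrow(bundle$proteins)) stop("empty species set", call. = FALSE)
  metrics <- domainMetrics(bundle$domains, bundle$profiles)
  if (!"species_id" %in% names(metrics))
    metrics$species_id <- bundle$proteins$species_id[
      match(metrics$protein_id, bundle$proteins$protein_id)]
  reps <- selectRepresentatives(bundle$proteins)
  protM <- proteinMetrics(bundle$profiles[reps$protein_id])
  sp <- speciesSummary(metrics, bundle$proteins, protM)
  fams <- familyProfiles(metrics)
  list(metrics = metrics, proteins = protM, species = sp, families = fams)
}

#' Disorder-complexity correlations for a bundle
#'
#' Spearman correlation of six per-species disorder measures against the
#' cell-type number: mean PSDR, percent IDPs, percent IDDs by the DSDR
#' rule, percent IDDs by the CDRN rule, percent disordered families by
#' the family-DSDR dominant rule and by the family-CDRN flag.
#'
#' @param bundle proteome bundle (needs cellTypes).
#' @param profile optional precomputed \code{\link{runProfile}} output.
#' @return data.frame with measure, rho, p, n.
#' @export
runCorrelate <- function(bundle, profile = NULL) {
  if (is.null(bundle$cellTypes)) stop("bundle has no cell-type table",
                                      call. = FALSE)
  if (is.null(profile)) profile <- runProfile(bundle)
  sp <- profile$species
  fam <- profile$families
  famAgg <- do.call(rbind, lapply(split(fam, fam$species_id), function(f)
    data.frame(species_id = f$species_id[1],
               pct_fam_dsdr = 100 * mean(
                 f$dominant_category %in% "intrinsically_disordered"),
               pct_fam_cdrn = 100 * mean(f$family_cdrn_flag),
               stringsAsFactors = FALSE)))
  sp <- merge(sp, famAgg, by = "species_id", all.x = TRUE)
  ct <- bundle$cellTypes$cell_types[match(sp$species_id,
                                          bundle$cellTypes$species_id)]
  measures <- c(mean_psdr = "mean_psdr", pct_idp = "pct_idp",
                pct_idd_dsdr = "pct_idd_dsdr", pct_idd_cdrn = "pct_idd_cdrn",
                pct_fam_dsdr = "pct_fam_dsdr", pct_fam_cdrn = "pct_fam_cdrn")
  measures <- measures[measures %in% names(sp)]
  rows <- lapply(names(measures), function(m) {
    r <- spearmanCorrelation(ct, sp[[measures[[m]]]])
    data.frame(measure = m, rho = r$rho, p = r$p, n = r$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Repeat-domain variation analysis for a bundle
#'
#' Per species: variation records for every repeating family (within- and
#' across-protein scopes) and the Fisher test comparing the no-variation
#' proportion between the two repetition scopes.
#'
#' @param bundle proteome bundle.
#' @param profile optional precomputed \code{\link{runProfile}} output.
#' @return list with \code{records} (all species' variation tables, with
#'   species_id) and \code{fisher} (per-species test results).
#' @export
runVariation <- function(bundle, profile = NULL) {
  if (is.null(profile)) profile <- runProfile(bundle)
  m <- profile$metrics
  recs <- list(); fish <- list()
  for (s in sort(unique(m$species_id))) {
    vt <- variationTable(m[m$species_id == s, , drop = FALSE])
    if (!nrow(vt)) next
    recs[[s]] <- cbind(data.frame(species_id = s), vt)
    ft <- noVariationProportionTest(vt)
    fish[[s]] <- data.frame(
      species_id = s, p = ft$p, defined = ft$defined,
      direction = if (is.na(ft$direction)) NA_character_ else ft$direction,
      n_within = sum(ft$table[, 1]), n_across = sum(ft$table[, 2]),
      stringsAsFactors = FALSE)
  }
  list(records = if (length(recs)) do.call(rbind, c(recs,
                                                    make.row.names = FALSE))
       else NULL,
       fisher = if (length(fish)) do.call(rbind, c(fish,
                                                   make.row.names = FALSE))
       else NULL)
}

#' Annotation enrichment of disordered families for a bundle
#'
#' Selection: families called IDD (dominant category intrinsically
#' disordered or family CDRN flag) in more than half of their carrying
#' species; universe: all families seen in the bundle. PTM-type
#' enrichment in IDDs is added when the bundle carries PTM sites.
#'
#' @param bundle proteome bundle (needs annotation).
#' @param profile optional precomputed \code{\link{runProfile}} output.
#' @return list with \code{families} (enrich table) and \code{ptm}
#'   (enrich table or NULL).
#' @export
runEnrich <- function(bundle, profile = NULL) {
  if (is.null(bundle$annotation)) stop("bundle has no annotation table",
                                       call. = FALSE)
  if (is.null(profile)) profile <- runProfile(bundle)
  fam <- profile$families
  share <- tapply(fam$family_idd, fam$family_id, mean)
  universe <- names(share)
  selection <- universe[share > 0.5]
  famEnrich <- enrich(selection, universe, bundle$annotation)
  ptmEnrich <- if (!is.null(bundle$ptm) && nrow(bundle$ptm))
    ptmTypeEnrichment(profile$metrics, bundle$ptm) else NULL
  list(families = famEnrich, ptm = ptmEnrich)
}

#' Run the full pipeline and optionally write the output tables
#'
#' @param bundle proteome bundle.
#' @param outDir optional directory for TSV outputs and run metadata.
#' @return list with profile, correlations, variation and enrichment.
#' @export
runAll <- function(bundle, outDir = NULL) {
  profile <- runProfile(bundle)
  correlations <- if (!is.null(bundle$cellTypes))
    runCorrelate(bundle, profile) else NULL
  variation <- runVariation(bundle, profile)
  enrichment <- if (!is.null(bundle$annotation))
    runEnrich(bundle, profile) else NULL
  res <- list(profile = profile, correlations = correlations,
              variation = variation, enrichment = enrichment)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeTSV(profile$metrics, file.path(outDir, "domain_metrics.tsv"))
    writeTSV(profile$species, file.path(outDir, "species_summary.tsv"))
    writeTSV(profile$families, file.path(outDir, "family_profiles.tsv"))
    if (!is.null(correlations))
      writeTSV(correlations, file.path(outDir, "correlations.tsv"))
    if (!is.null(variation$records))
      writeTSV(variation$records, file.path(outDir, "variation_records.tsv"))
    if (!is.null(variation$fisher))
      writeTSV(variation$fisher, file.path(outDir, "variation_fisher.tsv"))
    if (!is.null(enrichment)) {
      writeTSV(enrichment$families, file.path(outDir, "enrichment.tsv"))
      if (!is.null(enrichment$ptm))
        writeTSV(enrichment$ptm, file.path(outDir, "ptm_enrichment.tsv"))
    }
    jsonlite::write_json(
      list(package = "IDDomains",
           version = as.character(utils::packageVersion("IDDomains")),
           defaults = .published_defaults(),
           timestamp = format(Sys.time(), tz = "UTC")),
      file.path(outDir, "run_metadata.json"), auto_unbox = TRUE)
  }
  res
}
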