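## Seeded generator of complete synthetic proteome bundles with the
## statistical structure the downstream analyses assume: block-structured
## per-residue disorder calls with controllable DSDR/CDR composition,
## clade-structured species sets, a planted complexity gradient in the
## fraction of disordered families, family repetition within and across
## proteins, annotation tables with a planted enriched term, and PTM sites
## with planted excess density in disordered residues.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Default synthetic-proteome configuration
#'
#' The defaults define the study conditions the generator emulates:
#' 51 eukaryotic species spread over four kingdoms (two phyla each), cell
#' type numbers log-spaced from 2 to 220, a planted linear gradient of the
#' per-species disordered-family fraction from 0.08 to 0.45 along the
#' complexity rank (flat at the midpoint when \code{gradient} is FALSE),
#' domain lengths ~ Normal(120, 30) truncated at 30, disordered domains
#' carrying one disordered block covering 40-90\% of their residues,
#' structured domains carrying scattered blocks of at most 10 residues
#' totalling 0-15\%, linkers 35\% disordered in short blocks, 15\% of
#' families repeating within a protein and 25\% across proteins, and PTM
#' sites at 0.004 per residue with a 3x multiplier on disordered residues.
#'
#' @param seed integer seed; fully determines the generated bundle.
#' @param nSpecies number of species (default 51).
#' @param gradient plant the complexity gradient (default TRUE)?
#' @param sequences also generate amino-acid sequences (default TRUE;
#'   disable for large simulation sweeps that never touch sequences)?
#' @return nested configuration list.
#' @export
defaultSimConfig <- function(seed = 1L, nSpecies = 51L, gradient = TRUE,
                             sequences = TRUE) {
  list(
    seed = as.integer(seed),
    nSpecies = as.integer(nSpecies),
    sequences = isTRUE(sequences),
    kingdoms = c("Metazoa", "Fungi", "Viridiplantae", "Protista"),
    phylaPerKingdom = 2L,
    complexity = list(min = 2, max = 220),
    iddFrac = list(base = 0.08, span = 0.37, gradient = isTRUE(gradient)),
    families = list(core = 60L, kingdomSpecific = 40L, phylumSpecific = 30L,
                    speciesSpecific = 20L, youngDisorderBoost = 0.15),
    domain = list(meanLen = 120, sdLen = 30, minLen = 30L, maxLen = 400L),
    disorder = list(threshold = 0.5, structuredMax = 0.15,
                    disorderedRange = c(0.40, 0.90), structuredBlockMax = 10L,
                    typeIIFrac = 0.1, typeIVFrac = 0.1,
                    linkerP = 0.35, linkerBlockMax = 8L),
    repetition = list(withinFrac = 0.15, acrossFrac = 0.25, maxCopies = 3L,
                      conservedWithin = 0.7, conservedAcross = 0.45),
    protein = list(linkerMin = 10L, linkerMax = 50L),
    annotation = list(nTerms = 40L, termsPerFamily = 3L,
                      plantedTerm = "GO:PLANTED", plantedBaseP = 0.2,
                      plantedOR = 5),
    ptm = list(baselineDensity = 0.004, disorderedMultiplier = 3,
               types = c("Phosphoserine", "Phosphothreonine",
                         "N6-acetyllysine", "Omega-N-methylarginine"))
  )
}

.validateSimConfig <- function(cfg) {
  probs <- c(cfg$iddFrac$base, cfg$iddFrac$base + cfg$iddFrac$span,
             cfg$disorder$structuredMax, cfg$disorder$disorderedRange,
             cfg$disorder$linkerP, cfg$repetition$withinFrac,
             cfg$repetition$acrossFrac, cfg$annotation$plantedBaseP)
  if (any(probs < 0 | probs > 1))
    stop("infeasible configuration: probabilities must lie in [0, 1]",
         call. = FALSE)
  if (cfg$ptm$disorderedMultiplier < 0 || cfg$annotation$plantedOR < 0)
    stop("infeasible configuration: multipliers must be >= 0", call. = FALSE)
  if (cfg$domain$minLen < 2L || cfg$domain$maxLen < cfg$domain$minLen)
    stop("infeasible configuration: bad domain length bounds", call. = FALSE)
  if (cfg$nSpecies < 1L)
    stop("infeasible configuration: need at least one species", call. = FALSE)
  if (cfg$repetition$withinFrac + cfg$repetition$acrossFrac > 1)
    stop("infeasible configuration: repetition fractions exceed 1",
         call. = FALSE)
  invisible(TRUE)
}

#' Block-structured disorder calls with an exact disordered count
#'
#' Places \code{nDis} disordered residues into a track of length \code{L}
#' as blocks of at most \code{blockMax} residues separated by at least one
#' ordered residue, at randomized positions. With \code{blockMax = Inf}
#' the disordered residues form one consecutive run, which forces a CDR
#' whenever the run qualifies; small \code{blockMax} keeps DSDR
#' controllable while preventing CDRs.
#'
#' @param L track length.
#' @param nDis number of disordered residues (0..L).
#' @param blockMax maximal disordered block length.
#' @return logical vector of length L with exactly \code{nDis} TRUEs.
#' @export
makeBlockCalls <- function(L, nDis, blockMax = Inf) {
  L <- as.integer(L)
  stopifnot(L >= 1L, nDis >= 0L, nDis <= L)
  if (nDis == 0L) return(rep(FALSE, L))
  if (nDis == L) return(rep(TRUE, L))
  k <- max(1L, ceiling(nDis / blockMax))
  k <- min(k, nDis, L - nDis + 1L)  # need k-1 interior separators
  sizes <- rep(nDis %/% k, k)
  extra <- nDis %% k
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  nOrd <- L - nDis
  ## k+1 gaps (before, between, after); interior gaps >= 1
  gaps <- c(0L, rep(1L, k - 1L), 0L)
  spare <- nOrd - (k - 1L)
  if (spare > 0L) {
    add <- stats::rmultinom(1L, spare, rep(1, k + 1L))[, 1L]
    gaps <- gaps + add
  }
  v <- logical(L)
  pos <- 0L
  for (i in seq_len(k)) {
    pos <- pos + gaps[i]
    v[(pos + 1L):(pos + sizes[i])] <- TRUE
    pos <- pos + sizes[i]
  }
  v
}

.random_seq <- function(L) paste(sample(.AA20, L, replace = TRUE),
                                 collapse = "")

#' Generate a complete synthetic proteome bundle
#'
#' Builds species with ranked lineages and cell-type numbers, a family
#' universe with core (all-species), kingdom-, phylum- and
#' species-specific families, per-species disordered/structured family
#' states drawn with the planted complexity gradient (young clade-specific
#' families get a disorder boost), proteins assembled as
#' linker-domain-linker blocks with block-structured disorder calls,
#' repeat instances within and across proteins, an annotation table with
#' one planted enriched term, and PTM sites with planted excess density in
#' disordered residues. Identical configurations (including the seed)
#' yield identical bundles; the caller's RNG state is left untouched.
#'
#' @param config configuration list from \code{\link{defaultSimConfig}}.
#' @return list with species, lineages, cellTypes, proteins, profiles
#'   (named list of logical call tracks), domains, annotation, ptm,
#'   alignments, sequences (named character or NULL) and groundTruth.
#' @export
simulateProteome <- function(config = defaultSimConfig()) {
  .validateSimConfig(config)
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  n <- config$nSpecies
  species_id <- sprintf("sp%02d", seq_len(n))
  kingdom <- config$kingdoms[rep_len(seq_along(config$kingdoms), n)]
  phylum <- character(n)
  for (kg in unique(kingdom)) {
    ii <- which(kingdom == kg)
    phylum[ii] <- paste0(kg, "_phy",
                         rep_len(seq_len(config$phylaPerKingdom),
                                 length(ii)))
  }
  cell_types <- round(exp(seq(log(config$complexity$min),
                              log(config$complexity$max), length.out = n)))
  p_s <- if (config$iddFrac$gradient && n > 1L)
    config$iddFrac$base + config$iddFrac$span * (seq_len(n) - 1) / (n - 1)
  else rep(config$iddFrac$base + config$iddFrac$span / 2, n)

  species <- data.frame(species_id = species_id, superkingdom = "Eukaryota",
                        kingdom = kingdom, phylum = phylum,
                        cell_types = cell_types, planted_idd_frac = p_s,
                        stringsAsFactors = FALSE)
  lineages <- data.frame(species_id = species_id, superkingdom = "Eukaryota",
                         kingdom = kingdom, phylum = phylum,
                         species = species_id, stringsAsFactors = FALSE)
  class(lineages) <- c("lineage_table", "data.frame")

  ## family universe with age structure
  fam <- config$families
  nFam <- fam$core + fam$kingdomSpecific + fam$phylumSpecific +
    fam$speciesSpecific
  family_id <- sprintf("PF%05d", seq_len(nFam))
  age_class <- rep(c("core", "kingdom_specific", "phylum_specific",
                     "species_specific"),
                   c(fam$core, fam$kingdomSpecific, fam$phylumSpecific,
                     fam$speciesSpecific))
  homes <- character(nFam)
  kings <- unique(kingdom); phys <- unique(phylum)
  homes[age_class == "kingdom_specific"] <-
    rep_len(kings, fam$kingdomSpecific)
  homes[age_class == "phylum_specific"] <- rep_len(phys, fam$phylumSpecific)
  homes[age_class == "species_specific"] <-
    rep_len(species_id, fam$speciesSpecific)

  dis <- config$disorder; dom <- config$domain; repe <- config$repetition
  young <- age_class %in% c("phylum_specific", "species_specific")

  proteins <- list(); profiles <- list(); domains <- list()
  famState <- list()
  prot_counter <- 0L

  ## disordered archetypes: quadrant I (high DSDR, one long run), quadrant
  ## II (one CDR but DSDR <= 30, only for long domains), quadrant IV (DSDR
  ## just above 30 in scattered sub-CDR blocks); structured domains carry
  ## scattered short blocks and never qualify as IDDs
  newDomain <- function(L, disordered) {
    if (!disordered) {
      nDis <- round(stats::runif(1, 0, dis$structuredMax) * L)
      return(makeBlockCalls(L, nDis,
                            min(dis$structuredBlockMax, floor(0.4 * L))))
    }
    ty <- stats::runif(1)
    if (ty < dis$typeIIFrac && L >= 75L) {
      run <- sample(21:floor(0.3 * L), 1L)
      return(makeBlockCalls(L, run, Inf))
    }
    if (ty < dis$typeIIFrac + dis$typeIVFrac) {
      nDis <- max(round(stats::runif(1, 0.31, 0.39) * L),
                  floor(0.3 * L) + 1L)
      return(makeBlockCalls(L, nDis, min(15L, floor(0.4 * L))))
    }
    d <- stats::runif(1, dis$disorderedRange[1], dis$disorderedRange[2])
    nDis <- max(round(d * L), ceiling(0.4 * L) + 1L)
    makeBlockCalls(L, nDis, Inf)
  }
  newLinker <- function() {
    L <- sample(config$protein$linkerMin:config$protein$linkerMax, 1L)
    makeBlockCalls(L, round(dis$linkerP * L), dis$linkerBlockMax)
  }

  for (si in seq_len(n)) {
    sp <- species_id[si]
    present <- which(age_class == "core" |
                     (age_class == "kingdom_specific" & homes == kingdom[si]) |
                     (age_class == "phylum_specific" & homes == phylum[si]) |
                     (age_class == "species_specific" & homes == sp))
    p_dis <- pmin(1, p_s[si] + ifelse(young[present],
                                      fam$youngDisorderBoost, 0))
    state <- stats::runif(length(present)) < p_dis
    famState[[si]] <- data.frame(species_id = sp,
                                 family_id = family_id[present],
                                 age_class = age_class[present],
                                 p_disordered = p_dis, disordered = state,
                                 stringsAsFactors = FALSE)
    for (j in seq_along(present)) {
      f <- present[j]
      u <- stats::runif(1)
      if (u < repe$withinFrac) {
        copies <- if (repe$maxCopies <= 2L) 2L else
          sample(2:repe$maxCopies, 1L)
        nProt <- 1L
      } else if (u < repe$withinFrac + repe$acrossFrac) {
        copies <- 1L; nProt <- 2L
      } else {
        copies <- 1L; nProt <- 1L
      }
      total <- copies * nProt
      drawLen <- function() as.integer(min(dom$maxLen, max(dom$minLen,
                   round(stats::rnorm(1, dom$meanLen, dom$sdLen)))))
      ## conserved repeat groups reuse one call template, planting exact
      ## zero DSDR variation; within-protein repeats are conserved more
      ## often than across-protein repeats
      conserved <- total > 1L && stats::runif(1) <
        (if (nProt == 1L) repe$conservedWithin else repe$conservedAcross)
      doms <- if (conserved) rep(list(newDomain(drawLen(), state[j])), total)
      else lapply(seq_len(total), function(q) newDomain(drawLen(), state[j]))
      qi <- 0L
      for (pp in seq_len(nProt)) {
        prot_counter <- prot_counter + 1L
        pid <- sprintf("%s_p%05d", sp, prot_counter)
        calls <- newLinker()
        for (ci in seq_len(copies)) {
          qi <- qi + 1L
          dcalls <- doms[[qi]]
          st <- length(calls) + 1L
          calls <- c(calls, dcalls, newLinker())
          domains[[length(domains) + 1L]] <- list(
            protein_id = pid, family_id = family_id[f],
            start = st, end = st + length(dcalls) - 1L, species_id = sp)
        }
        profiles[[pid]] <- calls
        proteins[[length(proteins) + 1L]] <- list(
          protein_id = pid, gene_id = pid, species_id = sp,
          length = length(calls))
      }
    }
  }

  getf <- function(lst, field, mode) vapply(lst, `[[`, vector(mode, 1), field)
  proteins <- data.frame(
    protein_id = getf(proteins, "protein_id", "character"),
    gene_id = getf(proteins, "gene_id", "character"),
    species_id = getf(proteins, "species_id", "character"),
    length = getf(proteins, "length", "integer"),
    stringsAsFactors = FALSE)
  domTab <- data.frame(
    protein_id = getf(domains, "protein_id", "character"),
    family_id = getf(domains, "family_id", "character"),
    start = getf(domains, "start", "integer"),
    end = getf(domains, "end", "integer"),
    species_id = getf(domains, "species_id", "character"),
    stringsAsFactors = FALSE)
  domTab$family_name <- paste0("fam_", domTab$family_id)
  domTab$full_evalue <- 10^stats::runif(nrow(domTab), -30, -3)
  domTab$c_evalue <- 10^stats::runif(nrow(domTab), -30, -3)
  domTab <- domTab[, c("protein_id", "family_id", "family_name", "start",
                       "end", "full_evalue", "c_evalue", "species_id")]
  famState <- do.call(rbind, famState)

  ## annotation with one planted term, enriched in families that are
  ## disordered in the majority of their carrying species
  ann_cfg <- config$annotation
  disShare <- tapply(famState$disordered, famState$family_id, mean)
  famIDD <- names(disShare)[disShare > 0.5]
  terms <- sprintf("GO:T%03d", seq_len(ann_cfg$nTerms))
  ann <- data.frame(
    family_id = rep(family_id, each = ann_cfg$termsPerFamily),
    term = unlist(lapply(seq_len(nFam), function(i)
      sample(terms, ann_cfg$termsPerFamily))),
    stringsAsFactors = FALSE)
  p0 <- ann_cfg$plantedBaseP
  odds1 <- ann_cfg$plantedOR * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  pPlant <- ifelse(family_id %in% famIDD, p1, p0)
  planted <- family_id[stats::runif(nFam) < pPlant]
  if (length(planted))
    ann <- rbind(ann, data.frame(family_id = planted,
                                 term = ann_cfg$plantedTerm,
                                 stringsAsFactors = FALSE))
  ann <- ann[!duplicated(ann), , drop = FALSE]
  ann <- ann[order(ann$family_id, ann$term), , drop = FALSE]
  rownames(ann) <- NULL

  ## PTM sites: planted excess density in disordered residues
  ptm_cfg <- config$ptm
  allCalls <- unlist(profiles, use.names = FALSE)
  protOf <- rep(names(profiles), lengths(profiles))
  posOf <- unlist(lapply(lengths(profiles), seq_len), use.names = FALSE)
  pr <- ptm_cfg$baselineDensity *
    ifelse(allCalls, ptm_cfg$disorderedMultiplier, 1)
  hit <- which(stats::runif(length(allCalls)) < pr)
  ptm <- if (length(hit)) data.frame(
    protein_id = protOf[hit], position = posOf[hit], residue = "X",
    mod_type = sample(ptm_cfg$types, length(hit), replace = TRUE),
    stringsAsFactors = FALSE)
  else data.frame(protein_id = character(0), position = integer(0),
                  residue = character(0), mod_type = character(0))

  ## synthetic alignment summaries for within-species repeat pairs
  alignments <- .simulate_alignments(domTab)

  sequences <- NULL
  if (config$sequences) {
    sequences <- vapply(proteins$length, .random_seq, character(1))
    names(sequences) <- proteins$protein_id
    if (nrow(ptm))
      ptm$residue <- substr(sequences[ptm$protein_id], ptm$position,
                            ptm$position)
  }

  list(species = species, lineages = lineages,
       cellTypes = species[, c("species_id", "cell_types")],
       proteins = proteins, profiles = profiles, domains = domTab,
       annotation = ann, ptm = ptm, alignments = alignments,
       sequences = sequences,
       groundTruth = list(species = species, familyState = famState,
                          plantedTerm = ann_cfg$plantedTerm,
                          plantedFamilies = planted,
                          iddFamilies = famIDD,
                          config = config))
}

.simulate_alignments <- function(domTab) {
  key <- paste(domTab$species_id, domTab$family_id)
  i1 <- integer(0); i2 <- integer(0)
  for (ii in split(seq_len(nrow(domTab)), key)) {
    if (length(ii) < 2L) next
    prs <- utils::combn(ii, 2L)
    i1 <- c(i1, prs[1, ]); i2 <- c(i2, prs[2, ])
  }
  if (!length(i1))
    return(data.frame(query_id = character(0), subject_id = character(0),
                      identity_pct = numeric(0), align_len = integer(0),
                      query_len = integer(0), subject_len = integer(0),
                      q_start = integer(0), q_end = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      evalue = numeric(0)))
  m <- length(i1)
  qlen <- domTab$end[i1] - domTab$start[i1] + 1L
  slen <- domTab$end[i2] - domTab$start[i2] + 1L
  qs <- 1L + stats::rbinom(m, 3L, 0.3)
  qe <- qlen - stats::rbinom(m, 3L, 0.3)
  ss <- 1L + stats::rbinom(m, 3L, 0.3)
  se <- slen - stats::rbinom(m, 3L, 0.3)
  data.frame(
    query_id = sprintf("%s:%d-%d", domTab$protein_id[i1],
                       domTab$start[i1], domTab$end[i1]),
    subject_id = sprintf("%s:%d-%d", domTab$protein_id[i2],
                         domTab$start[i2], domTab$end[i2]),
    identity_pct = round(stats::runif(m, 30, 95), 1),
    align_len = qe - qs + 1L, query_len = qlen, subject_len = slen,
    q_start = qs, q_end = qe, s_start = ss, s_end = se,
    evalue = 10^stats::runif(m, -20, 0), stringsAsFactors = FALSE)
}

#' Simulate an annotation table with one planted enriched term
#'
#' Family-level generator for enrichment recovery experiments: a universe
#' of families, a disordered subset, background terms assigned uniformly,
#' and one planted term whose presence odds in disordered families exceed
#' those in the rest by \code{oddsRatio} (1 = null).
#'
#' @param nFamilies universe size (default 200).
#' @param iddFrac fraction of families in the disordered selection.
#' @param nTerms number of background terms.
#' @param termsPerFamily background terms drawn per family.
#' @param plantedBaseP planted-term probability outside the selection.
#' @param oddsRatio planted odds ratio (default 5).
#' @param seed integer seed.
#' @return list with annotation (data.frame family_id, term), selection,
#'   universe and plantedTerm.
#' @export
simulateAnnotation <- function(nFamilies = 200L, iddFrac = 0.5,
                               nTerms = 40L, termsPerFamily = 3L,
                               plantedBaseP = 0.2, oddsRatio = 5,
                               seed = 1L) {
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  fams <- sprintf("F%04d", seq_len(nFamilies))
  nSel <- round(iddFrac * nFamilies)
  selection <- fams[seq_len(nSel)]
  terms <- sprintf("GO:T%03d", seq_len(nTerms))
  ann <- data.frame(
    family_id = rep(fams, each = termsPerFamily),
    term = unlist(lapply(seq_len(nFamilies), function(i)
      sample(terms, termsPerFamily))),
    stringsAsFactors = FALSE)
  p0 <- plantedBaseP
  odds1 <- oddsRatio * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  pPlant <- ifelse(fams %in% selection, p1, p0)
  planted <- fams[stats::runif(nFamilies) < pPlant]
  if (length(planted))
    ann <- rbind(ann, data.frame(family_id = planted, term = "GO:PLANTED",
                                 stringsAsFactors = FALSE))
  ann <- ann[!duplicated(ann), , drop = FALSE]
  list(annotation = ann, selection = selection, universe = fams,
       plantedTerm = "GO:PLANTED")
}

#' Write a synthetic bundle to disk in the pipeline's external formats
#'
#' FASTA sequences, IUPred-style disorder scores, HMMER3 domtblout,
#' lineage / cell-type / annotation / PTM TSVs, BLAST 11-column tabular
#' alignments and a ground-truth JSON ledger.
#'
#' @param bundle output of \code{\link{simulateProteome}} (with sequences).
#' @param dir output directory (created if needed).
#' @return named vector of written paths.
#' @export
writeBundle <- function(bundle, dir) {
  if (is.null(bundle$sequences))
    stop("bundle has no sequences; rerun simulateProteome with ",
         "sequences = TRUE", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "proteome.fasta"),
    scores = file.path(dir, "disorder_scores.txt"),
    domains = file.path(dir, "domains.domtblout"),
    lineage = file.path(dir, "lineage.tsv"),
    cellTypes = file.path(dir, "cell_types.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    ptm = file.path(dir, "ptm.tsv"),
    alignments = file.path(dir, "alignments.tsv"),
    groundTruth = file.path(dir, "ground_truth.json"))
  writeFasta(bundle$sequences, paths["fasta"])
  thr <- bundle$groundTruth$config$disorder$threshold
  profs <- lapply(names(bundle$profiles), function(pid) {
    calls <- bundle$profiles[[pid]]
    scores <- ifelse(calls, thr + stats::runif(length(calls), 0.05, 0.45),
                     thr - stats::runif(length(calls), 0.05, 0.45))
    DisorderProfile(pid, scores = scores, threshold = thr)
  })
  names(profs) <- names(bundle$profiles)
  writeDisorderScores(profs, paths["scores"], bundle$sequences)
  lens <- stats::setNames(bundle$proteins$length, bundle$proteins$protein_id)
  writeDomtblout(bundle$domains, paths["domains"], lens)
  writeLineageTable(bundle$lineages, paths["lineage"])
  writeTSV(bundle$cellTypes, paths["cellTypes"])
  writeTSV(bundle$annotation, paths["annotation"])
  writeTSV(bundle$ptm, paths["ptm"])
  a <- bundle$alignments
  writeLines(sprintf("%s\t%s\t%.1f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.3g",
                     a$query_id, a$subject_id, a$identity_pct, a$align_len,
                     a$query_len, a$subject_len, a$q_start, a$q_end,
                     a$s_start, a$s_end, a$evalue),
             paths["alignments"])
  gt <- bundle$groundTruth
  jsonlite::write_json(
    list(plantedTerm = gt$plantedTerm, plantedFamilies = gt$plantedFamilies,
         iddFamilies = gt$iddFamilies, species = gt$species,
         familyState = gt$familyState, seed = gt$config$seed),
    paths["groundTruth"], auto_unbox = TRUE, digits = NA)
  paths
}
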