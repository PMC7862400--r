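## DSDR normalization, family-level dominant categories, repetition
## categories, and disorder-variation analysis of repeating domains.

#' Normalize a raw DSDR percentage onto the 0-3 grade scale
#'
#' Evaluates the fixed cubic interpolant
#' \deqn{y = x^3/78750 - 137 x^2/63000 + 253 x/2100}
#' which passes exactly through (0, 0), (10, 1), (30, 2) and (100, 3), so
#' that one unit of normalized DSDR corresponds to one disorder-grade step.
#' The cubic is increasing on \[0, 30\] but not globally monotone: it has a
#' local maximum near x = 47.3 and a local minimum near x = 66.9, an
#' inherent property of interpolating these four anchors with a cubic.
#'
#' @param x numeric DSDR percentages in \[0, 100\].
#' @return normalized values in \[0, 3\].
#' @examples
#' normalizeDSDR(c(0, 10, 30, 100))   # 0 1 2 3
#' @export
normalizeDSDR <- function(x) {
  if (any(is.na(x)) || any(x < 0 | x > 100))
    stop("DSDR must lie in [0, 100]", call. = FALSE)
  x^3 / 78750 - 137 * x^2 / 63000 + 253 * x / 2100
}

#' Re-derive the normalization cubic from its anchor points
#'
#' Solves the 4x4 Vandermonde system through the anchors
#' (0, 0), (10, 1), (30, 2), (100, 3) and returns the coefficients of
#' \eqn{y = a x^3 + b x^2 + c x + d} together with a \code{predict}
#' function. Provided so the shipped closed-form coefficients can be
#' verified independently.
#'
#' @param anchors data.frame with columns x, y (default: the four fixed
#'   anchor points).
#' @return list with a, b, c, d and \code{predict(x)}.
#' @export
fitNormalizationCubic <- function(anchors = data.frame(x = c(0, 10, 30, 100),
                                                       y = c(0, 1, 2, 3))) {
  stopifnot(nrow(anchors) == 4L)
  V <- outer(anchors$x, 3:0, `^`)
  co <- solve(V, anchors$y)
  list(a = co[1], b = co[2], c = co[3], d = co[4],
       predict = function(x) co[1] * x^3 + co[2] * x^2 + co[3] * x + co[4])
}

#' Dominant category of a label multiset
#'
#' The unique label whose proportion strictly exceeds 0.5, or
#' \code{NA_character_} ("no dominant category") when no label does.
#'
#' @param labels character vector of category labels (non-empty).
#' @return single label or \code{NA_character_}.
#' @export
dominantCategory <- function(labels) {
  if (!length(labels)) stop("empty label set", call. = FALSE)
  tab <- table(labels)
  w <- which(tab / length(labels) > 0.5)
  if (length(w) == 1L) names(tab)[w] else NA_character_
}

#' Repetition category of a family within one species
#'
#' \code{single_copy}: exactly one instance; \code{within_protein_only}:
#' several instances, all on one protein; \code{across_proteins_only}: at
#' most one instance per protein on at least two proteins; \code{both}:
#' any other multi-instance pattern.
#'
#' @param proteinIds protein identifiers of the family's instances.
#' @return single category string.
#' @export
repetitionCategory <- function(proteinIds) {
  n <- length(proteinIds)
  if (n < 1L) stop("at least one instance required", call. = FALSE)
  if (n == 1L) return("single_copy")
  perProt <- table(proteinIds)
  if (length(perProt) == 1L) return("within_protein_only")
  if (max(perProt) == 1L) return("across_proteins_only")
  "both"
}

.VARIATION_LEVELS <- c("no_variation", "low_variation", "high_variation")

#' Classify normalized-DSDR variation values
#'
#' Bins: 0 (no variation), (0, 1\] (low), (1, 3\] (high). Differences
#' below \code{eps} count as exact zero to absorb floating-point noise.
#'
#' @param values absolute differences of normalized DSDR, in \[0, 3\].
#' @param eps zero tolerance (default 1e-9).
#' @export
classifyVariation <- function(values, eps = 1e-9) {
  if (any(values < -eps | values > 3 + eps))
    stop("variation values must lie in [0, 3]", call. = FALSE)
  ifelse(values <= eps, "no_variation",
         ifelse(values <= 1, "low_variation", "high_variation"))
}

#' Pairwise disorder variation of a repeating family
#'
#' Enumerates all unordered instance pairs in scope — pairs on the same
#' protein (\code{within_protein}) or pairs on distinct proteins
#' (\code{across_proteins}) — and records the absolute difference of their
#' normalized DSDR values, its variation class, and the variation dominant
#' category of the pair classes.
#'
#' @param normDsdr numeric normalized DSDR per instance.
#' @param proteinIds protein identifier per instance.
#' @param scope \code{"within_protein"} or \code{"across_proteins"}.
#' @param instanceIds optional instance identifiers carried into the pair
#'   table (default index).
#' @return list with \code{applicable} (FALSE when fewer than two instances
#'   fall in scope), \code{pairs} (data.frame id1, id2, value, class) and
#'   \code{variation_dominant} (level or NA).
#' @export
pairwiseVariation <- function(normDsdr, proteinIds,
                              scope = c("within_protein", "across_proteins"),
                              instanceIds = seq_along(normDsdr)) {
  scope <- match.arg(scope)
  n <- length(normDsdr)
  empty <- list(applicable = FALSE,
                pairs = data.frame(id1 = character(0), id2 = character(0),
                                   value = numeric(0), class = character(0)),
                variation_dominant = NA_character_, scope = scope)
  if (n < 2L) return(empty)
  idx <- utils::combn(n, 2L)
  same <- proteinIds[idx[1, ]] == proteinIds[idx[2, ]]
  keep <- if (scope == "within_protein") same else !same
  if (!any(keep)) return(empty)
  i1 <- idx[1, keep]; i2 <- idx[2, keep]
  val <- abs(normDsdr[i1] - normDsdr[i2])
  cls <- classifyVariation(val)
  list(applicable = TRUE,
       pairs = data.frame(id1 = as.character(instanceIds[i1]),
                          id2 = as.character(instanceIds[i2]),
                          value = val, class = cls,
                          stringsAsFactors = FALSE),
       variation_dominant = dominantCategory(cls),
       scope = scope)
}

#' Family profiles for one or more species
#'
#' Aggregates per-instance metrics (\code{\link{domainMetrics}} output with
#' a species_id column) to one row per species x family: instance and
#' protein counts, median normalized DSDR (midpoint convention for even
#' counts), DSDR dominant category, repetition category, the family CDRN
#' flag (any instance with CDRN >= 1), and the family-level IDD call
#' (dominant category intrinsically disordered, or the CDRN flag).
#'
#' @param metrics per-instance metric table with species_id, family_id,
#'   protein_id, dsdr_grade, norm_dsdr, cdrn columns.
#' @return data.frame, one row per species x family.
#' @export
familyProfiles <- function(metrics) {
  key <- paste(metrics$species_id, metrics$family_id, sep = "\r")
  idx <- split(seq_len(nrow(metrics)), key)
  first <- vapply(idx, `[`, integer(1), 1L)
  dom <- vapply(idx, function(ii)
    dominantCategory(metrics$dsdr_grade[ii]), character(1))
  flag <- vapply(idx, function(ii) any(metrics$cdrn[ii] >= 1), logical(1))
  out <- data.frame(
    species_id = metrics$species_id[first],
    family_id = metrics$family_id[first],
    n_instances = lengths(idx),
    n_proteins = vapply(idx, function(ii)
      length(unique(metrics$protein_id[ii])), integer(1)),
    median_norm_dsdr = vapply(idx, function(ii)
      stats::median(metrics$norm_dsdr[ii]), numeric(1)),
    dominant_category = dom,
    repetition_category = vapply(idx, function(ii)
      repetitionCategory(metrics$protein_id[ii]), character(1)),
    family_cdrn_flag = flag,
    family_idd = (!is.na(dom) & dom == "intrinsically_disordered") | flag,
    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$species_id, out$family_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Variation records for all repeating families of a species
#'
#' @param metrics per-instance metric table for one species.
#' @return data.frame, one row per family x scope that has at least one
#'   pair, with n_pairs, counts per class and the variation dominant
#'   category; and attribute \code{"pairs"}: the concatenated pair table
#'   (family_id, scope, id1, id2, value, class).
#' @export
variationTable <- function(metrics) {
  fams <- split(seq_len(nrow(metrics)), metrics$family_id)
  recs <- list(); pairs <- list()
  for (f in names(fams)) {
    m <- metrics[fams[[f]], , drop = FALSE]
    iid <- paste0(m$protein_id, ":", m$start, "-", m$end)
    for (sc in c("within_protein", "across_proteins")) {
      v <- pairwiseVariation(m$norm_dsdr, m$protein_id, sc, iid)
      if (!v$applicable) next
      cls <- factor(v$pairs$class, levels = .VARIATION_LEVELS)
      tab <- table(cls)
      recs[[length(recs) + 1L]] <- data.frame(
        family_id = f, scope = sc, n_pairs = nrow(v$pairs),
        n_no_variation = as.integer(tab["no_variation"]),
        n_low_variation = as.integer(tab["low_variation"]),
        n_high_variation = as.integer(tab["high_variation"]),
        variation_dominant = v$variation_dominant,
        stringsAsFactors = FALSE)
      pairs[[length(pairs) + 1L]] <-
        cbind(data.frame(family_id = f, scope = sc), v$pairs)
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(family_id = character(0), scope = character(0),
               n_pairs = integer(0), n_no_variation = integer(0),
               n_low_variation = integer(0), n_high_variation = integer(0),
               variation_dominant = character(0))
  rownames(out) <- NULL
  attr(out, "pairs") <- if (length(pairs)) do.call(rbind, pairs) else NULL
  out
}

#' Fisher test: no-variation proportion, within- vs across-protein repeats
#'
#' Two-sided Fisher exact test on the 2x2 table of family counts
#' (no-variation dominant vs other) x (repeating within one protein vs
#' across proteins). A zero margin makes the comparison undefined.
#'
#' @param variation output of \code{\link{variationTable}}, or a 2x2 matrix
#'   with rows (no_variation, other) and columns (within, across).
#' @return list with the 2x2 \code{table}, \code{p} (NA when undefined),
#'   \code{odds_ratio}, \code{direction} ("within_higher",
#'   "across_higher" or "equal") and \code{defined}.
#' @export
noVariationProportionTest <- function(variation) {
  if (is.matrix(variation)) {
    tab <- variation
  } else {
    v <- variation
    mk <- function(sc) {
      d <- v$variation_dominant[v$scope == sc]
      c(no = sum(d == "no_variation", na.rm = TRUE),
        other = sum(is.na(d) | d != "no_variation"))
    }
    tab <- matrix(c(mk("within_protein"), mk("across_proteins")), nrow = 2,
                  dimnames = list(c("no_variation", "other"),
                                  c("within", "across")))
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(table = tab, p = NA_real_, odds_ratio = NA_real_,
                direction = NA_character_, defined = FALSE))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  p_within <- tab[1, 1] / sum(tab[, 1])
  p_across <- tab[1, 2] / sum(tab[, 2])
  dir <- if (p_within > p_across) "within_higher" else
    if (p_within < p_across) "across_higher" else "equal"
  list(table = tab, p = unname(ft$p.value),
       odds_ratio = unname(ft$estimate), direction = dir, defined = TRUE)
}

#' Compare family disorder between two clades
#'
#' Classifies each family shared by two clades by the difference of its
#' per-clade median normalized DSDR: \code{higher_in_A} when
#' median_A - median_B exceeds \code{deltaThreshold}, \code{higher_in_B}
#' when it is below -\code{deltaThreshold}, \code{similar} otherwise. The
#' default threshold of 1 normalized unit equals one disorder-grade step.
#'
#' @param medianA,medianB numeric vectors of per-family median normalized
#'   DSDR in clade A and B (same family order).
#' @param deltaThreshold strict cutoff on |difference| (default 1).
#' @return data.frame with delta and call columns.
#' @export
compareFamilyDisorderBetweenClades <- function(medianA, medianB,
                                               deltaThreshold = 1) {
  stopifnot(length(medianA) == length(medianB))
  delta <- medianA - medianB
  call <- ifelse(delta > deltaThreshold, "higher_in_A",
                 ifelse(delta < -deltaThreshold, "higher_in_B", "similar"))
  data.frame(delta = delta, call = call, stringsAsFactors = FALSE)
}
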