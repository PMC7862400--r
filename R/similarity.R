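## Repeat-domain sequence-similarity score computed from BLAST tabular
## alignment summaries.

#' Alignment coverage components of a BLAST HSP
#'
#' From a parsed BLAST tabular row: the matched fraction of the query
#' (\code{match_query_pct} = 100 (q_end - q_start + 1)/query_len), of the
#' subject (likewise on subject coordinates), and the offset of the first
#' matched query residue (\code{query_first_pct} = 100 (q_start - 1)/
#' query_len).
#'
#' @param alignments data.frame from \code{\link{readBlastTabular}} (or with
#'   the same column names).
#' @return the input with match_query_pct, match_subject_pct and
#'   query_first_pct columns appended.
#' @export
deriveComponents <- function(alignments) {
  a <- alignments
  if (any(a$query_len <= 0 | a$subject_len <= 0))
    stop("zero-length query or subject", call. = FALSE)
  a$match_query_pct <- 100 * (a$q_end - a$q_start + 1) / a$query_len
  a$match_subject_pct <- 100 * (abs(a$s_end - a$s_start) + 1) / a$subject_len
  a$query_first_pct <- 100 * (a$q_start - 1) / a$query_len
  a
}

#' Repeat-domain sequence similarity
#'
#' \deqn{Similarity = Identity\% \times
#'   \frac{[100 - |100 - MatchQuery\%|] + [100 - |100 - MatchSubject\%|]}
#'        {2 (100 - QueryFirst\%)}}
#' The absolute-value terms cap each coverage contribution at 100, so a
#' nominal coverage above 100\% (possible with gapped spans) is folded
#' back symmetrically. A query_first_pct of 100 makes the score undefined
#' (returned as NA).
#'
#' @param identityPct percent identity in \[0, 100\].
#' @param matchQueryPct,matchSubjectPct,queryFirstPct coverage components
#'   (see \code{\link{deriveComponents}}).
#' @return numeric similarity (NA where queryFirstPct = 100).
#' @examples
#' sequenceSimilarity(100, 100, 100, 0)   # 100, perfect self-hit
#' sequenceSimilarity(50, 80, 120, 10)    # 44.44...
#' @export
sequenceSimilarity <- function(identityPct, matchQueryPct, matchSubjectPct,
                               queryFirstPct) {
  undef <- queryFirstPct >= 100
  num <- (100 - abs(100 - matchQueryPct)) + (100 - abs(100 - matchSubjectPct))
  out <- identityPct * num / (2 * (100 - queryFirstPct))
  out[undef] <- NA_real_
  if (any(undef))
    warning(sum(undef), " pair(s) with query_first_pct >= 100: ",
            "similarity undefined")
  out
}

#' Keep the best HSP per query/subject pair
#'
#' Lowest E-value wins; ties keep the first row in file order (the
#' 11-column tabular format prescribed for \code{\link{readBlastTabular}}
#' carries no bit score).
#'
#' @param alignments parsed BLAST tabular data.frame.
#' @export
bestHspPerPair <- function(alignments) {
  key <- paste(alignments$query_id, alignments$subject_id, sep = "\r")
  o <- order(key, alignments$evalue)
  a <- alignments[o, , drop = FALSE]
  out <- a[!duplicated(key[o]), , drop = FALSE]
  out <- out[order(match(rownames(out), rownames(alignments))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Similarity table for repeat-domain alignments
#'
#' Best HSP per pair, coverage components and the similarity score.
#'
#' @param alignments parsed BLAST tabular data.frame.
#' @return data.frame with one row per query/subject pair.
#' @export
similarityTable <- function(alignments) {
  a <- deriveComponents(bestHspPerPair(alignments))
  a$similarity <- sequenceSimilarity(a$identity_pct, a$match_query_pct,
                                     a$match_subject_pct, a$query_first_pct)
  a
}

#' Join repeat-pair similarity with DSDR variation
#'
#' Matches similarity rows to variation pairs on the unordered instance-id
#' pair, for downstream plotting or association statistics (e.g. do
#' low-similarity repeats keep low DSDR variation).
#'
#' @param simTable output of \code{\link{similarityTable}} whose
#'   query_id/subject_id are instance identifiers.
#' @param variationPairs pair table (attribute \code{"pairs"} of
#'   \code{\link{variationTable}}): columns id1, id2, value, class.
#' @return data.frame with similarity and variation value per matched pair.
#' @export
similarityVsVariation <- function(simTable, variationPairs) {
  if (is.null(variationPairs) || !nrow(variationPairs) || !nrow(simTable))
    return(data.frame(id1 = character(0), id2 = character(0),
                      similarity = numeric(0), variation = numeric(0),
                      variation_class = character(0)))
  ukey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  sk <- ukey(simTable$query_id, simTable$subject_id)
  vk <- ukey(variationPairs$id1, variationPairs$id2)
  m <- match(vk, sk)
  keep <- !is.na(m)
  data.frame(id1 = variationPairs$id1[keep],
             id2 = variationPairs$id2[keep],
             similarity = simTable$similarity[m[keep]],
             variation = variationPairs$value[keep],
             variation_class = variationPairs$class[keep],
             stringsAsFactors = FALSE)
}
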