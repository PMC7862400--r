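#' DisorderProfile: per-residue disorder state of one protein
#'
#' Container for the per-residue intrinsic-disorder prediction of a single
#' protein: an optional numeric score track in \[0, 1\] and the binary
#' disordered/ordered call track derived from it by strict thresholding
#' (a residue is disordered iff its score exceeds the threshold).
#'
#' @slot proteinId single character, the protein identifier.
#' @slot scores numeric vector of per-residue disorder scores in \[0, 1\],
#'   or a zero-length numeric when only binary calls are available.
#' @slot calls logical vector, one element per residue; \code{TRUE} means
#'   the residue is called disordered.
#' @slot threshold single numeric in (0, 1); the call threshold that was
#'   applied to \code{scores} (kept for provenance).
#'
#' @name DisorderProfile-class
#' @aliases DisorderProfile-class
#' @exportClass DisorderProfile
setClass("DisorderProfile",
  representation(
    proteinId = "character",
    scores    = "numeric",
    calls     = "logical",
    threshold = "numeric"
  ),
  prototype(scores = numeric(0), threshold = 0.5)
)

setValidity("DisorderProfile", function(object) {
  msg <- character(0)
  if (length(object@proteinId) != 1L || is.na(object@proteinId) ||
      !nzchar(object@proteinId))
    msg <- c(msg, "'proteinId' must be a single non-empty string")
  if (length(object@calls) < 1L || anyNA(object@calls))
    msg <- c(msg, "'calls' must be a non-empty logical vector without NA")
  if (length(object@threshold) != 1L || is.na(object@threshold) ||
      object@threshold <= 0 || object@threshold >= 1)
    msg <- c(msg, "'threshold' must be a single number in (0, 1)")
  if (length(object@scores)) {
    if (length(object@scores) != length(object@calls))
      msg <- c(msg, "'scores' and 'calls' must have equal length")
    else {
      if (anyNA(object@scores) || any(object@scores < 0 | object@scores > 1))
        msg <- c(msg, "'scores' must lie in [0, 1]")
      else if (!identical(unname(object@scores > object@threshold),
                          unname(object@calls)))
        msg <- c(msg, "'calls' must equal 'scores > threshold' (strict)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DisorderProfile
#'
#' @param proteinId protein identifier.
#' @param scores optional numeric per-residue disorder scores in \[0, 1\].
#' @param calls optional logical call track; when omitted it is derived as
#'   \code{scores > threshold} (strict inequality, so a score exactly at the
#'   threshold is ordered).
#' @param threshold call threshold in (0, 1); default 0.5, the usual default
#'   for IUPred/SPOT-Disorder-style score tracks.
#' @return A \linkS4class{DisorderProfile}.
#' @examples
#' dp <- DisorderProfile("p1", scores = c(0.6, 0.4, 0.5))
#' disorderCalls(dp)   # TRUE FALSE FALSE
#' @export
DisorderProfile <- function(proteinId, scores = numeric(0), calls = NULL,
                            threshold = 0.5) {
  if (is.null(calls)) {
    if (!length(scores))
      stop("supply 'scores' or 'calls'")
    calls <- scores > threshold
  }
  new("DisorderProfile", proteinId = as.character(proteinId),
      scores = as.numeric(scores), calls = as.logical(calls),
      threshold = as.numeric(threshold))
}

#' @describeIn DisorderProfile-class protein identifier accessor
#' @param object,x a \code{DisorderProfile}
#' @export
setGeneric("proteinId", function(x) standardGeneric("proteinId"))

#' @rdname DisorderProfile-class
#' @export
setMethod("proteinId", "DisorderProfile", function(x) x@proteinId)

#' @rdname DisorderProfile-class
#' @export
setGeneric("disorderCalls", function(x) standardGeneric("disorderCalls"))

#' @rdname DisorderProfile-class
#' @export
setMethod("disorderCalls", "DisorderProfile", function(x) x@calls)

#' @rdname DisorderProfile-class
#' @export
setGeneric("disorderScores", function(x) standardGeneric("disorderScores"))

#' @rdname DisorderProfile-class
#' @export
setMethod("disorderScores", "DisorderProfile", function(x)
  if (length(x@scores)) x@scores else NULL)

#' @rdname DisorderProfile-class
#' @export
setMethod("length", "DisorderProfile", function(x) length(x@calls))

setMethod("show", "DisorderProfile", function(object) {
  n <- length(object@calls)
  cat("DisorderProfile for", object@proteinId, "\n",
      " ", n, "residues;", sum(object@calls), "disordered (",
      sprintf("%.1f%%", 100 * mean(object@calls)), ")\n",
      if (length(object@scores)) "  score track present" else
        "  binary calls only", "\n")
})
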