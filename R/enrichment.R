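## Hypergeometric over/under-representation with BH correction and the
## signed 14-grade log10(P) scale; plus the Fisher / Mann-Whitney /
## Spearman / least-squares helpers used across the analyses.

#' Hypergeometric tail probabilities
#'
#' For \code{k} hits in a selection of size \code{n} drawn from a universe
#' of size \code{N} containing \code{K} hits:
#' over-representation tail \eqn{P(X \ge k)} and under-representation tail
#' \eqn{P(X \le k)}. The two tails share the point mass at \code{k}, so
#' they always sum to at least 1.
#'
#' @param k,K,n,N integers with \code{0 <= k <= min(n, K)}, \code{n <= N},
#'   \code{K <= N}.
#' @return list with p_over and p_under.
#' @export
hypergeomTails <- function(k, K, n, N) {
  if (any(k < 0 | n < 0 | K < 0 | N < 0) || any(k > pmin(n, K)) ||
      any(n > N) || any(K > N) || any(k < n - (N - K)))
    stop("invalid hypergeometric bounds", call. = FALSE)
  list(p_over = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
       p_under = stats::phyper(k, K, N - K, n))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted P values, capped at 1, monotone non-decreasing in rank
#' order (\code{\link[stats]{p.adjust}} with method "BH").
#'
#' @param p numeric vector of P values in (0, 1\].
#' @export
bhAdjust <- function(p) stats::p.adjust(p, method = "BH")

#' Signed 14-grade log10(P) scale
#'
#' Maps an over-/under-representation tail pair to one of the 14 grades
#' \{-7..-2, -0.25, 0.25, 2..7\}. The direction is over-representation
#' (positive) when \code{pOver <= pUnder}, under-representation otherwise.
#' The magnitude bins on \code{-log10(P)} of the directional tail are:
#' grade 2 for \[1.301, 2), 3 for \[2, 3), 4 for \[3, 6), 5 for \[6, 9),
#' 6 for \[9, 12), 7 for >= 12, and 0.25 below 1.301 (mirrored with
#' negative signs for under-representation; 1.301 = -log10(0.05)).
#'
#' @param pOver,pUnder tail probabilities (vectors recycle).
#' @return numeric vector of grades.
#' @export
signedGrade <- function(pOver, pUnder) {
  mag <- function(l)
    ifelse(l >= 12, 7, ifelse(l >= 9, 6, ifelse(l >= 6, 5,
      ifelse(l >= 3, 4, ifelse(l >= 2, 3, ifelse(l >= 1.301, 2, 0.25))))))
  over <- pOver <= pUnder
  ifelse(over, mag(-log10(pOver)), -mag(-log10(pUnder)))
}

#' Spearman rank correlation
#'
#' Average ranks for ties; large-sample t approximation for the P value.
#' A constant vector leaves the coefficient undefined.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with rho, p, n and defined.
#' @export
spearmanCorrelation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, defined = FALSE))
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n, defined = TRUE)
}

#' Mann-Whitney U test
#'
#' Two-sided. Exact distribution when both samples have at most 8
#' observations and no ties (matching where exhaustive enumeration is
#' cheap); otherwise the normal approximation with tie correction.
#'
#' @param x,y numeric samples.
#' @param exact force exact (TRUE) or approximate (FALSE); default NULL
#'   auto-selects as above.
#' @return list with U (number of (x, y) pairs with x > y, ties counted
#'   half) and p.
#' @export
mannWhitney <- function(x, y, exact = NULL) {
  ties <- any(duplicated(c(x, y)))
  if (is.null(exact)) exact <- length(x) <= 8L && length(y) <= 8L && !ties
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = "two.sided", exact = exact, correct = FALSE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Ordinary least-squares line fit
#'
#' @param x,y numeric vectors (length >= 2, x not constant).
#' @return list with slope, intercept and r_squared.
#' @export
fitLine <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2L || stats::sd(x) == 0)
    stop("need >= 2 points with varying x", call. = FALSE)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  list(slope = unname(co[2]), intercept = unname(co[1]),
       r_squared = suppressWarnings(summary(fit)$r.squared))
}

#' Over/under-representation analysis of an annotated selection
#'
#' One hypergeometric test per annotated term: \code{k} = selection
#' members carrying the term, \code{K} = universe members carrying it,
#' against selection size \code{n} and universe size \code{N}. Over- and
#' under-representation P values are BH-corrected as two separate
#' one-sided families across terms, and the signed 14-grade score is
#' computed from the corrected tails. Results are ordered by term id.
#'
#' @param selection character vector of selected ids (subset of universe).
#' @param universe character vector of all ids.
#' @param annotation data.frame with columns \code{family_id} (or first
#'   column = id) and \code{term}.
#' @return data.frame with term, k, n, K, N, p_over, p_under, q_over,
#'   q_under, grade.
#' @export
enrich <- function(selection, universe, annotation) {
  universe <- unique(universe)
  selection <- unique(selection)
  if (!all(selection %in% universe))
    stop("selection must be a subset of the universe", call. = FALSE)
  idcol <- if ("family_id" %in% names(annotation)) "family_id" else
    names(annotation)[1]
  ann <- annotation[annotation[[idcol]] %in% universe, , drop = FALSE]
  terms <- sort(unique(ann$term))
  if (!length(terms))
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p_over = numeric(0),
                      p_under = numeric(0), q_over = numeric(0),
                      q_under = numeric(0), grade = numeric(0)))
  N <- length(universe); n <- length(selection)
  K <- vapply(terms, function(t)
    length(unique(ann[[idcol]][ann$term == t])), integer(1))
  k <- vapply(terms, function(t)
    length(intersect(selection, ann[[idcol]][ann$term == t])), integer(1))
  tails <- hypergeomTails(k, K, n, N)
  q_over <- bhAdjust(tails$p_over)
  q_under <- bhAdjust(tails$p_under)
  data.frame(term = terms, k = k, n = n, K = K, N = N,
             p_over = tails$p_over, p_under = tails$p_under,
             q_over = q_over, q_under = q_under,
             grade = signedGrade(q_over, q_under),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Terms-by-groups grade matrix
#'
#' Binds several \code{\link{enrich}} results into a heat-map-ready matrix
#' of signed grades (rows: terms, columns: groups; missing terms get NA).
#'
#' @param results named list of \code{\link{enrich}} outputs.
#' @export
gradeMatrix <- function(results) {
  terms <- sort(unique(unlist(lapply(results, `[[`, "term"))))
  out <- matrix(NA_real_, length(terms), length(results),
                dimnames = list(terms, names(results)))
  for (g in names(results)) {
    r <- results[[g]]
    out[r$term, g] <- r$grade
  }
  out
}
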