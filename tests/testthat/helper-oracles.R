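# Independent oracles used across the suite; deliberately naive
# implementations that share no code with the package internals.

# maximal runs of TRUE by position scanning, filtered by the CDR rule
bruteForceCDRs <- function(calls) {
  pos <- which(calls)
  L <- length(calls)
  if (!length(pos))
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0)))
  brk <- which(diff(pos) > 1L)
  starts <- pos[c(1L, brk + 1L)]
  ends <- pos[c(brk, length(pos))]
  len <- ends - starts + 1L
  keep <- if (L > 50L) len > 20L else len > 0.4 * L
  data.frame(start = starts[keep], end = ends[keep], length = len[keep])
}

# exact hypergeometric tails by direct combinatorial summation
enumHyperTails <- function(k, K, n, N) {
  lo <- max(0L, n - (N - K)); hi <- min(n, K)
  xs <- lo:hi
  pmf <- choose(K, xs) * choose(N - K, n - xs) / choose(N, n)
  list(p_over = sum(pmf[xs >= k]), p_under = sum(pmf[xs <= k]))
}

# exact two-sided Mann-Whitney p by exhaustive enumeration of all
# group-label assignments (ties allowed; R's doubling convention)
enumMannWhitneyP <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  uStat <- function(xi) {
    xv <- pooled[xi]; yv <- pooled[-xi]
    sum(outer(xv, yv, ">")) + 0.5 * sum(outer(xv, yv, "=="))
  }
  combs <- utils::combn(nx + ny, nx)
  us <- apply(combs, 2, uStat)
  u0 <- uStat(seq_len(nx))
  mid <- nx * ny / 2
  p <- if (u0 > mid) 2 * mean(us >= u0) else 2 * mean(us <= u0)
  min(1, p)
}

# tiny deterministic metrics table builder for family/variation tests
makeMetricsRow <- function(species, family, protein, dsdr, cdrn,
                           start = 1L, end = 100L) {
  data.frame(species_id = species, family_id = family, protein_id = protein,
             start = start, end = end, length = end - start + 1L,
             dsdr = dsdr, cdrn = cdrn,
             dsdr_grade = classifyDSDRGrade(dsdr),
             quadrant = classifyQuadrant(dsdr, cdrn),
             is_idd = isIDD(dsdr, cdrn),
             norm_dsdr = normalizeDSDR(dsdr),
             stringsAsFactors = FALSE)
}

makeLineages <- function() {
  structure(data.frame(
    species_id = c("human", "mouse", "yeast", "ecoli"),
    superkingdom = c("Eukaryota", "Eukaryota", "Eukaryota", "Bacteria"),
    kingdom = c("Metazoa", "Metazoa", "Fungi", "Proteobacteria_k"),
    phylum = c("Chordata", "Chordata", "Ascomycota", "Proteobacteria"),
    species = c("human", "mouse", "yeast", "ecoli"),
    stringsAsFactors = FALSE),
    class = c("lineage_table", "data.frame"))
}
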