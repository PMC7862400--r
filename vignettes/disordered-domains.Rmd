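---
title: "Quantifying intrinsic disorder at the protein-domain level"
author: "IDDomains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intrinsic disorder at the protein-domain level}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(IDDomains)
```

## The problem

Intrinsically disordered regions (IDRs) are protein segments without a
stable tertiary structure that nevertheless carry function — often in
signalling, regulation and molecular recognition. Most comparative
surveys of disorder operate at the whole-protein level (the fraction of
disordered residues per protein, PSDR). `IDDomains` instead works at the
level of Pfam domain instances: the same domain family can be structured
in one protein or species and disordered in another, and that variation
is invisible to protein-level statistics.

The package consumes the *outputs* of upstream tools — per-residue
disorder scores (IUPred/SPOT-Disorder-style tables), HMMER3 `domtblout`
domain coordinates, BLASTp tabular alignments, Swiss-Prot MOD_RES
features — and implements the domain-level statistics on top of them.
Running the predictors, HMMER or BLAST is out of scope.

## Metrics and classification rules

For a domain instance spanning residues $[s, e]$ of a protein with
binary per-residue disorder calls $c_i$:

* **DSDR** (domain structural disorder ratio)
  $= 100 \cdot \sum_{i=s}^{e} c_i / (e - s + 1)$, in percent.
* **CDR** (consecutive disordered region): a maximal run of disordered
  residues that is *longer than 20 residues* when the domain has more
  than 50 residues, or *longer than 40% of the domain length* otherwise.
  Both inequalities are strict; a run of exactly 20 residues (or exactly
  40%) does not qualify. At exactly 50 residues the short-domain rule
  applies, reading "more than 50" literally.
* **CDRN**: the number of CDRs in the instance.
* **IDD** (intrinsically disordered domain): DSDR $> 30$% *or*
  CDRN $\ge 1$. All classification thresholds are strict on the
  disordered side, so boundary values fall to the structured side.

DSDR grades partition $[0, 100]$ as: exactly $0$ (completely
structured), $(0, 10]$ (highly structured), $(10, 30]$ (moderately
unstructured), $(30, 100]$ (intrinsically disordered). The half-open
bins guarantee each value has exactly one grade.

The DSDR/CDRN quadrants cross the two rules: I (DSDR $> 30$, CDRN
$\ge 1$), II (DSDR $\le 30$, CDRN $\ge 1$), III (neither), IV (DSDR
$> 30$, CDRN $= 0$). Per species, the share of instances in I $\cup$ IV
is the DSDR-rule IDD percentage and I $\cup$ II the CDRN-rule
percentage; `speciesSummary()` reports both, which is what the
per-species scatter of one rule against the other uses.

Protein-level metrics mirror these definitions: PSDR over the whole
protein and the IDP call at PSDR $> 30$%, computed on representative
proteins (the longest isoform per gene; ties broken by the
lexicographically smallest protein identifier, purely for determinism).

## DSDR normalization

Family-level comparisons use a normalized DSDR: the unique cubic
$y = x^3/78750 - 137x^2/63000 + 253x/2100$ through the anchor points
$(0,0)$, $(10,1)$, $(30,2)$, $(100,3)$, so one normalized unit equals
one grade step. `fitNormalizationCubic()` re-derives the coefficients
from the anchors by solving the Vandermonde system, which the test suite
compares against the closed forms to $10^{-9}$.

A property worth knowing: the interpolant is increasing on $[0, 30]$ but
*not* globally monotone — it has a local maximum near $x = 47.3$ and a
local minimum near $x = 66.9$. This is inherent to forcing a cubic
through these four anchors. The tests assert the dip exists rather than
pretending monotonicity; consumers should treat normalized values
between 2 and 3 as grade-scale positions, not as a strictly order-
preserving transform of DSDR.

## Families, dominant categories, and repeat variation

A domain family is a Pfam accession; its instances in one species form a
`familyProfiles()` row carrying the median normalized DSDR (midpoint
convention for even counts), the **dominant category** (the DSDR grade
covering strictly more than half the instances, otherwise "none"), the
repetition category (single-copy / within-protein-only /
across-proteins-only / both), and the family CDRN flag (any instance
with a CDR). The family-level IDD call used for disordered width and for
family-level correlations is *dominant category = intrinsically
disordered OR the CDRN flag*; an instance-level alternative can be built
from the metrics table directly.

Repeat variation takes all unordered instance pairs of a family within a
scope — pairs on one protein, or pairs on distinct proteins — and
records $|\Delta|$ of normalized DSDR, binned as $0$ (no variation),
$(0, 1]$ (low), $(1, 3]$ (high); since the normalized scale is $[0, 3]$,
the bins are exhaustive. Differences below $10^{-9}$ count as zero to
absorb floating-point noise. The per-species contrast of the
no-variation dominant category between within-protein and
across-protein repeats uses a two-sided Fisher exact test
(sidedness is not dictated by the analysis itself; two-sided is the
standard choice and is recorded in the output). Enumerating *all* pairs
rather than consecutive repeats only is the simplest faithful reading of
"domain pairs".

Between-clade comparisons of shared families
(`compareFamilyDisorderBetweenClades`) call a family "higher in A" only
when the difference of per-clade medians exceeds a threshold, default
1.0 normalized unit = one grade step. The cutoff behind published
percentages of this kind is generally unstated, so the default is
explicit, configurable and echoed in output; we do not attempt to
reproduce any specific printed split.

## Distribution width, domain age, disordered width

These analyses are driven by a *ranked lineage table*: `species_id`
followed by rank columns from root-most to leaf-most (default
superkingdom, kingdom, phylum, species). The distribution-width scheme
is an ordered first-match-wins category list; the shipped default
classifies families as species-, phylum-, kingdom- or
superkingdom-specific, with a cross-superkingdom fallback. Published
width analyses of this kind use richer, hand-drawn category sets; those
are only defined graphically, so the scheme here is configuration, not
constant, and outputs record which scheme was used.

Domain age is the lowest common ancestor of the carrying species'
lineages, read off the representative species' lineage; depth 0 is the
root, so adding a carrying species can only keep or decrease the depth
(tested as a monotonicity property). Disordered width is the percentage
of carrying species in which the family is an IDD, with "widely
disordered" meaning strictly more than 50%.

## Repeat-pair sequence similarity

For a BLAST HSP between two repeat instances the score is

$$\mathrm{Similarity} = \mathrm{Identity\%} \times
\frac{[100 - |100 - M_q|] + [100 - |100 - M_s|]}{2\,(100 - Q_f)}$$

with $M_q, M_s$ the matched percentage of query and subject
($100\,(q_{end}-q_{start}+1)/q_{len}$ and the subject analogue) and
$Q_f = 100\,(q_{start}-1)/q_{len}$ the offset of the first matched query
residue. The absolute-value terms fold coverage above 100% back
symmetrically; $Q_f = 100$ makes the score undefined (returned as NA
with a warning). A perfect self-hit scores exactly 100. The score is
not symmetric under query/subject swap unless the offsets agree — a
documented, tested property. When several HSPs link the same pair, the
lowest E-value wins; the 11-column tabular layout the reader requires
carries no bit score, so ties fall back to file order.

## Enrichment statistics and the signed 14-grade scale

Over/under-representation uses exact hypergeometric tails
($P(X \ge k)$ and $P(X \le k)$; the two tails share the point mass at
$k$ and therefore always sum to at least 1), Benjamini–Hochberg
correction applied to the over- and under-direction as two separate
one-sided families across terms, and a signed 14-grade score on
$\log_{10} P$: grade $\pm 2$ for $1.301 \le -\log_{10} P < 2$ (1.301
$= -\log_{10} 0.05$), $\pm 3$ for $[2, 3)$, $\pm 4$ for $[3, 6)$,
$\pm 5$ for $[6, 9)$, $\pm 6$ for $[9, 12)$, $\pm 7$ at $\ge 12$, and
$\pm 0.25$ below 1.301. The direction is over-representation when the
over tail is the smaller one. Inside the `enrich()` driver the graded
quantity is the *corrected* tail, matching the procedure of correcting
P first and grading its logarithm; `signedGrade()` itself is a pure
function of two tail values, so grading raw tails is equally available.

Supporting statistics are deliberately delegated to base R —
`phyper`, `p.adjust(method = "BH")`, `fisher.test`, `wilcox.test`,
`cor.test(method = "spearman")`, `lm` — while the test suite checks the
hypergeometric tails against full combinatorial enumeration for every
universe size up to 60 and the Mann–Whitney p against exhaustive
permutation for both samples up to size 8 (tie-free cases; with ties or
larger samples the normal approximation with tie correction is used,
appropriate for the species-level sample sizes these comparisons see).

## PTM density

PTM sites are assigned to domain instances by position containment;
density is sites per residue within a category (the only unit comparable
across categories of different total size), with per-domain densities
retained for rank-based comparisons. For IDDs with CDRs, the residues
are partitioned into CDR and non-CDR parts; the two parts' site counts
always sum to the parent domain's count (a conservation property under
test). Modification types are compared at the description-string level
("Phosphoserine"), not collapsed into chemistry classes, because the
description is the unit the source feature table provides.

## The synthetic-proteome generator

`simulateProteome()` exists so every downstream stage can be exercised
and calibrated without any download. Its defaults define the simulated
study conditions:

* 51 eukaryotic species over four kingdoms (two phyla each), cell-type
  numbers log-spaced from 2 to 220 as the complexity measure;
* a planted linear gradient of the per-species disordered-family
  probability from 0.08 to 0.45 along the complexity rank (flat at the
  midpoint under `gradient = FALSE`), emulating the positive
  disorder–complexity association at the family level;
* a family universe with core (all-species), kingdom-, phylum- and
  species-specific families; young (phylum-/species-specific) families
  get a +0.15 disorder boost, planting the young-domains-are-more-
  disordered signal;
* disorder calls built as blocks, not i.i.d. residues, so DSDR and CDR
  content are controllable independently: disordered domains carry one
  long block covering 40–90% of residues (quadrant I), with 10%
  sub-populations of CDR-only (quadrant II) and high-DSDR-no-CDR
  (quadrant IV) archetypes; structured domains carry scattered blocks of
  at most 10 residues totalling at most 15%, which can never qualify as
  CDRs; linkers are 35% disordered in short blocks;
* 15% of families repeat within a protein and 25% across proteins;
  repeat groups are "conserved" (identical call templates, hence exactly
  zero DSDR variation) with probability 0.7 within proteins and 0.45
  across, reproducing the observed dominance of the no-variation class
  and its within-protein excess;
* an annotation table with one planted term at odds ratio 5 between
  majority-disordered families and the rest, and PTM sites at baseline
  density 0.004 per residue with a 3× multiplier on disordered residues.

Sequences are uniform random amino acids and exist only so the FASTA
path can be exercised; alignment summaries for repeat pairs are
constructed directly (running BLAST on random sequences would add cost
without adding signal). The generator is seeded, byte-stable for a fixed
configuration, and restores the caller's RNG state.

What passing recovery tests on these bundles shows — and does not show:
they demonstrate that the pipeline's estimators recover planted effects
of realistic magnitude at realistic sample sizes, and that null
configurations do not produce spurious calls. They do not certify
behaviour on real proteomes, where disorder-call autocorrelation,
domain-boundary error, annotation bias and non-uniform family sizes are
all richer than the generator's block model.

## Problem sizes and runtime choices

The default bundle (51 species, 150-family universe) profiles in a few
seconds. The repeated-recovery checks in the test suite use a slimmed
per-species size — a 66-family universe, sequences disabled — so that
200 gradient seeds plus 200 null seeds complete in minutes; the planted
gradient itself stays at its default. The PTM-recovery experiment uses
two clean archetypes (fully disordered vs fully structured domains) so
the per-category density ratio isolates the planted multiplier; with
mixed-DSDR archetypes the pooled ratio would dilute toward
$(0.65 \cdot 3 + 0.35)/(0.075 \cdot 3 + 0.925) \approx 2$ by
construction — a property of the measurement, not of the plant.

## Degenerate inputs and tie-breaks

Empty intervals, out-of-range DSDR, constant vectors in correlations,
zero Fisher margins, a query-first offset of 100%, empty annotation
tables and empty species all produce either explicit errors or
NA-flagged results, never silent numbers. Dominant categories need a
strict majority; at exactly one half the answer is "none". Ties in
representative-protein selection, best-HSP choice, and median
computation are resolved by lexicographic order, file order, and the
midpoint convention respectively — each chosen for determinism and
recorded here rather than left to implementation accident.

## Known limitations

* The disorder-call threshold default (0.5) matches IUPred/SPOT-style
  score conventions; other predictors need the threshold set per run.
* Overlapping Pfam hits are kept as independent instances; no overlap
  resolution is attempted.
* GO term ancestry is not propagated; annotation enrichment treats terms
  as flat labels.
* The distribution-width scheme is an approximation configured by rank
  names, not a reproduction of any particular published category set.
* The Swiss-Prot parser reads only ID/AC/SQ/FT MOD_RES lines.
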