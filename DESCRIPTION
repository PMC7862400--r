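Package: IDDomains
Title: Proteome-Wide Analysis of Intrinsically Disordered Protein Domains
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of per-residue intrinsic-disorder predictions at the
    protein-domain level. Computes the domain structural disorder ratio (DSDR) and
    consecutive disordered region count (CDRN) for Pfam domain instances, classifies
    domains into disorder grades and DSDR/CDRN quadrants, normalizes DSDR with a
    fixed cubic interpolant, derives family-level dominant categories, repetition
    categories and disorder-variation records for repeating domains, assigns
    taxonomic distribution width, domain age and disordered width from ranked
    lineages, scores repeat-pair sequence similarity from BLAST tabular output,
    relates post-translational modification site density to domain disorder, and
    performs hypergeometric over/under-representation analysis with
    Benjamini-Hochberg correction and a signed 14-grade log10(P) scale. A seeded
    synthetic-proteome generator with planted effects makes the full pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
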