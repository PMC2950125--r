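Package: geneage
Title: Gene Age Dating and Chromosomal Redistribution of Sex-Biased Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dates gene origination on a vertebrate species ladder by a
    single-origin parsimony rule over ortholog presence/absence evidence,
    classifies young genes into DNA-level duplicates, retrogenes and de novo
    genes, calls expression presence and testis-vs-ovary sex bias from
    replicated intensity matrices, and quantifies how sex-biased expression
    redistributes between the X chromosome and autosomes with gene age:
    per-branch X-linked gene-gain curves, contingency enrichment statistics,
    signed-log enrichment heatmaps, evolutionary-strata association,
    cross-species expression divergence from relative-abundance profiles,
    and an exponential-decay model of the male-biased proportion as a
    function of gene age. A seeded synthetic-data generator emulates the
    genomic and microarray inputs (two-peak X-linked gene gain, decay-model
    sex-bias fractions, meiotic sex chromosome inactivation, replicate noise
    and assembly-gap dropout) so that every stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
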