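---
title: "Methods: dating genes and tracking sex-biased expression across the X"
author: "geneage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dating genes and tracking sex-biased expression across the X}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geneage)
```

# The scientific problem

New genes keep arising on mammalian genomes, and where they land is not
random. Because the X chromosome is hemizygous in males, a recessive allele
that benefits males is visible to selection immediately when X-linked —
which should enrich new male-biased genes on the X. Pulling the other way,
meiotic sex chromosome inactivation (MSCI) transcriptionally silences the X
during male meiosis, so genes required in meiotic or post-meiotic germ cells
fare better on autosomes. Whether a male-biased gene sits on the X therefore
depends on how long these forces have acted on it — on its *age*. `geneage`
provides the machinery to estimate gene ages, call sex-biased expression,
and quantify how the two interact.

# Dating genes by single-origin parsimony

## The ladder

A `branch_ladder` is an ordered set of speciation splits along the focal
lineage. Branch 0 is the interval before the deepest split; branch `B` is
the focal-species-specific terminal. Each split carries the outgroup clade
that diverged there. Ages are megayears before present, stored negative;
branch midpoints place each branch on a time axis, with two conventions:
the youngest branch's midpoint is the centre of its interval (e.g. −3 myr
for a 6-myr-old terminal split) and the midpoint of the open-ended branch 0
is pinned at −500 myr. The built-in `human_ladder()` has 13 branches over 12
outgroups with splits at 450, 370, 310, 220, 180, 140, 105, 90, 60, 40, 25
and 6 myr; `mouse_ladder()` has 12 branches ending at the 37-myr mouse–rat
split. These are standard divergence times; any other ladder can be supplied
as a Newick tree plus split ages (`ladder_from_newick()`).

## The assignment rule

Evidence per gene is one call per outgroup species: `present` (a reciprocal
best syntenic match exists), `absent`, or `missing` (no reliable synteny —
assembly gaps, repetitive telomeric or pseudoautosomal context). Calls from
species in the same outgroup clade collapse to one call per split (any
presence wins, else any absence, else missing).

The origin is placed under a single-gain parsimony: for a candidate origin
branch `b`, a present call at a split deeper than `b` is impossible (it
would demand a second, independent gain), each absent call at a split
crownward of `b` costs one loss, missing calls cost nothing, and the gain
itself costs the same everywhere. The minimum-cost origin wins; ties resolve
to the *older* branch. Two flags record how the evidence was used:
`conflict_resolved` (a loss was inferred — an absence crownward of a
presence) and `gap_inferred` (the chosen branch leaned on missing calls).

Three consequences matter and are tested as properties:

* the assignment equals an exhaustive brute-force scoring of all origins
  (checked over every one of the 3^S call patterns for ladders of up to 7
  outgroups);
* adding a deeper present call, or censoring an absent call to missing,
  never rejuvenates an assignment;
* on loss-free evidence, *any* censoring only ages the assignment — so
  random assembly-gap dropout produces dating errors that are 100% toward
  older branches, and at 10% dropout at least 90% of genes still date
  exactly (the package tests this at 5,005 genes).

The tie-to-older convention deserves a note. When a deep present call is
itself contradicted by absences in every intervening outgroup, equal unit
costs for gains and losses are our construction — the loss-heavy corner of
the rule space is genuinely underdetermined by the biology. Under the
tie-to-older oracle, removing such a contested present call *can* move an
assignment younger; the monotonicity guarantees above are therefore stated
for consistent (loss-free) evidence, which is the regime assembly gaps
create.

Young genes are flagged by a branch cutoff (`flag_young`): on the human
ladder branches 8–12 (primate-specific), on the mouse ladder branches 8–11.

# Classifying the origin mechanism

Given all-against-all protein paralog hits, a young gene with no hit at
e-value ≤ 1e-6 and no annotated paralog is **de novo**. Otherwise the best
hit — lowest e-value, ties broken by longer aligned child span, then lexical
parent id — is inspected: if the parent has at least one intron *fully
contained* in its aligned interval while the child has none in its own, the
child is a **retrogene** (an RNA-level copy that lost its introns);
everything else is a **DNA-level duplicate**. Full containment is our
reading of "intron in the aligned region": it is conservative and
deterministic at interval boundaries, and it makes the classification
monotone — shrinking the aligned interval can only demote a retrogene call
to DNA-level duplicate, never the reverse. A gene whose only paralog
evidence is an annotation (no alignment to interrogate) is conservatively a
DNA-level duplicate, since the retrogene criterion cannot be evaluated.
Coordinates are 0-based half-open throughout.

# Expression calls

**Presence.** A gene is present in a tissue or cell type only when detected
in *all* replicates, absent only when undetected in all, ambiguous
otherwise; ambiguous genes are excluded from proportions, which are always
`present / (present + absent)`. Detection above background is a one-sided
rank-sum test of gene-level signal against a background sample, thresholded
on BH-adjusted values at 0.01.

**Sex bias.** Testis and ovary replicate groups are compared per gene on
log2(intensity + 1) with a pooled-variance t statistic whose variance is
shrunk toward the genome-wide mean variance: the per-gene variance gets
weight equal to its residual degrees of freedom and the genome-wide mean a
prior weight of 4. This is a deliberately plain stand-in for moderated-t
empirical-Bayes machinery: it reproduces the calls without fitting
hyperparameters, and a test cross-checks it against the reference
moderated-t implementation on synthetic data (>95% call agreement).
p-values are BH-adjusted across genes; FDR 0.05 is the default cutoff;
gonad-vs-gonad contrasts are labelled male/female bias because germline
contrasts dominate such comparisons. Arrays are assumed pre-normalised;
normalisation itself is out of scope. Multiple-testing correction is BH
throughout (a q-value-style estimator would need a tuning step; BH is
deterministic and slightly conservative).

# Composition statistics

* `branch_proportions()` — per-branch X-linked share of gene gains;
  branches with zero gains are undefined (NA), never 0.
* `bias_by_age()` — male-biased proportion among assayed genes per branch,
  separately for X and autosomes, dropping points covered by fewer than 5
  assayed genes (the probe-coverage rule), with unweighted least-squares
  trends against branch midpoint age.
* `bias_contingency()` — the 2×3 (X/autosome × male/female/unbiased) table
  for a gene subset, tested by Pearson chi-square without continuity
  correction (df = 2).
* `stage_presence_table()` — expressed proportions across spermatogenesis
  cell types by age class, with per-stage X-vs-autosome chi-square tests.
* `enrichment_heatmap()` — per branch × tissue, a Fisher exact test of
  expressed proportions; the score is −log10(p) signed positive when the X
  proportion exceeds the autosomal one, and clamped symmetrically at ±8 so
  a single astronomically small cell cannot dominate the colour scale.
  Tissues are ordered by average-linkage clustering on Euclidean distances
  between score columns; the linkage is presentation-only and no result
  depends on it.
* `strata_age_association()` — X genes cross-tabulated as old strata (1–3)
  vs young strata (4–5) against old vs young genes, one-sided Fisher for
  the association of old strata with old genes; PAR and undefined-stratum
  genes are excluded.

All p-values flow through one module (`chi_square_independence`,
`fisher_exact`, `wilcoxon_rank_sum`, `bh_fdr`) so there is a single source
of truth; the Fisher two-sided convention is the minimum-likelihood sum, and
rank-sum tests are exact for tie-free samples with min(n, m) ≤ 12 and use
the tie-corrected normal approximation otherwise.

# Expression divergence

A gene's relative abundance (RA) is its expression in one tissue divided by
its summed expression over all tissues; profiles are scale-invariant and
undefined (flagged, not zeroed) for all-zero genes. Divergence between
species is `D = Σ_t (RA1_t − RA2_t)²` — the *squared* Euclidean distance,
kept as the sum of squares without the square root, exactly as the quantity
is defined in this literature despite the "distance" name. For probability
vectors 0 ≤ D ≤ 2. Group contrasts (age class × chromosome class) are
pairwise rank-sum tests.

# The decay model

The male-biased proportion among genes born at age `t ≤ 0` is modelled as
`f(t) = N(e^{rt}(1−d)+d)`: `N = f(0)` is the male-biased fraction of
brand-new genes, `r` (per myr) the decay rate, `N·d` the deep-time plateau.
`fit_decay()` minimises `Σ w_i (p_i − f(t_i))²` with weights equal to the
per-branch gene counts — Gaussian maximum likelihood with variance ∝ 1/w —
under box constraints N > 0, r ≥ 0, 0 ≤ d ≤ 1. The objective has flat
valleys (small `r` trades off against `d`), so the optimiser is multi-start:
a data-driven start (N from the youngest branch, d from the oldest/youngest
ratio clipped to [0.01, 0.99]) crossed with a coarse grid of decay rates
(0.002–0.3/myr), plus jittered restarts from a fixed internal seed (so fits
are deterministic), each refined by box-constrained quasi-Newton with
parameter scaling and finished with a high-precision simplex polish.
Noiseless inputs are recovered to 1e-6 in all three parameters; repeated
fits are bit-identical. Fits are returned as a classed model object with
`print`, `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot` and
`simulate` methods (`simulate` draws binomial replicates at the fitted
curve).

# What the synthetic generator emulates — and what it does not

`sim_config()` fixes the study conditions; all randomness flows from its
mandatory seed and the generator is bit-reproducible under it. Defaults:

* **Gene gains**: ~4,860 genes over the 13 human branches, weighted toward
  the deep vertebrate core with a pronounced branch-5 pulse, scaled down
  about fourfold from a real genome so the full suite runs in seconds.
* **Two-peak X share**: 3% of gains are X-linked at baseline; the
  post-marsupial burst (branches 5–7 at 12/10/8%) and the recent burst
  (branches 11–12 at 8/12%) sit in the 8–14% band.
* **Sex bias**: the probability that a gene born at age t is male-biased
  follows the decay model per chromosome class — X: (N, r, d) =
  (0.74, 0.08, 0.42); autosomes: (0.30, 0.05, 0.90), i.e. essentially flat
  near 28%. Female bias rises with age on the X (10% young → 38% old) and
  is flat at 17% on autosomes.
* **Spermatogenesis**: per-stage presence probabilities by age and
  chromosome class; MSCI is a 37% silencing probability applied to old X
  genes in meiotic cells (half effect post-meiotically), and young X genes
  get a 70% post-meiotic expressed proportion — both chosen to reproduce
  the observed direction (old X silenced in meiosis; young X genes over 20
  percentage points above young autosomal genes post-meiotically).
* **Noise**: log-normal intensities (log2 sd 0.25, 4 gonad replicates, a
  planted 2-log2FC sex-bias effect), 2% replicate-level detection-flag
  flips, 10% ortholog-call dropout.
* **Divergence**: a second species shares each gene's cell-type profile up
  to log-normal perturbation (sd 0.3), tripled for young X genes.

The generator deliberately does **not** emulate probe-level artefacts,
normalisation residue, correlated replicate structure, phylogenetic
autocorrelation between neighbouring branches, gene-length or GC effects,
or sequence evolution. Passing round-trip tests therefore demonstrates that
the estimators recover the structure they assume, not that real microarray
data meet those assumptions.

# Numerical and design choices

* Chi-square tests never use a continuity correction, including 2×2 tables,
  for consistency with the df = 2 contrasts.
* Fisher two-sided p-values can exceed 1 by floating-point rounding in the
  minimum-likelihood sum and are clamped at 1.
* Zero-margin contingency rows/columns are a hard, named error for the
  chi-square path; a zero-margin 2×2 Fisher table is valid and gives p = 1.
* The heatmap clamp (±8 on the signed log10 scale) is symmetric; the
  association test for strata requires genes in both stratum classes but
  tolerates a missing age class (the degenerate table then gives p = 1).
* Branch histograms always include zero-gain branches; X-share at such
  branches is NA.
* `fit_decay` needs at least 4 points; with fewer X-linked branch points
  than that (tiny simulations), the pipeline's decay stage fails loudly
  rather than fitting an underdetermined curve.

# Problem sizes

The test suite simulates genomes of 260–10,010 genes depending on what a
test must resolve (binomial bounds on the two-peak curve use ~10k genes;
dropout-direction checks use ~5k; schema and smoke tests use a few hundred)
and completes in well under a minute. The acceptance script refits the decay
model from 11 branch proportions of 300 genes each; the recovered `N` has a
standard deviation near 0.05 under that binomial noise, which is a property
of the prescribed noise level, not of the optimiser (noiseless refits are
exact to 1e-6).

# Known limitations

* The dating rule assumes a strictly ladder-shaped species tree; trees with
  polytomies on the focal path are rejected rather than resolved.
* Equal gain/loss costs are a convention; loss-heavy histories (true gene
  loss in many consecutive outgroups) are dated older than a cost-asymmetric
  rule would date them.
* The shrinkage-t is not an empirical-Bayes moderated-t; with very few
  replicates and strongly heteroskedastic genes the two can disagree at the
  margin.
* Divergence D compares RA profiles only; it is blind to proportional
  expression changes shared across all tissues.
* Per-stage divergence percentages are reported as mean D × 100; other
  normalisations of the same quantity exist and are not asserted against.
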