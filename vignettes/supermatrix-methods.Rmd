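---
title: "Supermatrix construction, locus screening and topology tests: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supermatrix construction, locus screening and topology tests: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(supermatrix)
```

# Overview

`supermatrix` implements the data-assembly and quality-control stages of a
transcriptome-based phylogenomic study, together with the two topology
tests commonly paired with them.  The pipeline takes per-locus aligned
amino-acid orthogroups and their gene trees and produces a concatenated
supermatrix with partition bookkeeping, after

1. deleting duplicated records,
2. tree-based paralog pruning with support-value collapsing,
3. gene-occupancy filtering,
4. per-locus branch-length and compositional heterogeneity screening, and
5. gappy-site removal.

A compact amino-acid likelihood engine supports the stages that need
maximum-likelihood machinery at desk scale — gene-tree inference for
diagnostics, per-locus model selection, the SOWH parametric bootstrap —
and a seeded synthetic-data generator supplies inputs with known ground
truth so that every stage is testable without external data.

# Paralog pruning

Transcriptome orthogroups routinely contain several sequences per taxon.
The pruner assumes the gene tree tells paralogs apart and proceeds in
three steps.

**Support collapsing.** Internal edges with support *strictly below* 0.7
are contracted into polytomies (`collapse_low_support()`).  Supports equal
to 0.7 are kept; edges without support values are kept.  The contracted
edge's length is discarded — the collapsed tree is used only for the
topological decision that follows, never for branch-length diagnostics.

**Maximally inclusive subtree.** Every rooted subtree of the unrooted,
possibly multifurcating tree — one per directed edge, plus the whole
tree — is scored (`max_inclusive_subtree()`).  A candidate is *valid*
when each taxon contributes at most one sequence, except taxa whose
sequences within the candidate either form a clade containing only that
taxon or all attach to one polytomy node; such sets are in-paralogs and
are kept whole.  Among valid candidates the largest wins.  "Largest" is
measured in leaves; because neither the procedure's description nor the
original tool fixes tie behaviour, ties are broken deterministically by
(i) more distinct taxa, (ii) greater total non-gap residue count, (iii)
the lexicographically smallest sorted leaf-label set.  Determinism here
is what makes oracle testing (exhaustive enumeration on small trees)
possible.

**In-paralog reduction.** Within each retained in-paralog set all but the
longest sequence (most non-gap residues; ties by sequence id) are
deleted.  The result has at most one sequence per taxon.  Columns are not
realigned — all-gap columns are dropped, and realignment is left to the
caller, since it belongs to an alignment tool rather than this package.

Taxa are extracted from sequence ids as everything before the first `|`
(configurable), mirroring transcriptome contig naming.

# Occupancy filtering

A locus is kept at occupancy fraction *f* when its distinct-taxon count is
at least `ceiling(f * n_total_taxa)`.  The ceiling rule reproduces all the
usual printed thresholds: 10/20/30/40 taxa at 25/50/75/100% of 40, and
10/19/28 at 25/50/75% of 37.  Raising *f* can only shrink the locus set.

# Locus heterogeneity screening

Two families of per-locus indices are computed (`locus_diagnostics()`).

*Branch-length indices*, from the locus gene tree: the mean pairwise
patristic distance; the sample standard deviation of tip-to-root
distances (unrooted trees are midpoint-rooted first — the procedure needs
a root and midpoint rooting is the standard convention when none is
given); and the LB score, the percentage deviation of each taxon's mean
pairwise patristic distance from the tree-wide mean.  LB scores average
to zero on every tree by construction, and are invariant to rescaling all
branch lengths.  The per-locus scalar is the sample standard deviation of
the per-taxon LB scores, the usual heterogeneity summary; the mean of the
upper quartile would be an alternative, and the per-taxon scores are
exposed so either can be formed.

*Compositional indices*, from the alignment with gaps and ambiguity
excluded: RCFV, the mean over taxa of the summed absolute deviations of
per-taxon residue frequencies from the across-taxon mean (zero exactly
when all taxa share one composition); and a chi-square homogeneity test
on the taxa-by-residue count table, with expected counts from the
marginals, no continuity correction, and residues absent from the whole
locus dropped from the degrees of freedom.

**Elimination** (`filter_loci()`) is two-stage, and the order matters:
stage 1 removes loci whose `avg_pd`, `tip_root_sd` or `lb_index` is at or
above `median + 1.5 * IQR` (type-7 linear-interpolation quantiles; the
cutoff uses "greater than or equal"); stage 2 recomputes quantiles *on
the stage-1 survivors only* and removes loci with chi-square p below 0.05
or an IQR-flagged RCFV.  When an index is constant the IQR is zero and
every value would sit at the cutoff; that degenerate case is skipped
rather than eliminating everything.  Filters and thresholds are
configurable (`pipeline_config()`).

# Matrix construction

`concatenate_orthogroups()` builds the one-row-per-taxon matrix over the
union of taxa, gap-padding missing cells, with 1-based inclusive
partition coordinates written in the RAxML dialect
(`<MODEL>, <locus> = <start>-<end>`).  Gappy-site removal
(`remove_gappy_sites()`) drops columns whose gap proportion is *strictly*
above 0.5 and is applied per locus before concatenation, so partition
coordinates always describe the trimmed loci.  Missing-data percentages
count both `-` and `X` (ambiguity is treated as missing, following the
usual missing-data accounting); the overall figure is the mean cell-level
missingness.  A parsimony-informative column has at least two distinct
unambiguous residues each present in at least two sequences.

# The likelihood engine

The engine (`log_likelihood()`, `ml_search()` and friends) implements
Felsenstein pruning over the 20-state amino-acid alphabet with empirical
exchangeabilities (Poisson, JTT, WAG, LG — enough to exercise model
selection at desk scale) and discrete-gamma rate variation (4 categories,
category means; the shape is optimised by bounded one-dimensional search
when enabled).  The rate matrix is normalised to one expected
substitution per unit branch length and eigendecomposed once per model;
reconstructed transition probabilities are clamped to `[0, 1]`.  Site
patterns are compressed; gaps and ambiguity codes are fully ambiguous
tip states.

Branch lengths are optimised one edge at a time by golden-section search
on the edge's conditional likelihood, in log branch length over
`[1e-8, 10]`, sweeping the tree in preorder with partials refreshed so
every edge sees exact conditionals; a sweep that fails to improve the
full log-likelihood (numerically impossible except for round-off) is
rejected, so the per-sweep trace is non-decreasing.  Tree search is NJ +
NNI hill climbing: maximum-likelihood pairwise distances feed
`ape::nj()`, all nearest-neighbour interchanges of the current tree are
scored with a cheap partial optimisation (a valid lower bound, so
accepted moves always improve the true likelihood), and the best
improving neighbour is re-optimised fully.  With a monophyly constraint,
the start tree grafts the constrained taxa as a clade onto an NJ tree of
the remaining taxa and NNI moves violating the constraint are discarded.
NNI (rather than SPR) is sufficient at the 4-10 taxon scale the engine is
meant for; random restarts can be emulated by reseeding the distance
noise, but were not needed in any of the recovery experiments.

# Topology tests

**SOWH** (`sowh_test()`): the statistic is
`delta = lnL(unconstrained ML) - lnL(constrained ML)`, floored at zero
because the hypotheses are nested and small negative values can only be
optimiser round-off (floored values are logged).  The null distribution
comes from simulating `n_sim` data sets of the observed length on the
constrained ML tree with its fitted branch lengths (and re-fitted gamma
shape when the model has one; equilibrium frequencies come from the named
empirical model, configurable), then re-running both searches per data
set.  The p-value is `#{delta_sim >= delta_obs} / n_sim` — the plus-one
variant `(k + 1) / (n + 1)` is available — with a Clopper-Pearson
binomial interval recorded after every replicate, mirroring the usual
sequential reporting; adaptive stopping is deliberately off so runs are
reproducible.  When the unconstrained tree already satisfies the
constraint, `delta = 0` and `p = 1` — a valid outcome, not an error.

**Posterior model odds** (`posterior_model_odds()`): the frequency of
post-burn-in trees supporting one topological hypothesis divided by the
frequency supporting the alternative, with trees supporting neither
counted separately.  Zero support for the alternative gives infinite
odds.  Monophyly is decided on unrooted trees via bipartitions.

# The synthetic-data generator

The generator emulates the statistical structure the pipeline assumes,
at the data regime of a 40-transcriptome study: `synthetic_config()`
defaults to 40 taxa, 200 loci of 100-400 aligned amino acids, moderate
duplication and loss (0.2 events per unit branch length each), one
long-branch taxon at a 5x terminal rate multiplier, compositional bias on
a three-taxon group in a fifth of the loci at intensity 0.5, and a
Beta(2, 1) per-locus taxon-retention law (about a third missing data,
within the 20-77% range such matrices show).  Tests and the acceptance
script scale `n_taxa`/`n_loci`/lengths down from these defaults to keep
runs fast; the scaled sizes are stated where they are used.

Species trees are pure-birth (Yule) conditioned on the taxon count and
rescaled to unit height — the simplest ultrametric generator, sufficient
because downstream code never uses absolute time.  Gene trees evolve
inside the species tree by independent Poisson duplication and loss along
branches; copies evolve independently after duplication, each leaf is
labelled `taxon|copyN`, and the manifest records which leaf continues the
root lineage (the "original" copy, at most one per taxon) — the yardstick
for measuring how much pruning improves ortholog precision.  Loci whose
surviving copy count drops below two are dropped and recorded as such.

Sequences evolve along the gene tree under the configured model.  A
long-branch taxon's terminal branch is multiplied by its rate factor.  A
biased taxon's terminal branch evolves toward the mixed equilibrium
`(1 - b) * pi + b * target` — the default target concentrates half the
mass on A, G, P and S, a GC-rich codon-bias analogue — for the branch
itself plus one extra tree-height of exposure, representing a lineage
that has spent substantial time under the biased regime; bias confined to
a short terminal branch alone would barely move composition and no
compositional filter (including the real ones) would be expected to see
it.  Support values are 1.0 everywhere unless NNI noise is requested, in
which case edges not present in the undisturbed tree get Uniform(0, 1)
supports — the pipeline consumes supports, it does not estimate them.

Occupancy masks draw a per-locus retention probability from
`Beta(alpha, beta)` and retain each taxon independently with it, which
produces the wide per-locus occupancy spread (25-100%) and wide per-taxon
missingness real matrices show.  Every generator is a pure function of
its arguments including the seed (`withr::with_seed`), so datasets,
manifests and whole pipeline runs are byte-reproducible.

## What the generator does not emulate

Alignment error, indel structure beyond the occupancy mask, site-rate
autocorrelation, heterotachy, codon-level effects and contamination are
absent.  Passing tests therefore demonstrate the correctness and
calibration of the pipeline's decision rules on data satisfying its
assumptions, not robustness of those rules on real transcriptomes.

# Numerical and design notes

* Quantiles everywhere are type 7 (linear interpolation); IQR = Q3 - Q1.
* Per-pattern scaling keeps pruning partials in range; scalers are
  tracked in log space per rate category.
* ML distances cap at 10 substitutions/site; pairs with no shared
  unambiguous sites get the cap with a warning.
* NJ branch lengths are clamped at zero; search starts clamp at 1e-8.
* The chi-square test needs expected counts that are not too small; the
  calibration experiments use loci of 300 residues over 10 taxa
  (expected counts around 15 per cell), where the asymptotic reference
  distribution is accurate.
* SOWH experiments in the test suite use 6 taxa with 100-2000 sites and
  50-100 simulations per test — large enough for the calibration and
  power properties being checked, small enough to run on one CPU in
  minutes.
* `run_pipeline()` aborts with the failing stage's name; partial outputs
  already written are retained.

# Known limitations

The engine is deliberately desk-scale: no SPR, no CAT-like mixtures, no
parallel search, and tree search beyond ~15 taxa will be slow.  The SOWH
test inherits the usual caveat that misspecification of the simulating
model can inflate type-I error; calibration here is demonstrated under
the true model.  Posterior tree samples are ingested as plain multi-tree
Newick only.
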