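---
title: "Dissecting intra-plastome phylogenetic conflict: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting intra-plastome phylogenetic conflict}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastosig)
```

## The problem

Chloroplast genomes (plastomes) are routinely concatenated and analysed as a
single locus, on the assumption that the whole molecule shares one history.
In groups that radiated rapidly, however, the internal branches separating
major subclades are extremely short, most of the ~250 extractable plastid
loci are nearly uninformative about such a node, and the concatenated
topology can be decided by a handful of outlier loci whose signal conflicts
with the rest of the molecule. `plastosig` provides the machinery to expose
this situation: per-region plastome statistics and typed locus extraction, a
fixed-topology likelihood engine, locus-wise log-likelihood dissection
between competing resolutions of a contentious node, locus-removal
experiments, and RELL-based topology tests — plus a seeded simulator that
plants a known conflicting minority of loci so every claim in the pipeline
is testable without external data.

The package deliberately does **not** search tree space, align sequences,
assemble or annotate genomes, or select substitution models: resolved
candidate topologies, alignments and model choices are inputs.

## The likelihood engine

The core of the package is a classed model fit. `fit_topology(aln, tree,
model)` maximises the likelihood of a DNA alignment on a *fixed* topology
under GTR+I+Gamma and returns a `"topofit"` object with `print`, `summary`,
`coef`, `logLik`, `simulate` and `plot` methods.

### Model

The general time-reversible rate matrix is built as `q_ij = r_ij * pi_j`
(exchangeabilities in the order AC, AG, AT, CG, CT, GT, with GT fixed at 1
for identifiability), with the diagonal making rows sum to zero.
Among-site rate variation uses Yang's discrete-gamma approximation with
`K` equal-probability categories, each category carrying the conditional
mean of a Gamma(alpha, alpha) distribution over its quantile slab, so the
category rates average exactly 1. A proportion `p_inv` of sites is
invariant (rate 0).

**Rate normalisation.** With an invariant class present, the matrix is
scaled so the *expected* substitution rate over the full mixture is one,
i.e. `-sum_i pi_i q_ii = 1 / (1 - p_inv)`. This is the convention of
mainstream ML software and keeps branch lengths in expected
substitutions per site; it is also what makes the engine agree to within
round-off with an independent implementation on identical inputs (checked
in the test suite against `phangorn::pml`).

### Pruning

Per-site log-likelihoods come from Felsenstein's pruning algorithm over the
postorder edge list, computed per rate category on the compressed set of
unique site patterns, with per-pattern rescaling of partial likelihoods
(log-scale accumulators) to avoid underflow. Transition matrices
`P(t) = exp(Qt)` are computed by symmetrised eigendecomposition — exact for
a reversible `Q` and cheap to re-evaluate per branch. Gaps, `?`, `N` and
IUPAC ambiguity codes enter as indicator vectors over their compatible
states; the invariant-class contribution of a site is
`p_inv * sum_x pi_x` over the states `x` compatible with a constant column.
An all-gap column therefore has likelihood 1 (logged as a warning).
Because the model is reversible, root placement is irrelevant (the pulley
principle); input trees are unrooted before fitting.

### Optimisation

Fitting is coordinate-wise: a pass of per-branch 1-D optimisation
(Brent-style `optimize()` on the log of the branch length, bounded to
`[1e-8, 100]` substitutions/site) alternates with a model-parameter step
(Nelder-Mead on log/logit-transformed exchangeabilities, gamma shape, and
invariant proportion; Brent when only one parameter is free), until the
log-likelihood improves by less than `tol = 1e-4` per pass (at most 200
passes; non-convergence returns the best fit with a warning flag).
Improvements are accepted only if they do not decrease the likelihood, so
the trajectory is monotone. Base frequencies are *empirical* by default —
counted from the alignment — which keeps fits reproducible and matches
common practice; they are never ML-optimised unless the starting model is
used as-is (`empirical_freqs = FALSE` keeps the supplied values). A
two-taxon alignment has only one identifiable path length, so the second
root edge is pinned at ~0.

Whether per-topology branch lengths should be re-optimised before
site-likelihood comparison, or fixed values reused, is exposed through the
`free` flags of `fit_topology()` and `site_lnl_matrix()`; the pipeline
default re-optimises branch lengths for every candidate topology on the
same data, which is the constrained-ML convention.

## Locus-wise signal dissection

Given a topologies-by-sites matrix of per-site log-likelihoods
(`site_lnl_matrix()`), `locuswise_delta()` sums the site-wise difference
`lnL_A - lnL_B` over each locus's columns. The sign convention is always
first-label-minus-second (positive supports the first topology) and is
written into every output header. Columns outside all loci are aggregated
into a `"_unpartitioned"` pseudo-locus, making the conservation identity
exact: locus deltas always sum to the total log-likelihood difference.

Support classification follows the conventional thresholds: a locus is a
*strong* supporter when `|dlnL| > 2` and a *moderate* one when
`1 < |dlnL| <= 2`, with strict inequality at the boundary (a delta of
exactly 2 is moderate). With three candidate resolutions of a trichotomy
the dissection is pairwise for all three pairs, and a locus "supports" a
topology only when it beats *both* rivals, with class taken from the
weaker margin — no joint three-way statistic is invented.

`removal_experiment()` re-fits every candidate topology on the dataset
minus named loci and ranks them by total log-likelihood. Note a deliberate
deviation from the workflow it emulates: the experiment *re-scores supplied
candidates* rather than re-running a heuristic tree search, because tree
search is out of scope; with candidates covering the plausible resolutions
of the focal node the ranking carries the same information.

## Topology tests

All tests run on RELL resampling (resampling estimated log-likelihoods):
bootstrap replicates draw sites with replacement and re-sum the per-site
log-likelihoods without refitting, implemented by multinomial weight
vectors in blocks for memory safety. Every test takes an explicit integer
seed and is bitwise reproducible.

* **KH** — the observed statistic is the total log-likelihood difference;
  RELL replicates of the difference are centred at their mean to form the
  null. The default is two-sided, appropriate when neither topology is
  pre-specified as the null; a one-sided variant (`sided = "one"`) is
  provided because the classical conservatism relation of the SH test, and
  the asymptotic agreement of the AU test, are both statements about the
  one-sided statistic.
* **SH** — simultaneous over the candidate set: observed statistics are
  `max lnL - lnL_t`; the null uses per-topology centring and the maximum
  over topologies within each replicate. Against the one-sided KH
  probability the test is conservative, which the suite checks
  statistically (not per instance).
* **AU** — multiscale bootstrap: at each scale factor `r` in
  {0.5, 0.6, ..., 1.4} the RELL draw has `round(r * sites)` sites, giving
  bootstrap proportions `BP_t(r)`; the signed-distance/curvature model
  `qnorm(1 - BP) = d*sqrt(r) + c/sqrt(r)` is fitted by weighted least
  squares (weights from the delta method) and `p_au = 1 - pnorm(d - c)`.
  Bootstrap proportions identically 0 or 1 across scales mean the
  regression is void; the p value is then clamped to 0 or 1 and flagged
  `degenerate`.

p values are reported to four decimals alongside `deltaL`, the
log-likelihood distance behind the best candidate, and the seed is recorded
in the output. Published p values from other implementations can only be
matched approximately even on identical input, because the scale set,
sidedness and replicate streams of those implementations are not fully
specified.

## Plastome structure and locus extraction

Plastome records enter as single-record GenBank flat files (a minimal
hand-rolled parser/writer, since no installed offline parser exposes the
feature table); coordinates are 1-based inclusive throughout, matching the
GenBank convention native to R.

**Inverted-repeat detection** is not described in the workflows this
package emulates, so it is specified here: a seed-and-extend search on the
doubled (circular) sequence finds the longest pair of
reverse-complement-identical repeats of at least `min_ir = 1000` bp with 0
mismatches by default (both configurable); the two gaps between the copies
are the single-copy regions, the *longer* gap is called LSC (no length
ordering beyond that is assumed), and IRa is the copy that follows the
LSC. Exact, long IRs are the norm in the Lauraceae-like plastomes this
models; the mismatch budget exists for divergent boundaries. Rotating the
circle changes coordinates but no length or GC statistic, and a
convenience rotation (`rotate_plastome_record()`) normalises records to
LSC-start-at-1.

**Locus extraction** produces the five locus types used in gene-wise
conflict scans: coding regions (exons joined, minus-strand features
reverse-complemented), introns (gaps between consecutive exons, numbered
along the strand), tRNA and rRNA genes, and intergenic spacers (maximal
regions between adjacent *gene extents*, exon-level features merged per
gene first, named `geneA-geneB` with geneA upstream; zero-length spacers
skipped; the circular wrap spacer included). With
`ir_policy = "drop_one_copy"` the record is rotated to LSC-start and the
IRb copy removed before extraction, so repeat-region loci enter once.
Genes whose pieces are dispersed across the genome (the trans-spliced
`rps12` pattern) cannot be represented as a contiguous locus; they are
excluded and logged, since the emulated workflow does not say how they
were handled. Gene names are matched case-insensitively with copy
suffixes (`-1`, `_2`) stripped. The identity
`lsc + ssc + 2*ir = total` is enforced exactly, and on records whose
features tile without overlap the extracted loci tile the unduplicated
genome exactly (checked in the tests); overlapping annotations are
reported, not silently absorbed.

One emulated workflow removed a handful of taxa before locus extraction
but its published list is ambiguous (six removals, five names); this
package therefore takes an explicit exclusion list rather than guessing.

**Gap masking** strips whole alignment columns whose gap fraction exceeds
the threshold (thresholds of 0, 0.02, 0.1, 0.2, 0.5, 0.75 are the
conventional grid; 0 keeps only gap-free columns). Column stripping — as
opposed to masking residues in place — is chosen because it is the
behaviour needed downstream (every analysis consumes columns), and the
partition map is remapped onto the surviving columns, keeping emptied loci
as zero-length entries flagged `weak` rather than dropping them.
Ambiguity codes count as non-gap: they carry partial information.

## The synthetic world

`simulate_conflict_dataset()` is first-class, tested code, and its
defaults *are* the stated world of the package:

* **Taxa and trees.** Three subclades of two taxa each plus an outgroup.
  Terminal branches 0.008, subclade stems 0.004, outgroup 0.02
  substitutions/site — the low interspecific divergence typical of
  congeneric plastomes. The three candidate resolutions T1 (subclades
  I+II), T2 (II+III) and T3 (I+III) of the focal trichotomy come from
  `preset_topology()`.
* **The focal edge.** The majority tree's focal edge is 3e-4
  substitutions/site — a near-polytomy. This is the essential feature of
  the rapid-radiation regime: across ~240 loci totalling ~100 kb it yields
  only a few dozen decisive sites genome-wide, so most loci are almost
  uninformative about the node. The planted minority evolves on the
  alternative resolution with a focal edge of 0.005 (a detectable planted
  signal needs at least ~0.002), so its few loci carry *concentrated*
  conflicting signal. Only in this asymmetric regime does the documented
  phenomenon exist at all: the planted loci top the |dlnL| ranking, decide
  the concatenated winner, and removing them flips the ranking. With a
  firmer majority focal edge, the diffuse majority signal swamps any
  6-locus minority and nothing a small locus subset does can change the
  topology.
* **Loci.** 243 loci by default, lengths log-uniform on 100-3000 bp;
  planted loci are drawn from 500-3000 bp, because a conflicting locus
  much shorter than 500 bp carries too few informative sites to be
  detectable even in principle at these branch lengths.
* **Model.** GTR+I+Gamma4 with plastome-like composition (~39% GC),
  transition bias, gamma shape 0.5 and 30% invariant sites — desk-scale
  stand-ins for typical plastome estimates. The per-site rate (invariant
  or a gamma category) is drawn once per site and shared across the whole
  tree, matching the likelihood model's rates-across-sites assumption.

`synth_plastome_record()` generates the structural fixture: a ~152 kb
quadripartite circle (LSC, IRa, SSC, IRb; IRb the exact reverse complement
of IRa; region-specific GC of roughly 38/44/34%), carrying 112 unique
genes (78 CDS, 30 tRNA, 4 rRNA) of which 13 — all rRNAs, 7 tRNAs, 2 CDS —
are duplicated across the repeat, 16 one-intron and 2 two-intron genes.
The bases flanking the repeat are pinned so the planted IR is *exactly*
maximal, making boundary recovery testable to the base.

**What the generator does not emulate — and hence what a green test does
not establish:** there are no indels or alignment error (columns are
homologous by construction); conflict is planted by topology switching,
not generated by a coalescent, so it emulates the *pattern* of
incomplete-lineage-sorting-like discordance without its process; partially
duplicated boundary genes (the `rps12`/`ycf1` pattern) are absent, so
synthetic gene totals (125) are slightly below real plastome totals; and
real annotation noise (inconsistent naming, missing features) is absent.
Green tests establish that the *machinery* is exact and that the
planted-conflict phenomenon is recovered in the stated regime — not that
any particular real dataset behaves this way.

## Numerical choices

* Branch-length bounds `[1e-8, 100]`; per-branch optimisation on the log
  scale with `optimize()` tolerance 1e-7, tight enough for closed-form
  distance checks at 1e-6.
* Convergence tolerance 1e-4 log-likelihood units per full pass, 200
  passes maximum; the non-convergence path returns the best-so-far fit
  with a warning rather than an error.
* `P(t)` by symmetrised eigendecomposition; tiny negative entries from
  round-off are clipped at 0.
* Pattern compression before pruning; per-pattern log-scale accumulators.
* RELL replicates via `rmultinom` in blocks of at most ~2e7 cells.
* AU continuity clamp: bootstrap proportions are held away from 0 and 1 by
  half a replicate before the probit transform.
* Gene-name normalisation strips numeric copy suffixes and compares
  case-insensitively; ties in locus naming get `__2`-style suffixes.

## Known limitations

* The locus-removal experiment re-scores supplied candidate topologies; if
  the relevant alternative is not among the candidates it cannot be found.
* The AU implementation follows the standard multiscale-WLS construction
  but is not expected to reproduce other software's p values to the last
  digit (scale grid and replicate streams differ).
* IR detection assumes a single dominant inverted repeat; plastomes with
  drastically reduced or absent IRs are reported as errors, not guessed.
* The engine is desk-scale: dozens of taxa and ~10^5 sites are
  comfortable; it is not a replacement for optimised ML software at
  hundreds of taxa.
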