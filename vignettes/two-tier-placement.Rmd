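---
title: "Two-tier phylogenetic placement: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-tier phylogenetic placement: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A taxon with no previous molecular data has to be placed into a large,
well-sampled phylogeny. Rebuilding the whole tree from scratch every time a
new sequence arrives is wasteful and, at supermatrix scale, often infeasible;
accepting the published topology wholesale risks inheriting its artifacts.
`treeplacer` implements a two-tiered compromise:

1. **Large scale.** The published topology is kept as a hard constraint and
   only the new taxon (plus any designated unstable "rogue" taxa) is free to
   attach anywhere. Nonparametric bootstrapping of the constrained placement
   yields a tally of attachment edges, from which rogue-aware *effective
   support* and *cumulative region support* are computed.
2. **Small scale.** The region of the tree that captures essentially all of
   the bootstrap placements is extracted, padded with the most complete
   representatives of outgroup clades, and re-analysed. Rival placement
   hypotheses are then adjudicated with approximately unbiased (AU) topology
   tests on site-wise log-likelihoods.

Upstream of both tiers sits a data-hygiene stage: gene-by-gene quality
control of the new sequences, and a saturation screen that drops gene x
codon-position partitions whose fast sites have lost phylogenetic signal.

# Likelihood model

All likelihoods use reversible nucleotide models (JC69, HKY85, GTR) with
discrete-Gamma among-site rate variation. Rate matrices are scaled to one
expected substitution per site at stationarity, so branch lengths are in
substitutions per site. Gamma heterogeneity follows the equal-probability,
mean-of-category discretisation with four categories by default. Per-site
likelihoods are computed by the pruning algorithm in compiled code, with
IUPAC ambiguity codes contributing the partial likelihood of their state
sets and `-`/`?`/`N` acting as fully missing. Partitioned analyses use
unlinked models: each partition carries its own exchangeabilities,
frequencies, Gamma shape and a relative rate multiplier applied to shared
branch lengths.

**Pairwise distances are a deliberate exception to the discrete-Gamma
convention.** The HKY85+Gamma distances that feed the saturation screen, and
all `ml_pairwise_distance()` calls, integrate the Gamma mixture exactly via
the eigenvalue transform `(1 - lambda*t/alpha)^(-alpha)`. That is the
convention in which published Gamma-distance formulas are stated; under JC it
makes the Jin–Nei closed form `(3a/4)((1 - 4p/3)^(-1/a) - 1)` exactly
recoverable, which the test suite asserts to 1e-6. Tree likelihoods use the
discrete approximation, as the field's ML tools do.

Branch lengths are optimized by round-robin Brent searches over
`[1e-8, 10]` substitutions per site with a convergence tolerance of 1e-6
log-units; the cached-partials decomposition guarantees a non-decreasing
log-likelihood across sweeps, and a decrease beyond numerical noise is
treated as an internal error. Conditional-likelihood arrays are not rescaled
between nodes (beyond a cheap guard in the full-tree kernel), which is safe
for the tree sizes this package targets (up to roughly 150 tips); far larger
trees would need per-node scaling throughout.

# Saturation screen

For every gene x codon-position unit the screen builds two neighbor-joining
trees — one from uncorrected p-distances, one from HKY85+Gamma ML distances —
and pairs up their patristic (tip-to-tip) distances: `x` model-corrected,
`y` uncorrected. An unsaturated unit is near-linear in that plot; a
saturated one shows a plateau where growing corrected distance buys no
additional observed difference.

"Substantial deviation from linearity" is made operational with a
two-parameter rule, both parameters exposed and reported in every output:

* **plateau ratio** — OLS slope of the pairs above the median `x` divided by
  the slope at or below it; exclude when below `plateau_threshold`
  (default 0.5);
* **global slope** — OLS slope of all pairs; exclude when below
  `slope_threshold` (default 0.3). This second rule is what reliably catches
  fully saturated units, where both half-range slopes are near zero and
  their ratio is numerically meaningless.

The tree-building method behind the paired distances is Saitou–Nei neighbor
joining; only tip-to-tip distances are consumed downstream, so any
consistent distance-tree method would serve. The per-unit kappa for the
corrected distances is a pooled Kimura-style transition/transversion moment
estimate (median over pairs, floor at 1); it is deterministic, costs nothing,
and a screening distance does not reward a full ML fit. The Gamma shape is
fixed at 0.5, the conventional fallback when pairwise shape estimation is
unstable — which it always is. Taxa need `min_sites = 50` determinate sites
to enter a unit's matrices.

**Outliers.** Contaminated or mis-curated sequences sit far from all their
putative homologs. Each taxon is scored by its median model-corrected
tip-to-tip distance to all others and flagged when the score exceeds the
median score by `k = 5` robust deviations, where the MAD is floored at half
the median score. The floor encodes "extremely high" literally: in a
tightly clustered slow partition the raw MAD is nearly zero and a plain
median+MAD rule would flag ordinary long branches, while genuine
contamination sits near the random-sequence distance scale, an order of
magnitude above any such floor. Outliers are removed *before* the plateau
regression is fitted (a single extreme point otherwise owns the fit), the
flagged taxon loses only that marker, and both the flag and the triggering
score are reported.

# Placement, tallies and support

`place_query()` grafts the query onto every backbone edge in turn and
optimizes the three local branch lengths — pendant plus the two sub-edges —
by Brent coordinate sweeps, holding the rest of the tree fixed. Candidate
edges are compared by the resulting log-likelihood; the cached
conditional-likelihood decomposition makes one full placement linear in the
number of edges. Attachment starts from the edge midpoint with a pendant of
0.1 and is optimized away from there. For several new taxa,
`place_multiple()` inserts them in decreasing order of data availability and
finishes with one prune-and-replace refinement pass, which cannot decrease
the joint likelihood.

Bootstrap replicates resample sites with replacement within each retained
partition, preserving partition sizes and the unlinked models. Rogue taxa
are detached from the backbone and re-placed jointly with the query in every
replicate, reproducing the behaviour of genuinely unstable taxa rather than
freezing them in place. Within a replicate the edges are first ranked by a
cheap pendant-only optimization and only the top three receive the full
three-branch treatment (one sweep); the winning edge, not its likelihood, is
what the tally records, and the planted-attachment test suite shows this
screen does not disturb it.

Each replicate's descriptor is the canonical split set of its topology, so
deleting rogues is a set operation on splits and any grouping of the tally
can be recomputed after the fact:

* **effective support** of a relationship: the percentage of replicates in
  which, after deleting the rogues from the replicate tree, the clade
  `(focal \ rogues) + query` is present — i.e. the query attaches inside or
  as sister to the focal group. With no rogues this is the plain bootstrap
  support; it is non-decreasing as rogues are added.
* **region support** of a taxon set: the percentage of replicates whose
  attachment edge has region taxa on both of its sides. This is exactly the
  edge set of the region's subtrees plus the spine connecting them; note
  that for a region consisting of a single clade, attachment *sister to* the
  clade is outside the region — unions of clades are the intended use.

`select_subset()` greedily accumulates backbone clades until their union
reaches the requested region support (ties broken by fewer added taxa, then
lexicographically), prunes redundant clades, and adds the `k` least-missing
representatives of each named outgroup clade. A greedy union is not provably
minimal, but it is deterministic, transparent, and exact minimality would
change nothing downstream: the subset's purpose is to contain the plausible
attachment region, which the threshold enforces directly.

Placements are exported as jplace (version 3) with edge numbers embedded in
the newick string; tallies as tab-separated descriptor/count/percentage
tables.

# Hypothesis tests

`sitewise_matrix()` re-optimizes branch lengths independently per candidate
tree and stores per-site log-likelihoods on a common site order. RELL
bootstrapping resamples those columns without re-optimization. The AU test
is the general multiscale procedure: at each relative scale `r` in
0.5–1.4 (step 0.1), `ceiling(r*n)` sites are resampled `B` times (default
10,000) and each tree's probability of being the replicate maximum is
recorded, ties split equally. Per tree, `z(r) = qnorm(1 - BP(r))` is
regressed on `(sqrt(r), 1/sqrt(r))` by weighted least squares with weights
`B * dnorm(z)^2 / (BP (1 - BP))`, giving the signed distance `d` and
curvature `c`; the AU p-value is `1 - pnorm(d - c)`. Proportions of exactly
0 or 1 are continuity-corrected to `1/(2B)`; a tree with fewer than three
informative scales is reported with a degenerate p of essentially 0 or 1 and
a flag rather than a fitted value. Two-tree comparisons run the same
machinery on the pair — there is no special-case formula. The calibration
test in the suite simulates 500 exchangeable two-tree null matrices and
checks that a true tree is rejected at the 5% level between 2% and 9% of the
time.

Hypothesis trees for the final AU round are built by pruning the query from
the best small-scale tree and regrafting it according to each rival
descriptor (sister to a named taxon set). Testing every rival on the *best*
backbone avoids penalising a hypothesis for unrelated parts of its original
topology.

# The synthetic-study generator

Every stage above is exercised end to end on generated studies, so the
generator is first-class, seeded, and tested code. Its default study — the
conditions used throughout the test suite — is a 12-leaf backbone with
uniform branch lengths on (0.01, 0.07), giving family-level tip-to-tip
depths around 0.3 expected substitutions per site at relative rate 1, and
six markers totalling about 4.3 kb:

| marker | origin | length | kappa | Gamma shape | position rates |
|---|---|---|---|---|---|
| 2 protein-coding | mitochondrial (AT-rich) | 450 each | 8 | 1.0 | 0.7 / 0.3 / **15** |
| 1 rRNA-like | mitochondrial | 700 | 4 | 1.0 | 0.5 |
| 3 protein-coding | nuclear | 900 each | 3 | 1.0 | 0.5 / 0.25 / 1.0 |

The x15 third positions of the mitochondrial genes are the planted
saturation: their tip-to-tip divergence exceeds four substitutions per site,
deep in the plateau, while every other unit stays in the near-linear regime.
That separation *is* the ground truth the screen is scored against. The
query attaches at a random backbone edge with a pendant of 0.05. Sequences
evolve site by site from stationary root draws with exact transition
probabilities per Gamma category; the suite checks stationarity, the JC
expected p-distance at a known branch length, and per-edge transition
frequencies against `expm(Qt)` by chi-square.

Missing data are applied as whole taxon-by-marker blocks — the structure
real supermatrices have, and the one completeness ranking must see — chosen
at random until the global fraction is within two percentage points of the
target, never masking a taxon's last marker. Contamination is emulated by
replacing one taxon's block in one marker with i.i.d. uniform bases.

What the generator does **not** emulate: alignment error and indels,
base-composition heterogeneity across lineages, site-specific selection, and
model misspecification beyond the discrete/continuous Gamma mismatch.
Passing tests therefore demonstrate that the machinery is correct and
well-calibrated under its own model class, not that real supermatrices are
this well behaved.

# Problem sizes and defaults used in the checks

The test suite and the acceptance script run at desk scale, chosen so the
full suite completes in about ten minutes on one core: exhaustive likelihood
oracles on trees of 2–5 leaves; 10 seeded screening fixtures; 20 placement
studies (10–12 leaves, 5 kb, 100 bootstrap replicates each); 500 null
matrices of 200 sites with 1,000 RELL replicates per scale for the AU
calibration; and two full pipeline runs (20 replicates per tier) for the
byte-determinism check. The pipeline's empirical per-partition models
(moment kappa, fixed shape 0.5, rate multipliers from mean pairwise
distances) are the default because they are deterministic and fast;
`fit_model()` provides full ML fits where parameter estimates themselves are
of interest.

# Known limitations

* No conditional-likelihood rescaling in the placement kernels: intended for
  backbones up to low hundreds of tips, not thousands.
* Region support treats a single-clade region's subtending edge as outside
  the region; supply unions of clades when sister placements should count.
* The subset search is greedy, not provably minimal.
* Pairwise distances cap at 10 substitutions per site; fully saturated pairs
  sit at the cap, which the screen's global-slope rule is designed to absorb.
* The AU implementation follows the standard multiscale formulation; with
  very few informative scales it reports flagged degenerate values rather
  than extrapolating.
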