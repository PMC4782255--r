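---
title: "Island phylogeography from DNA barcodes: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Island phylogeography from DNA barcodes: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`haplogeo` analyses aligned, gap-free mitochondrial barcode fragments
sampled across an archipelago split by an ancient deep-sea divide. This
vignette records the models the package implements, the assumptions behind
them, the tunable parameters with their defaults and units, what the
synthetic-data generator does and does not emulate, and the places where a
genuinely open design question had to be settled one way.

## Data model

The unit of input is a pre-aligned set of equal-length sequences over
{A,C,G,T} (the motivating data are 644-bp COI barcodes) with one metadata
row per sample (species, site, coordinates, side of the trench,
zoogeographic category) and an island attribute table (area in km²,
coordinates, side). Three strictness rules are deliberate:

* gaps are an error, not a warning — the analyses assume positional
  homology with no indels, and a gap character signals an upstream
  alignment problem;
* IUPAC ambiguity codes are rejected unless `allow_ambiguous = TRUE`, in
  which case any comparison involving one counts as a difference (and,
  for K2P, conservatively as a transversion). Silent coercion would bias
  haplotype identity;
* the side-of-trench flag is an explicit metadata column, never inferred
  from coordinates: the divide is a curve on the sea floor, not a
  meridian.

## Haplotypes and distances

Haplotype identity is exact string equality; ids `H001`, `H002`, … follow
first-occurrence order so outputs are reproducible run to run. The
Kimura two-parameter distance separates transition proportion P from
transversion proportion Q:

$$d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q).$$

When either logarithm's argument is non-positive the distance is
undefined and the package raises an error rather than capping: at
intraspecific divergences (≲1%) saturation can only mean corrupted input.
The molecular-clock helper converts a divergence proportion to years at a
rate of 2.3% per million years by default (the standard invertebrate
mitochondrial calibration); the uncorrected p-distance is the default
input for that conversion, since at sub-percent divergences the K2P
correction is smaller than the calibration's own uncertainty.

## Statistical-parsimony networks

Two haplotypes may be connected at `j` mutational steps only while the
connection is credibly free of multiple hits. With mutations placed
uniformly over `L` positions, the probability that a path of `j` steps
strikes `j` distinct positions is

$$P(j; L) = \prod_{i=0}^{j-1}\left(1 - \frac{i}{L}\right),$$

and the connection limit `j_max` is the largest `j` with
`P(j; L) ≥ confidence` (default 0.95). This no-repeated-site model is the
package's reconstruction of the classical parsimony-probability
computation; the exact published recursion lives in literature not
shipped here, so the implementation is cross-checked against an
independently coded closed form (via log-gamma) in the test suite, is
monotone in `L` as required, and can always be bypassed with an explicit
`max_steps` override for comparability with published networks. The
limit is conservative at small confidence-boundary cases; for a 644-bp
fragment at 95% it allows connections of up to eight steps.

Construction is agglomerative: haplotype pairs are processed in
increasing step distance, and at each distance `d ≤ j_max` every pair of
components that were distinct at the end of level `d−1` is joined through
a chain of `d−1` abstract intermediate nodes. All equally short
between-component connections at a level are retained — loops are
information about ambiguity, and no random tie-breaking occurs anywhere.
No sequence reconstruction is attempted for intermediates.

### Outgroup (ancestral) probabilities

Which haplotype is oldest? Two documented strategies are provided:

* `freq_neighbors` (pipeline default): weight = own frequency plus the
  summed frequencies of directly connected sampled neighbours,
  normalised per component. This mirrors the frequency-plus-connections
  heuristic of classical parsimony software and reproduces its behaviour
  on star-shaped networks with a dominant hub.
* `frequency`: weight = frequency alone. Coalescent theory gives this
  estimator its warrant — the probability that a haplotype is the oldest
  in a sample is proportional to its frequency — and it is the strategy
  the ground-truth recovery experiments use.

The strategies agree on stars but can disagree on chains: the
neighbour-sum weight of a root and of its first descendant contain the
same two leading terms, so the neighbour heuristic cannot separate them,
while frequency can whenever sampling is deep enough for the age-frequency
correlation to show. This is why the dense-sampling recovery experiment
(every haplotype floored at three copies, 150–200 specimens per species)
uses the `frequency` strategy; with shallow field-scale sampling
(22–68 specimens) neither strategy should be over-read.

An ancestral call reports *all* weight maximisers (ties are never broken
silently), the sites where they were sampled, and a congruence verdict
against the species' zoogeographic category: Balkan-type requires all
ancestral localities west of the trench, Anatolian-type east, Wide admits
anything, and the continental/large-island category is congruent when the
ancestral localities resolve to a single side. Tied calls straddling both
sides give `indeterminate`.

## Trees

Neighbor-Joining runs on K2P distances through `ape`'s Saitou–Nei
implementation (exact on additive matrices, verified against randomized
additive instances); negative estimated branch lengths are clamped to
zero with a warning. Bootstrap support resamples alignment columns with
replacement, rebuilds distance and tree per replicate, and counts
bipartitions topologically (clamped zero-length branches still count);
replicates whose resampled distances saturate are dropped and the
denominator adjusted. Species-cluster screening (`monophyly_check`) is a
report, not a filter.

## Phylogenetic β diversity

For an island pair on the midpoint-rooted combined tree: `a` is the
branch length lying on root-to-tip paths of both islands' haplotypes, `b`
and `c` the lengths exclusive to each. Then

$$P\beta_{total} = \frac{b+c}{a+b+c},\quad
P\beta_{repl} = \frac{2\min(b,c)}{a+b+c},\quad
P\beta_{rich} = \frac{|b-c|}{a+b+c},$$

with the additivity identity holding exactly and every value in [0, 1].
Two conventions had to be fixed:

* **Rooting.** The decomposition needs a rooted tree; midpoint rooting is
  the least-assumption default (an outgroup tip can be designated
  instead by rooting before calling `beta_matrices`). With real data the
  choice shifts β magnitudes slightly; nothing in the package asserts one
  convention as canonical.
* **Root paths count.** Branches from the root down to an island's
  subtree belong to that island, so a single-haplotype island has
  positive phylogenetic diversity. Without this the decomposition would
  be undefined for singleton islands, which are common.

Mainland sites are excluded from β and Mantel analyses by default
(`islands_only = FALSE` to include them): the predictors are interisland
quantities.

## Barrier statistics

All matrix statistics share one unfolding: the strictly-lower triangle in
column-major order. Predictors are great-circle (haversine, R = 6371 km)
distance between island reference coordinates, a 0/1 indicator for
opposite sides of the trench, and |log₁₀ area_i − log₁₀ area_j|. The
Mantel test permutes rows and columns of one matrix simultaneously and
reports p = (#{r_perm ≥ r_obs} + 1)/(n_perm + 1) — never zero — with
10,000 permutations by default, one-tailed positive (the barrier
hypotheses are directional; two-tailed via flag). An exhaustive mode
enumerates all n! permutations for n ≤ 7. The partial Mantel statistic
correlates ordinary-least-squares residuals of the two triangles on the
conditioning triangles, permuting the predictor matrix and recomputing
its residuals each time; conditioning a matrix on itself yields a partial
r of exactly 0 by definition. Hierarchical partitioning fits all 2^k
predictor subsets and averages each predictor's R² increment over all
entry orderings, reported on the absolute R² scale so the contributions
sum to the full-model R² (identity enforced to 1e-10 in tests);
rank-deficient designs warn and share the joint contribution among
aliased predictors rather than failing, so that the symmetric
duplicated-predictor case behaves sensibly.

## The synthetic archipelago: a stated world

The generator exists so that every stage can be tested against known
truth, offline. Its defaults state one fixed world, chosen to mirror the
magnitudes of the motivating study system and then frozen:

| parameter | default | why |
|---|---|---|
| `L` | 644 bp | barcode fragment length |
| `n_species` | 10 | study-scale fauna |
| `samples_per_species` | 22–68 | study-scale sampling effort |
| `haplotypes_per_species` | 10–25 | ≈ 15 haplotypes/species, study scale |
| `mu_steps` | 1 | single-step budding keeps mean intraspecific divergence in the sub-percent (≈0.1–0.6%) regime |
| `species_divergence` | 0.015 | young congeneric radiation (~3% between species); keeps the pooled K2P tree far from saturation |
| `lambda_km` | 75 | dispersal decay scale; short relative to the ~600 km archipelago |
| `phi` | 0.25 | moderate trench penalty; recovery experiments use 0.05, null experiments 1 |
| `origin_bias` | 0.8 | fixed 8:2 W:E species composition (see below) |
| `freq_decay` | 0.7 | geometric age-frequency decay — the premise of frequency-based ancestral calls |
| box | 24.3–27.3°E × 34.5–40°N, trench at 25.8°E | tall N–S archipelago: distance and trench side are not collinear |

Mechanically: each species grows an infinite-sites budding genealogy
(every budding mutates previously untouched positions, so true pairwise
step counts are additive along the genealogy — the property the network
tests exploit); each daughter haplotype's home island is drawn around its
parent's island with probability ∝ exp(−d/λ)·φ^[crossing]; each specimen's
collection site is drawn from the same kernel around its haplotype's
home. Species ancestors diverge from a shared genus root; origins
alternate sides according to the fixed composition.

Two design points deserve their rationale on record:

* **Fixed, biased composition.** A replacement signal at the trench
  arises whenever the two sides hold different haplotypes; a
  *richness-difference* signal requires the sides to be *unequal* — one
  side must have lost or never received part of the clade's history.
  A symmetric world (fair-coin origins) makes the trench read as
  replacement only. The stated world therefore fixes a majority source
  side, 8:2, the way a real fauna has one composition rather than a
  distribution over compositions.
* **One dispersal scale.** Colonisation (deep time) and haplotype
  sharing (present day) both use λ. The two recoverable signals pull in
  opposite directions — replacement–distance sharpens as λ shrinks,
  richness–trench contrast cleans up as λ grows — and 75 km sits at the
  crossover. At the 12-island problem size of the recovery experiments
  this leaves the replacement–distance partial test with modest power;
  expanding the archipelago (more pairs) is the honest remedy, not a
  heavier thumb on λ.

What the generator does **not** emulate: coalescent resampling within
haplotypes, recombination and selection (absent from mtDNA assumptions
anyway), mainland populations, real coastline geometry, and any coupling
of island area to diversity — areas are log-normal noise, so a green
area-related test only establishes the absence of spurious signal, never
calibration of a real area effect. Green recovery tests establish that
the pipeline detects the signals this world encodes at the stated rates;
they do not certify effect-size estimates on real archipelagos.

## Numerical conventions

* Determinism: a single seed in the run config drives every permutation
  and bootstrap stream; reruns reproduce all statistics exactly, and the
  simulation writer is byte-identical under a fixed seed.
* Tolerances: β additivity 1e-12; branch-length round-trips 1e-9; the
  lmg identity 1e-10.
* Ties: never broken randomly — ancestral ties are all reported, equally
  short network connections all retained, NJ tie handling is the
  deterministic behaviour of `ape`'s implementation.
* Degenerate inputs: empty alignments, zero-variance distance triangles,
  saturated K2P pairs, and sub-minimum island counts raise immediately
  with stage-tagged errors in the pipeline.

## Known limitations

* Interisland distance uses island reference coordinates (haversine);
  nearest-coast distances are not computable from the data model, and on
  real data the choice of reference points materially affects Mantel
  magnitudes.
* The connection-limit probability model is a reconstruction (see above);
  its values are validated for internal consistency and monotonicity, not
  against historical software output, and the `max_steps` override exists
  precisely so published limits can be imposed.
* The neighbour-sum outgroup weighting is a heuristic with a documented
  failure mode on chains; treat shallow-sampling ancestral calls as
  hypotheses, not estimates.
* No multiple-testing correction is applied across the nine cells of the
  barrier report, by design; add one downstream if the use case needs it.
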