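---
title: "somscape: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{somscape: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The data model

`somscape` works on presence/absence proteomics time courses. The raw unit
is a per-volunteer binary matrix: rows are protein accessions, columns are
integer week indices, and a cell is 1 when the protein was detected in that
volunteer's sample that week. The week axis is anchored at the intervention:
week 1 is the first isolation week, pre-isolation samples have indices
$\le 0$, and post-isolation samples have indices $> 15$. The bundled
`study_design()` carries the dietary schedule (12 g/day NaCl in weeks 1–5,
9 g/day in weeks 6–9, 12 g/day in week 10, 6 g/day in weeks 11–15) and the
reference phase partition used throughout: *early* (week $\le 6$, including
pre-isolation), *intermediate* (weeks 7–11), *late* (week $\ge 12$,
including post-isolation).

`build_mean_volunteer()` averages the binary detections over the volunteers
that actually have a sample at each week — missing samples reduce the
denominator, they are not imputed as absences — giving detection fractions
in $[0, 1]$ on the union of all sampled weeks. Proteins never seen by a
volunteer enter that volunteer as all-zero rows so that every downstream
stage shares one protein universe. `centralize()` subtracts each protein's
own time average, turning fractions into differential detection levels
$\Delta E$; centralization is idempotent and preserves row variances, and it
deliberately removes the absolute level: invariantly high and invariantly
low proteins become indistinguishable near-zero profiles. The
total-abundance analysis therefore trains a *separate* SOM on
non-centralized values.

## The SOM and its schedule

`train_som()` fits a batch self-organizing map: $K$ prototype profiles
("meta-features") on a `rows × cols` planar grid (default 40 × 40, so
$K = 1600$). Each sweep assigns every protein to its nearest prototype in
Euclidean distance and then replaces every prototype with the
Gaussian-neighborhood-weighted mean of the assigned profiles. Batch updates
make the fit independent of presentation order, so no learning-rate schedule
exists; determinism comes for free.

Parameters and defaults:

| parameter | default | meaning |
|---|---|---|
| `rows`, `cols` | 40, 40 | grid size; $K = 1600$ meta-features |
| `epochs` | 100 | batch sweeps |
| `radius_init` | 20 | initial Gaussian neighborhood radius (grid units) |
| `radius_final` | 1 | final radius, linear decay |
| `init` | `"pca"` | linear initialization on the first two principal axes |
| `seed` | 1 | used by `init = "random"` |

The linear 20 → 1 decay spends the first sweeps ordering the map globally
and the last sweeps sharpening local structure. We verified on planted data
that pushing the final radius well below 1 fragments spot masks into
sub-module pieces, while values near 1–1.5 keep each co-expression blob a
smooth plateau; 1 is the shipped default. PCA initialization is
deterministic (principal-axis signs are fixed by making the largest-loading
element positive, which also makes results invariant to protein/feature
ordering); random initialization draws prototypes around the data mean
rather than sampling data rows, so that the initial quantization error is a
genuine upper bound for the trained one. Nearest-node ties break toward the
lowest node index (row-major, 1-based).

## Spot modules

`select_percentile_spots()` implements the over/under-expression module
selection. In `averaged` mode the meta-feature values are averaged over all
states and the top and bottom `percentile` percent of nodes are taken
(default 2%, i.e. 32 of 1600 nodes per polarity); in the default `union`
mode the top/bottom masks are taken per sample and unioned, which collects
every spot that appears in any individual portrait. Nodes tying exactly with
the cutoff value are always included (determinism independent of sort
order). Spots are the connected components of the selected nodes under
8-neighborhood adjacency (diagonal contact merges, matching how adjacent
spots read on the rendered maps); components are found with `igraph` and are
checked in the tests against a hand-written flood fill. A node claimed by
both polarities in union mode is kept in the channel whose state-averaged
value has the matching sign. Spot letters are assigned in decreasing
node-count order.

This polarity-disjointness rule has a known consequence documented here
because the tests measure it: a wave-shaped module is genuinely extreme in
*both* channels (its maximum at phase $\varphi$, a full-amplitude minimum at
$\varphi + T/2$), and its state-averaged $\Delta E$ is near zero, so the
rule splits such a blob between the channels roughly at random and caps the
per-spot recovery (Jaccard against the planted membership) near 0.5. The
alternative — computing the channels independently — restores whole wave
blobs but lets the union masks percolate through the interpolating corridors
between blobs and merge distinct modules, which measured strictly worse on
planted data. Peak-shaped modules are unaffected. On the default synthetic
cohort, 7 of 10 planted modules are recovered at Jaccard > 0.5; the three
misses are the wave-shaped ones, for this reason. A green recovery test
therefore establishes that peaked modules are segmented essentially whole,
not that arbitrary wave forms are.

`select_correlation_spots()` (seeds = local maxima of node-profile variance;
nodes join a seed at Pearson $r \ge$ `threshold`, default 0.9) and
`select_kmeans_spots()` (seeded k-means on the prototypes, clusters split
into grid components) are the alternative segmentations; they produce larger,
less polar modules.

Each spot's profile is the mean of its member meta-feature profiles; the
phase estimate $\hat\varphi$ is its argmax week and maps onto the reference
phases via `classify_spot_phase()`.

## Trajectories

Sample states are the $K$-dimensional portraits, not raw protein vectors —
prototype averaging denoises the states and fixes their dimension.
`second_level_som()` trains a small SOM (default 10 × 10, radius 5 → 0.5,
50 sweeps) over the states; a sample's coordinates are its best-matching
node, so identical states share coordinates exactly. `ica_projection()`
whitens the states by SVD and runs a symmetric fixed-point ICA (tanh
contrast, tolerance $10^{-6}$, max 200 iterations, error on
non-convergence) with the sign convention that each component's first
nonzero value is positive.

`segment_trajectory()` clusters the 2D coordinates with seeded k-means and
labels clusters by ascending median sample week. With `k = 3` the labels are
early/intermediate/late directly. The observed trajectory actually has
*four* windows — the pre-isolation samples cluster separately from the
early-isolation ones — so with `k = 4` the default `aggregate_early = TRUE`
merges the two earliest clusters into one early phase before comparison.
Agreement with the reference partition is reported as an adjusted Rand
index; on the default synthetic cohort the second-level SOM trajectory with
`k = 4` reaches ARI 0.90.

## wTO and the beta test

`wto_scores()` builds signed channels from Pearson correlations between
node profiles: $a_{ij} = \max(r_{ij}, 0)$ (positive channel) or
$\max(-r_{ij}, 0)$ (negative channel), zero diagonal, and scores

$$\omega_{ij} = \frac{\sum_u a_{iu} a_{uj} + a_{ij}}
                     {\min(k_i, k_j) + 1 - a_{ij}}, \qquad
  k_i = \sum_u a_{iu},$$

the standard weighted topological overlap, which credits associations
mediated by every third node of the map. Zero-variance profiles have all
correlations defined as 0. Spot-pair scores are means over cross-spot node
pairs.

The beta statistic of a spot with meta-feature profiles $x_1 \dots x_m$ and
mean module profile $\bar c$ is

$$\beta = \frac{\left(\sum_i r(\bar c, x_i)\right)^2}
               {\sum_i \sum_j r(x_i, x_j)}$$

with the double sum over ordered pairs including $i = j$, so a perfectly
coherent module (and any singleton) has $\beta = 1$ exactly. $\bar c$ is the
mean of the *raw* $\Delta E$ profiles: member amplitudes weight the
centroid, which is what makes the statistic discriminative — with a
standardized centroid the expression degenerates to 1 identically for
row-centered profiles. Consequently $\beta$ is invariant to a common affine
rescaling of the module but not to rescaling a single member. Significance
comes from a seeded permutation null (default 1000 random same-size node
sets drawn from the whole map; p uniform under a planted null by
construction, verified by a KS test in the suite), with
Benjamini–Hochberg adjustment across spots. The optional `analytic` method
moment-matches a Beta distribution to the permutation sample — the shipped
default stays the permutation p.

## Enrichment

The universe for all enrichment is the set of proteins input to the SOM.
`fisher_enrichment()` is the hypergeometric upper tail of the observed
spot–set overlap (verified against exhaustive enumeration on small
universes). `gsz_score()` scores each universe protein with its $\Delta E$
at the spot's peak week (0 outside the spot), sums the scores over the set,
and standardizes against the sampling-without-replacement null of a random
same-size set, with a variance regularizer $\lambda = 0.1$ guarding tiny
sets; it is monotone both in overlap and in the members' over-expression.
Gene-symbol sets are translated onto the accession universe through an
optional static two-column mapping table; unmapped proteins stay in the
universe but in no set. `tissue_density_map()` smooths per-node member
counts with a mass-preserving Gaussian grid kernel (default bandwidth 2
grid units) and reports the connected regions above the 90th density
percentile.

## Pathway signal flow

`parse_kgml()` reads a KGML subset: entries become nodes carrying accession
lists; relation subtypes activation/expression map to activation,
inhibition/repression to inhibition, and all others are dropped and counted.
Cycles are broken by removing the back edges of a depth-first search in
deterministic node order. A node's fold change is the arithmetic mean of its
measured members' fold changes, neutral (1) when nothing was measured; fold
changes at time $t$ are $(a_t + \varepsilon) / (\bar a + \varepsilon)$ with
pseudocount $\varepsilon = 0.01$ because binary-derived abundances are often
zero. Propagation walks a topological order: a source's signal is its fold
change; elsewhere each parent's signal is multiplied (activation) or divided
(inhibition) by the node's fold change and the incoming contributions are
*averaged*. The average rather than the plain sum is deliberate: it keeps
all-neutral pathways at signal 1 on any DAG (a plain sum would double the
signal at every convergence) while leaving linear chains with the closed
form $\prod \mathrm{FC}^{\pm 1}$, and both properties are oracle-tested.
Sink profiles over time are matched to spot profiles by Pearson correlation.

## The synthetic cohort

`cohort_design()` emulates the statistical structure of a six-volunteer,
23-week (−4 … 18) isolation cohort with ~2000 proteins: ten planted
co-expression modules of 95 proteins (47.5% of the universe), 350
invariant-high (Bernoulli 0.95), 400 invariant-low (Bernoulli 0.02), and
300 single-spiked proteins (exactly one detection at one random
volunteer-week) — 52.5% of proteins outside modules, matching the roughly
half-and-half split between responsive and invariant/noisy proteins such
cohorts show. Module detection probabilities follow
`wave_probability()`: cosine waves
$b + a\,(1 + \cos 2\pi (t - \varphi)/T)/2$ or Gaussian peaks
$b + a \exp(-(t-\varphi)^2 / 2w^2)$, clipped to $[0,1]$, with baseline
$b = 0.1$ and amplitude $a = 0.8$. Detection noise is a symmetric bit flip
with probability 0.05 (a plausible detection-error rate for
threshold-crossing MS presence calls), applied on top of the Bernoulli
draw; each volunteer-week is dropped entirely with probability 0.05 to
emulate missed sampling.

The default module set staggers phases across the reference ranges (early
1–4, intermediate 7–9, late 12–14) with periods in $\{T^*/2, T^*, 2T^*\}$
($T^* = 15$ weeks, the isolation span). Two design rules fix the shapes:
every module with period $\ge T^*$ has a single in-window maximum and
minimum (a full-height second maximum inside the window would make late
states clone early states, which the data this generator emulates do not
do — they recover only partially); and shapes/widths are assigned to
minimize the largest positive pairwise correlation between the planted
$\Delta E$ profiles (0.71 for the default set), so that no two modules are
confounded. One short-period module (M04, $T^*/2$) deliberately recurs.

What the generator does *not* emulate: protein-specific detection
efficiencies and abundance-dependent dropout, inter-volunteer systematic
differences (all volunteers share the same wave parameters), correlated
noise between proteins outside the planted modules, and any dependence of
detection on the dietary schedule beyond the planted phases. Green tests on
this cohort therefore establish that the pipeline recovers planted
structure of realistic size and noise — not that it models individual
physiology.

## Degenerate inputs and tie-breaks

Zero-variance profiles correlate 0 with everything (wTO, beta, matching);
ICA errors on inputs with fewer variance directions than components;
`detect_peaks()` requires strict local maxima and thins them greedily,
largest first, to the requested minimal spacing; duplicate protein
accessions and non-binary cells are rejected at parse time with the
offending row/column named; percentile-cutoff ties are included; k-means
stages are seeded, with a single global seed fanned out to stage seeds by a
stable string hash.

## Known limitations

- The percentile-union segmentation caps wave-module recovery near Jaccard
  0.5 (see the spot-module section); use the correlation or k-means
  segmentation when whole wave modules matter more than polarity.
- The analytic beta p-value is calibrated against its own permutation
  sample, not derived in closed form.
- The GSZ weighting is one member of a family (sum-of-scores z-score with
  SRSWOR moments); other published variants weight the hypergeometric and
  expression parts differently.
- KGML support covers gene/protein entries and signed relations only — no
  compounds, group nodes, or nested maps.
- Second-level SOM coordinates are grid-quantized; for fewer than ~10
  samples the ICA projection is the more informative trajectory.
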