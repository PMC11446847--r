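---
title: "Methods: from synapse tables to predicted ER receptive fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from synapse tables to predicted ER receptive fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

The anterior visual pathway (AVP) of *Drosophila* carries visual
information from the medulla of the optic lobe to the heading-direction
system of the central complex through three relays: MeTu projection
neurons (medulla to the small unit of the anterior optic tubercle,
AOTUsu), TuBu neurons (AOTUsu to bulb), and ER ("ring") neurons (bulb
to ellipsoid body). Given a synapse-level reconstruction — a table of
pre/post neuron pairs with 3-D contact positions and automatic
cleft-detection confidence scores, plus neuron annotations — this
package rebuilds the quantitative analyses of that pathway:
region-restricted synaptic weight matrices, MeTu subtype
classification from connectivity, dendritic-span morphometrics with
axial circular statistics, a medulla-column/eye coordinate system, and
per-column "receptive field" predictions for every ER neuron obtained
by back-tracing synaptic weights through the pathway.

Because real EM reconstructions are large, hand-curated and not
redistributable, the package ships a synthetic-connectome generator
with planted ground truth (`generate_connectome()`). Every stage of
the pipeline is validated end to end against what was planted.

# Pipeline stages and their models

## Filtering and weight matrices

`filter_synapses()` keeps contacts with cleft score at or above the
threshold (default 50) and removes autapses and contacts with the
background segmentation (sentinel id `"0"`; background rows are kept
at read time so raw counts stay auditable, and removed only here).

`neuron_weight_matrix()` counts synapses inside a region hull and
divides each pre–post count by the postsynaptic neuron's total number
of synapses in that region, giving fractional input weights in
$[0,1]$; with the complete pre set a post's column sums to exactly 1.
Posts with fewer than five total regional synapses are dropped — a
stability rule, since a weight computed over three or four contacts is
mostly noise. The phrase "total number of synapses in the region" is
ambiguous between input-only and input-plus-output; we default to
input-only (the quantity is then an input fraction) and expose
`denominator_side = "input_output"` for the other reading.
`type_weight_matrix()` aggregates whole cell types before
normalizing, which is not the average of individual weights — the two
are linked by the identity (checked in the tests) that the type weight
equals the denominator-weighted aggregation of the individual matrix.

Region membership is a convex-hull half-space test. Hull facets are
enumerated once per region by brute force over vertex triplets (a
triplet is a facet when all remaining vertices fall on one side of its
plane), then points are tested against all facet inequalities at once.
An optional `subtract` hull carves out an overlapping neighbour, as
needed when a medulla vertex cloud overhangs the lobula.

## Column geometry, layers, eye map

Each medulla column is anchored by one columnar neuron (Mi1). The
column axis is the first principal component of all its synaptic
sites, with the sign oriented towards a caller-supplied proximal
reference point (PCA sign is otherwise arbitrary); the column's depth
bounds are the 0.03/0.97 quantiles of site projections, computed with
linear interpolation between order statistics (the convention is not
fixed by the source material, so we state ours). A leading/second
eigenvalue ratio below 1.2 yields a warning — the axis of a nearly
isotropic cloud is not meaningful. Depths are expressed as percent of
the column span and looked up in the fixed M1–M10 layer table; the
intervals are half-open with the terminal edge closed, a choice we
made because the printed bounds touch without stating edge ownership.

Equatorial columns are those with seven or eight photoreceptors
(versus six elsewhere). `align_hex_grids()` maps columns to ommatidia
by searching integer axial-lattice offsets — constrained so the two
equator rows coincide, which collapses the search to essentially one
dimension — plus the two mirror orientations, minimizing the number of
unmatched points. Whether mirror flips should be allowed is not
documented for the original procedure; we search both and report which
orientation won. Ties break by offset magnitude, then
lexicographically, then unmirrored first, so the result is
deterministic.

## MeTu classification

`build_feature_vectors()` concatenates an upstream block (the
neuron's fractional input weight from each selected medulla input
type) and a downstream block (its fractional output to each AOTU
target type: ten TuBu types, the bilateral TuTu pair, AOTU046). The
"top five inputs per subtype, union across subtypes" selection is
implemented literally when provisional labels are supplied; without
them each neuron ranks its own inputs, which never drops a type that
matters to some channel.

`cluster_subtypes()` offers a seeded 2-D UMAP embedding with
model-based grouping, and an agglomerative dendrogram. The dendrogram
default is **euclidean** distance with average linkage: the features
are already normalized fractions, and correlation distance — the more
common choice for expression-style profiles — discards exactly the
magnitude contrasts that separate two channels projecting to the same
target type. Correlation distance remains available.

One genuine subtlety: a channel can comprise subpopulations that
differ **only** in their downstream target (dorsally versus ventrally
projecting neurons of the 2-D tiling channel). A tree cut at the
nominal number of subtypes then splits that channel and merges the two
most-similar true subtypes instead. The `merge_within = "in:"` option
resolves this the way the original analysis did — by medulla
connectivity: the tree is cut progressively deeper and clusters whose
upstream-block centroids are closer than the typical within-cluster
spread are merged until the requested number of groups remains; a cut
containing a cluster whose upstream spread is far above the typical
spread (the signature of two profiles cut together) is rejected.

`rule_subtype()` encodes the explicit printed rules: class from the
AOTUsu subregion of the axonal boutons; MeTu3a at ≤ 13 Mi15 synapses;
MeTu4d at < 15 lobula synapses; the remaining subtypes by dominant or
preferred TuBu partner. These thresholds are boundary-tested on both
sides in the suite.

## Morphometrics

`fit_span_ellipse()` is the maximum-likelihood 2-D Gaussian fit
(mean and covariance, optionally weighted); the span ellipse is the
1-sigma contour by default (`k_sigma` exposed — the contour level used
for display is a convention, not physics). The angle is measured from
the dorsal–ventral (vertical) axis of the projection plane, mapped to
[0°, 180°); the fit is rotation equivariant, which the suite checks
with random rotations. `rayleigh_axial()` doubles orientation angles
to remove the axial ambiguity and uses
$z = n \bar R^2,\; p = e^{-z}\bigl(1 + (2z - z^2)/(4n)\bigr)$
clamped to (0, 1]; its type-I error at $\alpha = 0.05$ is calibrated
by simulation to 0.05 ± 0.01 and its power is monotone in von Mises
concentration. `annulus_density()` uses equal-area annuli
($r_k = \sqrt{kA/\pi}$, default $A = 314.15\,\mu m^2$), and
`retinotopy()` reports the Spearman rank correlation between medulla
anterior–posterior and target dorsal–ventral positions.

## ER field back-tracing

A MeTu neuron's column occupancy is the fraction of its qualifying
synaptic sites nearest (perpendicular distance) to each column axis.
The published definition reads "fraction of presynaptic sites closed
to the column", which we read as "closest"; presynaptic sites are the
literal reading and the default of `column_occupancy()`, while
`analyze_connectome()` uses the dendritic (postsynaptic) switch, which
is the anatomically sensible quantity for a dendritic footprint — both
are exposed. The direct pathway value of column $c$ for one ER neuron
is

$$D(c) = \sum_b \sum_m w(b \to ER)\, w(m \to b)\, occ(m, c)$$

over TuBu neurons $b$ and MeTu neurons $m$; the indirect pathway
inserts the bilateral TuTu neurons. The AOTU046-mediated route is
excluded (its transmitter is unresolved) via the `exclude` argument.
Because occupancies sum to one, $\sum_c D(c)$ equals the total
TuBu-weighted MeTu inflow — a conservation identity the tests enforce
at $10^{-9}$. Direct and indirect values are reported separately and
never summed: they are putatively opposite in sign.

A column is "covered" when its direct value exceeds `eps`, default
exactly 0 — no threshold is documented for the original count, so any
positive weight covers. Outlines are boundaries of unions of hexagonal
eye-coordinate cells, computed combinatorially (edges shared by two
covered cells cancel; surviving edges stitch into loops), with the
cell size taken from the nearest-neighbour angular spacing of the eye
map. This is exact for lattice hexagons and needs no geometry library.

## Imaging analysis

`dff_from_raw()` subtracts an empty-control ROI frame by frame and
normalizes by $F_0$, the mean of the lowest decile of the subtracted
series. `stimulus_response()` computes per-trial responses as mean
dF/F in the 1-s stimulation window **minus** the 500-ms pre-stimulus
baseline; the source description literally says the subtraction the
other way around, but the recorded responses are positive, so we use
stimulus-minus-baseline and note the discrepancy here. Responsiveness
requires a one-sample Wilcoxon signed-rank p ≤ 0.05 across trials
*and* a mean response above the empty-control response. The standard
stimulus layout is 38 non-overlapping 18° tiles (a 7 × 6 grid minus
corners). `rf_ellipse()` interpolates mean responses bilinearly onto a
fine raster (zero-padded by one tile so contours close), extracts the
iso-contour at 20 % of maximum and fits the enclosed region with the
second-moment method (semi-axes $2\sqrt{\lambda_i}$, exact for a
filled ellipse). With 18° tiles, planted contours whose minor axis
approaches the tile size are recovered with a discretization bias of
order 5–10 %; the tests quantify this.

# The synthetic connectome

`generate_connectome()` plants, under one seed, everything the
pipeline is supposed to recover. Default study conditions: a 15 × 15
column lattice (225 columns, pitch 5,000 nm — the order of magnitude
of medulla column spacing), laid out as a rectangular hex patch so
anterior–posterior bins are vertical stripes at every elevation; ten
MeTu-like channels of 50 neurons each (the real MeTu population is a
few hundred per hemisphere); 80 dendritic and 30 axonal synapses per
neuron; Mi1-like anchors with 40 sites per column; one equator row
with 7–8 photoreceptor counts versus 6 elsewhere.

Channel structure mirrors the biology at the level the pipeline can
test: each subtype has an AOTUsu subregion, a Dirichlet input
fingerprint over 28 medulla input types (concentration 60 by default;
the separation is configurable because it is precisely the dial that
makes classification easy or hard), a dendritic centre band
(dorsal-third, equatorial, ventral-half, …), and downstream TuBu
types with per-synapse probabilities. The vertical channel
(MeTu1-like) has planted span ellipses of ratio 2.0 oriented
vertically (5° angular jitter) and is wired to its TuBu type by
anterior–posterior bin only — the planted strictly monotone
retinotopic map sends medulla AP position to AOTU DV position — so
downstream fields pool all elevations at one azimuth band. The 2-D
tiling channel (MeTu3c-like) instead splits dorsal/ventral between
two TuBu types whose bins are proportionally wider, keeping per-TuBu
convergence comparable; its downstream fields are compact 2-D tiles.
Each TuBu fans out to `divergence` ER neurons, so every ER inherits
one TuBu's field. The MeTu4-like channels receive lobula synapses
(about 30 per neuron, versus about 5 for the MeTu4d-like subtype,
straddling the 15-synapse rule). Noise contacts are injected last: a
5 % admixture of sub-threshold cleft scores, 30 background contacts,
10 autapses.

What the generator deliberately does **not** emulate: realistic
neurite morphology (synapse clouds are Gaussian, not skeletons),
hemispheric asymmetries, proofreading artefacts, type-count
heterogeneity across ER types, and the full 28-type input circuitry —
input "neurons" are small per-type pools. Passing tests therefore
certify the *analysis machinery* (filters, normalizations, geometry,
estimators, back-tracing) on data with known truth; they do not
certify biological conclusions about any real connectome.

# Numerical choices

* Hull facet tolerance is scale-relative (10⁻⁹ of the vertex extent);
  boundary points count as inside.
* Quantiles everywhere are type-7 (linear interpolation).
* Gaussian density-map smoothing uses a kernel truncated at 4σ and
  renormalized, on a grid padded by 4σ, so total mass is conserved to
  numerical precision; boundary handling beyond the pad is zero.
* Nearest-column ties resolve to the lexicographically smaller column
  id; hex-alignment ties by offset magnitude, then lexicographic
  offset, then unmirrored.
* The Wilcoxon responsiveness test uses the exact small-sample
  distribution automatically below the usual asymptotic regime.
* All stochastic stages take explicit integer seeds; identical seeds
  give byte-identical outputs.

# Problem sizes used by the test suite

The reference conditions above (225 columns, 500 MeTu-like neurons,
~77,000 synapses) run the full pipeline in a few seconds. Statistical
calibrations use 10,000 uniform simulations at n = 100 (Rayleigh
type-I error), 100 random three-layer fixtures (back-tracing oracle),
100 alignment trials with 5 % deletions (hex offsets), and 25
replicate draws of 300 points (span recovery); these sizes make the
Monte-Carlo error comfortably smaller than the tolerances they are
checked against.

# Known limitations

* The connectivity-aware cluster merging assumes the within-subtype
  feature spread is comparable across subtypes; strongly heteroskedastic
  profiles could defeat the purity heuristic.
* `rf_ellipse()` inherits an irreducible discretization bias from the
  18° stimulus tiling; receptive fields smaller than one tile are not
  resolvable.
* Hexagonal outlines assume the eye map is locally lattice-like; strong
  local distortions of ommatidial spacing would warp cell sizes.
* The upstream traversal reports two hops (matching the pathway depth
  it is compared against); deeper traversals would need cycle handling
  beyond the visited-set rule used here.

# Worked example

```{r, eval = FALSE}
library(avpconnect)

cn <- generate_connectome(synth_config(seed = 1))
res <- analyze_connectome(cn)

# classification against planted subtypes
mclust::adjustedRandIndex(res$clustering$labels,
                          cn$ground_truth$subtype[names(res$clustering$labels)])

# one ER neuron's predicted field
f <- res$fields[["ER4d_n01"]]
visual_area(f, res$eyemap)$n_covered
field_ellipse(f, res$eyemap)
```
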