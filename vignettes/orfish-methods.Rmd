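---
title: "Methods: combinatorial FISH decoding and spatial atlasing of the OR repertoire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combinatorial FISH decoding and spatial atlasing of the OR repertoire}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orfish)
```

## The problem

Mouse olfactory sensory neurons (OSNs) each express a single olfactory
receptor (OR) gene out of a family of roughly a thousand, and all OSNs
expressing one OR converge onto a small number of glomeruli in the
olfactory bulb (OB). Multiplexed error-robust FISH (MERFISH) makes it
possible to read out OR identity in situ at repertoire scale: each OR is
assigned a combinatorial barcode — a unique set of 4 readout bits out of
15 — and imaged over sequential hybridization rounds. `orfish` implements
the computational pipeline around this encoding: decoding OR identity of
somas in the main olfactory epithelium (MOE) and of glomeruli in the OB,
reconstructing serial sections into a 3D volume, quantifying the spatial
organization of the repertoire, transferring single-cell expression onto
the spatial maps, and cataloguing odor-evoked responses from the
immediate-early gene Egr1.

Everything is exercised end to end on synthetic data with known ground
truth, because the statistical structure of the signal — not any one
dataset — is what the pipeline's correctness rests on.

## Combinatorial encoding

A codebook assigns each receptor a distinct 4-of-15 bit set
(`build_codebook()`), enumerating all `choose(15, 4) = 1365`
constant-weight codes lexicographically, shuffling them with a seed, and
assigning them in input order. Constant-weight codes have even pairwise
Hamming distances of at least 2, which `validate_codebook()` verifies
together with uniqueness. Probe-level layout (`assemble_probe_records()`)
follows the split-probe design: each adjacent probe pair carries one bit
via a 15-nt 5' and a 15-nt 3' split readout flanking a 30–32-nt target
region, each bit repeated 4–10 times per transcript. Nucleotide sequences
are deliberately not generated — genome screening of target sequences is
outside this package's scope — so records carry layout metadata only.
The assignment permutation is a design freedom (the encoding only needs
uniqueness); seeding it makes every downstream artifact reproducible.

## Soma decoding in the MOE

A soma expressing one OR lights up in exactly its 4 on-bit channels, with
the shared anatomy of the soma inducing strong voxel-wise correlation
among those channels. `cube_correlation_map()` scans ~2.5 µm cubes
(stride half a cube, so somas are never split by a cube boundary) and
computes all 105 pairwise Pearson correlations per cube, then finds the
4-bit combination maximizing the mean of its 6 internal correlations by
exhaustive search over the 1365 quadruples. Two numerical choices matter:

* cubes in which a channel is (near-)constant have undefined correlation;
  these are flagged and treated as 0 rather than propagating NaN;
* quadruples are scored only for cubes whose *maximum* pairwise
  correlation exceeds a prefilter (0.3 by default). Since the mean of six
  correlations can never exceed their maximum, any prefilter at or below
  the candidate threshold (0.6) provably discards nothing the threshold
  would keep; it only bounds the exhaustive search.

Voxels of cubes whose best quadruple exceeds 0.6 become candidates
(`extract_candidate_voxels()`); where overlapping cubes disagree, a voxel
takes the quadruple of its best-scoring cube. Candidates are grouped per
quadruple and clustered into cells with DBSCAN
(`density_cluster_cells()`; radius 1.5 µm, at least 10 voxels — exposed
parameters, since the source procedure does not pin them down), and each
cluster's quadruple is matched against the codebook by exact lookup.
Per-cell Egr1 transcripts are counted as strict 3D local maxima above an
intensity threshold inside the cell's voxel set dilated by one voxel ring
(`count_egr1()`); the default threshold is a robust image-wide estimate
(median + 5 MAD) so it adapts to the channel's background.

## Molecule decoding and glomerulus identity in the OB

In the bulb, OR transcripts sit in axon terminals, so decoding is
molecule-level: `detect_spots()` finds strict 3D local maxima per readout
image with center-of-mass subvoxel refinement; `colocalize()` groups
spots co-localizing within 160 nm per axis (a box, following the per-axis
phrasing of the criterion) in at least 4 distinct bits, keeping exactly
the brightest 4 when more co-localize. Conflicts are resolved greedily by
descending seed-spot brightness, which is deterministic and matches the
intuition that the brightest detection anchors its molecule. A
brightness threshold separating molecules decoding to targeted vs
untargeted receptors is fitted as the 1-D split minimizing
misclassification (`fit_brightness_threshold()`).

Each segmented glomerulus (masks are an input; segmentation itself is an
external tool's job) is assigned its most-counted receptor iff the count
strictly exceeds 10 *and* strictly exceeds 10 times the highest count of
that receptor in any other glomerulus of the same hemi-section
(`assign_glomerulus_identity()`). Two interpretive choices are explicit:

* the enrichment denominator uses the *maximum* over other glomeruli
  (not the sum), and is floored at 1 transcript so a receptor seen
  nowhere else passes on count alone;
* the comparison unit is the hemi-section. Bilateral twin glomeruli of
  one receptor lie in the same coronal plane, so comparing across the
  whole section would make every bilateral pair defeat its own
  enrichment; treating hemi-bulbs as separate units (hemisphere derived
  from mask centroids, `glomerulus_centroids()`) matches the per-hemi-bulb
  framing of the identification counts.

`relaxed_consensus()` then rescues glomeruli with more than 5 (but not
more than 10) molecules when at least one other aligned bulb shows the
same receptor within 500 µm, labelling them `relaxed` and reporting
cross-bulb consensus positions.

## Serial-section alignment

Adjacent sections are aligned from the nuclear signal in three stages
(`rigid_align_pair()`): a coarse global angle grid (±10°, 0.5° steps)
with per-angle translation by Fourier cross-correlation, local refinement
at 0.05°, then ~100 µm subimages matched individually as features and a
rigid consensus re-fitted from the feature matches by least squares with
3×MAD outlier rejection. The interactive correction step of the original
workflow is replaced by this automated outlier rejection so the pipeline
runs headless. Remaining distortion is corrected by Gaussian-weighted
interpolation of the feature residuals (`residual_correction()`,
σ = 75 µm, about one glomerulus diameter). The kernel is truncated at 5σ:
within the feature field this changes nothing measurable, and it makes
the correction vanish far from any feature instead of extrapolating a
distant average. Chains of pairwise transforms compose into a stack
(`assemble_stack()`), with z the section index times the 16 µm section
thickness.

Bilateral comparison (`match_bilateral()`) reflects the right hemisphere
about the midline and registers it to the left by least squares over
matched receptor centroids (Kabsch); cross-animal maps register the same
way with reflection allowed (`align_maps_across_animals()`). The median
matched distance is the stereotypy statistic. With per-glomerulus
isotropic jitter σ the matched difference is normal with variance 2σ² per
axis, so the median distance concentrates at `sqrt(2)·σ` times the median
of a 3D chi distribution (≈ 2.18 σ) — the Monte-Carlo oracle the
acceptance suite checks against.

## Spatial organization statistics

The pairwise overlap between two OSN types in a section is the fraction
of cells with a neighbour of the other type within 200 µm, symmetrized as
`(#A near B + #B near A) / (|A| + |B|)` and averaged over sections where
both types occur (`overlap_matrix()`). Of the two readings of "fraction
of pairs of cells within a cutoff", the cells-with-neighbour form is
used: the fraction over the A×B product vanishes as cell numbers grow and
could not produce near-unit overlap between co-localized abundant types.

The central-peripheral index (`central_peripheral_index()`) embeds
receptors in 2D by classical multidimensional scaling of `1 − overlap`.
Receptor groups detached from the main overlap structure (connected
components of the graph joining pairs with overlap above 0.02) are
flagged as the "unusual zone" and excluded before embedding — these are
receptors confined to a patch rather than a ring, and forcing them onto
the ring trajectory would corrupt both. The 1D trajectory through the
main component is taken as geodesic distance along a k-nearest-neighbour
graph between its two farthest nodes, normalized to [0, 1]; this is the
principal-curve-by-graph-geodesics construction, deterministic by design
(a `seed` argument exists only for interface stability). Orientation is
canonicalized so the central end maps to 0, using a per-receptor radial
coordinate when supplied.

The basal-apical index is the mean over a receptor's cells of
`d_basal / (d_basal + d_apical)` between the two epithelial surfaces;
for synthetic slabs both surfaces are analytic planes so the depth is
exact. Bulb axis coordinates bin the dorsal-ventral position in 150 µm
bins (half-open on the left, so y = 300 µm falls in the bin centered at
225 µm) and take the anterior-posterior position as the mean z.

Genomic association clusters OR genes by single linkage at a 100 kb gap,
curves mean overlap against genomic distance, and compares the abundance
of receptors within 50 kb of an enhancer against the rest by rank-sum.
Phylogenetic association computes patristic distances from branch
lengths; a receptor set's sequence compactness is tested both by rank-sum
of within-set against remaining pairwise distances and by permutation
against size-matched random tip sets.

## Imputation

`impute_surface()` transfers type-averaged expression onto spatial
coordinates: every entity (cell or projection) inherits its receptor's
expression vector, surface values average all entities within a radius
(50 µm in the MOE, where the surface is the decoded cell cloud itself;
400 µm in the OB, where it is a 50 µm grid over the projection region),
and each gene divides by its 99th-percentile surface value, capped at 1.
The percentile uses the inverse-CDF (type 1) quantile so that after
scaling the 99th percentile of the normalized surface is exactly 1 —
interpolating quantile types would break this identity once values are
capped. Imputation is linear in expression before normalization, which
the tests exploit as an invariant.

Leave-one-out projection prediction (`loo_predict_projection()`) rebuilds
the surface without the evaluated receptor, finds the surface point (per
medial/lateral region) maximizing the Pearson correlation between the
imputed gene vector and the receptor's own profile, and measures the
distance to the true projection; permuting the receptor-to-expression
assignment gives the chance baseline. `embed_gene_patterns()` embeds
genes by `1 − r` of their spatial patterns and groups them with Leiden
clustering on a k-nearest-neighbour graph.

## Response catalogues

An OSN is active when it has strictly more than 5 Egr1 transcripts; a
receptor's response to a cue is the fraction of active cells, per animal,
averaged unweighted across animals (`response_fractions()`; fractions
with fewer than 10 pooled cells are undefined — at that support the
binomial standard error already reaches 0.16). Classes are strict:
strong above 0.5, partial above 0.1 (`classify_responses()`). Pairwise
cue sharing defaults to the row-conditional `|A∩B|/|A|` (the natural
reading of an asymmetric sharing matrix), switchable to Jaccard.
Concentration shifts are flagged against an empirical replicate band:
the 5th–95th percentile of replicate-pair differences in five
equal-count bins of the pair mean (`concentration_shift()`).
Mother-selective types require a response above 0.05 in mothers and more
than twice the virgin response. Differential expression between selected
and other OSN types uses a two-sided rank-sum test at raw p < 0.01 (with
a Benjamini–Hochberg column reported alongside), after an optional
female-cell filter on X/Y marker expression. `map_responses_to_atlas()`
weights cells and projections by their receptor's responding fraction and
bins projection densities along the bulb axes in 200 µm bins normalized
to unit area.

## The synthetic-data generators

`synthetic_config()` fixes the study conditions once:

* **Image-scale MOE section** (decoding): 400×400×5 voxels at
  0.5 µm lateral / 1 µm axial, 200 somas of radius 2.5 µm from a 50-OR
  panel, on-bit amplitude 20 over background 2 with noise SD 1. The four
  on-bit channels share one soma profile and log-normal voxel texture
  (SD 0.5) and differ by independent gains in [0.8, 1.2], giving the
  within-soma cross-channel correlation the decoder relies on. Somas keep
  8 µm minimum separation; placement failures raise an error rather than
  silently overlapping. Egr1 responders draw `6 + Poisson(3)` spots
  (always above the >5 threshold), non-responders `Poisson(0.3)`,
  matching the bimodal count histograms such screens show; spots are
  rendered as separated strict local maxima.
* **Atlas-scale MOE cells** (statistics): 46 ring receptors with ring
  radii evenly spaced over 450–1400 µm (SD 40 µm) plus 4 unusual-zone
  receptors confined to a central 100 µm patch — detached by more than
  the 200 µm overlap cutoff from the innermost ring, which is what makes
  the unusual zone identifiable at all. Depth offsets are uniform in
  [0.2, 0.8] of a 60 µm slab with SD 0.1. The epithelium is modelled as a
  slab (rings in-plane, depth along z) so both surfaces are analytic and
  the ground-truth depth is exact.
* **OB series**: 10 sections at 16 µm, 30-receptor panel, one medial and
  one lateral glomerulus (radius 40 µm) per hemisphere per receptor,
  mirrored about the midline with 30 µm jitter; medial and lateral pairs
  sit in different sections as in real bulbs. Thirty dominant molecules
  per glomerulus, background molecules of untargeted receptors at ~3×
  dimmer brightness, each molecule expanded into its 4 bit-spots with
  40 nm jitter.
* **Deformations**: rigid motions up to 8° and 20 px, sinusoidal
  displacement fields of 5 px amplitude and 1500 µm period. The period
  sits well above the 75 µm correction bandwidth; fields varying on the
  scale of the feature spacing are not recoverable by any local
  interpolation scheme, and the generator emulates sectioning
  distortions, which are smooth.

What the generators do *not* emulate — optical point-spread functions,
chromatic shifts, autofluorescence, segmentation errors in the input
masks, cell-density inhomogeneity of real turbinates — bounds what the
passing tests show: they validate the decoding and statistics under the
assumed signal structure, not robustness to instrument-specific
artifacts.

## Problem sizes and determinism

The test and acceptance runs use one 200-soma section for decoding, a
~9000-cell atlas for the spatial indices, 1000 receptors for the
stereotypy Monte-Carlo, and 40–60 receptor panels elsewhere; these sizes
put every planted effect several standard errors above its acceptance
threshold while keeping a full run in minutes on one CPU. Every stage is
seed-deterministic: generators restore the caller's RNG state, the
embedding and clustering steps are deterministic given their seed, and
the acceptance script derives all seeds from its single `--seed`
argument.

## Known limitations

* The cube scan assigns each voxel the quadruple of its best cube; cells
  of different receptors closer than a cube diagonal can still shed a few
  voxels to each other's quadruple (they then fail codebook lookup and
  reduce recall slightly rather than precision).
* The cp index is a 1D ordering: if real zones branched rather than
  nested, the single trajectory would average over branches; the detached
  unusual zone is handled, but partial detachment (weakly connected
  patches) follows the `min_overlap` connectivity threshold.
* `fit_brightness_threshold()` is a 0–1 loss split, not a density model;
  heavily imbalanced targeted/untargeted mixtures shift the optimum
  accordingly.
* Rank-sum p-values in the phylogenetic set test treat pairwise distances
  as exchangeable, ignoring their dependence through shared tips; the
  permutation test alongside does not have this defect and is preferred
  for inference.
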