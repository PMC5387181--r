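---
title: "Weighted connectome analysis of early brain development: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted connectome analysis of early brain development: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoconn)
```

## The problem

Structural brain networks of preterm and term neonates can be summarised as
weighted graphs: 91 parcellated grey-matter regions are the nodes, and each
pair of regions is joined by an edge whose streamline count and median
microstructure (FA, NDI, ODI from diffusion MRI) quantify the white-matter
connection between them. Two developmental questions drive the analysis:
how network organisation changes with post-menstrual age (PMA) at scan, and
how gestational age (GA) at birth — the degree of prematurity — alters the
weights of specific connections after maturation is accounted for.

The statistical obstacles are that raw network density differs strongly
between subjects (and itself falls with age), that total connection strength
differs even at matched density, and that a minority of subjects are scanned
twice. `neoconn` implements the full analysis chain that deals with each of
these, plus a synthetic cohort generator so the chain can be validated
end-to-end without access to infant imaging data.

## Multi-weight raw networks

A scan is a `multiweight_connectome`: a symmetric 91×91 streamline-count
matrix and per-edge median FA, NDI and ODI (each in [0, 1], defined only on
edges with at least one streamline). ODI is stored as dispersion; analyses
use the coherence weight 1−ODI, computed when networks are built.

`build_network()` applies the raw-network rule — only edges with at least 5
streamlines are kept — and attaches one of five weights: `FS` (an edge's
streamline count divided by the total over all surviving unordered edges, so
FS weights sum to one), `FA`, `NDI`, `ODI_C` (1−ODI) or `BINARY`. The FS
denominator counts each unordered edge once; a double-index sum would only
rescale FS by 2, and every normalised-weight analysis is invariant to that
choice (this invariance is asserted in the tests). The filter is applied
before the denominator is computed, so FS weights describe the filtered
network that is actually analysed.

## Cost correction, normalisation and null models

Because raw density falls with age, topology is compared at matched density:
`cost_threshold()` keeps the `k = round(d·M)` edges with the highest
streamline counts (round-half-up, so the achieved density is within `1/M` of
the target symmetrically), for every density on the grid 0.05–0.50 in steps
of 0.01 (`density_grid()`; 46 levels). The upper bound reflects the sparsest
raw network the analysis admits. Ranking is always by streamline counts
regardless of the weight carried; ties in counts are broken by higher NDI and
then lexicographically by node pair, a deterministic rule of this package's
choosing (not dictated by the method itself), which also makes the retained
edge sets nested across densities. `cost_integrate()` summarises any
per-density metric by its arithmetic mean over the grid.

At each density, `normalize_weights()` divides the retained weights by their
sum, removing total-strength differences so that only the *distribution* of
weights over the topology — relative FS/FA/NDI/(1−ODI) — is compared.

Graph measures follow the standard brain-connectivity-toolbox formulations:
density, total strength, median connectivity, global efficiency (mean inverse
geodesic distance over ordered pairs, `1/∞ = 0`), local efficiency (mean over
nodes of the global efficiency of the neighbourhood subgraph; degree-<2 nodes
contribute 0), characteristic path length (mean over *connected* ordered
pairs — disconnection is captured by global efficiency instead, keeping the
value finite on sparse thresholded graphs), clustering (binary triangle
ratio, or the Onnela geometric-mean form with weights rescaled by the
maximum for weighted graphs) and edge betweenness. Edge length is the
inverse of the weight; the map is isolated in one internal function so a
−log(w) alternative remains pluggable. Shortest paths, betweenness and
degree-preserving rewiring are delegated to igraph; the test suite checks
every metric against independent brute-force implementations (Floyd–Warshall
distances, exhaustive geodesic enumeration) to 1e−9 on hundreds of random
small graphs.

`random_equivalent()` produces degree-preserving randomised networks by
double-edge swaps and permutes the original weight multiset onto the rewired
topology: node count, degree sequence and the weight distribution are
preserved exactly, nodal strengths only approximately — an explicit,
documented limitation, since degree-and-strength-preserving nulls are a
different (and harder) construction. `small_world()` reports the normalised
path length α, normalised clustering γ and the small-world coefficient σ.
The conventional coefficient is γ/α and is the default; the reciprocal α/γ
form, which some reports print, is available via `sigma_form =
"alpha_over_gamma"`. We default to the conventional form rather than
guessing which was intended where the two appear interchanged. The null
ensemble size defaults to 100 with explicit seed control.

## Core and local connections

`identify_core()` ranks edges by betweenness centrality and takes the
minimal prefix accounting for 50% (configurable) of total betweenness as the
*core*; the rest are *local* connections. Edges tied with the boundary edge
are all included and the achieved share is reported — excluding an arbitrary
subset of indistinguishable edges would make the partition depend on
storage order. If every betweenness value is zero the partition degenerates
to the tie rule alone and is flagged (`all_zero`). Betweenness is computed
by default with inverse-streamline-count lengths, consistent with
count-based thresholding; weight-based and unit-length variants are
available because the choice is not uniquely determined by the method
description. `core_local_sweep()` cost-integrates the median core and local
weight (absolute or normalised) over the density grid.

## Minimum grid and edge-wise statistics

`subject_mask()` keeps each scan's strongest 30% of connections by
streamline count; `minimum_grid()` intersects the masks over *scans* (when a
subject is scanned twice both scans contribute; intersecting over subjects'
first scans is the obvious alternative and changes little because masks are
highly overlapping). Edge-wise association is restricted to this common
backbone.

`edgewise_association()` computes, per grid edge, a partial Spearman
correlation between the edge weight and either GA at birth or age at MRI.
Covariate control uses a linear mixed-effects model: sex (F = 0, M = 1),
SGA, respiratory support, NEC and the *other* age variable as fixed effects,
with a subject random intercept for repeated scans, fit by REML (lme4).
"Partial Spearman controlled via LME" is realised as double residualisation:
both the predictor and the edge weight are replaced by their marginal
residuals `y − Xβ̂`, then rank-correlated; single residualisation (weight
only) is available behind `method = "single"`. When every subject has one
scan the model reduces exactly to ordinary least squares, and the
implementation switches to a vectorised OLS path (tested to agree with the
per-edge route). P-values use the t approximation with `n − 2 − k` degrees
of freedom, where `k` is the number of covariate columns consumed by
residualisation; a seeded permutation option exists. BH-FDR at q = 0.05 is
applied across exactly the grid's edges for one predictor and one weight
kind — no correction across weight kinds, mirroring per-analysis families.
Relative (normalised) weights for edge-wise analysis are taken at the mask's
own density, 0.3, since no other density is implied by the construction.

Numerical details: constant covariate columns (e.g. no NEC cases in a small
cohort) are dropped before fitting since they duplicate the intercept;
genuinely collinear columns raise an error naming them. Mixed-model fits use
bobyqa with a Nelder–Mead fallback, and the per-edge fast path reuses the
fitted model structure via `refit()`, falling back to a fresh guarded fit if
that fails. Fits require at least 3 more scans than fixed-effect parameters.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure of a preterm/term
neonatal cohort — it is the test bed for the pipeline, not a model of
diffusion physics. Defaults encode the study conditions: 65 subjects with 8
scanned twice (73 scans), GA at birth uniform on 24.3–41.1 weeks (median
near 33), scans between 25 and 46 weeks PMA, and covariate frequencies
matching the cohort's clinical table (41/65 male, 19/65 SGA, 22/65
respiratory support, 7/65 NEC, 18/65 twins), with respiratory support more
frequent at low GA so covariate adjustment is non-vacuous.

The latent edge model has three layers:

* **Presence.** A fixed backbone (the strongest ~56% of edges, always
  present with counts ≥ 5) guarantees raw density above 0.5 — the sweep's
  feasibility precondition — and a non-empty minimum grid. Non-backbone
  edges appear with a logistic probability that declines with PMA; its
  intercept and slope are solved from the target density range [0.56, 0.88]
  at the PMA bounds, and a scan-level logit intercept (sd 1.0) keeps the
  density–age relation realistically noisy rather than deterministic.
  Backbone counts decline log-linearly (expected counts 250 down to 8)
  across a seeded random edge order, so count-based thresholds track the
  latent ordering; non-backbone counts are a shifted negative binomial whose
  support includes values below 5, so the streamline filter does real work.
* **Microstructure.** Edge FA and NDI rise (0.008 and 0.010 per week) and
  coherence 1−ODI falls (0.007 per week) with PMA, around edge-specific
  baselines, with independent edge noise (sd 0.03) and shared scan-level
  intercepts (sd 0.035/0.040/0.025). These slopes and noise scales were
  chosen once so that cohort-level Spearman correlations land in the rough
  0.65–0.85 band reported for neonatal cohorts of this kind, with the
  correct signs; they are not fit to any exact value.
* **Prematurity.** NDI on *local* edges (everything outside the designated
  core, the strongest `round(0.1·M)` backbone edges) additionally rises by
  0.008 per week of GA at birth; core edges carry no GA effect. This yields
  the dissociation the downstream analysis should recover: absolute NDI–GA
  effects in local connections only, and (through normalisation) relative
  NDI of the core moving opposite to the local connections.

`latent_design()` exposes the ground truth (core/local flags, GA-effect
flags, expected counts) and is the oracle for the recovery tests. All
randomness flows from one integer seed; identical configs give identical
cohorts. `simulate_edgewise_calibration()` is a targeted companion —
single-scan subjects, a fixed grid with a known split of signal and null
edges — used to estimate the empirical false-discovery proportion of the
edge-wise procedure.

What the generator does *not* emulate: spatial structure (no geometry or
hemispheric symmetry), streamline-level processing, non-linear maturation
curves, heteroscedastic age effects, or region-specific effect topography.
Passing recovery tests therefore demonstrate that the statistical chain is
correct and calibrated under the assumed data-generating model, not that the
biological conclusions of any particular cohort are reproduced.

## Problem sizes in the test-suite and acceptance runs

Module tests run on small parcellations (10–40 nodes) and cohorts of 1–12
subjects; metric oracles use 200 random graphs of at most 7 nodes, where
exhaustive path enumeration is cheap. The end-to-end recovery checks use
the full default cohort (73 scans, 91 nodes): 100 replicate cohorts for the
cohort-level sign checks, three replicates for the edge-wise power/FDP
check, and a 5-level density grid (step 0.1) for the core/local
cost-integration sign check — a sweep resolution chosen as sufficient for a
sign, with the full 46-level grid exercised where per-density values
themselves are under test. FDR calibration uses 200 replicate
calibration cohorts of 65 scans with 100 signal and 400 null edges.

## Known limitations

* Strength sequences of random equivalents are preserved only in
  distribution, not per node.
* `identify_core()` on graphs whose betweenness is entirely tied (e.g.
  complete graphs) returns the whole edge set rather than an arbitrary half.
* The t-approximation for partial Spearman p-values is asymptotic; for very
  small cohorts use the permutation option.
* Reading the long CSV dialect infers the node count from the largest edge
  index, so a trailing block of completely isolated nodes would be dropped;
  the cohorts this package targets are far denser than that.
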