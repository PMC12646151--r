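---
title: "Neighbourhood-based centrality and outcome classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neighbourhood-based centrality and outcome classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egotopo)
```

## Model and pipeline

`egotopo` analyses weighted, symmetric, zero-diagonal functional
connectivity matrices — one per patient and frequency band, with entries in
[0, 1] such as the phase-lag index (PLI) produces — and asks whether the
resected brain regions of epilepsy-surgery patients, or their network
neighbours, occupy a hub-like position, and whether that distinguishes
seizure-free (SF) from not-seizure-free (NSF) patients.

### Backbone

All topology is computed on a binarized backbone. The disparity filter
normalizes each edge by its endpoint's total strength,
`p_ij = w_ij / s_i`, and keeps the edge when the probability of a share
that large under a uniform split of `s_i` over the node's `k_i` edges,
`alpha_ij = (1 - p_ij)^(k_i - 1)`, falls below `alpha` (default 0.1) *from
at least one endpoint* (OR rule, strict inequality). Endpoints of weighted
degree 1 cannot assess their single edge; an edge between two such nodes is
dropped. These two conventions are not forced by the construction — an AND
rule and an always-keep rule for degree-1 edges are coherent alternatives —
but the OR rule follows the original backbone formulation and the degree-1
rule is the conservative choice; both are localized in `disparity_filter()`
if a user needs to change them. Because only weight *shares* enter, the
filter is invariant under global rescaling of the weights.

### Generalized centrality

Eight metrics describe each node `i` of the backbone:

* clustering coefficient `CC_i = 2 t_i / (k_i (k_i - 1))` (0 when
  `k_i < 2`, where the triad fraction is undefined);
* betweenness centrality `BC_i`, the fraction of shortest paths through
  `i`, normalized by `(N-1)(N-2)/2`; all tied shortest paths count equally
  (Brandes accumulation, via igraph); paths are computed on the binary
  graph since everything downstream of the filter is binary;
* clique-count curvature `C_i = sum_{m=1..3} (-1)^(m+1) Cl_im
  = 1 - k_i + t_i`, where `Cl_im` counts the m-cliques containing `i`;
  strongly negative values mark hubs, so this metric's *orientation* is
  inverted in all hypothesis tests;
* five descriptors of the extended neighbourhood `EN_i^d`: the subgraph
  induced by nodes at hop distance 1..d from `i`, excluding `i` and its
  incident edges. We record its size `N`, edge count `E`, and the Betti
  numbers `b0` (connected components), `b1` (independent cycles not filled
  by triangles) and `b2` (cavities not filled by tetrahedra) of its clique
  complex.

At `d = 1`, `N` equals the degree and
`CC_i = 2E / (N(N-1))` — identities the test suite asserts exactly on
random graphs, tying the neighbourhood module to the classical metrics.

### Homology

The clique complex stores all cliques up to size `dim_cap + 1`
(default `dim_cap = 3`, i.e. tetrahedra, the minimum for `b2` to be fully
defined; larger cliques carry no information for `b0..b2`). Betti numbers
are computed over the field with two elements as
`b_k = dim ker(boundary_k) - rank(boundary_{k+1})`, with ranks from Gaussian
elimination on the mod-2 boundary matrices. Mod-2 homology is standard for
flag complexes at this scale and gives an exactly verifiable integer
contract: the tests compare against an independently written brute-force
oracle on hundreds of random graphs and check the Euler–Poincaré identity
`n0 - n1 + n2 = b0 - b1 + b2` on every tetrahedron-free instance. An empty
neighbourhood (isolated node) returns all five metrics as 0, including
`b0 = 0`, so isolated nodes stay comparable rather than erroring.

The neighbourhood radius `d` is a required, logged parameter (default 2,
the scale at which neighbourhood structure first departs from the classical
clustering coefficient); results should always be reported together with
the radius used.

### Node sets and hypothesis tests

Per band — adjacency differs across bands, so the partition is recomputed —
nodes split into `RA` (resected), `N` (non-resected nodes adjacent to at
least one RA node) and `O` (the rest); `RAbar = N + O`. Four ordered
comparisons are tested, each under the hypothesis that the first set is
more central: `RA > RAbar`, `RA > N`, `RA > O`, `N > O`.

Distributional differences are assessed by a bootstrap z-test: resample
each sample with replacement (independently at the individual level, where
the two node sets differ in size; jointly over patients at the group level,
where per-patient set means are paired), record the difference of resampled
means per replica, and take `z = mean(diffs) / sd(diffs)` with a two-tailed
p-value from the standard normal. If all replica differences coincide the
normal limit is returned (`p = 1` for zero difference, else `p = 0`).
Bootstrap resample sizes equal the original sample sizes. Significance uses
the Bonferroni-corrected level `alpha' = 0.05 / (bands x metrics)`; at the
default 7 bands and 8 metrics, `alpha' = 0.05/56 ≈ 8.9e-4`. The divisor is
recomputed from the configuration, and subset runs (e.g. broadband only)
can pass `n_tests` explicitly to retain the full-study correction.

Two statistical caveats are properties of this test, not of the
implementation. First, the normal approximation to the bootstrap z is
anticonservative at small sample sizes: at n = 100 per sample the null
rejection rate at the 0.05 level is nominal (the calibration check in the
test suite uses 2000 simulated null tests at 10^3 replicas), but for
samples of 2–8 values — the size of typical resection sets — the true
false-positive rate is far above nominal even after Bonferroni correction.
Individual-level results on small RA sets should be read as descriptive.
Second, `N` and `O` are *selected by adjacency*: nodes connected to the RA
are on average more central than unconnected ones in any heterogeneous
network (the friendship paradox), so `N > O` differences do not by
themselves indicate pathology. The group-level paired test and the
outcome classification, which compare like with like across patients, are
the inferentially meaningful layers.

### Distinguishability and classification

Each comparison collapses to `r = +1 / -1 / 0` (significant with / against
the hypothesis / neither, after orientation flip for curvature; missing
comparisons — an empty node set, or sets below two nodes — score 0).
`D = sum over the 8 metrics of r` per pair (range -8..8), and
`D_comb = D(RA,N) + D(RA,O) + D(N,O)` (range -24..24). A continuous
variant `D'` replaces `r` with the Mann–Whitney AUC of separating the two
node sets' metric values, with backbone node strength added to the metric
list. Patients are classified SF (positive class) vs NSF by the
Mann–Whitney AUC of each score — ties count one half, making the AUC
invariant to any strictly increasing rescaling of `D`, so the choice of
threshold sweep is immaterial. Confidence intervals are percentile
intervals over 10^4 bootstrap resamples of the (score, label) rows;
replicates that lose a class are redrawn so exactly 10^4 usable replicates
remain. Pairs of tests are compared by the average crossing fraction
between one test's replicate distribution and the other's point AUC
(about 0.5 for identical tests, near 0 for separated ones), BH-corrected
at 0.05 across the comparison grid.

## The synthetic cohort generator

Patient MEG data cannot be shared, so the generator emulates what the
analysis actually consumes:

* **Weights.** Pairwise log-normal weights (meanlog 0, sdlog 0.59, rescaled
  to a maximum of 0.4). The log-sd was tuned once, by simulation over a
  grid, so that the disparity filter at `alpha = 0.1` leaves densities of
  about 0.049 on 90-node networks (10–90% range roughly 0.046–0.052,
  covering the 0.047–0.051 band reported for real PLI backbones) with
  giant components of 88–90 nodes.
* **Bands.** Seven bands per patient (broadband plus six canonical bands).
  Each band's log-weights are a correlated Gaussian mix of a patient-level
  latent matrix (`mix = 0.7` by default) with fresh noise, which preserves
  the marginal weight distribution — and hence the density calibration —
  exactly in every band; the broadband *is* the latent matrix.
* **Resections.** RA sizes uniform on 2–8 nodes by default: small focal
  resections on a 90-ROI parcellation. Empirical RA-size distributions
  vary by centre; the range is configurable.
* **Planted effects.** `ra_hub` multiplies all weights incident to RA
  nodes by `1 + strength` (in the latent, so all bands inherit an
  attenuated copy); `neighbour_hub` does the same for the non-RA node most
  strongly linked to the RA, which both makes it a hub and anchors it in
  `N`. Effects are clipped to [0, 1].
* **Seeds.** A master seed derives per-patient, per-band child seeds by a
  fixed integer hash, so cohorts are bit-reproducible and individual
  patients can be regenerated in isolation.

What the generator does *not* emulate: spatial geometry of a real atlas,
volume-conduction structure beyond the PLI's zero-lag insensitivity,
realistic MEG spectra (the phase-oscillator path in
`generate_phase_panel()` is a qualitative realism device: coupling raises
PLI, identical series give PLI 0), or empirically realistic effect sizes.
Passing end-to-end tests therefore shows that the pipeline *recovers
planted structure of the assumed form* and is calibrated under its own
null — not that any particular clinical effect size is detectable.

## Demonstration problem sizes

The test suite and the acceptance script exercise the pipeline at sizes
chosen to demonstrate each property while staying desk-sized: the
planted-effect recovery uses a 91-patient cohort (62 SF) on the broadband
network with an RA-hub strength of 2 and 10^3 bootstrap replicas for
individual tests (10^4 at the group level, where there are only 32 tests);
the null-coverage check uses 50 cohorts of 24 patients; homology oracles
run on graphs of up to 12 nodes where exhaustive subset enumeration is
feasible. Larger runs only sharpen the same comparisons.

## Numerical conventions

* Degenerate clustering (`k < 2`) is 0; the empty graph's giant component
  is reported as 1 (each node its own component).
* `sign(0)` contributes 0 in the PLI, so exactly zero-lag pairs score 0.
* Bootstrap zero-variance degeneracy returns the normal limit as above.
* Matrices read from disk are validated (square, symmetric within 1e-9,
  zero diagonal, [0, 1]) and exactly symmetrized; unknown RA ROI names
  fail with the offending patient and names.
* All user-facing tables index nodes by ROI label, never by position.

## Known limitations

Individual-level inference on very small node sets is anticonservative
(above); `b2` is computed from cliques only up to tetrahedra, so cavities
bounded by larger filled structures are not distinguished; no weighted or
persistent-homology variants; no alternative thresholding schemes (fixed
density, MST) — the disparity filter is the single thresholding method of
record.
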