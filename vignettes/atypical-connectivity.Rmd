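---
title: "Normative single-subject connectivity analysis: model, assumptions and design"
author: "painConn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative single-subject connectivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painConn)
```

## The model

`painConn` treats each chronic-pain patient as their own analysis unit.
The data object is a seed-to-atlas functional connectivity matrix: 76
pain-related seed coordinates correlated against 116 AAL atlas regions,
8,816 edges per subject. A normative cohort of 20 healthy controls
provides, for every edge, an empirical reference distribution; a patient
edge is *atypical* when its value is extreme relative to that
distribution under a label-shuffle permutation test with FDR control.

For edge $e$ with control values $x_1,\dots,x_n$ and patient value $y$,
the statistic is the absolute difference between group means,
$D_e = |\bar{x} - y|$. The null distribution reassigns which one of the
$n+1$ pooled values plays the patient role — the only label shuffles that
preserve the $n$-vs-$1$ group sizes — and

$$p_e \;=\; \frac{\#\{\,D_e^{(k)} \ge D_e\,\}}{n+1}, \qquad k = 1,\dots,n+1 ,$$

with ties compared at exact floating equality ("as large as or larger").
Benjamini–Hochberg step-up correction is applied across the 8,816 edges
*of that patient* (the procedure is framed one patient at a time, so
per-patient scope is the natural choice), and edges with adjusted
$p \le \alpha = 0.05$ form the patient's atypical set.

Downstream, atypical sets are aggregated across the cohort: per-edge
patient counts, per-node patient counts (a patient contributes at most 1
to a node however many of their edges touch it), strict recurrence
thresholds (node count > 10; edge count > 7, or > 3 for the seed-level
view), projection of edges onto the 18 anatomical location groups
(unordered pairs, self-pairs legal — thalamus-to-thalamus connectivity is
meaningful), a weighted group graph keeping pairs with count > 4, and hub
scores.

## Granularity of the permutation null, and the pooled variant

With $n = 20$ controls the per-edge null has exactly 21 distinct points,
so the smallest attainable p-value is $1/21 \approx 0.0476$. BH across
8,816 edges rejects at rank $k$ only when $p_{(k)} \le 0.05\,k/8816$;
with $\min p = 0.0476$ this is achievable only in near-degenerate
configurations (essentially all edges simultaneously extreme). The test
as literally specified therefore controls errors but has almost no
per-edge discovery power after FDR — an inherent property of a 21-point
null, not an implementation artifact.

The package therefore exposes a second, explicitly flagged null model,
`pooled_edges`, which pools the relabeling statistics of all edges of the
patient's matrix into one null distribution ($21 \times 8816$ values in
exact mode). This trades the per-edge exactness for resolution: it
assumes edges are exchangeable under the null after the variance-
stabilizing Fisher-z transform. It is **off by default**; analyses that
use it record the choice in the run manifest, and the acceptance script
uses it wherever a non-empty discovery set is required.

## Numerical choices

- **Scale.** Testing defaults to Fisher z ($\mathrm{atanh}\,r$), with $r$
  clipped to $\pm(1-10^{-7})$ so perfect correlations stay finite.
  Pearson $r$ is available; the choice is recorded in the manifest.
- **Monte-Carlo sampling.** Shuffles are drawn uniformly over the $n+1$
  distinct relabelings, so the exceedance count is exactly
  $\mathrm{Binomial}(n_{perm},\, k/(n+1))$; the implementation draws that
  count directly from a per-edge seeded sub-stream, which is
  distributionally identical to materializing shuffles and much faster.
  The default p-value rule is *plus-one*, $(1+b)/(1+n_{perm})$, which
  never returns zero; exact mode reports the true proportion.
- **Determinism.** Every stochastic component (generator subjects,
  per-edge Monte-Carlo streams) derives a deterministic 31-bit sub-seed
  from the run seed, so results are independent of evaluation order and
  bit-reproducible; the JSON manifest carries no timestamp for the same
  reason.
- **Degenerate inputs.** Constant time-series columns, NaN/NA values,
  mismatched shapes or scales, empty groups and empty graphs are rejected
  with informative errors rather than silently handled; missing
  timepoints are never imputed.
- **Thresholds.** All recurrence thresholds are strict inequalities
  ("more than"), exposed as configuration knobs with defaults 10 / 7 / 3
  / 4. Percentages are reported at one decimal with round-half-even.
- **Hub scores.** Weighted degree with self-loops counted twice (the
  standard graph convention), normalized by the maximum so the top hub
  scores exactly 1.00; an unweighted variant is available by flag since
  degree-centrality hub tables are sometimes computed either way.

## The synthetic generator

The generator defines the study conditions under which the pipeline is
validated:

- 20 controls and 56 patients by default, 76 x 116 edges;
- per-edge baseline means $\mu_e \sim N(0.3, 0.1)$ on the Fisher-z scale
  and between-subject SD $\sigma = 0.1$ — values chosen once to resemble
  typical resting-state edge distributions while keeping all values
  finite; the source study reports no empirical edge distributions, so
  these are stated assumptions, not fits;
- each patient receives `delta` (default 0.5, i.e. five between-subject
  SDs) added to a known set of injected edges (default 10 per patient,
  optionally concentrated on one anatomical group to emulate e.g. a
  thalamus-centred atypical network);
- patients are independent draws: the repeated-assessment redundancy that
  pooling longitudinal trials can introduce is deliberately not modeled;
- clinical outcomes can be linearly coupled to a chosen edge,
  $y = b_0 + b_1\,z_e + \varepsilon$; the default pipeline coupling uses
  slope 67.87 and intercept 8.71 (the magnitudes reported for the
  VAS-connectivity fit in the source cohort) so recovery can be checked
  against known truth. Ages are drawn around 58 ± 7 years and sex with
  the reference cohort proportions.

A time-series-level mode draws $T \times 192$ signals from a unit-variance
multivariate normal. The target correlation is sparse: designated base
edges (by default seed $k$ paired with atlas region $k$) carry
$\tanh(\mu_e)$, injected patient pairs carry $\tanh(\mu_e + \delta)$, and
all other pairs are uncorrelated; positive definiteness is verified by
Cholesky factorization and violations produce an error suggesting smaller
couplings. This emulates the correlational structure the connectivity
stage consumes, but none of the things that make real BOLD hard:
hemodynamic autocorrelation, scanner drift and noise spectra, motion
artifacts, or spatial dependence between neighboring regions. Passing
tests on synthetic data therefore demonstrate the statistical machinery,
not robustness to acquisition artifacts.

## What recovery can and cannot guarantee

At $\delta = 5\sigma$ an injected edge almost always attains the minimum
achievable exact p of $1/21$: the only competition comes from relabelings
in which a control plays the patient, and the shifted patient value leaks
into those relabeled means only through $\delta/n$. This is a
high-probability event, not a theorem — brute-force enumeration puts the
per-edge probability of a competing relabeling at roughly 0.75% under the
default conditions, so a cohort with 50 injected edges contains at least
one such edge in about a third of realizations. The test suite asserts
exact agreement with the enumeration oracle everywhere, and treats
"minimum p on every injected edge" as the near-certain event it is.

## Extraction from images

For users starting from 4D NIfTI volumes, atlas ROI signals are unweighted
voxel means over each label, and seed signals are means over in-brain
voxels within a 6 mm-radius sphere of the seed's MNI coordinate. The
source design gives only point coordinates for seeds, so the sphere
radius is an explicit configuration knob rather than a hidden constant;
RAS+ orientation and matching grids/affines are required, and a seed
whose sphere contains no in-brain voxels is an error, not an empty
signal. When a seed falls inside an atlas ROI, the resulting
near-unit edge is retained (host-region pairs are reported in the source
analysis); masking such edges is left to downstream filtering.

The packaged ROI tables are synthetic reconstructions: the 18 group names
and the per-group seed multiplicities (12 insula, 10 thalamus, 4 amygdala
seeds) follow the published design, but labels and coordinates are
plausible stand-ins, shipped as editable TSVs so users can substitute the
real tables.

## Problem sizes used in validation

The shipped tests run the full 76 x 116 design with 20 controls
throughout: 50 null patients for the false-positive calibration
(Monte-Carlo, 2,000 shuffles per edge), 12-patient thalamus-heavy cohorts
for hub ranking, 5-patient cohorts for recovery checks, and 100,000-draw
Monte-Carlo runs against exact enumeration on small toys. These sizes
were chosen to exercise every code path at the reference dimensions while
keeping the suite quick to run on a laptop.

## Known limitations

- The per-edge 21-point null is a faithful implementation of the
  described procedure, but per-edge FDR discoveries essentially require
  the pooled-edges variant; conclusions that depend on which variant was
  used should say so (the manifest records it).
- Confound regression, motion correction and all other preprocessing are
  out of scope; the pipeline trusts its inputs.
- Repeated assessments of the same patient must be resolved upstream;
  the aggregation stage rejects duplicated patient identifiers rather
  than silently double-counting.
- Clinical screens are reported without multiplicity correction across
  edges (mirroring the R^2-threshold screening practice they implement);
  they are descriptive, not confirmatory.
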