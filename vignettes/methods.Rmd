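---
title: "Methods: models, parameters and design choices in invrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in invrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the parameters that matter, and the design
decisions taken where the methodology left choices open. Code blocks are
illustrative and not evaluated; every empirical statement made here is one
the test suite or `scripts/acceptance.R` computes.

## 1. The analysis grid

All stages share one raster convention: cell-center registration, row 1 is
the northernmost row, and cell ownership is half-open — a point lying on a
shared edge belongs to the cell to the south/east. Rasters are exchanged
as single-band ESRI ASCII grids with a plain-text `.prj` sidecar carrying
the CRS (reading refuses files with no resolvable CRS rather than assuming
one); vectors travel as GeoJSON. Areas are cell tallies times a nominal
cell area (default 1 km² for the 1-km analysis grid); geodesic correction
is deliberately out of scope, so printed areas are exactly reproducible
from cell counts.

## 2. Occurrence screening

Raw records pass a two-step screen. Spatial thinning keeps the first
record per (species, 5-km thinning cell) after a deterministic sort by
(species, y, x) — determinism here makes whole-pipeline runs bit-identical
under a fixed seed. Species with fewer than five thinned records are
excluded; five presences is also the hard lower bound the fitter accepts.
Sampling effort is modelled by the target-group approach: a Gaussian
kernel density (`bandwidth` in cells, default 5) of all pooled records,
floored at a small epsilon so every valid cell retains positive mass, and
normalized to a probability surface from which the 10,000 background
points are drawn with replacement.

Collinearity screening works on the environmental stack directly:
variables are removed iteratively while any pairwise |r| exceeds 0.8 or
any variance-inflation factor exceeds 5, dropping the largest-VIF variable
each round (ties: larger mean |r|, then lexicographic). All-constant
layers are removed first with an explicit reason. VIF is computed by
regression (1/(1−R²)), so perfect collinearity is reported as infinite
rather than failing a matrix inversion.

## 3. The maximum-entropy model

For one species with presence cells {x_i} and background cells {b_k}, the
model is the Gibbs density p_λ(x) = exp(λ·f(x))/Z_λ over the background,
with features f built from each environmental variable's linear and
quadratic terms (products available by flag), z-scored over the
background sample. The fit minimizes

L(λ) = −mean_i[λ·f(x_i)] + log mean_k[exp(λ·f(b_k))] + Σ_j β_j |λ_j|.

- **Penalty schedule.** β_j = multiplier · s(m) · sd_presence(f_j) / √m,
  with s(m) interpolating (10, 30, 100) → (1.0, 0.6, 0.5) in the presence
  count m — a published-style schedule for the linear+quadratic feature
  class. Features whose presence spread is small (the informative ones)
  receive small penalties; diffuse features are damped. `beta = 0`
  switches to the unpenalized fit.
- **Optimizer.** Proximal Newton: an IRLS quadratic model of the
  log-partition term, an inner L1 coordinate-descent solve, and a
  backtracking line search. Convergence is declared when the largest KKT
  violation — |E_model f_j − E_presence f_j| beyond the β_j box — falls
  below `tol` (default 1e-5) within `max_iter` (default 500) outer
  iterations. First-order proximal-gradient methods were tried first and
  could not converge the strongly curved narrow-niche fits within that
  iteration budget; the second-order solver converges in tens of
  iterations at these feature counts (Hessians are ≤ ~20 × 20). A
  non-converged fit is returned flagged, never silently.
- **Logistic output.** HSI(x) = τ·e^η / (1 + τ·e^η) with τ = 0.5 and the
  centered score η(x) = λ·f(x) − log Z + H(p̂), H the entropy of the
  fitted density over background points; a cell with "typical" conditions
  (λ·f at the background average under the null) then maps to the middle
  of the scale. Ranks of HSI equal ranks of λ·f, so rank-based evaluation
  is unaffected by the centering choice.
- **Replication.** "10 replicates with a 75/25 split" is read as ten
  random 75/25 subsampling partitions; case-resampling bootstrap (with
  out-of-bag validation) is available via `resample = "bootstrap"`. The
  final suitability raster is the cell-wise mean of replicate logistic
  outputs, the final threshold the mean of replicate maximum
  sensitivity-plus-specificity thresholds, and AUC is reported as the
  held-out mean and range. Evaluation AUC is the rank-based (Mann-Whitney)
  probability that a presence outscores a background point, ties counting
  one half.
- **Variable importance.** Percent contribution uses permutation
  importance — the drop in training AUC when one variable is permuted
  across evaluation cells, truncated at zero and normalized to 100% —
  because the original software's path-attribution heuristic is not
  reproducible from its description. Jackknife gains (only-this-variable
  and without-this-variable refits, gain = log-likelihood improvement over
  the null model) are reported alongside.

## 4. Stacked richness and Jenks zoning

Per-species binary maps (HSI ≥ threshold) are summed into an integer
richness raster; a cell that is nodata in any layer propagates as nodata.
Zoning uses Jenks natural breaks: the exact O(k·n²) dynamic program on
weighted distinct values (compiled), which reduces to O(k·u²) for integer
richness with u distinct counts. For large continuous rasters the breaks
are computed on a seeded random sample capped at `sample_max = 10,000`
values — a sampled computation in the spirit of the 50,000-point practice
used at national scale, sized so the whole test suite stays fast; at these
grid sizes the sampled and full-data breaks are statistically
indistinguishable. The boundary convention everywhere is upper-closed:
value ≤ break → lower class. High suitability is zones 3–5 of the 5-zone
classification. When a degenerate stack has fewer distinct values than
zones, k is reduced with a warning and the pipeline keeps the top-(k−2)
zones as the high-suitability share.

## 5. Habitat degradation and quality

Each threat spreads from source cells (intensity r_y ∈ [0,1]) with
distance decay i(d): linear 1 − d/d_max, or exponential exp(−(2.99/d_max)
d) truncated at d_max — the constant 2.99 ≈ ln 20 puts the influence at
5% of its peak at the maximum impact distance, the canonical
habitat-quality convention. The shipped threat table (maximum distance,
weight, decay per factor — highway 2 km/0.85/linear, railway 1/0.65/linear,
urban 4/0.9/linear, port 1.5/0.95/exponential, farmland 8/0.7/linear,
river 0.5/0.5/exponential, tourism 3.5/0.65/exponential) is
config-overridable.

The influence field takes the **maximum** over source cells, r_y·i(d),
rather than a kernel sum: the dominant nearby source determines pressure,
and the degradation index

D(x) = Σ_r (w_r/Σw) · field_r(x) · β_x · S_{j(x),r}

then stays in [0,1] by construction with no ad-hoc renormalization. The
sweep is compiled (per-source kernel update, O(sources × kernel)), checked
in tests against a naive all-pairs oracle. β_x (accessibility) defaults
to 1 everywhere, as no accessibility layer is part of the protocol.

Quality is the half-saturation response Q = H_j·(1 − D^z/(D^z + K^z)),
z = 2.5 per the canonical model. K is calibrated by the half-of-maximum
rule from its initial 0.05, iterated to a fixed point (one application
suffices unless a configuration round changes D). The per-class habitat
scores H_j and the 7 × 7 sensitivity matrix are not printed in any source,
so the package ships defaults: wetland and primary vegetation score high
H, disturbance zones and corridors low H; disturbance zones keep moderate
(not near-zero) sensitivity so that sitting at the urban/farmland sources
shows up as the highest degradation — the pattern the emulated assessment
reports — while wetlands, placed away from disturbance by the generator,
stay least degraded. Both tables are configuration inputs and are excluded
from acceptance quantities.

Degradation tiers use fixed cuts (0.17, 0.31, 0.42, 0.55) with the shared
upper-closed convention, and the high-vulnerability mask is defined
directly as D ≥ 0.31, so a cell exactly at the threshold is vulnerable.
Those absolute cuts describe a national D distribution; an arbitrary
synthetic landscape can fall mostly below them, so the pipeline offers a
synthetic-data mode (`recompute_tiers_jenks = TRUE`) that re-derives the
five tier cuts by Jenks from the run's own D distribution and takes
"medium and above" (≥ the second break) as vulnerable. Package defaults
remain the fixed cuts.

## 6. The geographical detector

The factor detector is q = 1 − Σ_h N_h σ_h²/(N σ²) with population
variances — stated explicitly because sample variances change q at small
N. Its p-value uses the noncentral-F transformation of q (the standard
test; no multiple-testing correction is applied, and the report says so in
its metadata). Continuous factors are discretized by the shared Jenks code
into five classes; soil pH uses manual breaks (default 5.5, 6.5, 7.5,
config-overridable) for their chemical meaning. The interaction detector
computes q on the cross-partition and categorizes it against the
single-factor values (nonlinear weaken < min ≤ univariate weaken ≤ max <
bivariate enhance ≤ q_A + q_B, independent at equality within 1e-9,
nonlinear enhance above); singleton cross-strata are retained with zero
variance, which keeps the refinement property q_AB ≥ max(q_A, q_B) exact.
The risk detector reports stratum means with pairwise Welch tests; the
ecological detector compares two factors' within-stratum sums of squares
by F = [N_A(N_B−1)SSW_A]/[N_B(N_A−1)SSW_B], decided two-sided since either
factor may be the stronger stratifier, with a zero denominator reported
significant by convention.

## 7. Integration and gap analysis

Core invasion habitat is the logical AND of the high-suitability and
high-vulnerability masks; cells flagged by exactly one mask form the two
secondary-priority categories. Protected-area membership of a cell is
cell-center-in-polygon (even-odd rule), consistent with the half-open grid
convention, so boundary cells are unambiguous. The gap report satisfies
area(core) = area(protected core) + area(gap) exactly, and land-cover
composition fractions sum to one. Pathway analysis assigns each cell's
dominant dispersal pathway as the argmax of the weighted contribution
(w_r/Σw)·field_r·S, with deterministic tie-breaking in listing order
(highway before railway before river); "hotspot" — never formally defined
in the source methodology — is operationalized as the top Jenks class of a
pathway's positive contribution, with contiguity summarized by 8-connected
components. The per-pathway "mean corridor risk" averages the contribution
over the pathway's corridor footprint (field > 0 by default); its absolute
scale depends on the weight normalization and is therefore reported but
not compared against any external value.

## 8. The synthetic landscape: what it emulates, and what not

`synthetic_landscape()` generates the study conditions the tests run
under. Environmental layers are a random directional gradient plus
Gaussian-smoothed noise (correlation length `spatial_range = 15` cells),
rescaled to field-realistic units; nighttime lights and road density get
right-skewed marginals via an exponential transform. Construction enforces
what the screening stage assumes of a final variable roster: pairwise
|r| < 0.8 and VIF < 5, re-drawing a layer (fresh substream) if violated.
The 7-class land-cover map derives from the layers themselves
(disturbance score, wetness, vegetation), with wetlands placed away from
disturbance. Threats follow their real geometries — polygons around
disturbance and cropland patches, random smooth polylines for
highway/railway/river, point buffers for ports and tourism — and
protected areas are placed preferentially in low-disturbance cells,
reproducing the real-world mismatch between protection and anthropogenic
invasion pressure (a permutation test in the suite checks the placement
bias).

Species niches are Gaussian per variable (log-linear quadratic), so the
linear+quadratic feature class can represent the truth exactly and
parameter recovery is a sharp test. Default breadths are 0.2–0.45 of a
layer's standard deviation — narrow enough to emulate the strongly
discriminable species national assessments report, wide enough that the
curvature is estimable from tens of records. Species 1 is a designed
single-driver probe: nightlight-driven (the dominant predictor class in
this literature), breadth 0.12 sd, weight 1.5. Its driver is fixed rather
than drawn at random because per-driver identifiability varies widely on
any single landscape realization — some layer pairs are spatially
confounded within a narrow suitable band — and the probe is meant to test
the estimator, not the landscape draw.

The default fixture is a 200 × 200 grid, 12 species, 30–300 records each,
seed 20100898, with `bias_strength = 0`: the clean baseline isolates the
niche signal for the recovery experiments, and sampling bias is switched
on explicitly (`bias_strength > 0`) in the tests that exercise the
clustered-effort emulation and the target-group correction. The
observation-effort field is a smoothed random field thresholded into
"cities" (top decile), re-smoothed — effort contrast of roughly thirty to
one.

What the generator does **not** emulate: real geography or county
boundaries, real species' niches, temporal dynamics, biotic interactions,
or observation error in the environmental layers. Passing recovery tests
on this fixture therefore demonstrates estimator correctness under the
stated statistical structure, not performance on real occurrence
databases, whose biases are richer than a single effort field.

## 9. Numerical choices and problem sizes

Deterministic tie-breaks are used everywhere randomness is not explicit
(sorted species order, first-candidate threshold ties, listing-order
pathway ties), so identical seeds give bit-identical artifacts — asserted
file-by-file in the suite. All seeded helpers restore the caller's RNG
state; functions with irreducible randomness refuse to run without a seed.
The recovery experiment fits all 12 fixture species with 10 replicates
against 10,000 uniform background points, and the probe uses 5,000
records — sizes chosen so the whole experiment completes in a few minutes
on one CPU while the Monte-Carlo error stays well inside the stated
tolerances; the deterministic pipeline checks run on 60 × 60 landscapes
with 3–4 species, and the acceptance script's end-to-end run uses a
120 × 120 landscape with 8 species and biased sampling.

## 10. Known limitations

- The maxent implementation targets the model family, not bit-for-bit
  agreement with the original software; clamping diagnostics and feature
  classes beyond linear/quadratic/product are out of scope.
- The degradation model's max-aggregation is a deliberate departure from
  summed-kernel variants; both are defensible, and the field function is
  isolated so a sum-with-normalization variant can be added behind the
  same interface.
- Absolute pathway-risk values are normalization-dependent; only their
  ordering and dominance shares are meaningful.
- Geodesic areas, reprojection, and multi-band imagery are out of scope;
  the raster I/O is the plain-text ASCII grid format with a CRS sidecar.
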