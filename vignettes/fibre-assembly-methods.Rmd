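---
title: "Methods: hierarchical fibre assembly, rod SAXS analysis and ridge-based micrograph quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical fibre assembly, rod SAXS analysis and ridge-based micrograph quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FibreForge)
```

## The assembly model

FibreForge encodes the hierarchical assembly of the SYCE2-TEX12 complex,
the fibrous core of the synaptonemal complex central element. The model's
assumptions, in decreasing order of confidence:

* The obligate building block is a 2:2 hetero-tetramer: a rod 14 nm long
  (19 nm with its C-terminal S2C and Ctip helices), 2 nm wide and about
  2 nm thick. Lateral tessellation of two 2:2 complexes doubles the width
  to 4 nm at unchanged length, giving the 4:4 hetero-octamer.
* End-to-end association is mediated by anti-parallel S2C–Ctip four-helix
  bundles. Each junction consumes 5 nm of overlap, so an end-to-end fibre
  of `n` subunits has length `20 + 15 (n − 1)` nm: a 20-nm initial subunit
  plus 15-nm repeats, matching the 156 Å crystallographic translation along
  the fibre axis. `predictFibreLength()` and `enumerateAllowedLengths()`
  are exactly this arithmetic, and the bead models built by
  `buildFibreBeads()` reproduce it geometrically (overlapping grid sites at
  the junctions are merged, not double-weighted, so junctions are not
  artificially dense).
* Laterally, fibres repeat at 5-nm spacing; 10-nm fibres are laterally
  associated 4:4 fibres and bundles reach 40 nm. How many 4:4 fibres make
  a 10-nm fibre is not settled, so the lateral copy number is a free
  parameter of `fibreModelSpec()` rather than a constant.

Two longitudinal repeats coexist deliberately: the assembly rule uses the
15-nm increment for length arithmetic, while `latticeRepeats()` reports the
cell-derived 15.6 nm. Both are printed in the field's literature and the
package exposes both rather than reconciling them; the `AssemblyRule`
validity check only requires the two to agree within 1 nm.

The width taxonomy gates a measured width into {2:2 fibre, 4:4 fibre,
10-nm fibre, bundle}. Only nominal widths and population means are
established; the class boundaries (3, 7, 20, 40 nm) are this package's
choice of midpoints between the nominal widths, and are configurable.

The SC mass model treats the central region as a solvated protein prism:
`mass/µm = side² × 1000 nm³ × ρ × (1 − solvent)`, converted to daltons via
the unified atomic mass constant. The protein density behind the published
1.6–6.4 GDa/µm range is never stated; the default 1.33 g/cm³ is the
conventional protein mass density and reproduces the printed range to two
significant figures. It is a parameter, not a constant.

Heptad registers are assigned as `(residue + offset) mod 7 → a..g`, with
a/d flagged as hydrophobic core. Only the congruence structure is
convention-free; the letter labels depend on the offset convention, which
is chosen (when no offset is supplied) to maximize the number of supplied
residues on core positions, ties to the smallest offset. The package
stores residue indices only — no sequences.

## Bead models and forward scattering

Subunits are coarse-grained as rectangular-cross-section rods filled with
beads on a cubic grid of spacing `2 × beadRadius` with equal scattering
weights. The default bead radius of 0.25 nm makes the Debye curves of the
fibre models converge where the rod parameters are determined: halving the
radius changes the normalized forward curve by under 2% for
q ≤ 0.1 Å⁻¹ (the Guinier and cross-section windows), growing to ~7% by
0.2 Å⁻¹ where grid artifacts appear; a halving check in the test suite
pins this down. The rectangular cross-section is
a deliberate coarse-graining — no attempt is made to reproduce the
crystallographic envelope, hydration shell or excluded-volume contrast.
Consequently χ² values from `chi2Fit()` against these bead models are
internally consistent but not comparable to all-atom CRYSOL/FoXS fits of
experimental curves, and no experimental χ² value is asserted anywhere.

`debyeIntensity()` evaluates the Debye double sum exactly at q = 0
(`I(0) = (Σw)²` by construction) and accumulates pair distances into
0.02 Å bins at their weighted mean distance elsewhere; at the q values
used (≤ 0.4 Å⁻¹) the binning error is below floating-point noise of the
direct sum. `cylinderIntensity()` integrates the uniform-cylinder form
factor over the tilt angle with Gauss–Legendre quadrature and verifies
convergence against the next-higher order (relative 10⁻⁶), raising an
error rather than returning an unconverged result.

## Rod-geometry curve analysis

**Guinier fit.** `guinierFit()` fits `ln I` against `q²` over the largest
low-q window satisfying `q·Rg < 1.3` under self-consistent re-fitting.
Rod-like curves bend upward within that conventional window, which biases
a plain linear slope low by 2–8% across the 15–65 nm lengths of interest.
The estimator therefore refits the converged window with a second-order
term (`ln I ~ q² + q⁴`) and uses its limiting q² slope whenever the
quadratic term is statistically significant (|t| > 3); on featureless
noisy data the term is insignificant and the plain fit is kept. On
noiseless cylinders this brings the worst-case error across L ∈ {15, 19,
35, 65} nm, R ∈ {1.0, 1.7, 2.7} nm from −8% to below 0.4%.

**Cross-section fit.** `crossSectionFit()` fits `ln(qI)` against `q²` with
`q·Rc < 1.3`. The window's lower bound matters more than its upper bound:
the finite-length rolloff contaminates `ln(qI)` well above the
conventional `1.3/Rg` exclusion. The window therefore starts at
`max(1.3/Rg, 1.5·2π/L)` with the rod length estimated from Rg (refined
once via `Rg² = L²/12 + Rc²`), relaxing the length bound stepwise if too
few points remain. The quadratic correction is deliberately *not* applied
here: the contamination is not polynomial at the window base, and
extrapolating a quadratic to q = 0 overcorrects. Worst-case noiseless
error across the same grid is 2%.

**P(r) inversion.** `iftPofr()` inverts `I(q) = 4π ∫ p(r) sinc(qr) dr` by
Lawson–Hanson non-negative least squares (implemented in the package; the
kernels are ill-conditioned at weak smoothing and need a larger iteration
budget than available ports allow) with both endpoints anchored at zero
and a second-difference smoothness penalty. Numerical choices that
matter:

* unknowns are node *masses* `u = p·Δr`, which keeps the data term on a
  candidate-independent scale;
* the node count is shared by all Dmax candidates and chosen so the node
  spacing resolves the kernel at the highest measured q (`Δr ≲ 2/qmax`);
  coarser grids cannot represent the data at high q and their apparent
  misfit corrupts the Dmax scan;
* each kernel entry is the Gauss-quadrature cell average of the sinc, not
  a midpoint sample, since the sinc oscillates faster than the node
  spacing at high `q·Dmax`.

Dmax is selected from a candidate scan with three ingredients. Candidate
fit quality is evaluated at two fixed moderate penalties (α = 0.01, 0.1):
weak enough that a correct Dmax reaches the noise floor, strong enough
that a truncating candidate cannot contort its P(r) to hide. A candidate
is rejected if its total χ² exceeds the best achieved among moderately
larger candidates by more than 9 (a ~3σ likelihood-ratio criterion against
a *local* floor, so slow drift of the floor with candidate size does not
bias the choice), or if its P(r) piles more than 18% of its mean density
into the last 15% of r — the signature of truncation pressing displaced
pair mass against the anchored endpoint. The smallest surviving candidate
is reported. The returned P(r) then takes the largest α whose fit stays
within 10% of the best at that Dmax (the knee of the χ²(α) curve). On
simulated rods with the default 2% relative noise this recovers Dmax
within 5% for lengths 15–65 nm. The perceptual criteria of interactive
IFT programs are not reproduced.

`shannonChannels()` implements the information-theoretic guard: when
`Dmax ≥ π/qmin` the first Shannon channel is unsampled and the estimate is
flagged unreliable (the boundary case counts as unreliable);
`analyzeSECSeries()` reports Dmax as undetermined in that case and records
per-frame failures in its status column without aborting the series.

## Micrograph quantification

`preprocessMicrograph()` subtracts a Gaussian background estimate and
applies a radial FFT bandpass with 25% linear roll-offs, standardizing the
result to zero mean and unit variance; the DC component is always removed.

`detectRidges()` is a Steger-style line detector: scale-space Hessian at
scale σ (recommended `σ = w/(2√3)` for expected width w), line points
where the principal eigenvalue indicates a ridge of the image's polarity
with the sub-pixel extremum inside the pixel, linking by orientation
continuity with hysteresis, and per-point widths from the two
gradient-magnitude maxima along the local normal. Non-obvious choices:

* **Adaptive thresholds.** Defaults are
  `high = max(6·mad(strength), 0.02·max(strength))`, `low = high/3` —
  noise-calibrated on noisy images, contrast-calibrated on noise-free
  ones.
* **Width scale.** Widths are measured on a gradient field at unit scale,
  not the detection scale: edge maxima of a profile smoothed at the
  detection σ are displaced outwards by a large fraction of σ for thin
  fibres (a ~40% overestimate for 4-px fibres at σ = 2.3), while at unit
  scale the residual broadening is a few percent. No further Steger bias
  correction is applied; the residual bias is characterized by the
  calibration tests (within 10% for rendered widths 4–20 px, noise-free).
* **End localization.** The smoothed ridge response stays high for about
  one scale beyond the physical fibre end. The end cap, however, raises
  the "blobness" (ratio of the two principal curvatures) to ~0.5 exactly
  at the tip, so each trace end is cut at the outermost blobness crossing
  within 4σ of the end, with a half-response fallback. This keeps
  noise-free length errors within 5%.
* **Fragment repair and duplicates.** Noise occasionally interrupts the
  line-point criterion; the linker bridges up to 3-px gaps, and a merge
  pass joins trace ends that face each other within `max(10, 3σ)` px.
  Conversely, traces running along a longer trace's centreline (the same
  ridge picked up from an adjacent pixel band) and saddle-like traces
  (median blobness < −0.5, the shoulder artifacts flanking wide-fibre end
  caps) are suppressed.
* Traces are split at junctions; no attempt is made to reconnect crossing
  fibres. Polarity defaults to dark ridges, the common appearance of
  stain-accumulating fibres, and is an explicit parameter.

`fitWidthPopulations()` fits the 1-D Gaussian mixture with mclust
(unequal-variance model "V"), whose model-based hierarchical
initialization is deterministic — the same guarantee a fixed quantile
initialization would give, using the field's standard implementation —
and reports hard-assigned counts summing to the number of fibres,
components sorted by mean. `k = 1` returns the sample moments exactly.

## Synthetic data: what it does and does not emulate

The generators define the conditions under which every estimator here is
validated. `simulateSAXS()` adds Gaussian noise with
`sd(q) = 0.02·I(q) + floor` — intensity-proportional noise is standard
SAXS practice; Poisson counting statistics are deliberately omitted.
`simulateSECSeries()` builds frames as convex combinations of cached
species Debye curves; `elutionLadderMixtures()` is the standard five-frame
sweep from four-subunit 2:2 fibres (65 nm) to the single 4:4 complex used
by the trend tests. `simulateMicrograph()` lays fibres down as persistent
random walks (step 2 px, turning sd set by a 2000-nm persistence length,
no self-avoidance), renders rectangular cross-profiles convolved with a
1-px Gaussian PSF on a smooth gradient background with white noise
(default contrast/noise = 20), and returns exact ground truth; fibre
lengths are drawn from the discrete allowed lengths (2–6 subunits) and
widths from the 2-nm (±0.4) and 4-nm (±1.0) class distributions. Bundled
fibres would be represented as closely spaced 10-nm-class fibres with
lateral jitter; no stain physics, electron optics or assembly kinetics are
simulated, and no noise/contrast statistics of any real instrument are
claimed. Passing tests therefore demonstrate correctness of the
estimators under these statistical assumptions, not performance on any
particular microscope's images — for real data the detection parameters
must be set by the user, since the exact preprocessing and ridge-detection
settings used in published analyses are not recorded.

Problem sizes used by the test-suite and trend analyses — 140–250-point
log-spaced q grids starting at 0.004 Å⁻¹ (dense low-q sampling is where
size information lives), 256–512-px images with 4–16 fibres, five-frame
elution ladders, 50-repeat detection counts — are the package's choice of
representative scales for these methods.

## Known limitations

* Bead-model scattering has no hydration shell or excluded-volume terms;
  χ² values are internally comparable only.
* Dmax from noisy curves is intrinsically soft at the few-percent level:
  candidates ~8% below the true length can fit 2%-noise data with
  statistically acceptable χ²; the endpoint-load criterion is what
  restores accuracy, and it assumes the particle's P(r) approaches zero
  smoothly (true for rods and globular particles, not for density
  spikes at the maximum dimension).
* The ridge detector's width estimator assumes an isolated fibre profile;
  widths of fibres closer than ~4σ are biased by their neighbours.
* Heptad letters (not core flags) are convention-dependent.
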