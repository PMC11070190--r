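---
title: "Methods: quantifying host–diazoplast metabolite exchange from nanoSIMS ion counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying host-diazoplast metabolite exchange}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symbiotrace)
```

# The measurement model

nanoSIMS rasters report integer secondary-ion counts per pixel for a
small set of mass channels. Nitrogen is carried by the CN⁻ pair
(¹²C¹⁴N⁻, ¹²C¹⁵N⁻), carbon by the C₂⁻ pair (¹²C₂⁻, ¹³C¹²C⁻), and ³²S⁻
tracks protein. `symbiotrace` models each pixel's summed pair count as
Poisson with a compartment-specific density and the heavy/light split
as binomial with the compartment's true heavy-atom fraction. Two
consequences shape the whole package:

* the **ratio-of-sums** estimator (pool counts over an ROI, then take
  the ratio) is the maximum-likelihood atom-fraction estimate, and
* conditional on the total, the heavy count is binomial, so the atom
  percent carries an exact counting-statistics standard error
  `100·sqrt(p(1−p)/n)`.

Per-pixel ratios are deliberately never used: at natural abundance a
typical pixel holds zero heavy counts and the pixel ratio is undefined
or badly biased.

## Compartments

Cells decompose into three biological compartments plus background:

| class | signature |
|---|---|
| diazoplast | spherical, highest CN⁻ density |
| host(N) | above-background CN⁻ (cytoplasm, organelles) |
| host(−N) | background CN⁻ but high C₂⁻ (storage bodies) |

## Enrichment and activity

Unlabeled controls calibrate the natural-abundance baseline per
isotope: across control ROIs, the unweighted mean and SD of the atom
percent give the threshold `mean + 3·SD`. The SD is across-ROI scatter
(instrument variability), not the per-ROI counting SE, and the mean is
unweighted across compartments — when the source protocol is ambiguous
between pooling schemes we choose the simplest and say so. Calls are
strict (`>`), monotone in atom percent, and deliberately uncorrected
for multiple testing: the rule is a fixed cutoff convention, not a
testing procedure. A cell is *active* iff its pooled diazoplast ROI is
¹⁵N-enriched, *carbon-fixing* iff its pooled host(N) ROI is
¹³C-enriched; population fractions carry Wilson 95 % intervals.

## The transfer mass balance

Excess enrichment (atom fraction above the calibrated baseline) is
proportional to newly incorporated tracer. With host excess equal to
`s` times the diazoplast excess (estimated by through-origin least
squares over paired cells) and a diazoplast:host(N) volume ratio `v`,
the host's share of newly fixed nitrogen is

$$ f = \frac{s\,V_h}{s\,V_h + V_d} = \frac{s}{s+v}, $$

assuming equal nitrogen density per unit volume across compartments —
the assumption implicit in any volume-ratio argument of this kind, and
surfaced here as an explicit input. `f` is strictly increasing in `s`,
strictly decreasing in `v`, and `f + v/(s+v) = 1` exactly. At the
reported `s = 0.9` and `v = 0.06`, `f = 0.9375`. The through-origin
default reflects the constraint that a cell with zero diazoplast
fixation has nothing to transfer; an intercept option is retained
because the source analysis does not state its model. Uncertainty comes
from a cell-level bootstrap (percentile CI over resampled cells); the
regression is on excess enrichments so the baseline cancels.

# The synthetic-data generator

The generator is first-class, tested code: it defines the study
conditions under which every recovery claim is made.

* **Geometry.** One focal cell per raster (per-cell analyses need no
  mosaics): a host ellipse of semi-axes 10 × 5 µm (a ~20 µm cell) on a
  128 × 128 raster at 0.25 µm/px, containing four diazoplast discs of
  radius 1.55 µm and two host(−N) discs totalling 10 % of the host
  area. Volumes use a prolate-spheroid (host) and sphere (discs) model,
  giving a diazoplast:host volume ratio of 4·1.55³/(10·5²) ≈ 0.060 —
  the stated 6 %. Discs are placed by rejection sampling (100 retries
  per disc, 20 arrangement restarts, then an explicit geometry-infeasible
  error) with a 2-px clearance between discs and a 3-px inset from the
  host boundary, so distinct organelles remain resolvable — and
  topologically interior — at the raster resolution.
* **Counts.** Compartment CN⁻ densities default to 200 (diazoplast),
  100 (host(N)), 5 (host(−N)) and 2 (background) counts/px, C₂⁻ to
  80/80/150/2, and ³²S⁻ to 0.3 × the CN⁻ density. Acquisition
  parameters for the original data are unavailable, so densities are
  free simulation parameters chosen to give realistic per-ROI count
  depths (~10⁴–10⁵ pooled counts).
* **Isotopes.** Physical natural abundances (¹⁵N 0.003663, ¹³C 0.0111
  atom fraction) are kept separate from additive instrument offsets
  (defaults 0.000107 and 0.0063) so that simulated unlabeled material
  reproduces the measured control baselines of 0.377 atom % ¹⁵N and
  1.74 atom % ¹³C.
* **Population structure.** Each cell is active with probability
  `fracActive` (default 0.70, the 12-h prevalence) and carbon-fixing
  with probability `fracFixingC` (default 0.90, so that dual labeling
  is the modal outcome). Active cells draw a diazoplast excess ¹⁵N
  atom fraction from a lognormal (mean 0.01, CV 0.5 — strictly
  positive and right-skewed, like observed single-cell enrichment
  scatter) and set the host excess to `hostRatio` (default 0.9) times
  it. Carbon-fixing cells enrich host(N) by a lognormal excess (mean
  0.02) with 1.5× that excess in host(−N) (storage accumulates fixed
  carbon) and 0.8× in the diazoplast (carbon shared with the
  symbiont); these two multipliers are qualitative shape choices, not
  fitted values.
* **Determinism.** One config seed fans out deterministically to all
  draws; identical configs give bit-identical output.

What the generator does **not** emulate: sputtering depth, detector
dead time, quasi-simultaneous-arrival effects, raster drift,
multi-plane acquisition, and irregular organelle shapes. Passing
recovery tests therefore validate the estimators under the stated
counting model, not instrument-specific artifacts of real acquisitions.

# Segmentation: numerical choices

1. Gaussian smoothing (σ = 1 px) precedes all thresholding — raw
   Poisson pixels at low counts defeat any threshold.
2. Cell vs background: Otsu's threshold on the smoothed summed-CN
   image; largest connected component; holes filled (so host(−N)
   stays inside the footprint).
3. Diazoplasts: seeds above the within-cell CN quantile (default
   0.90); the final mask thresholds at the midpoint between the host
   level (median of sub-seed cell pixels) and the seed level — on
   noiseless rasters the midpoint crosses exactly at the compartment
   edge, which is what makes sub-pixel-exact recovery possible.
   Touching candidates are split by watershed on the distance map.
   Components must pass area (≥ 20 px) and circularity
   (4πA/P² ≥ 0.6) filters — "spherical" is the only shape criterion
   available. A seed level below 1.5× the host level means no
   diazoplast: an absent diazoplast is a valid output, not an error.
4. host(−N): cell pixels at background-level CN (below the
   background/host midpoint) whose smoothed C₂ density is ≥ 1.5× the
   within-cell median.
5. Boundary pixels follow the smoothed-value rule with no
   morphological tie-breaking; segmentation is fully deterministic.

On noiseless rasters (counts = expectations) the classes agree with
ground truth exactly away from a 1-px boundary band; on noisy default
simulations per-class pixel agreement is typically 97 %. The original
workflow's ROIs may have been drawn manually; this module is an
automated, reproducible surrogate and does not claim to replicate
manual outlines.

# Ancillary assays

* **Bulk IRMS.** δ ↔ ratio (`R = R_std(1+δ/1000)`, VPDB default
  0.0111802, overridable) and ratio ↔ atom % conversions are exact
  inverses to 1e−12. Condition comparisons report Welch t-tests and
  reuse the 3-SD convention for the enrichment call — a package
  convention for consistency with the single-cell rule, not a stated
  bulk test.
* **Diel ARA.** Rates are ethylene per µg chlorophyll per hour; GC
  peak-area calibration happens upstream. The "no clear diel pattern"
  flag uses a day:night ratio within 2-fold; the treatment effect is
  `100·(1 − mean_treated/mean_control)` with a replicate bootstrap CI,
  and is invariant to common rescaling. The Welch annotation returns
  `NA` on degenerate (zero-variance) inputs rather than failing.
* **qPCR.** Relative level `E^(Cq_ref − Cq_target)` with efficiency
  `E ∈ (1, 2]` a required input (assay efficiencies are
  protocol-specific); multiple reference genes combine by geometric
  mean of implied levels; fold changes are ratios of geometric means
  (log-scale symmetry). With `E = 2` this is exactly the classical
  2^−ΔΔCt, which the tests assert as an oracle identity.

# Problem sizes and validation

The test suite validates each operation against independent oracles:
closed forms (mass balance, Cq offsets, δ conversions), binomial and
Gaussian large-sample bounds, confusion matrices against simulation
ground truth, and bit-identity for reruns. Recovery studies use 30–200
cells on 64–128 px rasters and 100–2000 bootstrap resamples — sizes
chosen so the full suite runs in well under a minute on one CPU while
keeping Monte-Carlo error far below the tolerances asserted.

# Known limitations

* The mass balance assumes equal nitrogen density per volume and a
  user-supplied volume ratio; projected-area-based volume estimation is
  possible (`extractRois` provides equivalent radii) but is not the
  default, since the ratio is usually stated, not derived.
* No isotope-dilution or turnover kinetics: the transfer fraction
  describes the end-point distribution of tracer, not a flux.
* Enrichment calls are per-cell with a fixed 3-SD cutoff; no
  multiplicity control by design.
* Segmentation assumes roughly convex, bright diazoplasts; heavily
  overlapping organelles or strong drift would require a learned or
  3-D approach, which is out of scope.
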