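---
title: "Dual-tracer winter foraging inference: models, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-tracer winter foraging inference: models, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isotrack)
```

## The inference problem

Where a marine predator foraged in winter, and at what trophic level,
cannot be observed directly. Two indirect tracers are available and each is
ambiguous on its own:

* **Light-level geolocators** give daily positions with large error
  (radial RMS around ±186 km) — good for *where the population roamed*
  over a season, useless for trophic information.
* **Feather stable isotopes** (δ¹³C, δ¹⁵N in ‰) record the diet assimilated
  while the feather grew. The measured value confounds two things: the
  spatial isotopic *baseline* of the food web where the bird fed, and the
  bird's *trophic position* above that baseline. δ¹⁵N rises by roughly
  3.5 ‰ per trophic step; δ¹³C tracks baseline carbon sources.

`isotrack` combines the two: the geolocator data provide a spatial prior
and — crucially — an independent estimate of where the population was,
which lets the trophic component be separated from the baseline component
via a *calibration offset* against a reference isoscape.

## The model, stage by stage

### Tracks → utilisation prior

Fixes are filtered (equinox windows, when light-based latitude is
unreliable: 10 Sep–18 Oct and 20 Feb–2 Apr by default; then a forward
great-circle speed scan, default 500 km/day) and pooled per population and
winter into a Gaussian kernel density estimate on a 0.1° grid. The
bandwidth default is the 1.06 normal-reference rule
`1.06 · min(sd, IQR/1.34) · n^(-1/5)` averaged over the two axes, with 0.4°
as the conventional override. The KDE here is an *exact* kernel sum at
cell centres (density per square degree, integrating to ≈ 1), not a binned
approximation — the package's oracle tests require pointwise agreement
with a brute-force Gaussian sum at 10⁻⁶.

Individuals that left the study region during a feather's moult months are
excluded (the residency gate); fixes over land are retained, as is standard
for coastal species to avoid offshore bias.

### Calibration offset

Cells where the moult-season KDE exceeds 0.01 define the area the tracked
population used. The isoscape's δ¹³C and δ¹⁵N values are extracted over
that mask and summarised by median and sd; the feather population likewise.
The offset per isotope is estimated by Monte Carlo: 1000 independent draws
from `Normal(median_feather, sd_feather)` minus draws from
`Normal(median_isoscape, sd_isoscape)`; the mean of the differences is the
offset Δ_f-j, their sd its uncertainty. In the large-draw limit the offset
is the difference of medians and the sd is `sqrt(sd_f² + sd_j²)`. Draws are
independent rather than paired (the estimand is identical; pairing would
only change higher-order Monte-Carlo error). Because the offset absorbs
both tissue-type and trophic-level differences, *changes* in Δ¹⁵N_f-j
between years for the same species and feather type are read as changes in
trophic position.

### Bayesian assignment

For one feather and each grid cell *i* with isoscape values `(c_i, n_i)`:

```
L_i = φ(δ13C_f ; c_i + Δ13C_fj, σ²C) · φ(δ15N_f ; n_i + Δ15N_fj, σ²N)
σ² (per isotope) = measurement² + between-individual + calibration-sd²
```

The isotopes are treated as independent (diagonal covariance): the three
variance components are themselves estimated marginally per isotope, and no
data are available to estimate a covariance. Isoscape prediction variance
is *not* included by default — the reference assignment conditions list
only the three terms above — but `include_isoscape_sd = TRUE` adds it where
kriging sd surfaces exist.

The posterior is the cellwise product of the (normalised) utilisation prior
and the likelihood, renormalised. Prior support is hard: a cell the
tracked population never used gets posterior zero, with no flooring. This
matches the restriction of the analysis to the study region and makes the
prior genuinely informative; the cost is that an individual that truly
foraged outside the population's utilisation area cannot be recovered.

### Likely region and overlap

The "likely region" is the smallest set of highest-posterior cells holding
30 % of the probability mass, ties broken by cell index. Applications of
this assignment approach often describe the same region by a threshold
odds ratio of 1.42 said to represent the highest 30 % of assignment
probabilities; since that odds-ratio computation is conventionally left
undefined, the mass-quantile reading is implemented here and 1.42 is
carried as metadata only. Between-year comparisons use the directional cell-count
overlap `100·|A∩B| / |reference region|`; the denominator is always the
reference (earlier) year, and tests assert that convention, because the
measure is not symmetric.

### Prey context

Prey isoscapes are built from tissue samples by ordinary kriging
(spherical-with-nugget variogram by default, fitted by weighted least
squares with Cressie weights `n_pairs/γ²`; 12 lag bins to half the maximum
distance). Kriging is done in lon/lat degrees with isotropic distances —
over a basin a few hundred km across the latitude-scaling anisotropy is
second-order, and the same convention is used consistently for fitting and
prediction. δ¹³C and δ¹⁵N are kriged independently. Lipid-rich tissue
(e.g. pipefish muscle) is δ¹³C-corrected from the C:N mass ratio by the
Kiljunen mass-balance normalisation before kriging; the correction is
strictly non-negative, increasing in C:N, and undefined below the protein
baseline C:N = 0.775/0.246 ≈ 3.15 (an error, not a silent pass-through).

Predator–prey spacing compares population-mean feather values with mean
prey-isoscape values over the likely foraging region; a δ¹⁵N difference
within 3.5 ± 1.0 ‰ is flagged "consistent with direct consumption". The
window operationalises a qualitative judgement and is exposed in the
arguments.

Comparison statistics are deliberately small and exact: a Yates-corrected
2×2 chi-squared (the correction is always applied — it is what reproduces
the reference values 0.17 and 2.39, where the uncorrected statistics 0.69
and 2.99 do not), and a Mann-Whitney U with mid-ranks, full enumeration of
all labelings for pooled n ≤ 12 and a tie-corrected normal approximation
above. CPUE maps average catch per hour per ICES statistical rectangle
(30′ × 1°, decoded from the standard letter–digit scheme) and display
`log10(mean + 1)`; unsampled rectangles are nodata, never zero.

## The synthetic world

The generator exists so every stage can be tested against known truth:

* **Isoscapes**: linear lat/lon gradients plus smoothed white noise
  (Gaussian blur, 0.5° smoothing length, 0.3 ‰ sd). Defaults put δ¹⁵N
  around 10.5 ‰ and δ¹³C around −17.5 ‰ mid-grid with ranges of a few ‰
  across the basin — the scale of the reference surfaces. A blurred white
  -noise field is *not* a formal geostatistical simulation; it provides
  spatial structure for testing, and the variogram/kriging tests use a
  proper Cholesky simulation instead.
* **Tracks**: a biased random walk from the colony (−2.57°E, 56.19°N)
  towards a per-individual wintering centroid (drift 30 km/day capped at
  the remaining distance, step noise 20 km/day), July–March, then
  independent per-axis Gaussian observation error of 186/√2 km so the
  radial RMS error is the stated ±186 km.
* **Feathers**: isoscape value at the individual's true centroid + group
  trophic offset + `Normal(0, individual sd)`. Offsets (1.74–6.30 ‰ δ¹⁵N)
  and sds (0.5–1 ‰) follow the study populations' scales.
* **Two-winter contrast**: a "stay" species keeps its centroid but drops
  its δ¹⁵N offset from 4.63 to 1.74 ‰ in the poor winter (diet switch); a
  "move" species keeps a near-constant offset (6.13 → 6.30 ‰) but shifts
  its centroid ~450 km. Ten individuals per group by default, matching the
  study's 9–17.

What a green end-to-end test establishes: the pipeline recovers *injected*
movement and diet contrasts when the data are generated by the model it
assumes. What it does not establish: robustness to real-data features the
generator omits — individual foraging-site specialisation, moult-timing
variation between individuals, temporally varying baselines, non-Gaussian
geolocation error near equinoxes, or prior/feather mismatch when birds
moult outside the tracked season.

Two synthetic-world conventions deserve a note. First, the end-to-end
scenario's residency polygon is padded beyond the grid: with ±186 km
observation error, *some* fix of a full winter track is near-certain to
fall outside a tightly drawn box, which would exclude every simulated
individual; padding makes the gate test centroid eligibility, while the
residency operation itself is unit-tested against the tight polygon.
Second, the assignment moult window for the synthetic species is set to
November–February, the months the simulated walks occupy their wintering
centroid, so the prior and the feather-origin model refer to the same
place — the same consistency the real analysis gets from choosing
feather-specific moult windows.

## Numerical choices

* Posteriors must sum to 1 within 10⁻⁹; an identically zero
  prior-likelihood product (disjoint support) is an error, not a silent
  uniform.
* A likelihood that underflows to zero everywhere (feather far outside
  isoscape support) warns rather than errors — in population batches one
  aberrant feather should not kill the run, and the posterior stage will
  error if it truly cannot proceed.
* `likely_region` tie-break is ascending cell index, making regions
  deterministic on flat posteriors.
* Kriging with zero nugget and duplicated coordinates is singular; the
  policy (`error` or deterministic tiny `jitter`) is explicit. Negative
  kriging variances from round-off are clamped to zero.
* The speed filter is a forward scan from the last *retained* fix —
  a contraction and idempotent, both asserted as properties.
* All generators and Monte-Carlo stages take explicit seeds; reruns with
  the same seed are bit-identical.
* Min-max scaling of a constant surface and bandwidths of degenerate
  (zero-spread) samples are errors, because each silently produces
  meaningless downstream comparisons.

## Known limitations

* The calibration offset is population-level; individual specialisation is
  absorbed into the between-individual variance term.
* Hard prior support means assignment quality is bounded by geolocator
  coverage of the true moult area.
* The kriging neighbourhood is global (all samples per prediction), fine
  for dozens of samples, quadratic beyond that.
* Isotopes are assumed conditionally independent given location; a shared
  baseline driver could correlate them.
* The odds-ratio constant 1.42 is reported but never used in computation;
  if the original odds construction differed materially from the top-30 %
  mass region, region sizes (not orderings) would differ.
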