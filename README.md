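# isotrack

Dual-tracer inference of winter foraging location and trophic position for
marine predators, combining **light-level geolocator tracks** with
**feather stable isotopes** (δ¹³C, δ¹⁵N) against reference **isoscapes**.

Seabirds such as auks moult at sea in winter, when mortality is
concentrated and observation is hardest. Geolocators say roughly *where* a
population was (±186 km); feather isotopes say *what* was assimilated
while the feather grew — but confound the spatial baseline with trophic
level. `isotrack` implements the standard dual-tracer resolution of that
confound, for anyone comparing non-breeding foraging strategies between
years, populations or sympatric species:

1. **Tracks** — equinox and speed filtering of fixes, moult-window
   residency gating, Gaussian kernel utilisation surfaces (exact kernel
   sum at 0.1° cell centres, normal-reference bandwidth), scaled
   difference maps and directional percentage overlap.
2. **Isoscapes** — dual-isotope raster container, prey isoscapes by
   ordinary kriging (WLS spherical variogram with Cressie weights), and
   Kiljunen C:N lipid normalisation of δ¹³C.
3. **Assignment** — population calibration offsets
   Δ_f-j = feather − isoscape by 1000-draw Monte Carlo over the
   KDE-masked isoscape; per-cell bivariate-normal likelihood with total
   variance `measurement² + between-individual + calibration-sd²` per
   isotope; posterior = prior × likelihood renormalised; top-30 %
   probability-mass "likely regions"; population-summed surfaces and
   between-year region overlaps.
4. **Trophic statistics** — Yates-corrected 2×2 chi-squared, exact
   (enumerated) Mann-Whitney U for pooled n ≤ 12, predator–prey isotopic
   spacing against a 3.5 ‰ δ¹⁵N trophic step, and
   `log10(CPUE/hr + 1)` gridding on ICES statistical rectangles.
5. **Synthetic data** — seeded generators for isoscapes, biased-random
   -walk winter tracks with ±186 km geolocation error, and feathers =
   baseline + trophic offset + individual noise, with ground truth
   retained so every stage is testable end to end.

## Worked example

Simulate the package's two-winter contrast — a "stay" species that keeps
its wintering area but switches diet, and a "move" species that relocates
~450 km — then run the full pipeline and recover both contrasts:

```r
library(isotrack)

out <- two_winter_recovery(seed = 42, n_individuals = 8, resolution = 0.5)

out$results$stay_body_201415$offset
#> <calibration_offset> D13C_f-j = -0.65 (sd 0.81), D15N_f-j = 5.19 (sd 1.02), 1000 draws

sprintf("stay between-winter overlap: %.1f%%", out$stay_overlap)
#> "stay between-winter overlap: 90.5%"
sprintf("move between-winter overlap: %.1f%%", out$move_overlap)
#> "move between-winter overlap: 0.0%"
sprintf("stay offset change: %.2f permil (injected %.2f)",
        out$stay_offset_change, out$injected_change)
#> "stay offset change: 3.03 permil (injected 2.89)"
```

The derived calibration offset (here δ¹⁵N 5.19 ‰) is the population's mean
isotopic elevation above the reference isoscape — a proxy for trophic
position. The species that stayed put shows ~90 % overlap between its two
winters' likely foraging regions; the species that moved shows 0 %. The
diet-switching species' derived δ¹⁵N offset changes by 3.03 ‰ between
winters against 2.89 ‰ injected.

Classical comparisons come along for free:

```r
r <- yates_chisq(c(6, 4, 6, 8))   # winters x (left, stayed) counts
sprintf("chi-sq = %.2f, p = %.2f", r$statistic, r$p_value)
#> "chi-sq = 0.17, p = 0.68"
```

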