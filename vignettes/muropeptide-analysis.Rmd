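---
title: "Peptidoglycan composition, protein localization and PBP titration analysis with muroquant"
author: "muroquant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peptidoglycan composition, protein localization and PBP titration analysis with muroquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muroquant)
```

# Scope and models

muroquant analyzes three assay families that together characterize a
bacterial cell wall and one of its remodeling enzymes: muropeptide LC–MS
quantification with peptidoglycan (PG) summary statistics, single-cell
fluorescence localization profiling, and Bocillin-FL binding titrations.
Every stage has a synthetic-data generator with known ground truth, so the
whole pipeline is testable without any external data.

## Muropeptide mass library

A muramidase digest of PG yields muropeptides: GlcNAc–MurNAc disaccharides
carrying stem peptides, possibly crosslinked into dimers, trimers and
tetramers. The library enumerates linear oligomers (order 1–4) over a
configurable set of stem lengths (di- to pentapeptides assembled from
L-Ala, D-iGlu, meso-DAP, D-Ala), with 0 to *order* 1,6-anhydro-MurNAc
termini and optional borohydride reduction.

Masses are sums of condensed-residue monoisotopic masses with condensation
bookkeeping: one water per subunit, minus one water per crosslink, minus one
water per anhydro ring, plus 2 H per reduced free reducing end. Anhydro
termini carry no free reducing end and are never reduced. Monoisotopic
atomic masses are hard-coded to at least six decimals; positive-mode m/z is
$(M + z\,m_p)/z$ with $m_p = 1.007276$ Da. The test suite checks every
library mass against an independently coded elemental-formula oracle that
assembles the full molecular formula from free building blocks and converts
to mass once; agreement is required to $10^{-4}$ Da.

Design notes:

* Only the Gram-negative canonical chemotype is enumerated (D,D 4–3
  crosslinks; no amidation, acetylation or glycine substitutions).
  The in-house libraries used by vendor software are not published, so this
  scope is a reconstruction, and is flagged as such.
* Branched topologies are excluded: a linear chain has the same crosslink
  count, hence the same mass, so quantification is unaffected.
* Naming (`M4`, `D43`, `T444N`, …) is a package convention: oligomer letter,
  stem lengths in descending order, one `N` per anhydro terminus.
* Stem multisets such as {5,3} and {4,4} contain the same residues and are
  therefore exactly isobaric (`D53` vs `D44`). Mass alone cannot separate
  them; matching uses retention times when the library carries them, which
  is how such pairs are resolved in practice.

## EIC quantification

`extract_eic()` sums centroid intensities within a ±ppm window per scan
(default 10 ppm, appropriate for a Q-TOF). `match_run()` locates each
species' apex, takes the contiguous region above 5% of the apex as the peak,
and integrates by trapezoid after subtracting the window minimum as
baseline. The boundary walk may step over up to 2 consecutive sub-threshold
scans: in centroided data, mass noise occasionally pushes a single scan's
centroid outside the m/z window, and without gap tolerance such dropouts
would truncate peaks. Per species, the best charge state (z = 1–3) by area
is kept, so each species yields at most one identification.

The 5%-of-apex boundary and minimum-baseline rules remove a fixed fraction
(about 11%) of a Gaussian peak's area. Because the removal factor is
identical for species with equal peak widths, it cancels exactly in the
molar normalization, which is the only quantity used downstream. Molar
percentages assume equimolar detector response across muropeptides — a
stated assumption, not a measurement.

## PG summary statistics

From a quant table resolved against the library:

* oligomer percentages: sums of molar percentages by oligomer order;
* anhydro percentage: sum over species with at least one anhydro terminus,
  each species counted once (`count_termini = TRUE` weights by terminus
  count instead);
* crosslinks (per 100 species): $D + 2T + 3Q$ — a linear $n$-mer carries
  $n-1$ crosslinked bonds;
* mean glycan chain length: $100 / \text{anhydro}\%$, because every glycan
  strand ends in exactly one 1,6-anhydro-MurNAc.

Reports round half-up to two decimals; underlying values keep full
precision. The oligomer percentages must sum to 100 within 0.05 by default,
loose enough to accept published tables rounded to two decimals.

The reciprocal-anhydro estimator is exact when each detected species is a
single disaccharide unit. When units are bound into crosslinked oligomers
and anhydro species are counted once each, a dimer holding two units still
counts once, biasing the estimate low. This is a property of the field
formula itself; the estimator-recovery tests therefore run the digestion
simulator with monomer-only probabilities, the estimator's stated premise.

## Single-cell localization profiling

Cells are segmented from phase contrast by global Otsu threshold (dark on
light), 8-connected components, discarding objects under `min_area_px` or
touching the border. Per cell:

* principal axes from the second moments of the pixel coordinates; length
  and width are the projection extents (span + 1 pixel footprint) on the
  major/minor axes, length assigned to the larger;
* volume from a rod model — cylinder of diameter $w$ with hemispherical
  caps, $V = \pi (w/2)^2 (l - w) + \tfrac{4}{3}\pi (w/2)^3$ — matching
  cells that widen before dividing; a sphere is the $l < w$ fallback;
* total fluorescence = background-subtracted sum over the mask, clipped at
  0 per pixel; background defaults to the density-mode of non-cell pixels;
* axis profiles: pixel projections min–max normalized to [0, 1], binned
  (100 bins), fluorescence summed per bin, profile normalized to unit sum.
  Orientation is deterministic but arbitrary: the end with the lower mean
  image row is position 0 (no attempt is made to identify the host-attached
  pole). Profiles are per-cell unit-normalized *before* group averaging, so
  bright cells do not dominate the group mean.

Population grouping sorts by width or area and splits by fractions. Integer
group sizes are the half-up rounding of each quota with the final group
absorbing the residual; this convention reproduces a 60/20/10/10 split of
1258 cells as (755, 252, 126, 125) and of 10 cells as (6, 2, 1, 1).

`count_profile_peaks()` smooths with a 3-bin moving average and counts local
maxima (plateaus once; profile ends may be maxima) whose topographic
prominence reaches 0.2 of the smoothed maximum. An exactly flat profile has
no local maxima and returns 0.

## Titration quantification

Lane intensities are normalized per replicate to that replicate's
zero-concentration control, then averaged (sd with denominator $n-1$; a
single replicate reports sd 0 and a flag). Classification: *enhancement* if
the mean relative binding at the top concentration is ≥ 1.2; else
*inhibition* if any concentration falls to ≤ 0.5; else *weak*. Both
thresholds are package defaults exposed as arguments — the biology they
encode (binding improved at high dose, consistent with an allosteric
site) is qualitative. IC50 is interpolated linearly on log-concentration
between the bracketing points rather than fitted: with duplicate gels a
4-parameter fit is unstable, while interpolation is monotone and
assumption-free. If the first nonzero concentration is already below 0.5
its value is returned as an upper bound; a curve never reaching 0.5 has
IC50 `NA`.

# Synthetic generators: what they emulate

All generators take an explicit integer seed and are deterministic under
it; ground truth is always returned alongside the data.

* `gen_strands()` draws glycan strand lengths from a geometric distribution
  (memoryless termination — the simplest model with exactly one anhydro
  terminus per strand). `digest_strands()` partitions the units into
  oligomer species by drawn order probabilities and scatters the anhydro
  termini uniformly over units, emitting realized molar percentages plus
  directly counted crosslinks per 100 species — the counting oracle for the
  crosslink formula.
* `gen_lcms_run()` renders Gaussian elution peaks (sd 0.05 min, scan every
  0.25 s, 18-min run) with multiplicative ppm mass noise per centroid and a
  per-species amount CV. It does not simulate isotope envelopes, adducts,
  in-source fragmentation or chromatographic tailing.
* `gen_cell_images()` places non-overlapping capsule cells (widths following
  a right-skewed population in 0.66–1.50 µm in which 60% of cells fall
  below ~1.03 µm, as in a population dominated by young cells; mean length
  2.4 µm; pixel size 0.0645 µm, a 6.45 µm camera pixel behind a 100×
  objective). Fluorescence follows the localization model: two Gaussian
  polar foci centered on the pole caps whose weight hands over to a medial
  septal band as width grows (logistic in width, midpoint 1.08 µm,
  steepness 20 µm⁻¹), total signal = density × rod volume (constant
  density 5000 a.u. µm⁻³ by default), plus camera background and Gaussian
  read noise. No PSF/optics simulation, no cell-to-cell expression
  variability, no debris or uneven illumination — passing tests demonstrate
  correctness of the measurement code on idealized rods, not robustness to
  real micrograph artifacts.
* `gen_titration()` renders log-logistic inhibition
  ($1/(1+(c/\mathrm{IC50})^h)$) or saturating enhancement
  ($1 + a\,c/(c+K)$) with multiplicative lane noise, 7 concentrations over
  4 decades and duplicate replicates by default.

# Numerical choices and degenerate inputs

* Trapezoidal integration via `pracma::trapz`; EIC windows are relative
  (ppm), symmetric around the target.
* Eigen decomposition of the 2×2 pixel covariance gives the axes; masks
  under 5 pixels are rejected, and a zero-variance projection (1-pixel-wide
  line on its short axis) is an explicit error.
* Profiles with no signal above background error rather than returning a
  0/0 normalization.
* An exactly flat EIC integrates to 0 (baseline equals the trace);
  all-zero identification sets refuse to normalize.
* `round_half_up()` is used for reported tables because R's `round()` is
  round-half-even.
* Problem sizes in the test suite: 400 cells at 1024² px for the
  population-level imaging properties, 5000 strands for estimator recovery,
  200 seeded titrations for IC50 coverage — large enough that the checked
  bands (2 standard errors; 95% coverage) are meaningful for a population
  study of this kind.

# Known limitations

* Equimolar MS response is assumed; per-species response correction would
  need standards the package does not model.
* Isobaric stem combinations require retention times to separate; matching
  a library without RTs will co-identify them against one peak.
* The chain-length formula inherits the field's per-species anhydro
  counting bias under oligomerization (see above).
* The volume model is geometric; deeply constricted cells violate the
  single-capsule assumption and will be measured as one rod until they
  separate.
* Segmentation is a global threshold: it expects reasonably uniform
  illumination and non-touching cells.
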