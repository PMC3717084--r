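---
title: "From infrared band areas to QTLs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From infrared band areas to QTLs: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ftirqtl` implements a complete phenotyping-to-mapping chain for
ATR-FTIR spectra of mouse tissue measured across a two-allele
recombinant-inbred (RI) panel. This vignette documents the statistical
models, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the design decisions taken where
the problem was genuinely open. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## 1. Spectral model and preprocessing

A spectrum is absorbance on the canonical ascending grid 600–4000 cm⁻¹ at
1 cm⁻¹ spacing (3401 points); any input is linearly interpolated onto this
grid at read time, and descending instrument axes are reversed. All band
windows are interpreted on this grid, borders inclusive.

**Water-vapor correction.** Residual vapor appears as narrow rotational
lines superimposed on broad tissue bands. The in-house vendor routine the
field uses is not publicly available, so the corrector here subtracts
`α · reference` where the reference is a fixed comb of narrow
(σ = 1.3 cm⁻¹) lines in 1300–1900 cm⁻¹ and α minimizes the summed squared
second differences of the corrected spectrum over that window. Because
tissue bands are 10–80 cm⁻¹ wide, nearly all second-difference energy in
the window is vapor, and the closed-form least-squares α recovers a
planted coefficient to three decimals on noiseless input (asserted in the
tests). The substitution keeps the intent — remove sharp vapor structure
with a single fitted coefficient — while being fully testable against
planted artifacts.

**Quality test.** Three deterministic criteria with defaults calibrated
*once* against the generator's stated artifact levels and not revisited:

| criterion | statistic | default |
|---|---|---|
| intensity | global max absorbance | within [0.01, 10] |
| vapor residual | RMS second difference, 1837–1847 cm⁻¹ | ≤ 2e-3 |
| signal-to-noise | peak amide amplitude ÷ RMS of detrended 2000–2200 cm⁻¹ | ≥ 50 |

The 2000–2200 cm⁻¹ segment is biologically silent, so its detrended RMS
estimates the noise floor; the vapor score's floor is `noise_sd·√6`
(second differencing triples white-noise variance twice), which is why the
generator's default noise of 2e-4 AU — the order of a 32-scan co-added ATR
measurement — matters: at ten times that noise no vapor threshold can
separate clean from vapor-laden spectra.

**Normalization.** Min-max scaling computed on the amide window
(1500–1700 cm⁻¹) and applied to the whole spectrum, so the window spans
[0, 1] afterwards. Whether the original workflow took the extrema over the
window only or globally is ambiguous in the literature; the window reading
is used because it pins the dominant protein bands to a common scale for
every tissue, and it is documented here as this package's reading, not
asserted as the original one. The operation is idempotent and invariant
under positive affine transforms of the input (property-tested).

**Order.** The pipeline order is fixed: correct → quality test →
normalize → average (replicates → sample means → strain means). Averaging
and normalization do not commute except in degenerate cases, so the order
is asserted by an integration test rather than assumed.

## 2. Band integration and the trait menu

A band area is the signed trapezoidal integral of
`absorbance − baseline` over `[lower, upper]`, with the baseline the
straight line joining the spectrum's (interpolated) values at the two
borders. This is an emulation of endpoint-anchored "method B" vendor
integration, not a bit-match: the vendor's clipping behaviour for
negative lobes is undocumented, and the unclipped signed integral is used
because it makes the operator exactly linear in the spectrum and
invariant to constant offsets — both asserted as property tests. Borders
falling between grid points are interpolated; the integral runs border to
border.

The per-tissue windows, composites (A_FAT, A_SATF, A_UNSATF, A_COL,
A_PROT, A_GLYC) and ratios ship as one versioned TSV
(`inst/extdata/band_registry.tsv`) that a snapshot test compares
cell-for-cell against the published border set. Adipose carries 8 traits
(including unsaturated fat at 3006 cm⁻¹ and the saturated-to-unsaturated
ratio); liver and muscle carry 7 (glycogen instead). One published muscle
protein row contains an obvious typographical variant of "A1340"; it is
implemented as A1340, consistent with the muscle collagen definition.

## 3. Trait statistics

**Winsorization.** Outliers are values with |z| > 3 where z uses the mean
and SD over *all* animals of all strains for the trait (a single mean, as
the field describes it), replaced once by the nearest non-outlier value on
the same side, without recomputation. Note an arithmetic consequence: with
a sample of n values the largest attainable sample z is (n−1)/√n, so no
value can be flagged below n = 11; winsorization is only operative at
panel scale. Whole-strain exclusions (e.g. a tissue whose mean spectrum
failed QC) are applied after value-level winsorization.

**Heritability.** Broad-sense H² = clip((Vp − Ve)/Vp, 0, 1), with Ve the
df-weighted pooled within-strain variance of isogenic groups and Vp the
variance of RI animal-level values. The classical source names the method
but not the variance partition; animal-level Vp is the default
(`vp_scope = "strain_means"` is available) because it is the scale on
which Ve is estimated. In `run_pipeline()` the isogenic groups are the RI
strains themselves — every fully inbred strain is isogenic — since the
synthetic study contains no parental/F1 groups; the exported
`broad_sense_heritability()` accepts arbitrary isogenic groups when
parental data exist.

**Correlations.** Pearson r on strain means, pairwise-complete, two-sided
p from the t transform, Holm adjustment by default (Bonferroni by
argument). Holm is chosen because it is uniformly more powerful at the
same family-wise error and needs no independence assumption.

## 4. QTL mapping

The scan is single-marker regression on strain means — not interval
mapping at pseudomarkers — because with fully inbred strains and a dense
map the marker-regression likelihood-ratio statistic
`LRS = n·ln(RSS₀/RSS₁)` is the field's reporting convention. The identity
`LRS = −n·ln(1−r²)` gives an independent correlation-path oracle; the
acceptance suite holds the two paths to 1e-9 over 200 random panels.
LOD = LRS/(2·ln 10); the familiar 4.6 factor is display rounding of
2·ln 10 ≈ 4.605.

Numerical/degenerate choices: strains with missing genotype are dropped
at that marker (deletion, not imputation — the historical behaviour is
unknown, and deletion is the conservative choice); markers with fewer
than two strains per genotype class are skipped with a flag; a perfect
fit (RSS₁ = 0) is reported as a capped LRS of 1e4 with a `perfect_fit`
flag so permutation maxima stay finite. Strain means are unweighted: the
per-strain n varies only between 4 and 5 and no weighting convention is
documented for the original scans.

**Thresholds.** Per trait (not pooled), phenotype labels are permuted
`n_perm = 1000` times; the genome-wide significant (p < 0.05) and
suggestive (p < 0.63) LRS thresholds are the order statistics at
`ceil(0.95·n_perm)` and `ceil(0.37·n_perm)` of the max-LRS sample. On
complete panels the permutation scan runs through one centered
cross-product (`crossprod`) per trait, which is what keeps 400-trait
calibration runs in the acceptance suite tractable. The calibration
criterion — empirical genome-wide type-I error within 3 binomial SEs of
0.05 — is recomputed, not assumed.

**Support intervals.** 1.5-LOD = 6.9-LRS drop from the chromosome peak,
with each bound placed by linear interpolation in position between the
bracketing markers and truncated at chromosome ends. The additive effect
is half the difference of the homozygous class means, reported as a
magnitude plus the increasing allele; the signed value is kept as an
attribute.

## 5. The synthetic world

The generator is a stated world, not a tuning dial; its defaults are the
study design it emulates: 30 RI strains, 4–5 males per strain, 3
technical replicates per sample, two-allele homozygous genotypes.

* **Genotypes.** Marker mosaics are a Markov chain along each chromosome
  whose adjacent-marker discordance is the Haldane–Waddington RI
  expansion R = 4r/(1+6r) of the Haldane recombination fraction implied
  by the marker spacing. Breeding is *not* simulated
  generation-by-generation: the marginal adjacent-marker law is identical
  and the direct construction is orders of magnitude cheaper. Higher-order
  (three-marker) RI haplotype probabilities are therefore approximate —
  a deliberate non-goal.
* **Phenotypes.** Component amplitude = mean + Σ(±1 allele code ×
  additive effect) + strain deviate + animal deviate, floored at zero.
  ±1 coding makes the class-mean difference 2a, matching the convention
  of reporting the additive effect as half the class difference. Ground
  truth (QTL marker, deviates) is retained for recovery tests.
* **Spectra.** Sum of per-component Gaussian sub-band mixtures at the
  standard band positions, plus a linear baseline, a fixed vapor comb
  scaled by one coefficient, and white noise. Gaussians are used because
  no line shape is published and the Gaussian integral A·σ·√(2π) gives a
  closed-form oracle for the integrators. Component means make adipose
  lipid-dominated and liver/muscle protein-dominated, as in real tissue.

What the generator does **not** emulate — and hence what a green test
does not establish: ATR penetration-depth wavelength dependence,
Mie/baseline curvature beyond linear drift, CO₂ bands, instrument drift
between replicates, dominance or epistasis, linkage disequilibrium
between chromosomes, and real BXD haplotype block structure. Recovery
rates measured here are for the stated world, not a promise about any
particular instrument or panel.

## 6. Candidate filtering

The original cascade queried live databases; here every filter is a pure
predicate over a user-supplied annotation table so the cascade is
deterministic and offline. "Density" of nsSNPs/InDels is implemented as a
count threshold (default ≥ 1) since no density formula is published, and
"known or presumed gene function" plus "biological relevance" are one
keyword filter (the published enumeration is ambiguous between five and
six predicates beyond location). The retained set is monotone in the
variant threshold, which is property-tested.

## 7. Known limitations

* The vapor corrector assumes the contaminating comb is proportional to
  the reference; instrument-to-instrument vapor line-ratio variation is
  not modelled.
* Quality thresholds are calibrated to the generator's artifact levels;
  real instruments need a one-time recalibration through
  `default_quality_thresholds()`-shaped configs.
* The permutation scan's fast path requires a complete genotype matrix;
  panels with missing calls fall back to a per-marker loop.
* H² from RI-only designs uses within-strain replicates as the isogenic
  groups; with few animals per strain Ve is noisy and H² estimates are
  mildly conservative near the boundary (clipping at 0 and 1 biases the
  mean inward).
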