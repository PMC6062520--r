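---
title: "Methods: whole-cell MALDI-TOF drug-response marker discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-cell MALDI-TOF drug-response marker discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`wcmaldi` implements an automated workflow for discovering and quantifying
lipid/metabolite drug-response markers in whole-cell MALDI-TOF mass
fingerprints: raw profile spectra are reduced to a binned feature matrix,
drug-sensitive features are isolated by a two-step filtration (variance
thresholding, then concentration-response fitting), potencies are reported
as pIC50 values, and candidate m/z features are annotated by accurate-mass
arithmetic against a compound table. A synthetic-spectrum generator with
planted ground truth makes every stage testable without instrument data.

## Preprocessing model

Each spectrum is a profile (m/z, intensity) pair. The chain is applied in a
fixed order:

1. **TIC normalization.** Intensities are divided by their sum. All
   downstream statistics are therefore relative; a global intensity scale
   carries no information in MALDI.
2. **Top-Hat baseline.** The baseline is the grey-scale morphological
   opening (erosion, then dilation, flat structuring element of
   `2 * half_window + 1` points; default half-window 75 points). The opening
   never exceeds the signal, is idempotent, and removes every structure
   narrower than the element — so the element must be several peak widths
   wide. Implemented with the van Herk block algorithm (exact, O(n)).
   Because window dominance is undefined at the array ends, peaks are not
   reported within one half-window of the spectrum edges.
3. **Noise and peak picking.** The noise curve is `1.4826 ×` the running
   median of absolute baseline-corrected intensities, the MAD-consistent
   scale estimate for Gaussian noise, floored at `1e-12 ×` the maximum
   intensity. The noise half-window (default 250 points) is deliberately
   much wider than the peak-picking dominance half-window (default 20
   points, matching common TOF practice): a median computed on a
   peak-width-sized window follows the peak flanks and destroys the
   signal-to-noise ratio at exactly the apexes one wants to keep. Peaks are
   strict local maxima within the dominance window with SNR > 5.
4. **Binning.** Peaks of all spectra are pooled, sorted, and recursively
   split at the largest internal gap until every bin spans at most a 0.002
   *relative* m/z width and holds at most one peak per sample. The relative
   reading of the 0.002 tolerance matches the convention of the binning
   implementations used for TOF biotyping (at m/z 800 it is 1.6 Da, i.e.
   unit-resolution features such as "m/z 826.6"); an absolute 0.002 Da
   reading would be narrower than one grid step of typical exports.
   Bin centers are member means; absent peaks are stored as 0, not NA,
   because the variance filter and the curve fits need complete columns.

## Two-step marker filtration

**Step 1 — variance filter.** Per-feature sample variances are computed on
the TIC-normalized (not square-root-transformed) matrix; the square-root
transform is reserved for multivariate analysis. Because most features do
not respond to drug, the variance histogram is right-skewed and its
arithmetic mean sits right of the mode; features strictly above the mean are
kept. Note the dilution behaviour: adding inert (near-zero-variance)
features *lowers* the mean threshold, so the kept set can only grow — the
filter is conservative in feature-rich matrices and is meant as a cheap
pre-filter, not a significance test.

**Step 2 — concentration-response fits.** Technical replicates are averaged
per (compound, concentration, biological replicate). Each candidate feature
is fitted per biological replicate with the four-parameter logistic

$$f(x) = \mathrm{top} + \frac{\mathrm{bottom} - \mathrm{top}}
{1 + 10^{(\mathrm{LogIC50} - x)\,\cdot\,\mathrm{HillSlope}}}$$

where $x$ is log10 molar concentration (descending form; the ascending form
swaps top and bottom). Biphasic curves — rising signal collapsing under
overt toxicity at high dose — are handled by truncation: all concentrations
after the (last, on ties) maximal point are excluded before the ascending
fit, and a curve must retain at least five points. Each feature is fitted
both ways (descending on the full series, ascending on the truncated one)
and the higher-R² fit defines its direction; on noise-free data the
generating direction always wins, which the test suite asserts.

A feature is a **marker** when at least `n_reps_required` (default 3)
biological replicates were fitted, every replicate fit reaches `r2_min`
(default 0.9), and all share one direction. Potency is reported as
pIC50 = −LogIC50.

### Numerical strategy

For fixed (LogIC50, HillSlope) the plateaus enter linearly, so they are
profiled out exactly by a constrained 2-variable least-squares solve (KKT
candidate enumeration under top, bottom ≥ 0 and the direction's plateau
ordering). The remaining 2-parameter surface is minimized by bounded
L-BFGS-B from a 3 × 3 multi-start grid (HillSlope ∈ {0.5, 1, 2} ×
LogIC50 ∈ {min, median, max of x}); ties go to the smaller HillSlope.
Bounds — LogIC50 within the dose range ± 2 decades, HillSlope in
[0.05, 10] — stop plateau-only degeneracies. Failures (too few points,
constant response, no converged start) are returned as flagged objects with
R² = −∞, never thrown, so a screen over thousands of features cannot abort.
An independent dense grid search over the same profiled surface agrees with
the optimizer's SS_res to below 1e-6 in the tests.

**Vehicle handling.** A zero concentration cannot enter a log axis. By
default vehicle rows anchor the no-drug plateau at
`log10(lowest nonzero dose) − 2` decades — far enough below the lowest dose
that the logistic is flat there, close enough to keep the optimizer scale
sane; excluding vehicle rows entirely is a configuration option. The choice
only matters when vehicle data exist and the lowest dose is not already on
the plateau.

## Multivariate scores

PCA is computed by SVD of the column-centered (never variance-scaled)
square-root-transformed matrix. Group separation is summarized by a scatter
ratio `J = trace(S_between) / trace(S_within)`; it is invariant to rigid
rotations of score space and grows monotonically with inter-group mean
separation. It is used only for *ranking* preparation protocols, so only
this monotone behaviour matters; the same holds for the matrix-suppression
score `MSE_mod = 1 − (TIC share within ± 0.002 relative of any matrix
ion)`, computed here against a DHB cluster-ion default list
(user-overridable) and best applied to baseline-corrected spectra so the
chemical pedestal does not dilute the share. Both scores are documented
surrogates built from their published intent (higher = better separated /
better suppressed), not reimplementations of any specific published
formula.

## Accurate-mass annotation

Monoisotopic masses are summed from most-abundant-isotope IUPAC masses;
adduct m/z values book the electron mass explicitly (proton 1.007276 Da;
`[M+K]+` adds 38.963707 − m_e; the radical cation subtracts m_e =
0.000549 Da). ppm errors use the theoretical mass as denominator
(convention). Candidate hits are every (compound, adduct) pair within
3 ppm, ranked by error; lipid records carrying an odd acyl-carbon count are
excluded (even-chain biosynthesis rule) — the rule touches only records
with acyl metadata. Isotope patterns are exact convolutions over natural
abundances aggregated by nucleon number (no fine structure), truncated to
the monoisotopic peak upward; note that elements whose most abundant
isotope is not the lightest (Fe) have physical M−2 intensity that this
truncation ignores by design. CID fragments are assigned by neutral-loss
combinations (default depth 2, e.g. two CH₂COOH side-chain losses of heme
B, 59.0133 Da each, or the trimethylamine loss of phosphocholine,
59.0735 Da) within 1.5 mDa.

One caveat shipped as documentation rather than "corrected": printed
calibrant `[M+H]+` values in the source literature for this workflow (e.g.
sorafenib 463.0779) sit ≈ 2.016 Da below the proton-adduct masses computed
from the published formulas, consistent with `[M−H]+`-type species; the
bundled compound table stores formulas, and users choose adducts
explicitly.

## The synthetic-data generator

`simulate_experiment()` emulates reflector-positive whole-cell acquisitions
over m/z 200–2,000 on a uniform 0.02 Th grid: Gaussian peaks with FWHM =
m/z / 1000, an exponentially decaying chemical baseline on a constant
pedestal (real profiles never fall to exact zero — an earlier pedestal-free
draft broke the median noise estimator precisely because half the points
were exact zeros), DHB-like matrix cluster ions suppressed as
`1 / (1 + k · load)`, and additive Gaussian detector noise. The default
experiment matches the emulated study design: 8 half-log doses up to 30 µM,
8 technical replicates (lognormal, 15% CV), 3 biological replicates
(lognormal, 10% CV), one descending marker at m/z 826.57 with LogIC50
−6.5 and ~3.6-fold dynamic range, one biphasic marker at m/z 616.18
(ascending limb LogIC50 −6.5, toxic collapse 1.2 decades later), and
twelve inert lipid peaks. The working protocol is modeled at 5,000 cells
per spot (`cell_load = 5` reference units), at which matrix ions are
strongly suppressed — mirroring the optimization result that motivates the
suppression score. `simulate_cell_dilution()` scales analyte load with
cell count so the suppression score rises and saturates (plateau by about
5,000 cells under the defaults).

What the generator does *not* emulate: TOF flight-time (sqrt-spaced) m/z
grids, isotope envelopes in the profiles, m/z miscalibration between
spectra (the emulated workflow recalibrates in vendor software before
export), detector saturation, and chemical noise correlations. Passing
tests therefore demonstrate correctness of the computational chain under a
realistic noise model, not robustness to calibration drift or to
ion-suppression interactions between analytes.

## Problem sizes used in validation

The recovery battery runs 20 simulated experiments at the full default
scale (192 spectra of 90,001 points each per experiment) and requires the
planted descending marker to be called in ≥ 18 of 20 with median absolute
pIC50 error ≤ 0.2; unit tests use a reduced window (m/z 250–900, 0.05 Th)
that preserves all physics at lower cost. These sizes were chosen as the
smallest that exercise every code path at the study's replicate structure.

## Known limitations

- The variance threshold is a heuristic; features responding weakly on a
  high-variance background are lost before fitting.
- R² as fit-quality gate is scale-free but blind to structured residuals;
  no confidence intervals on pIC50 are computed (matching the emulated
  workflow).
- Direction classification by best R² can flip on very noisy, nearly flat
  series; such features fail the reproducibility gate in practice.
- Binning is global; systematic inter-spectrum m/z shifts larger than the
  relative tolerance would split features (recalibration is assumed
  upstream).
- Annotation is offline against a user compound table; no database
  queries, charge states beyond ±1, or fragmentation trees.
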