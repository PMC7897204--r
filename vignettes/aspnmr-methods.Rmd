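---
title: "Detecting aspartate degradation products by NMR fingerprinting: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting aspartate degradation products by NMR fingerprinting: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aspnmr)
```

## The measurement model

A ¹H-¹³C HSQC spectrum of a *denatured* protein collapses every residue of
one type onto essentially one set of cross-peaks at its random-coil
position. Degradation products of aspartate — a C-terminal Asp and an
N-terminal residue left by Asp-Xaa backbone cleavage, and isoaspartate or
its succinimide precursor formed by isomerization — are chemically distinct
residue types and therefore produce their *own* random-coil cross-peaks. If
such a peak falls outside the envelope of the 20 standard amino acids it is
an unambiguous, sequence-independent detector of the modification, and its
integral relative to the intact counterpart estimates the modified fraction.

`aspnmr` implements this logic in four layers: a pH-aware reference shift
library, Henderson–Hasselbalch titration models, peak-list matching and
calling, and a synthetic-data generator that provides ground truth for
validation.

## Reference library

The library stores measured random-coil shifts of six species — C-terminal
Asp, N-terminal Pro, internal Asp and Pro (within an Asp-Pro motif), isoAsp
and succinimide — at the two anchor conditions pH 2.3 and 7.4 in 7 M
urea-d₄/D₂O, plus their pKa values. Succinimide, N-terminal and internal
proline shifts change by ≤ 0.03 ppm between the anchors and are treated as
pH-independent; predictions for them return the neutral-pH entry (for the
one entry measured only at pH 2.3, the succinimide carbonyl, the acidic
entry is returned).

For the ionizing species, `predict_shift()` interpolates between the
anchors with the one-site model below, using the pKa of the group the atom
reports on: backbone atoms (C, Cα, Hα) use the α-carboxyl pKa where the
variant has one, side-chain atoms the side-chain pKa. The plateau shifts
are derived by inverting the model through the two measured anchors
(`derive_plateaus()`), which reproduces both anchors exactly and degrades
gracefully: when both anchors sit on the same side of the pKa the linear
system is near-singular and the function refuses with advice to use the
observed shifts directly.

### Background envelope and uniqueness

In practice the uniqueness judgement is made against a measured
denatured-protein spectrum (for instance lysozyme), for which no
machine-readable table exists. The packaged background is therefore an
explicit stand-in: a hand-compiled table of representative
random-coil ¹H/¹³C one-bond correlations for the 20 amino acids (accurate
to roughly 0.1 ppm, neutral-pH ionization states), harmonized for Asp and
Pro with the measured urea-condition entries, and replaceable via
`rc_library(background = )`. At query time the measured internal Asp/Pro
correlations (predicted at the query pH) are appended, so the acidic-pH
collapse of the Asp_C-term Cβ diagnostic onto protonated internal Asp is
reproduced.

Uniqueness of a candidate correlation is its scaled distance to the nearest
background correlation, `min √((ΔδH/tolH)² + (ΔδC/tolC)²)`, with defaults
tolH = 0.05 ppm and tolC = 0.5 ppm chosen as typical denatured-protein
linewidths plus table rounding (0.01/0.1 ppm print precision). A score of 1
means "on the boundary of some background tolerance ellipse"; because the
measured tables produce one candidate that lands on the boundary *exactly*
(Asp_C-term Cβ–Hβ2 against protonated internal Asp at pH 2.3), scores
within 10⁻⁶ of 1 count as overlapping. This makes the diagnostic set
conservative: at pH 7.4 it contains the Pro_N-term Cδ–Hδ, Asp_C-term Cβ–Hβ
and isoAsp Cβ–Hβ pairs; at pH 2.3 the Asp_C-term Cβ–Hβ pair drops out.

## Titration models

For fast-exchange ionization the observed shift is the population-weighted
average of the protonated (δ_min) and deprotonated (δ_max) forms:

$$\delta_{obs}(pH) = \delta_{min} + \frac{\delta_{max}-\delta_{min}}
{1 + 10^{\,pK_a - pH}}.$$

The literature writes this as two directional variants (shift increasing or
decreasing with pH); both are the same protonation-fraction average, so one
core is implemented and the equivalence is asserted by tests to 10⁻¹² ppm.
For a nucleus sensing two ionizable groups (C-terminal Asp: α-carboxyl and
side chain) the stepwise two-site form stacks two transitions around a
shared intermediate plateau δ_mid:

$$\delta_{obs} = \delta_{min0}
 + \frac{\delta_{mid}-\delta_{min0}}{1+10^{\,pK_{a1}-pH}}
 + \frac{\delta_{max2}-\delta_{mid}}{1+10^{\,pK_{a2}-pH}}.$$

The printed source form juxtaposes the first plateau and the first fraction
without an operator and names the intermediate plateau twice; the explicit
"+" with a single shared δ_mid is the only reading that is dimensionally
consistent and reproduces the stated limits (δ_min0 as pH → −∞, δ_max2 as
pH → +∞), and is what is implemented.

### Fitting

`fit_titration()` minimizes unit-weight squared residuals by
Levenberg–Marquardt (minpack.lm), with multi-start pKa initialization at
the pH of the steepest observed gradient (± 1 unit, plus pH quartiles) and
plateaus at the extreme observed shifts; box constraints keep pKa in
[0, 14]. Two-site fits are reported with pKa1 < pKa2; relabelling the sites
exchanges the transition amplitudes, so the intermediate plateau is
re-derived on sorting rather than swapped. `n_sites = "auto"` compares the
two models by corrected AIC. Confidence intervals come from
residual-resampling bootstrap (default 500 replicates, seed mandatory).
Series need ≥ 5 points for one-site and ≥ 7 for two-site fits.

A brute-force oracle (exhaustive pKa grid at 0.01 steps; plateaus by exact
linear solve at each grid point) lives in the test helpers, independent of
the fitting code, and the optimizer is required to agree with it to 0.02 pH
units.

### Resolving two sites: why a global fit

Each carboxyl-adjacent carbon predominantly expresses *its own* group's
transition: between the measured anchors, a Cα-type nucleus of C-terminal
Asp splits its 3.9 ppm change roughly 3.5/0.4 between the α-carboxyl and
side-chain events, a Cβ-type nucleus roughly 0.6/3.3. At a realistic peak
position scatter of 0.05 ppm, a two-site fit to a *single* such nucleus
determines the minor site poorly (simulations here show ~±0.25 scatter on
the minor pKa), and occasionally splits the one visible transition across
both pKa values with competitive residuals. This is a property of the data,
not the optimizer. The study resolves it by reading each event from the
nuclei that express it; `fit_titration_global()` makes that precise by
fitting all nuclei of a residue jointly with shared pKa values and
per-nucleus plateaus, which recovers both sites to ~±0.02 under the same
noise. The validation suite uses the global fit for two-site recovery, and
single-nucleus fits everywhere one site is involved.

`assign_pka_to_groups()` then labels each event by which atom class —
backbone (C, Cα, Hα) or side-chain — shows the larger *fractional* shift
change across it (fractional, so ¹H and ¹³C fits are commensurable); ratios
below 1.2 are flagged unassigned. Per-site pKa values across nuclei are
combined by amplitude-weighted mean rather than a plain mean: a nucleus
constrains a titration event in proportion to the shift change it shows
across it, and an unweighted mean would let near-zero-amplitude fits
contribute pure noise.

pKa values read directly in D₂O with an H₂O-calibrated meter are apparent
values; `d2o_correct()` subtracts the conventional 0.06 and tags the result
so the correction cannot be applied twice. No correction is applied by
default — reported values are direct-reading, like the library's.

## Peak lists and referencing

Sparky `.list` exports (header `Assignment w1 w2 [Data Height] [Volume]`)
are read with w1 = ¹³C, w2 = ¹H — the usual order for a ¹³C-HSQC with
carbon indirect — and `swap_axes` covers the opposite convention. CSV uses
explicit `dH_ppm`/`dC_ppm` columns. Shifts are stored at 10⁻⁴ ppm and all
comparisons use tolerances; ¹H outside [−1, 12] ppm or ¹³C outside
[0, 220] ppm fails validation with the offending line numbers.

Referencing follows the DSS-plus-indirect-ratio convention: the observed
DSS ¹H offset is subtracted from the proton axis, and because the ¹³C
reference frequency is a fixed ratio (0.251449530) of the ¹H reference
frequency, the induced carbon correction is ppm-identical to first order —
the same offset is subtracted (the neglected second-order term is
~10⁻⁶ ppm at typical offsets, far below linewidths). The `referenced` flag
blocks double application, and matching refuses unreferenced lists.

## Detection, calling, quantification

Diagnostics (uniqueness-filtered at the list's pH) plus the intact
counterpart correlations are matched to observed peaks greedily
nearest-first under the same scaled distance, one peak per diagnostic, ties
broken toward the lower-¹³C diagnostic; greedy rather than globally optimal
assignment is auditable and coincides with the optimal matching at this
peak density. Calls follow fixed rules: Asp-Xaa cleavage on Asp_C-term
Cβ–Hβ evidence at neutral pH, upgraded to Asp-Pro cleavage when Pro_N-term
Cδ–Hδ also matches; below pH 5 the Asp_C-term Cβ evidence is suppressed
(overlapped) and cleavage rests on Pro_N-term alone; isoAsp and succinimide
on their Cβ–Hβ pairs, with `multi_peak` confidence when both
stereo-partners match. Stereo-unassigned Hβ2/Hβ3 pairs are interchangeable.

The modified fraction is 100·V_mod/(V_mod + V_ref) from the matched
modified and intact cross-peaks of the same multiplicity, averaged over
stereo-partners, assuming equal per-C–H response — relaxation and
INEPT-transfer differences are ignored, and every report records that
approximation. Heights substitute for missing volumes with the fallback
recorded in the call.

## Synthetic data: what it emulates and what it does not

`simulate_peaklist()` emits one cross-peak per background correlation per
residue *type* present in the sequence (the degenerate random-coil picture;
a per-instance mode with sequence-context jitter is available), with
internal Asp/Pro taken from the measured urea-condition entries so each
residue type is represented exactly once. Each requested modification adds
its marker correlations at volume fraction f and depletes its intact
counterpart to 1 − f. Noise: i.i.d. Gaussian ppm offsets per axis (defaults
0.01 ppm ¹H, 0.1 ppm ¹³C — typical peak-picking scatter), log-normal
volumes with CV 0.05. Seeds are mandatory and the output is byte-identical
for identical specs.

The generator does **not** emulate lineshapes, t₁ noise, peak overlap
within the background envelope, sequence-context shift dispersion beyond
optional jitter, differential relaxation, or solvent/temperature effects.
Passing tests therefore demonstrate correctness of the matching, calling,
fitting and quantification logic under the stated statistical model — not
performance on crowded real spectra, where visual inspection of the
fingerprint region remains part of the workflow.

## Validation conditions and problem sizes

The packaged checks run, per condition: 100-seed one-site recovery
(12 points, pH 1.5–8, σ = 0.05 ppm; ±0.1 required in ≥ 95 seeds), 100-seed
two-site recovery via the global two-nucleus fit (16 points spanning
pH 1.6–9.8, the range the titrations were measured over; ±0.15 per site),
20-instance agreement with the grid-search oracle, 50-seed
simulate→detect→quantify closure at 10 % Asp-Pro cleavage (zero false or
missed calls, fractions within ±3 points), and exact library/detection
checks of the diagnostic coordinates (49.3, 40.8, 42.3 ppm). The
supplementary titration tables are not shipped, so the reproduction of the
reported pKa values (3.2; 3.4/5.0) runs on series generated at those
parameter values between the measured anchor shifts with 0.02 ppm noise — a
stand-in that validates the fitting machinery, not a re-analysis of the
original data.

## Known limitations

* The background table is approximate and neutral-pH; users comparing
  acidic-condition spectra should supply a matched background.
* Quantification inherits the equal-response approximation; for accurate
  stoichiometry, peaks should be compared within the same multiplicity and
  similar dynamics.
* No residue-level site localization: detection says *that* a modification
  is present (and how much), not where in the sequence.
* No Hill/cooperativity or ionic-strength corrections in the titration
  models; reported pKa values are apparent D₂O direct readings unless
  `d2o_correct()` is applied.
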