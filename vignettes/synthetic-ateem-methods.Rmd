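---
title: "Methods: the synthetic A-TEEM study and its analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the synthetic A-TEEM study and its analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the model behind the synthetic data generator, the
numerical choices in the estimation code, and their limitations. It is a
methods document, not a tutorial; see the README for worked examples.

# The measurement model

Each simulated sample is a beverage characterised by a UV–vis absorbance
spectrum $A(\lambda)$ on 240–800 nm (5 nm step, 113 points) and a
fluorescence EEM $F(\lambda_{em}, \lambda_{ex})$ on a 64-point emission
grid over 310–600 nm × a 29-point excitation grid over 260–400 nm
(5 nm step). The clean fluorescence signal is exactly trilinear:

$$F_i(\lambda_{em}, \lambda_{ex}) = \sum_{f=1}^{4} a_{if}\,
  b_f(\lambda_{em})\, c_f(\lambda_{ex})$$

with unit-norm Gaussian band profiles $b_f, c_f$ and non-negative
per-sample scores $a_{if}$. What is *measured* is this signal after
inner-filter attenuation, plus turbidity-scaled Rayleigh ridges, plus
heteroscedastic noise, in three replicates:

$$F^{obs} = F \cdot 10^{-(A(\lambda_{ex}) + A(\lambda_{em}))/2}
  + \tau\,(s_1 R_1 + s_2 R_2) + \varepsilon,
  \qquad \varepsilon \sim N(0, (\sigma_{add} + \sigma_{mult}|F|)^2)$$

where $R_1, R_2$ are Gaussian cross-section ridges along
$\lambda_{em} = \lambda_{ex}$ and $\lambda_{em} = 2\lambda_{ex}$ (sd 4 and
6 nm) and $\tau$ is the sample's turbidity index (below).

# The study design

Two classes mirror a beverage-authenticity setting: 15 "direct" samples
(freshly squeezed juice) and 20 "processed" samples (commercial,
thermally treated beverages), three replicate measurements each.

## Fluorophores

Four fluorophores with excitation/emission maxima 275/345
(hydroxybenzoic-acid-like), 275/318 (flavanol-like), 305/425
(ellagic-acid-like) and a dual-excitation (270, 365; amplitude ratio
0.8:1)/470 browning-like component. Only the maxima are
physically anchored; band *widths* are free parameters of the generator,
defaulting to 25 nm (emission) and 15 nm (excitation).

One deliberate exception: the flavanol-like component uses a 10 nm
excitation width although its stated maximum coincides with component 1's
at 275 nm. If two components shared an *identical* excitation profile, the
excitation loading matrix of the generating model would be exactly rank
deficient. The least-squares Tucker core behind CORCONDIA is then
indeterminate, and the diagnostic becomes meaningless noise even for a
perfect fit. No two real fluorophores have identical excitation spectra,
so distinct widths are both more realistic and necessary for the
diagnostic to be well defined.

## Score distributions

Per class and fluorophore, scores are drawn from a normal distribution
truncated at zero. The configured mean ± sd pairs (e.g. browning
component: 615 ± 418 direct, 8403 ± 5346 processed) are the moments of the
*truncated* distribution itself: the generator moment-matches the parent
normal by Nelder–Mead so that severe truncation (mass near zero, as for
the direct-class browning score) does not bias the configured means.
Without this retargeting the realised mean of a 615 ± 418 truncated draw
would be noticeably above 615.

## Absorbance

Each sample's absorbance is a sum of Gaussian bands:

* a UV band at 265 nm (direct) or 275 nm (processed), amplitude drawn per
  class;
* anthocyanin-like visible bands at 500 nm and a 430 nm shoulder (ratio
  0.35), scaled by a per-sample pigment level. Processed samples draw one
  of three scenarios with equal probability: unaltered, bands shifted
  +25 nm (addition of other fruits), or amplitude reduced to 30%
  (pigment decomposition). Direct samples are always unaltered;
* a nonenzymatic-browning band at 440 nm whose amplitude is tied to the
  sample's browning-fluorophore score (2 × 10⁻⁵ AU per score unit) plus a
  processed-class base level of 0.18 AU — thermal processing produces
  brown chromophores along with the fluorescent Maillard products;
* a particle-scattering baseline $\tau \cdot 0.12 \cdot (400/\lambda)^4$
  AU (Rayleigh's $\lambda^{-4}$ law, anchored at 400 nm).

## Turbidity

The turbidity index $\tau$ is class-definitional: direct-squeezed juice
retains pulp and colloids ($\tau \sim N(1.0, 0.12)$, truncated at 0) while
commercial processed beverages are clarified and filtered
($\tau \sim N(0.15, 0.04)$). One physical cause therefore manifests in
both measurement channels — it scales the Rayleigh ridge intensity in the
EEM (3000 and 1200 intensity units per unit $\tau$ for first and second
order) and the $\lambda^{-4}$ absorbance baseline. This is an explicit
modeling choice: together with the browning band it is what makes the
visible-region absorbance and the unfolded EEMs class-separable, the way
the real measurement channels of such a study are. The fluorescence score
distributions are untouched by it, so score-recovery behaviour is
unaffected.

# Preprocessing

The fixed order is IFE correction → Rayleigh excision → replicate
averaging. IFE correction must precede excision because the correction
factor applies to fluorescence, not to scatter that is then discarded
anyway; averaging last unions the replicate masks.

Two excision variants are used deliberately:

* **For PARAFAC** (`fillPolicy = "mask"`, half-widths 14/21 nm ≈ 3.5 ridge
  sd): scatter is non-trilinear, and the weighted ALS simply ignores
  missing cells, so generous excision costs little and leaves no ridge
  tails to distort the loadings.
* **For PCA/PLS-DA** (`fillPolicy = "interpolate_emission"`, half-widths
  10/15 nm): matrix methods need complete data, so excised cells are
  linearly interpolated along the emission direction; columns excised
  end-to-end fall back to masking with a warning.

# Estimation

## PARAFAC

Non-negative alternating least squares with missing-data support: each
mode update solves row-wise non-negative least squares exactly by passive-
set enumeration (feasible because $F \le 6$), weighting out missing cells.
Convergence is declared when the *fit fraction* changes by less than the
tolerance: $|\Delta SSR| / SS_{tot} < 10^{-8}$, which is scale-free in the
data's units. Multiple random starts (default 10; the tests and the
acceptance script use 2, which is sufficient at these noise levels) guard
against local minima; the best-SSR start is kept. Spectral loadings are
normalised to unit length with all magnitude in the scores, and components
are ordered by explained variation.

CORCONDIA computes the least-squares Tucker core of the fitted loadings
via per-mode pseudo-inverses and reports
$100\,(1 - \|G - I\|^2 / \|I\|^2)$ against the superidentity. Split-half
validation partitions samples into two class-stratified halves, refits
both, matches components by Tucker congruence over the best permutation,
and reports 100 × the mean absolute congruence of emission and excitation
loadings.

## PLS-DA

NIPALS PLS2 on mean-centered spectra against centered 0/1 dummy columns;
prediction is the argmax over predicted dummies. Leave-one-out
cross-validation scans latent-variable counts, and the chosen count is the
smallest whose CV error is within one misclassified sample of the minimum
(a parsimony rule). VIP scores are normalised so that the mean squared VIP
is 1 ($\sum_j VIP_j^2 = p$).

## Reproducibility

All randomness — simulation draws, ALS starts, split-half partitions —
derives from a single master seed; per-stage seeds are drawn from it with
`sample.int(2^31 - 1)`. Seeded fits save and restore the caller's RNG
state.

# Limitations

* Gaussian band shapes and purely additive band superposition; no Raman
  scatter, quenching, quantum-yield or instrument-drift modeling.
* Score distributions are truncated normals; heavy-tailed alternatives
  are not modeled.
* The turbidity and browning-absorbance couplings are simple linear
  mechanisms chosen for realism of the *class structure*, not calibrated
  to any instrument.
* The parsimony rule for latent-variable selection deliberately
  under-fits relative to minimising CV error; it follows common
  chemometric practice rather than optimising accuracy.
* The exact non-negative least squares solver enumerates passive sets and
  is exponential in the component count; it is intended for the small
  component numbers (≤ 6) typical of EEM work.
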