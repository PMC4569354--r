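---
title: "Source-space MEG connectivity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Source-space MEG connectivity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megnet)
```

This vignette documents the science inside `megnet`: the models each stage
assumes, the tunable parameters and why their defaults are what they are,
what the synthetic cohorts do and do not emulate, and the numerical
decisions a careful user should know about.

## The analysis model

The pipeline estimates frequency-resolved functional connectivity between
brain volume elements from sensor-level MEG, and tests group differences
nonparametrically. Its chain of assumptions:

- **Forward model.** Neural currents are modeled as point dipoles inside a
  spherically symmetric conductor. We use the closed-form field solution
  for that geometry, which has two properties the tests rely on: the field
  is linear in the dipole moment, and radially oriented dipoles produce no
  external magnetic field. A realistic single-shell head model would change
  the lead fields but none of the downstream algebra; the sphere was chosen
  because it is analytically checkable. Grid nodes whose lead field is
  numerically rank-zero (the sphere center) are flagged and excluded rather
  than silently zeroed.
- **Spectral model.** Each 10 s epoch is transformed with DPSS (Slepian)
  tapers whose half-bandwidth is the band's halfwidth; the taper count
  follows the Slepian convention `K = floor(2·T·W) − 1` (39 tapers for a
  10 s epoch at ±2 Hz). Band smoothing is realized as DPSS smoothing around
  a single center frequency per band; averaging a CSD over a within-band
  frequency grid is a defensible alternative that we did not adopt, because
  one center frequency per band matches the "frequencies of interest"
  framing and keeps the per-band Fourier coefficients projectable.
  The CSD is normalized by `1/fs` (unit-norm tapers), making the diagonal a
  spectral density; every downstream quantity (coherency) is scale-free.
- **Inverse model.** DICS unit-gain beamforming with λ = 5 % diagonal
  loading of the CSD (λ·tr(S)/n·I). Filters are computed on the real part
  of the regularized CSD — the standard practice, since the imaginary part
  does not contribute to a real-valued filter under Hermitian symmetry —
  while the complex CSD is retained for connectivity. The scalar
  orientation is the maximal-power direction within the numerical rank of
  `LᵀS⁻¹L` (the radial direction is always truncated in a sphere). The
  unit-gain normalization (`w·l = 1`) was chosen over unit-noise-gain; the
  choice only rescales power maps and cancels entirely in coherency. Note
  the dominant-eigenvector orientation has an arbitrary sign, so source
  amplitudes are recovered up to sign — immaterial for power and for
  `|Im coherency|`.
- **Connectivity.** The absolute imaginary part of coherency. Taking `|·|`
  immediately makes networks undirected by construction; the sign (lead
  vs lag) is discarded by design. Networks are never thresholded. Regional
  networks average all between-region node-pair weights and omit
  within-region pairs; the band-level CSD is averaged before the imaginary
  part is taken (one coherency per band), rather than averaging `|Im C|`
  over within-band frequencies.
- **Graph measures.** Strength, Onnela clustering (weights max-normalized
  per network), and characteristic path length with edge length `1/w`
  (`−log w` available via `length_map`). `1/w` is the convention of the
  standard brain-connectivity toolboxes. Disconnected networks are a hard
  error rather than being patched with harmonic means: dense coherence
  networks are always connected, so disconnection indicates a broken input.
- **Surrogate normalization.** "Randomly shuffling the connections" is
  ambiguous; we implement the full weight-permutation null (upper-triangle
  weights permuted, then symmetrized), which preserves the weight
  distribution but not the degree sequence. This is the default and the
  only implemented scheme; a degree-preserving rewiring null would preserve
  strength heterogeneity and is a known alternative we document as out of
  scope. On an all-equal-weight complete graph the surrogates equal the
  original and both normalized ratios are exactly 1 — a useful exactness
  check.
- **Inference.** All cluster-type tests share one permutation engine:
  mass-univariate pooled-variance t per feature, supra-threshold features
  clustered (spatial adjacency within 1.1× grid spacing for nodes;
  connected components for edges), cluster statistic = summed t for spatial
  clusters and component edge count for the network-based statistic
  (extent-based NBS; summed-t is available via `statistic = "mass"`), and a
  max-statistic permutation null per direction. Directions are tested
  separately at the stated alpha without alpha splitting, so the
  two-direction union rate is about twice the per-direction rate — the
  type-I guarantees of this package are therefore stated and tested
  per direction. When the number of distinct group assignments is small the
  labels are enumerated exhaustively; otherwise Monte-Carlo permutation
  includes the identity assignment, guaranteeing p ≥ 1/n_perm.

## Parameters that matter

| Parameter | Default | Units | Notes |
|---|---|---|---|
| epoch length | 10 | s | with 30 epochs per subject |
| analysis rate | 409.6 | Hz | resampling target |
| band-pass | 0.5–70 | Hz | Butterworth order 4, forward–backward |
| bands | δ 2±2 … γ 40±5 | Hz | center ± halfwidth |
| beamformer λ | 0.05 | — | diagonal loading fraction |
| grid spacing | 0.01 | m | demo configs use 0.03 m |
| surrogates | 100 | — | weight-shuffle null |
| node-cluster t / α | 2.0 / 0.01 | — | nodal strength test |
| NBS t / α | 3.5 / 0.05 | — | region-edge test |
| power-cluster t / α | 1.9 / 0.05 | — | source-power test |
| permutations | 5000 | — | demo configs use 500 |

The Butterworth order (4, effectively 8 after the two-pass application)
and the non-overlap of randomly selected epochs are choices the upstream
description leaves open; both are configurable, and the selection seed is
mandatory so epoch draws are reproducible.

## The synthetic cohorts

`simulation_config()` + `make_cohort()` generate two groups of
resting-state recordings. Source dynamics are narrow-band filtered
Gaussian noise; a coupled pair `(a, b)` is built by mixing into `b` a
Hilbert-phase-shifted copy of `a`'s signal with weight `c` and independent
noise with weight `√(1−c²)`, so `c` is the target source-level coherence
magnitude and the phase lag is exact. Group 2 ("patients") has each `c`
multiplied by `planted_group_effect`. Sensor data are lead-field
projections plus white channel noise (default SD 5×10⁻¹⁴ T against
10 nA·m dipoles, i.e. realistic magnetometer noise against cortical
source strengths); the per-subject SNR is recorded in the manifest.
Per-subject seeds are `master seed + subject ordinal`.

What this emulates: band-limited oscillatory coupling with a genuine time
lag, field spread (all sensors see all sources through the physics),
beamformer leakage, and finite-sample bias of `|Im coherency|`. What it
does not: 1/f broadband structure, nonstationarity, artifacts, epileptiform
discharges (excision is tested on synthetic markers instead), cortical
geometry, and realistic conductor shape. Passing tests therefore certify
the estimator chain and its statistics, not performance on any particular
clinical dataset.

Cohorts are synthesized directly at the analysis rate; the
downsampling operator is exercised separately on sensor-level fixtures.
One deliberate simplification is documented here rather than hidden:
resampling is implemented as a 400-tap zero-phase FIR anti-alias filter
(passband edge at 0.8× the target Nyquist) followed by spline
interpolation at the exact new sample times, which handles non-integer
rate ratios (3906.2 → 409.6 Hz) without the passband ripple a rational
polyphase approximation produced at this ratio.

## Calibration of the planted effect

The effect-recovery study (also run by `scripts/acceptance.R`) plants
lagged β₂ coupling between two contiguous 4-node patches with `c = 0.35`
and a group multiplier of 1.32, in cohorts of 13 + 19 subjects on a 3 cm
grid with 64 sensors. The multiplier was calibrated once, by a sweep over
{1.15, 1.25, 1.32, 1.40} (giving pooled Cohen's d of roughly 0.7, 1.5,
2.1, 2.6 on the most affected region edge), to put the edge-weight effect
size at d ≈ 2; it is fixed thereafter. Two patches rather than a single
node pair are planted because a single pair dilutes to invisibility when
averaged into region edges and yields one-node clusters that cannot beat a
max-cluster-mass null.

A note on why single planted pairs behave poorly is worth keeping in mind
when designing simulations: a region-level edge averages every node pair
between two regions, so an effect confined to one node pair is attenuated
by the product of the region sizes, while beamformer leakage spreads a
patch-level effect constructively.

## Numerical choices

- **DPSS computation.** Tapers are the top eigenvectors of the symmetric
  tridiagonal Slepian matrix, obtained by Sturm-sequence bisection plus
  inverse iteration with re-orthogonalization — O(K·N) rather than a dense
  O(N³) eigendecomposition, which matters at N = 4096. Orthonormality is
  maintained to ~1e-15 and the first taper's spectral concentration in
  ±W exceeds 0.999.
- **Rank handling.** `LᵀS⁻¹L` is rank-2 in a spherical conductor; the
  filter construction truncates eigenvalues below 1e-7 of the maximum and
  excludes rank-zero nodes from all downstream analyses (they are listed in
  the run manifest).
- **Invariances tested.** Forward-model linearity and rotation
  equivariance; coherence invariance to per-channel rescaling; network
  weight invariance to per-node positive rescaling and to a global phase
  (a per-node phase rotation is deliberately *not* an invariance of
  imaginary coherency — it re-times the node).
- **Determinism.** Every stochastic step takes an explicit seed; rerunning
  a pipeline with the same configuration reproduces results bit-for-bit,
  and the manifest carries a configuration hash.
- **Problem sizes.** The shipped demo and validation configurations use
  64 sensors, a 3 cm grid (93 nodes), 2 s epochs at 256 Hz and 500
  permutations — small enough to iterate on a laptop while leaving every
  algorithmic path identical to the full-scale settings, which are the
  package defaults (`default_config()`).

## Known limitations

- The spherical conductor cannot represent realistic head geometry; silent
  radial sources make a fraction of orientation space invisible, which a
  realistic model would only partially share.
- `|Im coherency|` is insensitive to genuinely zero-lag physiological
  coupling and its magnitude depends on SNR through beamformer leakage;
  between-group comparisons are valid, absolute values are not
  interpretable as coupling strength.
- The weight-shuffle surrogate null destroys degree structure; normalized
  clustering near 1 for random networks is a calibration statement about
  this null only.
- Mann–Whitney switches from the exact distribution to the tie-corrected
  normal approximation at min(n, m) > 8 or in the presence of ties; at the
  13/19 cohort scale p-values are approximation-based (they match a 10⁵
  permutation oracle to < 0.01 in the tests).
- The in-memory container with TSV/JSON/RDS writers replaces a
  self-describing binary container format; for very long recordings a
  chunked on-disk format would be preferable.
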