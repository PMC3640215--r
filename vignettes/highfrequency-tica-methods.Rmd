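---
title: "Methods: temporal ICA of high-frequency resting-state fluctuations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal ICA of high-frequency resting-state fluctuations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

At the TRs of conventional resting-state fMRI (2–3 s) every physiological
oscillation faster than ~0.25 Hz — heart beat near 1–1.3 Hz above all — is
aliased into the low-frequency band, where it contaminates connectivity
estimates without being identifiable. Fast multiband EPI at TR = 0.354 s
raises the Nyquist frequency to 1/(2·TR) ≈ 1.41 Hz, so the cardiac band is
critically sampled and can be *separated* rather than merely filtered.

`hftica` treats the high-pass-filtered, temporally concatenated multi-subject
data as a noisy linear mixture

$$X = \sum_j s_j m_j^\top + E, \qquad X \in \mathbb{R}^{\Sigma T \times V},$$

where the $s_j$ are temporally independent component time courses on the
concatenated group time axis and the $m_j$ are voxel maps that may overlap
freely — the point of *temporal* ICA, since spatial ICA assumes spatially
disjoint sources and cannot disentangle a pulsation map from a network map
occupying the same voxels. Estimation is the classical two-step: truncated
SVD $X \approx U_k D_k V_k^\top$ for prewhitening and dimensionality
reduction, then symmetric FastICA on $Z = \sqrt{n-1}\,U_k$, with maps
back-projected through the stored PC basis,
$M = W D_k V_k^\top / \sqrt{n-1}$. FastICA's identifiability assumption is
that at most one source is Gaussian; everything downstream relies on it.

A component extracted from concatenated data can be genuinely group-level or
driven by one subject. The consistency ratio — one subject's sum of squares
of the component time course divided by the summed sum of squares of all
other subjects — flags the latter: a ratio above 1 means a single subject
contributes more variance than everyone else combined, the typical signature
of a subject's own heart-beat component, and such components are discarded
from group interpretation (their spectra remain useful, e.g. for per-subject
heart-rate estimation).

## Pipeline order and parameters

Per subject: discard initial volumes → motion regression → voxel
standardization → (optional smoothing) → high-pass. The defaults:

* `n_discard = 24` volumes — T1 saturation transient at the start of an EPI
  run.
* Motion regression: least-squares residuals on an intercept plus the six
  rigid-body parameters. An intercept is included although data are demeaned
  later; it is standard GLM practice and harmless. Rank-deficient designs go
  through the pivoted QR with a warning rather than an error.
* `cutoff_hz = 0.25`: every DFT bin strictly *below* 0.25 Hz is zeroed
  (together with DC); the bin exactly at the cutoff is retained. Positive and
  negative frequencies are zeroed as conjugate pairs so the output is exactly
  real, the filter is exact on the grid, idempotent, and energy splits by
  Parseval into the retained and removed parts.
* Smoothing (`fwhm_voxels`, default 0 = off) is a separable Gaussian
  (σ = FWHM/2.3548) restricted to the mask with kernel renormalization at
  mask edges, so no signal bleeds into the exterior. It defaults off because
  the physical 6 mm kernel of real acquisitions is tied to a resampled 2 mm
  grid that has no analogue on the simulator's abstract voxel grid. Note the
  edge renormalization means a smoothed impulse conserves total mass only
  when its kernel support stays clear of the mask boundary.
* Decomposition dimensions: package-level defaults `n_pcs = 76`,
  `n_ics = 75`, the convention for a full-scale 10-subject study; for
  synthetic runs both are set to the known source rank (see below).
* FastICA: `logcosh` contrast (α = 1; `exp` and `cube` available), symmetric
  decorrelation (all components updated in parallel, so no deflation-order
  dependence), tolerance 1e-6 on the unmixing update, 1000 iterations, up to
  5 seeded restarts. Components are sign-canonicalized (positive spatial-map
  skewness, falling back to a positive largest-magnitude voxel) and ordered
  by explained variance, so results are reproducible and invariant
  conventions rather than arbitrary ICA output order.
* Characterization bands: 0.25–0.5, 0.5–0.75, 0.75–1.0, 1.0–1.25,
  1.25–1.4 Hz. The top edge follows the conventional printed 1.4 Hz rather
  than the exact Nyquist 1.412 Hz and is configurable. Band fractions are
  normalized by total power *within the analyzed range* — the denominator is
  stated explicitly because per-component spectra leave it ambiguous
  otherwise. Spectra are computed per subject segment and averaged: a single
  transform of the concatenated course would see the concatenation
  discontinuities as spurious broadband energy.
* Classification cascade (all thresholds in `classification_rules()`):
  technical if fraction(0.75–1.0) ≥ 0.5 and max/median spectral power ≥ 10;
  else cardiac if the peak lies in [1.0, 1.35] Hz and fraction(1.0–1.4)
  ≥ 0.4; else rsn if the five band fractions decrease (one tie within 5%
  relative tolerated) and fraction(0.25–0.5) ≥ 0.35; else pulsation if the
  fraction above 0.6 Hz is ≥ 0.5; else other. These encode qualitative
  spectral signatures as explicit, reproducible rules; they are deliberately
  simple and make no claim to optimality.

## What the simulator emulates — and what it does not

`default_sim_config()` defines the study conditions used throughout the test
suite and the acceptance script: 5 subjects, a 12×12×8 grid with an
ellipsoidal mask (≈ 900 in-mask voxels), 512 volumes at TR = 0.354 s,
snr = 5 (total source variance over white-noise variance, averaged over the
mask), four shared sources plus one single-subject cardiac oscillator per
subject. These sizes run the full pipeline in about a second, which is what
allows recovery statistics over 20 independent studies inside a test suite.

The source families mirror the component types seen in high-frequency
decompositions of real fast-TR data:

* **rsn** — skewed spectrum, amplitude highest just above the cutoff and
  decreasing continually (power ∝ f^(−2·0.75)); spatial map a two-node
  network of Gaussian blobs. The decay exponent 0.75 keeps the upper bands
  small but non-negligible; much steeper decays make the 0.75–1.4 Hz
  fractions so tiny that a percent of cross-component leakage dominates
  them.
* **technical** — band-limited noise in 0.8 ± 0.025 Hz with a spatial map
  that is constant within each slice and alternates sign every
  `band_period` slices, the slice-banded signature of a scanner artifact.
* **pulsation** — flat band-limited noise over 0.6–1.4 Hz on a
  ventricle-plus-vessel-like blob set.
* **cardiac** — a frequency-modulated oscillator per subject. Base rates are
  drawn once per subject from N(1.15, 0.08) Hz truncated to [1.0, 1.3] Hz
  (resting heart rates of 60–78 bpm, within the critically sampled band);
  slow sinusoidal frequency modulation with SD `jitter_sd = 0.03` Hz
  broadens the spectral peak the way heart-rate variability does, without
  requiring a cardiac-cycle model.

Two generator choices deserve emphasis because they are *necessary*, not
cosmetic:

1. **Amplitude modulation.** Band-limited Gaussian noise is Gaussian, and
   independent Gaussian sources are unidentifiable for FastICA — any
   rotation of them is equally independent. Real physiological and network
   signals are bursty; the generator reproduces this with a slow log-normal
   amplitude envelope, `exp(0.7·z)` with `z` lowpassed at 0.02 Hz, applied
   after spectral shaping and followed by re-projection onto the band (so
   modulation sidelobes do not leak out of it) and standardization. The
   resulting sources have excess kurtosis ≈ 2–4, which is what gives the
   non-Gaussianity-seeking ICA something to find. Without it, recovery
   collapses to chance rotations.
2. **Spatially extensive, overlapping maps.** With ≈ 900 voxels, 2440
   concatenated rows and snr 5, a source confined to a tight blob in an
   otherwise signal-free mask falls below the Marchenko–Pastur noise floor
   of the group PCA and is simply absent from the retained subspace. The
   default maps are therefore large and overlapping (networks with two
   nodes, whole-volume slice banding, multi-site pulsation), which is also
   the realistic regime — these component families span much of the brain.

For the same reason the synthetic decomposition uses `n_pcs = n_ics = 9`,
the exact source rank: concatenated shared sources are sums of per-subject
independent segments, and any *spare* retained dimension lets ICA split a
strong shared source into subject-restricted pieces (each piece, being
nonzero on one fifth of the time axis, is sparser and hence "more
non-Gaussian" than the whole). At real-data scale this splitting pressure is
held in check by the enormous voxel count; at desk scale the clean remedy is
a subspace that exactly spans the sources. The 76/75 convention of the
package defaults (one more PC than ICs) is kept for full-scale use.

The simulator does **not** emulate: hemodynamic-response convolution,
anatomy, registration error, scanner drift nonstationarity, or spatially
correlated noise. Motion is a smooth 6-parameter random walk whose variance
is injected at a small fraction (10%) of the noise variance — enough to make
the motion-regression stage testable, not a realistic motion model.
Consequently, passing recovery tests here demonstrates the correctness of
the pipeline's mathematics and its behavior under the stated noise model; it
does not certify performance on real scans.

## Numerical choices

* **Truncated SVD** computes the eigendecomposition of the Gram matrix on
  the smaller side, then a Rayleigh–Ritz refinement (dense SVD of the
  k-column projection `X V₀`). The Gram step alone loses half the digits on
  small singular values (squaring the condition number); the refinement
  restores near machine precision, which the dense-oracle tests check to
  1e-8 relative.
* **Whitening** uses `Z = √(n−1) U_k`. Because every voxel column of the
  group matrix is per-subject mean-centered, the whitened columns have
  exactly zero mean; the code verifies this rather than recentering.
  A zero singular value among the top k is an error (degenerate dimension),
  not something to paper over.
* **FastICA convergence** is declared when the maximum absolute change of
  the unmixing rows (1 − |⟨w_new, w⟩|) drops below 1e-6. A degenerate
  decorrelation (rank-deficient update) triggers a seeded restart instead of
  an error; persistent non-convergence across restarts errors out loudly.
  With the default synthetic conditions convergence typically takes on the
  order of tens of iterations.
* **Band edges**: bins are assigned to `[lo, hi)` bands, the last band
  closed above, so a partition of the analyzed range sums to exactly 1.
* **Constant voxels** cannot be standardized and are set to zero with a
  count recorded in the preprocessing provenance.
* **Matching** of estimated to ground-truth components (tests and acceptance
  only) maximizes summed |correlation| over assignments, solved exactly by
  dynamic programming over column subsets — at ≤ 20 components this is
  simpler than a Hungarian implementation and provably optimal, which the
  tests verify against brute-force permutation.

## Known limitations

* A broadband flat pulsation component has about half its power above 1 Hz,
  and its spectral peak falls anywhere in its band; whenever that peak lands
  in [1.0, 1.35] Hz the default cascade labels it cardiac. This ambiguity is
  intrinsic to a purely spectral rule set for broadband components — on real
  data one would add the spatial evidence (ventricular/vessel location vs.
  blob near large vessels) that the qualitative taxonomy itself uses.
* RSN components whose estimates carry a few percent of cardiac leakage can
  acquire a small 1.0–1.25 Hz bump that breaks the strictly-decreasing test
  beyond its one-tie tolerance, in which case they fall through to `other`.
  At the default study conditions this affects a few percent of RSN
  components across seeds.
* The consistency criterion needs at least two subjects; single-subject
  decompositions keep all components with an explicit note.
* `n_ics < n_pcs` means the IC product reconstructs the rank-`n_ics`
  projection, not the full rank-`n_pcs` PCA approximation; exact
  reconstruction holds when the two are equal, which is how the invariant is
  tested.

## Problem sizes used by tests and the acceptance script

Unit tests run on matrices of a few hundred rows and columns. The
end-to-end statistics (source recovery, consistency, classification) use 20
independent simulated studies under the default conditions above; filter and
SVD oracles use 488-point series and 50×200 / 200×200 matrices; band-fraction
calibration averages 100 white-noise spectra; the group-shape check simulates
a 10-subject, 1024-volume study on a reduced grid. All sizes were chosen so
the full suite and the acceptance script each complete in well under a
minute on a single CPU while keeping every statistical margin comfortable.
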