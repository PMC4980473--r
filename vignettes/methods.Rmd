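---
title: "Decomposing block-design fMRI into networks: model, fluctuation index, and coupling labels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing block-design fMRI into networks: model, fluctuation index, and coupling labels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`icafluct` analyzes multi-subject block-design fMRI in which two cognitive
states alternate — here called *imagery* and *suppression*, after the
thought-suppression paradigm the package emulates — without assuming that
task-related activity is constant within a block. The working hypothesis
is that sustained inhibition is unstable: a network engaged by suppression
fluctuates within the block, which a boxcar regression model treats as
noise. The package therefore combines a model-free decomposition with
statistics aimed specifically at within-block variability.

## The generative model behind the synthetic cohort

No real scans ship with the package. Instead, `simulate_cohort()` draws
cohorts from an explicit generative model whose structure matches what the
analysis assumes, so that every stage can be validated against known
ground truth:

* **Design.** Each run is 408 s at TR 2 s: a 24-s lead-in, then four
  pairs of 48-s imagery and 48-s suppression phases, each phase made of
  two 24-s sub-blocks cued by a 2-s flash. 204 volumes are acquired and
  the first 4 are discarded, leaving 200. Twenty subjects complete two
  runs each.
* **Spatial maps.** Components live on a 16 x 16 x 8 voxel grid with an
  ellipsoidal brain mask — large enough for eight distinct network blobs
  plus two artifact sources, small enough that the full pipeline runs in
  seconds. Maps are sums of 3D Gaussian blobs (sd 1.8 voxels, truncated
  at 1% of peak), mimicking smoothed network maps.
* **Time courses.** A network's time course is an HRF-convolved
  condition-dependent baseline plus a within-block fluctuation process:
  an AR(1) recursion (coefficient 0.5) restarted at each phase boundary
  and scaled to a condition-specific stationary standard deviation. AR(1)
  at this sampling rate concentrates power in the 0.005–0.1 Hz band the
  fluctuation index reads, which white noise would not. Innovations come
  from shared standard-normal latent streams mixed by the Cholesky factor
  of the coupling matrix, so the latent correlation between two coupled
  components equals the signed coupling weight exactly; for a single pair
  this reduces to `x_a = w z_c + sqrt(1 - w^2) z_a`.
* **The HRF** is the canonical double-gamma (response gamma with shape 6,
  undershoot with shape 16, ratio 1/6, unit rate), sampled at the TR and
  normalized to unit sum so that convolving a constant returns the same
  constant.
* **Artifacts.** Two components carry band-limited Gaussian noise in
  0.15–0.25 Hz; one sits inside the mask (physiological noise), the other
  in the grid corners outside the mask (edge/motion-like).
* **Self-report.** Each subject's fluctuation sds are jittered by a
  log-normal factor (sd 0.25). The binary "could you suppress your
  thoughts?" flag is a median split on the control component's injected
  suppression/imagery fluctuation ratio, which guarantees two non-empty
  groups for the association test.
* **Default effect sizes.** The suppression and imagery networks carry a
  unit condition baseline shift and a twofold fluctuation increase during
  suppression; they are coupled at -0.6, and the executive-control
  component is coupled at +0.6 to the suppression network. The remaining
  networks (attention, visual, default-mode, occipital, task-null) carry
  weaker or no task effects; the occipital component is deliberately
  marginal (baseline 0.25) so that the suppression network is the most
  task-related component, as in the study design the cohort emulates.
  Voxel noise is white with sd 0.7 against unit-peak maps.

What the generator does **not** emulate: head motion, slice-timing,
physiological cycles, scanner drift, spatial nonstationarity, or any
nonlinearity of the hemodynamic response. Passing tests therefore show
that the implementation is correct under its own assumptions — not that
real data satisfy those assumptions.

## Decomposition

`group_ica()` follows the standard temporal-concatenation recipe: each
run's 200 x 2048 data matrix is PCA-reduced over time to 1.5x the model
order, the reduced runs are stacked and whitened to the model order, and a
square unmixing matrix is estimated by natural-gradient Infomax with the
logistic nonlinearity. The unmixing matrix is re-orthonormalized
(symmetric decorrelation) after each step; on whitened data the optimum is
a rotation, so the constraint costs nothing and keeps source estimates
exactly uncorrelated. Defaults: learning rate 0.5, annealing factor
0.9995 per iteration, at most 512 iterations, convergence when the weight
change drops below 1e-7 in Frobenius norm, and up to five learning-rate
halvings on divergence.

Stability selection repeats the fit 10 times on bootstrap-resampled
(observations with replacement), randomly re-initialized data, pools all
estimates, and clusters them by average-linkage agglomeration on one minus
the absolute Pearson correlation. Each cluster contributes its centrotype,
and a quality index: mean intra-cluster minus mean extra-cluster
similarity. Similarity is computed between *spatial* source estimates by
default: with the orthonormal unmixing this makes the degenerate case of
identical repeated runs yield an index of exactly 1, giving the index a
clean calibration point. Time-course similarity — arguably closer to how
some toolboxes cluster — remains available via `similarity = "timecourse"`.

Subject-specific time courses and maps come from dual regression against
the z-scored group maps, and each map is flipped so its skewness is
positive, making all downstream statistics invariant to the inherent sign
ambiguity of ICA.

The configured model order defaults to 30 in `group_ica()`, the value
appropriate for whole-brain data; the synthetic cohort uses 10 (its true
source count) so that tests exercise a correctly specified decomposition
at tractable size.

## Artifact screening

A component's low-frequency power ratio (LFPR) is the summed raw
periodogram power of its demeaned time course between 0.003 and 0.10 Hz
divided by the sum between 0.15 and 0.25 Hz, band edges inclusive; a zero
denominator (below fft round-off) returns infinity. Hemodynamic signals
concentrate power at low frequencies, so small ratios flag artifacts. The
ratio is computed per subject and run and pooled by arithmetic mean (the
pooling rule is otherwise unconstrained; the mean is the simplest
unweighted choice). Components with a mean below 3 are labelled
`artifact_spectral`; between 3 and 3.5, `suspicious` — retained in the
analysis, conservatively; at or above 3.5 they pass the spectral screen.
Independently, a component whose suprathreshold (|z| > 2) voxels lie
mostly (> 0.5) outside the brain mask is `artifact_spatial` regardless of
its spectrum, since a spatially implausible source should not be rescued
by a clean spectrum. No Welch averaging or tapering is applied; both are
deliberate simplicity choices and configurable at the call site.

## Task-relatedness

Two complementary tests run on back-projected component time courses.

**Regression analysis.** Each run is modelled as `y = X b + e`, where `X`
holds eight task regressors: four HRF-convolved epoch boxcars (one per
condition sub-block type) and four HRF-convolved zero-duration cue
impulses, one per epoch type's onsets (this is the reading of "eight
regressors" that assigns one cue regressor to each epoch type; a pooled
single cue regressor is the obvious alternative and would change little,
since all cues share the same response here). An intercept is added
internally and excluded from contrasts. Per subject, run-wise
coefficients are averaged, and the contrast is the mean imagery
coefficient minus the mean suppression coefficient; a two-sided one-sample
t-test across subjects gives the group inference. Averaging runs within
subject before the group test keeps the random-effects logic at the
subject level.

**Pooled-cycle analysis.** All subjects, runs and block pairs are folded
onto one 96-s imagery-plus-suppression cycle by averaging; a two-sample
t-test compares the 24 imagery-phase samples against the 24
suppression-phase samples. This is the liberal, descriptive counterpart of
the regression test. By default no cycle samples are excluded — the full
48-s phases enter the test — but `exclude_cue_volumes` can drop the
cue-contaminated first volumes of each phase.

## Fluctuation index

The index adapts the Fano factor's idea — variability normalized by
magnitude — to continuous fMRI responses. Per component: the session time
course is band-passed at 0.005–0.1 Hz (4th-order Butterworth applied
forward and backward for zero phase), condition blocks are extracted with
the first 4 volumes (8 s) of each block dropped to avoid cue transients,
and the grand-average block response over all trials and subjects is
subtracted positionally from each trial. The standard deviation of one
subject's pooled residual time points, divided by the grand-average
response amplitude, is that subject's index for the condition.

The amplitude normalizer is the peak-to-trough range across the two
pooled condition responses of the component — a single number per
component, the "typical response magnitude". An earlier per-condition
normalizer was rejected: after cue trimming, the active-phase pooled
response is a plateau with a small range while the off-phase still
contains the decay tail, so per-condition ranges differ for reasons
unrelated to variability and corrupt the suppression/imagery index ratio
(injected ratios of 2 came back near 1). With the shared normalizer the
ratio reflects residual variability alone. The pooled-response standard
deviation is available as an alternative (`amplitude_mode = "sd"`).

The task effect is a paired two-sided t-test across subjects on
log-converted indices (paired because both conditions are measured in the
same subject; the logarithm symmetrizes ratios). The association with the
self-report flag is a two-sample t-test on log task-change ratios between
reporting groups. Zero indices are excluded with a warning count, and a
zero amplitude returns an infinite index rather than an error.

## Residual-correlation coupling

For a reference component — chosen automatically as the most
significantly suppression-related valid component, mirroring how such a
reference is singled out in practice — each other component's session
time course is band-passed (same 0.005–0.1 Hz band), cut into condition
blocks with the first 4 volumes discarded, linearly detrended per block,
and correlated block-wise with the reference. Correlations are
Fisher-Z-transformed (clipped at |r| = 1 - 1e-6), averaged over a
subject's blocks per task, and tested across subjects: a one-sample
t-test per task, plus a paired t-test for a task change. A pair is
labelled `positive` (`negative`) only when both per-task tests are
significant at alpha = 0.05 (uncorrected, matching per-pair reporting;
Bonferroni is a flag away) with concordantly positive (negative) mean Z;
everything else — including discordant significance — is `equivocal`.
Trials enter the pooled mean unweighted.

Note a structural caveat the method inherits: block-wise correlations on
band-passed data retain whatever shared task response survives trimming
and detrending, so strongly task-locked component pairs can earn a label
through response shape rather than residual coupling. The calibration
tests therefore measure the false-label rate on task-null pairs, where
the rule's nominal alpha-squared bound applies.

## Reference voxelwise GLM

For the sensitivity comparison, a conventional analysis runs per subject
and voxel: one regressor coding the imagery-minus-suppression signal
change (+/-0.5 boxcar coding, HRF-convolved, so its coefficient is the
condition difference itself), condition-onset nuisance regressors, and an
intercept; a motion-regressor slot exists but is unused on synthetic
data, which has none. Contrast images are averaged over runs and tested
across subjects voxel-wise; Bonferroni correction over in-mask voxels
replaces random-field theory — exact, dependency-free, and conservative,
which is the right bias for demonstrating *relative* sensitivity. The
demonstration (`sensitivity_gap()`) holds the mean condition effect fixed
while raising the within-block fluctuation sd over at least three levels:
surviving GLM voxels in the fluctuating network shrink monotonically
while the component-level regression contrast stays significant.

## Numerical and design choices

* Volume indices are 0-based in block bookkeeping; block intervals are
  half-open `[onset, onset + duration)`; all onsets must be multiples of
  the TR, and violations are rejected by field name.
* Every random quantity derives from one master seed through a
  deterministic integer-folding scheme, so identical configurations give
  byte-identical ground-truth sidecars.
* Whitening is enforced to 1e-6; PCA rejects requests beyond the
  numerical rank with the achievable rank in the message; back-projection
  rejects map Gram matrices with condition number above 1e8.
* Zero-variance inputs are handled explicitly: a constant map z-scores to
  zeros with a warning, a zero-variance block segment yields a missing
  correlation, and a degenerate t-test (all values identical at zero)
  reports t = 0, p = 1.
* The test suite and the acceptance script run the full cohort at its
  study-scale defaults (20 subjects x 2 runs x 200 volumes, 10
  components on the 16 x 16 x 8 grid) and scale Monte-Carlo replicate
  counts (30–1000 depending on the statistic) to keep each property
  estimable in minutes on one core.

## Limitations

The generator's networks are compact, stationary and linearly mixed;
real resting-state and task networks overlap, move and interact
nonlinearly. The LFPR screen presumes the artifact spectrum is
concentrated above 0.15 Hz, which holds for the simulated artifacts but
only approximately for real motion. The coupling labels quantify residual
correlation, not causality. And the sensitivity-gap demonstration shows a
mechanism — unmodelled fluctuation erodes boxcar-GLM detection — not a
general superiority claim for ICA pipelines.
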