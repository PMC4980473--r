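# icafluct

Group ICA of block-design fMRI with fluctuation and coupling analysis.

## The problem

When people alternate between visual imagery and thought suppression in
long (48-s) blocks, the network sustaining suppression does not hold a
constant activity level — inhibition is unstable, and the activity
fluctuates within the block. A conventional voxelwise GLM with boxcar
regressors treats that fluctuation as noise and can fail to detect the
network at the group level. `icafluct` implements the alternative,
model-free route for researchers analyzing such designs:

1. **Temporal-concatenation group spatial ICA** (two-stage PCA reduction,
   natural-gradient Infomax with the logistic nonlinearity) with
   **bootstrap stability selection**: the fit is repeated on resampled,
   re-initialized data, all estimates are clustered by average linkage on
   absolute correlation, and each cluster's centrotype is kept together
   with a stability index (mean intra- minus extra-cluster similarity).
   Subject time courses and maps come from dual regression.
2. **Spectral artifact screening** by the low-frequency power ratio
   LFPR = sum of periodogram power in 0.003–0.10 Hz / sum in
   0.15–0.25 Hz, with labels `artifact_spectral` (< 3), `suspicious`
   (< 3.5), and a spatial screen flagging components whose |z| > 2
   voxels lie mostly outside the brain mask.
3. **Task-relatedness**: per-subject OLS on eight HRF-convolved task
   regressors (4 epoch boxcars + 4 cue impulses) with a one-sample
   t-test across subjects on the imagery-minus-suppression contrast
   `Δβ`; plus a pooled-cycle two-sample t-test on the grand-average
   block cycle.
4. **Fluctuation index** — an fMRI adaptation of the Fano factor: after
   0.005–0.1 Hz band-pass filtering, the grand-average block response is
   subtracted from each trial and a subject's residual standard
   deviation is divided by the typical response amplitude. Task effects
   are tested on log indices (paired t), and the task-change ratio is
   related to a binary self-report (two-sample t on log ratios).
5. **Residual-correlation coupling**: block-wise Pearson correlation of
   band-passed, per-block detrended time courses against a reference
   component, Fisher-Z pooled over trials, tested per task across
   subjects, and labelled positive / negative / equivocal (both tasks
   must be significant with concordant sign).
6. A **reference voxelwise GLM** (Bonferroni-corrected random-effects
   group test) used to demonstrate the sensitivity gap: at matched mean
   effect, rising within-block fluctuation erodes GLM detections while
   the component-level test stays significant.

Because no suitable public dataset exists, the package ships a
**synthetic cohort generator** (`simulate_cohort()`) that writes standard
formats (4D NIfTI, BIDS-style `events.tsv` / `participants.tsv`, a JSON
ground-truth sidecar) and injects known spatial maps, condition-dependent
baselines and fluctuation sds, signed latent couplings, and dedicated
artifact components — so the whole pipeline is testable end to end.

## Worked example

```r
library(icafluct)

res <- run_pipeline(run_config(master_seed = 2))
m <- res$matching            # estimated component <-> ground-truth network
s <- res$summary
supp <- m$component[m$truth_name == "supp_net"]
round(s[supp, c("lfpr_mean", "delta_beta", "p1", "fluct_ratio", "fluct_p")], 4)
```

```
  lfpr_mean delta_beta p1 fluct_ratio fluct_p
7    6.6332    -0.1736  0      1.7893       0
```

The suppression network is spectrally clean (LFPR 6.6, far above the 3.5
screen), suppression-related (negative imagery-minus-suppression
contrast; the group p, about 1e-16, prints as 0 at 4 digits), and its
fluctuation index is 1.79-fold higher during suppression (paired log-t
p < 1e-4) — recovering the injected twofold increase. The coupling table
labels the imagery network `negative` (reciprocal activity) and the
executive-control component `positive`, and that control component
carries the strongest association with the simulated self-report
(`res$summary$report_p`). The voxelwise GLM detects the networks at low
fluctuation; `sensitivity_gap()` shows its detections shrinking
(e.g. 257 → 210 → 93 surviving voxels as the fluctuation sd rises
0.5 → 1.5 → 3.0) while the component-level p stays below 0.05.

A command-line wrapper with subcommands (`simulate`, `decompose`,
`screen`, `stats`, `fluct`, `coupling`, `glm`, `run-all`) is installed at
`inst/cli/icafluct.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/icafluct.R", package="icafluct"))')" \
  run-all --seed 2 --out results/demo
```

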