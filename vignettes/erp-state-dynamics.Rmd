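---
title: "Brain-state dynamics in event-related potentials: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-state dynamics in event-related potentials: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpstates)
```

## The problem

Multichannel EEG captures fast fluctuations in the statistical coupling
between scalp electrodes ("dynamic functional connectivity"). A compact way
to describe those fluctuations is to posit a small number of recurring
*brain states*, each characterised by a covariance pattern over channels,
with a hidden Markov chain switching between them. `erpstates` implements
this analysis for two-condition, within-subject ERP experiments: subjects
view stimuli under two conditions (here called `comfort` and `discomfort`,
after the 3D-viewing paradigm that motivates the defaults), their epoched
EEG is averaged into per-condition ERPs, and the package asks whether the
*temporal deployment* of connectivity states — which state the brain
occupies, when, and for how long — differs between the conditions.

## The model

The observation at time point $t$ is the vector $Y_t \in \mathbb{R}^M$ of
ERP signals on $M$ channels. Conditional on the hidden state
$S_t = k \in \{1,\dots,K\}$,

$$Y_t \mid S_t = k \;\sim\; \mathcal{N}(\mu_k, \Sigma_k),$$

and $S_t$ follows a first-order Markov chain with initial distribution
$\pi$ and transition matrix $A$. The state covariance $\Sigma_k$ is read as
the functional-connectivity pattern of state $k$; `fc_matrix()` returns it
as a covariance or rescaled to a correlation matrix.

Fitting is maximum-likelihood EM (Baum–Welch). The E-step runs a scaled
forward–backward pass per subject — each subject's ERP is a separate
sequence restarting from $\pi$, so no artificial transition is created by
concatenating subjects — and the M-step pools responsibilities across
subjects. Because EM is multimodal, `fit_hmm()` runs `n_restarts`
independent restarts from random responsibilities and keeps the fit with
the highest final log-likelihood (the maximum-likelihood analogue of
selecting the minimum variational free energy). Decoding uses the Viterbi
algorithm; ties are broken toward the lower state index so decoding is
deterministic.

Downstream, each subject-condition Viterbi path is summarised by:

* **fraction of time** (fractional occupancy) per state;
* **mean dwell time**: the mean length of consecutive runs of a state;
* **early/late period occupancy**: occupancy computed separately for
  samples at $\le$ `split_ms` (default 1100 ms post-onset) and after it.

Group inference uses paired t-tests on per-state occupancy and an
all-within 2×2×2 repeated-measures ANOVA (condition × state × period) on
the early/late occupancies of the two *dominant* states (highest overall
occupancy). With two levels per factor every effect has one numerator
degree of freedom, so each effect is computed exactly as the one-sample t
of its per-subject contrast and reported as $F = t^2$ with df $(1, n-1)$;
sphericity corrections are moot. Simple effects are paired t-tests on the
corresponding two-cell slices. Subjects lacking a required state in any
condition × period cell are excluded before the ANOVA (with the exclusion
logged), mirroring standard practice when a subject never exhibits a state.

## Pipeline and its tunable parameters

`run_pipeline()` chains: optional average rereference → baseline
correction (default window −200–0 ms) → trial averaging → component-window
amplitudes → paired-t electrode selection → HMM fit per condition →
cross-condition state matching → Viterbi decoding → state metrics →
statistics. The key knobs, with defaults chosen to match the reference
analysis design:

| parameter | default | meaning |
|---|---|---|
| `hmm$K` | 4 | number of hidden states |
| `hmm$n_restarts` | 20 | EM restarts; winner by final log-likelihood |
| `hmm$tol` | 1e-6 | relative log-likelihood change at convergence |
| `selection$alpha` | 0.05 | per-cell paired-t level, uncorrected |
| `selection$windows` | P1 90–130, early N1 100–140, late N1 180–220, P3 280–320 ms | component windows |
| `metrics$split_ms` | 1100 | early/late boundary (early is $\le$) |
| `preprocessing$baseline` | [−200, 0) ms | baseline window |
| `hmm$post_onset_only` | TRUE | HMM sees 0–epoch-end only |
| `hmm$standardize` | TRUE | z-score channels within subject |

Component windows are half-open in post-onset time
(`start_ms <= t < end_ms`), which makes window membership unambiguous at
any sampling rate. Electrode selection combines the four windows by union:
a channel is kept if *any* window shows a paired-t difference at `alpha`,
and the full per-window table is returned so a stricter pooling rule can
be applied downstream. Zero-variance difference cells are flagged
degenerate and never selected (a warning is raised) rather than erroring,
so constant channels cannot crash a run.

Both condition fits reuse the same restart seed sequence, so comfort vs
discomfort differences cannot be an artifact of initialisation luck. State
labels of independently fitted models are arbitrary; `match_states()`
aligns them by maximising, over all label permutations, the total Pearson
correlation between the upper triangles of the correlation-form FC
matrices, and the matching (permutation plus per-pair similarities) is
stored in the report for audit. The ANOVA's "state" factor uses the two
dominant states, and the weak-connectivity member of that pair is
identified as the one with the lower mean absolute off-diagonal
correlation in the first condition's fit.

## Numerical choices

Emission densities are evaluated through the Cholesky factor of each
$\Sigma_k$; covariance M-steps carry a ridge of $10^{-6}$ × mean diagonal,
which keeps updates positive-definite even when the data are rank-deficient
(for example after average rereferencing, which places the channel mean in
the null space). Forward–backward uses per-step normalisation, so
sequences of $10^5$ samples do not underflow. A state whose total
responsibility drops below one sample-equivalent is reinitialised once
within its restart; a second collapse abandons that restart with a
warning. EM stops when the relative log-likelihood change falls below
`tol` or at `max_iter` (default 500).

## The synthetic-data generator

No public ERP dataset accompanies the analysis this package validates
against, so the `synth` module generates studies with known ground truth.
It emulates the statistical structure the analysis assumes — not EEG
physiology:

* a sticky $K$-state chain (diagonal 0.9) with per-subject transition
  matrices drawn from a Dirichlet around the group matrix
  (`subject_jitter`, default 200);
* state-specific covariances in which identity is carried primarily by the
  *connectivity* structure: the weak state is near-diagonal (mean
  |off-diagonal correlation| < 0.15), the strong state couples channels
  through a heterogeneous positive one-factor loading (mean off-diagonal
  correlation ≈ 0.6), and intermediate states mix distinct random
  correlation patterns. A pure common-mode (equicorrelation) strong state
  was deliberately avoided: average rereferencing removes a common mode
  exactly, at any montage size. State means (sd 1 per channel) add
  moderate extra separation;
* time-inhomogeneous dynamics: before `split_ms` the strong-state
  transition column is upweighted (`early_bias` 2), after it the
  weak-state column is multiplied by the per-condition `late_bias`
  (defaults 1.0 comfort, 2.5 discomfort) — so the discomfort condition
  occupies the weak state more in the late period, the effect the
  statistics should detect;
* an ERP component effect: +2 signal units on the frontal–temporal half of
  the montage in the 90–130 ms window, discomfort only, giving the
  electrode-selection stage a real target;
* templates are state-conditional Gaussian draws smoothed by a short
  moving average (default 5 samples at 512 Hz ≈ 10 ms; raw white draws are
  unrealistically rough for ERP-like signals); trials are the template
  plus white noise (`noise_sd` 1), and pre-onset baseline samples are pure
  noise so baseline correction is exercised meaningfully.

What the generator does *not* model: eye/muscle artifacts, electrode
drift, volume conduction, spatially correlated noise (available as an
extension point but off by default), or a realistic 128-channel montage
geometry. Passing tests therefore demonstrate that the *pipeline
machinery* recovers the structure it assumes, under that structure — they
do not certify performance on real EEG.

## Scaled validation runs

The validation suite runs study-sized simulations at reduced problem
sizes, chosen once as the package's own test conditions:

* **recovery**: 20 sequences × 1500 samples, $K=4$, $M=8$, unsmoothed
  emissions from a homogeneous chain — the regime in which decoded paths
  should recover ground truth almost exactly;
* **calibration**: 500 null studies of 30 subjects for the three-way
  interaction and for the per-cell electrode-selection rate;
* **end-to-end**: 37 simulated subjects, $M=8$, 16 trials/condition at
  **128 Hz**, $K=4$, 20 restarts, split 1100 ms.

Two defaults are overridden at the 128 Hz, 8-channel scale, for stated
reasons rather than convenience. First, rereferencing is disabled:
subtracting an 8-channel mean removes 1/8 of every channel and with it
most of the common-variance connectivity signal, a distortion that is
negligible on dense montages where the subtracted mean carries 1/128
weight per channel. Second, the template smoothing window is 2 samples
instead of 5: the default is defined at 512 Hz (~10 ms), and keeping 5
samples at 128 Hz would quadruple the smoothing *duration*, blurring state
boundaries across half a typical dwell and contaminating every fitted
covariance with cross-state mean mixtures. Duration-matched smoothing
preserves the generator's intended temporal structure at the coarser rate.

## Known limitations

* The Gaussian observation model captures zero-lag covariance only; no
  autoregressive, time-embedded or spectral state models are provided.
* Restart selection is by maximised likelihood, not variational free
  energy; no priors, and no model-order selection beyond user-set `K`.
* The weak-state identification rule (lowest off-diagonal correlation
  among the two dominant states) is a heuristic; on single-channel
  selections connectivity is undefined and the pipeline falls back to the
  higher-indexed dominant state, logging the fact.
* The dataset interchange format is plain TSV + JSON; binary EEG formats
  (EDF, BrainVision, EEGLAB) are out of scope.
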