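---
title: "Methods: template matching and training-block composition for cVEP BCIs"
author: "cveptools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: template matching and training-block composition for cVEP BCIs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cveptools)
```

## The problem

A code-modulated visual evoked potential (cVEP) speller flickers each of
its targets with circular shifts of one pseudo-random binary code. The
occipital EEG tracks the flicker, so an unseen trial can be identified by
correlating it with per-target *templates* built from a user's training
data. Training is expensive — each calibration block cycles a cue through
all 32 targets — and EEG is non-stationary across days, so the practical
question this package addresses is: **how should training blocks recorded
on different days be composed into a classification model?**

The package provides the full offline pipeline: stimulus code handling, a
seeded synthetic EEG generator standing in for the (non-public) original
recordings, the CCA/ensemble-TRCA classifier, and the block-composition
evaluation protocols, all behind one model-fitting function,
`cvep_trca()`.

## Stimulus codes

Targets flicker with a 63-bit maximal-length sequence updated at 60 Hz
(one cycle = 1.05 s). Target $k$ uses the base code circularly
left-shifted by $2(k-1)$ bits; with 63 bits and 32 targets every shift is
distinct. An m-sequence is balanced (32 ones, 31 zeros) and has a
two-valued cyclic autocorrelation ($63$ at lag 0, $-1$ elsewhere in
$\pm1$ encoding), which is what makes shifted copies of the same code
separable by correlation.

The published shift description ("left shifting by $k \cdot 2$ bits" for
$k \ge 2$) would place the base code off the uniform two-bit grid (shift
$64 \equiv 1 \bmod 63$ for $k = 32$, and no target at shift 2). We default
to the uniform convention $\mathrm{shift}(k) = 2(k-1) \bmod 63$, which
makes target 1 the unshifted code and matches common cVEP practice; the
literal reading is available via `code_set(literal_shifts = TRUE)`.
`lfsr_msequence()` regenerates codes from a degree-6 primitive polynomial;
it is validated against the balance/autocorrelation invariants rather than
bit-for-bit, since different primitive polynomials give different (equally
valid) m-sequences.

## The classifier

Each trial is an $m \times n$ matrix with $m = 16$ channels and
$n = 2 \times 1.05\,\mathrm{s} \times 600\,\mathrm{Hz} = 1260$ samples.

**Spatial filters (CCA).** For class $i$, the training trials
$T_{i,1}, \dots, T_{i,n_b}$ are averaged into a template $\hat X_i$, and
the filter $w_i \in \mathbb{R}^m$ is the $X$-side weight of the first
canonical correlation between the horizontal concatenation
$\hat T_i = [T_{i,1} \cdots T_{i,n_b}]$ and the template tiled $n_b$
times. CCA maximises
$\rho = \max_{w_X, w_Y} \mathrm{corr}(X^\top w_X,\; Y^\top w_Y)$,
solved here in the whitened form: $\rho$ is the largest singular value of
$C_{XX}^{-1/2} C_{XY} C_{YY}^{-1/2}$.

Numerical choices:

* a ridge $\lambda I$ with $\lambda = 10^{-8}\,\mathrm{tr}(C)/m$ is added
  to both auto-covariances — concatenations of few short trials can be
  near-singular at $m = 16$;
* the sign indeterminacy is fixed by making the largest-magnitude entry
  of $w_X$ positive (and keeping the canonical correlation non-negative),
  so fits are bit-reproducible;
* weights are scaled to unit-variance canonical variates;
* channels are mean-centered before covariances are formed. Centering
  makes an exact algebraic reduction available: with centered trials the
  cross- and template-covariances coincide
  ($C_{XY} = C_{YY} = \hat X_i \hat X_i^\top / n$) and
  $C_{XX}$ is the mean per-trial covariance, so the fit needs only
  $m \times m$ matrices and never materialises the concatenation. The
  explicit route survives as `class_filter()`/`solve_cca()` and the test
  suite asserts both routes agree to machine precision.

A true TRCA eigen-decomposition (maximising inter-trial covariance) is
deliberately *not* used: this pipeline substitutes CCA-derived filters
into the TRCA-style ensemble template-matching scheme.

**Filter bank.** Before fitting or scoring, every trial is decomposed
into $K = 5$ sub-bands with lower edges 6, 14, 22, 30, 38 Hz and a shared
60 Hz upper edge: 4th-order Butterworth band-passes applied forward and
reverse (zero phase; the effective magnitude is the squared single-pass
response). Filters are designed with `signal::butter` in transfer-function
form with a pole-radius guard (max pole radius across the five bands is
0.98 at $f_s = 600$ Hz) and applied in compiled code to whole channel
matrices. Trials are short, so each end is reflect-padded by several
settling lengths before filtering and trimmed afterwards; the padding
scheme is this implementation's own choice, as is the decision to compute
spatial filters *per sub-band* (the alternative — one broadband filter
reused across bands — is not distinguishable from the published
description; per-band filtering matches ensemble-TRCA practice).

Sub-band correlations are combined with weights

$$a_k = \frac{k^{-1.25} + 0.25}{\sum_{j=1}^{K} (j^{-1.25} + 0.25)},$$

i.e. `r paste(round(subband_weights(5), 3), collapse = ", ")` for
$K = 5$ — decaying with $k$ because VEP energy concentrates in the low
bands.

**Decision rule.** The per-class filters are concatenated into the
ensemble matrix $W_k = [w_1 \cdots w_{32}]$ of sub-band $k$. A test trial
$X$ is scored against class $i$ as

$$\lambda_i = \sum_{k=1}^{K} a_k\,
  \rho\!\left(\mathrm{vec}(\hat X_{i,k}^\top W_k),\;
              \mathrm{vec}(X_k^\top W_k)\right),$$

the weighted Pearson correlation of the flattened ensemble projections,
and the predicted class is $\arg\max_i \lambda_i$ (ties broken toward the
lowest index, for determinism). Scores are convex combinations of
correlations and hence lie in $[-1, 1]$; a trial equal to its own
noiseless template scores exactly 1. The published decision-rule notation
correlates two training-side quantities and reuses one symbol for both
the class count and the sub-band count; the implementation follows the
ensemble-TRCA semantics — sum over sub-bands, arg-max over classes, test
trial substituted for the second argument. The full two-cycle window is
always used; there is no early stopping.

## The synthetic study generator

The original two-session recordings are not public, so the generator
produces data with exactly the statistical structure the classifier
assumes — a linear template model — with no claim of physiological
realism beyond it:

* **Subject** (`sample_subject()`): an evoked impulse response (0.25 s
  difference-of-gamma kernel; peak latency uniform in 0.09–0.15 s,
  amplitude log-normal with $\sigma_{\log} = 0.3$), a unit-norm spatial
  mixing vector concentrated on the "occipital" end of the 16-channel
  montage (Gaussian profile centered on channel 14, width 2.5 channels,
  per-channel log-normal jitter), an SNR scale, and a per-trial latency
  jitter SD (3 ms).
* **Trial**: the target's sample-domain code (circularly convolved with
  the kernel over one 630-sample cycle, tiled twice) times the mixing
  vector, plus noise: per-channel pink (1/f amplitude) and white noise
  mixed 80/20 in power, with a 10%-amplitude common-mode pink component
  to induce channel correlation. Noise is scaled so evoked power / noise
  power equals `snr_scale`.
* **Session effects** (`session_effect()`): amplitude gain
  $\sim \mathrm{lognormal}(0, 0.1)$, latency shift
  $\sim \mathcal N(0, 5\,\mathrm{ms})$, a smooth relative kernel
  perturbation (SD 0.15 of kernel RMS), and a noise gain — identical for
  all blocks of one session. These create the session-to-session
  degradation the protocols are designed to measure.
* **Study** (`simulate_study()`): per subject, two sessions with
  independent effects; session 1 carries block ids 1–6, session 2 ids
  7–12. Everything derives deterministically from one master seed.

`snr_scale = 0.25` is a calibration constant, chosen once so that
single-session leave-one-block-out accuracy of the default pipeline
averages ≈ 94–95%, the range reported for trained cVEP users; it lives in
`cvep_sim_config()`, not in the code.

What the generator does *not* emulate: eye blinks and movement artifacts,
electrode drift within a session, amplifier characteristics, montage
geometry, or any nonlinearity of the visual response. Passing tests on
synthetic data therefore demonstrate correctness of the *pipeline* —
code handling, filtering, CCA algebra, scoring, protocol bookkeeping —
and qualitative behaviours (session transfer loss, benefit of added
blocks), not performance claims about real EEG.

The "noiseless" limit used by the tests sets both the noise gain and the
latency jitter to zero (jitter is a noise source in the latency domain);
the generator is then fully deterministic and classification must be
exact. With jitter active, models trained on a single block can
occasionally confuse adjacent codes, because a one-trial template carries
that trial's jitter; from two training blocks upwards the synthetic study
classifies perfectly without sensor noise.

## Evaluation protocols

Blocks are indexed 1–6 (session 1) and 7–12 (session 2); the interleaved
sequence `seq = 1, 7, 2, 8, 3, 9, 4, 10, 5, 11, 6, 12` alternates days.

* **Cross-session** (`cross_session_plans()`): same-session cells are
  leave-one-block-out (model from 5 blocks, average over 6 folds) —
  testing a model on its own training blocks would be resubstitution;
  cross-session cells use all six source blocks against each target-day
  block.
* **Stepwise** (`stepwise_plans(test_block)`): the test block is removed
  from `seq` and step $s$ fits on the first $s$ remaining blocks,
  $s = 1..11$.
* **Variants** (`variant_plans()`): five fixed reduced-training splits
  (V1–V5). V3 keeps block 11 out of both sets even though only 5 and 6
  are ever dropped from models — the published construction is asymmetric
  there and is implemented literally.
* **Cross-subject** (`cross_subject_grid()`): model of subject $i$
  against data of subject $j$ for all pairs; the diagonal of a
  same-session grid reuses the leave-one-block-out cells.

Accuracies are stored as percentages; `aggregate_report()` first averages
within subject, then reports the mean and sample SD across subjects —
the layout of the published summary tables.

**Information transfer rate.** `itr()` implements the Wolpaw formula
$\mathrm{ITR} = \left(\log_2 N + P \log_2 P + (1-P)\log_2\frac{1-P}{N-1}\right)\cdot 60/T$
with $T = 3.1$ s (2.1 s gaze + 1.0 s pause) and $0\log 0 = 0$. Values at
or below chance ($P \le 1/N$) are clamped to zero — the published tables
floor a below-chance cell although the raw formula is positive there —
with `clamp = FALSE` exposing the raw value. ITR is strictly increasing
on $(1/N, 1]$ and equals $\log_2(N) \cdot 60/T$ at $P = 1$.

## Problem sizes used by the test suite

Unit tests run at the full 32-target, 16-channel, 1260-sample trial
geometry but mostly with 1–3 blocks per session, which exercises every
code path at a fraction of the full-study cost. The two multi-seed
behavioural checks use 20 independently seeded single-subject studies at
the full 2 × 6-block size each: one verifies that mean stepwise accuracy
is non-decreasing from step 1 to step 2 to step 11, the other that mean
inter-session accuracy falls below intra-session accuracy under default
session effects. Both are direction-only claims; the magnitudes on
synthetic data are not calibrated beyond the single `snr_scale` constant
described above.

## Known limitations

* The dataset container stores matrices as plain text: bit-exact
  (17-significant-digit decimals) and portable, but roughly 13 MB per
  block file — adequate for synthetic studies, not an archival EEG
  format.
* Real recordings can only enter through that container; no vendor EEG
  formats are read.
* No artifact rejection, re-referencing or notch filtering is applied —
  the published pipeline describes none.
* Statistical significance testing between protocol cells is out of
  scope; the numbers needed for it depend on the non-public recordings.
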