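---
title: "Inferring uncoupled power and connectivity dynamics with mdynemo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring uncoupled power and connectivity dynamics with mdynemo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Electrophysiological recordings (e.g. parcellated MEG amplitude envelopes)
show network activity that reorganises on the order of 100 ms. Two aspects
of that activity are usually summarised separately: *power*, the variance of
each channel's envelope, and *functional connectivity* (FC), the correlation
between channels. Most dynamic-network methods — sliding-window clustering,
hidden Markov models, single-dynamic network-modes models — implicitly force
power and FC to switch together. `mdynemo` implements a multi-dynamic
network-modes model that lets the two evolve as separate (but mutually
informed) latent processes, so the hypothesis "power and FC share one
dynamic" becomes testable rather than assumed.

## The generative model

Data are modelled as zero-mean Gaussian with a time-varying covariance

$$x_t \sim \mathcal N(0, C_t), \qquad C_t = G_t F_t G_t,$$

where $G_t$ is diagonal with strictly positive entries (per-channel standard
deviations: power) and $F_t$ is a unit-diagonal positive-definite matrix
(correlations: FC). Each factor is a convex mixture of a small basis of
*modes*:

$$G_t = \sum_{j=1}^{J_1} \alpha_{jt} E_j, \qquad
  F_t = \sum_{j=1}^{J_2} \beta_{jt} R_j.$$

The $E_j$ are diagonal with positive entries and the $R_j$ are correlation
matrices; the mode counts $J_1$ and $J_2$ are independent settings. The
mixing weights are row-wise softmax transforms of two latent logit
sequences, $\alpha_t = \mathrm{softmax}(\theta^1_t)$ and
$\beta_t = \mathrm{softmax}(\theta^2_t)$. The joint prior over the logits is
autoregressive: an LSTM consumes the concatenated history
$\theta^{1,2}_{1:t-1}$ and, per dynamic, a linear head emits the prior mean
while a softplus head emits an isotropic prior scale. Because the prior
conditions each dynamic on the history of *both* dynamics, the two time
courses can inform each other without being forced to agree.

## Inference

Training minimises the variational free energy of each 200-sample sequence:
the negative expected log-likelihood under one reparameterised posterior
sample plus the sum over $t \ge 2$ and both dynamics of the closed-form
Gaussian KL between posterior and prior. The posterior is amortized: a
bidirectional LSTM runs over the data sequence and per-dynamic heads emit a
mean vector and an isotropic scale per time point (a mean-field posterior
over time and dynamics). Amortization means unseen sessions can be scored
by a single encoder pass (`infer_mixing`), and it is what makes dual
estimation (`dual_estimate`) cheap: the temporal posteriors are frozen and
only the observation parameters are re-optimised on one session.

Because no automatic-differentiation framework is part of this package's
dependency set, the recurrent networks and every gradient are analytic:
batched LSTM backpropagation-through-time, softmax and softplus chains, and
the likelihood gradients with respect to mixing weights and mode matrices
(the latter in compiled code). The test suite pins all of this twice over —
finite-difference checks on every parameter group, and an independent
straight-line evaluation of the free energy (scalar loops, explicit
inverses and determinants) that the batched objective must match to 1e-6.

### Parameter constraints

Gradient training works on unconstrained parameters:

* $E_j$ diagonals are `softplus` of raw values — smooth, total, and standard
  for variance-like parameters;
* each $R_j$ is built from an unconstrained lower-triangular factor $L_j$ as
  $R_j = D^{-1/2} M D^{-1/2}$ with $M = L_j L_j^\top + 10^{-6} I$ and
  $D = \mathrm{diag}(M)$, which is unit-diagonal and positive definite for
  *any* raw input. The Cholesky factorisation is the canonical
  positive-definiteness check throughout, with a $10^{-6}$ tolerance floor.

### Training schedule

Settings that matter, with defaults and why:

* `sequence_length = 200`: sessions are chunked into non-overlapping
  200-sample sequences (remainders dropped); the recurrent state resets at
  sequence boundaries because the per-sequence loss makes cross-sequence
  state meaningless.
* `kl_anneal_epochs`: the KL weight ramps linearly from 0 to 1. Annealing
  lets the observation model find sensible modes before the temporal prior
  starts regularising the logits.
* `n_starts` (default 10): independent restarts with best-final-loss
  selection, since the loss surface is multimodal.
* `learning_rate` (Adam, default 1e-3) with `lr_decay`: the rate is halved
  smoothly over the second half of training, which stabilises the sharp,
  near-binary mixing courses that emerge late in training.
* `hidden_dim` (default 64): recurrent width of prior and encoder.
* one posterior sample per step for the likelihood term; batching supplies
  the variance reduction.
* the first time step's posterior is unpenalised — the KL sum starts at
  $t = 2$, exactly as the per-sequence objective is defined.
* divergence guard: a restart whose loss exceeds ten times its initial value
  is aborted and excluded from model selection.

Observation parameters initialise from data. Short-window (50-sample)
standard-deviation and correlation features are clustered by K-means into
$J_1$ and $J_2$ groups, and each mode starts at a (jittered) cluster
centroid — correlation centroids are shrunk toward the identity until
positive definite before factorisation. Centroid seeding plants one mode
per empirical regime; cold random initialisation, by contrast, is prone to
a characteristic local optimum in which two similar power modes merge into
one "background versus active" course with a visibly worse free energy.
With centroid seeding, independent restarts land in the same basin as a
ground-truth-initialised run on the simulations used here.

### PCA-incorporated training

Real envelope data benefit from orthogonalisation. For an orthonormal
full-rank rotation $W$, $\log\mathcal N(Wx \mid 0, WCW^\top) =
\log\mathcal N(x \mid 0, C)$, so the package trains with the encoder
reading the rotated data while the likelihood is evaluated in the original
space with the original-space modes. This is algebraically identical to
projecting every mode matrix ($\tilde E_j = W E_j W^\top$, etc.) and keeps
the learnt modes interpretable without any back-projection step.
`project_modes` exposes the projection itself for reporting.

## The simulator

`simulate_sessions` generates the conditions the model is tested under:
hidden Markov chains (uniform initial state; `stay_prob` on the transition
diagonal, remainder uniform) select one power and one FC state per sample,
and data are drawn from the implied $G F G$ covariance. Mixing is hard
one-hot, i.e. HMM-style binarised time courses — deliberately *not* the
model's own soft-mixture prior, so recovery is demonstrated under model
mismatch. `shared_dynamics = TRUE` drives both factors with a single chain.
Mode separation is controlled by two scales: power diagonals are
$\exp(\mathrm{sep_{power}}\, z)$ with standard-normal $z$, and FC modes are
correlation-normalised low-rank Gram matrices scaled by $\mathrm{sep_{fc}}$
(both collapse to identical modes at 0). Defaults (`sep_power = 0.4`,
`sep_fc = 0.6`, rank 3) give visually distinct mode maps — channel standard
deviations spanning roughly 0.5–2 and correlations reaching ±0.5 — typical
of what envelope data show while keeping states statistically
distinguishable within a ~50-sample lifetime.

What the simulator does *not* emulate: oscillatory (pre-envelope) signals,
spatial leakage between parcels, between-session variability in modes, and
non-Gaussian heavy tails. Passing recovery tests therefore demonstrates
correct inference under the model's own data regime plus binarised
dynamics, not robustness to every artefact of real recordings.

`simulate_task` adds event-locked structure by forcing a designated chain
into a designated state for a window after each onset with a given
probability; probability 0 is an exact null for calibration studies.

## Problem sizes used by the tests and the acceptance script

All heavy checks run at a desk scale chosen as the package's reference
conditions: 20 channels, 3 power + 3 FC states, `stay_prob = 0.98` (mean
lifetime 50 samples), four sessions of 12,800 samples; training with width
32, 40 epochs, KL annealing over 15, learning rate 1e-2 decaying by 0.3,
one restart. At this size one training run takes a few minutes on one CPU
core, and recovery is comfortably above the thresholds asserted in the
acceptance tests (time-course correlations ≥ 0.8, matched mode cosines
≥ 0.9, cross-dynamic coupling ≤ 0.2 for independent chains, ≥ 0.8 for a
shared chain). The single-dynamic comparison uses stronger power than FC
separation (0.6 vs 0.3), the regime in which the shared-dynamics model's
one time course should — and does — track power rather than FC.

## Post-hoc statistics

* **Renormalisation**: raw mixing weights ignore how *big* each mode is.
  `renormalise` reweights $\alpha_{jt}$ by $w_j$ = mean $E_j$ diagonal (and
  $\beta_{jt}$ by the mean absolute off-diagonal of $R_j$) and rescales rows
  to the simplex, so the courses read as contributions to total variance /
  total correlation.
* **Mode matching** (`match_modes`): cosine similarity between mean-centred
  spatial maps with an exact assignment search (mode counts are small
  enough that enumeration equals the Hungarian optimum).
* **Permutation engines**: all familywise inference uses maximum-statistic
  nulls with the add-one p-value estimator and a 5% mask. The cosine test
  permutes parcels within each map — preserving per-map value distributions
  while destroying spatial correspondence. Group coupling tests Fisher-z
  transform per-session correlations and sign-flip whole sessions. The
  evoked GLM is two-level: per-session OLS of baseline-corrected epochs on
  separate condition regressors with contrast vectors on top, then a group
  one-sample t per (time, mode) cell with sign-flip max-|t| correction
  across all cells. Baseline correction subtracts each trial's mean over
  the full pre-stimulus window.
* **Network recalculation** (`recalc_networks`): given any fixed mixing
  course, per-mode covariances solve the elementwise least-squares problem
  $\min \sum_t \|x_t x_t^\top - \sum_j m_{jt} C_j\|_F^2$ — an exact inverse
  of the generative construction as $T$ grows. This is how "what would the
  networks look like if the FC dynamic were ignored" is answered.

## Design choices made where the design was open

* Prior and posterior scales are isotropic per dynamic per time point
  (scalar softplus heads), matching the model statement above.
* Renormalisation weights use mean diagonal / mean absolute off-diagonal;
  any monotone magnitude summary would serve, and this one makes the two
  dynamics' weights dimensionally comparable.
* PCA is fit on session-concatenated standardised data (a group projection)
  rather than per session, matching the group-level generative model;
  eigenvector signs are fixed by making each row's largest-magnitude entry
  positive, for reproducibility.
* The sliding-window baseline assigns window features to window-centre
  samples and defaults to K = 4 clusters (mirroring the default mode
  count); k-means uses 10 restarts and an exposed seed.
* Group inference units are sessions.
* Session stores are plain-text (TSV matrices + JSON manifest) and model
  checkpoints are RDS files written at run time.

## Known limitations

* Means are assumed zero and the likelihood Gaussian; heavy-tailed envelope
  noise will leak into the inferred modes.
* Mode counts are fixed settings; the package offers no model selection
  over $J_1, J_2$.
* Single-CPU training: desk-scale by design. Sequence length, width and
  epochs trade off against runtime roughly linearly.
* The amortized posterior is mean-field over time and dynamics;
  uncertainty estimates are per-time-point and do not capture joint
  temporal uncertainty.
* Spectrally resolved (time-delay-embedded) covariances are out of scope;
  the model sees broadband envelope correlations only.
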