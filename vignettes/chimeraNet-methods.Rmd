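---
title: "chimeraNet: methods and design notes"
author: "chimeraNet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chimeraNet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

chimeraNet studies **chimera states** — network regimes in which one group of
coupled oscillators phase-synchronizes while another stays incoherent — as
precursors of epileptic seizures, on simulated EEG where the ground truth is
known. This vignette explains the models, the tunable parameters and their
units, the numerical choices, and the places where the design was genuinely
open and a decision had to be made. It states no empirical numbers beyond
what the package's tests and `scripts/acceptance.R` themselves compute.

## 1. The oscillator model

The generator integrates a two-community Kuramoto–Sakaguchi network,

$$\dot\theta_i \;=\; \omega_i \;+\; \frac{1}{C}\sum_{j=1}^{C} K_{ij}
\sin(\theta_j - \theta_i - \alpha),$$

with $K_{ij} = K$ within a community and $K_{ij} = rK$ across communities
(default $r = 0.7$). The mean-field $1/C$ normalization makes $K$ comparable
across montage sizes. Defaults: $C = 23$ channels split 12/11,
$K = 0.71$, $\alpha = 0.28$ rad — the chimera operating point — integrated
by classical fourth-order Runge–Kutta at the sampling step (1/256 s; the
integrator is compiled, and a convergence test checks that halving the step
moves final phases by less than $10^{-4}$ rad).

**Frequencies.** Community 0 (synchronization-prone) is centred at 2.3 Hz
(pathological delta slowing), community 1 (desynchronized) at 9.1 Hz with a
1.3 Hz spread (normal alpha rhythm). A key modelling decision: the
*within-network* spread of community 0 is small (sd 0.01 Hz, i.e.
near-identical oscillators, as in the chimera literature). With the
mean-field normalization above, the effective intra-community coupling is
$K \cdot n_0/C \approx 0.37$ rad/s; a community whose frequency spread is
of order $2\pi \cdot 0.5$ rad/s can never lock at any admissible $K$, so a
band-width-sized spread must be read as *across-recording* variability of
the band centre, not oscillator heterogeneity. Community 1 keeps the full
alpha-band spread — its incoherence is heterogeneity-driven and survives
every coupling the generator ever applies. The synchronization *contrast*
between the two communities is the chimera.

## 2. The synthetic episode and what it does (not) emulate

`generateEpisode()` produces one continuous recording with six segments —
baseline, emergence, stabilization, transition, ictal, post-ictal — by
scheduling three things per integration step:

* **coupling** $K(t)$: weak at baseline (0.1), ramping to 0.71 during
  emergence, held during stabilization, ramping to 1.2 through the
  transition, then decaying post-ictally;
* **frequency wander**: a per-oscillator, piecewise-constant detune
  (sd 0.8 rad/s, refreshed every 0.5 s) active at baseline and post-ictally
  and ramped out during emergence. Without it, the near-identical community-0
  oscillators would stay phase-aligned inside 5-second windows even when
  uncoupled, and interictal windows would be indistinguishable from chimera
  windows. Physically it stands for the frequency instability of interictal
  rhythms; synchronization stabilizes the rhythm as coupling takes over;
* **entrainment** $m(t)$: during the transition, natural frequencies migrate
  toward the delta rhythm ($\omega_i \to \bar\omega_0$), reaching full
  entrainment in the ictal segment. Coupling alone cannot drag an 8 rad/s
  frequency spread into lock under $K \le 1.5$; hypersynchronous seizure
  rhythms are frequency-entrained, not merely coupled, and the generator
  models exactly that. Post-ictally the frequencies revert.

Segment durations default to the canonical clinical progression (20 min
baseline, 20 min emergence, 45 min stabilization, 7.5 min transition,
1.5 min seizure, 10 min recovery), expressed in simulated seconds after a
10-fold time compression; **labels are always in uncompressed clinical
minutes**. `benchmarkEpisodeSpec()` is a short variant (about 100 s
simulated) used where tens of episodes are generated and a model trained in
minutes; dynamics and labelling rules are identical.

Observations are $x_c = \sin\theta_c + \varepsilon$,
$\varepsilon \sim N(0, 0.1)$. The generator targets the *phase structure*
the method consumes; it does not emulate 1/f background, spindles, muscle
artifact or volume conduction. Tests passing on this generator therefore
validate the pipeline's phase-processing logic and learnability, not
clinical performance.

**Labels.** Per 5-second window (50% overlap): `ychimera` applies the
contrast rule $\max(R_{cluster}) - \min(R_{cluster}) > 0.3$ (strict, with a
$10^{-12}$ floating-point guard) on the *true* communities' order
parameters; `ystate` is 0/1/2/3 for baseline / pre-ictal / ictal /
post-ictal by window midpoint; `ytime` is minutes to onset from the window
end, capped at 90, defined as 0 during the seizure and 90 afterwards. Note
that early post-ictal windows can legitimately carry `ychimera = 1`: the
entrained community decoheres faster than the delta community, which
briefly recreates a synchronization contrast (post-ictal slowing).

## 3. Phases, PLV, hypergraphs

Instantaneous phases come from the FFT-based analytic signal; the first and
last 0.5 s are flagged as an edge guard and excluded downstream (the
circular convolution distorts edges; the trajectory is also zero-padded to
a highly composite length because R's FFT is quadratic for prime lengths).
PLV is the modulus of the window-averaged unit phasor of the phase
difference, on raw in-window samples; within-window autocorrelation biases
PLV upward identically for all methods, so comparisons remain valid and no
correction is applied. Windows are half-open $[t, t+5)$ with 0-based time;
a sample on a boundary belongs to the later window.

The refiner (`refineAdjacency`) implements
$A = \mathrm{softmax}(\mathrm{MLP}(X_{feat}) \odot A_{PLV})$ with a
row-wise softmax, symmetrization $(M + M^T)/2$ and max-normalization back
to $[0,1]$ — a row softmax over 23 entries caps values near $1/23$, which
would make the printed clique threshold meaningless; the renormalization
restores the scale and is flagged loudly here. **Identity mode** (the
default throughout the package) passes the PLV matrix through unchanged up
to max-normalization, preserving its ranking exactly. The refiner is *not*
trained jointly with the main network: the clique step below is discrete
and blocks gradients, and rebuilding graphs every optimization step is not
viable at desk scale; the MLP exists, is initialisable and testable, and
the identity mode is the ablation baseline.

Hyperedges are all channel triplets whose three pairwise adjacencies
strictly exceed $\tau = 0.65$; enumeration is exhaustive and checked
against a brute-force oracle. "Entropy measures" among the channel features
is implemented as the spectral (Shannon) entropy of the Welch periodogram;
sample entropy was rejected for cost. Kurtosis in the artifact criteria is
the plain fourth standardized moment (Gaussian = 3, sinusoid = 1.5), which
is the only reading under which a threshold of 5.0 is sensible.

## 4. Chimera metrics

Spectral clustering (normalized Laplacian, k-means embedding, $k = 2$ by
default — the structure loss speaks of most and least synchronized
communities) runs per window, with labels aligned to the previous window by
maximal overlap to prevent label switching. The three-phase segmentation
reconstructs emergence (first run of $\ge 3$ chimera-positive windows),
stabilization (centred 5-window moving average of contrast above 0.3 with
slope magnitude below 0.01/window; the slope is a least-squares fit over a
$\pm 2$-window neighbourhood, which is far less noisy than a one-step
difference) and transition (first subsequent window whose minimum cluster
order parameter exceeds 0.7). All three constants are configuration
arguments and are reconstructions of a qualitative description, not
literature values.

## 5. The network

Node features per window are the nine signal features plus two structural
ones (node strength = mean adjacency to the other channels, and normalized
hyperedge participation); practical graph networks routinely append such
degree-style features, and here they carry the synchronization information
that per-channel statistics of near-sinusoidal signals cannot. All windows
of an episode are stacked into one block-diagonal hypergraph so an episode
is a single forward pass.

* **Hypergraph convolution**: per node, incident hyperedges are mean-pooled,
  scored by a two-layer attention net, softmax-normalized per node and
  summed; the aggregate is concatenated with the node state, linearly
  mapped, ELU-activated, layer-normalized, and residually connected
  (projected when dimensions change). Nodes in no hyperedge aggregate a
  zero vector — at baseline most nodes are isolated, which is itself
  informative. Dropout 0.3 in train mode.
* **Selective state-space blocks**: the continuous system
  $h' = A(z_t)h + B(z_t)z_t$, $y = C(z_t)h + D(z_t)z_t$ with all maps
  input-dependent affine functions, discretized by zero-order hold with a
  learnable step $\Delta = e^{\log\Delta}$ (init 0.01). A full
  input-dependent $d \times d$ state matrix is computationally implausible;
  $A$ is diagonal and parameterized $-\mathrm{softplus}(\cdot)$, which
  guarantees stability ($\bar A = e^{\Delta A} \in (0,1)$); $\bar B =
  (\bar A - I)A^{-1}B$ uses a series fallback for small $|A\Delta|$. The
  recurrence is linear in sequence length; a doubling parallel-prefix scan
  is provided and tested against the naive recurrence.
* **Heads**: chimera (sigmoid), state (4-way softmax), time (ReLU, minutes;
  its output bias starts positive so the ReLU is alive at init), each with
  batch normalization over the window batch and dropout. The physics heads
  map each window embedding to phases ($\pi\tanh$), frequencies
  (softplus), coupling (sigmoid) and phase lag ($\frac{\pi}{2}$ sigmoid);
  biases are set so fresh models output $K \approx 0.7$ and
  $\alpha \approx \pi/6$. The frequency bias starts near the drift scale
  that wrapped window-to-window phase differences can actually resolve
  (well under $\pi$ per two hops, i.e. a fraction of a rad/s) — starting it
  at a carrier frequency would make the physics residual enormous and its
  gradient would fight the task heads through the shared trunk.

Desk-scale defaults are two convolution layers (16, 32), two blocks of
dimension 32 and 16-wide heads; `modelConfig(fullScale = TRUE)` selects
the full-size architecture (64–128–256, four blocks, 128-wide heads).

The whole network, its reverse-mode gradients (a small tape-based
autodiff engine with fused adjoints for the attention aggregation and the
diagonal scan), AdamW and the training loop are implemented in base R; a
test validates every parameter group's gradient against central finite
differences at relative error below $10^{-3}$.

## 6. Losses and training

The multi-task objective is the weighted sum with weights 1.0 (chimera
focal loss, $\gamma = 2$, $\alpha = 0.7$), 0.8 (state cross-entropy with
label smoothing $\varepsilon = 0.1$), 0.5 (time Huber loss with a 5-minute
knot), 0.03 (Kuramoto-consistency loss: squared mismatch between central
circular finite differences of the per-window phase estimates and the
mean-field vector field evaluated with the model's own $\hat\omega, \hat K,
\hat\alpha$) and 0.02 (chimera structure loss
$-|R_{sync} - R_{desync}| + \lambda_{div} H$). Two ambiguities are worth
recording: $\lambda_{div}$ has no literature value (default 0.1,
configurable), and the printed structure-loss formula *penalizes* community
-size entropy while its accompanying prose says entropy is encouraged; the
printed sign is the default and `entropySign = -1` selects the prose
reading. The community assignment inside the structure loss comes from
spectral clustering on the predicted phases and is treated as constant for
the gradient (a straight-through choice; the discrete clustering has no
useful derivative).

Training: AdamW (weight decay 0.01), main learning rate 3e-4 with the
physics heads at exactly 0.1 of it, cosine annealing, global gradient
clipping at norm 1.0, early stopping on validation chimera accuracy with
patience 15. One optimization step processes one episode (roughly 40–80
windows, the same order as a 32-window batch). Optional self-supervised
pretraining masks $\lceil 0.15\,C \rceil$ nodes per window (a learned mask
token replaces their features) and reconstructs masked features (MSE) and
masked rows of the thresholded adjacency (BCE); it reconstructs *input*
features, the simpler of the two readings of the reconstruction target,
and is off by default at desk scale.

The learnability check ("overfit a single episode to total loss below
0.1") runs with $\varepsilon = 0$: with label smoothing on, the smoothed
cross-entropy has an entropy floor of about $0.43 \times 0.8$, so the
bound is only meaningful for the unsmoothed objective — the natural
reading of an overfit sanity check.

## 7. Evaluation

Episode-level stratified folds (greedy assignment by decreasing seizure
count under fold-size caps) mirror patient-level splits. Alarms fire at the
k-th consecutive supra-threshold window (default $k = 2$) with a 30-minute
refractory period — the alarm policy is a package definition, exposed in
configuration, since FP/hr is meaningless without one. A seizure counts as
predicted at horizon $H$ if an alarm falls in $[onset - H, onset)$ on the
uncompressed clock; false positives are alarms outside all pre-ictal and
ictal intervals, and the FP/hr denominator excludes pre-ictal and ictal
time (alarms during a seizure are neither true nor false positives).
Confidence intervals are percentile bootstrap over episodes (1000
resamples); bias-corrected variants are out of scope.

## 8. Problem sizes and determinism

All randomness flows through integer seeds (kept below $2^{31}$); episode
generation, ICA, clustering, dropout, fold splits and bootstrap are
reproducible from a single seed. The test and acceptance workloads use the
sizes the package was designed around: 20 replicate simulations of 60 s for
parameter recovery, 10 stabilization fixtures of 120 s for band and density
calibration, 20 full default episodes for the contrast rule, and a
40-episode benchmark (30 train / 10 held-out, three training seeds) for the
learnability and ablation checks.

## 9. Known limitations

* The generator's chimera is heterogeneity-stabilized (one near-identical
  community, one broadly spread), not the classical identical-oscillator
  chimera sustained purely by the phase lag; the latter needs parameter
  regimes (near-$\pi/2$ lag) the operating point does not visit.
* The chimera-detection task on synthetic episodes saturates near its label
  noise (windows straddling segment boundaries), so small architectural
  ablations land within a window or two of each other; ordering comparisons
  between near-equal variants are correspondingly fragile.
* The wrapped central difference in the physics loss resolves phase drifts
  only below $\pi$ per two window hops; carrier-frequency dynamics alias.
  The loss is a consistency regularizer on slow collective drift, not a
  spectroscopic estimate.
* Real-EEG effects (artifacts beyond the five ICA criteria, non-stationary
  montages, volume conduction) are untouched by construction.
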