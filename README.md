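# chimeraNet

Chimera states — network regimes in which one community of coupled
oscillators phase-synchronizes while another stays incoherent — appear in
intracranial and scalp EEG tens of minutes before epileptic seizures: a
delta-band region locks while the surrounding alpha-band cortex keeps its
normal, desynchronized rhythm, and the contrast collapses into global
synchronization at onset. chimeraNet is an R package for studying this
mechanism end to end on simulated oscillator networks with known ground
truth. It is written for methods researchers in computational neuroscience
and network physiology who need a controlled, fully seeded test bed for
chimera detection and physics-informed seizure prediction — not for
clinical use.

The package provides:

* a **Kuramoto–Sakaguchi generator** of labelled synthetic EEG episodes.
  The network obeys
  `dθᵢ/dt = ωᵢ + (1/C) Σⱼ Kᵢⱼ sin(θⱼ − θᵢ − α)` with two communities
  (delta-band, 2.3 Hz, synchronization-prone; alpha-band, 9.1 ± 1.3 Hz,
  desynchronized), coupling `K = 0.71`, phase lag `α = 0.28` rad and
  cross-community ratio `r = 0.7`. Episodes traverse the pre-seizure
  progression — baseline, chimera emergence, stabilization, rapid
  transition, seizure, recovery — with per-window labels
  (chimera flag, 4-class state, minutes-to-onset capped at 90);
* **preprocessing**: polyphase resampling, zero-phase 4th-order Butterworth
  bandpass (1–50 Hz), the five ICA artifact-component criteria
  (kurtosis > 5, high-frequency power ratio > 40%, frontal Fp1/Fp2 weight
  > 70%, 1-s-lag autocorrelation < 0.3, EOG correlation > 0.8), and
  channel-wise z-scoring from interictal statistics only;
* **phase connectivity**: Hilbert-transform instantaneous phases and
  windowed phase-locking values
  `PLVᵢⱼ = |⟨exp(i(φᵢ − φⱼ))⟩|` over 5-second windows with 50% overlap;
* **hypergraph construction**: feature-conditioned adjacency refinement and
  exhaustive 3-clique detection at threshold τ = 0.65, with hyperedge
  density diagnostics (10–30% operating range);
* **chimera metrics**: spectral communities on PLV, per-cluster Kuramoto
  order parameters `R = |Σ exp(iφ)|/N`, the contrast labelling rule
  `max(R) − min(R) > 0.3`, windowed chimera-index series and three-phase
  segmentation;
* a **hypergraph-convolution + selective state-space network** with
  physics-extraction heads (phases, frequencies, coupling, phase lag),
  trained under a multi-task objective (focal, smoothed cross-entropy,
  Huber) plus Kuramoto-consistency and chimera-structure losses, with its
  own reverse-mode autodiff, AdamW, cosine schedule and early stopping —
  all in base R;
* an **evaluation harness**: stratified episode folds, alarm generation,
  horizon sensitivity, false positives per hour, bootstrap confidence
  intervals and Cohen's kappa;
* a thin CLI (`inst/exec/chimeranet`) with `simulate`, `preprocess`,
  `detect-chimera`, `build-hypergraph` and `evaluate-alarms` subcommands.

## A worked example

```r
library(chimeraNet)

params <- defaultKuramotoParams(seed = 1)
params
#> KuramotoParams: C = 23 (communities 12/11), K = 0.710, alpha = 0.280 rad, r = 0.70
#>   mean frequency: 2.30 Hz (community 0), 9.07 Hz (community 1)

ep <- generateEpisode(benchmarkEpisodeSpec(seed = 1))
ep
#> LabeledEpisode: 102.0 s, onset at 84.0 s, 39 windows (22 chimera, states: 10/23/1/5)

head(windowLabels(ep), 3)
#>   start  end clusterR0 clusterR1   contrast ychimera ystate    ytime
#> 1   0.0  5.0 0.1829838 0.2767252 0.09374144        0      0 13.16667
#> 2   2.5  7.5 0.3334248 0.2628773 0.07054749        0      0 12.75000
#> 3   5.0 10.0 0.4683362 0.2382791 0.23005711        0      0 12.33333
```

Baseline windows show both communities incoherent (order parameters near
the 23-channel finite-size floor, contrast well under the 0.3 rule), state
0 and a time-to-onset in uncompressed clinical minutes. During the
stabilization segment the delta community locks (`clusterR0` above 0.9)
while the alpha community stays near 0.27, the contrast clears 0.3 and the
windows are chimera-labelled. Downstream:

```r
phases <- analyticPhase(ep@signal)     # Hilbert phases, 0.5 s edge guard
plvs   <- plvMatrices(phases)          # one 23 x 23 PLV matrix per window
hg     <- detect3Cliques(refineAdjacency(NULL, plvs[[30]]), tau = 0.65)
hg
#> Hypergraph: 23 nodes, 220 hyperedges (tau = 0.65, density 12.4%)
```

220 hyperedges is exactly the number of triplets inside a fully locked
12-channel community (`choose(12, 3)`), and 12.4% density sits inside the
10–30% operating range. Parameter recovery inverts the dynamics by linear
regression:

```r
p <- defaultKuramotoParams(interCouplingRatio = 1, seed = 3)
est <- estimateKuramotoParams(simulateKuramoto(p, duration = 60, seed = 3))
round(c(K = est$couplingK, alpha = est$phaseLagAlpha), 3)
#>     K alpha
#> 0.708 0.280
```

Training the reduced network on a 40-episode benchmark
(`benchmarkEpisodeSpec`, 30 train / 10 held-out) takes about a minute per
run on one CPU and reaches held-out window-level chimera accuracy around
0.9; see `tests/testthat/test-acceptance.R` for the exact protocol and
`vignettes/chimeraNet-methods.Rmd` for the model and design notes.

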