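---
title: "Structural spine plasticity in the olfactory-bulb network: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural spine plasticity in the olfactory-bulb network: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinesim)
```

## The model

`spinesim` simulates the circuit formed by the excitatory mitral cells (MCs)
and the inhibitory granule cells (GCs) of the olfactory bulb. The two
populations interact exclusively through reciprocal dendrodendritic synapses:
a single spine excites the GC and inhibits the MC it contacts. Firing rates
follow

$$\tau_M \frac{dM}{dt} = -M + F_M\!\left(S - \gamma W^{(mg)} G\right), \qquad
  \tau_G \frac{dG}{dt} = -G + F_G\!\left((W^{(mg)})^T M - g_{thr}\right),$$

with the saturating MC activation $F_M(x) = [\tanh x]_+$ (rates in $[0,1)$)
and the rectifier $F_G(x) = [x]_+$. $W^{(mg)}$ is a **binary** MC-by-GC
adjacency matrix: all synapses share the weight $\gamma$, and learning acts
purely through the *presence* of synapses (structural plasticity), not their
strength. GC dynamics are instantaneous ($\tau_G = 0$), so GC rates are
slaved to the MC rates and only the MC equation is integrated.

Each trial presents one stimulus and applies one round of stochastic
synaptic turnover driven by the steady-state activities. The per-pair rate is
$R_{ij} = M_i\,\phi(G_j)$ with the bidirectional resilience

$$\phi(G) = [G - G^{(0)}]_+ \,(G - G^{(1)}),$$

which is zero below $G^{(0)}$ (inert spines — this is what lets learned
connectivity survive periods when its odors are absent), negative on
$(G^{(0)}, G^{(1)})$ (removal of spines on weakly driven GCs) and positive
above $G^{(1)}$ (Hebbian formation on strongly co-driven pairs). Over a trial
of duration $\Delta t$, an absent synapse forms with probability
$P^+_{ij} = 1 - e^{-\lambda_f [R_{ij}]_+ \Delta t}$ and a present one is
removed with $P^-_{ij} = 1 - e^{-\lambda_r [-R_{ij}]_+ \Delta t}$.

Hebbian growth needs a homeostatic brake. Two are implemented:

* **top-k competition** (`variant = "topk"`): before the stochastic update,
  any GC holding more than `k` synapses keeps only the `k` with the largest
  $R_{ij}$; synapses pruned this way are not re-formed within the same trial.
* **resource-pool competition** (`variant = "pool"`): each GC owns
  $P^{all} = N_{conn} + P_0$ units of a building resource; forming a synapse
  consumes one unit, removal returns it ($P_j + n_j = P^{all}$ holds
  exactly). The resilience becomes
  $\tilde\phi(G, P) = \tilde\phi_{form}(G)\,P/P_0 - \tilde\phi_{rem}(G)$ with
  sigmoidal formation/removal terms, so the effective formation threshold
  $\tilde G^{(1)}$ *slides up* as the pool empties — a structural analogue of
  a sliding-threshold rule. Because $\tilde\phi$ is generally nonzero even at
  low activity, pool runs insert one "air" trial (uniform spontaneous input)
  after every four training trials; these trials relax every pool toward
  $P_0$ and every degree toward $N_{conn}$. Note that for fill levels
  noticeably below $P_0$, $\tilde\phi(0, P) < 0$, so only the upper threshold
  exists (`effective_thresholds()` returns `g0 = NA` there); this is a
  genuine feature of the functional form, not a failure.

A third, **random control** (`variant = "random"`) changes spine counts
toward a globally ramped target at uniformly random positions, with no
dependence on activity. It isolates which phenomena actually require
activity-dependent stability: graded discriminability changes do not, but
disinhibition of individual MCs does.

## Default parameters

`model_params()` carries the standard simulation values: $N_{MC} = 240$,
$N_{GC} = 1000$, $N_{conn} = 60$, $k = 66$, $\tau_M = 1$, $\tau_G = 0$,
$\Delta t = 1$, $g_{thr} = 4.4$, $\gamma = 5\cdot10^{-4}$, $G^{(0)} = 1$,
$G^{(1)} = 4$, $\lambda_f = 6\cdot10^{-4}$, $\lambda_r = 6\cdot10^{-3}$, and
the classification threshold $\theta = 0.2$. `resource_params()` carries the
pool-model values ($\kappa_{form} = 2.5$, $\kappa_{rem} = 5$, $r_{form} = 2$,
$r_{rem} = 1$, $R_0 = 0.8$, $P_0 = 20$, $\lambda_f = \lambda_r = 1$,
$\gamma = 4.2\cdot10^{-4}$). Two context-specific $\gamma$ values recur:
$1.7\cdot10^{-4}$ for naturalistic-style stimuli under top-k, and
$1.7\cdot10^{-3}$ for the pool model with simplified stimuli. All are plain
function arguments and YAML-overridable via `load_config()`.

Time is measured in units of $\tau_M$; one trial ($\Delta t = 1$) represents
one odor presentation, so "training for 3000 steps" means 3000 presentations.

## Steady-state solver

Per trial the package integrates only the MC equation with instantaneous GCs:
an explicit scheme $M \leftarrow M + h\,(F_M(\cdot) - M)/\tau_M$ starting
from $F_M(S)$, declared converged when $\max_i |dM_i/dt| <$ `solver_tol`
($10^{-6}$ by default). The two rectifiers make the map nonsmooth near the GC
threshold, where a full step can enter a slowly decaying flip-flop mode; the
step is therefore halved whenever the residual fails to shrink by at least
3% per iteration and allowed to recover (×1.1, capped at `solver_h` = 0.5)
once it shrinks again. Integration time is accumulated along these adaptive
steps, so the error horizon `solver_t_max` defaults to a generous
$500\,\tau_M$; exceeding it raises an error naming the stimulus. Trained
networks with strong inhibitory blocks are the demanding case — the Jacobian
$-I - \gamma\,D_1 W D_2 W^T$ has real spectrum $\le -1$, so the continuous
flow is strongly stable and convergence is a question of step-size control
only. Within training loops each stimulus's solution warm-starts the next
solve of the same stimulus. Correctness is checked against an independent,
heavily damped fixed-point oracle and against `deSolve` ODE integration on
small random networks.

Event draws use exact geometric skip-sampling under a per-column probability
bound instead of one RNG draw per MC-GC pair; with trial event probabilities
of order $10^{-3}$ this changes nothing statistically (it is exact thinning)
and dominates the speed of full-scale runs. All randomness, in R and in the
compiled core, is drawn from R's RNG stream, so a run is bit-reproducible
from its seed.

## Stimuli

*Simplified* stimuli are scaled Gaussian bumps over the MC index axis
(default: amplitude 2, centers 85 and 135, full width at half maximum 50
channels, so the two odors span channels ≈60–110 and ≈110–160), presented on
top of a uniform air baseline of 0.2. *Naturalistic-style* stimuli emulate
calibrated glomerular activation maps: a raw map is shifted so its 40th
percentile is zero — chosen so that roughly 60% of channels are activated by
a strong presentation — and scaled to maximum 1; the air baseline is 0.1.
Mixtures are assembled as $[\,p\tilde S^{(A)} + (1-p)\tilde S^{(B)} +
\tilde S^{(air)}]_+$; the rectifier is applied only at assembly, so
calibrated patterns keep their sub-percentile negative values until then.

Because the imaging dataset behind the original maps has no public
accession, `surrogate_glomerular_set()` generates synthetic stand-ins:
smoothed Gaussian random fields passed through the same calibration. Pairwise
Pearson similarity is controlled exactly through a one-factor construction
with empirical Gram–Schmidt orthogonalization (pattern $i$ correlates with
the reference pattern exactly at its target $a_i$, and with pattern $j$ at
$a_i a_j$); per-pattern affine calibration leaves correlations untouched.
The spatial correlation length defaults to 4 channels — short enough that
60:40 vs 40:60 mixtures of independent surrogates retain a handful of
super-threshold contrast channels, which is the regime in which the hard
task operates; longer correlation lengths wash out mixture contrast
entirely. The surrogates reproduce the calibration statistics and
controllable similarity of real maps but not their heavy-tailed hotspot
structure; quantitative statistics that depend on those tails (e.g. the
depth of familiarization change indices) land at smaller magnitudes than
with real maps, while every directional phenomenon is preserved.

## Metrics

With $r^{(X)} = M^{(X)} - M^{(air)}$ the response to odor $X$: an MC is
*responsive* if $\max(r^{(A)}, r^{(B)}) > \theta$ and *divergent* if
$|M^{(A)} - M^{(B)}| > \theta$. Per-cell discriminability assumes
Poisson-like spiking (variance ≈ mean rate):
$d_i' = |M_i^{(A)} - M_i^{(B)}| / \sqrt{M_i^{(A)} + M_i^{(B)}}$, and the
optimal linear readout gives $F_{opt} = \sum_i (d_i')^2$, which never
decreases as MCs are added. Two population averages of $d'$ are recorded at
every step: over divergent cells only (`mean_di_prime`, the default
convention, defined as 0 when no cell is divergent) and over all MCs
(`mean_di_prime_all`). In hard tasks the divergent count hovers near zero,
which makes the divergent-only average a noisy statistic; directional
statements about trends therefore use the all-MC average, which is also the
natural reading of a population-mean $\langle d_i'\rangle$. The *change
index* of an MC-odor pair across training is
$CI = (r_{after} - r_{before})/(r_{after} + r_{before})$, computed from odor
responses (odor minus air); pairs with zero denominator are excluded
(returned as `NA`), and per-odor CI summaries average over MCs that are
responsive to that odor before or after training.

## Protocols and their design choices

**Easy/hard task** (`run_easy_hard()`): pre-train 1500 trials on a separate
odor pair, then train 3000 trials on the task pair, alternating stimuli.
Easy = the two dissimilar base odors; hard = their 60:40 and 40:60 mixtures.
Trial counts follow the statistically-steady criterion (the trailing 20% of
the recorded mean-$d'$ trace varies by <5% in the default runs); they are
arguments, not constants.

**Familiarization** (`run_familiarization()`): pre-train on two background
odors (alternating), then train on backgrounds + one familiar odor (uniform
random draws), probing the familiar and 11 novel odors at the phase
boundaries. The default surrogate ensemble gives the novels similarities
0.85…0 to the familiar odor. The random control ramps each GC's target
degree linearly from $N_{conn}$ to $1.2\,N_{conn}$ over the training phase —
the increase itself is what matters; 20% is a moderate choice consistent
with a "mean number of connections increased during training" scenario, and
its pre-training phase is static (nothing activity-independent happens
before the global signal arrives).

**Amplitude re-exposure** (`run_amplitude_retrain()`): pre-train on two
dissimilar odors, then re-train with one odor scaled by a sweep factor;
report the fraction of pre-trained synapses (on MCs activated by that odor)
retained, and the mean change of those MCs' responses at the original
amplitude. The default sweep {0.05, 0.1, 0.25, 0.5, 1}× was fixed from a
GC-activity diagnostic on the pre-trained network: at ≤0.05× most trained
GCs fall below $G^{(0)}$ (inert), around 0.1× they sit inside the removal
band, and from ≈0.25× upward they exceed $G^{(1)}$ (stable) — the sweep must
straddle those three regimes for the retention dip to be visible, and a
sweep confined to ≥0.5× sits entirely on the stable plateau.

**Interference** (`run_interference()`): learn pair 1, train pair 2, retrain
pair 1, 1500 trials per phase, tracking both pairs' Fisher discriminants
throughout. Both pairs default to 60:40/40:60 mixture (hard) pairs, since
forgetting is only visible after discriminability has first been *gained*.
Pair-1 components sit at channels 60/100 (width 12); the interfering pair-2
components sit at 120/160, sharing one shoulder with pair 1. This partial
overlap was chosen over full overlap after a regime scan: with full overlap
the shared GCs are driven strongly enough that forgetting outraces
relearning, whereas partial overlap drives them into the removal band and
yields the reported regime — forgetting present, relearning faster than both
initial learning and forgetting. With fully disjoint pair-2 components,
pair-1 memory is largely retained; it still erodes slowly because the
uniform air baseline inside every presented stimulus keeps trained GCs
marginally above $G^{(0)}$ under the default parameters (a known limitation
of this parameter set, visible as a slow decay of pair-1 $F_{opt}$ even
without interference).

## What the tests do and do not show

The synthetic generators reproduce the *conditions* of the study —
population sizes, thresholds, stimulus calibration, similarity structure —
so the test suite demonstrates the mechanisms: differential easy/hard
learning, odor-specific subnetworks in $W^{(mm)}$, disinhibition exclusive
to activity-dependent plasticity, non-monotonic amplitude-dependent
forgetting, interference and fast relearning, and exact resource
conservation. Magnitudes that hinge on the statistics of real glomerular
imaging maps (most visibly the mean familiarization change index, which
saturates near −0.10 with surrogates) should not be read as quantitative
predictions for real data. Problem sizes used by the automated checks are
the full 240×1000 network for the task protocols and reduced networks
(≤40 GCs) for oracle and conservation checks.

## Numerical conventions

Ties in the top-k ranking are broken uniformly at random with the run RNG;
homeostasis acts per GC, independently across GCs. When more formations are
drawn on a GC than its pool can fund, a uniformly random subset of the
accepted candidates is kept (one resource unit each); formation on an empty
pool is suppressed. Percentile calibration uses linear interpolation between
order statistics (`quantile` type 7). Degenerate inputs error early and
loudly: non-finite inputs to activations, zero-variance stimuli in
similarity, negative rates in $d'$, mixture fractions outside $[0,1]$, and
solver non-convergence (which names the offending stimulus). CSV exports fix
floats at 9 significant digits so a manifest re-run reproduces files
byte-for-byte.
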