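---
title: "Dendritic normalisation in sparse neural networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dendritic normalisation in sparse neural networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dendnorm)
```

This vignette is the package's account of the science it implements: the
models and their assumptions, the parameters that matter, the numerical
choices, and the places where the design was genuinely open and a choice
had to be made. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The passive-cable foundation

A dendrite is modelled as a sealed, unbranched passive cylinder with
radius $r$ (default 1 µm), axial resistivity $r_a$ (150 Ω·cm class values;
default 100 Ω·cm), membrane leak conductivity $g_l$ (default
$5\times10^{-5}$ S/cm²), and specific capacitance $c$ (default 1 µF/cm²).
These give the length constant $\lambda = \sqrt{r/(2 r_a g_l)}$ (1000 µm
at the defaults), the electrotonic length $L = l/\lambda$, the
semi-infinite input conductance $G_\infty = \pi r^2/(\lambda r_a)$, and
the membrane time constant $\tau_l = c/g_l$ (20 ms). The public interface
takes micrometres and converts internally to CGS-electrical units.

The steady transfer resistance from electrotonic location $X$ to the soma
is $R_L(X) = \cosh(L-X) / (G_\infty \sinh L)$; with a compact soma of
radius $\rho$ the denominator becomes
$G_\infty \sinh L + G_s \cosh L$ with $G_s = 4\pi\rho^2 g_l$. The printed
form of the soma-loaded resistance in the source literature adds a bare
conductance to dimensionless terms; we implement the dimensionally
consistent reading above and let the compartmental oracle adjudicate — a
finite-difference discretisation with an explicit somatic compartment
agrees with it to well under 1%.

Averaging over a synapse placed uniformly along the cable gives the mean
somatic sensitivity $\mu_{\Delta v} = \Delta_{syn}/(L G_\infty)$ (sealed
case) — exactly proportional to $1/L$. The variance is derived directly as
$\mathrm{Var}_X[\Delta_{syn} R_L(X)]$ in closed form,
$(L + \sinh L\cosh L)/(2 L D^2) - \mu^2$, because the printed variance
factor is typographically mangled in the source; quadrature confirms the
closed form to $10^{-6}$ relative.

Transient responses use the cosine-mode expansion of the cable Green's
function: mode $n$ decays with $\tau_n = \tau_l (1 + (\pi n/L)^2)^{-1}$.
One derivation note: the location-average of $\cos^2(n\pi X/L)$ is exactly
$1/2$, so each mode contributes half its squared amplitude to the
variance; the printed series carry an extra factor $1/2$ relative to this
exact average, and the implementation follows the derivation (the
Monte-Carlo oracle over synapse locations distinguishes the two clearly).
The "variance of the total voltage" is reported as the time integral of
the instantaneous location variance, evaluated in closed form per mode;
the exact variance of the time-integrated response is kernel-independent
and therefore cannot be what the kernel-dependent printed bands show.

Series are truncated when the next term's bound falls below $10^{-9}$ of
the running sum, with a hard cap of $10^4$ terms; doubling the term count
is verified to change nothing beyond the tolerance. The peak of the mean
response is found by bracketed root-finding on the stationarity condition
after a log-spaced scan ($t = 0$ is a trivial root because the
double-exponential response rises quadratically).

The compartmental oracle discretises the cable into at least 200
compartments (400–600 in the tests). Steady states are a tridiagonal
solve; transients diagonalise the conductance/capacitance pencil so each
spatial mode is convolved with the synaptic kernel in closed form — no
time-stepping error, which makes 0.1–1% agreement attainable with modest
spatial resolution.

## 2. The normalisation family and its gradients

An afferent weight vector $v$ with in-degree $n = \|v\|_0$ maps to
effective weights $w = e \, v / \prod_{p} \|v\|_p$, with orders drawn from
$\{0,\dots,5\}$ (one or two of them) and excitability $e$ either a single
shared scalar $s$ or per-neuron $g_i$. The gradients are the exact chain
rule of this map; for $p \ge 1$ the Jacobian term uses
$\mathrm{sign}(v)|v|^{p-1}$ so signed weights are handled for every order.
Two deliberate deviations from the printed gradient formulas:

- The printed joint and per-neuron excitability gradients carry an extra
  factor of $g_i$ relative to the exact chain rule of their stated
  parametrisations. We use the exact chain rule: central finite
  differences validate every scheme and both excitability modes to
  $\sim 10^{-9}$, and the headline dendritic case agrees with its printed
  form exactly.
- Tangency: for a single order $p \ge 1$ the gradient satisfies
  $\nabla_v C \cdot v = 0$ (scale invariance of the parametrisation), and
  for $p = 2$ a gradient step preserves $\|v\|_2$ to second order. For
  $p = 1$ the norm itself can change at first order even though
  $\nabla_v C \perp v$; the tests assert exactly what holds.

Excitability parameters are trained by the same SGD step as the weights.
They are initialised to 1 by default. With order-0 normalisation and a
wide fan-in the combined factor $(s/n)^2$ initially suppresses raw-weight
learning, and the optimisation of $s$ must first grow the scale; an
`s_init = "indegree"` option starts $s$ at the layer's mean in-degree
(the scale towards which its optimisation converges) for users who want
to skip that bootstrap phase. The packaged experiments keep the neutral
default.

## 3. Sparse networks, SET, and the training experiments

Layers hold raw weights on an Erdős–Rényi mask (each edge with
probability $\varepsilon$, $N(0,1)$ weights, zero-in-degree neurons
rescued with one random afferent since the dendritic scheme divides by
$n$). Hidden activations are sigmoid (or threshold-linear), the output is
a fully connected softmax with log-likelihood cost for classification, or
a single sigmoid unit with per-sequence mean-squared error for the
recurrent addition task. Minibatch gradients are averaged over samples,
so the learning rate is minibatch-size invariant; biases start at zero.

For BPTT the gradient accumulates over the whole sequence (no truncation;
sequences are at most ~50 steps, and the hidden state resets at sequence
starts). The reported cost divides by the sequence length, but the update
does not: with per-timestep averaging the effective step shrinks with
sequence length and, at the learning rate used here (0.05), training
never leaves the trivial constant-output solution on fresh data.

SET rewiring excises the $\lfloor \zeta E \rfloor$ weakest contacts of a
pool and regrows the same number uniformly among absent pairs with fresh
$N(0,1)$ weights. "Weakest" defaults to the absolute *effective* weight
$|w|$ — the functional strength after normalisation — with the raw
$|v|$ ranking available behind a flag; ties are broken by a random
permutation; regrowth may reuse just-excised slots. In the two-stream
recurrent variant the feedforward and recurrent connections form one
joint pool, so weak feedforward contacts compete with weak recurrent
contacts, and each stream carries its own shared excitability.

Study conditions follow the original experiments: $\eta = 0.05$,
minibatch 10, $\varepsilon = 0.2$ and $\zeta = 0.15$ for the image task
($M = 30$ hidden units at desk scale), $\varepsilon = 0.3$ for the
recurrent task ($M = 50$ hidden units, two input units, one output unit,
epochs of fresh sequences). Desk-scale problem sizes, stated here as the
package's chosen conditions: the image task uses the synthetic
10-class generator (28×28, Gaussian bumps clustered towards the image
centre so central pixels are the informative ones, pixel noise sd 0.3 —
calibrated so a nearest-template classifier exceeds 90%) with 50 images
per class and 5 epochs; the recurrent experiments use 20-bit addends
(LSB first, addends below $2^{m-1}$ so the sum fits without overflow),
100 epochs of 250 sequences for the dense-feedforward runs and of 1000
sequences for the joint-pool runs, and five seeded repetitions where the
original used one hundred.

What the synthetic generators do and do not emulate: the image classes
are linearly well-separated Gaussian templates — they reproduce the
centre-weighted information structure and the scale of MNIST-class
inputs, but none of the within-class style variability, so absolute
accuracies are not comparable to benchmark values and all comparisons in
the tests are between seed-matched architectures on identical data. The
binary-addition generator is the original task exactly, only shorter.

Two known desk-scale limitations, recorded after substantial exploration
rather than tuned away. First, at these sizes the unnormalised control
*learns the image task faster in accuracy* than the freshly initialised
normalised network (the $(s/n)^2$ bootstrap above); the normalised
network's advantages that do reproduce here are the training-cost
ordering (it avoids the control's early saturated-overconfidence cost
spike) and the reduced between-run variability. Second, the degree
restructuring of the recurrent mask under SET — the drop of the average
shortest path length well below its initial value — did not emerge in
this implementation under any of the ranking metrics, learning-rate
regimes, sequence lengths, or convergence levels explored; the trained
masks stay close to their Erdős–Rényi statistics. The joint-pool
both-input statistic, by contrast, reproduces strongly: normalised
networks spread feedforward contacts to most hidden neurons while the
control concentrates them.

## 4. The directed path-length convention

The average shortest path length is the mean over ordered pairs
$(i, j)$, $i \ne j$, of the directed BFS distance, with unreachable pairs
excluded; self-loops never count. A symmetrised variant sits behind a
flag. Exact brute-force (Floyd–Warshall) agreement is tested on small
graphs. For directed ER graphs with $n = 50$, $p = 0.3$ this convention
gives $1.7068 \pm 0.0010$ (standard error over 100 graphs; an analytic
two-step approximation gives 1.708), which the acceptance suite compares
against the reported initial value.

## 5. The self-organising network of spatially extended neurons

Each neuron is an *equivalent-cylinder* dendrite: a single unbranched
cable of length $l_i$. The full 3D morphology synthesis of the original
model (minimum-spanning-tree growth in conical/spherical regions,
balancing factors, 5 µm resampling) is deliberately replaced by this
abstraction: the normalisation mechanism depends only on the
length–connectivity proportionality and the transfer resistance, both of
which the cylinder preserves exactly.

Connectivity: 30% of ordered E→E pairs (no self-connections), 70% of E→I
and of I→E, no I–I. Local weight magnitudes are gamma distributed; the
source states both "mean 0.2, sd 0.2" and explicit shape/rate (0.2, 1),
which are inconsistent — the default follows the explicit density
parameters (mean 0.2, sd ≈ 0.45), with a `gamma_moments = "mean_sd"`
switch (shape 1, rate 5) that is flagged at initialisation. Signs follow
the source population.

Dynamics are discrete with one synaptic delay per step: the somatic
voltage is the sum over afferents whose source spiked on the previous
step of (signed local weight) × (steady transfer resistance at the
synapse's location on the postsynaptic cable), plus external drive;
neurons above threshold spike. Each letter of the two-word stream
(`a b…b c` / `x y…y z`, five dedicated input neurons per letter, 30 in
all) drives its group with a suprathreshold current (twice the
threshold). E–E synapses undergo soft-bounded pair STDP: potentiation by
$\eta(syn_{max} - w)$ on pre-then-post, depression by $\eta w$ on
post-then-pre ($\eta = 0.05$). After each epoch (1000 presentations by
default; 300 at the test scale) SET excises the weakest E–E contacts by
local weight and regrows gamma-weighted contacts at uniform locations,
and the excitatory dendrites are resized so that $l_i / n_i$ is exactly
the population mean ratio, with all afferent locations re-drawn on the
new cable. Inhibitory neurons are resized at initialisation only.

Parameters the source leaves open, and how they were fixed (chosen once,
with the reasoning below, before the acceptance checks were frozen):

- **Population sizes** ($N_e = 100$, $N_i = 60$). Under the symmetric
  STDP rule the long-run drift of an active weight settles at
  $syn_{max}(1-\eta)/(2-\eta) \approx syn_{max}/2$. With the stated
  connection fractions and a common weight scale, inhibitory feedback
  balances a fully synchronous, fully potentiated excitatory volley only
  when $p_{ie} N_i \bar w \gtrsim p_{ee} N_e \, syn_{max}/2$, i.e.
  $N_i \approx 0.6 N_e$. With the SORN-typical $N_i = 0.2 N_e$ the
  saturated state is self-consistent and every exploratory run ran away
  to near-total synchrony regardless of the STDP rate — this model has no
  homeostatic threshold (deliberately, as in the source), so stability
  must come from the balance itself.
- **synmax** (0.4): twice the mean initial weight, so the STDP drift
  fixed point coincides with the initial mean and the weight scale is
  stationary. Initial and regrown gamma draws are clipped to
  $[0, syn_{max}]$ to honour the bound invariant.
- **Spike threshold**: set by `calibrate_threshold()` to the voltage of
  $K = 3$ co-active average-resistance synapses at the STDP fixed point.
  A rate-targeted calibration (5–10% initial spike probability) proved
  unworkable: thresholds low enough to produce that rate were
  supercritical (runaway), and stability-first thresholds left a
  drive-only reservoir; the $K$-synapse rule was selected by scanning
  $K \in \{2,3,4,6,8\}$ for stable rates and a functioning prediction
  task, and is recorded (with the achieved rate) in every run manifest.
- **Training budget**: 25 epochs of 300 presentations at test scale
  (50 epochs of 1000 at the default config), readout trained for 8–20
  epochs on a fresh frozen-plasticity stream.

The readout trains a dense 30-hidden-unit classifier from the
instantaneous excitatory spike vector to the next letter. The raw
held-out accuracy is rescaled to
$(acc - b)/(m^* - b)$ with $m^* = ((W-1) + 1/2)/W$ for word length
$W = n_{rep} + 2$ (perfect within words, a coin flip at word onsets) and
$b = \sum_\ell f_\ell^2$ the accuracy of a letter-frequency-matched
guesser, both computed from the evaluation stream itself, never
hard-coded. The repeat-difficulty sweep trains the reservoir at the
reference $n_{rep} = 4$ and scores streams with $n_{rep} \in \{2,4,6,8\}$
(one self-organisation phase per seed; scoring sweeps the stream
difficulty).

The point-neuron control replaces every transfer resistance by the fixed
somatic input resistance of the population's initial mean-length cable,
severing the length–connectivity link while keeping initialisation,
drive, plasticity and rewiring identical.

## 6. Workbench and reproducibility

Experiments are driven by flat YAML configs with one section per module;
`run_experiment()` fills in every default explicitly and writes a JSON
manifest (full config, seed, package version, summary metrics) next to
the CSV learning curves, so a run is reproducible from its manifest
alone. All randomness flows from a single integer seed. The CLI
(`inst/cli/workbench.R`) is a thin wrapper over `run_experiment()` and
`compare_runs()`; the package functions are the primary interface.

## 7. Known limitations

- Branched morphologies, active conductances and conductance-based
  synapses are out of scope throughout; the cable is passive and
  unbranched, synapses are current sources.
- The synthetic image task measures relative training behaviour, not
  benchmark accuracy; no external datasets are required or downloaded
  (the IDX reader is an optional convenience and is never exercised by
  the experiments).
- Desk-scale training budgets change which effects are visible (see §3);
  the package reports what its own runs compute.
- The SORN operates in a stimulus-locked, inhibition-balanced regime
  rather than the asynchronous-irregular regime of large reservoirs;
  scores at different $n_{rep}$ are noisy at these sizes and are
  averaged over seeds in the tests.
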