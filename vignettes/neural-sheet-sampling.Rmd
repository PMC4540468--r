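---
title: "Neural sampling in spiking sheets: model, plasticity, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural sampling in spiking sheets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sheetsampler)
```

## The generative model and its sampler

`sheetsampler` treats a sheet of stochastic spiking neurons as a Markov
chain whose state occupancy realizes Bayesian inference.  The hidden
state is the binary vector $z \in \{0,1\}^K$ of network neurons ("active
within the last PSP duration $\tau$"); the observed state is the binary
vector $y$ of input channels.  The model factorizes as prior times
likelihood:

$$p(z \mid \theta) \propto \exp\!\left(\tfrac12 z^\top \hat W z + z^\top \hat b\right),
\qquad
p(y \mid z, \theta) = \prod_i p(y_i \mid z, \theta),$$

where $\hat W$ combines nonnegative excitatory couplings with strong
negative couplings between any two neurons whose afferent fields
overlap.  The negative couplings implement the structural assumption
that at most one hidden cause generates an input channel at a time
(winner-take-all); each $p(y_i \mid z)$ is an exponential-family
distribution whose parameter is selected by the single active parent, or
a default parameter when no parent is active.  Bernoulli inputs are used
throughout the packaged experiments; Poisson and Gaussian variants are
supported by `translate_likelihood()`.

With the parameter identification of `network_from_model()` —
$V_{ki} = \mathrm{logit}\,\pi_{ki} - \mathrm{logit}\,\pi_{0i}$,
$b_k = \hat b_k - A_k$, recurrent weights equal to the prior couplings —
the membrane potential $u_k = b_k + \sum_j W_{kj} z_j + \sum_i V_{ki} y_i$
equals the conditional log-odds
$\log \frac{p(z_k = 1 \mid z_{\setminus k}, y)}{p(z_k = 0 \mid z_{\setminus k}, y)}$
for every state.  This *neural computability condition* is what licenses
reading spikes as MCMC: a neuron that fires with probability
$\sigma(u_k - \log\tilde\tau)$ whenever it is not refractory implements a
Gibbs-like transition whose stationary law is the posterior.  The
package checks the identity symbolically down to $10^{-9}$ over
exhaustive small state spaces (`conditional_log_odds()` is computed from
the enumerated joint, independently of the membrane formula).

Strong inhibition is the *finite* value $-100$, not $-\infty$, so that
exact enumeration and the sampler share one well-defined distribution;
states violating the constraint keep mass of order $e^{-100}$, which is
below every tolerance used anywhere.  The hard-constraint enumeration
(`valid_states()`) is used where a state *count* or a sum over valid
states is wanted (log-likelihood evaluation), with error bounded by
$K^2 e^{-100}$.

## Discrete-time dynamics

The simulator advances in steps of $\delta t = 1$ ms with
$\tilde\tau = \tau/\delta t = 10$ steps.  Within a step, inputs update
first, then network neurons are visited in a fresh uniformly random
order; a state transition is visible to neurons visited later in the
same step.  A neuron is eligible to spike iff it is inactive or in the
last step of its active period (so an immediate re-spike continues the
active state without a gap); a spike sets the state countdown to
$\tilde\tau$.  Input channels spike with per-step probability
$p_i = 1 - (1 - x_i)^{1/\tilde\tau}$, which makes the stationary
activation $\langle y_i \rangle$ equal the scheduled target $x_i$.

Two implementation details matter for efficiency but not for the
distribution sampled:

* input spikes are drawn by geometric skip-ahead (one uniform per spike
  rather than one per channel per step) — the realized process is the
  same per-step Bernoulli process;
* the afferent drive $\sum_i V_{ki} y_i$ is maintained incrementally as
  channels toggle, with a periodic exact recomputation to cap
  floating-point drift.

Randomness comes from a package-private PCG32 stream seeded from R, so
every run is reproducible bit-for-bit from its seed.  The consumption
order is fixed: input spike draws as gaps expire, the visit-order
shuffle, eligible-neuron spike draws in visit order, then (wake-sleep
only) the companion sampler's shuffle and draws.

## Plasticity rules

Four rules, all local, applied as Euler updates on the per-step states:

* **Afferent Hebbian**: $\Delta V_{ki} = \delta t\,\eta_V\, z_k (y_i -
  \sigma(V_{ki} + V_{0i}))$.  The sigmoid is the Bernoulli mean function;
  for Poisson/Gaussian inputs it is replaced by the family's
  $\partial A/\partial V$.  On average this update ascends a variational
  lower bound on the data log-likelihood (verified against
  finite differences of the explicit bound in the test suite).
* **Homeostatic intrinsic**: $\Delta b_k = \delta t\,\eta_b\,(m_k - z_k)$.
  This is the E-step of a variational EM scheme: it drives the network
  to sample from the distribution closest to the exact posterior among
  those with long-term activations $m_k$, absorbing the non-local
  normalizers $A_k$ that exact inference would require.
* **Wake-sleep recurrent**: $\Delta W^{exc}_{kj} = \delta t\,\eta_W\,
  (z_k z_j - s_k s_j)$ where $s$ is the state of a companion network
  that shares the recurrent weights by reference, receives no input, and
  regulates its own biases homeostatically toward the wake marginals
  ($\Delta \hat b_k \propto z_k - s_k$).  The companion takes one step
  per wake step.
* **Heuristic recurrent**: $\Delta W^{exc}_{kj} = \delta t\,\eta_W\,
  [z_k z_j - (m_k m_j + \tan(\tfrac{\pi}{2} W_{kj}/W_{max})/\gamma)]$.
  The tangent LTD term makes the fixed point invert the arctan
  weight–covariance map $W(c) = \frac{W_{max}}{\pi/2}\arctan(\gamma c)$,
  so the rule reproduces wake-sleep equilibria from purely local
  information once $(W_{max}, \gamma)$ are fitted
  (`fit_ltd_parameters()`, synapses below weight 0.01 excluded from the
  fit because clipping at zero censors them).

**Batched flushing.**  The $V$, $W^{exc}$ and companion-bias updates are
accumulated as pre/post coincidence counts per step and flushed as one
Euler update every 50 ms (`flush_every`), evaluating the slow
weight-dependent terms once per flush.  Every learning timescale
$1/\eta$ in the packaged protocols is 0.1 s or longer, so the batching
is 2–3 orders of magnitude below the dynamics it integrates; fixed
points are identical by construction.  Homeostatic $b$ updates remain
per-step.  Weights are clipped at zero by default (the neuroscientific
convention; `nonneg = FALSE` restores the signed theory) and heuristic
weights at $W_{max}(1 - 10^{-6})$ so the tangent stays finite.

**Timescale ordering.**  The scheme assumes
$\tau \ll \tau_{inp} \ll 1/\eta_b \ll 1/\eta_V$ (a factor of roughly
5–20 per relation suffices in practice).  The packaged configurations
respect this ordering; it is a modelling assumption, not a validated
precondition, so user configurations that violate it will run but may
not converge.

## What the synthetic inputs emulate

All inputs are Poisson-like spike trains with piecewise-constant target
activations — the statistical caricature the model is built for.  The
five protocol generators produce: conflict-free alternation of stored
patterns on a six-neuron chain; Dirichlet-drawn local patterns presented
through Gamma-timed on/off chains at non-overlapping locations; stripe
patterns whose inner locations are determined by two outer cues under an
exclusion rule; spatial motifs (grid/diagonal/checkerboard, diameter
8–12 inputs, always exceeding the 6×6 afferent fields) at random
non-overlapping torus locations; and a nested weak/strong pattern pair
for a two-neuron group.  None of these exhibit refractory input
statistics, spike-timing structure within the PSP window, or
non-stationary rates within a segment, so passing tests demonstrate
correctness of the sampler and learning dynamics under the model's own
assumptions — not robustness to natural spike trains.

Choices the sources leave open, fixed here once: the nested-pattern pair
is a 4×4 active block with its 2×2 corner as the weak subset (only the
strict-containment structure matters, and the reproduced
runaway/silent activations confirm it suffices); nested patterns cycle
in 1 s blocks (the printed "1000s" duration is read as 1000 ms, since
1000-second blocks cannot give three patterns equal time in a 5000 s
run); the chain protocol alternates patterns in 100–300 ms segments with
0.4 activation probability per pattern under the no-adjacent-conflict
rule; stripe indexing uses width-2 vertical stripes
($\lfloor ((j-1) \bmod 6)/2 \rfloor$), the only reading that yields
three disjoint patterns tiling the 6-wide field.

## Numerical choices

* All probability arithmetic is in log space with log-sum-exp;
  `PosteriorTable` normalization is exact to $10^{-12}$.
* `calibrate_prior_biases()` solves $\langle z_k\rangle_{p(z|\theta)} =
  m_k$ by the damped fixed-point iteration $\hat b \leftarrow \hat b +
  \tfrac12(\log m - \log\langle z\rangle)$ to a residual of $10^{-6}$
  (exact closed forms recovered for independent neurons).  These are the
  biases a Bayesian observer would infer from the network's long-term
  response, and they are what the log-likelihood evaluation uses for a
  learned network.
* `log_likelihood()` restores the Bernoulli base measure $h(y)$, so its
  values are absolute log-densities (comparable across parameter
  settings), and sums over the inhibition-respecting states.
* Enumeration caps: `valid_states()` refuses $K > 24$;
  full $2^K$ enumeration is used for cross-checks up to $K = 20$.
  For disjoint populations the valid-state recursion prunes to the
  product form automatically (the 7-population topology enumerates its
  $4^7 = 16384$ states directly).
* `fit_ltd_parameters()` profiles $W_{max}$ (linear given $\gamma$) and
  optimizes $\gamma$ on a log scale — no starting-value sensitivity.

## Problem sizes used in the packaged checks

The reference learning runs span 10,000–25,000 simulated seconds; the
package's own checks run each protocol to its plateau rather than to the
original wall-clock: the cue/consistency task runs 12,000 s (recurrent
weights plateau by ~8,000 s; the test asserts the endpoint sits within
0.05 of its final-window time average), the overlapping sheet trains for
3,000 s before the silent-column measurement, the 12×12 motif sheet uses
a 250 s warm-up and 100 s measurement (its homeostatic timescale is
$1/\eta_b = 0.1$ s), and the nested-pattern control runs its full
5,000 s.  Sampling-exactness checks use $10^6$ steps against enumerated
posteriors of $K \le 4$ networks.

## Known limitations

* The recurrent heuristic rule carries no convergence guarantee; its
  parameters $(W_{max}, \gamma)$ are task-fitted constants, and the
  package exposes but does not automate rate schedules ("variable
  learning rates" are mentioned for the large-sheet experiment without
  values; constants are the default).
* Inhibition is direct negative coupling; interneurons are not modelled,
  and inhibitory weights are never plastic.
* The continuous-time limit is not simulated; all guarantees are for the
  discrete-time chain.
* Likelihood families beyond Bernoulli are implemented in the
  translation layer and the R-level plasticity rule but the compiled
  simulation loop assumes Bernoulli inputs (the packaged experiments are
  all Bernoulli).
* Log-likelihood traces include the base measure; reported curves that
  omit it differ by a constant offset.
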