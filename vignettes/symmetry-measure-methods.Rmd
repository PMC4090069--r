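---
title: "Quantifying symmetry in neural connectivity: models and methods"
author: "netsym"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying symmetry in neural connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netsym)
```

## The symmetry measure

Cortical microcircuits are not wired at random: pairs of neurons are found
in *bidirectional* (reciprocal) motifs — both neurons project to each other
with comparable strength — and *unidirectional* motifs, where only one
direction carries weight, more or less often than chance predicts. `netsym`
condenses the reciprocity of a whole weighted directed network into a
single number.

For an $N \times N$ connectivity matrix $W$ with non-negative weights
$w_{ij}$ (row = postsynaptic, column = presynaptic; zero diagonal), every
unordered pair $(i, j)$ gets the normalised asymmetry

$$
z_{ij} \;=\; \frac{|w_{ij} - w_{ji}|}{w_{ij} + w_{ji}} \in [0, 1],
$$

and the network's symmetry measure is

$$
s \;=\; 1 - \frac{1}{P}\sum_{\text{counted pairs}} z_{ij},
$$

where $P$ is the number of pairs with at least one nonzero weight. Pairs
with both weights zero carry no information about reciprocity (and tiny
weights are not experimentally measurable anyway), so they are excluded
rather than counted as "symmetric"; `pairDecompose()` tallies them
separately, and an entirely empty matrix yields an explicit error rather
than a silently extreme $s$. A detection floor can optionally zero
sub-threshold weights first (`floor`), mimicking a measurement limit;
by default only exact zeros are excluded.

Because $z$ is a ratio, $s$ needs no knowledge of the maximal weight and is
invariant under rescaling of $W$, under transposition, and under relabeling
of the neurons. $s = 1$ means fully reciprocal, $s = 0$ strictly one-way.

```{r measure}
w <- matrix(0, 3, 3)
w[1, 2] <- 0.2; w[2, 1] <- 0.6   # z = 0.4/0.8 = 0.5
w[1, 3] <- 0.5; w[3, 1] <- 0.5   # z = 0
symmetryMeasure(WeightMatrix(w))  # pair (2,3) is (0,0): excluded
```

## Null models: what does a random network look like?

An observed $s$ is only meaningful against the distribution of $s$ over
random networks. Two weight families are supported (`nullModelSpec()`):

* **uniform** on $[w_{\min}, w_{\max}]$ (defaults $[0, 1]$);
* **truncated Gaussian** with mean at the interval midpoint and standard
  deviation $\sigma$ (default $0.1$, i.e. variance $0.01$). The truncation
  mass outside the interval must stay below $10^{-4}$, so the truncated law
  is indistinguishable from a true Gaussian for practical purposes; wider
  $\sigma$ is rejected at validation.

*Pruning* models developmental synapse elimination: each directed
connection is independently and permanently set to zero with probability
$p$. Conditioned on a pair being counted (at least one weight alive), the
pair law is an exact two-component mixture: with weight $(1-p)/(1+p)$ both
weights survive and $(u, v) = (w_{ij}+w_{ji},\, |w_{ij}-w_{ji}|)$ follows
the continuous unpruned joint density; with weight $2p/(1+p)$ exactly one
survives, so $z = 1$ on the line $v = u$. `nullDensities()` exposes all the
densities in closed form (for the Gaussian family the sum/difference laws
come from products of normal densities and normal CDFs).

### Moments

The mixture gives the exact identity
$$
E[z;\,p] \;=\; \frac{(1-p)\,E[z;\,0] + 2p}{1+p},
$$
and the same identity for $E[z^2]$. Unpruned moments: the uniform family
has closed forms $E[z;0] = 2\ln 2 - 1 \approx 0.3863$ and
$E[z^2;0] = 3 - 4\ln 2$; the Gaussian moments are computed by 2-D
quadrature of $z$ against the product of truncated densities. The
integrand's $|a - b|$ kink on the diagonal defeats naive quadrature over
the square (a bias of about $5\times10^{-4}$), so the integral is taken
over the smooth triangle $b < a$ and doubled; the result
($E[z;0] \approx 0.11525$ at $\sigma = 0.1$) agrees with a $4\times10^6$-sample
Monte-Carlo oracle to within its standard error, and with the analytic
factorisation $E[v]\,E[1/u]$ (valid because $u$ and $v$ are uncorrelated,
see below) to three digits.

For a network of $N$ neurons,
$$
\mu_s = 1 - \mu_z, \qquad
\sigma_s^2 = \frac{\sigma_z^2}{E[P]}, \qquad
E[P] = (1 - p^2)\,\frac{N(N-1)}{2},
$$
since each pair survives pruning of both its weights with probability
$1 - p^2$. `momentsS()` returns these; `mcNullStatistics()` recomputes them
by brute force from generated networks and is used throughout the tests as
the independent check.

```{r nulls}
momentsS(nullModelSpec("uniform"), 30)
momentsS(nullModelSpec("gaussian", sigma = 0.1), 30)
```

Two robust orderings follow and are verified by simulation: **pruning
biases toward asymmetry** ($\mu_s$ strictly decreases in $p$, because the
single-survivor component has $z = 1$), and **Gaussian weights bias toward
symmetry** (weights concentrate near the mean, so reciprocal differences
are small: $\mu_s \approx 0.885$ versus $0.614$ for uniform at $p = 0$).

### Correlation of $u$ and $v$

For the Gaussian family, $u = a + b$ and $v = |a - b|$ are independent up
to truncation effects (for equal-variance Gaussians $a+b \perp a-b$), which
justifies factorising their joint law; `correlationUV()` measures the
sample Pearson correlation, $|\rho| < 0.01$ at $10^6$ pairs. The same
near-zero correlation holds for the uniform family — reflecting the exact
symmetry $(a, b) \mapsto (w_{\min} + w_{\max} - a,\, w_{\min} + w_{\max} - b)$,
which flips $u$ about its mean while fixing $v$, so $\mathrm{cov}(u, v) = 0$
for any family symmetric about the interval midpoint (independence still
fails for the uniform family; only the linear correlation vanishes).

## Hypothesis test

`significanceTest()` standardises the observed measure,
$z_{\text{score}} = (s_{\text{obs}} - \mu_s)/\sigma_s$, and converts it to
a p-value under a normal approximation of the $s$ null — reasonable since
$s$ averages hundreds of nearly independent pairs. The default is
two-sided, which is conservative and lets both tails speak; one-sided
alternatives (`"greater"`, `"less"`) are available for directional
questions such as the stimulation protocols below. The verdict is
`symmetric` / `asymmetric` when the null is rejected above / below the
mean, `random` otherwise. No small-$P$ correction is applied; for very
small or heavily pruned networks the normal approximation degrades.

## Motifs

Inverting the measure gives a data-driven classification threshold: a pair
is called *unidirectional* when its $z$ exceeds the null mean
$\bar z = 1 - \mu_s$ of the matching random ensemble, *bidirectional*
otherwise (ties count as bidirectional). Over ensembles spanning the whole
range of $s$, the bidirectional fraction rises linearly with $s$ and the
two motif curves cross where both equal $1/2$.

### Prescribed-$s$ ensembles

Random networks only cover a narrow band of $s$, so the full range is
sampled by construction (`prescribedSNetwork()`): per pair the larger
weight is drawn from the family, $z$ from a Gaussian centred at
$1 - s_{\text{target}}$ clipped to $[0,1]$, and the smaller weight is
$a(1-z)/(1+z)$, which respects the weight bounds by construction. Drawing
the *larger* weight from the family (rather than filling one triangle of
the matrix and inverting) slightly changes the marginal weight
distribution, but all downstream checks compare against the *measured* $s$,
which is marginal-independent.

The spread of the prescribed $z$ is a free parameter. The default is
adaptive, $\sigma_z = \min(0.5,\ 1.4\,\min(s_t, 1 - s_t))$: wide in the
mid-range so that each network carries a broad within-network distribution
of pair asymmetries (as genuinely random networks do — this is what makes
the motif-fraction-vs-$s$ relation linear, $R^2 \approx 0.96\text{–}0.98$),
and narrowed near the extremes so boundary clipping does not pull the
realised mean off target (within about $0.015$ mid-range, $0.05$ at the
extremes). A narrow fixed spread (say $0.05$) makes every pair nearly
identical and turns the motif-fraction curve into a step — exact linearity
over the full domain is unattainable for *any* $z$ law supported on
$[0, 1]$, so the linear description should be read as holding to good
approximation, best near the null mean.

## The eigenvalue comparator

Real symmetric matrices have real spectra, so the fraction of complex
eigenvalues is a natural alternative asymmetry diagnostic
(`fractionComplexEigenvalues()`; an eigenvalue counts as complex when
$|\mathrm{Im}\,\lambda|$ exceeds `relTol` times the spectral radius, with
an absolute floor of `relTol` — exact-real eigenvalues come out with
imaginary part exactly zero from the solver, but rounding noise needs the
floor). Complex eigenvalues arrive in conjugate pairs, so the count is
always even.

`spectralSweep()` contrasts three ensembles — symmetric (mirrored),
asymmetric (one direction drawn from the family, the other at most `eps`),
and random — across pruning levels, recording both the eigenvalue fraction
and $s$. Without pruning the symmetric ensemble is perfectly detectable
(fraction $0$). Under pruning, however, the asymmetric and random
ensembles' eigenvalue fractions overlap within two pooled standard
deviations at every pruning level tried, while $s$ keeps the same pairs of
ensembles many standard deviations apart — the case for the pair-based
measure. The $s$ separation itself shrinks as pruning grows (about
$30$ pooled SD at $p = 0.2$ down to about $5$ at $p = 0.8$, $N = 30$,
$300$ networks per cell): with heavy pruning the random null's $\mu_s$
approaches the asymmetric ensemble's near-zero $s$, so no statistic could
keep an arbitrarily large gap there.

## The spiking-network case study

To show the measure tracking *learning*, the package simulates $N$ leaky
integrate-and-fire neurons, all-to-all connected with plastic excitatory
weights, driven by external stimulation protocols.

**Membrane.** $V$ decays toward $V_{\text{rest}} = -70$ mV with time
constant $\tau_m = 10$ ms, using the exact per-step factor
$e^{-\Delta t/\tau_m}$ ($\Delta t = 1$ ms) rather than forward Euler —
unconditionally stable and testable in closed form. Each presynaptic spike
delivered after a one-step synaptic delay adds $1\,\text{mV} \times w$;
each external event adds $30$ mV, enough to jump from rest to $10$ mV above
the $-50$ mV threshold, so external events force firing. After a spike the
membrane resets to rest.

**Escape noise.** Spikes are stochastic: the instantaneous rate is
$\rho(V) = \rho_0\, e^{(V - \theta)/\Delta u}$ and the per-step firing
probability $1 - e^{-\rho(V)\Delta t}$. The defaults $\rho_0 = 1$/ms and
$\Delta u = 2$ mV put the probability below $10^{-4}$ per step at rest and
above $0.999$ after an external kick; both constants are configurable.

**Triplet STDP.** Each neuron carries two presynaptic traces ($\tau_{r1} =
16.8$ ms, $\tau_{r2} = 575$ ms) and two postsynaptic traces ($\tau_{o1} =
33.7$ ms, $\tau_{o2} = 47$ ms) that decay exponentially and jump on the
neuron's own spikes. When neuron $k$ fires, its incoming weights are
potentiated, $w_{kj} \mathrel{+}= \eta\, r_1^{(j)}\,(A_2^+ + A_3^+ o_2^{(k)})$,
and its outgoing weights depressed,
$w_{jk} \mathrel{-}= \eta\, o_1^{(j)}\,(A_2^- + A_3^- r_2^{(k)})$, with the
trace values read *before* this spike's own increments, and hard clipping
to $[0, 1]$. The amplitudes are the visual-cortex nearest-spike triplet
set, $A_2^+ = 4.6\times10^{-3}$, $A_3^+ = 9.1\times10^{-3}$,
$A_2^- = 3.0\times10^{-3}$, $A_3^- = 7.5\times10^{-9}$, which matches the
trace time constants above; consistently with that parameter set the traces
*reset to 1* on a spike (nearest-spike interaction) by default, with the
accumulating `+1` variant available via `traceMode = "accumulate"`.
Pruned connections are masked before learning and never move.

**Protocols.** The *frequency protocol* stimulates each neuron
periodically at its own rate, evenly spaced over `rateRange` with Gaussian
jitter (SD = 5% of the period). The triplet term makes sustained high-rate
firing net-potentiating; below roughly 10–12 Hz depression wins. The
default band, 15–35 Hz, keeps every neuron above the crossover, so all
pairs potentiate bidirectionally and $s$ climbs toward 1 (with rates
straddling the crossover, mixed-rate pairs become unidirectional instead
and $s$ can even fall — worth knowing when changing `rateRange`). The
*sequential protocol* stimulates neurons in fixed order with a 20 ms
inter-neuron delay (jitter SD = 5% of the delay): the consistent
pre-before-post timing potentiates forward connections and depresses the
reverse ones, driving $s$ toward 0. The learning rate defaults to
$\eta = 2$ for both protocols, calibrated once so that the steady state is
reached within a few simulated minutes.

```{r sim}
cfg <- simulationConfig("sequential", nNeurons = 10, durationMs = 30000)
res <- runSimulation(cfg, seed = 1)
head(sTrajectory(res), 3)
tail(sTrajectory(res), 1)   # drifting below the uniform null mean 0.614
```

The initial weights are drawn from either family, so at $t = 0$ the
distribution of $s$ over seeds matches the corresponding null; one-sided
tests against that null quantify how far each protocol has moved the
network. Simulations are bitwise reproducible per seed.

### What the generators do and do not emulate

The synthetic ensembles reproduce the statistical structure the null
theory assumes: i.i.d. weights, independent Bernoulli pruning, independent
pairs. Real connectomes violate all three (distance-dependent connectivity,
common-input correlations, heavy-tailed weights), and the simulator is a
deliberately small all-excitatory toy network without inhibition,
conductance synapses or realistic delay distributions. Passing tests
therefore validate the statistic and its null calibration, not any claim
that cortical connectivity follows these generative models; on real data
the choice of null family is a modelling decision the test's verdict
depends on, as the uniform-vs-Gaussian contrast makes explicit.

## Numerical choices and problem sizes

* Exact exponential decay factors for membrane and traces; 1 ms step.
* Gaussian family sampled by rejection from the parent normal (exact
  truncation; rejection rate below $10^{-4}$ under the narrowness
  constraint).
* Quadrature over the $b < a$ triangle (kink avoidance), absolute
  tolerance $10^{-8}$.
* Ties at the motif threshold classify as bidirectional; the "both zero"
  test is exact equality after the optional floor.
* Eigenvalue complexity tolerance is relative to the spectral radius with
  an absolute floor.
* Validation errors name the offending matrix index.

The test suite and the acceptance script use Monte-Carlo sizes chosen for
tight-but-quick statistics on one CPU: $10^4$ networks for the headline
uniform check (3-standard-error agreement), $2\times10^3$ per pruning grid
point, $10^6$ pairs for the correlation, 100 networks per prescribed-$s$
target, 300 networks per spectral cell, and 10 seeds of a 10-neuron,
200-second simulation per protocol. All results are reproducible from the
seeds recorded in the outputs.

## Known limitations

* The normal approximation of the $s$ null thins out for very small $N$ or
  $p$ near 1 (few counted pairs); `momentsS()` reports the expected pair
  count so users can judge.
* Signed (inhibitory) weights, self-edges and multigraphs are out of
  scope by design.
* The Gaussian family requires the narrowness condition; wide Gaussians
  would need their own truncated-law moments.
* The motif-fraction-vs-$s$ relation is linear to $R^2 \approx 0.96$–$0.98$,
  not exactly — see the prescribed-$s$ section.
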