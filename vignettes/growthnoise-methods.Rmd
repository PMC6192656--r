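---
title: "Methods: an integrated stochastic model of expression, metabolism and growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an integrated stochastic model of expression, metabolism and growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthnoise)
```

## The model

A growing bacterium is described by the proteome mass fractions
$\phi_i = n_i/M$ of its protein species, where $M$ is total protein mass.
Under tight protein-density homeostasis, cell volume tracks $M$, so $\phi_i$
is a concentration proxy and $\sum_i \phi_i = 1$ identically. Differentiating
$\phi_i$ in time gives

$$\dot\phi_i = \pi_i - \mu\,\phi_i,$$

with $\pi_i$ the per-mass synthesis rate of species $i$ and
$\mu = \dot M / M$ the instantaneous growth rate. Summing over species and
using $\sum\phi_i = 1$ yields $\mu = \sum_i \pi_i$: the growth rate *is* the
total synthesis rate. Synthesis is driven by metabolism and perturbed by
gene-expression noise,

$$\pi_i = f_i\,\mu_d(\boldsymbol\phi) + N_i,$$

where $\mu_d(\boldsymbol\phi)$ — the deterministic growth rate afforded by a
composition — is intensive (degree-0 homogeneous: scaling all abundances
leaves it unchanged), $f_i$ is the constant fraction of metabolic flux
allocated to species $i$ ($\sum_i f_i = 1$), and each $N_i$ is an independent
zero-mean Ornstein–Uhlenbeck source with amplitude $\theta_i$
(units $h^{-3/2}$), reversion rate $\beta_i$ ($h^{-1}$) and stationary
variance $\theta_i^2/(2\beta_i)$. Consequently
$\mu = \mu_d(\boldsymbol\phi) + \sum_i N_i$: every source perturbs growth
both instantly (through total synthesis) and with a delay (through its
effect on the composition and hence on $\mu_d$). Active protein degradation
(a percent-level correction to dilution) and cell-division partitioning
noise are outside the model's scope.

At the zero-noise fixed point, stationarity of $\dot\phi_i$ forces
$\phi_{0,i} = f_i$ and $\mu_0 = \mu_d(\boldsymbol\phi_0)$: the mean
composition equals the allocation (`steady_state()`).

## Growth control

The logarithmic sensitivities
$C_i^\mu = (\phi_i/\mu_d)\,\partial\mu_d/\partial\phi_i$ evaluated at
$\boldsymbol\phi_0$ are growth-control coefficients (GCCs): they are exactly
the transfer coefficients with which composition fluctuations reach the
growth rate in the linearized model. They relate to the flux-control
coefficients (FCCs) of metabolic control analysis by
$C_i^\mu = C_i^J - \phi_{0,i}$, because flux is extensive where growth rate
is intensive. Euler's homogeneous-function theorem then gives the two sum
rules $\sum_i C_i^J = 1$ and $\sum_i C_i^\mu = 0$: the excess of one protein
is the lack of another. A protein with no metabolic function has
$C_i^J = 0$ and hence $C_i^\mu = -\phi_i$, so maintaining a non-metabolic
sector of mass $\phi_H$ forces the metabolic sector to carry positive
control $+\phi_H$ (`gcc_fcc_convert()`, `nonmetabolic_sector()`).

Two GCC estimators are exposed for a Monod growth curve
$\mu = \mu_{max}\phi_O/(\phi_{half}+\phi_O)$ and they differ on purpose:

* `monod_log_slope()` returns the one-dimensional log-slope
  $\phi_{half}/(\phi_{half}+\phi_O)$ of the curve, the natural estimator
  when an empirical growth-vs-expression curve is all that is measured.
  At $\phi_O/\phi_{half} \in \{0.3, 1.3, 15\}$ it gives
  $\{0.77, 0.43, 0.063\}$ (two significant figures), and it is the
  estimator used by the many-protein builder.
* `gcc_numeric()` differentiates the intensive extension
  $\mu_d(\boldsymbol\phi/\sum\phi)$ by central differences in
  log-composition (relative step $10^{-5}$); for the Monod subtype the
  target set's summed coefficient is
  $(\phi_{half}/(\phi_{half}+\phi_O))(1-\phi_O)$ — the extra $(1-\phi_O)$
  reflects that raising $\phi_O$ inside a closed proteome dilutes
  everything else. The two estimators agree in the small-$\phi_O$ limit.

Only the one-dimensional log-slope reproduces the conventionally quoted
operon values above, which is why the builder uses it.

## Linear-noise statistics

Substituting the synthesis and growth equations into $\dot\phi_i$ and
linearizing around $\boldsymbol\phi_0$ gives, with wiring coefficients
$w_{s,i}$ (1 for a private source on its own gene, the member weight for a
shared operon source),

$$\frac{d\,\delta\phi_i}{dt} = -\mu_0\,\delta\phi_i +
  \sum_s (w_{s,i}-\phi_{0,i})\,N_s .$$

The allocation feedback $f_i\,\delta\mu_d$ cancels the dilution response
$\phi_{0,i}\,\delta\mu_d$ exactly, so *concentration fluctuations are
independent of the GCCs* — the GCC vector affects $\delta\mu$ and
$\delta\pi_i$, not $\delta\phi_i$. Every $\delta\phi_i$ is a one-pole filter
(rate $\mu_0$) applied to a weighted sum of OU sources, and all stationary
second moments follow in closed form as finite sums of exponentials with
rates $\mu_0$ and $\beta_s$ (confluent forms are used when
$\beta_s = \mu_0$). Three per-source correlators are the building blocks
(`basis_functions()`): the source autocovariance $B(\tau) \propto
e^{-\beta|\tau|}$, the filter-output autocovariance $S(\tau)$ (symmetric),
and the asymmetric source–output cross-covariance $A(\tau)$. Their closed
forms are validated in the test suite against numerical quadrature
(time-domain convolution and Wiener–Khinchin integrals).

The stationary concentration CV of protein $i$ is

$$\eta_i^2 = \frac{(1-\phi_{0,i})^2}{\phi_{0,i}^2}
  \frac{\mathrm{Var}(N_i)}{\mu_0(\mu_0+\beta_i)} +
  \sum_{j\neq i} \frac{\mathrm{Var}(N_j)}{\mu_0(\mu_0+\beta_j)}$$

for private sources (generalized through the wiring otherwise): an
intrinsic term plus an extrinsic term collecting every other source through
dilution. The same algebra yields the covariance between two identical
reporter constructs, which contains a *negative* between-reporter
transmission term $-2\,(1-\phi_{0,b})/\phi_{0,b}\cdot
\mathrm{Var}(N_b)/(\mu_0(\mu_0+\beta_b))$: one reporter's synthesis noise
dilutes the other, so the dual-reporter covariance is not a clean extrinsic
noise readout and can be negative with no extrinsic noise at all
(`dual_reporter_covariance()`).

### Cross-correlations and noise modes

`xcorr_analytic()` computes the stationary Pearson cross-correlation
$r(\tau) = \mathrm{corr}(x(t+\tau), \mu(t))$ for $x$ either a concentration
$\phi_i$ or a synthesis rate $\pi_i$. **Lag convention:** positive $\tau$
means the expression signal is evaluated *later* than growth; a curve
leaning to positive $\tau$ indicates growth fluctuations preceding the
signal. This convention was chosen because it makes the mode phenomenology
read correctly: synthesis noise hits the growth rate instantly and the
concentration with a delay, so the autogenic mode of the
concentration–growth correlation leans to positive $\tau$, while the effect
of production on growth via accumulated concentration is delayed, so the
control mode of the production–growth correlation leans to negative
$\tau$. Pearson normalization (divide by $\sigma_x\sigma_\mu$) is used
throughout so analytic curves are directly comparable to empirical
correlation estimates.

The correlation decomposes additively into named modes:

* **control** — the focal unit's fluctuations transferring to growth in
  proportion to its GCC ($S$-shaped for concentration, $A(-\tau)$-shaped
  for production; amplitude scales linearly with $C^\mu$);
* **autogenic** — the focal synthesis noise entering $\mu = \sum\pi$
  instantly ($A(\tau)$-shaped for concentration, $B$-shaped for
  production; amplitude proportional to the unit's mean mass fraction and
  source variance);
* **dilution** (concentration only) — all sources' growth effect diluting
  the focal concentration;
* **transmission** (production only) — all sources feeding back into the
  focal synthesis rate through $\mu_d$.

For an operon member the control and autogenic modes appear twice: an
operon-level instance (shared source, the operon's summed GCC and mass) and
a private-reporter instance. The mode columns sum to the total at machine
precision by construction, and the decomposition was verified against
stochastic simulation of the full nonlinear model (the package's central
equivalence check).

## Fitting noise amplitudes to observed CVs

`noise_amplitudes_from_cvs()` inverts the CV relation: with
$v_s = \mathrm{Var}(N_s)/(\mu_0(\mu_0+\beta_s))$ the target CVs are linear
in the $v_s$, so amplitude assignment is a linear solve, augmented by
equality constraints (e.g. operon amplitude $= 1.5\times$ reporter
amplitude) when shared sources add unknowns. Redundant systems (e.g. two
proteins, whose CVs are tied by $\sum\phi = 1$) are solved by least squares
with a consistency check; a negative solved $v_s$ means some target CV lies
below its extrinsic floor and is reported as infeasible, naming the source.

## The trajectory simulator

`simulate_cell()` integrates the full nonlinear model. The OU sources use
their exact Gaussian transition
$N(t{+}dt) = N(t)e^{-\beta dt} + \mathcal N(0, \theta^2(1-e^{-2\beta
dt})/(2\beta))$, so the noise driver has no discretization bias at any step;
$\phi$ follows a forward-Euler step on $\dot\phi_i = \pi_i - \mu\phi_i$,
adequate in the small-noise regime the model assumes. Defaults: $dt =
10^{-3}$ h (an order of magnitude below $0.1/\max(\beta,\mu_0)$ for all
models shipped here; a hard precondition rejects coarser steps), burn-in
$20/\mu_0$, recording every $0.01$ h, initial state $\phi = f$ with noise
states drawn from their stationary law. $\sum\phi = 1$ is dynamically
invariant ($d(\sum\phi)/dt = \mu(1-\sum\phi)$); the integrator nevertheless
projects $\phi$ back onto the simplex after each step and records the
largest pre-projection drift as a diagnostic (of order $10^{-16}$ at the
default step; the projection can be disabled). Transient negative
excursions of a $\phi_i$ are legitimate linear-regime behavior; an
excursion beyond $-10$ stationary SDs aborts the run with advice to reduce
the step or the noise, since it signals a breakdown of the small-noise
regime. Synthesis rates are recorded as evaluated at the step start, so
recorded $\mu$ equals $\sum_i\pi_i$ identically. All randomness flows
through R's RNG: a seed makes runs bit-reproducible.

Empirical cross-correlations (`estimate_xcorr()`) use the standard
time-series convention (global means, denominator $n\sigma_x\sigma_y$) on
the recorded grid, with the same lag convention as the analytics. Standard
errors come from a circular block bootstrap: contiguous circularly-wrapped
blocks of length $10/\mu_0$ (ten times the slowest model timescale) are
resampled 200 times and the whole statistic recomputed. These bootstrap
parameters are package choices, selected for decorrelation at the slowest
timescale; they are exposed as arguments.

## The many-protein cell

`build_many_protein()` assembles a 1021-species model: 1018 background
proteins plus the lac operon represented as three genes Y, Z and G (LacY,
LacZ, GFP reporter) sharing the operon mass equally, each with a private
source plus one shared operon-level source $N_O$ wired with weight $1/3$
per member (so the shared source enters the summed synthesis rate exactly
once). Three growth conditions sit on a Monod curve with
$\mu_{max} = 0.8\,h^{-1}$, $\phi_{half} = 0.005$ and
$\phi_{0,O}/\phi_{half} \in \{0.3, 1.3, 15\}$ (slow, intermediate, fast);
the operon GCC in each condition is the curve's log-slope there
($0.77, 0.43, 0.063$). GCC assignment: background proteins are shuffled
into the non-metabolic sector until it first reaches 25% of total mass
(each getting $C^\mu_h = -\phi_h$); GFP is non-metabolic
($C_G^\mu = -\phi_{0,G}$); Y and Z split the remaining operon control
equally; the metabolic background draws non-negative raw scores
$\phi_i \times \mathrm{Exp}(1)$ (larger abundance, larger control) and is
then shifted in proportion to mass so the grand total is exactly zero. A
single linear constraint cannot fix both a shift and a scale, and the
mass-proportional shift was chosen because it preserves the
abundance–control trend while keeping the correction spread over the whole
sector. Noise amplitudes are fitted so that each lac protein has CV 0.15,
the operon amplitude is 1.5 times the GFP amplitude, every background CV
matches the proteome table, and all reversion rates equal
$4\mu_{max} = 3.2\,h^{-1}$.

### The synthetic proteome and what it does (and does not) emulate

No protein abundance dataset ships with the package;
`generate_background_proteome()` draws one. It emulates two features of
measured single-cell proteomics: a log-normal abundance spectrum and the
phenomenological noise law $\eta^2 = a/\langle n\rangle + b$ (intrinsic
$1/\langle n\rangle$ limb, extrinsic floor $b$) with log-normal scatter.
Defaults: $10^{\mathcal N(1.0,\,0.3^2)}$ copies, $a = 1$, $b = 0.03$,
scatter 0.2 (log10). The abundance spread deserves comment, because one
statistic of the draw controls the physics: the mass-participation ratio
$\sum_j \phi_j^2$, which (weighted by the CVs) sets the total mass-weighted
background noise $\sum_j v_j$ — the extrinsic floor of every CV, the size
of the global dilution mode, and hence the contrast of the reporter
construct's own modes. A wide spectrum (log10 SD near 1) concentrates tens
of percent of proteome mass in single background species, an unrealistic
proteome in which the global dilution mode swamps the reporter construct
entirely and expression–growth correlations carry almost no information
about the focal gene. The defaults instead emulate a low-abundance
single-cell library (top mass fractions below one percent), which keeps
the reporter's control and autogenic modes resolvable — the regime in which
the model's characteristic phenomenology appears: the slow condition's
concentration–growth correlation is control-dominated and nearly symmetric;
toward the fast condition the autogenic modes take over, the
concentration–growth peak weakens and skews positive, the
production–growth peak narrows, grows and loses its asymmetry; and the
zero-lag correlation can contradict the sign of the operon's GCC in both
directions (a negative-control operon with positive correlation when the
autogenic mode dominates, and a positive-control operon with negative
correlation when the reporter's private noise dominates the shared
signal). All generator constants are exposed, and a user-supplied abundance
table in the TSV schema replaces the synthetic draw for exact-dataset work.

What the generator does not emulate: correlated abundances across
functional modules, heavy non-log-normal tails, measurement error in the
CVs, or any particular dataset's values. Tests passing on synthetic draws
therefore validate the model machinery and its qualitative regimes, not
dataset-specific numbers.

### Comparing conditions

Peak height and asymmetry of analytic curves are compared across conditions
on lag windows scaled to each condition's own slowest timescale
($\pm 6/\mu_0$, 241 points), not on a fixed window: the slow condition's
correlations decay over $1/\mu_0 \approx 5.4$ h, and a fixed few-hour
window truncates them, making asymmetry integrals incomparable across
conditions. `xcorr_asymmetry()` reports
$\int_0^{\tau_{max}}[r(\tau) - r(-\tau)]\,d\tau$, optionally normalized by
$\int|r|\,d\tau$ to a dimensionless skew (used for "nearly symmetric"
checks, threshold 0.1).

## Problem sizes and numerical tolerances

The shipped test suite validates the analytics against simulation with a
5000 h toy-model trajectory at $dt = 10^{-3}$ h (the package's standard
equivalence run; agreement within 3 bootstrap SEs at every lag on a 121-lag
grid), a 4000 h dual-reporter run, and 1500–2000 h runs for driver
exactness and step-halving consistency. Structural identities (sum rules,
mode additivity, round trips) are held to $10^{-8}$–$10^{-12}$ —
double-precision-safe margins, not model claims. Fitted-constraint checks
(lac CVs, amplitude ratio) are held to $10^{-8}$.

## Known limitations

* Allocation fractions are constant: no dynamic gene regulation
  ($f_i$ independent of $\boldsymbol\phi$), so regulatory feedback on
  correlation timescales is absent.
* The analytics are first-order in the noise; strongly nonlinear phenomena
  (e.g. stochastic growth arrest) are out of reach, and simulation-analytic
  agreement degrades if CVs are pushed far beyond the tens-of-percent
  regime.
* No cell division, partitioning noise, or non-protein biomass; protein
  degradation is neglected against dilution.
* The proteome is synthetic (see above); conclusions about any specific
  organism require importing measured abundances and CVs.
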