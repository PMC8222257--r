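---
title: "Reconstructing plant–pollinator networks from visitation counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing plant–pollinator networks from visitation counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollinet)
```

## The model and its assumptions

Visitation data record how many times each pollinator species was observed on
each plant species: a matrix **M** of non-negative integers. The scientific
object of interest is not **M** but the latent network of *preferred
interactions* — the binary incidence matrix **B** saying which pollinators
actually use which plants. `pollinet` treats **M** as a noisy measurement of
**B** through a generative model:

$$M_{ij} \sim \mathrm{Poisson}(\mu_{ij}), \qquad
  \mu_{ij} = C\,\sigma_i \tau_j (1 + r B_{ij}),$$

with iid Bernoulli($\rho$) edges. The assumptions this encodes:

* visits to different pairs, and repeated visits to the same pair, are
  independent given the rates (reasonable when observations are spaced out);
* a single global effort scale $C$ applies to all pairs (one survey protocol);
* abundance acts multiplicatively and separably ($\sigma_i \tau_j$), and is
  confounded with detectability — $\sigma$ and $\tau$ should be read as
  "observable abundance", not counts of individuals;
* preference is a single global factor: an edge multiplies the visit rate by
  $1 + r$. There is no pair-specific interaction strength; the network is
  binary by design.

Because $\sigma$ and $\tau$ are only identified up to scale, both are
constrained to sum to one, making them relative abundances.

## Priors and tunable parameters

| parameter | meaning | prior | default knob |
|---|---|---|---|
| $C$ | sampling effort (expected visits at unit abundance product) | uniform on $(0,\infty)$, optionally truncated at `c_upper` | — |
| $r$ | preference factor (unitless rate multiplier) | Exponential(`lambda_r`) | `lambda_r = 0.01`, mean 100 |
| $\rho$ | prior edge probability / connectance | Uniform(0, 1) | — |
| $\sigma,\tau$ | relative abundances | flat Dirichlet on the simplex | — |

The improper uniform prior on $C$ is safe because the marginal posterior
carries an explicit $e^{-C}$ factor; `c_upper` exists for users who prefer a
proper bounded prior, and is enforced as a hard truncation. `lambda_r = 0.01`
is weakly informative: it caps absurd preference factors (posterior mass above
$r \sim 10^3$ is penalized) while leaving the empirically relevant range
$r \in [10, 100]$ essentially flat.

## Marginalization and sampling

The joint posterior $P(\mathbf{B}, \theta \mid \mathbf{M})$ factorizes over
entries of **B**, so the network can be summed out exactly, leaving

$$\log P(\theta \mid \mathbf{M}) = -C + \sum_{ij} M_{ij}\log(C\sigma_i\tau_j)
  + \sum_{ij} Y_{ij} + \log P(\theta) + \text{const},$$

where each $Y_{ij}$ is a two-term log-sum-exp over the edge/no-edge branches.
`pollinet` evaluates $Y_{ij}$ by the standard max-branch rearrangement so the
computation stays finite up to at least $r = 10^4$, $C = 10^6$ and counts of
$10^4$ (covered by tests). The $\log M_{ij}!$ constants are dropped everywhere
except `log_likelihood()`, which keeps them so that its exponential is a true
probability.

Sampling uses Hamiltonian Monte Carlo on an unconstrained parameterization:
$\log C$, $\log r$, $\mathrm{logit}\,\rho$, and — instead of stick-breaking —
the log-gamma ("softmax") chart for each simplex: unconstrained coordinates
$s_i$ with density $\exp(s_i - e^{s_i})$ and $\sigma = \mathrm{softmax}(s)$.
This reproduces the flat Dirichlet prior *exactly* (it is the law of
$\log \mathrm{Gamma}(1,1)$ variables), costs one redundant dimension per
simplex, and has a diagonal, overflow-free gradient. The log-density and its
analytic gradient are implemented in C++; a finite-difference test guards the
gradient.

Warmup adapts the step size by dual averaging to a target acceptance
statistic of 0.8 and estimates a diagonal mass matrix from the middle half of
warmup. Trajectory lengths are jittered uniformly up to
`int_time / step_size` leapfrog steps (capped at `max_leapfrog`) to avoid
periodic orbits. Non-finite Hamiltonians or gradients — possible when a
trajectory overshoots into the far tails — are treated as divergences and
rejected. Defaults follow the reference protocol: 4 chains × 5000 warmup ×
500 retained draws (2000 pooled draws).

## Multimodality, initialization, and the trapped-chain check

The marginal posterior is genuinely multimodal. Two mechanisms matter:

1. *Effort/preference trade-off*: secondary optima explain large counts with
   inflated $C$ and $r$ and distorted abundances, often hundreds of log-units
   below the dominant mode but locally stable.
2. *Complement degeneracy*: a species with **no** edges and abundance $x$ is
   likelihood-equivalent to one with edges to **every** partner and abundance
   $x/(1+r)$; only the Bernoulli prior separates the two, by just
   $k\,\mathrm{logit}(1-\rho)$ log-units for a degree-$k$ species. For
   zero-degree species in small networks this gap is a handful of log-units
   and no continuous sampler will cross it.

Random prior draws as starting points (a natural first choice) land chains in
mechanism-1 modes often enough to be unusable, and failures can be silent
when all chains agree on the wrong mode. Each chain therefore initializes
from the best of five short L-BFGS ascents of the marginal log-posterior,
started from dispersed, data-informed points: abundances near the observed
margins, $r$ log-uniform over two decades, and $C$ solved from the model's
first moment $E[\sum M] = C(1 + r\rho)$. The resulting optimum is then
*polished* against mechanism 2: any row or column whose edge probabilities
are majority-on is tentatively complement-flipped (abundance scaled by
$1+r$), re-optimized, and kept if the posterior improves. Chains start from
independent jittered optima, so the multi-chain diagnostic retains power.

After sampling, `check_convergence()` reports split-chain $\widehat R$ for
$C$, $r$, $\rho$ and flags a chain as *trapped* when its mean log-posterior
falls more than 5 within-chain standard deviations below the best chain's.
`run_fit()` and `recovery_experiment()` respond to a flag the way the
protocol prescribes: re-run the whole calculation with a fresh seed, up to a
configurable budget. The 5-sd rule is deliberately conservative; complement
modes a few log-units below the dominant one are below its detection floor,
which is visible as occasional sub-perfect edge recovery at saturating effort
in small networks.

## What the synthetic generator emulates — and what it does not

`generate_network()`, `generate_parameters()` and `generate_visitation()`
draw from the model itself: Bernoulli($\rho$) edges, Dirichlet abundances
(symmetric, with concentration < 1 giving the skewed abundance distributions
typical of real communities; concentration 1 — the model's own prior — is
the default stated world), and Poisson counts. The canonical recovery
scenario used across the tests is 10 plants × 15 pollinators, $C = 500$,
$r = 40$, $\rho = 0.25$; the "well-sampled single site" stand-in is
8 × 21 with $C = 17$, $r = 46$, $\rho = 0.24$, which lands at roughly 200
visits and 1.2–1.4 observations per pair, matching the scale of the surveys
the method targets.

A green synthetic test therefore establishes *self-consistency*: the sampler
recovers parameters and edges of data that truly follow the model. It does
not establish that field data follow the model — that is what the
posterior-predictive check is for — and it cannot speak to effects the
generator lacks: temporal turnover within a survey, observer-specific biases,
spatial structure, or pair-specific preferences.

## Numerical and design choices

* **Edge probabilities are Rao-Blackwellized**: `posterior_edge_matrix()`
  averages the closed-form $Q_{ij}(\theta_k)$ over draws rather than counting
  sampled binary networks — same expectation, strictly less variance.
  `posterior_average()` samples networks explicitly (default one per draw)
  because general $f(\mathbf{B}, \theta)$ admits no closed form.
* **Predictive uncertainty**: the per-entry predictive standard deviation is
  reported as $\sqrt{\lambda_{ij}}$ (exact for Poisson given $(B,\theta)$);
  the cross-draw spread of $\lambda$ is exposed separately (`lambda_sd`)
  rather than folded in, keeping the two uncertainty sources distinguishable.
* **$X^2$ degrees of freedom** are reported as $n_p n_a$, per the reference
  analysis. Empirically the posterior-predictive mean of $X^2$ exceeds
  $n_p n_a$ by roughly (number of fitted parameters)/(cells), plus a
  contribution from cells where $\mu_{ij} r \approx 1$ (rare-species pairs
  whose edge state stays ambiguous and inflates predictive variance). The
  $\chi^2(n_p n_a)$ reference is accurate in the regime where both terms are
  small — many counts per cell and $n_p + n_a \ll n_p n_a$ — and the
  calibration test runs there (25 × 50, uniform abundances, $C = 4000$:
  measured mean $X^2/\mathrm{dof} \approx 1.06$). On an 10 × 15 problem at
  $C = 500$ the same procedure yields $\approx 1.27$; this is a property of
  the statistic, not a lack of fit, and is why $X^2$ should be read against
  its expectation qualitatively ("well below dof") for small matrices.
* **NODF ties**: pairs with equal degrees, or whose smaller member has degree
  zero, contribute exactly 0 — the decreasing-fill requirement. This matters
  because sampled networks routinely contain zero-degree species.
* **Degree distributions** over the posterior average the per-sample
  fractions $p_k$, not pooled counts; the "Poisson fit" to an inferred degree
  distribution is simply its mean (the ML estimate), no shape fitting.
* **Zero-count species** are legal input: the model stays proper, but their
  abundance coordinates are informed only by the prior, so `sample_parameters()`
  warns. Missing cells, by contrast, are rejected by the readers — absence of
  observation must be an explicit zero.
* **Aggregation** (`aggregate_visitation()`) matches species by exact label
  string and sums counts over the union of species; it is the right tool when
  the inputs measure approximately the same underlying system.

## Scaled-down test properties

Two spec-level properties are checked at reduced size to stay inside the test
runtime budget, as noted in the test files: the monotone improvement of edge
recovery with effort runs at 6 × 8 over 10 seeds (instead of 20), and the
entropy-vs-effort comparison averages 6 seeded replicates, because a single
data realization can legitimately buck the trend.

## Known limitations

* Complement-degenerate modes within a few log-units of the dominant one are
  sampled as the prior weighs them, but chains do not move *between* such
  modes; very small networks at very high effort can report confident edge
  probabilities for zero-degree species' complements.
* The trapped-chain rule compares chains; if every chain lands in the same
  secondary mode the failure is invisible. The multistart-plus-polish
  initialization makes this rare but cannot exclude it.
* $\sigma$ and $\tau$ conflate abundance with detectability; comparing them
  to field abundance measurements requires external data and is out of scope.
* One preference factor for the whole network; systems with strongly
  pair-specific preferences violate the model and should show up as large
  $X^2$.
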