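# pollinet

Bayesian reconstruction of plant–pollinator interaction networks from noisy
visitation counts.

## The problem

Field studies of pollination record how often each insect species was seen
visiting each plant species, giving a count matrix **M** (plants × pollinators).
Ecologists usually turn these counts into a network by thresholding — "connected
if seen together at least once (or five times)" — but visitation data conflate
the *preferred interactions* that matter ecologically with sampling effort,
species abundances, observation errors and plain Poisson noise. Thresholded
networks systematically distort connectance, nestedness and degree
distributions, especially for rare species.

`pollinet` is for network ecologists who want the network *and* the error bars:
it infers the posterior probability of every plant–pollinator edge, posterior
distributions of network metrics, and a model check telling you whether the
answer can be trusted.

## The model

Counts are independent Poisson draws whose means combine four effects:

    M_ij ~ Poisson(mu_ij),    mu_ij = C * sigma_i * tau_j * (1 + r * B_ij)

* **B** — the unknown binary incidence matrix (the network; `B_ij = 1` means
  pollinator *j* preferentially visits plant *i*), with iid Bernoulli(ρ) prior;
* **C** — sampling effort (observation time/area), uniform prior;
* **σ, τ** — relative plant and pollinator abundances, each summing to one
  (they also absorb detectability), flat Dirichlet priors;
* **r** — preference factor: an edge multiplies the visit rate by `1 + r`;
  exponential prior with rate λ = 0.01;
* **ρ** — prior edge probability (the connectance parameter), uniform prior.

Because the posterior factorizes over entries of **B**, the network can be
summed out analytically, leaving a marginal posterior over θ = (C, r, ρ, σ, τ)
that is sampled with Hamiltonian Monte Carlo (analytic gradients in C++; four
chains, 5000 warmup iterations and 500 retained draws each by default, with a
trapped-chain diagnostic mirroring the "repeat the whole run" protocol).
Conditional on each draw, every edge has the closed-form probability

    Q_ij = rho (1+r)^M_ij e^{-C r sigma_i tau_j} /
           (1 - rho + rho (1+r)^M_ij e^{-C r sigma_i tau_j})

and averaging Q over draws gives `P(B_ij = 1 | M)`. Any network statistic
(connectance, NODF nestedness, degree distributions, ...) becomes a posterior
distribution by evaluating it on incidence matrices sampled from Q. Model
adequacy is checked posterior-predictively with the discrepancy
`X² = Σ (M_ij − λ_ij)²/λ_ij` against its χ² reference with `n_p × n_a` degrees
of freedom, where λ is the predictive mean matrix.

## Worked example

A synthetic survey at the scale of a well-sampled single-site month
(8 plants × 21 pollinators, 240 visits) ships with the package:

```r
library(pollinet)
M <- load_visitation_matrix(system.file("extdata",
        "synthetic_visitation_8x21.csv", package = "pollinet"))
observations_per_pair(M)             # 1.429 visits per species pair

draws <- sample_parameters(M, prior_config(),
                           sampler_config(chains = 4, warmup = 2000, draws = 500),
                           seed = 1)
print(draws)
#> parameter_draws: 2000 draws (4 chains x 500), 8 plants x 21 pollinators
#>   posterior means: <C> = 14.3, <r> = 68.1, <rho> = 0.296
check_convergence(draws)
#> split Rhat: C = 1.044, r = 1.039, rho = 1.030 ... no trapped chains

Q <- posterior_edge_matrix(draws, M)   # P(edge | data) for every pair
predictive_mean(draws, M)
#> predictive_summary: X^2 = 29.55 on 168 dof (X^2/dof = 0.176)

metric_distribution(function(B, th) nodf(B), draws, M, seed = 2)
#> metric distribution: mean 28.7, sd 6.041, 95% CI [17.42, 41.52] (2000 samples)
mean_degree(Q, "plants"); mean_degree(Q, "pollinators")
#> 6.17        2.35
```

Reading the output: the posterior mean preference factor `<r> ≈ 68` says
pollinators visit their preferred plants tens of times more often than others;
`X²/dof = 0.18 « 1` says the fitted model reproduces the observed counts well;
and NODF nestedness is reported with a credible interval rather than a single
thresholded number. The warning about zero-count species (emitted during
sampling) flags abundance parameters that the data cannot pin down.

A command-line interface wraps the same pipeline:

```sh
Rscript -e 'pollinet::pollinet_cli()' fit -i counts.csv -o outdir --seed 1
Rscript -e 'pollinet::pollinet_cli()' simulate -o synth.csv --np 10 --na 15
```

`fit` writes a full artifact bundle (draw archive, edge probabilities,
predictive summary, metric traces, manifest with seeds and versions).

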