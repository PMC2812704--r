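---
title: "Hierarchical models for neighbourhood variation in log-DUP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical models for neighbourhood variation in log-DUP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupcar)
```

## The question and the model

Duration of untreated psychosis (DUP) — the days between onset of a first
psychotic episode and first contact with mental health services — is
heavily right-skewed; on the natural-log scale it is approximately normal.
The scientific question this package addresses is whether any of that
variation sits at the *neighbourhood* level: do people in some electoral
wards go untreated longer than in others, once individual age, sex and
ethnicity are accounted for?

For individual $j$ in ward $i$ ($i = 1,\dots,K$; $j = 1,\dots,n_i$) the
response is $T_{ij} = \log_e \mathrm{DUP}_{ij}$ and

$$T_{ij} = \mu_{ij} + e_{ij}, \qquad e_{ij} \sim N(0, \sigma_e^2),$$

with the most general regression surface

$$\mu_{ij} = \alpha + \beta_1 x_{ij1} + \cdots + \beta_8 x_{ij8}
            + R_i + S_i.$$

The eight covariates are age (years), a male indicator, and six 0/1
ethnicity dummies against a white British baseline. $R_i \sim N(0,
\sigma_R^2)$ is an exchangeable ("unstructured") ward effect. $S_i$ is an
intrinsic conditional autoregressive (ICAR) spatial effect:

$$S_i \mid S_{j \ne i} \sim N\!\left(\bar S_i, \sigma_S^2/\nu_i\right),
\qquad \bar S_i = \frac{1}{\nu_i} \sum_{j \in \delta_i} S_j,$$

where $\delta_i$ is the set of wards adjacent to ward $i$ and $\nu_i$
its size, so each ward's effect is smoothed towards its neighbours'.

Six nested forms of $\mu_{ij}$ make up the model ladder
(`model_spec()`): R only; R + covariates; covariates only (single-level);
S only; S + covariates; and covariates + R + S. Comparing them by the
Deviance Information Criterion (DIC) asks the neighbourhood question
directly: if the single-level model wins, ward membership carries no
useful signal.

## Fitting: a bespoke conjugate Gibbs sampler

All six models are fitted by the same Gibbs sampler (`run_chain()`, core
loop in C++). Every full conditional is conjugate:

* $(\alpha, \beta)$ — one joint multivariate-normal draw (better mixing
  than coordinate-wise updates);
* each $R_i$ — normal, precision $n_i/\sigma_e^2 + 1/\sigma_R^2$;
* each $S_i$ — normal, precision $n_i/\sigma_e^2 + \nu_i/\sigma_S^2$,
  mean the precision-weighted blend of the ward's residual mean and the
  ICAR neighbour mean, updated in a fixed sequential scan;
* the three variances — conjugate draws whose form depends on the prior
  (below).

**ICAR identifiability.** The ICAR prior is improper: it only constrains
pairwise differences, so a constant shift of $S$ (per connected
component) is unidentified. After every $S$ scan the sampler recentres
$S$ to sum to zero within each component and absorbs the removed mean
into $\alpha$. On a connected graph this is an exact likelihood-invariant
move; with several components the observation-weighted mean is absorbed,
which is exact only when the components' shifts coincide — multi-component
maps are supported but the intercept then soaks up a weighted compromise.
Isolated wards are refused under spatial models unless `allow_islands =
TRUE` pins their effect at zero (with a warning).

**Variance-component updates.** The ICAR log-density has rank $K - c$
($c$ = number of connected components), so the $\sigma_S^2$ conditional
uses $K - c$ in its exponent, with scale sum
$\sum_{i \sim j} (S_i - S_j)^2$ over unique edges. Under the default
uniform prior on the SD, the conditional for each precision is a gamma
distribution truncated at the bound; it is drawn exactly by quantile
inversion rather than rejection, so the sampler's cost is deterministic.

**Priors.** The study says only that priors were "minimally informative",
so the choice is ours: Normal(0, sd 100) on $\alpha$ and $\beta$, and
Uniform(0, 100) on each SD. The vague Gamma(0.001, 0.001)-on-precision
convention of the WinBUGS era is available
(`prior_spec(variance_prior = "gamma_precision")`) for sensitivity
checks, but it is not the default because it is known to behave badly
exactly where this analysis lives — variance components close to zero.

**Initialisation and defaults.** Chain $c$ starts from the least-squares
fixed effects jittered by $(c-1) \times 0.1$ residual SDs, with variance
starts cycling through $(0.5, 1, 2) \times$ the residual-variance
estimate, giving the overdispersion split-chain R-hat needs. Defaults are
2 chains, 10,000 burn-in, 20,000 retained, thin 1. The source analysis
reported none of these settings, so they are this package's own: at this
problem size (hundreds of cases, ~32 wards) the fully conjugate sampler
mixes in tens of iterations and a default run takes about a second.

## Model assessment

`compute_dic()` uses $\mathrm{DIC} = \bar D + p_D$ with
$p_D = \bar D - D(\bar\theta)$, where the deviance is *conditional* on
all effects $(\alpha, \beta, R, S, \sigma_e^2)$ — the random effects are
"in focus". This matters: with the ward effects shrunk towards zero, 32
random effects cost only ~2 effective parameters, which is the behaviour
that lets an almost-empty hierarchical model compete with the
single-level one.

`variance_partition()` reports the share of total variance at the area
level. Because $\sigma_S^2$ is a conditional, not marginal, variance, the
spatial contribution is measured as the empirical variance of the
sampled $S$ vector at each iteration (denominator $K$), added to
$\sigma_R^2$ where present, and divided by (itself + $\sigma_e^2$). The
default summarises the *per-iteration* ratios by median and 95% interval
— interval width then propagates the (large) uncertainty of small
variance components, visibly inflating the estimate relative to a
plug-in ratio; `method = "point"` gives the plug-in version at posterior
medians, and the difference between the two modes is itself informative.

`gelman_rubin()` is the split-chain potential scale reduction; values
above 1.05 raise a warning that the pipeline records in its manifest but
never treats as fatal.

## The synthetic world

The patient-level records behind the original analysis are not deposited,
so `simulate_dataset()` generates data from the full model above, with
defaults that *are* the stated study conditions rather than tuning knobs:

* `make_lattice_graph(4, 8)`: 32 wards on a rook-contiguity lattice, a
  stand-in for the real urban contiguity map (which is out of scope);
* mean cases per ward $314/32 = 9.8125$, drawn as
  $1 + \mathrm{Poisson}(\mathrm{mean} - 1)$ so no ward is empty (the
  handling of genuinely empty wards is a data-layer policy, not a
  generator feature); this reproduces the reported scale of a median ~8
  cases per ward, range ~1–31, total ~314;
* $\alpha = 4.2$ log-days (median DUP near $\exp(4.24) \approx 69.5$
  days), $\beta$ = the reported covariate estimates (age 0.052/year, sex
  0.24, ethnicity contrasts $-0.13$ to $-1.2$), $\sigma_e = 1.9$,
  $\sigma_R = 0.11$, $\sigma_S = 0.19$;
* age uniform on the 16–64-year eligibility window; fair-coin sex. The
  source reports no ethnicity mix, so the default (30% white British,
  10% other white, 25% black Caribbean, 20% black African, 3% Asian, 7%
  mixed, 5% other) is a single, plausible inner-London first-episode
  choice — configurable, never fitted to anything;
* an optional diagnosis label (70% non-affective / 30% affective by
  default) so the subgroup pipeline can be exercised; the real
  class-by-ward structure is unknown and not emulated;
* $S$ is drawn from the sum-to-zero-constrained proper subspace of the
  ICAR via eigendecomposition of the graph Laplacian — the standard
  identifiable representation.

What the generator does *not* emulate: referral pathways, DUP
measurement error, the excluded no-fixed-abode mechanism, informative
missingness, or real London geography. A green test therefore
establishes that the *machinery* is correct under the stated generative
world, not that the original estimates are reproduced — the acceptance
checks are deliberately property-based (conjugate closed forms, Laplacian
pseudo-inverse oracles, coverage and model-selection recovery) for that
reason.

## Numerical and design choices

* Zero-day DUP values are rejected by default; `zero_dup = "offset"`
  substitutes 0.5 days and logs it. Silent transforms corrupt analyses.
* Empty wards are retained in the graph by default (they still borrow
  spatial strength); `drop_empty_wards = TRUE` reproduces the
  study-faithful behaviour of ignoring them.
* Age is untransformed and uncentred by default so the coefficient is
  "per year of age" on the reported scale; `center_age = TRUE` is
  available for conditioning.
* Equal-tailed (not HPD) 95% intervals, median point estimates.
* All randomness flows from one root seed: `simulate_dataset()` splits
  it into effect/count/noise streams, `run_chain()` derives per-chain
  seeds, `run_six_models()` per-model seeds — identical configuration
  and seed give byte-identical outputs, including the JSON manifest
  (which deliberately records no timestamps).
* "Large spatial signal" in the model-selection recovery checks is fixed
  a priori at conditional $\sigma_S = 3$, chosen so the marginal spatial
  SD on the 4×8 lattice is comparable to $\sigma_e = 1.9$.

## A worked run

```{r ladder, eval = FALSE}
graph <- make_lattice_graph(4, 8)
sim <- simulate_dataset(graph, simulation_params(seed = 1))
run <- run_six_models(sim$records, graph, n_iter = 12000,
                      burn_in = 4000, n_chains = 2, seed = 2)
run$comparison
format_report_table(run$reports)
export_ward_effects(run$samples$model2)
```

Under the default (near-null) world the single-level covariate model
typically attains the minimum DIC and the hierarchical models report an
area-level variance share of around 1% with wide intervals — the same
qualitative verdict the machinery was built to test. Subgroup reruns
(`run_subgroups()`) repeat the whole ladder within the non-affective and
affective diagnosis classes.

## Known limitations

* No proper-CAR ($\rho$-parameterised) or spatio-temporal extensions; no
  Metropolis fallback — the sampler is conjugate-only by design.
* No WAIC/LOO; DIC is the comparison tool because the analysis it
  re-implements is defined in those terms.
* The multi-component recentring compromise above.
* Whether the original ward map used queen or rook contiguity is
  unknown; the lattice stand-in uses rook, and nothing downstream
  depends on the choice.
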