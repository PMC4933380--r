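---
title: "Dynamical influence: model, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamical influence: model, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netinflux)
```

## The quantity being estimated

Knockout experiments probe the total loss of a protein, but most mutations
perturb activity only slightly. `netinflux` quantifies the phenotypic
leverage of such small perturbations through a dynamical model: given an
ODE network with species trajectories $y_c(t)$ under stimulation
conditions $c$ (each a set of $t = 0$ overrides, typically a ligand
addition, simulated over a horizon $T_c$), the influence of rate constant
$k_i$ is

$$\kappa_i^2 \;=\; \sum_c \sum_y \frac{1}{T_c} \int_0^{T_c}
\left[ \frac{d y_c(t)}{d k_i}\, \frac{k_i}{y_{\max}} \right]^2 dt ,$$

evaluated at the model's reference rate constants $k^*$, with $y_{\max}$
the maximum of species $y$ over *all* conditions jointly. Dividing by
$k_i$'s own scale and by $y_{\max}$ makes the integrand unit-free; a
control coefficient $d\ln y / d\ln k$ would do the same but is undefined
for species that start (and may remain) at zero concentration, which is
common in signaling models. Two invariances follow and are enforced by
tests: $\kappa$ is unchanged when any species' concentration units are
rescaled, and unchanged when $k_i$'s units are rescaled.

Domain influence is the geometric mean over the $N_d$ rate constants
annotated to domain $d$:
$D_d = \left(\prod_r \kappa_r\right)^{1/N_d}$. A geometric mean is the
right average for quantities spread over orders of magnitude; it is
permutation-invariant in the domain's constants and homogeneous of degree
one. A mutation in a domain perturbs all of its rate constants at once,
with weights that differ mutation by mutation; lacking systematic data on
those weight distributions, the geometric mean is a neutral summary, and
domain-specific perturbation distributions could replace it when such
data exist.

### Assumptions

* Dynamics are deterministic ODEs; stochastic regimes (low copy numbers)
  are out of scope, so the method should be applied to models where a
  continuous approximation is defensible.
* Stimulation is a $t=0$ override; mid-course events are not modeled.
* Only parameters flagged as rate constants — those representing
  structure-dependent reaction rates — are scored.
* Rate laws are arbitrary arithmetic expressions; mass action is not
  assumed.

## Numerical implementation

Sensitivities $dy/dk$ are obtained by integrating the forward sensitivity
system $\dot S = J_y S + J_k$ alongside the state (one integration pass
per condition), with Jacobians derived symbolically from the rate-law
expressions. The integrator is `deSolve::lsoda` (stiff-capable), with
`rtol = 1e-8` and `atol = 1e-10 * max(1, initial concentrations)`; the
time integral uses the trapezoid rule on a uniform grid of
`n_grid = 512` intervals by default. Doubling the grid moves $\kappa$ by
less than 0.1 % on smooth cascade fixtures, and the test suite compares
sensitivities against central finite differences (relative step
$10^{-4}$) at tightened tolerances (`rtol = 1e-10`) so that the
comparison reflects the sensitivity system rather than integration error.

Degenerate inputs are resolved as follows:

* species with $y_{\max} = 0$ (identically zero in every condition) have
  an undefined normalization and contribute zero to the sum;
* rate constants with $k^* = 0$ score $\kappa = 0$ — the $k_i$ factor
  annihilates the integrand — and are reported via a message;
* a domain containing a $\kappa = 0$ parameter scores $D = 0$: zero
  propagates through the geometric mean rather than being floored,
  because flooring would invent information about a dynamically inert
  direction. These domains are reported via a message.

The finite-perturbation variant replaces $dy/dk$ with the central
difference $[y(k(1+\delta)) - y(k(1-\delta))]/(2\delta k)$, one parameter
at a time, with $\delta = 0.25$ by default, and takes $y_{\max}$ from the
unperturbed reference runs. As $\delta \to 0$ it converges to the
differential influence (verified at $\delta = 10^{-3}$). At
$\delta = 0.25$ the two methods agree in value to a few percent on
cascade fixtures; note that a *rank* correlation computed over only a
handful of parameters is sensitive to near-ties — two $\kappa$ values
0.1 % apart can legitimately swap order under a finite perturbation —
so rank agreement should be judged over the full parameter complement of
a model, not tiny subsets.

The key-species restriction recomputes the species sum over a stated
subset (the species a model's authors considered central) while keeping
$y_{\max}$ over all conditions; passing the full species set reproduces
the full computation exactly.

## Model-derived covariates

Protein abundance is the sum of initial concentrations of all species
assigned to a protein, with a complex counting once toward each member
(membership is a `;`-separated list in the species table). The domain
graph has an edge between any two domains that participate in a reaction
together (their annotated parameters share a rate law); degree is the
simple degree, and betweenness centrality is normalized by
$(n-1)(n-2)/2$ so it is the *fraction* of shortest paths through the
node, with equal-length paths splitting credit fractionally (Brandes
semantics). Because only rank correlations are consumed downstream, the
normalization constant does not affect any reported statistic. External
protein-interaction edge lists are unioned and deduplicated before the
same statistics are computed.

## The statistical layer

Within a network, associations use Spearman rank correlations with
mid-ranks for ties; associations with binary essentiality use the
rank-biserial coefficient in Cliff's-delta form
$r_b = 2U_1/(n_1 n_0) - 1$ with half-credit for ties (any
monotone-equivalent definition yields identical permutation p-values).
Partial correlations are product-moment correlations of OLS residuals
after regressing each target on the controls (binary controls as 0/1),
with listwise deletion across *all* involved variables; simple
correlations delete listwise per pair.

Across networks, the Hunter–Schmidt random-effects estimators combine
per-network correlations $r_i$ weighted by domain counts $n_i$:
$\hat\rho_0 = \sum n_i r_i / \sum n_i$;
$\hat\sigma_r^2 = \sum n_i (r_i - \hat\rho_0)^2 / \sum n_i$;
$\hat\sigma_e^2 = [\sum n_i (1-r_i^2)^2/(n_i-1)] / \sum n_i$;
$\hat\sigma_\rho^2 = \max(0,\, \hat\sigma_r^2 - \hat\sigma_e^2)$
(truncated at zero, the standard convention when sampling error exceeds
the observed spread); $\mathrm{SE} = \hat\sigma_r/\sqrt{K}$ and the 95 %
CI is $\hat\rho_0 \pm 1.96\,\mathrm{SE}$. This estimator was preferred
over $r$-to-$Z$ weighting for its accuracy when population heterogeneity
is large. A known limitation documented by our simulations: at moderate
$K$ (around 18 networks) the interval is mildly anti-conservative —
$\hat\sigma_r$ is biased slightly downward when the mean is estimated
from the same $K$ studies, and 1.96 is a large-$K$ quantile — so
empirical coverage sits near 91–93 % rather than 95 %. The package
reports the interval as defined; users wanting exact frequentist coverage
should rely on the permutation tests, which our null simulations show to
be calibrated (type-I error statistically compatible with the nominal
5 %).

### Permutation schemes

The null hypothesis is independence of two variables *within* each
network. Each variable is permuted at the level where it is defined,
independently within each model:

* **param_influence** — domain influences are not exchangeable (domains
  share reactions), so the per-parameter $\kappa$ values, the basic unit
  of the analysis, are permuted and $D$ is recomputed from the permuted
  values;
* **domain_level** — domain-level variables (evolutionary rate) are
  permuted directly;
* **protein_level** — protein-level covariates are permuted as
  per-protein tuples, so domains of one protein always retain identical
  covariate values. By default all protein-level covariates move as one
  joint tuple (preserving their mutual dependence); a switch permits
  permuting only the tested covariate, which matters only for
  partial-correlation nulls.

For partial correlations, the residual vectors themselves are permuted
within each model, which breaks the target association while preserving
every relationship with the controls. The statistic is always the
sample-size-weighted mean correlation across models; the two-sided
p-value is the fraction of permuted absolute means at least as large as
the observed one, reported as `< 1/N_perm` when no permuted value is as
extreme (the numeric field then stores $1/N_{\text{perm}}$ with a flag,
keeping p in $(0, 1]$). Listwise deletion is applied once, before
permuting, so the complete-case set is held fixed under the null.
Permutations run within each model with the `domain_level` scheme
vectorized over permutations via precomputed ranks.

### Between-model agreement and overlapping domains

Influences of domains shared by two models are compared by Spearman
correlation over the shared set (pairs with fewer than 4 shared domains
are excluded as too noisy), and pair correlations are combined with the
same $n$-weighted mean, $n$ being the overlap count. Because shared
domains could inflate across-model significance, a randomization retains
each multi-model domain in exactly one uniformly chosen model per
replicate and reruns the analysis, summarizing the replicate
distributions by their 50th (5th, 95th) quantiles.

## What the synthetic generator emulates — and what it does not

`make_cascade_network()` produces mass-action ligand–receptor–kinase
cascades: reversible ligand binding, per-tier reversible kinase binding,
catalytic phosphorylation, and first-order dephosphorylation, with rate
constants drawn log-normally (sdlog 0.5) around 1 and stimulation by
ligand doses of 0.5 and 2 over a horizon of $10 + 5\,n_{\text{tiers}}$
time units — long enough for the response to propagate through all
tiers. Domains partition each protein's constants (a single-tier kinase
carries its four-parameter motif on one binding domain; deeper cascades
split binding and phospho-site domains and assign each catalytic
constant also to the upstream kinase's catalytic domain, exercising
many-to-many annotation). These fixtures conserve protein mass and are
small enough for exhaustive oracle checks; they do *not* reproduce the
topology, kinetic diversity (non-mass-action rate laws), or stiffness of
curated models, so passing tests demonstrate correctness of the
machinery, not biological conclusions about any real network.

`make_meta_population()` emulates the random-effects model directly: each
of $K = 18$ networks draws a true correlation
$\rho_i \sim N(\rho_0 = -0.25,\ \sigma_\rho = 0.15)$ clamped to
$(-0.999, 0.999)$ (keeping the copula well-defined), then draws
$8$–$40$ domains whose $(\omega, D)$ ranks follow a Gaussian copula with
latent Pearson correlation $2\sin(\pi\rho_i/6)$ — the closed-form
transform that makes the population Spearman correlation equal $\rho_i$.
$\omega$ maps to a log-normal dN/dS-like scale (median 0.1, sdlog 0.8)
and $D$ to a log-normal scale spanning orders of magnitude (sdlog 1.5);
only ranks enter the statistics, so these marginals are cosmetic.
Protein-level covariates are drawn per protein from a latent Gaussian
with common pairwise correlation 0.25, mapped to natural scales (tissue
counts 1–45, log-normal expression, Poisson-like degree, a Beta(1,8)
centrality in $[0,1]$, essentiality at 50 % prevalence, Beta(8,2)
knockout growth rate), and are independent of $(\omega, D)$ by default,
so the planted signal is exactly the $\omega$–$D$ population
correlation. Real data differ in ways this generator deliberately
ignores: covariates correlate with evolutionary rate, missingness is
informative, domain counts per protein are skewed, and per-network true
correlations need not be Gaussian.

`make_parameter_ensemble()` stands in for posterior ensembles of rate
constants by multiplying $k^*$ by independent log-normal factors; real
ensembles have strongly correlated ("sloppy") parameter directions,
which this stand-in does not reproduce, so ensemble comparisons here
test the machinery and the qualitative jitter-monotonicity, not the
quantitative spread of any published ensemble.

## Problem sizes used by the tests and the acceptance script

The tests run cascades of 1–3 tiers (4–14 rate constants, grids of
48–512 intervals), brute-force oracles on instances of at most 10
elements or nodes, 500 replicate studies for CI coverage, 300–400
replicates at $N_{\text{perm}} = 1000$ for permutation calibration, and
ensembles of up to 50 parameter sets. These sizes give sub-percent Monte
Carlo resolution on the reported rates while keeping a full run in a few
minutes on one CPU; all of them are set in the test and script sources
and scale up by changing the obvious arguments.

## Known limitations

* SBML import covers a pragmatic Level 2/3 subset (species, parameters,
  reactions with MathML kinetic laws, constant initial assignments);
  events, rules, delays, and function definitions are rejected
  explicitly rather than silently misread.
* The Hunter–Schmidt CI undercovers mildly at moderate $K$ (see above);
  the permutation tests are the calibrated inference route.
* Influence compares perturbations *within* one model; comparing raw
  $\kappa$ or $D$ values across models requires assumptions the method
  does not make — hence all across-model statements go through ranks and
  the meta-analysis.
* Whether a protein-level permutation should move covariates jointly or
  singly is not determined by the method's definition; both are
  implemented (`joint =`), and the choice only affects
  partial-correlation nulls.
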