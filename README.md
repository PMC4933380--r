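# netinflux

Amino-acid substitutions rarely destroy a protein; they nudge its
biochemical activity. `netinflux` asks how much such a nudge matters to the
cell, using ordinary-differential-equation models of signaling and
biosynthetic networks: it scores every reaction rate constant by the
**dynamical influence** its perturbation exerts on the network's
trajectories, aggregates those scores to protein domains, and provides the
statistical machinery — per-network rank correlations, random-effects
meta-analysis across networks, and structured permutation tests — to relate
domain influence to evolutionary rate (dN/dS) and to classical correlates
such as expression level, network topology, and knockout phenotype. It is
aimed at molecular-evolution and systems-biology researchers who want to
test selection-on-dynamics hypotheses on collections of curated network
models.

## The method

For a network simulated under stimulation conditions *c* over horizons
*T_c*, the influence of rate constant *k_i* is

    kappa_i^2 = sum_c sum_y (1/T_c) * int_0^{T_c} [ (dy_c(t)/dk_i) * k_i / y_max ]^2 dt

evaluated at the published reference values *k*\*, where *y_c(t)* is the
trajectory of molecular species *y* and *y*_max its maximum over **all**
conditions. The *k_i / y*_max normalization makes the integrand a
unit-free log-derivative scaled to each species' dynamic range (a plain
control coefficient d ln y / d ln k would be undefined for the many
signaling species that start at zero concentration). Sensitivities
*dy/dk* are integrated by the forward sensitivity system alongside the
state; a finite-perturbation variant (±25 % by default) covers mutations
of moderate effect.

The influence of a protein domain *d* annotated with *N_d* rate constants
is their geometric mean,

    D_d = ( prod_r kappa_r )^(1/N_d),

appropriate because sensitivities range over orders of magnitude.

Per-network associations between domain variables use Spearman rank
correlations (rank-biserial for binary essentiality; OLS-residual partial
correlations for adjusted effects). Across *K* networks, correlations
*r_i* with domain counts *n_i* are combined by the Hunter–Schmidt
random-effects estimators

    rho0    = sum(n_i r_i) / sum(n_i)
    var_r   = sum(n_i (r_i - rho0)^2) / sum(n_i)
    var_e   = sum(n_i (1 - r_i^2)^2 / (n_i - 1)) / sum(n_i)
    sd_rho  = sqrt(max(0, var_r - var_e))
    SE      = sqrt(var_r) / sqrt(K),   CI95 = rho0 +/- 1.96 SE

Permutation tests scramble each variable at the level where it is defined
— rate-parameter influences (with *D* recomputed), domain-level rates, or
protein-level covariate tuples — independently within each model, and
compare the observed weighted mean correlation to its permutation null.

## Worked example

```r
library(netinflux)

# a two-tier ligand -> receptor -> kinase cascade with domain annotations
cas <- make_cascade_network(n_tiers = 2, seed = 7)
cas$network
#> <reaction_network> cascade2: 9 species, 10 parameters (10 rate constants), 10 reactions

trajs <- simulate_conditions(cas$network, cas$conditions)
infl  <- parameter_influence(trajs, cas$network)
dom   <- domain_influence(infl, cas$annotation)
dom
#>   domain_id protein_id     D N_d
#> 1     R0-LB         R0 0.259   2
#> 2     K1-KB         K1 0.806   2
#> 3     K1-PS         K1 1.157   2
#> 4     K2-KB         K2 0.801   2
#> 5     K2-PS         K2 0.872   2
#> 6    K1-CAT         K1 0.756   1
```

The receptor's ligand-binding domain (`D = 0.26`) influences the dynamics
far less than kinase 1's phospho-site (`D = 1.16`): perturbing
(de)phosphorylation rates reshapes every downstream trajectory, while
ligand binding is buffered. `N_d` counts the rate constants behind each
geometric mean.

```r
# 18 synthetic networks with a planted population correlation of -0.25
pop  <- make_meta_population(K = 18, rho0 = -0.25, sigma_rho = 0.15, seed = 7)
meta_correlation(pop, c("omega", "D"))
#> <meta_analysis_result> rho0 = -0.232 (95% CI -0.357, -0.106), sigma_rho = 0.193, K = 18

permutation_test(pop, c("omega", "D"), scheme = "domain_level",
                 n_perm = 10000, seed = 7)
#> <permutation_result> scheme domain_level: observed mean r = -0.2315, two-sided p <0.0001 (N_perm = 10000)

meta_partial_correlation(pop, c("omega", "D"), c("B", "X", "d"))
#> <meta_analysis_result> rho0 = -0.149 (95% CI -0.221, -0.076), sigma_rho = 0.000, K = 18
```

The meta-analysis recovers the planted mean correlation (−0.23 vs the true
−0.25) with a confidence interval excluding zero; none of 10,000
within-model permutations produced as extreme a weighted mean, so the
two-sided p-value is reported as `<0.0001`; and the association survives
controlling for expression breadth, expression level, and degree.

Models can also be read from files: the native YAML schema
(`read_network_yaml()`) or an SBML Level 2/3 subset (`read_sbml()`), with
domain annotations and covariates as TSV.

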