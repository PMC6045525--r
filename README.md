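# mglca

Multigroup latent class models for binary musculoskeletal-pain indicators.

## The problem

Epidemiological surveys of musculoskeletal pain record yes/no symptoms at
several anatomic sites — here neck, shoulder, upper back and low back in a
cohort of 1611 schoolchildren. Site-by-site prevalences miss the point that
pain clusters: the scientific object is the *combination* of sites, and the
question is whether a small number of unobserved risk groups explains the
associations among sites, and whether those groups look the same across
gender and age.

`mglca` implements that analysis end to end for biostatisticians and
epidemiologists: latent class analysis (LCA) of binary indicators,
class-count selection, posterior assignment, multigroup models with a
measurement-invariance test, Table-1-style prevalence descriptives, and a
seeded synthetic-cohort generator parameterized by the published estimate
tables (no subject-level data are deposited with the study).

## The model

A C-class latent class model treats each subject's response pattern
x = (x_1, ..., x_J), x_j in {0, 1}, as a draw from a mixture of
independent-Bernoulli products:

    P(x) = sum_c  gamma_c  prod_j  rho_cj^(x_j) (1 - rho_cj)^(1 - x_j)

with membership probabilities gamma on the simplex and item-response
probabilities rho_cj in [0, 1]. Items are conditionally independent given
class; items missing at random are marginalized out of the likelihood.
Estimation is multi-start EM with a maximum-absolute-deviation (MAD)
convergence criterion. Fit is judged on the complete-case pattern table by
G² and Pearson X²; model selection uses G²-based criteria AIC = G² + 2p and
BIC = G² + p·log(n). Measurement invariance of rho across G groups is
tested by the chi-square difference between the constrained (shared-rho)
and free fits on (G−1)·C·J degrees of freedom. With three classes the
severity convention labels them *minor*, *moderate* and *major* pain.

## Worked example

Simulate a cohort from the packaged general-model estimates and refit:

```r
library(mglca)

fx     <- load_fixture("table2")                       # published 3-class model
cohort <- simulate_lca(fx, n_total = 1611, seed = 20180713)
fit    <- fit_em(cohort, 3, em_config(seed = 1, n_starts = 20))
print(fit)
```

```
<lca_fit> C = 3, J = 4, n_used = 1611
  loglik -3222.236 | G2 3.215 (df 1, p 0.073) | AIC 31.22 | BIC 106.60
  converged: TRUE (final MAD 9.96e-09, 2529 iterations)
<lca_params> 3 classes x 4 items
gamma:
   minor moderate    major 
   0.361    0.552    0.087 
rho:
          neck shoulder upper_back low_back
minor    0.000    0.013      0.008    0.135
moderate 0.343    0.227      0.223    0.341
major    0.898    0.641      0.676    1.000
```

The refitted model passes the G² screen (p = 0.073 > 0.05) and lands near
the generating values: the major pain class holds 8.7% of the cohort
(generator: 7.1%) with a neck-pain probability of 0.898 (generator: 0.88)
and certain low-back pain. Mixing the published rho by the published gamma
reproduces the published marginal prevalences:

```r
round(100 * model_implied_marginals(group_params(fx$params, 1)), 1)
#>       neck   shoulder upper_back   low_back 
#>       27.9       20.7       19.1       34.2
```

— the published neck and shoulder figures are 27.9% and 20.7%.

## The analysis workflow

The numbered drivers under `analysis/` run the full study shape on a
synthetic cohort and write their tables under `results/`:

| script | what it does |
|---|---|
| `analysis/01_simulate.R` | draws the 1611-subject gender-age cohort |
| `analysis/02_descriptives.R` | per-stratum prevalence, Wilson CIs, homogeneity tests, letter subscripts |
| `analysis/03_class_enumeration.R` | 2–4 class sweep with the GOF screen and 5% AIC/BIC rule |
| `analysis/04_multigroup_invariance.R` | gender / age / gender-age fits and Chi²-difference invariance tests |

Each stage is a thin narrative wrapper over exported functions
(`simulate_lca`, `descriptives_table`, `select_classes`,
`invariance_test`, ...), so everything they do is unit-tested package code.
`run_analysis()` executes the same pipeline in one call. The methods
vignette (`vignettes/multigroup-lca-methods.Rmd`) documents the model,
conventions, numerical choices and known limitations.

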