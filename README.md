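# dallaltest

Homogeneity tests for intraclass dependence in bilateral binary data.

## The problem

Trials on paired organs (ophthalmology, otolaryngology) record for each
patient whether 0, 1 or 2 organs responded. The two organs of one patient
are correlated, and under **Dallal's model** that correlation is carried by
a single parameter per group: the conditional probability
γ<sub>i</sub> = P(one organ responds | the other responds), assumed free of
the marginal response rate π<sub>i</sub>. The per-patient outcome in group
*i* is trinomial with

    p0 = 1 − (2 − γ)π,   p1 = 2π(1 − γ),   p2 = πγ,
    max{0, 1 − 1/(2π), 2 − 1/π} ≤ γ ≤ 1.

The package is for biostatisticians who need to test whether that
dependence is the *same* across g groups,

    H0: γ1 = … = γg   vs   H1: γi ≠ γj for some i ≠ j,

with the response rates free. It provides:

* closed-form maximum likelihood estimates, unconstrained and under H0
  (`mle_unconstrained()`, `mle_constrained()`), with `tidy()`/`glance()`
  methods, plus the Fisher information and its closed-form inverse;
* three asymptotic tests — likelihood ratio, score, Wald-type — referred to
  χ²(g−1) (`dallal_test()`);
* exact small-sample p-values on any of the three statistics: conditional
  (multivariate hypergeometric, both margins fixed) and Basu-type
  unconditional maximization over the null parameter space
  (`exact_test()`, `conditional_pvalue()`, `m_pvalue()`), with full
  table-space enumeration (`enumerate_tables()`);
* a Monte Carlo engine for type-I-error and power studies and enumerated
  exact sizes (`tie_study()`, `power_study()`, `exact_size_study()`), with
  `autoplot()` methods.

## Worked example

The bundled four-group retinitis pigmentosa study (216 patients, number of
affected eyes by genetic type):

```r
library(dallaltest)
rp <- dallal_fixture("rp_table2")
dallal_test(rp)
#> # A tibble: 3 × 6
#>   method statistic    df p.value reject flags
#>   <chr>      <dbl> <int>   <dbl> <lgl>  <chr>
#> 1 lrt         4.46     3   0.216 FALSE  ""
#> 2 score       4.18     3   0.242 FALSE  ""
#> 3 wald        5.76     3   0.124 FALSE  ""
```

None of the three tests rejects at α = 0.05: there is no evidence that the
eye-to-eye dependence differs between the four genetic groups. The common
dependence is then estimated under H0:

```r
glance(mle_constrained(rp))
#> # A tibble: 1 × 5
#>   constrained loglik n_groups     n    df
#>   <lgl>        <dbl>    <int> <dbl> <int>
#> 1 TRUE         -16.6        4   216     5
tidy(mle_constrained(rp))$gamma[1]
#> [1] 0.8246445
```

i.e. a patient whose one eye is affected has an estimated 82.5% chance that
the other is too. For small samples, the exact machinery replaces the
χ² calibration:

```r
tab <- bilateral_table(c(1, 0, 1, 0, 2, 0))   # two groups of two patients
tidy(exact_test(tab, "conditional", "score"))
#> # A tibble: 1 × 6
#>   method statistic observed_statistic p.value tail_size space_size
#>   <chr>  <chr>                  <dbl>   <dbl>     <int>      <int>
#> 1 C      score                      3   0.333         2          4
```

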