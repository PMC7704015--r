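---
title: "Testing homogeneity of intraclass dependence in bilateral binary data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing homogeneity of intraclass dependence in bilateral binary data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dallaltest)
```

## The model

Clinical studies of paired organs (eyes, ears) record, for each patient, how
many of the two organs responded: 0, 1 or 2. Treating the two organs as
independent Bernoulli trials ignores the strong within-patient correlation
that such data almost always show. Dallal's model captures that correlation
with a single extra parameter per group: alongside the marginal response
rate $\pi_i$ of group $i$, the conditional probability

$$\gamma_i = P(\text{one organ responds} \mid \text{the other responds})$$

is assumed *not to depend on* $\pi_i$. The per-patient outcome is then
trinomial with

$$p_{0i} = 1 - (2-\gamma_i)\pi_i, \qquad
  p_{1i} = 2\pi_i(1-\gamma_i), \qquad
  p_{2i} = \pi_i\gamma_i,$$

which is a valid probability law exactly when

$$\max\{0,\ 1 - \tfrac{1}{2\pi_i},\ 2 - \tfrac{1}{\pi_i}\}
  \le \gamma_i \le 1 .$$

$\gamma_i = \pi_i$ is independence between the organs and $\gamma_i = 1$
complete dependence; this flexibility is what makes the model suitable when
a condition is almost always bilateral yet prevalence varies widely across
groups. The package tests

$$H_0:\ \gamma_1 = \cdots = \gamma_g \quad\text{versus}\quad
  H_1:\ \gamma_i \ne \gamma_j \ \text{for some } i \ne j,$$

i.e. whether the *strength of within-patient dependence* is shared across
groups, with the response rates $\pi_i$ free throughout.

## Estimation

Both the unconstrained and the common-$\gamma$ maximum likelihood estimates
have closed forms (`mle_unconstrained()`, `mle_constrained()`):

$$\hat\pi_i = \frac{m_{1i} + 2m_{2i}}{2m_i}, \quad
  \hat\gamma_i = \frac{2m_{2i}}{m_{1i} + 2m_{2i}}, \qquad
  \tilde\gamma = \frac{2S_2}{S_1 + 2S_2}, \quad
  \tilde\pi_i = \frac{(m_{1i}+m_{2i})(S_1+2S_2)}{2m_i(S_1+S_2)},$$

where $m_{li}$ counts patients with $l$ responding organs in group $i$,
$m_i$ is the group size and $S_l$ the response totals. A group with no
responding organs leaves $\gamma_i$ unidentified; the package reports `NA`
with a flag rather than inventing a number. The test suite verifies the
closed forms against a derivative-free numerical maximizer of the trinomial
likelihood on 200 random tables with $g \in \{2,3,4\}$ and group sizes 5-50
(agreement to $10^{-6}$), and verifies the closed-form inverse of the Fisher
information against the assembled expected negative Hessian on 100 random
interior parameter draws (identity to $10^{-8}$).

```{r mle-example}
rp <- dallal_fixture("rp_table2")
rp
tidy(mle_unconstrained(rp))
glance(mle_constrained(rp))
```

## Asymptotic tests

`dallal_test()` offers the likelihood ratio, score and Wald-type statistics,
each asymptotically $\chi^2_{g-1}$ under $H_0$:

```{r test-example}
dallal_test(rp)
```

The likelihood ratio and score statistics use simplified closed forms in
the counts; the Wald statistic is the quadratic form $d^\top A^{-1} d$ on
successive $\hat\gamma$ differences, with $A$ the symmetric tridiagonal
matrix built from the estimated variances
$\hat a_i = 4m_{1i}m_{2i}(m_{1i}+m_{2i})/(m_{1i}+2m_{2i})^4$. We evaluate
the quadratic form by a linear solve for every $g$; published elementwise
expressions for $A^{-1}$ exist for small $g$ and the suite checks the solve
against the $g = 2, 3, 4$ closed forms to $10^{-10}$, but the solve is the
implementation — it is exact, stable, and free of transcription risk.

Degenerate tables need explicit conventions, because the exact machinery
below evaluates the statistics on *every* table of an enumerated space:

* $S_1 = 0$ or $S_2 = 0$: all groups share a boundary $\hat\gamma$, so the
  likelihood ratio and score statistics are defined as 0 (no evidence of
  heterogeneity).
* a group with $m_{1i} + 2m_{2i} = 0$ has no information about $\gamma_i$
  and is dropped from the Wald contrast, reducing the degrees of freedom
  (flagged `dropped-groups`).
* $\hat a_i = 0$ (a boundary $\hat\gamma_i$) alongside a nonzero contrast
  makes $A$ singular with signal: the statistic is $+\infty$ and the
  p-value 0, i.e. maximal evidence. An all-zero contrast gives 0. A
  consequence worth knowing: under these conventions the Wald test can
  produce exact-zero p-values, so its rejection rate does not vanish as
  $\alpha \to 0$ on small samples; the likelihood ratio and score tests are
  unaffected.

## Exact tests

Large-sample $\chi^2$ calibration fails for the small samples bilateral
studies often have, so two exact constructions are provided on top of any
of the three statistics (`exact_test()`).

**Conditional (C).** Fixing both margins (group sizes and response totals)
induces a multivariate hypergeometric law on the space of tables,
$P(\mathbf m) \propto \prod_i m_i!/(m_{0i}!m_{1i}!m_{2i}!)$ normalised by
$N!/(S_0!S_1!S_2!)$ — the only normalisation under which the probabilities
sum to one, which the suite asserts to $10^{-12}$. The p-value sums the
probabilities of all members whose statistic reaches the observed one.

**Maximization (M).** Basu's unconditional construction fixes only the
group sizes and maximizes the tail probability over the *null* parameter
space. We take that space to be $\pi \in [0,1]^g$ with a **common**
$\gamma$ between $\max_i \{\text{lower bound}(\pi_i)\}$ and 1. A
group-specific-$\gamma$ reading of the nuisance space is sometimes
displayed, but maximizing over parameters outside $H_0$ contradicts the
construction's guarantee and inflates the p-value toward 1; the common-
$\gamma$ space is the one under which the size guarantee below actually
holds.

Numerical choices, all surfaced as arguments and recorded in the result:

* tail membership uses an absolute tolerance of $10^{-9}$ so that
  floating-point ties land inside the tail (the observed table is always a
  member, hence $p > 0$);
* the maximization runs a full grid — 21 points per parameter dimension by
  default, intersected with the constraint — followed by Nelder–Mead
  refinement (relative tolerance $10^{-10}$) from the 5 best grid points,
  on a logistic-transformed scale that keeps every iterate feasible;
* the reported value is the best found: a guaranteed *lower* bound on the
  supremum. Doubling `grid_points` keeps the grid nested, so the grid part
  of the search is monotone by construction;
* tail probabilities factor over groups (per-group trinomial probability
  vectors over each group's $\binom{m_i+2}{2}$ compositions), so
  multinomial coefficients are computed once per space, not once per
  parameter point; for two groups a whole $(\pi_1, \pi_2)$ grid slice is a
  single matrix product;
* enumeration refuses spaces above `cap` ($10^7$ by default) with the
  exact combinatorial count in the message — $\prod_i \binom{m_i+2}{2}$,
  e.g. 4,356 tables for two groups of 10 and $\binom{12}{2}^3 = 287{,}496$
  for three (a published count of 287,492 for that case is a typo; the
  product of binomial coefficients is authoritative).

Because the tails of the M construction are nested in the observed
statistic, exact size computations only maximize once per *unique*
statistic value (`exact_size_study()`). At group sizes (5, 5) with the
score statistic the M test's exact size over a dense null grid stays below
$\alpha = 0.05$ — the defining guarantee — while the asymptotic tests can
exceed it; the acceptance suite recomputes this.

## Simulation engine

`simulate_tables()` draws group-wise trinomial tables;
`tie_study()` / `power_study()` wrap it into type-I-error and power
experiments and return tidy tibbles ready for `autoplot()`. The generator
emulates exactly the sampling model above: independent patients, a common
$(\pi, \gamma)$ per group, multinomial sampling with fixed group sizes.
What it deliberately does *not* emulate: covariate structure,
patient-level heterogeneity in $\pi$, misclassification, or dependence
between groups — so robust behaviour in these studies speaks to the
model's own sampling assumptions, not to violations of them.

Default replication is $R = 2{,}000$ per grid point, a desk-scale setting
chosen so a full $(\pi, \gamma)$ surface remains interactive; any study can
be rerun at $R = 10{,}000$ or more by changing one argument. The
documented robustness bands are used throughout: at $\alpha = 0.05$ a test
is *liberal* above an empirical rate of 0.06, *conservative* below 0.04,
*robust* between. Every grid point gets its own substream seed derived
deterministically from the master seed, so results are reproducible and
independent of evaluation order; Monte Carlo standard errors
$\sqrt{p(1-p)/R}$ accompany every estimate, and stochastic assertions in
the test suite use 3-SE bands.

```{r power, fig.width = 6, fig.height = 3.5}
pw <- power_study(c(15, 15), pi = c(0.2, 0.3),
                  gamma1 = seq(0.2, 0.9, by = 0.1), gamma_other = 0.1,
                  R = 500, seed = 42)
autoplot(pw)
```

The suite's stochastic checks use $g = 2$ with $m = 200$, $\pi = 0.3$,
$\gamma = 0.6$ and $R = 5{,}000$ for the null calibration of the asymptotic
tests, and $m = 15$, $\pi = (0.2, 0.3)$, $\gamma_2 = 0.1$, $R = 2{,}000$
for the power ordering; exact-size enumeration uses group sizes (5, 5)
with a $51 \times 51$ null grid.

## The bundled examples

`dallal_fixture("rp_table2")` is the four-group retinitis pigmentosa study
(216 patients, affected eyes by genetic type) used as the worked example
throughout: its statistics, p-values and both sets of MLEs are reproduced
by the acceptance suite to four decimals (one published constrained
estimate, 0.5675 for the second group, differs from the closed form 0.5672
in the final digit and is compared at $5\times10^{-4}$).

The otitis media study is shipped twice — `"ome_table4"` (the tabulated
version, $N = 31$) and `"ome_mstar"` (the inline flat-vector version,
whose third group reads (6, 0, 7) and so implies $N = 37$). The two
published presentations of the same data disagree, and the statistics
published alongside them are reproducible from neither; both fixtures are
therefore bundled verbatim as demonstration data, neither is privileged,
and no numerical claims are tied to them.

## Limitations

* The M p-value is a lower bound on the supremum; pathological tail
  surfaces with spikes between grid points could in principle evade the
  refinement, though the factored trinomial tails here are smooth.
* Unconditional enumeration grows as $\prod_i \binom{m_i+2}{2}$; beyond
  the cap only the conditional method is practical (no network algorithm
  is provided).
* One-sided alternatives, small-sample corrections (continuity, Bartlett)
  and confidence intervals for $\gamma$ are out of scope, as are competing
  dependence models (constant-ratio and common-correlation formulations).
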