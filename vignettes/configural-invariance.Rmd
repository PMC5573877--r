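---
title: "Testing and respecifying configurally invariant factor models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing and respecifying configurally invariant factor models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permcfa)
```

## The problem

Comparing groups on a latent construct presupposes that the measurement
model has the same *configuration* — the same pattern of fixed (near-zero)
and free (substantial) parameters — in every group. That assumption,
configural invariance, is conventionally checked by fitting the configural
multigroup CFA and inspecting its overall fit (the likelihood-ratio
chi-square, CFI, RMSEA). But overall fit confounds two different null
hypotheses: that the groups share a configuration, and that the posited
model is exactly correct. A model that approximates every group equally
imperfectly is configurally invariant yet will be rejected by overall-fit
criteria, especially at large *N*. `permcfa` implements two tools that
disentangle the hypotheses:

1. a **permutation test** that refers the observed fit statistics to
   empirical null distributions obtained by randomly reassigning group
   labels and refitting — under label exchangeability these distributions
   embody "same configuration, whatever the overall misfit", so the test
   keeps its nominal size even when the model is wrong for all groups
   alike; and
2. **multivariate (G-df) modification indices** — score (Lagrange
   multiplier) tests of freeing the *same* fixed parameter simultaneously
   in all G groups — which respect configural invariance during
   respecification, unlike the conventional 1-df index that frees a
   parameter in a single group.

## Model and estimation

For group $g$ the model is $\Sigma_g = \Lambda_g \Psi_g \Lambda_g' +
\Theta_g$ with unit-variance factor identification ($\mathrm{diag}(\Psi_g)
= 1$, all on-target loadings free) so that every loading is estimated per
group. Mean structure is excluded: all the statistics involved are
functions of covariances only. With divisor-$n$ sample covariances $S_g$,
maximum likelihood minimises

$$F = \sum_g \frac{n_g}{N}\Big[\log|\Sigma_g| - \log|S_g| +
\mathrm{tr}\big(S_g\Sigma_g^{-1}\big) - p\Big],$$

and $T = N\,F_{\min}$ is the test statistic with $df = \sum_g [p(p+1)/2 -
q_g]$. Because the configural model carries no cross-group constraints,
each group is fitted independently by Fisher scoring with step halving
(expected-information Newton steps), converging when the gradient's
infinity norm drops below `tol = 1e-6` (at most 500 iterations). Residual
variances are not constrained positive: Heywood cases are admissible and
flagged in the convergence record rather than prevented, and
non-positive-definite implied matrices encountered during a step are
rejected by the step-halving line search. Starting values are
$0.7\,\mathrm{sd}$ for loadings, $0.5\,\mathrm{var}$ for residual
variances, and 0 for covariances; replication loops warm-start from a
pooled-sample fit.

Fit indices follow the conventions that reproduce standard multigroup
software output: CFI uses the per-group independence baseline (closed form,
$df_b = G\,p(p-1)/2$), and RMSEA is
$\sqrt{G}\sqrt{\max(T - df, 0)/(df\,N)}$ — the $\sqrt{G}$ multiplier and
the $N$ (not $N - G$) denominator were validated against published
multigroup values. The RMSEA interval inverts the noncentral chi-square
distribution by bisection on the noncentrality parameter (tolerance 1e-8).

## Score tests, EPC, and the respecification loop

The candidate constraints are every fixed-to-zero cross-loading and
residual covariance (factor covariances are free by construction and
factor variances are identification constraints, so neither is ever a
candidate). At the constrained MLE, the gradient $s$ and expected
information $H$ of the discrepancy are evaluated over the free-plus-
candidate parameter set; with $v$ the candidate's information conditional
on the free parameters, the 1-df index in group $g$ is $(n_g/2)\,s^2/v$,
the EPC is $-s/v$, and the SEPC rescales the EPC by model-implied standard
deviations. Because no parameter enters more than one group's implied
covariance, the information matrix is block-diagonal over groups and the
G-df simultaneous statistic is exactly the sum of the per-group 1-df
indices — an identity the test suite checks to 1e-8 and the package
exploits computationally.

The iterative loop mirrors how these indices are meant to be used: free
the largest G-df index significant at the Bonferroni level
$\alpha/\text{(candidate count)}$ in all groups, refit, repeat until none
is significant. The Bonferroni denominator stays at the *initial*
candidate count across iterations (the alternative of re-computing it per
iteration changes the threshold only slightly and is not the convention
the reference rates were produced under). Ties in the index are broken by
the canonical candidate order (cross-loadings by indicator then factor,
then residual covariances by row then column), making the loop fully
deterministic.

## The permutation test

`permutation_test()` shuffles the group column uniformly at random
(preserving group sizes and the pooled data multiset), refits the
configural model, and records chi-square, CFI and RMSEA per permutation.
The p-value is the plain proportion of permuted statistics at least as
*bad* as observed (chi-square/RMSEA: $\geq$; CFI: $\leq$); the add-one
convention $(b+1)/(B+1)$ is available for users who want p-values bounded
away from zero. With the same `df`, `N` and `G` in every refit, RMSEA is a
monotone transform of chi-square, so their permutation p-values coincide;
CFI's baseline varies with the permuted moments, so its p-value can
differ. Nonconverged permutation fits are excluded from numerator and
denominator and counted (warning above 5%). The default `B = 500`
balances p-value granularity against runtime; the Monte Carlo harness uses
`B = 100`, which is sufficient for a 5%-level decision.

## The synthetic-data generator and the Monte Carlo study

`study_population()` encodes the reference population: four groups, two
factors with three indicators each, loadings 0.6/0.7/0.8, residual
variances $1-\lambda^2$ (unit indicator variances), factor correlations
0.2/0.3/0.4/0.5 across groups, and residual covariances 0.2 (indicators
1 and 4) and 0.15 (indicators 2 and 5) in *all* groups. The analysis model
omits the two residual covariances, so exact fit fails
($\chi^2(32) = 54.05$ against the population matrices at $n = 100$ per
group) while configural invariance holds — the regime in which overall-fit
criteria mislead and the permutation test should not. Samples are
multivariate normal via a Cholesky factor of each group's implied
covariance; the generator emulates continuous, normal, complete data and
deliberately not the ordinal, skewed or missing-data features of real
questionnaire data, so passing rates here speak to the statistics'
behaviour under their own assumptions, not to robustness.

`run_study()` replicates: draw $n = 100$ per group, fit, record the
overall-fit decisions (LRT at $\alpha = .05$, CFI < .95, RMSEA > .06), the
permutation decision ($\alpha = .05$, chi-square criterion), the
multivariate-MI loop flags (familywise error: any freed parameter outside
the omitted pair; power: at least one / both omitted parameters freed),
and — without acting on it — whether the single largest 1-df index
significant at $0.05/84$ targets a non-omitted parameter (identity-level,
group-agnostic matching). Replications with nonconverged configural fits
are redrawn up to three times, then dropped and counted. Each replication
derives its own seed from the master seed, so results are identical under
serial and parallel execution.

Reference conditions use 1,000 replications; the test suite runs a
250-replication profile with `B = 100` (binomial-standard-error bands are
widened accordingly), and `scripts/acceptance.R` runs the modification-loop
rates at the full 1,000 replications plus the permutation sub-study at 250.
These sizes keep the whole suite within a few minutes on one core while
leaving Monte Carlo error well inside the comparison bands.

## Numerical and design choices

* **Expected, not observed, information** throughout the score tests —
  the convention of the SEM software whose published index values the
  package reproduces.
* **Degenerate inputs**: singular sample covariances (constant or
  collinear columns) and missing values are rejected with explicit errors;
  `df = 0` models fit exactly (RMSEA is then undefined and errors);
  candidates whose conditioned information is numerically singular get
  `NA` indices with a warning, never a silent 0.
* **p-value convention**: plain proportion by default for fidelity to the
  permutation literature; `pvalue = "addone"` avoids exact zeros.
* **Known limitations**: no mean structure, no missing data (FIML), no
  robust/scaled test statistics, no ordinal indicators, and no tests of
  metric/scalar/strict invariance — the package addresses the configural
  stage only. When configural invariance itself is rejected, the
  multivariate indices are not the right tool (the groups should not be
  respecified jointly).

## A worked population-level example

```{r example, eval = FALSE}
pop <- study_population()
fit <- cfa_fit(configural_spec(pop), population_moments(pop, n = 100))
fit
#> Multigroup CFA fit (maximum likelihood)
#>   groups: 4   N = 400
#>   chi-square(32) = 54.05, p = 0.0087
#>   CFI = 0.962   RMSEA = 0.083, 90% CI [0.042, 0.120]

head(mod_indices(fit), 3)
#> Modification indices (multivariate)
#>   label group     mi df p_value epc sepc
#>  x1~~x4   all 32.099  4 1.8e-06  NA   NA
#>  x2~~x5   all 23.224  4 1.1e-04  NA   NA
#>  x1~~x5   all  5.978  4 2.0e-01  NA   NA

modification_loop(configural_spec(pop), population_moments(pop, 100))
#> Modification trace: x1~~x4 -> x2~~x5
```

Free of sampling error, the loop frees exactly the two omitted residual
covariances and stops: the multivariate indices point at the true
misspecification without ever breaking configural invariance.
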