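---
title: "Asymmetric integration of matched cohorts: model, algorithm, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Asymmetric integration of matched cohorts: model, algorithm, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asymclr)
```

## The statistical problem

`asymclr` tests genetic variants for association with disease status in a
*primary* cohort of 1:1 matched case–control pairs, while borrowing strength
from *auxiliary* matched cohorts whose relevance is unknown a priori. The
asymmetry is deliberate: the auxiliary cohorts exist only to improve
inference in the primary one, and the method must be free to discard any of
them entirely.

## Conditional logistic regression on pair differences

Within stratum $i$ the case and control share their matching variables, so a
logistic model with stratum-specific intercepts conditions down to a
likelihood that depends on the data only through the covariate difference
$Z_i = X_{i1} - X_{i2}$ (case minus control):

$$\ell(\beta) = \sum_i \left[ Z_i\beta - \log(1 + e^{Z_i\beta}) \right].$$

This is the likelihood of a no-intercept logistic regression of an all-ones
response on $Z$, a fact the test suite exploits as an independent oracle.
The score is $Z^\top(1-\mu)$ and the Hessian $-Z^\top W Z$ with
$\mu_i = \operatorname{logit}^{-1}(Z_i\beta)$ and $W =
\operatorname{diag}\{\mu_i(1-\mu_i)\}$. `fit_clr()` maximizes it by
Newton–Raphson with step-halving.

The model deliberately contains genotype only. Matching covariates are
conditioned out by design; including them as covariates is near-collinear
with the stratification and destabilizes the fit, so the data structures do
not even store them. The machinery nonetheless accepts vector $\beta$ for
reuse beyond single-variant scans.

**Numerical choices.** Convergence is declared when the log-likelihood
changes by less than $10^{-10}$; at most 50 Newton iterations, each with up
to 20 step-halvings; `log1p`-based softplus evaluation avoids overflow. A
coefficient wandering past $|\beta| > 15$ on the dosage scale flags
quasi-separation (odds ratios beyond $e^{15}$ are meaningless here) and the
fit is reported non-converged rather than silently returned; such variants
are excluded from downstream FDR input. A dataset whose differences are all
zero is rejected as degenerate. Missing dosages are rejected, not imputed:
the upstream imputation pipeline is the right place to handle them, and
silent single-value imputation would bias $Z$ toward zero.

## Relevance p-values and the weight map

Each auxiliary cohort $k$ receives a *relevance p-value* $q_k$ from a
homogeneity likelihood-ratio test: fit the primary cohort, the auxiliary
cohort, and the pooled data, and refer
$2[\ell_0(\hat\beta_0) + \ell_k(\hat\beta_k) -
(\ell_0+\ell_k)(\hat\beta_{pool})]$ to $\chi^2_p$. Small $q_k$ means
detectable heterogeneity. The precise test behind $q$ is an open design
point — any statistic whose null is uniform under homogeneity works — so it
is isolated behind the single function `relevance_pvalue()` and can be
swapped without touching the optimizer.

Weights come from the two-knot map $\omega = 0$ for $q \le q_A$, linear
interpolation on $(q_A, q_B]$, and $1$ above $q_B$. The degenerate case
$q_A = q_B$ is resolved as the right-continuous step $\omega =
\mathbf{1}\{q > q_A\}$; any fixed convention works because the optimizer
sees it only as a limit.

## The LOOCV objective and the one-step approximation

The knots are chosen to minimize the leave-one-stratum-out cross-validated
negative log-likelihood of the primary cohort: each local stratum's
likelihood contribution evaluated at the estimate fitted without it.
Refitting $n_0$ times per candidate $(q_A, q_B)$ would be prohibitive, so
the left-out estimate is approximated by one Newton step from the full
weighted fit,

$$\hat\beta_0^{-j} \approx \hat\beta_0 - A^{-1} Z_j^\top (1-\mu_j)/(1-v_{jj}),
\qquad A = Z_0^\top W_0 Z_0 + \sum_k \omega_k Z_k^\top W_k Z_k,$$

with $v_{jj}$ the leverage (diagonal of $W_0^{1/2} Z_0 A^{-1} Z_0^\top
W_0^{1/2}$). By the Sherman–Morrison identity this equals a Newton step
taken with the exact leave-one-out Hessian, so the only error is the
truncation of the Newton iteration. That error scales like the leverage
times the squared step length, roughly $O(n_0^{-2})$ per stratum. In our
measurements the per-stratum relative error is typically 5–10% at
$n_0 = 20$, drops below 2% around $n_0 \approx 70$ (the smallest cohort
size the method is meant for), and below 0.5% by $n_0 = 150$. Attaching
auxiliary data shrinks $A^{-1}$ and with it both the leverages and the
error, so the approximation is most accurate exactly where it is used. An
exact-refit mode (`cv_objective(..., exact = TRUE)`) exists for testing and
systematically shows the one-step objective to be slightly optimistic
(under-corrected estimates stay closer to the full-data fit). At very small
$n_0$ the one-step approximation should not be trusted for per-stratum
quantities.

**Optimization.** The constraint $0 \le q_A \le q_B \le 1$ is enforced
smoothly by $q_A = a$, $q_B = a + (1-a)b$ with $(a, b) \in [0,1]^2$, and the
box is searched with L-BFGS-B using forward-difference gradients (step
$10^{-4}$; the objective is piecewise-smooth in the knots). Because many
knot pairs induce identical weight vectors when $K$ is small, the objective
is cached by weight vector and the optimizer is multi-started from the
$3\times3$ grid $\{0.05, 0.5, 0.95\}^2$ plus the all-weights-zero corner —
guaranteeing the selected objective never exceeds the local-only objective
among evaluated candidates, i.e. integration can always fall back to no
integration. Ties are broken by the first-found lowest objective.

**What the weights do in practice.** Under homogeneity $q$ is uniform on
$(0,1)$ — relevant cohorts do *not* produce $q$ near 1 — so the selected
weights for relevant auxiliaries are high on average but not uniformly near
1; the reliable signature is the contrast (mean selected $\omega \approx
0.8$ for shared-effect auxiliaries versus $\approx 0.05$ for conflicting
ones in our simulations), and that is what the test suite asserts.

## Prescreening and the per-variant pipeline

Only variants with MAF strictly above 5% (common variants, where effect
estimates are stable) and a local Wald p-value below 0.05 enter the
integration; others keep their local result with integration marked
skipped. The prescreen conserves computation for the most promising
variants and is applied identically to observed and permuted data.

## Permutation FDR

Adaptive weights make the integrated Wald p-values anti-conservative under
the null — they are computed as if the weights were fixed — and linkage
disequilibrium correlates tests across variants, so rank-based FDR
procedures (Benjamini–Hochberg) do not apply. Instead, case/control labels
are swapped within each stratum with probability 1/2 under **one**
genome-wide plan per cohort (a per-variant plan would destroy the LD
structure the permutation is meant to preserve), the entire pipeline —
prescreen, relevance tests, weight optimization — is re-run from scratch on
the permuted data, and the FDR at observed level $p_i$ is estimated by
$\min(m_i^\ast/m_i, 1)$, where $m_i$ and $m_i^\ast$ count observed and
permuted p-values $\le p_i$ (ties counted with $\le$ on both sets). The raw
estimates are made monotone by replacing each with the minimum over larger
thresholds. FDR is estimated within one primary cohort's result set at a
time, never pooled across cohorts.

A single permutation is cheap but noisy: under a global null it declares
false discoveries in a substantial fraction of replicates, while averaging
$m^\ast$ over ten plans (`estimate_fdr_multi()`) nearly eliminates them.
The package defaults to one iteration for cost parity with the
single-iteration procedure and exposes `B` for the more robust variant;
the acceptance script quantifies the gap.

## Post-processing

Significant variants are pruned by greedy LD clumping: sort by p-value,
keep the best, and drop any variant within 250 kb *and* with $r^2 > 0.5$
against an already-kept one (both conditions required; $r^2$ from in-sample
dosage correlation by default, or from a user-supplied reference panel).
TSS proximity uses signed distances (negative upstream of the gene on
either strand; nearest-TSS ties broken by annotation order) and a 2×2
within/beyond ±250 kb table compared between identified and randomly
sampled reference SNPs. The chi-squared test applies the Yates continuity
correction: on the reference table reconstructed from the printed
percentages the corrected statistic reproduces the published value
(11.365 versus 11.36; uncorrected Pearson gives 12.51), which identifies
the corrected statistic as the one actually used. Window comparisons use
strict `<` for "within".

## The synthetic-data generator

`simulate_cohorts()` emulates the features of imputed matched-cohort
genotype data that the pipeline is sensitive to: per-variant allele
frequencies spanning the common-variant cutoff, dosages as
$\mathrm{Binomial}(2, f)$ counts plus truncated Gaussian imputation noise
(sd 0.05 by default) clipped to $[0, 2]$ so values cluster near 0/1/2, a
14-cohort default size template spanning 71–1964 strata, and per-cohort
effects that may be shared, heterogeneous, or null. Case labels are drawn
directly from the conditional-likelihood kernel — member 1 is the case with
probability $e^{g_1\beta}/(e^{g_1\beta} + e^{g_2\beta})$ — rather than by
simulating a population and matching on covariates, because the pipeline
never sees matching covariates; this guarantees the fitted coefficient is
consistent for the generating value (verified by parameter recovery tests).

What the generator does **not** emulate: realistic LD blocks (variants are
independent; clumping tests build correlated pairs explicitly), population
stratification and admixture (handled by matching in the real design, out
of model here), genotyping batch effects, and missingness. Passing tests
therefore demonstrate the statistical machinery, not robustness to these
real-data complications. With several causal variants the kernel acts on
the summed linear predictor, so per-variant marginal fits are mildly
attenuated; single-causal-variant designs are used wherever consistency is
asserted.

## Problem sizes used by the tests and acceptance script

Simulation-based checks run at deliberately modest sizes chosen to keep the
full suite in the minutes range while leaving each property's signal-to-noise
comfortable: null calibration at 2000 variants × 500 strata; the power-gain
experiment at the template's "small local, five large auxiliaries" shape
(150 + 5×400 strata, shared log-OR 0.3, 100 replicates); the
anti-conservativeness panel at 1000 null variants; the single- versus
ten-iteration FDR comparison at 12 replicates of 150 variants. Seeds are
explicit everywhere; the acceptance script derives every stream from its
single `--seed`.

## Known limitations

* Only 1:1 matched strata; no m:n sets, no Firth or exact-conditional
  corrections for sparse data.
* The relevance test assumes both fits converge; an auxiliary cohort with
  separation at a variant is dropped (weight 0) for that variant.
* Single-iteration FDR control is liberal by construction; use `B = 10`
  when compute allows.
* The integrated p-value is never interpretable at face value; only its
  permutation-referenced FDR is.
* In-sample LD is a noisy stand-in for a reference panel at small sample
  sizes.
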