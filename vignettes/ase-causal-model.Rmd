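---
title: "The ASE structural causal model: methods, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ASE structural causal model: methods, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aseCausal)
```

## The model

The allostatic self-efficacy (ASE) account of fatigue and depression makes
directional claims: metacognition of allostatic control (`M`) drives fatigue
(`F`); fatigue and general self-efficacy (`S`) drive depression (`D`), with a
possible synergistic (interaction) component; age (`A`) and gender (`G`) are
demographic confounders feeding every questionnaire variable. Under
linearity and Gaussian noise this is the structural causal model

\[
\begin{aligned}
A &= N_A, \qquad G = N_G \ (\text{Bernoulli}),\\
M &= \theta_1 A + \theta_2 G + N_M,\\
F &= \theta_3 M + \theta_4 A + \theta_5 G + N_F,\\
S &= \theta_6 A + \theta_7 G + N_S,\\
D &= \theta_8 F + \theta_9 S + \theta_{10} FS + \theta_{11} A + \theta_{12} G + N_D,
\end{aligned}
\]

with jointly independent noises. Its graph `dag_j0()` carries the testable
content: d-separations in the graph must appear as conditional
independencies in any distribution the model generates (the Markov
condition), and backdoor-valid covariate sets license causal-effect
estimation by adjustment.

Two modelling conventions are worth stating explicitly:

* **The interaction is a term, not an edge.** $\theta_{10} F S$ lives in the
  structural equation for `D` only; the graph keeps just `F -> D` and
  `S -> D`. This keeps d-separation semantics standard while the analytic
  interaction effect
  $\partial^2 E[D \mid do(F, S)] / \partial f \, \partial s = \theta_{10}$
  remains available through `analytic_interaction_ace()`.
* **Noise draw order is fixed** (`A, G, M, S, F, D`) independently of which
  equations an intervention overrides, so a seed denotes the same underlying
  noise realisation across observational and interventional sampling. This
  couples `do()`-samples across arms, which is convenient for
  finite-difference contrasts.

## d-separation and graph revision

`is_d_separated()` decides separation by reachability on the moralised
ancestral subgraph; the test suite proves it equivalent to a brute-force
path-enumeration oracle on *every* DAG with up to four nodes, exhaustively.
`is_valid_adjustment_set()` implements the backdoor criterion: no descendant
of a treatment in the set, and separation of treatment and outcome in the
graph with the treatment's outgoing edges removed.

`reconcile_single_edge()` scores one-edge additions against observed test
decisions symmetrically: a d-separated statement predicts "not rejected", a
connected one predicts "rejected", and each disagreement counts one
mismatch. Candidates default to ordered pairs among the endogenous
questionnaire variables `{M, F, S, D}` — age and gender are exogenous
demographics whose edges are not up for revision — and the restriction can
be lifted. Ties are broken lexicographically by edge label, which is why the
`M -> S` revision ranks above the observationally equivalent `S -> M` on the
published decision pattern; the method cannot distinguish the two
orientations from the five tested statements, and the report should be read
accordingly.

When decisions from several test families disagree, `majority_decisions()`
requires a strict majority to call a rejection (two of three families). This
is how the mixed published verdict on `M ⊥ D | F,A,G,S` (one family rejects,
two do not) enters reconciliation as "not rejected".

## Conditional-independence tests

**MIcg.** For continuous `x, y` and mixed conditioning sets, rows are
stratified by the configuration of the discrete conditioners (a variable is
treated as discrete when it takes at most two observed values — gender
here). Within stratum $g$ the partial correlation $r_g$ of `x` and `y`
given the continuous conditioners yields the deviance contribution
$-N_g \log(1 - r_g^2)$, and the total is referred to
$\chi^2_{df}$ with $df$ = number of strata. The df rule deserves a note:
with two gender strata it implies $df = 2$, and the published PBIHB
statistic/p pairs satisfy the $\chi^2_2$ tail identity to three significant
figures — an internal-consistency check the test suite asserts. Each
stratum must hold at least (number of continuous conditioners + 3) rows;
smaller strata raise an error rather than silently degrading, and zero
residual variance (or $|r_g| = 1$) is a degenerate-input error because the
statistic would be infinite. Being an asymptotic test, MIcg runs slightly
hot at the study scale: its measured type-I error at $n = 60$ is a little
above the nominal 0.01 but stays within the calibration band the acceptance
test checks.

**GCM.** Residuals of `x ~ z` and `y ~ z` are formed by a configurable
learner — boosted regression trees by default (300 trees, depth 2, learning
rate 0.1, single-threaded, seeded) or exact least squares — and the
normalised mean of the residual products is referred to a standard normal,
two-sided. The population-style standard deviation
$\sqrt{\smash{\overline{R^2} - \bar R^2}}$ is used, matching the statistic's
definition. With a linear learner the statistic is exactly symmetric in
`(x, y)` and equivariant under affine rescaling (sign-flipping under
negative scale), both asserted in the tests against hand-computed
least-squares algebra.

**KCI.** Gaussian kernels with median-heuristic bandwidths on standardised
columns; the conditioning set is regressed out of the centred kernel
matrices by kernel ridge regression (penalty $10^{-3}$); the statistic is
$\mathrm{tr}(\tilde K_{x|z} \tilde K_{y|z})$ with a moment-matched gamma
null built from the eigenvalue products of the residualised kernels, so the
test is fully deterministic — no permutation. One deliberate departure from
the classical construction: *both* arguments are kernelised jointly with
`z`, not just the first. In calibration simulations this variant sat closer
to nominal level in the conditional case and it makes the statistic exactly
symmetric in `(x, y)`. The gamma-approximated conditional test remains
somewhat conservative, which costs power rather than validity. Kernel
matrices are $n \times n$, so the test is intended for cohort-sized data
(hundreds of rows), not the $n = 5000$ simulations — the pipeline lets you
select families per run for exactly this reason.

**Decision rule.** The five-statement structural family uses Bonferroni at
family level 0.05, i.e. 0.01 per test; the three-estimator effect families
use 0.05/3 ≈ 0.017, one-sided in the predicted (negative) direction.

## Effect estimators

**Regression adjustment** is ordinary least squares of outcome on treatment
plus the adjustment set; the one-sided p is the lower t-tail with the fit's
residual degrees of freedom (an exact identity the tests assert).

**Generalised propensity score.** The treatment is modelled as Gaussian
linear in the adjustment set; stabilised inverse-density weights
$w_i = \hat f(t_i) / \hat f(t_i \mid z_i)$ are truncated at their
0.1st/99.9th percentiles; the outcome is then regressed on the treatment by
weighted least squares with HC1 sandwich standard errors. The truncation
level was chosen by calibration: truncating at the conventional 1st/99th
percentiles visibly biased the estimate toward zero in simulations (the
discarded tails carry real balancing information in a well-specified
Gaussian design), while the milder cut only tames extreme density ratios
and keeps near-nominal interval coverage, as the acceptance test verifies
at $n = 5000$.

**DML.** Partially linear model with K-fold cross-fitting (default 5):
out-of-fold nuisance fits $\hat m(z) = E[t\mid z]$ and
$\hat\ell(z) = E[y \mid z]$ (boosted trees by default, linear optionally),
residual-on-residual slope, and the Neyman-orthogonal score's empirical
variance for the standard error with normal-approximation intervals. Those
intervals can undercover at small $n$ with few folds — the known
finite-sample price of nuisance estimation — so the coverage test runs at
$n = 2000$ with five folds, where coverage is nominal.

**The interaction effect.** For regression, $\theta_{10}$ is read off the
product term of `D ~ F + S + F:S + z`. For the propensity and DML routes the
product $T = FS$ is treated as the continuous treatment with `{F, S}`
joined to the controls. One consequence is specific to DML: since $FS$ is a
*deterministic function* of the controls, a flexible learner can reproduce
it almost exactly and collapse the treatment residual, so
`interaction_ace()` defaults the DML nuisance learner to linear — the
nonlinear part of $FS$ then supplies the identifying variation, which is
precisely the partially linear reading of the interaction equation.

Variables enter all estimators on their raw questionnaire scales; no
standardisation is applied anywhere, so coefficients are per-point effects
on instrument scales.

## The synthetic cohort generator

`default_pbihb_like_config()` emulates the PBIHB questionnaire table:
$N = 60$ healthy adults, age $\sim N(30, 8)$ (clipped to 18–65 whole years
in range mode), balanced Bernoulli gender, and the four questionnaire
scores generated by the structural equations with documented default
coefficients. The defaults were set once, by design considerations, and are
constants of the package rather than estimates:

| parameter | value | role |
|---|---|---|
| $\theta_3$ | $-0.48$ | metacognition -> fatigue, the anchored "true" effect |
| $\theta_{10}$ | $0$ | interaction off by default |
| $\theta_1, \theta_2$ | $0.06,\ 0.8$ | demographics -> M |
| $\theta_4, \theta_5$ | $0.06,\ 0.6$ | demographics -> F |
| $\theta_6, \theta_7$ | $0.15,\ 2.0$ | demographics -> S |
| $\theta_8, \theta_9$ | $2.0,\ -0.6$ | F, S -> D |
| $\theta_{11}, \theta_{12}$ | $-0.05,\ 1.5$ | demographics -> D |
| noise sd | $8,\ 1.5,\ 1.1,\ 4.5,\ 5$ | A, M, F, S, D |

Scale conventions: `M` is the MAIA subscale-3 + subscale-8 sum (0–10, half
points), `F` the FSS *mean* score (1–7, ninths), `S` the GSES total (10–40,
integers), `D` the CES-D total (0–60, integers). The FSS mean convention —
rather than the 9–63 total — was chosen because a per-point
metacognition-to-fatigue coefficient of about $-0.48$ is only dimensionally
sensible on that scale; the loader accepts either convention, with raw-scale
coefficients differing accordingly. In range mode values are clipped to the
instrument bounds *then* rounded to the instrument granularity, with ties
rounded half away from zero; clipping is mild at the default noise scales,
preserving ranks essentially perfectly (asserted in the tests).

Demographic effect sizes were targeted at per-equation questionnaire-typical
explanatory power (roughly $R^2 \in [0.1, 0.3]$). The depression equation is
the one deliberate exception: $\theta_9$ and the `D` noise scale were set by
an analytic power calculation so that, under the revised graph with an
`M -> S` coefficient of 0.5, the weakest implied dependence
(`M` vs `D` given `F, A, G`) is reliably detectable at the $n = 5000$
simulation scale; this pushes the `D` equation's $R^2$ somewhat above the
questionnaire-typical band. With the default noise scales the weakest
dependence has partial correlation near $-0.07$ — structure testing at the
study scale ($n = 60$) would have essentially no power against it, which is
why the structure-recovery simulations run at $n = 5000$.

What the generator does *not* emulate: skewed or floor-effected score
distributions (CES-D in healthy cohorts piles up near zero), item-level
measurement structure, missingness, selection into the study, or unmeasured
confounding. Passing tests on synthetic data therefore demonstrate that the
estimators and tests recover the truth *under the model's own assumptions* —
linearity, Gaussianity, causal sufficiency — not that those assumptions hold
for any real cohort.

## Problem sizes and determinism

The test suite and acceptance script use: exhaustive d-separation checks on
all DAGs up to 4 nodes; 200-replicate estimator-recovery studies at
$n = 5000$; 1000-replicate MIcg calibration at $n = 60$; 100-replicate
structure-recovery runs at $n = 5000$; and interventional contrasts at
$n = 10^5$. Every stochastic component (sampling, fold splits, boosted-tree
fits) is governed by an explicit seed argument, and identical seeds
reproduce every number bit-for-bit.

## Known limitations

* The five tested statements cannot orient the suggested `M -> S` edge;
  reconciliation reports the lexicographically first of the tied candidates.
* MIcg is asymptotic and mildly anticonservative at $n = 60$; the kernel
  test's gamma approximation is conservative in the conditional case.
* DML intervals undercover at small $n$; use more folds or larger samples
  for calibrated inference.
* The propensity estimator assumes a Gaussian linear treatment model; it is
  well specified for data generated by this SCM but not robust to treatment
  models that violate it.
* No latent-variable machinery: the revision search assumes causal
  sufficiency, and score-based structure search is out of scope by design.
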