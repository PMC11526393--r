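---
title: "Methods: score-based latent variable forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: score-based latent variable forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A questionnaire scale is scored with a latent variable model: a single
factor $\eta$ assumed to drive $m$ ordinal items. When the item
parameters differ between subgroups of the population (differential item
functioning), a single model fitted to everyone produces biased scores:
two people with the same trait level get systematically different scores
because of who they are, not what they are. The group structure behind
such parameter heterogeneity is rarely known in advance, may involve
interactions of several covariates, and cannot be enumerated by hand.

`lvforest` searches for *relevant subgroups* — regions of the covariate
space in which the measurement model both fits and has covariate-stable
parameters — with an ensemble of score-based model trees, and estimates
each person's score by averaging empirical Bayes modal (EBM) scores over
all relevant subgroups that contain them. People contained in no relevant
subgroup receive no score; their fraction is reported as the
*nonconvergence rate*.

## The measurement model

For ordinal item $i$ with $K_i$ ordered categories the graded response
model in its probit form is

$$P(Y_i \ge k \mid \eta) = \Phi(\lambda_i\,\eta - \kappa_{ik}),
  \qquad k = 2, \dots, K_i,$$

with strictly increasing thresholds $\kappa_{i1} < \dots <
\kappa_{i,K_i-1}$, discrimination (loading) $\lambda_i$, and $\eta \sim
N(\mu_\eta, \phi)$. Numeric items follow the linear factor model $Y_i =
\pi_i + \lambda_i \eta + \epsilon_i$. Identification fixes the reference
item's loading to 1 and its first threshold to 0; $\mu_\eta$ and $\phi$
are free. Fixing the first threshold rather than the latent mean keeps
subgroup-specific latent means on a common scale, which matters when
scores from different subgroups are pooled and ranked.

Equivalently, each ordinal item discretises a normal latent response
$Y_i^* = \lambda_i \eta + \epsilon_i$, $\epsilon_i \sim N(0,1)$. On the
standardised $Y^*$ scale the model implies thresholds
$(\kappa_{ik} - \lambda_i\mu_\eta)/\sqrt{\lambda_i^2\phi + 1}$ and
pairwise correlations $\ell_i \ell_j$ where $\ell_i =
\lambda_i\sqrt\phi / \sqrt{\lambda_i^2\phi+1}$ is the standardised
loading. Sample statistics live on that standardised scale; reported
parameters are on the conditional-probit metric above, so data simulated
from a parameter table are recovered on the generating scale.

## Two estimators, two jobs

**Normal-theory ML** (`fit_ml_cfa()`) treats every item as numeric and
maximises the multivariate-normal likelihood of the single-factor
covariance structure $\Sigma(\theta) = \phi\lambda\lambda' +
\mathrm{diag}(\psi)$. This deliberately misspecified fit exists for one
reason: its casewise score contributions $\psi(y_j, \hat\theta)$ (the
per-row gradients of the log density) feed the instability tests that
drive tree growth, and they are cheap at every node. Intercepts are
profiled (their MLE is the column mean); variances are optimised on the
log scale; residual variances hitting the $10^{-6}$ lower bound mark a
Heywood case and disqualify the node.

**Limited-information WLS** (`fit_wls()`) is the estimator whose
parameters are actually used for scoring. Stage one
(`estimate_polychoric()`) computes probit thresholds from cumulative
proportions (empty categories are collapsed into their lower neighbour),
two-step polychoric / polyserial / Pearson correlations, and the
asymptotic covariance $\Gamma$ of the stacked statistics from per-case
influence functions, including the propagation of threshold-estimation
noise into the two-step correlations. Stage two minimises the diagonally
weighted least squares discrepancy. Under diagonal weights every free
threshold fits its own statistic exactly and the fixed reference
threshold pins $\mu_\eta$ given the loadings, so the numeric search runs
over the $m$ standardised loadings only (parameterised through `tanh` to
stay in $(-1,1)$); this is algebraically identical to DWLS over the full
free parameter vector but far better conditioned at node sizes of a few
hundred.

**Fit statistic.** The reported chi-square is the plain DWLS discrepancy
$T = n \hat F_D$, and RMSEA is $\sqrt{\max(0, (T - \mathrm{df}) /
(\mathrm{df}\, n))}$. That is the first-line statistic conventional
ordinal-CFA software prints, and the scale on which the RMSEA cutoffs
used in this literature (0.05 lenient, 0.03 strict) are calibrated.
During development we also evaluated the full-weight discrepancy at the
DWLS solution, its minimised version, and trace-corrected (mean-scaled
and scaled-shifted) statistics on the built-in heterogeneous design;
only the plain statistic places the pooled misfit of the heterogeneous
design at RMSEA $\approx 0.09$ with per-subgroup fits in 0.00–0.04 —
the calibration the retention cutoffs in this literature assume; the
trace-corrected variants sit noticeably higher on this design. The mean-scaled statistic is kept in the fit object
(`T_scaled`) for calibrated chi-square testing. For 5 ordinal items with
7 categories the statistic has $40 - 35 = 5$ degrees of freedom.

## Instability tests and splitting

With the scores ordered by a covariate $Z$, the empirical fluctuation
process is
$$B(t_j) = \hat I^{-1/2} n^{-1/2} \sum_{l \le j} \psi_{(l)},$$
with $\hat I$ the outer-product-of-gradients information estimate
(pseudo-inverse square root if rank-deficient). Under stability $B$
behaves like a $k$-dimensional Brownian bridge. Test families:

* numeric covariates — supLM: $\max_t \|B(t)\|^2 / (t(1-t))$ over the
  trimmed window $t \in [0.1, 0.9]$;
* ordinal covariates — the same functional restricted to observed level
  boundaries;
* unordered categorical covariates — the LM statistic
  $\sum_c (n/n_c)\,\|\Delta B_c\|^2$ with its asymptotic
  $\chi^2_{k(C-1)}$ null.

Critical values for the sup-type statistics are simulated from the
corresponding Brownian-bridge functional. The numeric null is evaluated
on a canonical 300-point grid in $[0.1, 0.9]$ and cached per parameter
count $k$; the observed statistic is maximised over the data positions
mapped onto the same grid, so statistic and null share one functional.
Ordinal nulls are simulated at the observed boundary fractions (rounded
to $1/100$ for caching). All null draws use a dedicated fixed RNG stream
that is saved-and-restored around the simulation, which makes p-values
reproducible, independent of call order, and non-disruptive to the
caller's RNG — a requirement of the forest's determinism contract.
Tied covariate values stay in one block: the process is evaluated only at
the last row of each tie group. Ties among p-values at selection go to
the first covariate in declared order.

Split points maximise the same score statistic over all admissible cuts
(both children at least `min_size` rows). Categorical covariates are
searched exhaustively over binary level partitions up to 10 levels;
beyond that, levels are ordered by their mean first score coordinate and
scanned like an ordinal covariate.

A node stops when no sampled covariate is Bonferroni-significant at
level $\alpha/\text{mtry}$, when no admissible cut exists, or when the
ML fit fails or is a Heywood case. There is no depth limit.

## The forest

Each tree is grown on a random subsample drawn *without replacement*
(`sample_fraction`, default 0.9), with `mtry` (default 2) candidate
covariates re-drawn at every node. Subsampling rather than a classic
with-replacement bootstrap is a deliberate choice: duplicated rows are
tied on every covariate and carry identical score rows, which makes the
ordered cumulative score process locally over-dispersed relative to its
Brownian-bridge null — on homogeneous data the tests then
reject far above their nominal level and every tree splits on noise. With distinct
rows the tests hold their nominal size. The default fraction 0.9 keeps
enough rows per tree that a tree can reach the effective depth a size-n
bootstrap tree would (whose minimum node size counts duplicated rows);
at 0.632 the per-tree rate of finding a qualifying subgroup on the
built-in heterogeneous design drops well below what a full-size
bootstrap ensemble achieves, while at 0.9 it matches it.

Every terminal node (including an unsplit root) is then validated
against the *full* sample: its rule is re-applied, the node is re-fitted
with WLS, and instability is re-assessed against **all** partitioning
covariates, not only those sampled during growth. A node becomes a
relevant subgroup only if the rule matches at least `min_size` rows, the
WLS fit converges with RMSEA at or below `rmsea_cutoff`, and every
re-assessment p-value exceeds $\alpha/R$. Qualifying nodes score all
matching rows by EBM; a person's final score is the unweighted mean over
all relevant subgroups containing them. Because validation operates on
full-sample row sets, identical row sets discovered by different trees
are validated once (memoised), which also makes the homogeneous-data
ensemble collapse exactly onto the naive single-model scores.

## EBM scoring

The EBM score of a response pattern is the maximiser over $\eta$ of the
log posterior: normal prior $N(\mu_\eta, \phi)$ plus the graded-response
and/or Gaussian log-likelihood. Probit category probabilities are
log-concave in $\eta$, so the posterior is strictly concave and the mode
is the unique root of the posterior score function; it is found by
vectorised bisection on $[\mu_\eta - 8\sqrt\phi,\ \mu_\eta + 8\sqrt\phi]$
to tolerance $10^{-8}$, one pass for all unique patterns. Probabilities
are floored at $10^{-300}$ and probit arguments clamped at $\pm 12$ for
the derivative evaluation; a mode at the interval boundary is flagged
unavailable. Categories collapsed during estimation are merged the same
way before scoring.

## The built-in study designs

`simulate_sim1()` regenerates the heterogeneous benchmark: 10
model-compliant subgroups of 500 rows, 5 items with 7 categories,
thresholds and discriminations from the built-in parameter tables
(`sim1_parameters()`), subgroup-specific latent means (0.77–1.76) and
variances (0.54–1.15), and 30 partitioning covariates. Subgroup $h$ is
clamped to $\{num_h \le 50\} \cap \{cat_h \in \{1,3,5\}\} \cap
\{ord_h \ge 4\}$; rows of other subgroups that fall into the clamped
$num/cat$ region get $ord_h \le 3$, so the three-condition rule
identifies $R_h$ exactly, yet no single tree can isolate all ten.
`simulate_sim2()` is the smaller 3-subgroup, 8-item/5-category variant
with 6 covariates and a two-condition rule; its generating parameters
are drawn by a declared sampler (loadings U(0.4, 1.6) with the reference
fixed at 1; thresholds sorted N(0, sd 1.5) with the first item's first
threshold shifted to 0; Var($\eta$) U(0.5, 1.5); E($\eta$) U(-0.5, 1.5))
— these are defaults of this package, not reconstructions of anything.
Unclamped covariates are uniform on their printed ranges (num 1..200;
ord/cat 1..5). `simulate_homogeneous()` generates the null design: one
parameter set, covariates independent of everything.

What the generator does *not* emulate: missing data, acquiescence or
other response styles, cluster/panel dependence, covariates correlated
with the trait inside a subgroup, and multidimensional traits. Passing
tests therefore certify the algorithmic pipeline under clean
measurement-model data, not robustness to real survey pathologies.

## Defaults and problem sizes

| parameter | default | why |
|---|---|---|
| `min_size` | 200 | smallest node for which the 35-parameter WLS fit and the $k=15$-dimensional OPG information are usable |
| `mtry` | 2 | benchmark ensemble setting; redrawn at every node |
| `alpha` | 0.05 | family-wise level, Bonferroni-corrected per node and per validation |
| `rmsea_cutoff` | 0.05 | lenient simulation profile; 0.03 is the strict profile for applications |
| `n_sim` | 1999 | null-simulation replicates; p-value floor 1/2000 well below $\alpha/R$ thresholds in use |
| `sample_fraction` | 0.9 | see above |
| `n_trees` | 100 | enough for several qualifying subgroups at the low per-tree discovery rate of overlapping designs; full-scale runs use many thousands |

The test suite and the acceptance script scale the full-size experiment
down so a complete run stays in the tens of minutes on one core: the
ordering comparison uses 3 regenerated data sets with 30–60-tree
ensembles instead of 10,000 trees; the reduced-forest accuracy check uses
120 trees and is evaluated on the covered subsample; the size simulation
uses 1,000 replicates of a 3-item Gaussian model at $n = 500$; parameter
recovery uses one draw at $n = 50{,}000$. These sizes are the package's
own choices and are fixed in the code.

## Known limitations

* One latent factor. The data structures would extend to several factors,
  but nothing in the estimation or scoring path handles vector traits.
* The single-tree comparator scores every terminal node whose WLS fit
  converges, with no fit screening; on heavily mixed nodes those scores
  are poor, and its pooled accuracy here sits a few hundredths below what
  implementations whose node fits fail on the worst mixtures report
  (failures there restrict scoring to a better-fitting subset).
* The reported chi-square is the unscaled DWLS discrepancy; use
  `T_scaled` for calibrated hypothesis tests.
* With few trees the forest may find no relevant subgroup; coverage, not
  accuracy, is the price of small ensembles (accuracy on the covered
  subsample is stable across ensemble sizes).
* Reference-item pathologies (first category empty in a node) shift the
  latent-mean anchor; such fits are flagged (`anchor_shifted`) and their
  node scores are comparable only internally.
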