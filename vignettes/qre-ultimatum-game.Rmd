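---
title: "Structural estimation of fairness from ultimatum-game play"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural estimation of fairness from ultimatum-game play}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qreug)
```

## The model

In the ultimatum game a proposer offers a split of fixed stakes and a
responder accepts (the split is implemented) or rejects (both get
nothing). In the game studied here the stakes are divisible into eleven
offers $s \in \{0, 0.1, \dots, 1\}$, expressed as fractions of the stakes,
which are normalized to a surplus of 1 inside all utilities.

Players value their own payoff but dislike unequal splits, symmetrically
in either direction (an ERC-type motivation function): the utility of
receiving payoff share $\sigma$ of surplus $c = 1$ is

$$u(\sigma) = \sigma - \frac{b}{2}\left(\sigma - \tfrac12\right)^2,$$

where $b \ge 0$ is the *fairness* (inequality-aversion) coefficient,
assumed common to a population. A rejected play yields zero surplus; the
payoff share of a zero surplus is defined as $\tfrac12$, so the loss term
vanishes and the rejection utility is exactly 0.

Choices are noisy best responses: each decision is logit in its expected
utility with precision $\lambda \ge 0$ (*rationality*). $\lambda = 0$
gives uniform random play, $\lambda \to \infty$ recovers best replies and
hence, with $b = 0$, the subgame-perfect prediction of minimal offers and
universal acceptance. Because the responder moves after observing the
offer, the appropriate equilibrium concept is the *agent* quantal response
equilibrium: each information set acts as an independent logit agent. The
responder accepts offer $s$ with probability
$p_R(s) = 1/(1 + e^{-\lambda u(s)})$, independently of the proposer's
mixed strategy, and the proposer's offer probabilities are a softmax with
precision $\lambda$ over the expected utilities
$p_R(s)\,u(1 - s)$. The equilibrium is therefore computed in a single
backward pass, and `ug_fixed_point_error()` verifies that re-applying
both response maps leaves it unchanged (at most 1e-12 in practice; the
computation is exact up to floating-point evaluation of the two maps).

```{r equilibrium}
eq <- ug_equilibrium(b = 13.97, lam = 6.83)
round(as.data.frame(eq)[, 1:3], 2)
```

## Estimation

For observations $(s_k, d_k)$ — offer and acceptance dummy — the
log-likelihood at $(b, \lambda)$ sums
$\ln p_P(s_k) + d_k \ln p_R(s_k) + (1 - d_k)\ln(1 - p_R(s_k))$ over
pairs. `ug_fit()` maximizes it with a bounded quasi-Newton search
(`optim`, L-BFGS-B) from a multistart grid ($b \in \{1, 5, 10, 25, 50\}$,
$\lambda \in \{2, 5, 10, 50\}$, the Cartesian product per free
parameter), with $b \in [0, 500]$ and $\lambda \in (0, 100]$. The bounds
deserve comment:

* **$b \ge 0$.** Negative inequality aversion (a taste for unequal
  splits) is outside the model's intended interpretation; the lower bound
  plus a bound-hit flag keeps the pure self-interest restriction
  ($b = 0$, available as `b_fixed_zero` in `ug_model_spec()`) an explicit
  boundary case rather than an accident of the optimizer.
* **$\lambda \le 100$.** On near-degenerate samples (a handful of pairs,
  no rejections) the likelihood is almost flat in $\lambda$ beyond
  moderate values, and the estimate runs away; the cap with a bound-hit
  flag makes that visible. The 9-pair Mutanda resettled group exercises
  this: under the shared-fairness restriction its rationality estimate
  sits exactly at 100 and is flagged.
* Convergence uses `factr = 1e4` (about 1e-12 relative on the objective);
  estimates within 1e-3 of a bound are flagged. Probabilities are floored
  at 1e-300 inside logarithms so optimizer excursions where a rejected
  offer has predicted acceptance near 1 stay finite, and the proposer
  softmax uses log-sum-exp with max subtraction so the objective is
  finite up to $\lambda = 100$ across the whole $b$ range.

Multi-group restrictions are expressed as partitions: `ug_model_spec()`
lets any subset of groups share one $b$ and/or one $\lambda$, and
`ug_fit_spec()` maximizes the joint likelihood under those constraints,
reporting per-group components that sum to the joint value. Nested
specifications are compared with `ug_lr_test()` (twice the log-likelihood
difference against a chi-squared with the difference in free-parameter
counts; tiny negative statistics from optimizer tolerance are clipped at
zero, anything below $-10^{-6}$ is treated as an optimizer failure).

```{r fits}
groups <- list(resettled = ug_fixture("all_resettled"),
               traditional = ug_fixture("all_traditional"))
shared <- ug_fit_spec(ug_model_spec(groups, "all", "all"))
free <- ug_fit_spec(ug_model_spec(groups))
ug_lr_test(shared, free)
```

Standard errors come from a nonparametric bootstrap
(`ug_bootstrap()`): proposer–responder pairs are resampled with
replacement within each group — the pair is the independent observation
in the likelihood, and nothing smaller (offers and responses are linked)
or larger (pairs were anonymous, one-shot matches) is — and the model is
refit on each resample. The reported SE is the standard deviation of the
bootstrap estimates and the p-value uses the normal approximation
$2\Phi(-|\hat\theta|/\mathrm{SE})$; a percentile construction would be
equally defensible at these sample sizes, and the normal form was chosen
for being the construction the SE itself already implies. Refits start
from the full-data optimum plus one central fallback start
$(b, \lambda) = (5, 5)$ rather than the full multistart grid — a
1000-replicate bootstrap repeats the fit a thousand times and the
full-data grid search already certifies the relevant basin (see the
grid-oracle check below). Starts are pulled 0.5% inside the bounds
because a line search started exactly on a boundary optimum stalls.
Non-converged replicates are dropped and counted; more than 10% failures
aborts with an error rather than quietly reporting an SE from a biased
subset.

## Data reconstruction

The field data — 117 proposer–responder pairs across three Zimbabwean
resettlement areas and their neighboring traditional villages — are
published only as per-offer counts with per-offer rejection rates. Those
tables ship with the package, and `ug_fixture()` expands them into
individual observations: a row with $n$ offers and rejection rate $r$
becomes $\mathrm{round}(rn)$ rejections (half-up) and the rest
acceptances. Every product $rn$ in the shipped tables is within 0.04 of
an integer, so the reconstruction is exact; the expander nevertheless
refuses any row where $rn$ is farther than 0.25 from an integer, and
every reconstructed group is validated against the published group size
and overall rejection rate before it is returned. Two source quirks are
handled explicitly: the summary table swaps the names of the 64-pair and
34-pair areas relative to the detail tables (the fixtures follow the
detail tables), and the 64-pair Mupfurudzi area is only published merged
across resettlement status, so no per-status Mupfurudzi fixtures exist.

```{r fixtures}
ug_descriptives(ug_fixture("pooled_all"))
```

Model fit against observed play is summarized by a count-weighted Pearson
correlation (`ug_weighted_cor()`) between observed frequencies (or
rejection rates) and equilibrium predictions, restricted to offers
actually observed — unobserved offers carry no information about fit and
would otherwise dominate the responder comparison through the model's
confident predictions at never-made extreme offers.

## The synthetic-data generator

`ug_simulate()` draws play from the model itself: for each pair an offer
from the equilibrium offer distribution, then an acceptance from the
responder's acceptance probability at that offer, consuming one uniform
stream pair by pair so both margins are reproducible under one seed. It
emulates exactly what the structural model assumes — independent,
identically distributed one-shot pairs with population-level parameters.
It deliberately does *not* emulate individual heterogeneity in $b$,
village-level clustering, or any learning across rounds (the experiment
was anonymous and one-shot), so recovery results validate the estimator
under the model's own assumptions, not robustness to their violation.

`ug_recovery()` wraps the simulate-and-refit loop and reports bias and
RMSE per parameter, plus coverage of $\pm 2\,\mathrm{SE}$ bootstrap
intervals on a subsample of replicates. The validation settings used in
the test suite — truth $(b, \lambda) = (10, 7)$, near the pooled
estimates; 100 replicates at 100 and 1000 pairs — give estimates whose
bias is small relative to the bootstrap SEs at the field sample sizes and
whose RMSE falls with $n$, which is what the tests assert.

## Numerical checks and known limitations

The test suite cross-checks the optimizer against a brute-force oracle: a
200 × 200 grid over $b \in [0, 50]$, $\lambda \in (0, 20]$ must never
beat the reported optimum by more than 0.01 nats on the pooled data. Tie-
breaking in diagnostics of the $\lambda \to \infty$ limit takes the
lowest-index grid offer.

Limitations worth keeping in mind:

* Preferences are population-level; decision error is the only channel
  for individual heterogeneity, and proposers and responders are assumed
  to share one preference pair.
* Small groups with little outcome variation (two distinct outcomes, no
  rejections) leave $(b, \lambda)$ nearly unidentified along a ridge;
  the fitter flags single-offer all-accepted groups as non-identifiable
  and flags bound-hitting estimates, but estimates from such groups
  should be read as ridge locations, not point identifications.
* The asymmetric (disadvantage-only) inequality-aversion variant is out
  of scope, as are games other than the 11-offer ultimatum game and
  heterogeneous-agent extensions.

## The analysis scripts

The numbered scripts under `analysis/` run the full pipeline on the
embedded data and write CSV tables under `results/`: descriptives
(`01`), maximum-likelihood estimates with bootstrap SEs (`02`),
likelihood-ratio tests per area (`03`), observed-vs-predicted tables
with weighted correlations (`04`), and the parameter-recovery experiment
(`05`). They are thin drivers over the exported functions — every
computation they perform is available, and tested, through the package
API — so they double as the command-line interface of the package.
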