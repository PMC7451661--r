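---
title: "Adaptive interval designs for phase I dose finding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive interval designs for phase I dose finding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aboin)
```

## The decision model

A phase I dose-finding trial treats successive cohorts at one of $J$
pre-specified doses and must decide, after each cohort, whether to
escalate, stay, or de-escalate. Interval designs make this decision by
comparing the observed dose-limiting-toxicity (DLT) rate
$\hat p_j = y_j / n_j$ at the current dose against two boundaries
$\lambda_1 < \lambda_2$ around the target rate $\phi$: escalate when
$\hat p_j \le \lambda_1$, de-escalate when $\hat p_j \ge \lambda_2$,
otherwise stay.

The boundaries come from three point hypotheses about the current dose's
true DLT rate $p_j$:

* $H_0$: $p_j = \phi$ (the dose is the MTD),
* $H_1$: $p_j = \phi_1 < \phi$ (sub-therapeutic; escalation is correct),
* $H_2$: $p_j = \phi_2 > \phi$ (over-toxic; de-escalation is correct).

Choosing the action whose hypothesis has the highest posterior probability
minimizes the probability of an incorrect decision. With equal prior
weights this yields the closed forms

$$\lambda_1 = \frac{\log\frac{1-\phi_1}{1-\phi}}
  {\log\frac{\phi(1-\phi_1)}{\phi_1(1-\phi)}}, \qquad
  \lambda_2 = \frac{\log\frac{1-\phi}{1-\phi_2}}
  {\log\frac{\phi_2(1-\phi)}{\phi(1-\phi_2)}},$$

implemented in `boin_boundaries()`. The conventional choices
$\phi_1 = 0.6\,\phi$ and $\phi_2 = 1.4\,\phi$ are the defaults. It always
holds that $\lambda_1 < \phi < \lambda_2$, both boundaries tend to $\phi$
as $\phi_1, \phi_2 \to \phi$, and $\lambda_1$ is increasing in $\phi_1$ —
properties the test suite checks numerically on a grid.

## Historical information as hypothesis priors

When relevant external data exist (the canonical case is a pediatric trial
following an adult trial of the same agent), they can be expressed as
per-dose prior probabilities $\pi_{0j}, \pi_{1j}, \pi_{2j}$ of the three
hypotheses. Unequal weights simply add the log prior odds, scaled by
$1/n_j$, to the numerators of the same derivation
(`prior_boin_boundaries()`):

$$\lambda_{1j} \;\text{gains}\; n_j^{-1}\log(\pi_{1j}/\pi_{0j}), \qquad
  \lambda_{2j} \;\text{gains}\; n_j^{-1}\log(\pi_{0j}/\pi_{2j}).$$

This is the exact Bayes decision boundary: escalate when
$\pi_{1j} L(\phi_1) > \pi_{0j} L(\phi)$, where $L$ is the binomial
likelihood. A prior favouring "this dose is still below the MTD" eases
escalation; one favouring "this dose is the MTD" resists de-escalation.
The influence decays like $1/n_j$, so data dominate eventually. For the
de-escalation boundary we use the odds $\pi_{0j}/\pi_{2j}$ throughout —
the form the symmetric derivation produces — and deliberately provide no
alternative parameterization.

Note that the prior tilt is strong at trial-relevant sample sizes: with
$n_j = 3$ and a 70%/15% split between $H_0$ and $H_1$, the escalation
boundary can drop below zero (escalation becomes impossible until more
patients accrue). This is the intended Bayes behaviour of the formula, not
a defect; it is the reason the package recommends prior-informed variants
only when the historical information is genuinely strong, and it makes
these designs markedly stickier at the prior's presumed MTD than their
no-prior counterparts.

### Eliciting the prior table

`elicit_prior_table()` expands an investigator's MTD-confidence vector
$(\pi_{0,1}, \dots, \pi_{0,J})$ into the full $3 \times J$ table:

1. the under/over-dose odds $\pi_{1j}/\pi_{2j}$ are anchored at 9 at the
   lowest dose, $1/9$ at the highest, and 1 at the best MTD guess (an
   extreme guess overrides its extreme anchor with 1);
2. $\pi_{1j} = (1 - \pi_{0j})\cdot\text{odds}/(1+\text{odds})$ at the
   anchors, with the under-dose row filled between anchors by linear
   interpolation in the dose index;
3. the over-dose row is the residual $1 - \pi_{0j} - \pi_{1j}$.

Two conventions deserve comment. First, the default anchors are
nine-to-one odds — a 90%/10% split of the non-MTD probability mass at the
extreme doses — which reproduces the published worked table for this
algorithm exactly (e.g. $\pi_{1,1} = 0.9 \times 0.8 = 0.72$ for
$\pi_{0,1} = 0.2$); ten-to-one odds, sometimes quoted for the same
construction, would instead give $0.727$. Both anchors are exposed as
arguments. Second, interior cells use standard index-linear interpolation
between the anchor doses; with a single intermediate dose per side this is
the plain average of the two anchors, and unlike a literal "divide by the
dose index" reading it stays monotone for any number of intermediate
doses.

The elicitation fails loudly (rather than clipping) when the confidence
vector leaves no room for a positive over-dose probability, because
clipping would silently break column normalization. Validation
(`validate_prior_table()`) enforces column sums of 1, entries strictly
inside $(0,1)$, a non-increasing under-dose row and a non-decreasing
over-dose row. Mirror symmetry — reversing the confidence vector and
taking reciprocal anchors — holds exactly at the anchor doses; the
interpolated interior cells are mirror-symmetric only when the confidence
vector itself is palindromic with linear flanks, because the over-dose row
is a residual of a linear row rather than linear itself.

## Adaptive shrinking boundaries

Fixed boundaries cannot use the fact that late in a trial the estimate at
a well-explored dose is much more precise than after one cohort. The
adaptive variant re-defines the hypothesis rates as functions of the
per-dose sample size,

$$\phi_1(n_j) = \phi - \Delta_1\, n_j^{-g_1}, \qquad
  \phi_2(n_j) = \phi + \Delta_2\, n_j^{-g_2},$$

and evaluates the same closed forms at these shrinking rates
(`aboin_boundaries()`; `aboin_prior_boundaries()` adds the prior tilt).
The decision interval therefore contracts toward $\phi$ as evidence
accrues. Defaults:

* $\Delta_1 = \Delta_2 = 0.4\,\phi$, so that at $n_j = 1$ the adaptive
  pair *equals* the fixed pair — the adaptive design is a strict
  generalization;
* $g_1 = 0.4$, $g_2 = 0.9$: the upper boundary shrinks faster, tightening
  control of over-dosing before control of under-dosing (unequal
  exponents are the tool for asymmetric safety preferences);
* a lead-in of $N_1 = 6$ patients (total accrual, not per dose) during
  which the fixed pair is used, giving the shrinkage a stable footing;
  with cohorts of three this means the first decision is always made with
  fixed boundaries. During the lead-in the *plain* fixed pair is used
  even for the prior-informed variant.

The shrinkage is monotone ($\lambda_1$ non-decreasing, $\lambda_2$
non-increasing in $n_j$) and both boundaries converge to $\phi$, which
preserves long-term-memory coherence (the design never escalates from a
dose whose observed rate exceeds $\phi$, nor de-escalates from one below
$\phi$) and yields consistency: once the interval is narrower than the gap
to the neighbouring doses' rates, allocation concentrates at the MTD. In
a finite trial of 30 patients the fixed and adaptive variants behave very
similarly; the advantage appears at large sample sizes, where a fixed
interval that happens to contain a neighbouring dose's true rate is an
absorbing trap that the shrinking interval escapes. With a non-uniform
prior the upper boundary's prior tilt decays like $n_j^{g_2-1}$ relative
to its shrinkage term, so convergence to $\phi$, while monotone, is slow.

## Trial conduct

`run_trial()` (and the interactive helpers `decide()`,
`effective_boundaries()`, `safety_eliminate()`, `select_mtd()`) implement
the standard conduct of interval designs:

* cohorts of 3 up to 30 patients by default, starting at the lowest dose;
* edge rules: indicated escalation at the top dose, or de-escalation at
  the bottom dose, become "stay"; escalation never targets an eliminated
  dose;
* safety elimination: a dose with $n_j \ge 3$ and
  $\Pr(p_j > \phi \mid y_j, n_j) > 0.95$ under a Beta(1, 1) prior is
  removed along with all higher doses; eliminating the lowest dose
  terminates the trial with no MTD. These constants (flat prior, 0.95
  cutoff, minimum of three patients) are the established defaults of
  interval-design software and are exposed via `design_spec()`;
* final selection: isotonic regression (weighted pool-adjacent-violators)
  of the per-dose posterior-mean estimates $(y_j+0.05)/(n_j+0.1)$ with
  inverse-posterior-variance weights over treated, non-eliminated doses;
  the dose whose monotone estimate is closest to $\phi$ is selected, ties
  breaking toward the higher dose when the tied estimates are below
  $\phi$ and toward the lower dose otherwise. The light Beta(0.05, 0.05)
  shrinkage and variance weighting follow the reference isotonic selector
  for this design family; we use it in preference to unweighted raw-rate
  pooling so that packaged simulations are comparable with published
  operating characteristics.

The observed rate entering each decision is cumulative at the current
dose only. Boundaries are recomputed at every decision as pure functions
of the state, which keeps the simulator exactly reproducible.

## Simulating operating characteristics

`run_oc()` simulates many independent trials on a true dose-toxicity
scenario and reports the four standard metrics: percentage of correct MTD
selection (PCS), mean patients at the true MTD, and the risks of over-
and underdosing — the share of trials in which strictly more than 60% of
treated patients were above, respectively below, the true MTD. The 60%
threshold is the convention of the packaged study and is configurable
(`f_over`, `f_under`); 80% is the other threshold seen in this
literature. Early-terminated trials count as incorrect selections and
contribute their realized sample size to the allocation denominators.

Seeding is hierarchical: each scenario-by-design cell derives a 31-bit
seed from the master seed and the two labels, and each replicate seeds
its own stream from the cell seed and the replicate index. Replicates are
therefore order-independent, and adding a cell never perturbs another.

`builtin_fixtures()` packages the complete study configuration: ten
five-dose scenarios per target (20% and 30%), in each of which the true
MTD's rate equals the target exactly; the confidence vector
$(0.2, 0.45, 0.7, 0.45, 0.2)$ with its guess at dose 3; and the six
default design variants. `run_grid()` plus `oc_pivot()` reproduce the
conventional scenario-by-design report with an unweighted `Average`
column.

### What the simulations do and do not show

The generator draws each cohort's DLT count as independent
Bernoulli outcomes at the dose's true rate. It does not model accrual
time, late-onset or cumulative toxicity, patient heterogeneity, or
misclassified DLTs, so passing operating characteristics say nothing
about those features of real trials; they validate the decision logic,
the elimination rule and the selector under the idealized binomial model
that this design family (and its published evaluations) assume.

Problem sizes were chosen to keep the full suite fast while leaving
Monte-Carlo error well inside the assertion tolerances: boundary
properties are checked exhaustively on grids ($\phi$ from 0.1 to 0.4,
$n_j$ to 100), coherence on 1,000 logged trials, study reproduction on
2,000 replicates per cell (PCS standard error about 1 percentage point,
assertions at 3), and the large-sample comparison on 500 replicates of
3,000-patient trials, where the adaptive design's PCS advantage is large
enough to be unambiguous at that replication.

## Known limitations

* The prior-informed variants assume the three-point hypothesis
  structure; richer priors (full toxicity curves, between-trial
  heterogeneity) are out of scope.
* The elicitation requires a unique designated maximum in the confidence
  vector; multi-modal vectors are rejected rather than guessed at.
* No accrual-time or late-onset-toxicity modelling, no cohort-size
  adaptation, and no comparator designs (model-based reassessment, 3+3)
  are included.
* With strong priors and small $n_j$ the prior-informed boundaries can
  leave the $(0,1)$ interval or cross; crossing triggers a validation
  warning, and values outside $[0,1]$ simply mean the corresponding
  action cannot be triggered at that sample size.
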