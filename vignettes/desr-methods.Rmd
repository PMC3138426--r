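---
title: "Dual endpoint stopping rules: model, computation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual endpoint stopping rules: model, computation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(desr)
```

## The outcome model

Each patient in a single-arm phase II trial is classified into one of three
mutually exclusive outcomes: tumour response (probability $p_r$), early
progressive disease — progression at the first post-treatment assessment —
(probability $p_p$), or neither (stable disease / later progression,
probability $1 - p_r - p_p$). Patients are independent and identically
distributed, so the stage counts follow a trinomial distribution, and the
stage II counts are independent of stage I given the rates. This is the
entire stochastic model: there is no time-to-event structure, no response
subcategories, and no patient-level covariates.

Hypotheses are placed on both endpoints. The drug is uninteresting when
$r \le r_{nul}$ **and** $epd \ge epd_{nul}$; it is of interest when
$r \ge r_{alt}$ **or** $epd \le epd_{alt}$ — activity on a single endpoint
suffices. The constructor `dual_hypotheses()` enforces $r_{nul} < r_{alt}$,
$epd_{alt} < epd_{nul}$, and $r_{alt} + epd_{nul} \le 1$ so that the null
configuration is a valid trinomial.

## The rule

A DESR design is four integer bounds on top of the stage sizes $(n_1, n_2)$:

* stop at stage I (accept the null) iff responses $\le s_r$ **and**
  progressions $\ge s_p$ — a *joint* futility signal; a low response count
  alone does not stop the trial if few patients progressed early;
* otherwise accrue $n_2$ more patients and reject the null iff cumulative
  responses $\ge a_r$ **or** cumulative progressions $\le a_p$.

All bounds are inclusive and are applied as **absolute counts**. When a
historical trial under-accrued (e.g. 25 patients against a planned 30), the
bounds are not rescaled. This convention is the only reading that reproduces
every printed verdict of the two historical cohorts shipped with the package,
including an under-accrued stage I of 14 patients and a final rejection at
4 responses of 29 rather than 30. A trial that continued past stage I but has
no stage II data gets the verdict `indeterminate` — the rule set cannot be
applied counterfactually.

Two encodings extend the bounds to degenerate single-endpoint designs:
$s_p = n_1 + 1$ ("never stop on progression") and $a_p = -1$ ("never reject
on progression"). With those, a response-only two-stage rule is a special
case of the same lattice computation.

## Exact operating characteristics

`prob_stage1_stop()` sums the trinomial pmf over the stage I stop region;
`prob_reject()` convolves the stage I continuation states with the stage II
lattice:

$$P(\text{reject}) = \sum_{(k_r,k_p) \notin \text{stop}} P_1(k_r,k_p)
  \left[1 - P_2\!\left(j_r \le a_r - 1 - k_r,\; j_p \ge a_p + 1 - k_p\right)\right]$$

The joint tail $P_2$ is precomputed once per rate configuration by cumulative
summation over the stage II lattice with a fixed summation order, so repeated
evaluations are bit-reproducible. The pmf itself is evaluated in log space
(`dtrinom()`), with the $0 \log 0 = 0$ convention so degenerate rates such as
$(p_r, p_p) = (0, 1)$ are exact. The expected sample size follows the
identity $EN = n_1 + n_2(1 - PES)$, which holds exactly by construction and
is asserted in the tests.

Power uses the **borderline-value construction**: desirable drugs are modelled
as a 50/50 mixture of a configuration at the response boundary
$(r_{alt}, epd_{nul})$ and one at the progression boundary
$(r_{nul}, epd_{alt})$ — a mixed population of drugs each active on one
endpoint, not necessarily both. Type I error is evaluated at the point null
$(r_{nul}, epd_{nul})$. Both are explicit, overridable arguments of
`oc_desr()` because other evaluation populations are defensible; in
particular, published threshold tables for this design were generated by a
proprietary simulation whose evaluation scheme (point rates versus rates
drawn from distributions) is not fully documented. Under the point-null
model here, the 15 + 15 design with bounds $(1, 8, 4, 14)$ has exact
$\alpha = 0.111$ and $PES_{nul} = 0.679$, materially different from the
historically printed $0.025$ and $0.90$ for the same bounds. The package
therefore treats published operating-characteristic columns as annotations,
never as test targets; the threshold *bounds* themselves, which are what the
rule applies to data, are shipped as fixtures and validated cell-by-cell
against both historical cohorts.

## Threshold search

`desr_search()` enumerates all candidates over closed finite ranges —
$s_r \in [0, n_1]$, $s_p \in [0, n_1+1]$, $a_r \in [s_r+1, n_1+n_2]$,
$a_p \in [-1, n_1+n_2]$ — computes exact operating characteristics for each,
and keeps those with $\alpha \le$ `alpha_max` and power $\ge$ `power_min`.
Among feasible candidates the default selection maximises $PES_{nul}$, then
minimises $EN_{nul}$ (equivalent given the EN identity, kept for clarity of
intent), then maximises power, with remaining ties broken by the fixed
enumeration order — so the search is deterministic and exhaustive. The
selection list is configurable since no single optimality criterion is
canonical for this design family. The enumeration is organised so the
stage II joint tail is computed once per rate configuration and shared across
all $\approx n_1^2 (n_1+n_2)^2 / 2$ candidates; a 15 + 15 search takes well
under a second.

Infeasibility is a *result*: `desr_search()` returns a marker object and
`desr_derive_table()` flags the row rather than dropping it. Notably, the
classic constraint pair ($\alpha \le 0.05$, power $\ge 0.8$) is infeasible at
$n_1 = n_2 = 15$ for hypotheses $(r: 0.05/0.2,\ epd: 0.6/0.4)$ under the
exact point-null model: half the borderline mixture differs from the null
only through the EPD margin (0.4 vs 0.6), which 30 patients cannot separate
at that error level; the attainable power ceiling at $\alpha \le 0.05$ is
about 0.66. Relaxing to $\alpha \le 0.12$, power $\ge 0.75$ recovers exactly
the historical bounds $(1, 8, 4, 14)$ — consistent with those bounds having
been derived under a more forgiving evaluation scheme.

## Monte Carlo verification and synthetic cohorts

`estimate_oc_mc()` is an independent estimator of everything `oc_desr()`
computes exactly: vectorised trinomial draws per replicate, the drug class
drawn per replicate (not per patient) from the mixture weights, binomial
standard errors per field. Each call runs on a private, explicitly seeded RNG
stream and restores the caller's RNG state, so results are byte-reproducible
and tests cannot interfere with each other. The exact-vs-MC agreement test
uses 200,000 replicates and a 3-standard-error band; the convergence test
checks the error stays within its shrinking 3-SE band over a quadrupling
ladder of replicate counts.

`generate_trial_records()` emulates a cohort of trials all testing drugs with
the same true rates, with full two-stage accrual (as when investigators
continue regardless of the formal rule, which happened in seven of the eight
stage-I-stopped trials of the Gehan cohort). What it does **not** emulate:
heterogeneous per-trial drug rates, informative under-accrual, investigator
overrides, or missing stage II reporting — all present in real cohorts. A
passing recovery test therefore shows the decision and counting machinery is
correct under the stated model, not that real cohorts behave like the model.

## Classic designs

The Fleming-type rule is implemented as given bounds (early accept at
$\le$ `accept_bound` stage I responses, optional early reject, final reject
at $\ge$ `final_reject_bound` cumulative responses); deriving such bounds
from error rates via normal approximations is out of scope. Early rejection
is disabled by default because the historical cohort never invoked it — one
trial continued with 7 of 15 responses.

For Gehan's design, stage I is sized as the smallest $n$ with
$(1-p)^n \le \beta$ (14 at $p = 0.2$, $\beta = 0.05$) and stops only on zero
responses. Stage II is sized for estimation precision: the package uses the
exact one-sided upper 75% binomial (Clopper–Pearson) bound $\tilde p$ for the
stage I response fraction and returns
$\max(0, \lceil \tilde p(1-\tilde p)/se^2 - n_1 \rceil)$ — a conservative
interpretation, documented as such because no closed formula is canonical.
Gehan's framework, being estimation-oriented, prescribes no end-of-trial
activity criterion at all; for rule-set comparisons the package calls a drug
active when the cumulative observed response rate reaches `r_alt_eval`
(default 0.2). That convention reproduces all 23 historical activity
verdicts and is an explicit parameter, not a historical claim.

## Comparison machinery

`compare_cohort()` applies any named set of rules to a trial table and
tabulates per-trial verdicts plus summary counts (stage I stops, final
rejections, pairwise stopped-but-continued counts, pairwise final agreement).
Two conventions matter. First, a trial stopped by investigators is carried
as a flag: its rule verdicts are still computed mechanically, and the flag
lets analyses exclude it from "trials that continued" tallies, matching how
such a trial is narrated in practice. Second, `indeterminate` agrees with
`indeterminate` and disagrees with any determinate verdict — two rules that
both lack stage II data are not in conflict.

For cohorts whose stage II size varied per trial,
`select_design_for_record()` picks the threshold row with
$n_2 = n_{tot} - n_1$ and errors loudly when that size is missing; a trial
with no stage II data only needs the stage I bounds, which are constant
across rows of a derived table with fixed $n_1$.

## Problem sizes and numerical choices

Exactness tests compare the lattice computation against an independent
quadruple-loop enumeration (tolerance $10^{-12}$) on designs sampled across
$n_1, n_2 \in [2, 20]$ under a fixed seed — sizes where the brute-force
oracle remains fast. Monte Carlo checks use 200,000 replicates (alpha/power
standard errors around $10^{-3}$); synthetic-cohort recovery uses 10,000
trials. Probabilities are accumulated in double precision with fixed
summation order; no log-sum-exp is needed beyond the log-space pmf because
every summand is nonnegative and the lattices are small. Ties in the
threshold search are resolved by enumeration order $(s_r, s_p, a_r, a_p)$
ascending; floating-point comparisons of selection criteria use a $10^{-12}$
slack so that mathematically equal candidates fall back to enumeration
order.

## Known limitations

* Operating characteristics are evaluated at user-specified point rates or
  finite mixtures; rates drawn from continuous priors are not supported
  (though any discrete mixture can be supplied).
* EPD is a trial-level count; the model has no assessment-time structure, so
  "early" is whatever the trial's first evaluation defined.
* The comparison machinery judges rules on *observed* counts, inheriting the
  accrual patterns of the historical cohorts; it does not model what stage II
  would have shown for trials that stopped.
* Published operating-characteristic columns for this design family are not
  reproducible from the documented point-null model (see above) and are
  deliberately not test targets.
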