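---
title: "Measuring the impact of double-zero studies: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the impact of double-zero studies: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hibi)
```

## The problem

Meta-analyses of rare binary outcomes routinely contain trials in which
*neither* arm recorded a case. Under the usual two-stage relative-effect
estimators (odds ratio, risk ratio) such double-zero studies carry no
information — their contribution to every pooled sum is exactly zero — and
common practice is to drop them. But "invisible to this estimator" is not
the same as "irrelevant": had those trials observed even a handful of
cases, the pooled conclusion might have moved. The harms index (Hi) and
benefits index (Bi) quantify exactly how far the observed data are from
that tipping point.

**Hi** is the minimum total number of cases that, when added to the
*treatment* arms of the double-zero studies (arm sizes fixed, so each
added case displaces a non-case), changes either the direction of the
pooled effect (OR/RR crossing 1) or its statistical significance.
**Bi** is the analogous minimum for the *control* arms. Added treatment
cases push the pooled effect toward harm, added control cases toward
benefit — hence the names. If no combination within the search cap
produces a change, the index is defined to be 0, and only when
Hi = Bi = 0 can one conclude that the double-zero studies cannot alter the
meta-analysis' direction or significance.

## Applicability and zero-structure subtypes

The method needs something to perturb and something to compare against:
at least one double-zero study, and at least one study with a case
somewhere. `check_applicability()` enforces exactly that operational
condition. Independently, `classify_zero_structure()` reports a
descriptive subtype label: `MA-DZ` (double-zero studies alongside
nonzero studies), `MA-MZ`/`MA-CMZ` (mixtures of single-zero and
double-zero studies), and the inapplicable cases `MA-SZ`/`MA-CSZ` (only
single-arm zeros, which Peto and Mantel–Haenszel handle natively) and
`MA-CDZ` (every study double-zero: the data already say "no difference",
and there is no reference analysis to perturb).

The boundary between the two mixture labels is not operationally pinned
down by the index definition, so this package fixes a rule and reports it:
`MA-CMZ` requires single-zero, double-zero **and** fully-nonzero studies
to be present with neither arm's total case count zero; any other mixture
is `MA-MZ`. The label is informational only — the Hi–Bi gate is the
operational applicability condition above, never the label.

## The exact method

With `n` double-zero studies and at most `m` added cases per study, each
candidate scenario is a vector of additions, one entry per double-zero
study; there are `(m+1)^n` combinations including the all-zero reference
(fewer if an arm has under `m` participants, in which case the arm size
caps that study's range). `compute_index_exact()`:

1. pools the meta-analysis with all double-zero studies **excluded**
   (reference estimate and p-value) — single-zero and nonzero studies are
   present in every pooling;
2. enumerates the combinations in ascending order of total added cases,
   breaking ties by concentrating cases in the larger studies (larger
   trials move the pooled effect more, so the search reaches changes
   sooner); the ordering is total, then reverse-lexicographic over
   studies ranked by descending total sample size (ties: treatment-arm
   size, then input order);
3. re-pools the full dataset under each combination and compares
   direction and significance to the reference;
4. returns the total of the first changing combination — which, by the
   ordering, is also the minimum total over all changing combinations —
   or 0 if none changes.

Two conventions matter at the boundaries. A pooled log-effect of exactly
0 has direction 0, and direction 0 never counts as a crossing: a change
of direction means moving from one side of the null to the other, not
merely reaching it. Significance is the strict comparison `p < alpha`
(default `alpha = 0.05`, two-sided), and a flip in either direction —
significant to non-significant or the reverse — counts as a change.

Combinations on which an engine fails (in practice: beta-binomial
non-convergence) are recorded in the trace as *inestimable* and skipped
when taking the minimum; if more than 10% of a trace is inestimable the
result carries a warning flag rather than a silent answer.

### Why the cap is 3

The per-study cap `m = 3` comes from the rule of three: a trial that
observed zero cases in an arm of size `n` has an upper 95% confidence
limit of `3/n` on the case rate, so scenarios adding more than 3 cases to
such an arm sit outside what the observed zeros make plausible. The same
logic at a 99.3% interval gives the stricter value
`round(-log(0.007)) = 5`, exposed as `strict_cutoff()`. The cap doubles
as the impact cutoff: an index of 0 is *no impact*, an index in
`(0, cutoff]` is a *potential impact* (the change is reachable with a
plausible number of cases — keep the double-zero studies in the
synthesis), and an index above the cutoff is *almost no impact*.

The search space grows as `(m+1)^n`, so the exact method refuses more
than `4^10 = 1,048,576` combinations per index unless forced
(`force = TRUE`); at that point the approximating method is the intended
tool.

## The approximating method

`compute_index_approx()` evaluates only the single most influential
double-zero study. Each double-zero study is scored by its Peto
weighted-effect contribution after tentatively adding 1 case to its
treatment arm — that contribution is the study's `O − E` term, which for
a double-zero study with `g` added treatment cases equals `g·n2/N`, so
studies with a relatively large control arm score highest. Ties go to
the larger total sample size, then input order. For balanced arms the
score is size-invariant (`n2/N = 1/2` exactly), so among balanced
candidates the size tie-break is what selects the largest study.

The pivot then receives `g = 1, …, min(3n, arm size)` cases in the target
arm while the other double-zero studies stay at zero, for at most
`3n + 1` poolings per index including the reference — with 10 double-zero
studies, 31 poolings instead of over a million. The same pivot (chosen by
the treatment-arm rule) is reused for Bi; re-selecting per arm would cost
one extra pooling sweep and, in the balanced and mildly unbalanced
settings the method targets, selects the same study. Under automatic mode
`hibi()` switches from exact to approximating at `n >= 7` double-zero
studies. Because the pivot search is a subset of the exact search, the
approximating index can only be equal or larger (it may need one more
case, or miss a change entirely); with a single double-zero study the two
search spaces coincide and the methods agree exactly — both facts are
exercised in the test suite.

## Pooling engines

**Peto odds ratio (default).** Per study, `O − E = a − (a+c)·n1/N` and
the hypergeometric variance
`V = (a+c)(N−a−c)·n1·n2 / (N²(N−1))`; pooled log OR `ΣO−E / ΣV`, standard
error `1/√ΣV`, normal p-value. No continuity correction anywhere:
single-zero studies enter natively (this is the reason the method's
default is Peto), and double-zero studies contribute `O − E = V = 0`.

**Mantel–Haenszel risk ratio.** Used when the RR measure is requested
(Peto cannot estimate an RR). Pooled RR `Σ(a·n2/N) / Σ(c·n1/N)` with the
Greenland–Robins variance for the log RR; zero cells enter as zeros, and
a pooled arm with no cases at all leaves the RR undefined (an error that
suggests the OR measure).

**Beta-binomial one-stage model.** Each arm of each study is one
observation: cases `y ~ BetaBin(n, mu, rho)` with
`logit(mu) = intercept + effect·treat` and a single overdispersion
parameter `rho` shared across arms; the treatment coefficient is a log
odds ratio. Here double-zero studies *are* informative — their likelihood
terms depend on the parameters — which is precisely why a one-stage
engine is offered alongside the two-stage ones. The log-likelihood is
written out once in `betabin_loglik()` and everything (the fit, and the
independent grid-search oracle in the tests) maximizes that same
function.

Numerical choices for the beta-binomial fit: L-BFGS-B from three
deterministic starts (effect −1, 0, +1; intercept at the logit of the
crude rate; `logit(rho)` at −2.94), objective tolerance `factr = 1e4`
(about 2e-12 relative), parameter box `[-15, 15]` for the coefficients
and `[-12, 8]` for `logit(rho)`. The lower overdispersion bound is
deliberate: as `rho → 0` the beta-binomial tends to its binomial limit,
and below `rho ≈ 6e-6` the `lgamma` differences in the likelihood cancel
catastrophically in double precision, manufacturing a spurious flat
optimum; at the bound the model is numerically indistinguishable from
binomial for realistic trial sizes, so nothing is lost. Standard errors
come from the observed information at the optimum; a failed solve, a
non-positive effect variance, or a positive optimizer code is reported
as `converged = FALSE` and treated downstream as an inestimable pooling,
never silently replaced.

## The synthetic generator

`generate_meta()` emulates the setting the indices are meant for: `k`
two-arm trials with per-arm sizes uniform on `n_range`, control cases
`Binomial(n, p0)`, treatment cases `Binomial(n, p1)` with
`logit(p1) = logit(p0) + log(true_or)`, and an optional treatment:control
size ratio. A required number of double-zero studies is enforced by
redrawing whole datasets until the count is hit (bounded at `1e5`
draws): zeros arise from genuinely low risk, exactly the mechanism that
produces them in practice, rather than from zeroing cells after the
fact. The cost of honesty is that infeasible requests (say, double-zero
studies at `p0 = 0.5` with hundreds of participants) fail loudly at the
rejection bound instead of fabricating implausible data.

What the generator does *not* emulate: between-study heterogeneity in
the baseline risk or the effect, correlation between arm sizes and risk,
selective reporting, or multi-arm designs. Tests that pass on this
generator therefore demonstrate the algorithmic properties of the
indices (count laws, minimality, duality, exact–approximate agreement),
not the field performance of the method on heterogeneous corpora.

`compare_exact_approx()` is the batch harness for studying the
approximating method: per simulated dataset it computes Hi and Bi by
both methods, classifies each analysis as impacted
(`0 < index <= cutoff`) or not, and reports the agreement table,
sensitivity and specificity with the exact method as gold standard, plus
the share of both-impacted cases where the approximating index needs
exactly one more case than the exact one.

## Simulation sizes used in the tests

The test suite keeps every study small enough to re-run routinely:
100-dataset batches for the Peto-oracle and duality properties
(2–10 studies, 1–2 double-zero), 200 datasets for the one-double-zero
exact≡approximate equivalence, a 50-study/500-per-arm single fit for
beta-binomial null recovery, and 2,000 simulated studies for the
generator's marginal check. These sizes are chosen so each property has
enough replicates to fail loudly under a wrong implementation while the
whole suite stays in the minutes range.

## Known limitations

- The indices inherit the engine's conventions: a different pooling model
  (random-effects, continuity-corrected) would give different Hi/Bi; this
  package deliberately restricts to the three engines above.
- The exact method's cost is exponential in the number of double-zero
  studies; the budget guard and the approximating method are mitigations,
  not removals, of that cost.
- The approximating method can understate impact (finite sensitivity)
  but, searching a subset of scenarios, never invents one.
- Cases, not events: inputs where a count exceeds the arm's sample size
  are rejected, so event-per-patient data must be collapsed to cases
  before use.
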