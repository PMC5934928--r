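---
title: "Rank-invariant analysis of paired ordinal data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-invariant analysis of paired ordinal data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svensson36)
```

## The problem

Patient-reported outcome questionnaires such as the RAND-36 produce ordered
categorical responses. Evaluating an instrument's *test-retest reliability*
(scores stable when nothing has changed clinically) and *responsiveness*
(scores move when patients genuinely improve) therefore means analysing
**paired ordinal data**, where differences, means and Pearson correlations
are not meaningful operations. This package implements Svensson's
rank-invariant method, which decomposes paired ordinal change into a
systematic group-level component and an individual heterogeneity component
using only the ordering of the categories, together with the surrounding
machinery a validation study needs: RAND-36 scoring, internal consistency on
the latent (polychoric) scale, and a synthetic cohort generator so the whole
chain is testable without patient data.

## The measures

All measures are computed from the `C x C` table of paired categories
(`paired_table`), rows = occasion 1, columns = occasion 2, higher category =
better health.

**Percentage agreement (PA)** — the proportion of identical paired ratings
(optionally within `k` scale steps). Purely descriptive.

**Relative position (RP)** — with `X` and `Y` independent draws from the
occasion-1 and occasion-2 *marginal* distributions,
`RP = P(Y > X) - P(Y < X)`, in `[-1, 1]`. Positive RP is a systematic shift
toward better categories at the second occasion. If the probability of a
higher rating at follow-up is 0.70 and of a lower one 0.27, `RP = 0.43`.
The ROC-style curve of the two cumulative marginals (`roc_points`) shows
this shift as a bow away from the identity diagonal.

**Relative concentration (RC)** — `RC = kappa * (c21 - c12)`, where `c21` is
the probability that an occasion-2 draw lies strictly between two ordered
independent occasion-1 draws and `c12` the mirror image. Positive RC means
ratings concentrate toward the scale's centre at the second occasion; the
curve takes an S shape. We normalise with `kappa = 4`, which makes RC reach
`+1` in the extreme configuration where occasion-1 mass is split between the
scale ends and all occasion-2 mass lies strictly between them
(`c21 = 1/2 * 1/2 = 1/4`, `c12 = 0`). The constant is exposed in
`analysis_config()` because only the range and the sign semantics of RC are
fixed by convention.

**Relative rank variance (RV)** — individual heterogeneity. Each cell
`(i, j)` receives two *augmented mean ranks*: subjects ordered primarily by
the occasion-1 category with occasion-2 ties broken, and vice versa;
subjects sharing a cell get the cell mid-rank (the `(count + 1)/2` offset).
Then `RV = (6 / n^3) * sum counts[i,j] * (rbar1[i,j] - rbar2[i,j])^2`. RV is
zero exactly on *rank-transformable* patterns — paired distributions fully
explained by a common monotone shift, including all diagonal tables — and
values above 0.2 conventionally flag individual departures from the common
pattern of change. The nominal range is 0 to 1; extreme reversal patterns
(e.g. all pairs crossing) can push the estimator above 1, which we report
unclipped with a warning rather than truncate silently.

```{r measures}
tab <- paired_table(rbind(0, c(27, 3, 70), 0), categories = 1:3)
relative_position(tab)
```

### Standard errors, intervals, significance

The study design reports RP, RC and RV with standard errors and 95%
confidence intervals, declaring an effect significant exactly when zero is
outside its interval. No closed-form SE is part of the method's published
description, so the package uses the **leave-one-pair-out jackknife**:
every observed pair is removed in turn (equivalently, each non-empty cell
decremented, weighted by its count) and
`SE = sqrt((n-1)/n * sum (theta_(-i) - mean)^2)`. For PA this reproduces the
closed form `sqrt(p(1-p)/(n-1))` algebraically, and for RP it agrees with a
bootstrap to within a few percent at realistic sizes — both are enforced in
the test suite. Intervals are normal-approximation `estimate ± z * se`
(`z = 1.96` at 95%); the RV interval is clipped below at 0, its natural
boundary, and a clipped-to-zero bound counts as *covering* zero. Because the
jackknife/normal choice is ours, printed SE/CI values from other software
implementations of the method are not expected to agree digit-for-digit.

A warning is issued below 12 pairs (the method is considered usable down to
roughly ten-twelve subjects, but fragile), and when RV exceeds 0.2.

## RAND-36 scoring

The 36 items are recoded to 0-100 (higher = better) by the standard RAND
recode, shipped as an editable CSV (`inst/extdata/rand36_recode.csv`) so a
non-standard dialect can be swapped in without code changes. Eight subscales
are the mean (optionally median) of their member items; item 2
(Health change) is kept as an ordinal 5-category item, reverse-recoded so
higher = better, and analysed with the Svensson measures directly. The
default missing policy is **complete-case**: a subscale is scored only when
every member item is answered, mirroring the validation-study rule that
imputation may bias estimates; the RAND half-rule (score when at least half
the items are answered) is available for compatibility. The median
aggregator is offered because mean-based subscale scores take many more
distinct values, which mechanically lowers PA and raises RV; rank-invariance
of the measures makes the finer category set otherwise harmless.

## Ordinal alpha

Internal consistency is computed on polychoric correlations (ordinal alpha)
rather than Pearson correlations of raw scores: the ordinal items are
treated as discretisations of latent normal constructs, so only continuity
of the construct, not of the data, is assumed. Estimation is two-step
maximum likelihood — thresholds fixed at the marginal normal quantiles, then
a bounded scalar search for the correlation in `(-0.999, 0.999)` (tolerance
1e-8) maximising the multinomial likelihood with bivariate-normal cell
probabilities. The rectangle probabilities use Plackett's identity (the
derivative of the bivariate normal CDF in the correlation is the bivariate
density), reducing each cell to a one-dimensional adaptive quadrature at
relative tolerance 1e-10; the zero-threshold closed form
`P11 = 1/4 + asin(rho)/(2*pi)` cross-checks it in the tests. Estimates
pinned at the search bound (e.g. perfectly concordant items) are flagged
`converged = FALSE` with a warning rather than silently returned. Zero-count
marginal categories are collapsed away; an optional 0.5 continuity
correction handles sparse interior zeros. Items are orientation-aligned
(a strictly monotone relabelling) before the pairwise matrix is built, and
alpha is `(k/(k-1)) * (1 - k / sum(R))`. Rows with any missing item are
dropped, consistent with the complete-case rule. By default alphas use
baseline responses only; pooling occasions or cohorts is an explicit caller
choice (the pooled-groups variant is what the combined-samples analysis
script does).

## The synthetic cohort generator

The generator defines the study conditions under which the package is
exercised; it is deliberately simple and fixed:

* Subject trait `theta ~ N(0,1)` per latent block (one block per subscale
  plus one for Health change). Occasion latents
  `eta_t = sqrt(r)*theta + sqrt(1-r)*eps_t + delta*1(t=2)`, so `r` is the
  latent test-retest correlation and `delta` an improvement shift in latent
  SD units. Note the occasion-2 *marginal* is `N(delta, 1)` regardless of
  `r`, so the expected RP depends on `delta` (and the thresholds) only;
  `r` governs the joint distribution — PA and RV.
* Item latents load on the block factor with loading `lambda`
  (`lambda = 0.85` default, giving pairwise inter-item correlations of
  `0.72` and alphas in the observed 0.8-0.97 range); thresholds default to
  equiprobable categories on each item's native 2-6 point scale;
  reverse-scored items are mapped to their documented raw orientation.
* Missingness is item-level MCAR at rate 0.008, chosen so that the share of
  patients complete on a 10-item subscale at both occasions (~85%) matches
  the completeness range a study of this kind reports. No informative
  dropout, practice effects or administration-mode effects are modelled —
  passing tests therefore say nothing about such mechanisms in real data.
* Completion dates: baseline fixed, follow-up offsets uniform on 7-17 days
  (stable design, n = 84) or 50-70 days (improving design, n = 97, with 12
  extra late returns on 75-120 days so the eligibility filter has work to
  do). The stable design uses `r = 0.8, delta = 0`; the improving design
  `r = 0.6, delta = 0.5`, i.e. a moderate effect with more individual
  variation, which reproduces the qualitative pattern of the study designs:
  RP intervals covering zero under stability, mostly significantly positive
  RPs with RV > 0.2 under improvement.

All randomness flows from a single mandatory seed; the same configuration
and seed yield byte-identical cohorts.

## Pipeline conventions and numerical choices

* Eligibility windows are **inclusive** at both ends (7-17, 50-70 days);
  a negative day difference is an error (mislabeled occasions), and every
  exclusion is logged with its day count.
* Cross-tab summaries round percents to the nearest integer, so the three
  triangle percents need not sum to 100.
* Subscale-score Svensson analyses use the pooled sorted unique score
  values of both occasions as the ordinal category set.
* Subscale mean CIs are normal-based (`mean ± 1.96 * sd/sqrt(n)`).
* Degenerate inputs error early with named messages: empty pair lists,
  ratings outside the category set, out-of-range raw responses (named by
  item and value), `n < 2` for any SE.
* Test and simulation sizes were chosen to make every check sharp but
  desk-scale: 1,000 random tables for the oracle-equivalence properties
  (exact oracles at 1e-12/1e-9, Monte-Carlo RC oracle at 10^6 draws within
  0.01), 10,000-replicate bootstrap vs jackknife on a 1,000-pair table,
  polychoric recovery at n = 2,000, alpha recovery at n = 5,000, and 200
  replicates of n = 84 for nominal CI coverage.

## Known limitations

* The RC normalisation and the jackknife/normal interval machinery are this
  package's documented choices; other implementations of the method may
  print different SE/CI (and hence significance) values for the same table.
* RV above 1 is possible for adversarial reversal patterns; it is reported
  with a warning, and whether the nominal 0-1 range is exact or asymptotic
  for such tables is left open.
* Polychoric estimation assumes an underlying bivariate normal per item
  pair; strongly skewed latent constructs will bias alpha.
* The generator's single-factor-per-subscale structure has no cross-subscale
  correlation by default and MCAR missingness only; it validates the
  analysis machinery, not the RAND-36's factorial structure.
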