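---
title: "Assessing established dominance in rat dyads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing established dominance in rat dyads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadrank)
```

## The problem

Once two cage-mate rats have settled their relationship, overt aggression all
but disappears, and rank expresses itself through subtle priority of access
to resources. dyadrank quantifies that expression from annotated behavioral
event logs of home-cage competition tests: a trial-based food competition for
a limited number of palatable pellets (mFC; and a food-deprived variant,
mFCD), sucrose competition with continuous (SC) or intermittent (SCI) bottle
access, water competition under deprivation (WC), and the tube test (TT).
The unit of analysis is the dyad; every index is a within-pair contrast.

## Indices

For each test, consumption is the test's natural unit: pellets eaten (mFC,
mFCD), drinking duration in seconds (SC, SCI, WC), or trial wins (TT). The
**Dominance Index** normalizes the within-pair difference by the pair total:

$$\mathrm{DI} = 100\,\frac{C_A - C_B}{C_A + C_B} \in [-100, 100].$$

A positive DI means animal A holds priority access. Pairs with
$|\mathrm{DI}| \le 10$ — less than a 5% deviation from equal consumption —
are classified *unstable* (no reliable hierarchy); larger values classify the
pair as A- or B-dominant. We treat the band as inclusive at its boundary so
the 5%-difference rule and the band agree exactly there. A session with zero
total consumption has no defined DI and is classified unstable with a reason
flag rather than silently coerced to 0.

The tube test produces highly polarized DIs, so the **Conflict Resolution
Index** grades it by how quickly trials resolve:
$\mathrm{CRI} = \mathrm{DI} / \bar\ell$, where $\bar\ell$ is the mean latency
over *completed* trials of the session (units: percent per second). The
formula's denominator ("time to solve the conflict") admits several
aggregates; the mean over completed trials is the least-structured reading
and preserves the intended behavior that fast, decisive wins score higher.
Resistant trials — the presumed loser refuses to enter the tube — are
excluded from wins and latencies but counted and reported separately.

The **Conflict Index** measures how much conflict a test induces: pair
pushing time divided by pair drinking time (bottle tests) or by the mean
latency to eat all 10 pellets (food tests).

## Trial alignment and interval accounting

The trial tests run five trials in a 900-s session: a 60-s inter-trial
interval followed by 120 s of reward access, giving nominal time-0 moments
(door opening / bottle placement) at 60, 240, 420, 600 and 780 s. Because
the apparatus is operated manually, observed time-0 values may be supplied
per trial and take precedence. All trial-aligned quantification uses the
window from 40 s before to 80 s after time 0; feeder exploration within a
window is split at time 0 into an anticipatory and a reward phase.

Bouts are half-open intervals $[t_{start}, t_{stop})$ in seconds from
session start, which makes abutting bouts non-overlapping and overlap
arithmetic exact. Boundary-spanning bouts are *clipped* to the window, not
dropped, so duration mass inside the window is preserved exactly; the test
suite checks the interval arithmetic against a 0.01-s discretized overlap
oracle. Zero-length bouts are rejected at ingestion (they almost always
indicate annotation errors), and ratios with empty denominators (e.g.
pushing success with zero pushing bouts) are *missing*, not zero, so
bout-less animals never create spurious ties downstream.

Because consumption is only observable for 80 s in each of 5 trials, percent
time consuming is normalized by 400 s in the trial tests and by the full
600 s in SC and WC, making consumption levels comparable across tests.

## Peak-conflict epochs in the water competition

Water-deprived pairs alternate long drinking bouts until both are satiated,
so whole-session consumption is nearly symmetric and the DI sits in the
noise band — yet the interaction is not symmetric. `peak_conflict_epoch()`
slides a 120-s window (one trial-length of reward access; step 1 s, both
exposed in the configuration) across the session and returns the window
maximizing the pair's summed drinking and pushing time, breaking ties toward
the earliest window. Within-epoch drinking, pushing and per-bout pushing
success support re-classification at the moments where asymmetries actually
surface. The epoch length, step and the equal weighting of drinking and
pushing in the objective are design choices of this package with no single
canonical value in the field, so all three are configurable.

## Reliability and the weight-controlled regression

If rank is a stable trait of the pair, DIs should correlate across tests.
`cross_test_reliability()` computes Pearson correlations over pairs with a
defined DI in both tests (cells with fewer than 3 overlapping pairs are
reported missing), with two-sided p-values from the t transform.

Body weight matters specifically in the tube test's first encounters, so the
link between food-competition rank and tube-test outcome is assessed on
weight residuals: pellets eaten are regressed on each animal's own weight;
the day-1 tube CRI is regressed on a weight covariate; and the CRI residuals
are regressed on the pellet residuals. The CRI is pair-level while pellets
are animal-level, and no single covariate choice is canonical. Our default
uses the within-pair weight difference (A − B) for the CRI stage and the
within-pair difference of pellet residuals as the final regressor, because
the CRI is inherently relational; a per-animal variant (signed CRI against
each animal's own weight) is available via `weight_covariate = "own"`.

## The statistics suite

Comparisons of dominant vs submissive animals are paired and small
(typically up to 20 pairs), so the workhorse is the Wilcoxon signed-rank
test. For n ≤ 15 the p-value is exact: the null distribution of the
signed-rank sum is built by convolution over the (possibly tied,
average-rank) rank magnitudes, equivalent to enumerating all 2^n sign
assignments; zero differences are dropped before ranking (the conventional treatment,
stated here because published analyses rarely say which they use). Above n = 15 a
normal approximation with tie and continuity corrections takes over, and a
z-deviate is always reported for comparability with z-style reporting in the
literature. Paired t, Kruskal–Wallis, one-way ANOVA with Tukey HSD, Pearson
correlation and a Kolmogorov–Smirnov normality gate wrap the standard R
implementations behind a uniform result container. Bonferroni families are
never inferred: the caller declares them (`bonferroni_family()`), because
published analyses rarely enumerate the family size m explicitly.

## What the synthetic cohorts emulate

No raw behavioral recordings ship with this package, so validation rests on
a generative model of a dyad with a single latent dominance strength
$\delta \in [-1, 1]$ shared across tests — the "stable trait" hypothesis
made literal. Its footprint per test:

* **mFC/mFCD** — each trial's 10 pellets split $\mathrm{Binomial}(10,\,
  0.5 + 0.2\delta)$; pair latency-to-all-pellets lognormal with median 20 s
  (day 1), 14 s (day 2), 8 s (deprived), sdlog 0.3; Poisson pushing
  (3 bouts/trial/animal) with per-bout success probability
  $\mathrm{logit}^{-1}(2.5\,\delta\cdot\mathrm{side})$; anticipatory feeder
  exploration elevated (more so for the dominant); grooming elevated in the
  subordinate.
* **SC/SCI** — drinking share $0.5 + 0.15\delta$ plus noise (sd 0.03); low
  pushing with continuous access, more exploration and per-trial drinking
  with intermittent access.
* **WC** — near-equal totals (share gain only 0.02, noise sd 0.02), so the
  whole-session DI usually sits inside the noise band; the subordinate emits
  *more* pushing bouts (asymmetry 0.3) but per-bout success strongly favors
  the dominant (logit gain 4). Rank is therefore recoverable from pushing
  efficiency in the peak-conflict epoch even though consumption is
  uninformative.
* **TT** — the first day-1 trial is won by A with probability
  $\mathrm{logit}^{-1}(5\delta + 0.25\,\Delta w)$, where $\Delta w$ is the
  within-pair weight difference in percent (weights enter day 1 only: body
  size tips first territorial encounters); thereafter the winner of each
  trial repeats with probability 0.93, and contested (non-persisting) trials
  re-draw from the dominance logistic. Latencies are lognormal with median
  8 s on the very first encounter and 3.5 s afterwards. On day 2, pairs
  whose day-1 record was strongly polarized (|DI| ≥ 80) refuse trials with
  probability 0.095 each, yielding roughly 9% resistant day-2 trials.

Cohorts draw $|\delta| \sim U(0.25, 1)$ with random sign — established
hierarchies with mostly clear ranks and a minority near the noise band —
and body weights with within-pair differences below 10% (age-matched
animals). Each pair owns one seeded random stream, so enlarging a cohort
never perturbs existing pairs, and a whole cohort is byte-reproducible from
its seed. An independent-delta-per-test ablation provides the null against
which the reliability analysis is judged: the shared-trait cohorts must
produce correlated reward-test DIs and the ablation must not.

All effect sizes above are *calibrated choices*, selected once so that the
generator reproduces the qualitative structure described for these tests
(consumption asymmetry without weight effects, near-symmetric WC totals with
asymmetric pushing efficiency, polarized streaky tube outcomes with a day-1
weight effect, and recoverability of the pellet–CRI link in 16-pair cohorts);
real studies report test statistics, not generative parameters, so none of
these numbers is an empirical estimate. Likewise the lognormal/exponential
bout-duration and placement distributions are stand-ins — real bout-duration
distributions are not published. The generator does **not** emulate
inter-bout temporal correlations, spatial behavior, day-to-day identity
drift, annotation noise, or aggression; passing tests therefore show that
the *pipeline* recovers structure a cohort actually contains, not that real
rats match these distributions.

## Validation study sizes

The shipped tests and the acceptance script run, at fixed seeds: formula
oracles on 1,000 random inputs; interval accounting against the discretized
oracle on 200 random logs (generated at centisecond resolution, the
granularity frame-based annotation produces, so the 0.01-s grid oracle is
exact); exact Wilcoxon p vs full sign-flip enumeration on 50 datasets with
n ≤ 10; dominant-identification recovery over 500 simulated mFC sessions at
$\delta = 1$ (the Binomial(50, 0.7) tail makes ≈98% the expected rate);
water-competition and tube-test pattern checks over 200 replicates each;
cross-test reliability on 20-pair cohorts (10 shared-trait cohorts, 200
independent-delta cohorts for the null); and the weight-residual regression
over 200 cohorts of 16 pairs. For the independent-delta null we assert each
cross-test correlation separately (within ±0.45 in ≥90% of cohorts, with
mean ≈ 0): with six simultaneous correlations each bounded with probability
≈0.95, a joint all-six bound would hold only ≈74% of the time under the null
itself.

## Known limitations

* Dyads only; no Elo/David's-score longitudinal ranking for larger groups.
* Bouts are taken as annotated: no minimum-gap merging or smoothing, no
  inter-rater reliability modeling.
* Whether annotated bouts may span trial boundaries in a given dataset is an
  upstream convention; this package clips rather than discards either way.
* The CRI aggregate (mean completed-trial latency) and the regression's
  weight covariate are defensible choices among several; both are exposed as
  parameters rather than hidden.

## A minimal run

```{r example, eval = FALSE}
cohort <- simulate_cohort(n_pairs = 20, seed = 1)
fit <- dominance_analysis(cohort)
print(fit)
plot(fit, type = "di")
write_report(fit, "report/")
```
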