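---
title: "Repertoire overlap and social bonding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repertoire overlap and social bonding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gesturenet)
```

## The scientific problem

Primates living in fission–fusion societies — chimpanzees are the canonical
case — maintain differentiated networks of strong and weak social bonds
while spending much of their time in small, shifting parties. Grooming
maintains strong bonds but is time-limited; gestural communication has been
proposed as a complementary bonding mechanism. One observable trace of that
process is the *overlap structure* of gestural repertoires: for any dyad,
some gesture types are present in both individuals' repertoires
(homogeneous gestures) and some in only one (heterogeneous gestures). If
communicative similarity and social bonding feed each other, dyads with
greater repertoire overlap should spend more time in bonding behaviours.

`gesturenet` implements the full analysis chain for this question from
focal-animal field data: repertoire scoring, dyadic bonding-rate
construction, network assembly and centrality, permutation-based network
inference, and sequence-level mixed models — together with a synthetic data
generator that plants a known overlap–bonding coupling so every stage can
be validated end to end.

## Data model

Two observation streams are assumed, both as plain CSV:

* **Scan records**: instantaneous samples taken at fixed intervals during a
  focal follow (default nine scans at 2-min intervals over 18 min). Each
  scan records the party (individuals within roughly 35 m), the subset
  within 10 m, the focal's nearest adult neighbour with distance and mutual
  visual attention, and the activity of focal and neighbour.
* **Gesture events**: one intentional gesture each, with signaller,
  recipient, gesture type, sensory modality (visual, tactile, short-range
  auditory, long-range auditory), panthoot accompaniment, and the
  recipient's response (presence; emotional display vs goal-directed
  action; vocal component).

The numeric code 999 denotes missingness in all tabular files and is never
interpreted as data. Identifier sets within a cell are
semicolon-separated.

## Repertoire scoring

An individual's repertoire is the set of gesture types it was observed to
produce, as signaller, towards adult recipients. Gesture types enter the
analysis only if they pass the intentionality filter: the fraction of a
type's occurrences satisfying the intentionality criteria (audience
present, response waiting, sensitivity to attention state, persistence),
pooled across subjects, must exceed 60%. We read "above the threshold" as
*strictly* greater than 0.60; a configuration switch
(`intentionality_filter(strict = FALSE)`) gives the at-or-above reading,
because the boundary case is not decidable from the published wording
alone.

Dyadic overlap is quantified three ways:

* **Cohen's κ** between the two presence/absence vectors over a common
  catalog: $\kappa = (p_o - p_e) / (1 - p_e)$ from the 2×2 contingency
  table, where $p_o$ is observed agreement and $p_e$ the
  product-of-marginals chance agreement. Identical non-constant repertoires
  give κ = 1; complementary half-full repertoires give κ = −1. When
  $p_e = 1$ (e.g. two empty modality repertoires) κ is undefined and the
  dyad's tie is left missing, excluded from network means and regressions,
  and logged.
* **Homogeneous repertoire size** $|A \cap B|$ and **heterogeneous
  repertoire size** $|A \setminus B| + |B \setminus A|$, both symmetric in
  the dyad (a pair with 5 and 2 mutually unshared types has heterogeneous
  size 7 in both orderings).
* **Sequence-level classification**: each distinct type used in a gesture
  sequence is homogeneous iff present in the recipient's repertoire too;
  the per-sequence homogeneous/heterogeneous sizes feed the mixed models.

**Catalog universes.** Per-modality κ is computed over that modality's
catalog only, so agreement in, say, tactile gestures is not diluted by the
size of the visual catalog; the "all gestures" κ uses the full catalog.
This choice is the package's own: it makes per-modality statistics
invariant to the other modalities' catalog sizes.

**Unobserved recipients.** When a sequence's recipient has no observed
repertoire (never focal, or empty), homogeneity against it is undecidable;
the sequence is flagged and its sizes set missing rather than classified
against an empty vector.

## Sequences and panthoot recipients

A gesture sequence is a run of gestures by one signaller towards the same
recipient, in the same context, with inter-gesture gaps of at most 30 s.
Context is an explicit categorical column when present and ignored
otherwise. Sequence identifiers are deterministic, making the grouping
idempotent and stable under re-sorting.

Gestures accompanied by panthoots (broadcast vocalizations) lack a single
observable addressee, so recipients are assigned by rule: all-visual
panthoot sequences go to the most dominant party member other than the
signaller; sequences containing any auditory gesture go to the focal's
nearest neighbour (unusable and flagged when no neighbour was recorded).
Dominance is operationalized from pantgrunt degrees — pantgrunts are
directed up the hierarchy, so individuals are ranked by pantgrunt-given
indegree (descending), ties broken by outdegree (ascending; dominant
individuals pantgrunt less — the top-ranked male in the packaged
demographic table has the highest indegree and zero outdegree) and then by
id. The field data behind the published analysis do not state this
operationalization; it is our inference, and it is deterministic.

## Bonding rates

For focal *i* and partner *j*, the rate of a bonding behaviour is

$$\text{minutes per hour} = 60 \cdot \frac{n_\text{behaviour}}{n_\text{party}}$$

where $n_\text{party}$ counts scans of *i*'s follows with *j* in the party
and $n_\text{behaviour}$ those where the behaviour's condition held. Each
scan stands for one scan interval of time, so the interval length cancels;
this is the natural estimator for "duration per hour co-present in the same
party" under instantaneous sampling. Rates are missing (not zero) for dyads
never co-present, and lie in [0, 60] otherwise.

Behaviour conditions: joint feeding/resting/travelling and the two
attention states require *j* to be the nearest neighbour within 2 m with
the matching activity or attention flag; proximity requires only
nearest-neighbour status within 2 m (so it bounds the nested behaviours
from above); grooming given/received/mutual is read from the focal's
activity code towards its nearest neighbour, without the 2-m condition —
the published behaviour table attaches "within 2 m and nearest neighbours"
to the joint activities, attention and proximity but not to the grooming
rows, and grooming implies contact in any case. Rates are directed
(computed from *i*'s follows only), matching the treatment of proximity
networks as directed.

The scan-independence check pairs, for every (focal, partner) dyad, the
within-10-m (or party) counts at two scan positions across follows and
applies a Wilcoxon signed-rank test. The statistic reported is
T = min(W⁺, W⁻) over non-zero differences with average ranks for ties; the
two-tailed p-value is exact for N ≤ 100 (the null distribution of the rank
sum is built by generating-function convolution over the doubled ranks,
which accommodates ties) and a tie-corrected normal approximation beyond.
Degenerate inputs (all differences zero) are reported as not applicable
rather than given an arbitrary p.

## Networks and centrality

Dyadic matrices are labelled square matrices with a structurally undefined
diagonal. κ and repertoire-size networks are undirected (symmetry is
asserted on construction); rate networks are directed. Normalized degree
centrality is the mean off-diagonal row value (outdegree; behaviour
directed at others), column value (indegree), or either for undirected
networks (*n*-degree). Missing ties are excluded from the means by default
— dividing by the count of *observed* ties — with `zero_fill = TRUE`
available to mimic tools that zero-fill incomplete matrices; the published
analysis does not state which convention its software used, so the
package's default is the one that does not manufacture zero ties.

## Permutation inference

Dyadic observations are non-independent, so both network-level and
node-level models use permutation reference distributions.

**MRQAP with double semi-partialling** (`mrqap_dsp()`): point estimates are
OLS on the z-scored vectorized off-diagonal dyads (standardized betas;
listwise deletion of dyads missing anywhere). For each predictor, the
predictor matrix is residualized on the remaining predictors, the residual
matrix is permuted by joint row/column node permutations, and the model is
refitted with the permuted residuals in place of the predictor; the
two-tailed p-value is $(\#\{|\beta^*| \ge |\hat\beta|\} + 1)/(n_{perm}+1)$.
Because the residuals are orthogonal to the other predictors, the
unpermuted refit reproduces the full-model coefficient exactly
(Frisch–Waugh), and permuting residuals rather than the raw matrix keeps
the other predictors' explanatory role intact under the null — the
property that makes the procedure robust to network autocorrelation and
skew. With one predictor the procedure reduces to plain QAP regression.
Default 2000 permutations at network level and 10000 at node level, where
the node-level test permutes the outcome vector across nodes. The add-one
p-value convention keeps p strictly positive, and every result records its
seed, permutation count and the number of dyads used.

Degenerate inputs error early and informatively: collinear predictor pairs
are named, constant outcomes are rejected, and fewer complete dyads than
predictors + 2 is an error.

## Mixed models

Sequence-level analyses (e.g. response presence on homogeneous and
heterogeneous repertoire size) use random-intercept models with the focal
signaller as the grouping factor — observations are clustered within
signallers, and random slopes are deliberately omitted because the
questions concern population-level associations. Binary responses use a
binomial family with logit link (Laplace approximation, `lme4`);
continuous responses use a gaussian identity model (`lmerTest`, giving
Satterthwaite p-values) — the published account names only the
binomial-logit structure, so the gaussian case is our documented
assumption for continuous outcomes. With a single grouping level the model
degenerates analytically to ordinary regression, and the package fits
exactly that, noting it in the diagnostics. Optimizer warnings and
numerical failures are captured in the result's diagnostics with
`converged = FALSE` (falling back to the fixed-effects fit when the mixed
fit fails outright) — never silently discarded. A heuristic separation
check flags binomial fits with coefficients or standard errors beyond 15
on the logit scale.

## The synthetic data generator

`synthetic_config()` encodes the study design the package targets: 12
adults (six male, six female), rotating 18-min focal follows of nine scans
at 2-min intervals, four modality catalogs of 30/12/8/10 types, and about
4.5 gesture events per follow so that 120 follows give on the order of 550
sequences.

Repertoires are a group-wide core (fraction `overlap_core` of each
modality catalog, default 0.5) plus individual-specific types: by default
each non-core type is carried independently with probability
`extra_type_prob` (0.35), which yields a closed-form expectation for the
dyadic κ used in the recovery tests; a `disjoint` mode partitions the
non-core pool so individuals share nothing beyond the core.

Party membership is drawn per follow with dyad-specific inclusion
probabilities (baseline 0.7 on the probability scale, plus a stable
dyad-level logit deviation with standard deviation `dyad_overlap_sd`,
default 0.8) — a deliberately simple stand-in for fission–fusion dynamics,
which field descriptions characterise but do not parameterize. Within a
scan, each party member is within 10 m with probability 0.6; the nearest
neighbour is drawn uniformly from those, and is within 2 m with
probability $\mathrm{logit}^{-1}(b_0 + \beta_b \cdot z(\kappa_{ij}))$,
where $b_0$ is `proximity_base` (−1.0), $z(\kappa)$ the standardized
dyadic κ, and $\beta_b$ the `bonding_effect`. This is the planted coupling
between repertoire overlap and bonding time.

The default `bonding_effect = 0.65` was calibrated by simulation so that
the *realized* standardized dyadic effect of κ on the directed proximity
rate averages 0.50 under the default design (20 seeds: mean 0.503, sd
0.058) — the per-scan binomial noise attenuates the logit coefficient, so
the calibrated value is what makes "a standardized dyadic effect of 0.5"
true of the generated data. It was fixed once, before the validation
suite was run against it.

Response structure: a gesture present in the recipient's repertoire
(homogeneous) draws a response with probability 0.75, emotional with
probability `emotional_response_prob_homog` (0.6) given a response; a
heterogeneous gesture draws a response with probability 0.55, goal-directed
with probability `goal_response_prob_heterog` (0.6).

Determinism: one stream is seeded from `config$seed`; per-follow sub-seeds
are drawn up front, so output is byte-identical across runs and robust to
changes in how much randomness one follow consumes.

**What the generator does not emulate** — and hence what passing tests do
not establish about field data: realistic ranging and ecology, time-varying
oestrous state, observation effort imbalance between focals, observer error
in party/proximity scoring, gesture-type discovery (types are input
labels), and any acquisition dynamics (repertoires are static within a
run). Validation against it demonstrates the *pipeline's* statistical
correctness (calibration, power, recovery), not the field conclusions.

## Validation design and problem sizes

The test suite validates each stage against independent oracles and the
whole chain against the generator's planted parameters. Exhaustive checks:
κ against a brute-force contingency computation for all 4096 pairs of
length-6 presence vectors; the signed-rank p against full enumeration of
sign assignments. Monte-Carlo checks (sizes chosen to give stable checks
at desk scale): MRQAP null calibration with 500 replicates of independent
12-node networks at 199 permutations (rejection rate within binomial 99%
bounds of 0.05); power above 80% over 200 generator replicates at the
calibrated standardized effect of 0.5; mixed-model recovery of a planted
logit effect of 1.0 across 200 replicates of 12 groups × 50 observations
(mean bias below 0.1, Wald coverage within [0.90, 0.98]); and bounded,
proximity-nested rates on every generated dataset.

## Known limitations

* MRQAP variants that permute the raw outcome or predictor matrices are
  not offered; double semi-partialling is the only tested mode.
* The normalized-degree missing-tie convention (exclude vs zero-fill) can
  change centrality values for sparse matrices; both are available but
  exclusion is the tested default.
* Exact printed coefficients from the original field analyses are not
  reproducible without the original supplementary data; the package
  validates method correctness on synthetic data instead.
* The Wilcoxon exact p uses the convolution distribution conditional on
  the observed tie pattern, which is the standard exact treatment but can
  differ from software that always uses the normal approximation.
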