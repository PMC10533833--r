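---
title: "Temporal attitude networks from mixed questionnaire panels: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal attitude networks from mixed questionnaire panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelnet)
```

## The problem

`panelnet` studies how the uptake of biomedical HIV-prevention strategies —
pre-exposure prophylaxis (PrEP) and viral-load sorting (VLS) — relates to the
beliefs that surround it, and how those relations change over repeated
questionnaire waves in a cohort of men who have sex with men. The analytic
frame is the causal attitude network: the behaviours, demographics and belief
items are nodes of a pairwise Markov random field (MRF), and an edge is the
conditional association between two nodes given all others. Over four waves
the package estimates one network per wave, quantifies the accuracy and
stability of what was estimated, summarises each network (strength
centrality, global strength, communities, average shortest path length),
tests whether networks differ across waves, and fits marginal trend models
for each node.

Because the cohort data are available only on request, the package ships a
generator that simulates panels from *known* networks with the cohort's
structure, so that every stage of the pipeline can be exercised — and
checked against ground truth — without any download.

## The generating model

The ground truth for a wave is a pairwise MRF over a roster of 35 nodes
(3 binary: PrEP, VLS, steady partner; 32 gaussian: standardized age, an HIV
risk-perception composite, 21 PrEP-belief and 9 VLS-belief items on 1–7
scales). Writing $w_{ij}$ for the symmetric weight matrix (zero diagonal),
$\tau_i$ for node thresholds and $b_{pi}$ for a participant-by-node random
intercept,

* a gaussian node is drawn from
  $N(\tau_i + b_{pi} + \sum_j w_{ij} x_j,\ \sigma^2)$ with $\sigma = 1$,
* a binary node is Bernoulli with the same linear predictor on the logit
  scale.

With a common conditional SD the gaussian block is a Gaussian MRF with
precision $(I - W_{gg})/\sigma^2$, so planted gaussian–gaussian weights are
exactly the model's partial correlations when $\sigma = 1$ — this is what
makes oracle checks possible (`oracle_pcor()`). Sampling is by Gibbs with a
fixed scan order and a default of 200 burn-in sweeps, one retained draw per
participant-wave; the pairwise MRFs here mix quickly, and the acceptance
checks confirm the sampler reproduces the implied partial correlations.

Three deliberate distortions of the ideal model are worth knowing about:

* **Truncation.** Belief values are clipped to the 1–7 scale after sampling.
  For nodes whose mean sits 2 SD or more inside the bounds this is mild; for
  floor-heavy nodes (risk perception, mean near 1.8) it raises the mean and
  shrinks the variance slightly.
* **Participant intercepts.** One intercept per participant *per node*
  (SD `within_person_sd`, default 0.8) is drawn once and reused across
  waves. This is what creates within-person correlation over time. Because
  the intercept enters the conditional of the MRF, it also inflates
  cross-sectional associations relative to the planted conditional weights
  — the marginal covariance becomes
  $(I-W)^{-1} + \sigma_b^2 (I-W)^{-2}$ rather than $(I-W)^{-1}$. The
  default of 0.8 was chosen because it produces marginal belief SDs near
  1.4–1.6 and a cross-wave ICC around 0.4, both realistic for repeated
  questionnaire items; all ground-truth *recovery* tests set
  `within_person_sd = 0` so the estimand equals the planted network.
* **Attendance.** The number of visits per participant is drawn from the
  cohort's printed visit-count distribution ((54, 130, 189, 259)/632 for
  1–4 visits) and the attended waves are chosen uniformly — attendance is
  non-monotone, as in the cohort, not a dropout process.

The default wave networks (`default_true_networks()`) plant a constant
belief–belief backbone plus uptake-related edges whose wave profile follows
the reported pattern: efficacy and affordability connect to PrEP use early,
side-effect, procedural and social-norm beliefs late, with most change
between waves 1 and 2. Thresholds are calibrated mean-field-style so that
marginal belief means track the published descriptive table and PrEP
prevalence rises from roughly 10% to roughly 31% (the logistic thresholds
include a logistic-normal correction $\sqrt{1 + 0.346\,v}$ for the variance
$v$ of the fluctuating linear predictor, without which small prevalences
come out visibly too high). The `cas` (condomless anal sex) and `condom`
indicators are generated from configurable logistic models on PrEP and VLS
(defaults: `cas` $\sim$ logit$^{-1}(-0.5 + \mathrm{PrEP} + \mathrm{VLS})$,
condom use lower among PrEP users), giving a CAS prevalence near 45% at the
last wave. Age is treated as a standardized gaussian node throughout, since
no scaling convention is stated for the original analysis.

## Scale construction and descriptives

Multi-item measures (risk perception, the self-efficacy items) are combined
into row-mean composites only if their internal consistency exceeds 0.7 —
Pearson's $r$ for two items, Cronbach's $\alpha$ otherwise
(`internal_consistency()`, `combine_items()`). A composite failing the gate
is left as items and flagged; this failure branch is this package's
robustness extension, since in the motivating analysis all composites
passed. Per-wave uptake tables (`describe_uptake()`) count ten strategy
categories whose partition identities (only-PrEP + only-VLS + both =
any-biomedical; any-biomedical + no-biomedical = N) are tested exactly, and
display percentages are rounded half-away-from-zero while raw percentages
are kept in the machine output. A participant absent from a wave simply
contributes nothing to that wave (complete-case per wave).

## Network estimation

**Mixed graphical model** (`estimate_mgm()`): one L1-penalized regression
per node (linear for gaussian, logistic for binary) on all other columns,
all columns standardized so cross-family weights share a scale. The penalty
is chosen per node by the extended BIC with $\gamma = 0.25$,
$EBIC_\gamma = -2\ell + k\log n + 2\gamma k \log(p-1)$, over a 50-point
log-spaced path from $\lambda_{max}$ down to $0.01\lambda_{max}$. An edge
survives under the AND rule (default) when both directions are nonzero; its
weight is the mean of the two coefficients, and sign-disagreeing pairs are
dropped and recorded (`sign_conflicts`) because the downstream strength and
comparison machinery needs signed reals. By default the selected supports
are refitted without penalty before averaging (relaxed estimates): lasso
shrinkage would otherwise bias every reported weight toward zero by roughly
the selected $\lambda$, and the refit makes gaussian–gaussian weights
agree with the partial-correlation reading to within sampling error (the
acceptance suite verifies per-edge recovery within 0.05 at $n = 5000$).
`refit = FALSE` restores raw penalized weights.

**EBIC graphical lasso** (`estimate_ebic_glasso()`): for the continuous
subset, block coordinate-descent graphical lasso (implemented in C++ with
warm starts along the path) over 100 log-spaced penalties, selected by
$EBIC_\gamma$ with $\gamma = 0.5$ and $E$ = number of nonzero off-diagonal
precision entries; partial correlations are
$-\theta_{ij}/\sqrt{\theta_{ii}\theta_{jj}}$. In the unregularized limit
this reproduces inverse-covariance partial correlations to $10^{-3}$,
which is tested.

The two $\gamma$ defaults (0.25 mixed, 0.5 glasso) are the common defaults
for the respective estimators; the motivating analysis does not state its
values, so printed edge weights are matched qualitatively, never
bit-exactly.

## Accuracy and stability

`bootstrap_edges()` re-estimates the mixed network on B nonparametric
resamples of participants and reports percentile 95% intervals per edge —
percentile rather than normal-theory because reported intervals of this
kind are visibly asymmetric. Resamples in which a column degenerates are
skipped and counted (a warning fires beyond 5%). For speed the resample
fits reuse the full sample's penalty path bounds; EBIC selection still
happens within each resample, and full re-derivation is available.
`edge_difference_test()` declares two edges distinct when the bootstrap
interval of their difference excludes zero. `casedrop_strength_stability()`
drops 10–70% of participants, correlates subset strength with full-sample
strength, and summarises with the CS coefficient (largest drop fraction
keeping the correlation at or above 0.7 in at least 95% of subsamples).

## Communities, centrality, connectivity

Strength is the sum of absolute incident weights; global strength is the
sum over all edges (the handshake identity between the two is tested to
$10^{-12}$). Average shortest path length uses Dijkstra over distances
$1/|w_{ij}|$, excluding and counting disconnected pairs.
`consensus_communities()` interprets "walktrap iterated 1000 times" as
walktrap (walk length 4, on absolute weights) applied to networks
re-estimated on 1000 bootstrap resamples — walktrap itself is deterministic
on a fixed graph, so resampling is the only reading under which a 90%
co-membership criterion is meaningful. Consensus clusters are the connected
components of the pairs co-assigned in more than 90% of iterations; nodes
in no such pair stay singletons.

## Comparing networks across waves

`nct()` is a permutation network-comparison test on the continuous-variable
networks (the three binary nodes are excluded, following the source test's
scope): networks per group by EBIC glasso, null distribution by pooling
rows and re-splitting into the original group sizes with full re-estimation
per permutation. It reports the global-strength difference test, the
structure-invariance test (maximum absolute edge difference), and per-edge
differences with Holm correction (uncorrected p also emitted). P-values use
the +1 convention and so lie in (0, 1]; the test is bit-reproducible under
a fixed seed and symmetric in its group labels (enforced by a canonical
internal ordering of the groups). Waves share participants, but the
permutation scheme treats groups as independent — the published test
supports nothing else — and a warning flags overlapping ids. The package
runs the four reported pairs (T1,T4), (T1,T2), (T2,T3), (T3,T4) via
`nct_pairwise_schedule()`. `hybrid_difference_report()` reproduces the
hybrid reporting convention: significance from the continuous-network test,
displayed magnitudes from the mixed networks, with |difference| < 0.15
kept in machine output but left off the display list. Inside the test the
glasso path is shortened to 30 penalties (the selection is insensitive to
the denser path at these sizes, and the permutation loop re-estimates
hundreds of networks).

## Trend models

`fit_gee_trend()` solves the generalized estimating equations for an
intercept + time model (waves coded 1–4, equally spaced, matching the
"per subsequent time-point" reading even though the calendar gap between
the first two waves is a year), clustered on participant, with an
exchangeable working correlation by default (independence available; with
independence the point estimates equal pooled regression, which is tested)
and robust sandwich covariance with Wald inference. Binomial outcomes are
reported as odds ratios per wave with exp-transformed intervals; gaussian
outcomes as the per-wave coefficient. The solver is written in the package
(no GEE library is required) and reduces exactly to `glm` when every
cluster has one observation. `trend_sensitivity_all_predictors()` fits the
multivariable logistic GEE of PrEP (or VLS) on time plus all other roster
nodes, flagging |coefficient| > 10 as separation.

## Pipeline and determinism

`run_full_study()` executes the stages in the analysis order behind a
validated `study_config()`, writing every stage's outputs (CSV / JSON /
GraphML) before the next begins and recording a manifest with versions,
stage seeds and wall times. Stage seeds derive from the master seed by a
stable polynomial hash of the stage name (`stage_seed()`), so adding a
stage never shifts earlier stages' randomness; identical configs produce
byte-identical outputs apart from manifest timings. The CAS sensitivity
stage re-estimates the latest wave on the CAS-reporting subset and tests
structure invariance of full wave vs subset, aborting below 50 rows.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run everything at sizes a desk
machine handles comfortably, chosen as this package's own trade-off between
Monte-Carlo error and turnaround: recovery at $n = 5000$ over 50 seeds
(10 seeds in the script), comparison-test calibration with 250 null
replicates of 200 permutations each at $p = 8$, $n = 300$ per group
(100 in the script), bootstrap coverage with 100 outer replicates of
$B = 300$ (30 in the script), GEE recovery with 200 replicates at the
cohort's $n = 632$, and a full simulated-cohort run with 250 permutations
per wave pair. Bootstrap and community defaults (B = 1000 style runs)
remain available through the function arguments.

## Known limitations

* The generator plants a single network per wave; it does not model
  response styles, item-level measurement error beyond the MRF, or
  informative attrition — passing tests show the pipeline recovers MRF
  structure, not that real questionnaire data satisfy an MRF.
* Edge weights involving binary nodes mix logistic and linear coefficient
  scales; their average is a conventional, not canonical, quantity, so
  cross-family weights are comparable within this package but not across
  estimators.
* The comparison test's independent-groups permutation ignores the overlap
  of participants across waves; with strong within-person correlation its
  type-I error on overlapping waves is conservative rather than exact.
* No ordinal-specific machinery (polychoric correlations, ordinal
  reliability) and no categorical nodes beyond binary.
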