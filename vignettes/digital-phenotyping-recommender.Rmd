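---
title: "Profiling and exercise recommendation from digital-phenotyping data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling and exercise recommendation from digital-phenotyping data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The setting

`phenorec` implements the analysis pipeline of a chatbot-based
psychological well-being program. Participants in a one-month trial
answer a baseline questionnaire (demographics, behavioral-addiction and
well-being items) and then interact with a chatbot that prompts them
twice a day with an ecological momentary assessment (EMA) of mood on a
0–10 scale, walks a scripted decision tree driven by their answers, and
proposes one of 17 positive-psychology / CBT exercises at each leaf.
After an exercise the participant rates its usefulness (0–4) and their
current life satisfaction (0–5).

The statistical problem is a small-n, large-p one: roughly 81
participants described by 130 post-encoding features. Direct supervised
fitting of an exercise-utility function on 130 features is hopeless at
that sample size, so the pipeline takes the unsupervised route:

1. encode everything into a numeric, unit-scaled, expert-weighted
   feature table;
2. form *soft* behavioral clusters under a weighted Manhattan metric;
3. explain the clusters with Shapley feature contributions;
4. recommend exercises by comparing each cluster's usefulness ratings
   with the cohort's, weighting clusters by the test participant's
   proximity to them.

Because no participant-level data ships with the package, a synthetic
cohort generator reproduces the statistical structure the analysis
assumes, and all tests run against it.

## The synthetic cohort generator

`generate_cohort()` plants four latent behavioral profiles with
cardinalities 19/16/24/22 in a cohort of 81. Each profile elevates a
small signature set of 0–4 ordinal items:

* profile 1 — online notifications, texting, insomnia, bad mood,
  neighborhood problems;
* profile 2 — online notifications, social media, attention problems,
  low energetic charge; young (age ~20);
* profile 3 — no behavioral signature at all: mostly workers, older
  (age ~30). A purely socio-demographic phenotype;
* profile 4 — obsessive thoughts, pain, attention problems, low
  energetic charge; mostly students.

**Effect size.** Signature items are shifted by 2.25 points on the 0–4
scale — three SDs of the default item dispersion (`noise_sd = 0.75`).
We first tried a two-SD shift; with ten behavioral items, sixty filler
habit items and thirty-one text-sentiment scores all contributing L1
noise, the planted partition was recovered at an adjusted Rand index of
only ~0.6 and was not reliably the silhouette optimum. Since the study
design this generator emulates *did* exhibit a clean four-cluster
silhouette structure, we fixed the shift at three SDs, which yields
ARI ≈ 0.95 and a silhouette-selected k = 4 across seeds. The shift is
absolute (not proportional to `noise_sd`), so `noise_sd` acts as a pure
separability dial: at `noise_sd = 0` every behavioral item, the age and
the occupation are deterministic functions of the profile and the
partition is perfectly recoverable (ARI = 1); larger values blur it.

**Calibrated marginals.** The cohort-level quantities a reader would
check first — the gender mix (62.1/35.6/2.3% female/male/no-answer),
mean baseline life satisfaction 3.06, mean endpoint satisfaction 4.1,
and countrywise composition — are drawn by randomly permuting a fixed
marginal histogram whose counts come from largest-remainder rounding of
the target proportions at n = 81. The seed decides *who* gets which
value, not how many of each there are, so these means are reproduced at
any seed up to integer rounding (e.g. the realized baseline mean is
248/81 ≈ 3.062). Usefulness ratings are instead i.i.d. draws from a
discrete 0–4 distribution with mean 3.77: with ≈3,900 rating events the
sampling error of the grand mean is under 0.01, so no histogram fixing
is needed.

**Well-being trajectory.** Each participant's life satisfaction drifts
linearly from their baseline value to their endpoint value over the 30
days; in-program satisfaction feedback adds N(0, 0.3) noise and rounds,
while the final end-of-program feedback reports the endpoint value
exactly. EMA mood is twice the current latent satisfaction plus a
profile-specific mood offset and N(0, 1.2) response noise, rounded into
0–10. Text answers are not generated: the NLP layer's numeric outputs
(emotion/polarity in [0,1]) are attached directly to EMA response
events, and 31 pre-aggregated sentiment scores sit in the baseline
table.

**Exercise preferences.** Each profile prefers half the catalogue
(alternating by exercise parity); preferred exercises are rated from a
mean-3.88 distribution and dispreferred ones from a mean-3.66
distribution, so the grand mean stays at 3.77 while clusters differ in
a way the recommender can exploit.

**Adherence.** Prompts are answered with probability 0.8 (a free
parameter; the emulated study does not report one), jittered by
participant; rates of exactly 0 or 1 are honored exactly so degenerate
configurations stay degenerate.

What the generator does *not* emulate: real EMA time-of-day and
weekday structure, attrition, item nonresponse, correlated measurement
error between questionnaire items, and any genuine text. Passing tests
therefore demonstrate that the pipeline recovers structure *of the kind
assumed*, not that it would recover structure from arbitrary real data.

## Preprocessing

`build_feature_table()` walks the feature schema in declared order and
produces a deterministic column layout:

* categorical features are one-hot encoded into exhaustive, exclusive
  indicators;
* numeric features are discretized at empirical quantiles (default five
  bins, matching the age bands 16–19, 20–22, 23–25, 26–32, 33+ used for
  reporting); intervals are right-closed so a value equal to an edge
  falls into the lower bin — a convention that must be fixed once for
  reproducibility;
* ordinal and text-derived features are min-max scaled to [0,1]; a
  constant column maps to all zeros;
* interaction aggregates (mean EMA, response count, mean usefulness,
  exercises completed, mean emotion/polarity) are computed per
  participant from the event log, with a configurable fill value for
  participants without matching events, then scaled.

Expert weights express feature importance in the Manhattan metric;
weight zero removes a feature entirely (expert feature selection). An
indicator block inherits its parent's weight divided by the number of
indicators, so a five-category feature does not get five votes where a
scaled ordinal gets one. Default weights: 3 for the profile-driving
features (behavioral items, age, occupation), 1 for baseline
satisfaction, 0.5 for the remaining demographics and the interaction
aggregates, 0.1 for filler items.

Missing values are disallowed in synthetic data; when reading external
data the validator (`validate_inputs()`) reports out-of-range and
referentially inconsistent rows instead of silently imputing.

## Clustering

The dissimilarity between participants x and y is the weighted
Manhattan distance d(x, y) = Σⱼ wⱼ |xⱼ − yⱼ|. `fit_kmeans_l1()` runs
Lloyd iterations under this metric. The centroid update is the
coordinate-wise *median* of the cluster members: the median minimizes
the absolute-deviation sum per coordinate, and the feature weights
factor out of each coordinate's minimization, so the plain member
median is exactly the weighted-L1-optimal update. (A mean update — the
textbook K-means step — does not descend this objective; it is kept
behind `centroid_update = "mean"` for comparison.) Restarts are seeded
with distance-proportional (k-means++-style) sampling under the same
metric; on small problems this makes a 10-restart ensemble find the
global optimum (verified against exhaustive partition search in the
test suite) in well over 95% of cases. Emptied clusters are re-seeded
at the point farthest from its current centroid. Convergence is
declared when the assignment vector stops changing, with a 300
iteration cap.

Soft membership follows the inverse-distance rule
mᶜ(x) = (1/(d_c + ε)) / Σ_c' (1/(d_c' + ε)) with ε = 1e−9; a point at
distance zero from one or more centroids has its membership spread
uniformly over exactly those clusters. Memberships are nonnegative, sum
to one, and their argmax reproduces the hard assignment.

The number of clusters is chosen by the silhouette method over
k ∈ {2, …, 8}, with silhouettes computed under the same weighted
metric; singleton clusters contribute width 0, ties go to the smaller
k, and an all-identical input raises an error rather than returning an
arbitrary k. Stability is assessed by refitting under perturbed expert
weight vectors and reporting pairwise adjusted Rand indices
(`cluster_stability()`; ARI via `mclust`).

## Shapley explanation

Cluster membership is explained as a cooperative game: the payoff of a
feature coalition S is the soft membership probability mᶜ(z) of the
explained cluster at the hybrid point z that takes x's values on S and
the training-table column medians elsewhere. Three choices matter:

* **the value function is the membership probability**, not the hard
  label, so a contribution reads as "how much this feature moves the
  probability of belonging to cluster c";
* **one-hot blocks are grouped as a single player** (their parent
  feature). Per-category attributions of an exhaustive indicator block
  are mutually constrained and uninterpretable one at a time; grouping
  yields one value for "age", one for "occupation", matching how the
  cluster summaries are read;
* **the background is the column-wise median** of the training table —
  the most typical participant in each coordinate.

Exact enumeration over all 2^p coalitions is used up to p = 15 grouped
players; beyond that the estimator is permutation sampling with
antithetic ordering pairs (each sampled ordering is paired with its
reverse; the Monte-Carlo SE is computed over pair means). Both modes
satisfy the efficiency axiom exactly — the contributions telescope to
mᶜ(x) − mᶜ(median) — and exact mode is verified in the tests against an
independent all-orderings oracle, symmetry and dummy axioms included.

`summarize_cluster_contributions()` averages the signed contributions
over each cluster's members and ranks features by absolute aggregate;
features below the display threshold (default 0.04) are omitted from
the printed summary, mirroring the convention of not displaying weak
features in cluster-summary figures. Because membership probabilities
of k ≈ 4 diffuse clusters move on a scale of a few hundredths, the
thresholded display is sparse; ranking, not magnitude, is the robust
output, and the planted-signature recovery test checks exactly that.

## Recommendation

For each exercise e, `fit_utility_stats()` computes the overall mean
ū_e and *population* SD σ_e of its 0–4 ratings plus per-cluster means
ū_{c,e}, aggregating by the participants' hard labels (the fitting-side
cluster assignment). For a test participant x:

* cluster weights ω_c = exp(−λ d_c), the negative exponential smoothing
  of x's centroid distances; λ defaults to 1 on the scaled distances
  and is configurable — larger λ approaches hard assignment to the
  nearest cluster;
* per-cluster score S_c(e) = (ū_{c,e} − ū_e) / σ_e, the normalized
  deviation of the cluster's usefulness distribution from the cohort's;
* expected utility U(e) = Σ_c ω_c S_c(e) / Σ_c ω_c, invariant under
  rescaling of the ω's.

Degenerate cases fall back to a score of 0 ("assume average
usefulness"): exercises unrated overall, exercises with σ_e = 0, and
clusters with fewer than `min_cluster_ratings` ratings for the
exercise. This keeps cold-start exercises recommendable rather than
excluded. Ranking ties break toward the smaller exercise id so reruns
are reproducible. The whole chain is checked against a from-scratch
brute-force recomputation on a six-participant toy problem at 1e−12.

## Numerical and testing choices

* All randomness flows through explicit integer seeds; a fixed
  configuration and seed reproduce every output file byte for byte
  (timestamps in the run manifest are deliberately absent).
* Silhouette-selection and profile-recovery properties are exercised at
  the default study size (81 × 130) over 20 seeds with 5–10 restarts
  per fit, sizes at which the full suite completes in a few minutes on
  one CPU.
* Exhaustive oracles run at deliberately tiny sizes: partition search
  at n ≤ 10, k ≤ 3; all-orderings Shapley at p ≤ 4; full 2^p
  enumeration at p = 8.

## Limitations

* The generator's four-profile structure is favorable by construction;
  the pipeline's behavior under weak or hierarchical cluster structure
  is exercised only through the `noise_sd` dial.
* Shapley sampling cost grows linearly in participants × permutations ×
  players; the default 50 permutations for 114 grouped players is a
  ranking-grade, not magnitude-grade, setting.
* The recommender assumes ratings missing completely at random within
  clusters; selection effects of the decision tree (low-mood
  participants see low-mood-branch exercises more often) are present in
  the synthetic data but not modeled in the scoring.
* With ~81 participants, per-cluster per-exercise rating counts are
  small; σ_e-normalized deviations are noisy, which is why the default
  keeps `min_cluster_ratings` low and treats scores as rankings rather
  than calibrated utilities.
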