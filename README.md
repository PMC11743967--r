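# phenorec

Behavioral profiling and personalized exercise recommendation from
digital-phenotyping data.

`phenorec` is an R package plus analysis workflow for chatbot-based
psychological well-being programs in which participants answer a
baseline questionnaire and then interact with a scripted chatbot:
twice-daily EMA mood prompts (0–10), decision-tree dialogues, proposed
well-being exercises from a 17-item catalogue, usefulness ratings (0–4)
and life-satisfaction ratings (0–5). It is aimed at researchers who
want to profile such a cohort and personalize exercise delivery when
the number of descriptive features (here 130) far exceeds the number of
participants (here 81), which rules out direct supervised fitting.

## Method

The pipeline is unsupervised-then-shallow-supervised:

1. **Encoding.** Mixed-type baseline data and variable-length
   interaction logs become a participants × features matrix in [0,1]:
   one-hot encoding for categoricals, empirical-quantile binning for
   numerics (age bands 16–19, 20–22, 23–25, 26–32, 33+), min–max
   scaling for ordinal items, and per-participant aggregation of the
   event log. Experts assign per-feature weights `w`; weight 0 removes
   a feature.
2. **Soft clustering.** Dissimilarity is the weighted Manhattan
   distance `d(x, y) = Σⱼ wⱼ |xⱼ − yⱼ|`. K-medians (Lloyd iterations
   with coordinate-median updates, k-means++-style seeding, best of
   `n_init` restarts) minimizes the within-cluster L1 objective; k is
   chosen by the silhouette method over k ∈ {2..8}. Membership is soft:
   `m_c(x) ∝ 1/(d_c + ε)`, normalized over clusters.
3. **Explanation.** Shapley values attribute `m_c(x)` to (grouped)
   features against a column-median background — exact coalition
   enumeration up to 15 players, antithetic permutation sampling above
   that. Per-cluster summaries average signed contributions over
   members (display threshold 0.04).
4. **Recommendation.** For exercise e and cluster c the score is the
   normalized utility deviation `S_c(e) = (ū_{c,e} − ū_e)/σ_e`; a test
   participant's cluster weights are `ω_c = exp(−λ d_c)`; the expected
   utility `U(e) = Σ_c ω_c S_c(e) / Σ_c ω_c` ranks the catalogue.

Because participant-level trial data is not distributable, the package
includes a first-class synthetic cohort generator
(`generate_cohort()`, `simulate_sessions()`) that plants four
behavioral profiles (19/16/24/22 members) and calibrates the
cohort-level marginals — 62.1% female, mean baseline satisfaction 3.06,
mean endpoint satisfaction 4.1, mean exercise usefulness 3.77 — so the
full pipeline is testable end to end. See the vignette
(`vignettes/digital-phenotyping-recommender.Rmd`) for the design and
its limitations.

## Worked example

```r
library(phenorec)

cfg    <- cohort_config(seed = 1)          # 81 participants, 4 profiles
cohort <- generate_cohort(cfg)
events <- simulate_sessions(cohort, config = cfg, seed = 2)

ft <- build_feature_table(cohort, events)  # default 130-column schema
ft
#> feature_table: 81 participants x 130 columns ( 114 features )

sel <- select_k_silhouette(ft, 2:8, n_init = 5, seed = 3)
sel$profile
#>  k silhouette
#>  2  0.2495307
#>  3  0.2463753
#>  4  0.2716302
#>  5  0.2170219
#>  6  0.1587503
#>  7  0.1596749
#>  8  0.1207466

model <- sel$model                         # k = 4 maximizes the silhouette
model
#> cluster_model: k = 4 | n = 81 | weighted-L1 objective = 640.166
#> cluster sizes: 16/24/19/22

stats <- fit_utility_stats(events_to_utility_records(events), model,
                           recommender_config(n_exercises = 17))
rank_exercises(ft$values[1, ], model, stats)
#> recommendation_ranking: top 5 of 17 exercises
#>  exercise_id expected_utility rank
#>           15        0.3782466    1
#>            5        0.2837394    2
#>            9        0.2706524    3
#>  ...
```

The silhouette profile peaks at k = 4, the planted number of profiles;
cluster sizes approximately recover the planted 19/16/24/22 split (ARI
≈ 0.94 against the latent labels). The ranking says that, for this
participant, exercise 15 is rated about 0.38 overall-SD units more
useful by the clusters the participant resembles than by the cohort at
large, making it the top recommendation.

The same steps, with narrative and saved tables, live in the numbered
drivers `analysis/01_simulate.R` … `analysis/05_recommend.R`, which
write their outputs under `results/`.

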