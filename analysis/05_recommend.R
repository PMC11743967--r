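#!/usr/bin/env Rscript
# Step 5 — rank the exercise catalogue for a held-out test participant.
#
# Fits the per-exercise utility statistics (overall and per-cluster mean
# usefulness), then scores each exercise for a new participant by the
# cluster-weighted normalized utility deviation: cluster weights are a
# negative exponential of the participant's distance to each centroid,
# and an exercise's score in a cluster is (cluster mean - overall mean) /
# overall SD of its ratings.

suppressPackageStartupMessages(library(phenorec))

ft <- read_feature_table("results/feature_table.csv")
model <- read_cluster_model("results/cluster_model.json")
raw <- read_cohort("results/cohort")

stats <- fit_utility_stats(events_to_utility_records(raw$events), model,
                           recommender_config(n_exercises = 17))
write_utility_stats(stats, "results/utility_stats.json")

# held-out test participant: simulate a fresh baseline row from a profile-4
# style configuration and embed it with the training encoders
test_cfg <- cohort_config(n_participants = 1L, profile_sizes = 1L,
                          seed = 99L)
test_row <- generate_cohort(test_cfg)
test_row$latent_profile <- 4
x <- encode_participant(ft, test_row)

ranking <- rank_exercises(x, model, stats,
                          recommender_config(lambda = 1, n_exercises = 17))
cat("normalized cluster weights:",
    paste(sprintf("%.3f", ranking$weights), collapse = " "), "\n")
print(ranking, n = 17)
write.csv(ranking$ranking, "results/test_participant_ranking.csv",
          row.names = FALSE)

# per-cohort-participant rankings (top choice per participant)
top <- vapply(seq_along(ft$participant_ids), function(i) {
  rank_exercises(ft$values[i, ], model, stats,
                 recommender_config(n_exercises = 17))$ranking$exercise_id[1]
}, numeric(1))
cat("distribution of top-ranked exercise over the cohort:\n")
print(table(top))
write.csv(data.frame(participant_id = ft$participant_ids, top_exercise = top),
          "results/cohort_top_exercises.csv", row.names = FALSE)
cat("wrote results/utility_stats.json, test_participant_ranking.csv,",
    "cohort_top_exercises.csv\n")
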