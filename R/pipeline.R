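# End-to-end orchestration: generate -> preprocess -> cluster -> explain
# -> recommend, with a deterministic run manifest.

#' Assemble a full pipeline configuration
#'
#' @param cohort a [cohort_config()].
#' @param schema feature schema (list of [feature_spec()]).
#' @param k_grid candidate cluster counts for silhouette selection; a
#'   single value forces that k.
#' @param n_init K-medians restarts.
#' @param explain_mode,n_samples Shapley mode and permutation count.
#' @param threshold display threshold for the cluster summaries.
#' @param recommender a [recommender_config()].
#' @param seed master seed propagated to every stochastic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            schema = default_feature_schema(),
                            k_grid = 2:8, n_init = 10L,
                            explain_mode = "sampling", n_samples = 50L,
                            threshold = 0.04,
                            recommender = recommender_config(
                              n_exercises = cohort$n_exercises),
                            seed = cohort$seed) {
  structure(list(cohort = cohort, schema = schema, k_grid = k_grid,
                 n_init = as.integer(n_init), explain_mode = explain_mode,
                 n_samples = as.integer(n_samples), threshold = threshold,
                 recommender = recommender, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Generates the synthetic cohort and interaction logs, builds the
#' weighted feature table, selects k by silhouette (or fits the forced k),
#' fits the soft clustering, computes Shapley cluster summaries, fits the
#' utility statistics, and ranks the catalogue for every participant. All
#' artifacts are written under `output_dir` together with a manifest that
#' records the seed and output files (no wall-clock fields, so reruns
#' with the same config are byte-identical).
#'
#' @param config a [pipeline_config()].
#' @param output_dir directory for the report bundle.
#' @param write_figure if TRUE and ggplot2 is installed, also writes a
#'   stacked-bar contribution chart (a non-deterministic binary artifact,
#'   excluded from the manifest).
#' @return invisibly, a list with the in-memory stage results (`cohort`,
#'   `events`, `ft`, `selection`, `model`, `summaries`, `stats`,
#'   `rankings`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir,
                         write_figure = FALSE) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cohort <- stage("generate", generate_cohort(config$cohort))
  events <- stage("simulate", simulate_sessions(
    cohort, config = config$cohort, seed = config$seed + 1L))
  paths <- write_cohort(cohort, events, output_dir)

  ft <- stage("preprocess",
              build_feature_table(cohort, events, config$schema))
  ft_path <- file.path(output_dir, "feature_table.csv")
  write_feature_table(ft, ft_path)

  selection <- stage("cluster", {
    if (length(config$k_grid) == 1) {
      model <- fit_kmeans_l1(ft, config$k_grid, n_init = config$n_init,
                             seed = config$seed + 2L)
      sil <- silhouette_l1(ft$values, model$hard_labels, ft$weights)$mean
      list(k = config$k_grid,
           profile = data.frame(k = config$k_grid, silhouette = sil),
           model = model)
    } else {
      select_k_silhouette(ft, config$k_grid, n_init = config$n_init,
                          seed = config$seed + 2L)
    }
  })
  model <- selection$model
  write_cluster_model(model, file.path(output_dir, "cluster_model.json"))
  utils::write.csv(selection$profile,
                   file.path(output_dir, "silhouette_profile.csv"),
                   row.names = FALSE)

  summaries <- stage("explain", {
    explanations <- explain_cohort(ft, model, mode = config$explain_mode,
                                   n_samples = config$n_samples,
                                   seed = config$seed + 3L)
    summarize_cluster_contributions(explanations, model,
                                    threshold = config$threshold)
  })
  summary_df <- summary_to_table(summaries)
  utils::write.csv(summary_df,
                   file.path(output_dir, "cluster_summaries.csv"),
                   row.names = FALSE)
  if (write_figure && requireNamespace("ggplot2", quietly = TRUE)) {
    fig <- plot_cluster_contributions(summaries)
    ggplot2::ggsave(file.path(output_dir, "cluster_contributions.png"),
                    fig, width = 7, height = 4, dpi = 150)
  }

  stats <- stage("recommend", fit_utility_stats(
    events_to_utility_records(events), model, config$recommender))
  write_utility_stats(stats, file.path(output_dir, "utility_stats.json"))
  rankings <- do.call(rbind, lapply(seq_along(ft$participant_ids),
    function(i) {
      r <- rank_exercises(ft$values[i, ], model, stats,
                          config$recommender)$ranking
      cbind(data.frame(participant_id = ft$participant_ids[i]), r)
    }))
  utils::write.csv(rankings, file.path(output_dir, "rankings.csv"),
                   row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("phenorec")),
    seed = config$seed,
    n_participants = config$cohort$n_participants,
    n_features = ncol(ft$values),
    selected_k = selection$k,
    files = c("baseline.csv", "events.jsonl", "feature_table.csv",
              "feature_table.csv.meta.json", "cluster_model.json",
              "silhouette_profile.csv", "cluster_summaries.csv",
              "utility_stats.json", "rankings.csv")
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, events = events, ft = ft,
                 selection = selection, model = model,
                 summaries = summaries, stats = stats,
                 rankings = rankings, manifest = manifest,
                 paths = paths))
}

#' Write a cohort configuration as YAML
#'
#' @param config a [cohort_config()].
#' @param path YAML file path.
#' @return invisibly, `path`.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a cohort configuration from YAML
#'
#' Unknown fields are rejected; the result is validated like any other
#' [cohort_config()].
#'
#' @param path YAML file path.
#' @return a `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown cohort configuration field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(cohort_config, raw)
}

#' Validate raw input files
#'
#' Schema and range checks for a baseline CSV and a JSON-lines event log:
#' EMA values in 0--10, usefulness in 0--4, satisfaction in 0--5, known
#' event kinds, and referential integrity (every event participant present
#' in the baseline table). Violations are reported with row numbers.
#'
#' @param baseline_path baseline CSV path.
#' @param events_path JSON-lines event log path.
#' @return data.frame of violations (`file`, `row`, `problem`); zero rows
#'   means the inputs are clean.
#' @export
validate_inputs <- function(baseline_path, events_path) {
  violations <- list()
  flag <- function(file, row, problem) {
    violations[[length(violations) + 1]] <<-
      data.frame(file = file, row = row, problem = problem,
                 stringsAsFactors = FALSE)
  }

  baseline <- utils::read.csv(baseline_path, stringsAsFactors = FALSE)
  if (!"participant_id" %in% names(baseline)) {
    flag("baseline", NA, "missing participant_id column")
  }
  if ("baseline_wellbeing" %in% names(baseline)) {
    bad <- which(baseline$baseline_wellbeing < 0 |
                   baseline$baseline_wellbeing > 5)
    for (r in bad) flag("baseline", r, "baseline_wellbeing outside 0-5")
  }
  dup <- which(duplicated(baseline$participant_id))
  for (r in dup) flag("baseline", r, "duplicate participant_id")

  events <- read_events(events_path)
  kinds <- c("ema_prompt", "ema_response", "tree_step",
             "exercise_proposed", "exercise_feedback",
             "satisfaction_feedback")
  check_range <- function(col, lo, hi) {
    bad <- which(!is.na(events[[col]]) &
                   (events[[col]] < lo | events[[col]] > hi))
    for (r in bad) {
      flag("events", r, paste0(col, " outside ", lo, "-", hi))
    }
  }
  check_range("ema_value", 0, 10)
  check_range("usefulness", 0, 4)
  check_range("satisfaction", 0, 5)
  bad_kind <- which(!events$event_kind %in% kinds)
  for (r in bad_kind) flag("events", r, "unknown event_kind")
  no_ex <- which(events$event_kind == "exercise_feedback" &
                   is.na(events$exercise_id))
  for (r in no_ex) flag("events", r, "exercise_feedback without exercise_id")
  unknown <- which(!events$participant_id %in% baseline$participant_id)
  for (r in unknown) {
    flag("events", r, "participant not present in baseline table")
  }

  if (length(violations) == 0) {
    return(data.frame(file = character(0), row = integer(0),
                      problem = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, violations)
  rownames(out) <- NULL
  out
}
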