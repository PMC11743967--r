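# Exercise recommendation: cluster-level normalized utility deviations,
# negative-exponential distance weighting, and expected-utility ranking.

#' Recommender configuration
#'
#' @param lambda rate of the negative exponential smoothing that converts
#'   centroid distances into cluster weights (`omega_c = exp(-lambda *
#'   d_c)`); larger values concentrate weight on the nearest cluster.
#' @param min_cluster_ratings minimum number of ratings a cluster must
#'   have for an exercise before its deviation score counts (otherwise the
#'   score falls back to 0, i.e. "no evidence of deviation").
#' @param n_exercises catalogue size.
#' @return list of class `recommender_config`.
#' @export
recommender_config <- function(lambda = 1.0, min_cluster_ratings = 1L,
                               n_exercises = 17L) {
  stopifnot(lambda > 0, min_cluster_ratings >= 0, n_exercises >= 1)
  structure(list(lambda = lambda,
                 min_cluster_ratings = as.integer(min_cluster_ratings),
                 n_exercises = as.integer(n_exercises)),
            class = "recommender_config")
}

#' Aggregate usefulness ratings overall and per cluster
#'
#' For each exercise: the overall mean and population standard deviation
#' of its 0--4 usefulness ratings, and the per-cluster means and rating
#' counts, with clusters taken from the participants' hard labels.
#' Exercises with no ratings are flagged unrated.
#'
#' @param records data.frame with `participant_id`, `exercise_id`,
#'   `usefulness` (see [events_to_utility_records()]).
#' @param model a `cluster_model` fitted on the same cohort.
#' @param config a [recommender_config()].
#' @return object of class `utility_stats`: `overall` (data.frame per
#'   exercise: mean, sd, n, rated), `cluster_mean` and `cluster_n`
#'   (k x n_exercises matrices).
#' @export
fit_utility_stats <- function(records, model,
                              config = recommender_config()) {
  stopifnot(is.data.frame(records))
  if (nrow(records) > 0) {
    bad <- !(records$usefulness %in% 0:4)
    if (any(bad)) {
      stop("usefulness ratings outside 0-4 at record(s) ",
           paste(utils::head(which(bad), 5), collapse = ", "),
           call. = FALSE)
    }
    unknown <- setdiff(unique(records$participant_id),
                       model$participant_ids)
    if (length(unknown) > 0) {
      stop("utility records reference participants unknown to the ",
           "cluster model: ", paste(utils::head(unknown, 5),
                                    collapse = ", "), call. = FALSE)
    }
    bad_ex <- records$exercise_id < 1 |
      records$exercise_id > config$n_exercises
    if (any(bad_ex)) {
      stop("exercise_id outside the catalogue 1..", config$n_exercises,
           call. = FALSE)
    }
  }
  ne <- config$n_exercises
  k <- model$k
  overall <- data.frame(exercise_id = seq_len(ne), mean = NA_real_,
                        sd = NA_real_, n = 0L, rated = FALSE)
  cluster_mean <- matrix(NA_real_, k, ne)
  cluster_n <- matrix(0L, k, ne)
  if (nrow(records) > 0) {
    cl <- model$hard_labels[match(records$participant_id,
                                  model$participant_ids)]
    for (e in seq_len(ne)) {
      u <- records$usefulness[records$exercise_id == e]
      if (length(u) == 0) next
      overall$mean[e] <- mean(u)
      overall$sd[e] <- sqrt(mean((u - mean(u))^2)) # population SD
      overall$n[e] <- length(u)
      overall$rated[e] <- TRUE
      for (c_i in seq_len(k)) {
        uc <- records$usefulness[records$exercise_id == e & cl == c_i]
        cluster_n[c_i, e] <- length(uc)
        if (length(uc) > 0) cluster_mean[c_i, e] <- mean(uc)
      }
    }
  }
  structure(list(overall = overall, cluster_mean = cluster_mean,
                 cluster_n = cluster_n, k = k, n_exercises = ne),
            class = "utility_stats")
}

#' Cluster weights for a test participant
#'
#' Converts the participant's weighted Manhattan distances to the cluster
#' centroids into cluster weights by negative exponential smoothing:
#' `omega_c = exp(-lambda * d_c)`, so nearer clusters weigh more.
#'
#' @param x feature vector in the model's column space.
#' @param model a `cluster_model`.
#' @param config a [recommender_config()].
#' @return list with `raw` (exp(-lambda d)), `normalized` (summing to 1),
#'   and `distances`.
#' @export
cluster_weights <- function(x, model, config = recommender_config()) {
  d <- drop(dist_to_centroids(matrix(x, nrow = 1), model$centroids,
                              model$weights_used))
  raw <- exp(-config$lambda * d)
  list(raw = raw, normalized = raw / sum(raw), distances = d)
}

#' Normalized utility-deviation score of an exercise for a cluster
#'
#' `S_c(e) = (mean_{c,e} - mean_e) / sd_e`: how much more (or less) useful
#' cluster c found exercise e than the cohort did, in units of the
#' exercise's overall rating spread. Returns 0 when the exercise is
#' unrated overall, when its overall SD is 0, or when the cluster has
#' fewer than `min_cluster_ratings` ratings for it (fallback to "average
#' usefulness", keeping cold-start exercises recommendable).
#'
#' @param e exercise id.
#' @param c_i cluster index.
#' @param stats a `utility_stats`.
#' @param config a [recommender_config()].
#' @return scalar score.
#' @export
exercise_score <- function(e, c_i, stats, config = recommender_config()) {
  if (e < 1 || e > stats$n_exercises) {
    stop("exercise ", e, " is outside the catalogue 1..",
         stats$n_exercises, call. = FALSE)
  }
  ov <- stats$overall[e, ]
  if (!ov$rated || ov$sd == 0) return(0)
  if (stats$cluster_n[c_i, e] < config$min_cluster_ratings) return(0)
  (stats$cluster_mean[c_i, e] - ov$mean) / ov$sd
}

#' Rank the exercise catalogue for a test participant
#'
#' Expected utility of exercise e:
#' `U(e) = sum_c omega_c S_c(e) / sum_c omega_c`, with cluster weights
#' `omega` from [cluster_weights()] and per-cluster deviation scores from
#' [exercise_score()]. Exercises are ranked by decreasing expected
#' utility; ties break deterministically toward the smaller exercise id.
#'
#' @param x feature vector of the test participant.
#' @param model a `cluster_model`.
#' @param stats a `utility_stats` fitted on the same cohort.
#' @param config a [recommender_config()].
#' @return object of class `recommendation_ranking`: `ranking`
#'   (data.frame `exercise_id`, `expected_utility`, `rank`, sorted by
#'   rank) and `weights` (the normalized cluster weights used).
#' @export
rank_exercises <- function(x, model, stats,
                           config = recommender_config()) {
  stopifnot(stats$n_exercises >= 1)
  w <- cluster_weights(x, model, config)
  scores <- vapply(seq_len(stats$n_exercises), function(e) {
    s_c <- vapply(seq_len(model$k), function(c_i) {
      exercise_score(e, c_i, stats, config)
    }, numeric(1))
    sum(w$raw * s_c) / sum(w$raw)
  }, numeric(1))
  ord <- order(-scores, seq_along(scores))
  ranking <- data.frame(exercise_id = ord,
                        expected_utility = scores[ord],
                        rank = seq_along(ord))
  structure(list(ranking = ranking, weights = w$normalized,
                 raw_weights = w$raw),
            class = "recommendation_ranking")
}

#' @export
print.recommendation_ranking <- function(x, n = 5, ...) {
  cat("recommendation_ranking: top", n, "of", nrow(x$ranking),
      "exercises\n")
  print(utils::head(x$ranking, n), row.names = FALSE)
  invisible(x)
}

#' Serialize utility statistics to JSON
#'
#' @param stats a `utility_stats`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_utility_stats <- function(stats, path) {
  payload <- list(overall = stats$overall,
                  cluster_mean = unclass(as.data.frame(stats$cluster_mean)),
                  cluster_n = unclass(as.data.frame(stats$cluster_n)),
                  k = stats$k, n_exercises = stats$n_exercises)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read utility statistics written by [write_utility_stats()]
#'
#' @param path JSON path.
#' @return a `utility_stats`.
#' @export
read_utility_stats <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cm <- as.matrix(as.data.frame(p$cluster_mean))
  cn <- as.matrix(as.data.frame(p$cluster_n))
  dimnames(cm) <- dimnames(cn) <- NULL
  structure(list(overall = as.data.frame(p$overall), cluster_mean = cm,
                 cluster_n = cn, k = as.integer(p$k),
                 n_exercises = as.integer(p$n_exercises)),
            class = "utility_stats")
}
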