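# Chatbot session simulation: EMA prompts, decision-tree walks, exercise
# proposals and feedback events.

#' Build a chatbot decision tree
#'
#' The scripted dialogue starts from the EMA mood answer (0--10), branches
#' into mood bands, asks one follow-up question per band, and ends in a
#' leaf that triggers one exercise from the catalogue. Leaves partition the
#' catalogue so every exercise is reachable.
#'
#' @param n_exercises number of exercises the leaves must cover.
#' @return list of class `decision_tree` with `breaks` (upper EMA bounds of
#'   the mood bands), `branches` (leaf ids per band) and `leaves` (named
#'   map leaf id -> exercise id).
#' @export
decision_tree <- function(n_exercises = 17L) {
  n_exercises <- as.integer(n_exercises)
  stopifnot(n_exercises >= 1)
  n_branches <- min(4L, n_exercises)
  per_branch <- largest_remainder(n_exercises, rep(1, n_branches))
  leaf_ids <- sprintf("leaf_%02d", seq_len(n_exercises))
  leaves <- stats::setNames(seq_len(n_exercises), leaf_ids)
  splits <- cumsum(per_branch)
  branches <- lapply(seq_len(n_branches), function(b) {
    from <- if (b == 1) 1L else splits[b - 1] + 1L
    list(id = sprintf("branch_%d", b),
         question = sprintf("follow_up_%d", b),
         leaf_ids = leaf_ids[from:splits[b]])
  })
  names(branches) <- vapply(branches, `[[`, character(1), "id")
  tree <- list(
    breaks = switch(as.character(n_branches),
                    "1" = numeric(0), "2" = 5, "3" = c(3, 7), c(2, 5, 8)),
    branches = branches,
    leaves = leaves
  )
  class(tree) <- "decision_tree"
  tree
}

#' Validate a decision tree against an exercise catalogue
#'
#' @param tree a [decision_tree()].
#' @param n_exercises catalogue size.
#' @return the tree, invisibly; errors on a leaf referencing an unknown
#'   exercise or a branch referencing an unknown leaf.
#' @export
validate_tree <- function(tree, n_exercises) {
  bad <- tree$leaves[tree$leaves < 1 | tree$leaves > n_exercises]
  if (length(bad) > 0) {
    stop("decision tree leaf maps to unknown exercise id: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  referenced <- unlist(lapply(tree$branches, `[[`, "leaf_ids"))
  unknown <- setdiff(referenced, names(tree$leaves))
  if (length(unknown) > 0) {
    stop("decision tree branch references unknown leaf: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  invisible(tree)
}

event_columns <- function() {
  c("participant_id", "timestamp", "event_kind", "ema_value", "tree_node",
    "exercise_id", "usefulness", "satisfaction", "emotion", "polarity")
}

#' Simulate chatbot interaction logs for a cohort
#'
#' Emits, per participant, `trial_days * prompts_per_day` EMA prompt events.
#' Each answered prompt produces an EMA response (with attached NLP-derived
#' emotion/polarity scores in \[0,1\]), a root-to-leaf decision-tree walk,
#' an exercise proposal, a usefulness rating (0--4) and an in-program life
#' satisfaction rating (0--5). A final satisfaction event at the end of the
#' program carries each participant's endpoint value. Life satisfaction
#' drifts linearly from the participant's baseline to their endpoint;
#' baseline and endpoint marginals are calibrated to the configured means.
#'
#' @param cohort baseline table from [generate_cohort()].
#' @param tree a [decision_tree()]; defaults to the catalogue-sized tree.
#' @param config the [cohort_config()] used for the cohort.
#' @param seed seed for the session-level randomness.
#' @return data.frame of events (one row per event) with ISO-8601
#'   timestamps; unused fields are NA.
#' @export
simulate_sessions <- function(cohort, tree = NULL, config = cohort_config(),
                              seed = config$seed + 1L) {
  stopifnot(nrow(cohort) >= 1)
  if (is.null(tree)) tree <- decision_tree(config$n_exercises)
  validate_tree(tree, config$n_exercises)
  set.seed(seed)
  n <- nrow(cohort)
  t_dial <- min(config$noise_sd / 0.75, 1)
  n_prompts <- config$trial_days * config$prompts_per_day
  prompt_hours <- round(seq(9, 20, length.out = max(config$prompts_per_day, 1)))
  mood_shift <- c(-1.2, -0.4, 0, -0.6)
  start <- as.Date(config$start_date)

  endpoint <- draw_calibrated(
    n, satisfaction_probs(config$wellbeing_final_mean), 0:5)

  u_hi <- usefulness_probs(config$usefulness_mean, "hi")
  u_lo <- usefulness_probs(config$usefulness_mean, "lo")

  acc <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- cohort$participant_id[i]
    profile <- cohort$latent_profile[i]
    s0 <- cohort$baseline_wellbeing[i]
    s1 <- endpoint[i]
    # per-participant adherence jitter; exact rates 0 and 1 stay exact
    rate <- if (config$response_rate %in% c(0, 1)) config$response_rate else
      clamp(config$response_rate + stats::rnorm(1, 0, 0.05 * t_dial), 0, 1)
    n_resp <- round(n_prompts * rate)
    resp_idx <- if (n_resp > 0) sort(sample.int(n_prompts, n_resp)) else
      integer(0)

    rows <- list()
    add <- function(kind, ts, ema = NA_real_, node = NA_character_,
                    ex = NA_real_, use = NA_real_, sat = NA_real_,
                    emo = NA_real_, pol = NA_real_) {
      rows[[length(rows) + 1]] <<- list(
        participant_id = pid, timestamp = ts, event_kind = kind,
        ema_value = ema, tree_node = node, exercise_id = ex,
        usefulness = use, satisfaction = sat, emotion = emo, polarity = pol)
    }
    ts_at <- function(day, hour, minute) {
      sprintf("%sT%02d:%02d:00", format(start + (day - 1), "%Y-%m-%d"),
              hour, minute)
    }

    for (p in seq_len(n_prompts)) {
      day <- (p - 1) %/% config$prompts_per_day + 1
      slot <- (p - 1) %% config$prompts_per_day + 1
      hh <- prompt_hours[slot]
      add("ema_prompt", ts_at(day, hh, 0))
      if (!(p %in% resp_idx)) next

      s_d <- s0 + (s1 - s0) * day / config$trial_days
      ema <- round(clamp(2 * s_d + mood_shift[min(profile, 4)] +
                           stats::rnorm(1, 0, 1.2), 0, 10))
      emo <- round(clamp(ema / 10 + stats::rnorm(1, 0, 0.1 * t_dial), 0, 1), 4)
      pol <- round(clamp(ema / 10 - 0.05 + stats::rnorm(1, 0, 0.1 * t_dial),
                         0, 1), 4)
      add("ema_response", ts_at(day, hh, 1), ema = ema, emo = emo, pol = pol)
      add("tree_step", ts_at(day, hh, 2), node = "root", ema = ema)

      branch_idx <- findInterval(ema, tree$breaks + 1) + 1
      branch <- tree$branches[[branch_idx]]
      add("tree_step", ts_at(day, hh, 3), node = branch$id)
      leaf <- branch$leaf_ids[sample.int(length(branch$leaf_ids), 1)]
      ex <- unname(tree$leaves[leaf])
      add("exercise_proposed", ts_at(day, hh, 4), node = leaf, ex = ex)

      preferred <- ((ex + profile) %% 2) == 0
      u <- sample(0:4, 1, prob = if (preferred) u_hi else u_lo)
      add("exercise_feedback", ts_at(day, hh, 10), ex = ex, use = u)
      sat <- round(clamp(s_d + stats::rnorm(1, 0, 0.3), 0, 5))
      add("satisfaction_feedback", ts_at(day, hh, 11), sat = sat)
    }
    add("satisfaction_feedback", ts_at(config$trial_days, 21, 0), sat = s1)

    acc[[i]] <- rows
  }

  rows <- unlist(acc, recursive = FALSE)
  ev <- data.frame(
    participant_id = vapply(rows, `[[`, character(1), "participant_id"),
    timestamp = vapply(rows, `[[`, character(1), "timestamp"),
    event_kind = vapply(rows, `[[`, character(1), "event_kind"),
    ema_value = vapply(rows, `[[`, numeric(1), "ema_value"),
    tree_node = vapply(rows, `[[`, character(1), "tree_node"),
    exercise_id = vapply(rows, `[[`, numeric(1), "exercise_id"),
    usefulness = vapply(rows, `[[`, numeric(1), "usefulness"),
    satisfaction = vapply(rows, `[[`, numeric(1), "satisfaction"),
    emotion = vapply(rows, `[[`, numeric(1), "emotion"),
    polarity = vapply(rows, `[[`, numeric(1), "polarity"),
    stringsAsFactors = FALSE
  )
  rownames(ev) <- NULL
  ev
}

#' Extract usefulness rating records from an event log
#'
#' @param events event data.frame from [simulate_sessions()] or
#'   [read_events()].
#' @return data.frame with `participant_id`, `exercise_id`, `usefulness`.
#' @export
events_to_utility_records <- function(events) {
  fb <- events[events$event_kind == "exercise_feedback", , drop = FALSE]
  out <- data.frame(participant_id = fb$participant_id,
                    exercise_id = fb$exercise_id,
                    usefulness = fb$usefulness,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a cohort and its event log to disk
#'
#' Baseline table as a UTF-8 CSV with header; events as JSON-lines, one
#' event object per line with NA fields omitted. Both round-trip losslessly
#' through [read_cohort()] / [read_events()].
#'
#' @param cohort baseline data.frame.
#' @param events event data.frame.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written (`baseline`, `events`).
#' @export
write_cohort <- function(cohort, events, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  baseline_path <- file.path(dir, "baseline.csv")
  events_path <- file.path(dir, "events.jsonl")
  utils::write.csv(cohort, baseline_path, row.names = FALSE)
  write_events(events, events_path)
  invisible(list(baseline = baseline_path, events = events_path))
}

#' @rdname write_cohort
#' @param path JSON-lines file path.
#' @export
write_events <- function(events, path) {
  lines <- vapply(seq_len(nrow(events)), function(i) {
    row <- as.list(events[i, , drop = FALSE])
    row <- row[!vapply(row, function(v) is.na(v), logical(1))]
    as.character(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a cohort baseline table written by [write_cohort()]
#'
#' @param dir directory holding `baseline.csv` and `events.jsonl`.
#' @return list with `cohort` and `events` data.frames.
#' @export
read_cohort <- function(dir) {
  cohort <- utils::read.csv(file.path(dir, "baseline.csv"),
                            stringsAsFactors = FALSE)
  cohort[] <- lapply(cohort, function(col) {
    if (is.integer(col)) as.numeric(col) else col
  })
  list(cohort = cohort, events = read_events(file.path(dir, "events.jsonl")))
}

#' Read a JSON-lines event log
#'
#' @param path JSON-lines file path.
#' @return event data.frame in the standard column order; missing fields NA.
#' @export
read_events <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cols <- event_columns()
  chr <- c("participant_id", "timestamp", "event_kind", "tree_node")
  if (length(lines) == 0) {
    ev <- as.data.frame(stats::setNames(
      lapply(cols, function(cl) {
        if (cl %in% chr) character(0) else numeric(0)
      }), cols), stringsAsFactors = FALSE)
    return(ev)
  }
  parsed <- lapply(lines, function(l) jsonlite::fromJSON(l))
  ev <- as.data.frame(stats::setNames(lapply(cols, function(cl) {
    vals <- lapply(parsed, function(p) p[[cl]])
    if (cl %in% chr) {
      vapply(vals, function(v) if (is.null(v)) NA_character_ else
        as.character(v), character(1))
    } else {
      vapply(vals, function(v) if (is.null(v)) NA_real_ else
        as.numeric(v), numeric(1))
    }
  }), cols), stringsAsFactors = FALSE)
  rownames(ev) <- NULL
  ev
}
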