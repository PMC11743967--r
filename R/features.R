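# Preprocessing: mixed-type baseline data plus variable-length interaction
# logs -> a numeric, [0,1]-scaled, expert-weighted feature table.

#' Declare a feature for the preprocessing pipeline
#'
#' @param name raw column name (or derived column name for interaction
#'   aggregates).
#' @param kind one of `"categorical"` (one-hot encoded), `"numeric"`
#'   (quantile-discretized then one-hot), `"ordinal"` (kept numeric,
#'   min-max scaled), `"text_derived"` (numeric NLP output, scaled), or
#'   `"interaction_aggregate"` (computed from the event log, scaled).
#' @param categories exhaustive, exclusive category list (categorical only).
#' @param n_quantile_bins number of quantile bins (numeric only).
#' @param weight non-negative expert importance weight for the weighted
#'   Manhattan metric; weight 0 drops the feature (expert feature
#'   selection). Indicator columns produced by one feature share its weight
#'   divided by the number of indicators.
#' @param aggregation `"mean"`, `"count"` or `"sum"` (aggregates only).
#' @param event_kind event type the aggregate is computed over.
#' @param field event field aggregated (ignored for `"count"`).
#' @param fill value used for participants with no matching events.
#' @return list of class `feature_spec`.
#' @export
feature_spec <- function(name,
                         kind = c("categorical", "numeric", "ordinal",
                                  "text_derived", "interaction_aggregate"),
                         categories = NULL, n_quantile_bins = 5L,
                         weight = 1, aggregation = NULL, event_kind = NULL,
                         field = NULL, fill = 0) {
  kind <- match.arg(kind)
  stopifnot(weight >= 0)
  if (kind == "categorical") {
    stopifnot(length(categories) >= 2)
  }
  if (kind == "numeric") stopifnot(n_quantile_bins >= 2)
  if (kind == "interaction_aggregate") {
    if (is.null(aggregation) ||
        !aggregation %in% c("mean", "count", "sum")) {
      stop("unknown aggregation for feature '", name,
           "': must be mean, count or sum", call. = FALSE)
    }
    stopifnot(!is.null(event_kind))
  }
  structure(list(name = name, kind = kind, categories = categories,
                 n_quantile_bins = as.integer(n_quantile_bins),
                 weight = weight, aggregation = aggregation,
                 event_kind = event_kind, field = field, fill = fill),
            class = "feature_spec")
}

#' Default feature schema for the trial data
#'
#' Encodes the baseline questionnaire (demographics one-hot, age in five
#' quantile bins, the ten behavioral items and baseline satisfaction as
#' scaled ordinals, filler habit items, pre-aggregated text-sentiment
#' scores) plus six aggregates of the interaction log, for 130
#' post-encoding columns in total. Expert weights: 3 for the profile-driving
#' features (behavioral items, age, occupation), 1 for baseline
#' satisfaction, 0.5 for the remaining demographics and the interaction
#' aggregates, 0.1 for filler items.
#'
#' @return list of [feature_spec()] objects, in deterministic column order.
#' @export
default_feature_schema <- function() {
  tab <- behavioral_item_table()
  c(
    list(
      feature_spec("gender", "categorical",
                   categories = c("female", "male", "no_answer"),
                   weight = 0.5),
      feature_spec("country", "categorical",
                   categories = c("italy", "switzerland"), weight = 0.5),
      feature_spec("occupation", "categorical",
                   categories = c("student", "worker", "other"), weight = 3),
      feature_spec("education", "categorical",
                   categories = c("high_school", "bachelor", "master",
                                  "other"), weight = 0.5),
      feature_spec("ses", "categorical",
                   categories = c("low", "moderately_low", "moderate",
                                  "moderately_good", "good"), weight = 0.5),
      feature_spec("age", "numeric", n_quantile_bins = 5L, weight = 3)
    ),
    lapply(tab$items, function(nm) feature_spec(nm, "ordinal", weight = 3)),
    list(feature_spec("baseline_wellbeing", "ordinal", weight = 1)),
    lapply(sprintf("habit_%02d", seq_len(n_filler_habits)),
           function(nm) feature_spec(nm, "ordinal", weight = 0.1)),
    lapply(sprintf("nlp_%02d", seq_len(n_filler_sentiment)),
           function(nm) feature_spec(nm, "text_derived", weight = 0.1)),
    list(
      feature_spec("ema_mean", "interaction_aggregate", weight = 0.5,
                   aggregation = "mean", event_kind = "ema_response",
                   field = "ema_value", fill = 0),
      feature_spec("ema_response_count", "interaction_aggregate",
                   weight = 0.5, aggregation = "count",
                   event_kind = "ema_response", fill = 0),
      feature_spec("usefulness_mean", "interaction_aggregate", weight = 0.5,
                   aggregation = "mean", event_kind = "exercise_feedback",
                   field = "usefulness", fill = 0),
      feature_spec("exercises_completed", "interaction_aggregate",
                   weight = 0.5, aggregation = "count",
                   event_kind = "exercise_feedback", fill = 0),
      feature_spec("emotion_mean", "interaction_aggregate", weight = 0.5,
                   aggregation = "mean", event_kind = "ema_response",
                   field = "emotion", fill = 0),
      feature_spec("polarity_mean", "interaction_aggregate", weight = 0.5,
                   aggregation = "mean", event_kind = "ema_response",
                   field = "polarity", fill = 0)
    )
  )
}

#' One-hot encode a categorical column
#'
#' Expands the column into exhaustive, exclusive 0/1 indicator columns,
#' one per category; each row has exactly one 1.
#'
#' @param x character (or factor) vector.
#' @param categories allowed categories, in output column order.
#' @return numeric matrix with `length(categories)` columns named after the
#'   categories.
#' @export
one_hot_encode <- function(x, categories) {
  x <- as.character(x)
  bad <- setdiff(unique(x), categories)
  if (length(bad) > 0) {
    stop("value(s) outside declared categories: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  m <- vapply(categories, function(cat) as.numeric(x == cat),
              numeric(length(x)))
  m <- matrix(m, nrow = length(x),
              dimnames = list(NULL, categories))
  m
}

#' Discretize a numeric column at empirical quantiles
#'
#' Bin edges come from the empirical quantile function (or from `breaks`
#' if supplied, e.g. the study's standard age bands 16--19, 20--22,
#' 23--25, 26--32, 33+); intervals are right-closed, so a value equal to
#' an edge falls in the lower bin. An all-identical column collapses to a
#' single constant indicator with a warning.
#'
#' @param x numeric vector.
#' @param n_bins number of quantile bins (ignored when `breaks` given).
#' @param breaks optional explicit interior+outer break points; the first
#'   and last may be -Inf/Inf.
#' @param labels optional bin labels.
#' @return list with `indicators` (0/1 matrix, one column per bin),
#'   `breaks`, and `labels`.
#' @export
quantile_discretize <- function(x, n_bins = 5L, breaks = NULL,
                                labels = NULL) {
  stopifnot(length(x) > 0)
  if (is.null(breaks)) {
    stopifnot(n_bins >= 2)
    qs <- stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                          names = FALSE, type = 7)
    breaks <- unique(qs)
    breaks[1] <- -Inf
    breaks[length(breaks)] <- Inf
    breaks <- unique(breaks)
  }
  if (length(breaks) < 2) {
    warning("column has a single distinct value; using one constant bin")
    ind <- matrix(1, nrow = length(x), ncol = 1,
                  dimnames = list(NULL, labels %||% "bin_1"))
    return(list(indicators = ind, breaks = c(-Inf, Inf),
                labels = colnames(ind)))
  }
  if (is.null(labels)) labels <- paste0("bin_", seq_len(length(breaks) - 1))
  bin <- cut(x, breaks = breaks, labels = labels, right = TRUE,
             include.lowest = TRUE)
  ind <- one_hot_encode(as.character(bin), labels)
  list(indicators = ind, breaks = breaks, labels = labels)
}

#' Aggregate interaction events into a per-participant column
#'
#' @param events event data.frame.
#' @param spec a [feature_spec()] with kind `"interaction_aggregate"`.
#' @param participant_ids participants the output is aligned to.
#' @return numeric vector, one value per participant; participants with no
#'   matching events receive `spec$fill`.
#' @export
aggregate_interactions <- function(events, spec, participant_ids) {
  stopifnot(inherits(spec, "feature_spec"),
            spec$kind == "interaction_aggregate")
  sel <- events[events$event_kind == spec$event_kind, , drop = FALSE]
  out <- rep(spec$fill, length(participant_ids))
  names(out) <- participant_ids
  if (nrow(sel) == 0) return(unname(out))
  vals <- switch(spec$aggregation,
    count = tapply(rep(1, nrow(sel)), sel$participant_id, sum),
    mean = tapply(sel[[spec$field]], sel$participant_id,
                  function(v) mean(v, na.rm = TRUE)),
    sum = tapply(sel[[spec$field]], sel$participant_id,
                 function(v) sum(v, na.rm = TRUE))
  )
  hit <- intersect(names(vals), participant_ids)
  out[hit] <- vals[hit]
  unname(out)
}

#' Min-max scale a numeric column to \[0,1\]
#'
#' Maps the minimum to 0 and the maximum to 1, affinely in between; a
#' constant column maps to all zeros.
#'
#' @param x numeric vector.
#' @return list with `values` (scaled vector), `min`, and `range` (0 for a
#'   constant column).
#' @export
min_max_scale <- function(x) {
  stopifnot(length(x) > 0, !anyNA(x))
  lo <- min(x)
  rg <- max(x) - lo
  if (rg == 0) return(list(values = rep(0, length(x)), min = lo, range = 0))
  list(values = (x - lo) / rg, min = lo, range = rg)
}

#' Build the participants-by-features table
#'
#' Applies the schema in order: one-hot encoding for categoricals,
#' quantile discretization for numerics, min-max scaling for ordinal and
#' text-derived columns, and event-log aggregation for interaction
#' features. Features with expert weight 0 are dropped before encoding.
#' Indicator columns inherit the parent feature's weight divided by the
#' number of indicators, so a multi-category feature cannot dominate the
#' L1 metric by fan-out alone. Column order is deterministic: schema
#' order, then category/bin order.
#'
#' @param baseline baseline data.frame (one row per participant, with a
#'   `participant_id` column).
#' @param events event data.frame (may have zero rows).
#' @param schema list of [feature_spec()]; defaults to
#'   [default_feature_schema()].
#' @return object of class `feature_table`: list with `participant_ids`,
#'   `values` (numeric matrix, all entries in \[0,1\]), `weights` (per
#'   column), `column_feature` (parent feature of each column), and
#'   `encoders` (category maps, bin edges and scaling parameters needed to
#'   embed new participants consistently).
#' @export
build_feature_table <- function(baseline, events = NULL,
                                schema = default_feature_schema()) {
  stopifnot(is.data.frame(baseline), "participant_id" %in% names(baseline))
  ids <- baseline$participant_id
  if (!is.null(events) && nrow(events) > 0) {
    unknown <- setdiff(unique(events$participant_id), ids)
    if (length(unknown) > 0) {
      stop("event log references participants absent from the baseline ",
           "table: ", paste(utils::head(unknown, 5), collapse = ", "),
           call. = FALSE)
    }
  }
  blocks <- list()
  weights <- list()
  parents <- list()
  encoders <- list()
  for (spec in schema) {
    if (spec$weight == 0) next
    if (spec$kind %in% c("categorical", "numeric", "ordinal",
                         "text_derived") &&
        !spec$name %in% names(baseline)) {
      stop("schema references missing baseline column: ", spec$name,
           call. = FALSE)
    }
    block <- switch(spec$kind,
      categorical = {
        m <- one_hot_encode(baseline[[spec$name]], spec$categories)
        colnames(m) <- paste(spec$name, spec$categories, sep = "=")
        encoders[[spec$name]] <- list(kind = "categorical",
                                      categories = spec$categories)
        m
      },
      numeric = {
        qd <- quantile_discretize(baseline[[spec$name]],
                                  spec$n_quantile_bins)
        m <- qd$indicators
        colnames(m) <- paste(spec$name, qd$labels, sep = "=")
        encoders[[spec$name]] <- list(kind = "numeric", breaks = qd$breaks,
                                      labels = qd$labels)
        m
      },
      {
        raw <- if (spec$kind == "interaction_aggregate") {
          if (is.null(events)) {
            stop("schema requires an event log for aggregate feature: ",
                 spec$name, call. = FALSE)
          }
          aggregate_interactions(events, spec, ids)
        } else {
          baseline[[spec$name]]
        }
        sc <- min_max_scale(raw)
        encoders[[spec$name]] <- list(kind = spec$kind, min = sc$min,
                                      range = sc$range,
                                      aggregation = spec$aggregation,
                                      event_kind = spec$event_kind,
                                      field = spec$field, fill = spec$fill)
        matrix(sc$values, ncol = 1, dimnames = list(NULL, spec$name))
      }
    )
    blocks[[length(blocks) + 1]] <- block
    weights[[length(weights) + 1]] <-
      rep(spec$weight / ncol(block), ncol(block))
    parents[[length(parents) + 1]] <- rep(spec$name, ncol(block))
  }
  values <- do.call(cbind, blocks)
  rownames(values) <- ids
  ft <- list(participant_ids = ids, values = values,
             weights = unlist(weights), column_feature = unlist(parents),
             encoders = encoders)
  class(ft) <- "feature_table"
  ft
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table:", nrow(x$values), "participants x", ncol(x$values),
      "columns (", length(unique(x$column_feature)), "features )\n")
  invisible(x)
}

#' Embed a new participant into an existing feature space
#'
#' Applies the category maps, bin edges and scaling parameters stored in a
#' fitted [build_feature_table()] to a single baseline row (plus optional
#' events), so a test participant lands in the same \[0,1\] coordinate
#' system as the training cohort. Values outside the training range are
#' clipped to \[0,1\].
#'
#' @param ft a `feature_table`.
#' @param baseline_row one-row data.frame of raw baseline fields.
#' @param events optional events for the participant.
#' @return named numeric vector aligned to `colnames(ft$values)`.
#' @export
encode_participant <- function(ft, baseline_row, events = NULL) {
  stopifnot(inherits(ft, "feature_table"), nrow(baseline_row) == 1)
  out <- numeric(0)
  for (nm in names(ft$encoders)) {
    enc <- ft$encoders[[nm]]
    vals <- switch(enc$kind,
      categorical = as.numeric(enc$categories ==
                                 as.character(baseline_row[[nm]])),
      numeric = {
        bin <- cut(baseline_row[[nm]], breaks = enc$breaks,
                   labels = enc$labels, right = TRUE, include.lowest = TRUE)
        as.numeric(enc$labels == as.character(bin))
      },
      interaction_aggregate = {
        spec <- feature_spec(nm, "interaction_aggregate",
                             aggregation = enc$aggregation,
                             event_kind = enc$event_kind, field = enc$field,
                             fill = enc$fill)
        raw <- if (is.null(events)) enc$fill else
          aggregate_interactions(events, spec,
                                 baseline_row$participant_id)
        if (enc$range == 0) 0 else clamp((raw - enc$min) / enc$range, 0, 1)
      },
      { # ordinal / text_derived
        if (enc$range == 0) 0 else
          clamp((baseline_row[[nm]] - enc$min) / enc$range, 0, 1)
      }
    )
    out <- c(out, vals)
  }
  stats::setNames(out, colnames(ft$values))
}

#' Write a feature table as CSV plus a JSON sidecar
#'
#' The CSV holds the scaled matrix (participants in rows); the sidecar
#' holds weights, parent features and the encoder state needed by
#' [encode_participant()].
#'
#' @param ft a `feature_table`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.meta.json`.
#' @return invisibly, the two paths.
#' @export
write_feature_table <- function(ft, path) {
  df <- data.frame(participant_id = ft$participant_ids, ft$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(weights = ft$weights, column_feature = ft$column_feature,
               column_names = colnames(ft$values), encoders = ft$encoders)
  meta_path <- paste0(path, ".meta.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(csv = path, meta = meta_path))
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path (sidecar expected at `<path>.meta.json`).
#' @return a `feature_table`.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  values <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- df$participant_id
  colnames(values) <- meta$column_names
  encoders <- lapply(meta$encoders, function(e) {
    if (!is.null(e$breaks)) e$breaks <- as.numeric(e$breaks)
    e
  })
  ft <- list(participant_ids = df$participant_id, values = values,
             weights = as.numeric(meta$weights),
             column_feature = meta$column_feature, encoders = encoders)
  class(ft) <- "feature_table"
  ft
}
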