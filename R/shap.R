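# Shapley-value explanation of soft cluster membership. The "game" payoff
# is the membership probability of one cluster; players are features (an
# indicator block produced by one raw feature acts as a single player);
# out-of-coalition players are set to the background column medians.

# Named list of column-index groups, one per parent feature.
feature_groups <- function(ft) {
  if (inherits(ft, "feature_table")) {
    split(seq_len(ncol(ft$values)), factor(ft$column_feature,
                                           levels = unique(ft$column_feature)))
  } else {
    cols <- colnames(ft) %||% paste0("x", seq_len(ncol(ft)))
    stats::setNames(as.list(seq_len(ncol(ft))), cols)
  }
}

background_reference <- function(background) {
  X <- if (inherits(background, "feature_table")) background$values else
    as.matrix(background)
  apply(X, 2, stats::median)
}

# Evaluate the membership value function for many coalitions at once.
# `masks` is a logical matrix (coalitions x players).
coalition_values <- function(masks, x, ref, groups, model, cluster) {
  Z <- matrix(rep(ref, each = nrow(masks)), nrow = nrow(masks))
  for (j in seq_along(groups)) {
    cols <- groups[[j]]
    on <- masks[, j]
    if (any(on)) {
      Z[on, cols] <- matrix(rep(x[cols], each = sum(on)), nrow = sum(on))
    }
  }
  membership_matrix(Z, model)[, cluster]
}

#' Shapley contributions of features to a cluster membership
#'
#' Attributes the difference between a participant's membership
#' probability in cluster `cluster` and the background expectation to the
#' individual features. Exact mode enumerates all `2^p` feature
#' coalitions (allowed up to 15 grouped features); sampling mode averages
#' marginal contributions over random feature orderings and reports a
#' Monte-Carlo standard error per feature. Both modes satisfy the
#' efficiency axiom exactly: the contributions sum to
#' `m_c(x) - m_c(background)`.
#'
#' @param x feature vector in the model's column space.
#' @param cluster cluster index the membership of which is explained.
#' @param model a `cluster_model`.
#' @param background a `feature_table` (or matrix); its column medians are
#'   the reference input, and its `column_feature` map defines the grouped
#'   players.
#' @param mode `"exact"`, `"sampling"`, or `"auto"` (exact when 15 or
#'   fewer players).
#' @param n_samples permutations in sampling mode.
#' @param seed integer seed (sampling mode).
#' @param participant_id optional identifier carried into the result.
#' @return object of class `shap_explanation`: `phi` (named contribution
#'   vector), `baseline` (background membership), `prediction`
#'   (`m_c(x)`), `se` (NA in exact mode), `cluster`, `mode`.
#' @export
shapley_membership <- function(x, cluster, model, background,
                               mode = c("auto", "exact", "sampling"),
                               n_samples = 200L, seed = 1L,
                               participant_id = NA_character_) {
  mode <- match.arg(mode)
  groups <- feature_groups(background)
  ref <- background_reference(background)
  p <- length(groups)
  if (mode == "auto") mode <- if (p <= 15) "exact" else "sampling"
  if (mode == "exact" && p > 15) {
    stop("exact Shapley enumeration requested for ", p, " grouped ",
         "features; 2^p coalitions is infeasible above 15 - use ",
         'mode = "sampling"', call. = FALSE)
  }

  if (mode == "exact") {
    n_masks <- 2^p
    masks <- matrix(FALSE, n_masks, p)
    for (j in seq_len(p)) {
      masks[, j] <- bitwAnd(seq_len(n_masks) - 1L, bitwShiftL(1L, j - 1L)) > 0
    }
    v <- coalition_values(masks, x, ref, groups, model, cluster)
    sizes <- rowSums(masks)
    # Shapley kernel weight for a coalition of size s (excluding player j):
    # s! (p - s - 1)! / p!  ==  1 / (p * choose(p - 1, s))
    wt <- 1 / (p * choose(p - 1, 0:(p - 1)))
    phi <- numeric(p)
    idx <- seq_len(n_masks) - 1L
    for (j in seq_len(p)) {
      bit <- bitwShiftL(1L, j - 1L)
      without <- which(bitwAnd(idx, bit) == 0)
      with_j <- without + bit
      phi[j] <- sum(wt[sizes[without] + 1] * (v[with_j] - v[without]))
    }
    se <- rep(NA_real_, p)
  } else {
    set.seed(seed)
    # antithetic pairs: each sampled ordering is paired with its reverse,
    # whose marginal contributions are negatively correlated with the
    # original's — a standard variance reduction for permutation sampling.
    # The SE is computed over the pair means, which are i.i.d.
    n_pairs <- max(1L, ceiling(n_samples / 2))
    one_perm <- function(ord) {
      masks <- matrix(FALSE, p + 1, p)
      for (pos in seq_len(p)) {
        masks[(pos + 1):(p + 1), ord[pos]] <- TRUE
      }
      v <- coalition_values(masks, x, ref, groups, model, cluster)
      out <- numeric(p)
      out[ord] <- diff(v)
      out
    }
    pair_means <- matrix(0, n_pairs, p)
    for (s in seq_len(n_pairs)) {
      ord <- sample.int(p)
      pair_means[s, ] <- (one_perm(ord) + one_perm(rev(ord))) / 2
    }
    phi <- colMeans(pair_means)
    se <- if (n_pairs > 1) {
      apply(pair_means, 2, stats::sd) / sqrt(n_pairs)
    } else {
      rep(NA_real_, p)
    }
  }

  v_empty <- coalition_values(matrix(FALSE, 1, p), x, ref, groups, model,
                              cluster)
  v_full <- coalition_values(matrix(TRUE, 1, p), x, ref, groups, model,
                             cluster)
  structure(list(participant_id = participant_id,
                 cluster = as.integer(cluster),
                 phi = stats::setNames(phi, names(groups)),
                 se = stats::setNames(se, names(groups)),
                 baseline = unname(v_empty), prediction = unname(v_full),
                 mode = mode, n_samples = if (mode == "sampling")
                   as.integer(n_samples) else NA_integer_),
            class = "shap_explanation")
}

#' Explain every participant's membership in their own cluster
#'
#' @param ft the training `feature_table` (also used as background).
#' @param model a fitted `cluster_model` on `ft`.
#' @param mode,n_samples,seed passed to [shapley_membership()].
#' @return list of `shap_explanation`, one per participant, each for the
#'   participant's hard-assigned cluster.
#' @export
explain_cohort <- function(ft, model, mode = "sampling", n_samples = 50L,
                           seed = 1L) {
  stopifnot(inherits(ft, "feature_table"))
  lapply(seq_along(ft$participant_ids), function(i) {
    shapley_membership(ft$values[i, ], model$hard_labels[i], model, ft,
                       mode = mode, n_samples = n_samples, seed = seed + i,
                       participant_id = ft$participant_ids[i])
  })
}

#' Per-cluster feature-contribution summary
#'
#' For each cluster, averages the signed contributions over the cluster's
#' members, ranks features by absolute aggregate contribution, and drops
#' features whose absolute aggregate falls below the display threshold
#' (default 0.04, matching the reporting convention of leaving weak
#' features out of the cluster summaries).
#'
#' @param explanations list of `shap_explanation` (e.g. from
#'   [explain_cohort()]).
#' @param model the `cluster_model`.
#' @param threshold display threshold on the absolute aggregate score.
#' @return object of class `cluster_feature_summary`: list of data.frames
#'   (`feature`, `score`, `rank`), one per cluster; empty clusters yield
#'   an empty summary with a warning.
#' @export
summarize_cluster_contributions <- function(explanations, model,
                                            threshold = 0.04) {
  clusters <- seq_len(model$k)
  out <- lapply(clusters, function(c_i) {
    exps <- Filter(function(e) e$cluster == c_i, explanations)
    if (length(exps) == 0) {
      warning("no explanations for cluster ", c_i, "; empty summary")
      return(data.frame(feature = character(0), score = numeric(0),
                        rank = integer(0)))
    }
    phis <- do.call(rbind, lapply(exps, `[[`, "phi"))
    score <- colMeans(phis)
    keep <- abs(score) >= threshold
    score <- score[keep]
    ord <- order(-abs(score))
    data.frame(feature = names(score)[ord], score = unname(score[ord]),
               rank = seq_along(ord), stringsAsFactors = FALSE)
  })
  names(out) <- paste0("cluster_", clusters)
  structure(out, class = "cluster_feature_summary", threshold = threshold)
}

#' @export
print.cluster_feature_summary <- function(x, ...) {
  for (nm in names(x)) {
    cat(nm, ":",
        if (nrow(x[[nm]]) == 0) "(no feature above threshold)" else
          paste(sprintf("%s (%.3f)", x[[nm]]$feature, x[[nm]]$score),
                collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Export a cluster-contribution summary as a tidy data.frame
#'
#' @param summary a `cluster_feature_summary`.
#' @return data.frame with `cluster`, `feature`, `score`, `rank`.
#' @export
summary_to_table <- function(summary) {
  do.call(rbind, lapply(seq_along(summary), function(i) {
    df <- summary[[i]]
    if (nrow(df) == 0) return(NULL)
    cbind(data.frame(cluster = i), df)
  }))
}

#' Stacked-bar chart of per-cluster feature contributions
#'
#' One stacked bar per cluster, segments colored by feature, mirroring the
#' usual cluster-explanation summary figure. Requires ggplot2.
#'
#' @param summary a `cluster_feature_summary`.
#' @return a ggplot object.
#' @export
plot_cluster_contributions <- function(summary) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_cluster_contributions requires ggplot2", call. = FALSE)
  }
  df <- summary_to_table(summary)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$cluster),
                                   y = abs(.data$score),
                                   fill = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "cluster", y = "mean |contribution| to membership",
                  fill = "feature") +
    ggplot2::theme_minimal()
}
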