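# Soft distance-based clustering under a weighted Manhattan metric:
# Lloyd iterations with coordinate-median centroid updates, silhouette
# model selection, inverse-distance soft memberships, and stability
# across expert weight sets.

#' Weighted Manhattan (L1) distance
#'
#' `sum(w * abs(x - y))`; the dissimilarity between two participants in the
#' scaled feature space, with expert weights `w`.
#'
#' @param x,y numeric vectors of equal length.
#' @param w non-negative weights (recycled scalar allowed).
#' @return non-negative scalar.
#' @export
weighted_manhattan <- function(x, y, w = 1) {
  if (length(x) != length(y)) {
    stop("dimension mismatch: length(x) = ", length(x), ", length(y) = ",
         length(y), call. = FALSE)
  }
  if (length(w) == 1) w <- rep(w, length(x))
  if (length(w) != length(x)) {
    stop("dimension mismatch: weights have length ", length(w),
         call. = FALSE)
  }
  stopifnot(all(w >= 0))
  sum(w * abs(x - y))
}

# Distance-proportional (k-means++ style) seeding under the weighted L1
# metric: later centroids are drawn with probability proportional to the
# distance from the already-chosen ones, which makes restarts far more
# likely to reach the global optimum than uniform seeding.
init_centroids_pp <- function(X, k, w) {
  n <- nrow(X)
  idx <- sample.int(n, 1)
  while (length(idx) < k) {
    D <- dist_to_centroids(X, X[idx, , drop = FALSE], w)
    nearest <- apply(D, 1, min)
    nearest[idx] <- 0
    idx <- c(idx, if (sum(nearest) == 0) {
      pool <- setdiff(seq_len(n), idx)
      pool[sample.int(length(pool), 1)]
    } else {
      sample.int(n, 1, prob = nearest)
    })
  }
  X[idx, , drop = FALSE]
}

# n x k matrix of weighted L1 distances from rows of X to rows of C.
dist_to_centroids <- function(X, C, w) {
  k <- nrow(C)
  out <- matrix(0, nrow = nrow(X), ncol = k)
  for (c_i in seq_len(k)) {
    out[, c_i] <- colSums(w * abs(t(X) - C[c_i, ]))
  }
  out
}

# Full n x n weighted L1 distance matrix.
weighted_l1_distmat <- function(X, w) {
  Xw <- sweep(X, 2, w, `*`)
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    D[i, ] <- colSums(abs(t(Xw) - Xw[i, ]))
  }
  # weights multiply |x - y| linearly, so scaling columns first is exact
  D
}

as_table_matrix <- function(table) {
  if (inherits(table, "feature_table")) {
    list(X = table$values, w = table$weights, ids = table$participant_ids)
  } else {
    X <- as.matrix(table)
    list(X = X, w = rep(1, ncol(X)),
         ids = rownames(X) %||% as.character(seq_len(nrow(X))))
  }
}

#' Fit K-medians under the weighted Manhattan metric
#'
#' Lloyd iterations: assign each participant to the nearest centroid under
#' the weighted L1 distance, then update each centroid coordinate-wise to
#' the median of its members (the L1-optimal update; the feature weights
#' factor out of each coordinate's minimization, so the plain member median
#' minimizes the weighted objective). Best of `n_init` seeded restarts by
#' total within-cluster distance. An emptied cluster is re-seeded at the
#' point farthest from its current centroid.
#'
#' @param table a `feature_table`, or a plain numeric matrix (unit
#'   weights).
#' @param k number of clusters, `2 <= k <= n` (k = n gives singleton
#'   clusters with objective 0).
#' @param n_init number of random restarts.
#' @param max_iter iteration cap per restart.
#' @param seed integer seed.
#' @param centroid_update `"median"` (default, descends the L1 objective)
#'   or `"mean"` (classic update, kept for comparison).
#' @return object of class `cluster_model`: `k`, `centroids`,
#'   `hard_labels`, `memberships` (inverse-distance soft memberships),
#'   `objective`, `objective_history` (per accepted iteration of the best
#'   restart), `weights_used`, `participant_ids`.
#' @export
fit_kmeans_l1 <- function(table, k, n_init = 10L, max_iter = 300L,
                          seed = 1L, centroid_update = c("median", "mean")) {
  centroid_update <- match.arg(centroid_update)
  tm <- as_table_matrix(table)
  X <- tm$X
  w <- tm$w
  n <- nrow(X)
  stopifnot(k >= 1, k <= n, n_init >= 1)
  set.seed(seed)
  best <- NULL
  for (run in seq_len(n_init)) {
    C <- init_centroids_pp(X, k, w)
    labels <- rep(0L, n)
    history <- numeric(0)
    for (iter in seq_len(max_iter)) {
      D <- dist_to_centroids(X, C, w)
      new_labels <- max.col(-D, ties.method = "first")
      # re-seed emptied clusters at the point farthest from its centroid
      empty <- setdiff(seq_len(k), unique(new_labels))
      for (e in empty) {
        far <- which.max(D[cbind(seq_len(n), new_labels)])
        message("re-seeding emptied cluster ", e, " at participant ", far)
        C[e, ] <- X[far, ]
        new_labels[far] <- e
      }
      obj <- sum(D[cbind(seq_len(n), new_labels)])
      history <- c(history, obj)
      if (identical(new_labels, labels)) break
      labels <- new_labels
      for (c_i in seq_len(k)) {
        members <- X[labels == c_i, , drop = FALSE]
        C[c_i, ] <- if (centroid_update == "median") {
          apply(members, 2, stats::median)
        } else {
          colMeans(members)
        }
      }
    }
    D <- dist_to_centroids(X, C, w)
    obj <- sum(D[cbind(seq_len(n), labels)])
    if (is.null(best) || obj < best$objective) {
      best <- list(centroids = C, labels = labels, objective = obj,
                   history = history)
    }
  }
  dimnames(best$centroids) <- list(NULL, colnames(X))
  model <- list(k = as.integer(k), centroids = best$centroids,
                hard_labels = best$labels,
                objective = best$objective,
                objective_history = best$history,
                weights_used = w,
                participant_ids = tm$ids,
                centroid_update = centroid_update)
  model$memberships <- membership_matrix(X, model)
  class(model) <- "cluster_model"
  model
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("cluster_model: k =", x$k, "| n =", length(x$hard_labels),
      "| weighted-L1 objective =", format(x$objective, digits = 6), "\n")
  cat("cluster sizes:", paste(tabulate(x$hard_labels, x$k), collapse = "/"),
      "\n")
  invisible(x)
}

#' Soft cluster membership by inverse distance
#'
#' Membership in cluster c is proportional to the reciprocal of the
#' weighted Manhattan distance to its centroid:
#' `m_c = (1/(d_c + eps)) / sum_c' (1/(d_c' + eps))`. A point at zero
#' distance from one or more centroids gets membership spread uniformly
#' over exactly those clusters.
#'
#' @param x feature vector (or matrix of rows to score).
#' @param model a fitted `cluster_model`.
#' @param eps numerical guard added to each distance.
#' @return probability vector over the k clusters (or an n x k matrix).
#' @export
soft_membership <- function(x, model, eps = 1e-9) {
  if (is.null(dim(x))) {
    drop(membership_matrix(matrix(x, nrow = 1), model, eps))
  } else {
    membership_matrix(x, model, eps)
  }
}

membership_matrix <- function(X, model, eps = 1e-9) {
  D <- dist_to_centroids(X, model$centroids, model$weights_used)
  M <- matrix(0, nrow = nrow(D), ncol = ncol(D))
  zero_rows <- rowSums(D == 0) > 0
  if (any(zero_rows)) {
    Z <- D[zero_rows, , drop = FALSE] == 0
    M[zero_rows, ] <- Z / rowSums(Z)
  }
  if (any(!zero_rows)) {
    inv <- 1 / (D[!zero_rows, , drop = FALSE] + eps)
    M[!zero_rows, ] <- inv / rowSums(inv)
  }
  M
}

#' Mean silhouette width under the weighted Manhattan metric
#'
#' @param X feature matrix.
#' @param labels cluster labels.
#' @param w feature weights.
#' @return list with `mean` and per-point widths `widths`; singleton
#'   clusters contribute width 0.
#' @keywords internal
silhouette_l1 <- function(X, labels, w) {
  D <- weighted_l1_distmat(X, w)
  if (all(D == 0)) {
    stop("silhouette undefined: all points are identical", call. = FALSE)
  }
  n <- nrow(X)
  ks <- sort(unique(labels))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) {
      s[i] <- 0
      next
    }
    a <- sum(D[i, own]) / (sum(own) - 1)
    b <- min(vapply(setdiff(ks, labels[i]), function(c_i) {
      mean(D[i, labels == c_i])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  list(mean = mean(s), widths = s)
}

#' Select the number of clusters by the silhouette method
#'
#' Fits K-medians for each candidate k and returns the k maximizing the
#' mean silhouette coefficient computed with the weighted Manhattan
#' distance (ties go to the smaller k).
#'
#' @param table a `feature_table` or matrix.
#' @param k_grid candidate cluster counts.
#' @param n_init restarts per fit.
#' @param seed integer seed.
#' @return list with `k` (selected), `profile` (data.frame of k and mean
#'   silhouette), and `model` (the fitted model at the selected k).
#' @export
select_k_silhouette <- function(table, k_grid = 2:8, n_init = 10L,
                                seed = 1L) {
  tm <- as_table_matrix(table)
  stopifnot(all(k_grid >= 2), all(k_grid <= nrow(tm$X) - 1))
  models <- list()
  sil <- numeric(length(k_grid))
  for (j in seq_along(k_grid)) {
    models[[j]] <- fit_kmeans_l1(table, k_grid[j], n_init = n_init,
                                 max_iter = 300L, seed = seed + j)
    sil[j] <- silhouette_l1(tm$X, models[[j]]$hard_labels, tm$w)$mean
  }
  best <- which.max(sil)
  list(k = k_grid[best],
       profile = data.frame(k = k_grid, silhouette = sil),
       model = models[[best]])
}

#' Clustering stability across expert weight sets
#'
#' Refits the clustering under each supplied feature-weight vector and
#' reports the pairwise adjusted Rand index between the hard labelings,
#' plus raw pairwise label agreement (after best-match relabeling is not
#' applied; raw agreement is the proportion of pairs of participants on
#' which two labelings agree about co-membership).
#'
#' @param table a `feature_table`.
#' @param weight_sets list of per-column weight vectors (at least 2).
#' @param k number of clusters.
#' @param n_init restarts per fit.
#' @param seed integer seed.
#' @return list with `ari` (pairwise ARI matrix) and `labelings`.
#' @export
cluster_stability <- function(table, weight_sets, k, n_init = 10L,
                              seed = 1L) {
  stopifnot(inherits(table, "feature_table"), length(weight_sets) >= 2)
  labelings <- lapply(seq_along(weight_sets), function(j) {
    tb <- table
    tb$weights <- weight_sets[[j]]
    fit_kmeans_l1(tb, k, n_init = n_init, seed = seed)$hard_labels
  })
  m <- length(labelings)
  ari <- matrix(1, m, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      ari[i, j] <- ari[j, i] <-
        mclust::adjustedRandIndex(labelings[[i]], labelings[[j]])
    }
  }
  list(ari = ari, labelings = labelings)
}

#' Serialize a cluster model to JSON
#'
#' @param model a `cluster_model`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_cluster_model <- function(model, path) {
  payload <- list(k = model$k,
                  centroids = unclass(as.data.frame(model$centroids)),
                  column_names = colnames(model$centroids),
                  hard_labels = model$hard_labels,
                  memberships = unclass(as.data.frame(model$memberships)),
                  objective = model$objective,
                  weights_used = model$weights_used,
                  participant_ids = model$participant_ids,
                  centroid_update = model$centroid_update)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cluster model written by [write_cluster_model()]
#'
#' @param path JSON path.
#' @return a `cluster_model`.
#' @export
read_cluster_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  centroids <- as.matrix(as.data.frame(p$centroids))
  colnames(centroids) <- p$column_names
  model <- list(k = as.integer(p$k), centroids = centroids,
                hard_labels = as.integer(p$hard_labels),
                objective = p$objective,
                objective_history = numeric(0),
                weights_used = as.numeric(p$weights_used),
                participant_ids = p$participant_ids,
                centroid_update = p$centroid_update,
                memberships = as.matrix(as.data.frame(p$memberships)))
  dimnames(model$memberships) <- NULL
  class(model) <- "cluster_model"
  model
}
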