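# Independent oracles and small fixtures used across the suite.

# Exhaustive K-medians oracle: minimal weighted-L1 within-cluster cost over
# every assignment of n points to at most k clusters. Independent of the
# Lloyd path in the package.
oracle_kmedians_objective <- function(X, k, w = rep(1, ncol(X))) {
  n <- nrow(X)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    assign <- grid[r, ]
    obj <- 0
    for (c_i in unique(assign)) {
      members <- X[assign == c_i, , drop = FALSE]
      med <- apply(members, 2, stats::median)
      obj <- obj + sum(t(abs(t(members) - med)) %*% w)
    }
    if (obj < best) best <- obj
  }
  best
}

# All permutations of 1..p (small p only).
all_permutations <- function(p) {
  if (p == 1) return(list(1L))
  sub <- all_permutations(p - 1)
  out <- list()
  for (s in sub) {
    for (pos in 0:(p - 1)) {
      out[[length(out) + 1]] <- append(s, p, after = pos)
    }
  }
  out
}

# Shapley oracle: average marginal contribution over ALL orderings of the
# players — a different enumeration route than the package's
# subset-weight formula.
oracle_shapley <- function(value_fn, p) {
  perms <- all_permutations(p)
  phi <- numeric(p)
  for (ord in perms) {
    s <- integer(0)
    v_prev <- value_fn(s)
    for (j in ord) {
      s <- c(s, j)
      v_now <- value_fn(s)
      phi[j] <- phi[j] + (v_now - v_prev)
      v_prev <- v_now
    }
  }
  phi / length(perms)
}

# Hand-built cluster model (no fitting).
toy_model <- function(centroids, w = rep(1, ncol(centroids)),
                      participant_ids = character(0),
                      hard_labels = integer(0)) {
  structure(list(k = nrow(centroids), centroids = centroids,
                 weights_used = w, hard_labels = hard_labels,
                 participant_ids = participant_ids,
                 objective = NA_real_, objective_history = numeric(0),
                 centroid_update = "median"),
            class = "cluster_model")
}

# Brute-force expected utility for one test participant, straight from the
# definitions: omega_c = exp(-lambda d_c), S_c(e) = (mean_ce - mean_e)/sd_e,
# U(e) = sum_c omega_c S_c(e) / sum_c omega_c.
oracle_expected_utility <- function(x, centroids, w_feat, labels, ids,
                                    records, n_exercises, lambda = 1) {
  d <- apply(centroids, 1, function(ce) sum(w_feat * abs(x - ce)))
  omega <- exp(-lambda * d)
  sapply(seq_len(n_exercises), function(e) {
    u <- records$usefulness[records$exercise_id == e]
    if (length(u) == 0) return(0)
    mu <- mean(u)
    sd_e <- sqrt(mean((u - mu)^2))
    s_c <- sapply(seq_len(nrow(centroids)), function(c_i) {
      members <- ids[labels == c_i]
      uc <- records$usefulness[records$exercise_id == e &
                                 records$participant_id %in% members]
      if (length(uc) == 0 || sd_e == 0) 0 else (mean(uc) - mu) / sd_e
    })
    sum(omega * s_c) / sum(omega)
  })
}

# Small, fast study configuration for module-level tests.
small_config <- function(seed = 1L, ...) {
  cohort_config(n_participants = 24L, profile_sizes = c(6L, 6L, 6L, 6L),
                trial_days = 4L, seed = seed, ...)
}

# Match each fitted cluster to the latent profile of the majority of its
# members.
match_clusters_to_profiles <- function(labels, profiles) {
  vapply(sort(unique(labels)), function(c_i) {
    as.integer(names(which.max(table(profiles[labels == c_i]))))
  }, integer(1))
}

final_satisfaction <- function(events) {
  sf <- events[events$event_kind == "satisfaction_feedback", ]
  vapply(split(sf, sf$participant_id), function(d) {
    d$satisfaction[which(d$timestamp == max(d$timestamp))[1]]
  }, numeric(1))
}
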