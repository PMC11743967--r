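# Weighted-L1 K-medians, silhouette selection, soft membership, stability.

test_that("weighted Manhattan distance matches hand computations", {
  expect_equal(weighted_manhattan(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(weighted_manhattan(c(0.2, 0.5), c(0.7, 0.5), c(1, 1)), 0.5)
  expect_equal(weighted_manhattan(c(0, 0), c(1, 0), c(0, 1)), 0)
  expect_equal(weighted_manhattan(c(1, 2), c(4, 0), c(0.5, 2)), 5.5)
  expect_error(weighted_manhattan(c(1, 2), c(1, 2, 3)),
               "dimension mismatch")
})

test_that("K-medians solves the 1-D two-cluster toy exactly", {
  X <- matrix(c(0, 0.1, 0.9, 1.0), ncol = 1)
  m <- fit_kmeans_l1(X, 2, n_init = 5, seed = 1)
  expect_equal(sort(drop(m$centroids)), c(0.05, 0.95))
  expect_equal(m$objective, 0.2)
  # k = n gives singleton clusters and zero objective
  expect_equal(fit_kmeans_l1(X, 4, n_init = 5, seed = 1)$objective, 0)
})

test_that("fitted objective matches the exhaustive-partition oracle", {
  cases <- list(list(n = 8, p = 2, k = 3), list(n = 10, p = 3, k = 2),
                list(n = 7, p = 1, k = 3))
  hits <- 0
  total <- 0
  for (case in cases) {
    for (s in 1:4) {
      set.seed(100 * case$n + s)
      X <- matrix(stats::runif(case$n * case$p), ncol = case$p)
      w <- stats::runif(case$p, 0.5, 2)
      ft <- structure(list(values = X, weights = w,
                           participant_ids = as.character(seq_len(case$n)),
                           column_feature = paste0("f", seq_len(case$p)),
                           encoders = list()), class = "feature_table")
      fitted <- fit_kmeans_l1(ft, case$k, n_init = 10, seed = s)$objective
      oracle <- oracle_kmedians_objective(X, case$k, w)
      expect_gte(fitted, oracle - 1e-9)
      total <- total + 1
      if (abs(fitted - oracle) < 1e-9) hits <- hits + 1
    }
  }
  # restart ensembles find the global optimum in at least 95% of cases
  expect_gte(hits / total, 0.95)
})

test_that("the L1 objective is non-increasing across Lloyd iterations", {
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(stats::runif(60), ncol = 3)
    m <- fit_kmeans_l1(X, 3, n_init = 1, seed = s)
    expect_true(all(diff(m$objective_history) <= 1e-9), info = s)
  }
})

test_that("soft memberships follow the inverse-distance rule", {
  C <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), ncol = 2, byrow = TRUE)
  model <- toy_model(C)
  # equidistant from all four centroids
  expect_equal(soft_membership(c(0.5, 0.5), model), rep(0.25, 4))
  # exactly at a centroid: all mass on the zero-distance cluster
  expect_equal(soft_membership(c(1, 0), model), c(0, 1, 0, 0))
  # distances (1, 3) -> memberships (0.75, 0.25)
  m2 <- toy_model(matrix(c(0, 4), ncol = 1))
  expect_equal(soft_membership(1, m2), c(0.75, 0.25), tolerance = 1e-6)
})

test_that("membership vectors are probabilities and match hard labels", {
  cfg <- small_config(seed = 13)
  co <- generate_cohort(cfg)
  ev <- simulate_sessions(co, config = cfg, seed = 14)
  ft <- build_feature_table(co, ev)
  m <- fit_kmeans_l1(ft, 4, n_init = 5, seed = 13)
  expect_true(all(m$memberships >= 0))
  expect_equal(unname(rowSums(m$memberships)), rep(1, nrow(ft$values)),
               tolerance = 1e-9)
  expect_equal(max.col(m$memberships, ties.method = "first"),
               m$hard_labels)
})

test_that("silhouette selection finds two planted blobs", {
  set.seed(21)
  X <- rbind(matrix(stats::rnorm(30, 0, 0.05), ncol = 2),
             matrix(stats::rnorm(30, 1, 0.05), ncol = 2))
  sel <- select_k_silhouette(X, 2:6, n_init = 5, seed = 3)
  expect_equal(sel$k, 2)
  expect_equal(nrow(sel$profile), 5)
})

test_that("mean silhouette agrees with the cluster-package reference", {
  skip_if_not_installed("cluster")
  set.seed(31)
  X <- matrix(stats::runif(40), ncol = 2)
  w <- c(1.5, 0.5)
  labels <- rep(1:2, each = 10)
  ours <- phenorec:::silhouette_l1(X, labels, w)
  D <- phenorec:::weighted_l1_distmat(X, w)
  ref <- cluster::silhouette(labels, dmatrix = D)
  expect_equal(ours$widths, unname(ref[, "sil_width"]), tolerance = 1e-12)
})

test_that("identical points make the silhouette undefined", {
  X <- matrix(1, nrow = 5, ncol = 2)
  expect_error(phenorec:::silhouette_l1(X, c(1, 1, 2, 2, 2), c(1, 1)),
               "undefined")
})

test_that("planted profiles are perfectly recovered at zero noise", {
  cfg <- cohort_config(noise_sd = 0, seed = 17)
  co <- generate_cohort(cfg)
  ev <- simulate_sessions(co, config = cfg, seed = 18)
  ft <- build_feature_table(co, ev)
  m <- fit_kmeans_l1(ft, 4, n_init = 10, seed = 17)
  expect_equal(mclust::adjustedRandIndex(m$hard_labels,
                                         co$latent_profile), 1)
})

test_that("clustering is stable across perturbed expert weight sets", {
  cfg <- cohort_config(noise_sd = 0, seed = 19)
  co <- generate_cohort(cfg)
  ev <- simulate_sessions(co, config = cfg, seed = 20)
  ft <- build_feature_table(co, ev)
  set.seed(19)
  sets <- list(ft$weights,
               ft$weights * stats::runif(length(ft$weights), 0.9, 1.1),
               ft$weights * stats::runif(length(ft$weights), 0.9, 1.1))
  st <- cluster_stability(ft, sets, k = 4, n_init = 5, seed = 19)
  expect_equal(unname(st$ari), matrix(1, 3, 3))
  # random labels agree with fitted labels only at chance level
  set.seed(20)
  rand <- sample(1:4, nrow(co), replace = TRUE)
  expect_lt(abs(mclust::adjustedRandIndex(st$labelings[[1]], rand)), 0.15)
})

test_that("cluster models round-trip through JSON", {
  cfg <- small_config(seed = 23)
  co <- generate_cohort(cfg)
  ev <- simulate_sessions(co, config = cfg, seed = 24)
  ft <- build_feature_table(co, ev)
  m <- fit_kmeans_l1(ft, 3, n_init = 3, seed = 23)
  path <- withr::local_tempfile(fileext = ".json")
  write_cluster_model(m, path)
  back <- read_cluster_model(path)
  expect_equal(back$centroids, m$centroids, tolerance = 1e-12)
  expect_equal(back$hard_labels, m$hard_labels)
  expect_equal(back$memberships, unname(m$memberships), tolerance = 1e-12)
  expect_equal(back$objective, m$objective, tolerance = 1e-12)
})
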