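two_epoch_records <- function(amw, ach, ndvi, epochs = c(2007, 2019)) {
  n <- length(amw) / 2
  data.frame(region_id = rep(seq_len(n), 2),
             epoch = rep(epochs, each = n),
             amw_m = amw, ach_m = ach, ndvi = ndvi)
}

test_that("features are min-max scaled over the pooled epochs", {
  rec <- two_epoch_records(amw = c(2, 10, 6, 6), ach = c(5, 5, 5, 5),
                           ndvi = c(0.2, 0.4, 0.6, 0.8))
  X <- normalize_features(rec)
  expect_equal(unname(X[, "amw"]), c(0, 1, 0.5, 0.5))
  expect_equal(unname(X[, "ach"]), rep(0, 4))   # constant factor maps to 0
  expect_equal(unname(X[, "ndvi"]), c(0, 1, 2, 3) / 3)
  expect_error(normalize_features(rec[rec$epoch == 2007, ]), "two epochs")
})

test_that("identical records in both epochs normalize to identical rows", {
  rec <- two_epoch_records(amw = c(3, 7, 3, 7), ach = c(2, 9, 2, 9),
                           ndvi = c(0.5, 0.7, 0.5, 0.7))
  X <- normalize_features(rec)
  expect_equal(unname(X[1:2, ]), unname(X[3:4, ]))
})

test_that("pooled and per-epoch normalization differ under an epoch shift", {
  rec <- two_epoch_records(amw = c(1, 2, 1, 2), ach = c(2, 4, 6, 8),
                           ndvi = rep(0.5, 4))
  pooled <- normalize_features(rec)
  per_a <- (c(2, 4) - 2) / 2    # epoch-A-only scaling of heights
  expect_false(isTRUE(all.equal(unname(pooled[1:2, "ach"]), per_a)))
})

test_that("the cosangle metric behaves as one minus cosine similarity", {
  expect_equal(cosangle(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cosangle(c(1, 0), c(0, 1)), 1)
  expect_equal(cosangle(c(1, 0), c(1, 1)), 1 - 1 / sqrt(2))
  expect_equal(cosangle(c(1, 0), c(-1, 0)), 2)   # antipodal, upper bound
  expect_equal(cosangle(c(1, 0), c(1, 1), variant = "sqrt"),
               sqrt(2 * (1 - 1 / sqrt(2))))
  expect_error(cosangle(c(0, 0), c(1, 1)), "zero")
})

test_that("k = 1 clustering returns the distance-minimizing medoid", {
  af <- archetype_features(per = 3)
  m <- cluster_cells(af$X, k = 1)
  expect_true(all(m$labels == 1))
  n <- nrow(af$X)
  totals <- vapply(seq_len(n), function(i) {
    sum(vapply(seq_len(n), function(j) cosangle(af$X[i, ], af$X[j, ]),
               numeric(1)))
  }, numeric(1))
  expect_equal(m$medoids, which.min(totals))
})

test_that("k-medoids matches brute-force enumeration on a tiny instance", {
  set.seed(5)
  X <- rbind(archetype_directions()[c(1, 1, 1, 8, 8, 8), ] +
               matrix(rnorm(18, 0, 0.02), ncol = 3))
  X <- pmax(X, 0); colnames(X) <- c("amw", "ach", "ndvi")
  m <- cluster_cells(X, k = 2)
  D <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) D[i, j] <- cosangle(X[i, ], X[j, ])
  objective <- function(meds) sum(apply(D[, meds, drop = FALSE], 1, min))
  best <- min(apply(utils::combn(6, 2), 2, objective))
  expect_equal(objective(m$medoids), best, tolerance = 1e-12)
})

test_that("planted archetypes are recovered with high agreement", {
  af <- archetype_features(per = 6, noise_sd = 0.01)
  m <- cluster_cells(af$X, k = 8, seed = 1)
  ari <- mclust::adjustedRandIndex(m$labels, af$labels)
  expect_gte(ari, 0.9)
  # cluster 1 is the tallest-profile cluster by construction of the ordering
  ach_means <- tapply(af$X[, "ach"], m$labels, mean)
  expect_equal(order(-ach_means), seq_len(8))
})

test_that("duplicating every row leaves the partition unchanged", {
  af <- archetype_features(per = 3)
  X2 <- rbind(af$X, af$X)
  attr(X2, "region_id") <- rep(attr(af$X, "region_id"), 2)
  attr(X2, "epoch") <- rep(attr(af$X, "epoch"), 2)
  m1 <- cluster_cells(af$X, k = 4, seed = 1)
  m2 <- cluster_cells(X2, k = 4, seed = 1)
  n <- nrow(af$X)
  expect_equal(m2$labels[seq_len(n)], m2$labels[n + seq_len(n)])
  expect_equal(mclust::adjustedRandIndex(m1$labels, m2$labels[seq_len(n)]), 1)
})

test_that("bootstrap memberships are normalized, deterministic, and sharp when separated", {
  af <- archetype_features(per = 10, noise_sd = 0.01)
  m <- cluster_cells(af$X, k = 8, seed = 1)
  M1 <- bootstrap_membership(af$X, m, reps = 1, seed = 2)
  expect_true(all(M1 %in% c(0, 1)))          # single replicate is one-hot
  M <- bootstrap_membership(af$X, m, reps = 40, seed = 2)
  expect_equal(unname(rowSums(M)), rep(1, nrow(M)), tolerance = 1e-9)
  expect_true(all(apply(M, 1, max) >= 0.99)) # perfectly separated clusters
  M2 <- bootstrap_membership(af$X, m, reps = 40, seed = 2)
  expect_identical(M, M2)
  expect_error(bootstrap_membership(af$X, m, reps = 0), "domain")
})

test_that("overlapping clusters yield genuinely fuzzy memberships", {
  set.seed(8)
  a <- c(1, 0.5, 0.3); b <- c(1, 0.62, 0.3)  # ~5 degrees apart
  X <- rbind(matrix(rep(a, 15), ncol = 3, byrow = TRUE),
             matrix(rep(b, 15), ncol = 3, byrow = TRUE)) +
    matrix(rnorm(90, 0, 0.06), ncol = 3)
  X <- pmax(X, 1e-3); colnames(X) <- c("amw", "ach", "ndvi")
  m <- cluster_cells(X, k = 2, seed = 1)
  M <- bootstrap_membership(X, m, reps = 40, seed = 3)
  expect_true(any(apply(M, 1, max) < 0.9))
})

test_that("exchange matrices count flows and conserve marginals", {
  la <- stats::setNames(c(1, 1, 1, 1, 1), paste0("r", 1:5))
  lb <- stats::setNames(c(1, 1, 2, 2, 2), paste0("r", 1:5))
  M <- exchange_matrix(la, lb, k = 2)
  expect_equal(M["1", "2"], 3L)
  expect_equal(M["1", "1"], 2L)
  expect_equal(sum(M), 5L)
  # identity exchange is diagonal
  Mi <- exchange_matrix(la, la, k = 2)
  expect_true(all(Mi[row(Mi) != col(Mi)] == 0))
  expect_error(exchange_matrix(la, lb[1:4], k = 2), "mismatched")

  set.seed(13)
  for (i in 1:10) {
    k <- sample(2:6, 1); n <- sample(10:40, 1)
    ids <- paste0("g", seq_len(n))
    a <- stats::setNames(sample(k, n, replace = TRUE), ids)
    b <- stats::setNames(sample(k, n, replace = TRUE), ids)
    M <- exchange_matrix(a, b, k)
    expect_equal(unname(rowSums(M)), tabulate(a, k))
    expect_equal(unname(colSums(M)), tabulate(b, k))
    expect_equal(sum(M), n)
  }
})

test_that("a single cluster's profile equals the global means", {
  rec <- two_epoch_records(amw = c(300, 900, 600, 1200),
                           ach = c(5, 8, 4, 9), ndvi = c(0.5, 0.7, 0.6, 0.65))
  X <- normalize_features(rec)
  m <- cluster_cells(X, k = 1)
  prof <- cluster_profiles(m, X, rec)
  expect_equal(prof$amw_m, mean(rec$amw_m))
  expect_equal(prof$ach_m, mean(rec$ach_m))
  expect_equal(prof$size_first, 2L)
  expect_equal(prof$size_last, 2L)
  expect_equal(prof$growth_pct, 0)
})

test_that("planted cross-epoch migrations are recovered exactly when noiseless", {
  # 12 regions in a narrow/tall/green archetype; epoch B moves regions
  # 9..12 to a wide/short/dull one. The archetypes differ in profile shape
  # (cosangle is magnitude-blind): (0, 1, 1) vs (1, 0, 0) after pooled
  # min-max scaling, so the planted split is orthogonal under the metric.
  moved <- 9:12
  wf <- rep(1, 12); hf <- rep(1, 12); vf <- rep(1, 12)
  wf[moved] <- 4      # 600 -> 2400 m
  hf[moved] <- 0.25   # 12 -> 3 m
  vf[moved] <- 0.625  # 0.8 -> 0.5
  cfg <- demo_scene_config(widths = 600, heights = 12, ndvi = 0.8,
                           region_size_px = 20, nx = 240, ny = 120)
  pr <- generate_scene_pair(cfg, change_spec(width = wf, height = hf,
                                             ndvi = vf), seed = 6)
  recs <- rbind(extract_regions(pr[[1]], spacing = 300),
                extract_regions(pr[[2]], spacing = 300))
  X <- normalize_features(recs)
  m <- cluster_cells(X, k = 2, seed = 1)
  labs <- labels_by_epoch(m)
  M <- exchange_matrix(labs[[1]], labs[[2]], k = 2)
  # cluster 1 = tall archetype by the ACH ordering; flow 1 -> 2 = 4 regions
  expect_equal(M["1", "2"], 4L)
  expect_equal(M["1", "1"], 8L)
  expect_equal(M["2", "1"], 0L)
  expect_equal(sum(M), 12L)
})
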