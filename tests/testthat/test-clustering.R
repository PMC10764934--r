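test_that("correlation distance equals scaled squared Euclidean on row-standardized frames", {
  set.seed(1)
  r <- 30L
  for (rep in 1:20) {
    x <- rnorm(r); y <- rnorm(r)
    xs <- (x - mean(x)) / sd(x); ys <- (y - mean(y)) / sd(y)
    expect_equal(1 - cor(x, y), sum((xs - ys)^2) / (2 * (r - 1)),
                 tolerance = 1e-12)
  }
})

test_that("noiseless frames from orthogonal templates are perfectly partitioned", {
  fx <- orthogonal_frame_pool(k = 3L, r = 24L, frames_per = 10L)
  fit <- kmeans_correlation(fx$pool, 3L, n_init = 3L, seed = 4L)
  expect_lt(fit$inertia, 1e-12)
  # same partition as the truth up to label renaming
  expect_equal(length(unique(paste(fit$labels, fx$truth))), 3L)
  # centroids correlate perfectly with their templates
  m <- match_caps(fit$centroids, fx$templates)
  expect_equal(m$r, rep(1, 3), tolerance = 1e-12)
})

test_that("k-means is deterministic given a seed and labels partition the pool", {
  set.seed(2)
  pool <- matrix(rnorm(200 * 12), 200, 12)
  f1 <- kmeans_correlation(pool, 4L, seed = 9L)
  f2 <- kmeans_correlation(pool, 4L, seed = 9L)
  expect_identical(f1$labels, f2$labels)
  expect_identical(f1$inertia, f2$inertia)
  expect_identical(sum(f1$sizes), 200L)
  expect_identical(tabulate(f1$labels + 1L, 4L), f1$sizes)
  # occupancy ordering: label 0 is the largest cluster
  expect_true(all(diff(f1$sizes) <= 0))
})

test_that("within-initialization objective is non-increasing", {
  set.seed(5)
  pool <- matrix(rnorm(300 * 10), 300, 10)
  fit <- kmeans_correlation(pool, 3L, n_init = 1L, seed = 7L)
  expect_true(all(diff(fit$inertia_trace) <= 1e-10))
})

test_that("constant frames and degenerate pools are rejected", {
  pool <- rbind(matrix(rnorm(20 * 6), 20, 6), rep(1, 6))
  expect_error(kmeans_correlation(pool, 2L, seed = 1L), "constant frame")
  expect_error(kmeans_correlation(matrix(rnorm(12), 2, 6), 3L, seed = 1L),
               "more frames")
  expect_error(pool_frames(list()), "empty cohort")
})

test_that("pooling concatenates standardized series and keeps the subject map", {
  set.seed(6)
  mk <- function(id) zscore_series(roi_ts(matrix(rnorm(240 * 8), 240, 8), id))
  pooled <- pool_frames(list(mk("a"), mk("b")))
  expect_identical(dim(pooled$pool), c(480L, 8L))
  expect_identical(pooled$lengths, c(240L, 240L))
  expect_identical(pooled$subject, rep(1:2, each = 240L))
  raw <- roi_ts(matrix(rnorm(40), 10, 4), "raw")
  expect_error(pool_frames(list(raw)), "standardized")
})

test_that("correlation k-means induces the same partition as Euclidean geometry", {
  # nearest-centroid assignment in Euclidean distance on row-standardized
  # frames must reproduce the converged correlation-distance assignment
  set.seed(8)
  for (rep in 1:20) {
    pool <- matrix(rnorm(80 * 10), 80, 10)
    fit <- kmeans_correlation(pool, 3L, n_init = 2L, seed = rep)
    std_rows <- function(m) t(apply(m, 1, function(v) (v - mean(v)) / sd(v)))
    xs <- std_rows(pool)
    d2 <- as.matrix(dist(rbind(xs, std_rows(fit$centroids))))[1:80, 81:83]
    expect_identical(unname(max.col(-d2, ties.method = "first") - 1L),
                     fit$labels)
  }
})

test_that("validity indices pick k = 2 for two well-separated groups", {
  set.seed(10)
  fx <- orthogonal_frame_pool(k = 2L, r = 20L, frames_per = 25L)
  pool <- fx$pool + matrix(rnorm(length(fx$pool), 0, 0.15), nrow(fx$pool))
  vt <- compute_validity(pool, k_range = 2:6, seed = 3L, n_init = 2L)
  expect_identical(nrow(vt), 5L)
  expect_identical(vt$k[which.max(vt$silhouette)], 2L)
  expect_true(all(is.finite(unlist(vt[, -1]))))
  expect_error(compute_validity(pool, k_range = 1:4), "k_range")
})

test_that("Calinski-Harabasz typically shrinks with k on a single Gaussian cloud", {
  wins <- 0L
  for (s in 1:10) {
    set.seed(100 + s)
    pool <- matrix(rnorm(60 * 12), 60, 12)
    vt <- compute_validity(pool, k_range = c(2L, 5L), seed = s, n_init = 2L)
    wins <- wins + (vt$calinski_harabasz[1] > vt$calinski_harabasz[2])
  }
  expect_gte(wins, 6L)
})

test_that("a 19-row validity table covers k from 2 to 20", {
  set.seed(11)
  pool <- matrix(rnorm(120 * 8), 120, 8)
  vt <- compute_validity(pool, k_range = 2:20, seed = 1L, n_init = 1L,
                         max_iter = 20L)
  expect_identical(nrow(vt), 19L)
  expect_identical(vt$k, 2:20)
})

test_that("Z maps are subject-level means over their standard error", {
  # four subjects whose CAP-0 mean for ROI 1 is forced to 1, 2, 3, 4
  mk <- function(v, id) fake_series(cbind(rep(v, 4), rnorm(4)), id)
  series <- Map(mk, 1:4, paste0("s", 1:4))
  assignments <- rep(list(rep(0L, 4L)), 4L)
  z <- compute_cap_zmaps(series, assignments, k = 1L)
  expect_equal(z$zmaps[1, 1], 2.5 / (sd(1:4) / 2), tolerance = 1e-12)
  expect_equal(z$zmaps[1, 1], 3.873, tolerance = 1e-3)

  # symmetric subject means cancel to Z = 0
  series2 <- Map(mk, c(1, -1), c("a", "b"))
  z2 <- compute_cap_zmaps(series2, rep(list(rep(0L, 4L)), 2L), k = 1L)
  expect_equal(z2$zmaps[1, 1], 0)

  # a CAP visited by fewer than 2 subjects is flagged, not zeroed
  expect_warning(
    z3 <- compute_cap_zmaps(series, list(c(0L, 0L, 0L, 1L), rep(0L, 4L),
                                         rep(0L, 4L), rep(0L, 4L)), k = 2L),
    "visited by 1 subject")
  expect_true(all(is.na(z3$zmaps[2, ])))
})

test_that("network attribution matches hand-computed proportions", {
  atlas <- data.frame(roi_index = 0:3, roi_name = letters[1:4],
                      network = factor(c("A", "A", "B", "B")))
  z <- matrix(c(3, -2.5, 1, 2), 1)
  att <- attribute_networks(z, atlas, z_threshold = 1.96)
  expect_equal(unname(att$proportion[1, ]), c(5.5 / 7.5, 2 / 7.5),
               tolerance = 1e-12)
  expect_equal(sum(att$proportion[1, ]), 1)
  expect_equal(unname(att$positive[1, ]), c(3, 2))
  expect_equal(unname(att$negative[1, ]), c(2.5, 0))

  # concentration in one network
  z_dmn <- matrix(c(5, 4, 0.5, -1), 1)
  att2 <- attribute_networks(z_dmn, atlas)
  expect_equal(unname(att2$proportion[1, ]), c(1, 0))

  expect_warning(att3 <- attribute_networks(matrix(rep(0.5, 4), 1), atlas),
                 "no ROI exceeds")
  expect_true(all(att3$proportion == 0))
})

test_that("CAP spatial similarity is a correlation matrix detecting anti-pairs", {
  set.seed(12)
  a <- rnorm(30)
  z <- rbind(a, -a, rnorm(30))
  s <- cap_similarity(z)
  expect_equal(diag(s), rep(1, 3), ignore_attr = TRUE)
  expect_equal(s[1, 2], -1)
  expect_equal(s, t(s))
  expect_true(all(s >= -1 & s <= 1))
})

test_that("match_caps recovers a known permutation", {
  set.seed(13)
  ref <- matrix(rnorm(5 * 40), 5, 40)
  perm <- c(3L, 1L, 5L, 2L, 4L)
  x <- ref[perm, ] + matrix(rnorm(200, 0, 0.05), 5, 40)
  m <- match_caps(x, ref)
  expect_identical(m$perm, perm)
  expect_true(all(m$r > 0.95))
})
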