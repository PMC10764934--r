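test_that("dwell time and occurrence rate follow run-length bookkeeping", {
  # single uninterrupted run
  d <- dwell_and_occurrence(rep(0L, 240L), k = 2L, tr_seconds = 2)
  expect_equal(d$dwell_time[1], 480)
  expect_equal(d$total_dwell_time[1], 480)
  expect_equal(d$occurrence_rate[1], 1)
  expect_true(is.na(d$dwell_time[2]))
  expect_equal(d$occurrence_rate[2], 0)

  # hand-enumerated runs: CAP0 has runs (2, 1), CAP1 has run (2)
  d2 <- dwell_and_occurrence(c(0L, 0L, 1L, 1L, 0L), k = 2L, tr_seconds = 2)
  expect_equal(d2$dwell_time, c(3, 4))
  expect_equal(d2$total_dwell_time, c(6, 4))
  expect_equal(d2$occurrence_rate, c(0.6, 0.4))
  expect_equal(d2$n_runs, c(2L, 1L))

  expect_error(dwell_and_occurrence(c(0L, 5L), k = 2L), "labels must lie")
  expect_error(dwell_and_occurrence(1L, k = 2L), "T >= 2")
})

test_that("dwell/occurrence conservation holds on random sequences", {
  set.seed(20)
  for (rep in 1:50) {
    k <- sample(2:6, 1)
    t_len <- sample(50:300, 1)
    seq <- sample(0:(k - 1), t_len, replace = TRUE)
    d <- dwell_and_occurrence(seq, k, tr_seconds = 2)
    expect_equal(sum(d$total_dwell_time), t_len * 2)
    expect_equal(sum(d$occurrence_rate), 1)
    # mean run length x number of runs = total occupancy
    vis <- d$visited
    expect_equal(d$dwell_time[vis] * d$n_runs[vis], d$total_dwell_time[vis])
    tm <- estimate_transition_matrix(seq, k)
    expect_identical(sum(tm$counts), t_len - 1L)
  }
})

test_that("transition matrix estimation counts one-step pairs without smoothing", {
  tm <- estimate_transition_matrix(c(0L, 0L, 1L, 1L, 0L), k = 2L)
  expect_identical(tm$counts, matrix(c(1L, 1L, 1L, 1L), 2))
  expect_equal(tm$transition, matrix(0.5, 2, 2))

  # constant sequence: absorbing observation, other rows missing not zero
  tm2 <- estimate_transition_matrix(rep(1L, 10L), k = 3L)
  expect_equal(tm2$transition[2, 2], 1)
  expect_true(all(is.na(tm2$transition[c(1, 3), ])))

  # transitions are directional
  tm3 <- estimate_transition_matrix(c(0L, 1L, 1L, 0L, 1L), k = 2L)
  expect_false(isSymmetric(tm3$transition))
})

test_that("stationary distribution solves mu P = mu", {
  expect_equal(stationary_distribution(matrix(0.5, 2, 2)), c(0.5, 0.5))
  p <- matrix(c(0.9, 0.1, 0.5, 0.5), 2, byrow = TRUE)
  expect_equal(stationary_distribution(p), c(5 / 6, 1 / 6), tolerance = 1e-12)
  # deterministic 3-cycle is doubly stochastic: uniform
  cyc <- rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
  expect_equal(stationary_distribution(cyc), rep(1 / 3, 3))
  # reducible chain is refused with the unreachable states listed
  red <- rbind(c(1, 0), c(0.5, 0.5))
  expect_error(stationary_distribution(red), "reducible.*1")
  set.seed(21)
  for (rep in 1:20) {
    p <- random_chain(sample(2:6, 1))
    mu <- stationary_distribution(p)
    expect_equal(as.vector(mu %*% p), mu, tolerance = 1e-10)
    expect_equal(sum(mu), 1)
    expect_true(all(mu > 0))
  }
})

test_that("trajectory entropy matches closed forms for simple chains", {
  # deterministic cycles carry no randomness
  for (k in 2:5) {
    cyc <- diag(k)[c(2:k, 1), ]
    expect_equal(trajectory_entropy(cyc), matrix(0, k, k))
  }
  # symmetric 2-state chain: every trajectory entropy is 2 bits
  expect_equal(trajectory_entropy(matrix(0.5, 2, 2)), matrix(2, 2, 2))
  # 2-state chains: H_12 = h_1 / P_12 (trajectory 1 -> 2 is geometric)
  for (a in c(0.1, 0.3, 0.7)) {
    p <- rbind(c(1 - a, a), c(0.4, 0.6))
    h1 <- -(1 - a) * log2(1 - a) - a * log2(a)
    expect_equal(trajectory_entropy(p)[1, 2], h1 / a, tolerance = 1e-10)
  }
})

test_that("first-return entropy identity H_jj = H(P) / mu_j holds", {
  set.seed(22)
  for (rep in 1:30) {
    p <- random_chain(5)
    hh <- trajectory_entropy(p)
    mu <- stationary_distribution(p)
    expect_lt(max(abs(diag(hh) - entropy_rate(p) / mu)), 1e-9)
  }
})

test_that("trajectory entropy agrees with the truncated enumeration oracle", {
  set.seed(23)
  chains <- c(lapply(1:4, function(i) random_chain(2)),
              lapply(1:4, function(i) random_chain(3)))
  for (p in chains) {
    hh <- trajectory_entropy(p)
    k <- nrow(p)
    for (i in seq_len(k)) for (j in seq_len(k)) {
      expect_equal(hh[i, j], enumeration_trajectory_entropy(p, i, j),
                   tolerance = 1e-3)
    }
  }
})

test_that("trajectory entropy input contracts are enforced", {
  expect_error(trajectory_entropy(rbind(c(0.5, 0.4), c(0.5, 0.5))),
               "row-stochastic")
  expect_error(trajectory_entropy(rbind(c(1, 0), c(0.3, 0.7))), "reducible")
})

test_that("dynamic profiles leave unreachable entries missing, never zero", {
  # state 2 observed only as the final frame: no outgoing transition
  pr <- dynamic_profile(c(0L, 0L, 1L, 0L, 2L), k = 3L)
  expect_true(all(is.na(pr$transition[3, ])))
  expect_true(all(is.na(pr$trajectory_entropy)))
  expect_equal(pr$occurrence_rate, c(0.6, 0.2, 0.2))

  # irreducible observed chain gets a full entropy matrix on visited states
  set.seed(24)
  seq <- simulate_markov_chain(random_chain(3), 400L)
  pr2 <- dynamic_profile(seq, k = 3L)
  expect_true(all(is.finite(pr2$trajectory_entropy)))
  expect_true(all(pr2$trajectory_entropy >= 0))
  vis <- pr2$visited
  expect_equal(rowSums(pr2$transition[vis, , drop = FALSE]), rep(1, sum(vis)),
               tolerance = 1e-12)
})

test_that("longer self-transitions yield longer estimated dwell times", {
  mean_dwell <- function(self, seed) {
    set.seed(seed)
    p <- make_transition_matrix(self, 4L, seed = seed)
    seq <- simulate_markov_chain(p, 10000L)
    dwell_and_occurrence(seq, 4L, tr_seconds = 2)$dwell_time[1]
  }
  wins <- sum(vapply(1:5, function(s) mean_dwell(0.8, s) > mean_dwell(0.5, s + 50),
                     logical(1)))
  expect_gte(wins, 4L)
})

test_that("dynamics_table flattens profiles into the long format", {
  pr <- dynamic_profile(c(0L, 1L, 0L, 1L, 1L), k = 2L, subject_id = "s1")
  tab <- dynamics_table(list(pr))
  expect_setequal(unique(tab$metric),
                  c("dwell", "total_dwell", "occurrence", "transition",
                    "persistence", "traj_entropy"))
  expect_identical(nrow(tab), 3L * 2L + 4L + 4L)
  pers <- tab[tab$metric == "persistence", ]
  expect_equal(pers$cap_from, pers$cap_to)
  expect_equal(tab$value[tab$metric == "occurrence"], c(0.4, 0.6))
})
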