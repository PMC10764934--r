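#' Dwell time and occurrence rate of a CAP label sequence
#'
#' Dwell time of a CAP is the mean duration of its maximal contiguous runs,
#' in seconds (run length in frames times TR); total dwell time is its total
#' occupancy in seconds; occurrence rate is the fraction of frames assigned
#' to it. A CAP never visited has missing dwell times and occurrence 0.
#'
#' @param seq integer vector of 0-based CAP labels, length T >= 2.
#' @param k number of CAPs.
#' @param tr_seconds repetition time in seconds; default 2.
#' @return list with numeric length-K vectors \code{dwell_time},
#'   \code{total_dwell_time}, \code{occurrence_rate}, integer \code{n_runs}
#'   and logical \code{visited}.
#' @export
dwell_and_occurrence <- function(seq, k, tr_seconds = 2) {
  seq <- .check_labels(seq, k)
  t_len <- length(seq)
  runs <- rle(seq)
  dwell <- rep(NA_real_, k)
  total <- numeric(k)
  n_runs <- integer(k)
  for (c in 0:(k - 1L)) {
    len <- runs$lengths[runs$values == c]
    n_runs[c + 1L] <- length(len)
    total[c + 1L] <- sum(len) * tr_seconds
    if (length(len)) dwell[c + 1L] <- mean(len) * tr_seconds
  }
  list(dwell_time = dwell,
       total_dwell_time = total,
       occurrence_rate = total / (t_len * tr_seconds),
       n_runs = n_runs,
       visited = n_runs > 0L)
}

.check_labels <- function(seq, k) {
  seq <- as.integer(seq)
  if (length(seq) < 2L) stop("label sequence must have T >= 2", call. = FALSE)
  if (anyNA(seq) || any(seq < 0L) || any(seq >= k))
    stop("labels must lie in 0..", k - 1L, call. = FALSE)
  seq
}

#' Empirical transition matrix of a label sequence
#'
#' Counts one-step transitions c_ij = #\{t : seq_t = i, seq_{t+1} = j\} and
#' normalizes rows to probabilities. Rows of states with no outgoing
#' transition are NA (never silently zero); no smoothing is applied unless
#' \code{pseudo > 0} adds a Laplace pseudo-count for sensitivity analyses.
#'
#' @param seq integer vector of 0-based labels, length T >= 2.
#' @param k number of CAPs.
#' @param pseudo Laplace pseudo-count added to every cell; default 0.
#' @return list with \code{counts} (K x K integer) and \code{transition}
#'   (K x K row-stochastic with NA rows for unvisited states).
#' @export
estimate_transition_matrix <- function(seq, k, pseudo = 0) {
  seq <- .check_labels(seq, k)
  counts <- matrix(0L, k, k)
  from <- seq[-length(seq)] + 1L
  to <- seq[-1L] + 1L
  for (t in seq_along(from)) counts[from[t], to[t]] <- counts[from[t], to[t]] + 1L
  num <- counts + pseudo
  rs <- rowSums(num)
  p <- num / rs
  p[rs == 0, ] <- NA_real_
  list(counts = counts, transition = p)
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Solves mu P = mu with sum(mu) = 1 by a direct linear solve. P must be
#' irreducible (every state reachable from every other); otherwise the
#' unreachable states are reported.
#'
#' @param p K x K row-stochastic matrix.
#' @return numeric length-K probability vector, strictly positive.
#' @export
stationary_distribution <- function(p) {
  .check_stochastic(p)
  .check_irreducible(p)
  k <- nrow(p)
  # (P' - I) mu = 0 with the normalization row appended; solve by least squares
  a <- rbind(t(p) - diag(k), rep(1, k))
  b <- c(rep(0, k), 1)
  mu <- as.vector(qr.solve(a, b))
  mu <- pmax(mu, 0)
  mu / sum(mu)
}

.check_stochastic <- function(p, tol = 1e-9) {
  if (!is.matrix(p) || nrow(p) != ncol(p))
    stop("transition matrix must be square", call. = FALSE)
  if (anyNA(p))
    stop("transition matrix contains missing rows (unvisited states); ",
         "restrict to the visited subchain first", call. = FALSE)
  if (any(p < -tol) || any(abs(rowSums(p) - 1) > tol))
    stop("matrix is not row-stochastic (rows must sum to 1)", call. = FALSE)
}

.check_irreducible <- function(p) {
  k <- nrow(p)
  adj <- p > 0
  reach <- adj | diag(k)
  for (i in seq_len(ceiling(log2(k)) + 1L))
    reach <- (reach %*% reach) > 0
  if (!all(reach)) {
    bad <- which(!apply(reach, 2L, all)) - 1L
    stop("chain is reducible; unreachable state(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Per-state step entropy of a transition matrix
#'
#' h_i = -sum_j P_ij log P_ij with 0 log 0 = 0; base-2 by default (bits).
#'
#' @param p K x K row-stochastic matrix.
#' @param base logarithm base; 2 for bits (default), exp(1) for nats.
#' @return numeric length-K vector.
#' @export
step_entropy <- function(p, base = 2) {
  terms <- ifelse(p > 0, -p * log(p, base = base), 0)
  rowSums(terms)
}

#' Entropy rate of an ergodic Markov chain
#'
#' H(P) = sum_i mu_i h_i, the expected per-step entropy under the stationary
#' distribution.
#'
#' @inheritParams step_entropy
#' @return scalar entropy rate.
#' @export
entropy_rate <- function(p, base = 2) {
  sum(stationary_distribution(p) * step_entropy(p, base = base))
}

#' Entropy of Markov trajectories
#'
#' For an irreducible chain with transition matrix P, entry (i, j) is the
#' Shannon entropy of the random trajectory started in state i and stopped
#' on first hitting state j; the diagonal (j = i) is the entropy of the
#' first-return trajectory. Low entropy towards a destination means that
#' destination is reached along predictable routes (it is "more accessible").
#'
#' Computed by solving, for each destination j, the defining recursion
#' H_ij = h_i + sum_\{m != j\} P_im H_mj, a K x K linear system, where h_i is
#' the per-step entropy of row i. The solution satisfies the first-return
#' identity H_jj = H(P) / mu_j with H(P) the entropy rate and mu the
#' stationary distribution, which serves as an internal cross-check.
#'
#' @param p K x K row-stochastic irreducible matrix.
#' @param base logarithm base; 2 for bits (default).
#' @return K x K matrix of trajectory entropies (non-negative).
#' @references Ekroot, L. and Cover, T. M. (1993). The entropy of Markov
#'   trajectories. IEEE Transactions on Information Theory 39(4), 1418-1421.
#' @export
trajectory_entropy <- function(p, base = 2) {
  .check_stochastic(p)
  .check_irreducible(p)
  k <- nrow(p)
  h <- step_entropy(p, base = base)
  out <- matrix(NA_real_, k, k)
  for (j in seq_len(k)) {
    pj <- p
    pj[, j] <- 0                       # trajectories stop at j
    a <- diag(k) - pj
    if (rcond(a) < 1e-12)
      stop("trajectory-entropy system ill-conditioned for destination ",
           j - 1L, call. = FALSE)
    out[, j] <- solve(a, h)
  }
  pmax(out, 0)
}

#' Full dynamic profile of one subject
#'
#' Bundles all dynamic metrics of a single CAP label sequence: dwell times,
#' occurrence rates, the transition matrix (diagonal = persistence
#' probabilities) and the trajectory-entropy matrix. Entropy requires the
#' observed transition matrix restricted to visited states to be
#' irreducible; otherwise the entropy matrix stays NA for the affected
#' entries (excluded pairwise from group tests downstream, never zeroed).
#'
#' @param seq integer vector of 0-based labels.
#' @param k number of CAPs.
#' @param tr_seconds repetition time in seconds.
#' @param subject_id optional identifier carried into the output.
#' @param base entropy logarithm base (2 = bits).
#' @param pseudo optional Laplace pseudo-count for the transition matrix.
#' @return An object of class \code{dynamic_profile}.
#' @export
dynamic_profile <- function(seq, k, tr_seconds = 2, subject_id = NA_character_,
                            base = 2, pseudo = 0) {
  occ <- dwell_and_occurrence(seq, k, tr_seconds)
  tm <- estimate_transition_matrix(seq, k, pseudo = pseudo)
  ent <- matrix(NA_real_, k, k)
  vis <- which(occ$visited)
  if (length(vis) >= 1L) {
    sub <- tm$transition[vis, vis, drop = FALSE]
    ok <- !anyNA(sub) &&
      all(abs(rowSums(sub) - 1) < 1e-9) &&
      .is_irreducible(sub)
    if (ok && length(vis) >= 2L)
      ent[vis, vis] <- trajectory_entropy(sub, base = base)
    else if (ok && length(vis) == 1L)
      ent[vis, vis] <- 0               # single absorbing state: no randomness
  }
  structure(
    list(subject_id = subject_id,
         k = as.integer(k),
         dwell_time = occ$dwell_time,
         total_dwell_time = occ$total_dwell_time,
         occurrence_rate = occ$occurrence_rate,
         n_runs = occ$n_runs,
         transition = tm$transition,
         counts = tm$counts,
         trajectory_entropy = ent,
         visited = occ$visited,
         tr_seconds = tr_seconds),
    class = "dynamic_profile")
}

.is_irreducible <- function(p) {
  ok <- TRUE
  tryCatch(.check_irreducible(p), error = function(e) ok <<- FALSE)
  ok
}

#' @export
print.dynamic_profile <- function(x, ...) {
  cat(sprintf("<dynamic_profile> subject '%s', k = %d, %d CAP(s) visited\n",
              x$subject_id, x$k, sum(x$visited)))
  cat("occurrence:", paste(sprintf("%.3f", x$occurrence_rate), collapse = " "), "\n")
  invisible(x)
}

#' Dynamic profiles for every subject of a fitted CAP model
#'
#' @param model \code{cap_model} with per-subject assignments.
#' @param tr_seconds repetition time; defaults to the value carried by the
#'   model (from the pooled cohort), else 2.
#' @param base,pseudo passed to [dynamic_profile()].
#' @return named list of \code{dynamic_profile} objects.
#' @export
cohort_dynamics <- function(model, tr_seconds = NULL, base = 2, pseudo = 0) {
  stopifnot(inherits(model, "cap_model"), !is.null(model$assignments))
  if (is.null(tr_seconds)) tr_seconds <- if (!is.null(model$tr_seconds)) model$tr_seconds else 2
  out <- lapply(seq_along(model$assignments), function(i) {
    dynamic_profile(model$assignments[[i]], model$k, tr_seconds,
                    subject_id = names(model$assignments)[i],
                    base = base, pseudo = pseudo)
  })
  names(out) <- names(model$assignments)
  out
}

#' Long-format table of dynamic metrics
#'
#' Flattens a list of dynamic profiles into a tidy table, one row per
#' subject x metric x CAP (or CAP pair for matrix metrics).
#'
#' @param profiles list of \code{dynamic_profile} objects.
#' @return data.frame with columns \code{subject_id}, \code{metric}
#'   (dwell, total_dwell, occurrence, transition, persistence,
#'   traj_entropy), \code{cap_from}, \code{cap_to} (NA for vector metrics),
#'   \code{value}.
#' @export
dynamics_table <- function(profiles) {
  rows <- lapply(profiles, function(pr) {
    k <- pr$k
    caps <- 0:(k - 1L)
    vec <- data.frame(
      subject_id = pr$subject_id,
      metric = rep(c("dwell", "total_dwell", "occurrence"), each = k),
      cap_from = rep(caps, 3L), cap_to = NA_integer_,
      value = c(pr$dwell_time, pr$total_dwell_time, pr$occurrence_rate))
    grid <- expand.grid(cap_from = caps, cap_to = caps)
    mat <- data.frame(
      subject_id = pr$subject_id,
      metric = ifelse(grid$cap_from == grid$cap_to, "persistence", "transition"),
      cap_from = grid$cap_from, cap_to = grid$cap_to,
      value = pr$transition[cbind(grid$cap_from + 1L, grid$cap_to + 1L)])
    ent <- data.frame(
      subject_id = pr$subject_id,
      metric = "traj_entropy",
      cap_from = grid$cap_from, cap_to = grid$cap_to,
      value = pr$trajectory_entropy[cbind(grid$cap_from + 1L, grid$cap_to + 1L)])
    rbind(vec, mat, ent)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
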