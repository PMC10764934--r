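#' Pool standardized frames across subjects
#'
#' Stacks all subjects' standardized frames into one N x R matrix (N = sum of
#' per-subject frame counts), ordered by subject then time, together with a
#' frame-to-subject map so per-subject label sequences can be recovered after
#' clustering.
#'
#' @param series list of standardized \code{roi_ts} objects with equal R.
#' @return list with \code{pool} (N x R matrix), \code{subject} (integer
#'   vector length N, index into \code{series}), \code{subject_ids},
#'   \code{lengths} (frames per subject) and \code{tr_seconds}.
#' @export
pool_frames <- function(series) {
  if (length(series) == 0L) stop("empty cohort: no series to pool", call. = FALSE)
  std <- vapply(series, function(s) isTRUE(s$standardized), logical(1))
  if (!all(std))
    stop("all series must be standardized before pooling; offending subject(s): ",
         paste(vapply(series[!std], `[[`, "", "subject_id"), collapse = ", "),
         call. = FALSE)
  rs <- vapply(series, function(s) ncol(s$data), integer(1))
  if (length(unique(rs)) != 1L)
    stop("series disagree on ROI count: ", paste(unique(rs), collapse = ", "),
         call. = FALSE)
  trs <- vapply(series, function(s) s$tr_seconds, numeric(1))
  lens <- vapply(series, function(s) nrow(s$data), integer(1))
  list(pool = do.call(rbind, lapply(series, `[[`, "data")),
       subject = rep(seq_along(series), lens),
       subject_ids = vapply(series, `[[`, "", "subject_id"),
       lengths = lens,
       tr_seconds = trs[1])
}

# Row-standardize frames so that 1 - cor(x, y) = ||xs - ys||^2 / (2 (R - 1)).
# Errors on constant frames, which have no defined correlation distance.
.row_standardize <- function(x, what = "frame") {
  m <- rowMeans(x)
  v <- rowSums((x - m)^2) / (ncol(x) - 1L)
  bad <- which(v <= 0)
  if (length(bad))
    stop("constant ", what, "(s) (zero variance across ROIs): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  (x - m) / sqrt(v)
}

# k-means++ seeding in the correlation distance: first centroid uniform,
# each next frame drawn with probability proportional to its squared
# distance to the nearest centroid chosen so far.
.init_kmeanspp <- function(xs, k) {
  n <- nrow(xs)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  d <- 1 - tcrossprod(xs, xs[idx[1], , drop = FALSE])[, 1] / (ncol(xs) - 1L)
  for (i in 2:k) {
    w <- pmax(d, 0)^2
    idx[i] <- if (sum(w) > 0) sample.int(n, 1L, prob = w) else sample.int(n, 1L)
    di <- 1 - tcrossprod(xs, xs[idx[i], , drop = FALSE])[, 1] / (ncol(xs) - 1L)
    d <- pmin(d, di)
  }
  xs[idx, , drop = FALSE]
}

# Correlation of every row of xs (row-standardized) with every row of the
# (not necessarily standardized) centroid matrix.
.frame_centroid_cor <- function(xs, centroids) {
  cs <- .row_standardize(centroids, what = "centroid")
  tcrossprod(xs, cs) / (ncol(xs) - 1L)
}

#' Temporal k-means clustering of frames with a correlation distance
#'
#' Clusters pooled frames into K co-activation patterns (CAPs) by Lloyd's
#' algorithm under the distance d(x, y) = 1 - Pearson(x, y) between frames.
#' This equals squared Euclidean distance on row-standardized frames divided
#' by 2(R - 1), so updates use cluster means of row-standardized frames.
#' The best of \code{n_init} random initializations (frames drawn uniformly
#' as starting centroids) by total within-cluster distance is kept.
#' Cluster labels are relabelled by pooled occupancy, largest cluster first,
#' so label 0 is always the most occupied CAP.
#'
#' @param pool N x R matrix of standardized frames (or a list from
#'   [pool_frames()], whose map is then carried through).
#' @param k number of CAPs (>= 2).
#' @param n_init independent random initializations; default 5.
#' @param max_iter iteration cap per initialization; default 500.
#' @param init \code{"kmeanspp"} (default) seeds each initialization by
#'   D-squared sampling in the correlation distance (the k-means++ scheme,
#'   which modern k-means implementations apply under random restarts);
#'   \code{"uniform"} draws starting centroids uniformly from the frames.
#' @param seed integer seed making the run reproducible.
#' @return An object of class \code{cap_model}: \code{k}, \code{centroids}
#'   (K x R cluster means of row-standardized frames), \code{labels}
#'   (length-N 0-based pooled assignment), \code{assignments} (per-subject
#'   list of 0-based sequences, when a pooled input with map was given),
#'   \code{inertia} (total within-cluster correlation distance),
#'   \code{inertia_trace} (objective after each assignment step of the best
#'   run), \code{seed}, \code{sizes}.
#' @export
kmeans_correlation <- function(pool, k, n_init = 5L, max_iter = 500L,
                               init = c("kmeanspp", "uniform"), seed = 1L) {
  map <- NULL
  if (is.list(pool) && !is.null(pool$pool)) { map <- pool; pool <- pool$pool }
  init <- match.arg(init)
  stopifnot(is.matrix(pool), k >= 2L)
  n <- nrow(pool)
  if (n <= k) stop("need more frames (", n, ") than clusters (", k, ")", call. = FALSE)
  xs <- .row_standardize(pool)
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (rep_i in seq_len(n_init)) {
    centroids <- if (init == "kmeanspp") .init_kmeanspp(xs, k)
                 else xs[sample.int(n, k), , drop = FALSE]
    labels <- integer(n)
    trace <- numeric(0)
    for (iter in seq_len(max_iter)) {
      s <- .frame_centroid_cor(xs, centroids)
      new_labels <- max.col(s, ties.method = "first")
      trace <- c(trace, sum(1 - s[cbind(seq_len(n), new_labels)]))
      # re-seed any emptied cluster from the frame farthest from its centroid
      empty <- setdiff(seq_len(k), unique(new_labels))
      if (length(empty)) {
        d_own <- 1 - s[cbind(seq_len(n), new_labels)]
        for (e in empty) {
          far <- which.max(d_own)
          new_labels[far] <- e
          d_own[far] <- -Inf
          message("k-means: re-seeded empty cluster ", e, " from farthest frame ", far)
        }
      }
      converged <- identical(new_labels, labels)
      labels <- new_labels
      if (converged) break
      centroids <- t(vapply(seq_len(k),
                            function(c) colMeans(xs[labels == c, , drop = FALSE]),
                            numeric(ncol(xs))))
    }
    s <- .frame_centroid_cor(xs, centroids)
    inertia <- sum(1 - s[cbind(seq_len(n), labels)])
    if (is.null(best) || inertia < best$inertia)
      best <- list(centroids = centroids, labels = labels,
                   inertia = inertia, trace = trace)
  }
  # relabel by occupancy (descending; ties keep original order)
  counts <- tabulate(best$labels, nbins = k)
  ord <- order(-counts, seq_len(k))
  relab <- integer(k); relab[ord] <- seq_len(k)
  labels0 <- relab[best$labels] - 1L
  model <- structure(
    list(k = as.integer(k),
         centroids = best$centroids[ord, , drop = FALSE],
         labels = labels0,
         assignments = NULL,
         subject_ids = NULL,
         tr_seconds = NULL,
         inertia = best$inertia,
         inertia_trace = best$trace,
         seed = seed,
         sizes = counts[ord]),
    class = "cap_model")
  if (!is.null(map)) {
    model$assignments <- split(labels0, map$subject)
    names(model$assignments) <- map$subject_ids
    model$subject_ids <- map$subject_ids
    model$tr_seconds <- map$tr_seconds
  }
  model
}

#' @export
print.cap_model <- function(x, ...) {
  cat(sprintf("<cap_model> k = %d, %d frames, inertia = %.4f, seed = %s\n",
              x$k, length(x$labels), x$inertia, format(x$seed)))
  cat("cluster sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Cluster-number validity indices over a range of k
#'
#' Computes, per candidate k, the within-cluster distance sum (elbow
#' criterion), mean silhouette and Dunn index in the correlation-distance
#' geometry, and Calinski-Harabasz and Davies-Bouldin in the Euclidean
#' geometry of row-standardized frames.
#'
#' @param pool N x R matrix (or [pool_frames()] output) of standardized frames.
#' @param k_range integer vector of candidate cluster numbers, default 2:20.
#' @param seed integer seed.
#' @param n_init,max_iter passed to [kmeans_correlation()].
#' @return data.frame with one row per k: \code{k}, \code{elbow_wss},
#'   \code{silhouette}, \code{calinski_harabasz}, \code{davies_bouldin},
#'   \code{dunn}.
#' @export
compute_validity <- function(pool, k_range = 2:20, seed = 1L,
                             n_init = 5L, max_iter = 500L) {
  if (is.list(pool) && !is.null(pool$pool)) pool <- pool$pool
  n <- nrow(pool)
  if (any(k_range < 2L) || any(k_range >= n))
    stop("k_range must lie within [2, N-1]", call. = FALSE)
  xs <- .row_standardize(pool)
  dmat <- 1 - stats::cor(t(pool))          # correlation distances, N x N
  out <- lapply(seq_along(k_range), function(i) {
    k <- k_range[i]
    fit <- kmeans_correlation(pool, k, n_init = n_init, max_iter = max_iter,
                              seed = seed + i - 1L)
    lab <- fit$labels + 1L
    data.frame(k = k,
               elbow_wss = fit$inertia,
               silhouette = .mean_silhouette(dmat, lab),
               calinski_harabasz = .calinski_harabasz(xs, lab),
               davies_bouldin = .davies_bouldin(xs, lab),
               dunn = .dunn_index(dmat, lab))
  })
  do.call(rbind, out)
}

.mean_silhouette <- function(dmat, lab) {
  k <- max(lab)
  n <- length(lab)
  if (k < 2L) return(NA_real_)
  sil <- numeric(n)
  for (i in seq_len(n)) {
    di <- dmat[i, ]
    own <- lab == lab[i]
    n_own <- sum(own) - 1L
    if (n_own == 0L) { sil[i] <- 0; next }   # singleton convention
    a <- sum(di[own]) / n_own
    b <- min(vapply(setdiff(seq_len(k), lab[i]),
                    function(c) mean(di[lab == c]), numeric(1)))
    sil[i] <- (b - a) / max(a, b)
  }
  mean(sil)
}

.calinski_harabasz <- function(x, lab) {
  n <- nrow(x); k <- max(lab)
  g <- colMeans(x)
  w <- 0; b <- 0
  for (c in seq_len(k)) {
    xc <- x[lab == c, , drop = FALSE]
    mc <- colMeans(xc)
    w <- w + sum(sweep(xc, 2L, mc)^2)
    b <- b + nrow(xc) * sum((mc - g)^2)
  }
  (b / (k - 1)) / (w / (n - k))
}

.davies_bouldin <- function(x, lab) {
  k <- max(lab)
  cent <- t(vapply(seq_len(k), function(c) colMeans(x[lab == c, , drop = FALSE]),
                   numeric(ncol(x))))
  scat <- vapply(seq_len(k), function(c) {
    xc <- x[lab == c, , drop = FALSE]
    mean(sqrt(rowSums(sweep(xc, 2L, cent[c, ])^2)))
  }, numeric(1))
  mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      (scat[i] + scat[j]) / sqrt(sum((cent[i, ] - cent[j, ])^2))
    }, numeric(1)))
  }, numeric(1)))
}

.dunn_index <- function(dmat, lab) {
  k <- max(lab)
  diam <- max(vapply(seq_len(k), function(c) {
    idx <- which(lab == c)
    if (length(idx) < 2L) 0 else max(dmat[idx, idx])
  }, numeric(1)))
  sep <- min(vapply(seq_len(k - 1L), function(i) {
    min(vapply((i + 1L):k, function(j) {
      min(dmat[lab == i, lab == j, drop = FALSE])
    }, numeric(1)))
  }, numeric(1)))
  sep / diam
}

#' Group-level Z-statistic CAP maps
#'
#' For each CAP, averages every subject's standardized frames assigned to it
#' into a subject-level mean map, then forms the across-subject one-sample
#' Z statistic per ROI: mean divided by the standard error (sample SD over
#' contributing subjects divided by the square root of their number).
#' Subjects contributing no frame to a CAP are excluded from that CAP's map;
#' CAPs visited by fewer than two subjects get an all-NA row and a warning.
#'
#' @param series list of standardized \code{roi_ts} objects.
#' @param assignments per-subject list of 0-based CAP label sequences
#'   (e.g. \code{model$assignments}).
#' @param k number of CAPs; default inferred from the labels.
#' @return list with \code{zmaps} (K x R), \code{n_subjects} (subjects
#'   contributing to each CAP), \code{subject_means} (K-list of n_c x R
#'   matrices of subject-level mean maps).
#' @export
compute_cap_zmaps <- function(series, assignments, k = NULL) {
  stopifnot(length(series) == length(assignments))
  if (is.null(k)) k <- max(unlist(assignments)) + 1L
  r <- ncol(series[[1]]$data)
  subject_means <- vector("list", k)
  for (c in seq_len(k)) {
    rows <- lapply(seq_along(series), function(s) {
      idx <- which(assignments[[s]] == c - 1L)
      if (!length(idx)) return(NULL)
      colMeans(series[[s]]$data[idx, , drop = FALSE])
    })
    subject_means[[c]] <- do.call(rbind, rows)
  }
  zmaps <- matrix(NA_real_, k, r)
  n_subj <- integer(k)
  for (c in seq_len(k)) {
    v <- subject_means[[c]]
    n_subj[c] <- if (is.null(v)) 0L else nrow(v)
    if (n_subj[c] < 2L) {
      warning("CAP ", c - 1L, " visited by ", n_subj[c],
              " subject(s); Z map undefined", call. = FALSE)
      next
    }
    mu <- colMeans(v)
    se <- apply(v, 2L, stats::sd) / sqrt(n_subj[c])
    zmaps[c, ] <- ifelse(se > 0, mu / se, NA_real_)
  }
  list(zmaps = zmaps, n_subjects = n_subj, subject_means = subject_means)
}

#' Attribute CAPs to functional networks
#'
#' Two complementary readings of a CAP's Z map against a network atlas.
#' Method 1: the proportion of the summed absolute Z statistic of
#' supra-threshold ROIs (|Z| > \code{z_threshold}) inside each network,
#' relative to all supra-threshold ROIs. Method 2: per network, the summed
#' |Z| over supra-threshold positively activated ROIs and, separately, over
#' supra-threshold de-activated ROIs.
#'
#' @param zmaps K x R matrix of CAP Z statistics.
#' @param atlas atlas data.frame from [read_atlas()].
#' @param z_threshold significance cut-off on |Z|; default 1.96.
#' @return list with \code{proportion}, \code{positive}, \code{negative}
#'   (each K x n_networks, columns named by network) and \code{z_threshold}.
#' @export
attribute_networks <- function(zmaps, atlas, z_threshold = 1.96) {
  stopifnot(ncol(zmaps) == nrow(atlas))
  nets <- levels(atlas$network)
  k <- nrow(zmaps)
  prop <- pos <- neg <- matrix(0, k, length(nets), dimnames = list(NULL, nets))
  for (c in seq_len(k)) {
    z <- zmaps[c, ]
    supra <- !is.na(z) & abs(z) > z_threshold
    if (!any(supra)) {
      warning("CAP ", c - 1L, ": no ROI exceeds |Z| > ", z_threshold,
              "; attribution is all zero", call. = FALSE)
      next
    }
    total <- sum(abs(z[supra]))
    for (j in seq_along(nets)) {
      in_net <- atlas$network == nets[j]
      prop[c, j] <- sum(abs(z[supra & in_net])) / total
      pos[c, j] <- sum(abs(z[supra & in_net & z > 0]))
      neg[c, j] <- sum(abs(z[supra & in_net & z < 0]))
    }
  }
  list(proportion = prop, positive = pos, negative = neg,
       z_threshold = z_threshold)
}

#' Spatial similarity between CAP maps
#'
#' Pairwise Pearson correlation between CAP Z maps (rows). Strongly
#' anti-correlated pairs mark CAPs with opposite spatial configurations.
#'
#' @param zmaps K x R matrix (K >= 2).
#' @return K x K symmetric correlation matrix with unit diagonal.
#' @export
cap_similarity <- function(zmaps) {
  stopifnot(nrow(zmaps) >= 2L)
  stats::cor(t(zmaps))
}

#' Match CAPs to reference patterns by spatial correlation
#'
#' Finds the one-to-one assignment of rows of \code{x} to rows of \code{ref}
#' maximizing the total Pearson correlation (exhaustive over permutations for
#' K <= 8, greedy beyond). Used to align estimated centroids with generating
#' templates, or CAP sets across different k or atlases.
#'
#' @param x K x R matrix (e.g. centroids or Z maps).
#' @param ref K x R reference matrix (e.g. templates).
#' @return list with \code{perm} (row of \code{ref} matched to each row of
#'   \code{x}), \code{r} (matched correlations) and \code{total}.
#' @export
match_caps <- function(x, ref) {
  stopifnot(nrow(x) == nrow(ref))
  k <- nrow(x)
  cc <- stats::cor(t(x), t(ref))
  if (k <= 8L) {
    perms <- .permutations(k)
    tot <- apply(perms, 1L, function(p) sum(cc[cbind(seq_len(k), p)]))
    best <- perms[which.max(tot), ]
  } else {
    best <- integer(k)
    avail <- seq_len(k)
    for (i in order(-apply(cc, 1L, max))) {
      j <- avail[which.max(cc[i, avail])]
      best[i] <- j
      avail <- setdiff(avail, j)
    }
  }
  best <- unname(best)
  list(perm = best, r = unname(cc[cbind(seq_len(k), best)]),
       total = sum(cc[cbind(seq_len(k), best)]))
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(c(seq_len(n))[-i][sub], nrow(sub), n - 1L))
  }))
}
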