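#' Covariate-adjusted two-sample group test
#'
#' Tests a per-subject quantity for a group difference while controlling for
#' nuisance covariates, as the group coefficient of the ordinary
#' least-squares model \code{value ~ group + covariates} (categorical
#' covariates dummy-coded, reference = first level alphabetically). With no
#' covariates this reduces exactly to the classical pooled-variance
#' two-sample t-test. Subjects with any missing value are dropped listwise.
#'
#' @param values numeric vector, one per subject.
#' @param group factor or vector with exactly two levels; the reported
#'   contrast is second level minus first (alphabetical) level.
#' @param covariates optional data.frame of nuisance covariates (e.g. age,
#'   sex, education, site, mean framewise displacement).
#' @return list with \code{t}, \code{df}, \code{p} (two-tailed),
#'   \code{estimate} (adjusted group difference), \code{group_means},
#'   \code{group_sem} (raw per-group mean and standard error of the mean)
#'   and \code{n} (subjects used after listwise deletion).
#' @export
adjusted_group_test <- function(values, group, covariates = NULL) {
  group <- factor(group)
  if (nlevels(group) != 2L)
    stop("`group` must have exactly two levels", call. = FALSE)
  df <- data.frame(.value = values, .group = group)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0L) {
    covariates <- as.data.frame(covariates)
    for (v in names(covariates))
      if (is.character(covariates[[v]])) covariates[[v]] <- factor(covariates[[v]])
    df <- cbind(df, covariates)
  }
  keep <- stats::complete.cases(df)
  df <- df[keep, , drop = FALSE]
  if (!all(levels(group) %in% unique(as.character(df$.group))))
    stop("both group levels must be present after dropping missing values",
         call. = FALSE)
  n_cov <- ncol(df) - 2L
  if (nrow(df) < n_cov + 3L)
    stop("too few complete cases (", nrow(df), ") for ", n_cov, " covariate(s)",
         call. = FALSE)
  fit <- stats::lm(.value ~ ., data = df)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  row <- grep("^\\.group", rownames(sm))[1]
  means <- tapply(df$.value, df$.group, mean)
  sems <- tapply(df$.value, df$.group,
                 function(x) stats::sd(x) / sqrt(length(x)))
  list(t = unname(sm[row, "t value"]),
       df = fit$df.residual,
       p = unname(sm[row, "Pr(>|t|)"]),
       estimate = unname(sm[row, "Estimate"]),
       group_means = means, group_sem = sems,
       n = nrow(df))
}

#' Partial Pearson correlation
#'
#' Pearson correlation between the OLS residuals of \code{x} and \code{y}
#' after regressing each on the covariates (plus an intercept). The p-value
#' uses t = r sqrt((n - 2 - c) / (1 - r^2)) with c covariate columns of the
#' dummy-coded design, on n - 2 - c degrees of freedom. With no covariates
#' this is the plain Pearson correlation and its usual test.
#'
#' @param x,y numeric vectors of equal length.
#' @param covariates optional data.frame of covariates.
#' @return list with \code{r}, \code{p}, \code{df} and \code{n}.
#' @export
partial_pearson <- function(x, y, covariates = NULL) {
  df <- data.frame(.x = x, .y = y)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0L) {
    covariates <- as.data.frame(covariates)
    for (v in names(covariates))
      if (is.character(covariates[[v]])) covariates[[v]] <- factor(covariates[[v]])
    df <- cbind(df, covariates)
  }
  keep <- stats::complete.cases(df)
  df <- df[keep, , drop = FALSE]
  n <- nrow(df)
  if (ncol(df) > 2L) {
    design <- stats::model.matrix(~ ., data = df[, -(1:2), drop = FALSE])
    n_cov <- ncol(design) - 1L
    rx <- stats::lm.fit(design, df$.x)$residuals
    ry <- stats::lm.fit(design, df$.y)$residuals
  } else {
    n_cov <- 0L
    rx <- df$.x - mean(df$.x)
    ry <- df$.y - mean(df$.y)
  }
  if (n < n_cov + 4L)
    stop("too few complete cases (", n, ") for ", n_cov, " covariate column(s)",
         call. = FALSE)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("constant residuals; partial correlation undefined", call. = FALSE)
  r <- stats::cor(rx, ry)
  dfree <- n - 2L - n_cov
  tval <- r * sqrt(dfree / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(tval), dfree), df = dfree, n = n)
}

#' Benjamini-Hochberg FDR adjustment within a family
#'
#' Step-up adjusted q-values q_(i) = min_\{j >= i\}(p_(j) m / j), capped at 1,
#' computed over the declared family of m tests. NA entries are passed
#' through without contributing to m.
#'
#' @param pvals numeric vector of raw p-values in [0, 1].
#' @return numeric vector of q-values, same order as the input.
#' @export
fdr_bh <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  out <- rep(NA_real_, length(pvals))
  p <- pvals[ok]
  m <- length(p)
  if (m) {
    ord <- order(p)
    scaled <- p[ord] * m / seq_len(m)
    q <- pmin(1, rev(cummin(rev(scaled))))
    out[ok][ord] <- q
  }
  out
}

#' Pearson chi-square test for a 2 x 2 table
#'
#' Pearson's chi-square without continuity correction, df = 1. Used for
#' categorical demographics (e.g. sex counts per group).
#'
#' @param tab 2 x 2 matrix of non-negative integer counts with positive
#'   marginals.
#' @return list with \code{chi2}, \code{df}, \code{p}.
#' @export
chisq_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)))
  if (any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("all marginals must be positive", call. = FALSE)
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Mann-Whitney U test (normal approximation, tie-corrected)
#'
#' Two-sided rank-sum test for continuous demographics (age, education).
#' U counts pairs (x_i, y_j) with x_i < y_j plus half the ties; z is the
#' tie-corrected normal approximation without continuity correction.
#'
#' @param x,y numeric samples.
#' @return list with \code{U}, \code{z}, \code{p}.
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be non-empty", call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # pairs with x > y (+ half ties)
  mu <- n1 * n2 / 2
  nties <- table(r)
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(nties^3 - nties) / (n * (n - 1)))
  z <- if (sigma2 > 0) (u - mu) / sqrt(sigma2) else 0
  list(U = u, z = z, p = if (sigma2 > 0) 2 * stats::pnorm(-abs(z)) else 1)
}

#' Group contrasts of dynamic metrics with family-wise FDR
#'
#' Runs [adjusted_group_test()] for every dynamic metric of a cohort and
#' controls the false discovery rate within metric families mirroring how
#' such results are reported: per-CAP metrics (dwell, total dwell,
#' occurrence) within the K CAPs; matrix metrics (transition including
#' persistence, trajectory entropy) within the K x K paths.
#'
#' @param dyn long-format table from [dynamics_table()].
#' @param manifest cohort manifest (subject_id, group, covariates).
#' @param covariate_names character; default
#'   \code{c("age","sex","education","site","mean_fd")}. Covariates constant
#'   across the cohort are dropped automatically.
#' @param group_levels optional length-2 character to subset/order groups.
#' @return data.frame (class \code{stat_table}): metric, cap_from, cap_to,
#'   per-group mean and SEM, t, df, p, q, family, n.
#' @export
group_contrast_table <- function(dyn, manifest,
                                 covariate_names = c("age", "sex", "education",
                                                     "site", "mean_fd"),
                                 group_levels = NULL) {
  manifest <- droplevels(manifest[match(unique(dyn$subject_id), manifest$subject_id), ])
  if (!is.null(group_levels)) {
    keep <- manifest$group %in% group_levels
    manifest <- droplevels(manifest[keep, ])
    dyn <- dyn[dyn$subject_id %in% manifest$subject_id, ]
    manifest$group <- factor(manifest$group, levels = group_levels)
  }
  covs <- .usable_covariates(manifest, covariate_names)
  fam_of <- c(dwell = "dwell", total_dwell = "total_dwell",
              occurrence = "occurrence",
              transition = "path_transition", persistence = "path_transition",
              traj_entropy = "path_entropy")
  keys <- unique(dyn[, c("metric", "cap_from", "cap_to")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    key <- keys[i, ]
    sel <- dyn$metric == key$metric &
      dyn$cap_from == key$cap_from &
      (is.na(key$cap_to) & is.na(dyn$cap_to) |
         !is.na(key$cap_to) & !is.na(dyn$cap_to) & dyn$cap_to == key$cap_to)
    vals <- dyn$value[sel][match(manifest$subject_id, dyn$subject_id[sel])]
    res <- tryCatch(adjusted_group_test(vals, manifest$group, covs),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(metric = key$metric, cap_from = key$cap_from, cap_to = key$cap_to,
               mean_g1 = res$group_means[1], sem_g1 = res$group_sem[1],
               mean_g2 = res$group_means[2], sem_g2 = res$group_sem[2],
               t = res$t, df = res$df, p = res$p,
               family = unname(fam_of[key$metric]), n = res$n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- NA_real_
  for (f in unique(out$family)) {
    idx <- out$family == f
    out$q[idx] <- fdr_bh(out$p[idx])
  }
  class(out) <- c("stat_table", "data.frame")
  out
}

.usable_covariates <- function(manifest, covariate_names) {
  covs <- manifest[, intersect(covariate_names, names(manifest)), drop = FALSE]
  varying <- vapply(covs, function(v) length(unique(v[!is.na(v)])) > 1L, logical(1))
  if (!all(varying)) covs <- covs[, varying, drop = FALSE]
  if (ncol(covs) == 0L) NULL else covs
}

#' Symptom-severity correlations of dynamic metrics
#'
#' Partial Pearson correlation of every dynamic metric with a clinical score
#' (e.g. HAMD-17) within one group, adjusting for nuisance covariates, with
#' BH-FDR within the same metric families as [group_contrast_table()].
#'
#' @param dyn long-format table from [dynamics_table()].
#' @param manifest cohort manifest; subjects with missing score are dropped.
#' @param score_col manifest column holding the clinical score; default
#'   \code{"hamd"}.
#' @param group optional group level to restrict to (e.g. the patient group).
#' @param covariate_names as in [group_contrast_table()].
#' @return data.frame: metric, cap_from, cap_to, r, p, q, family, n.
#' @export
symptom_correlation_table <- function(dyn, manifest, score_col = "hamd",
                                      group = NULL,
                                      covariate_names = c("age", "sex", "education",
                                                          "site", "mean_fd")) {
  if (!is.null(group))
    manifest <- droplevels(manifest[manifest$group == group, ])
  manifest <- manifest[!is.na(manifest[[score_col]]), ]
  dyn <- dyn[dyn$subject_id %in% manifest$subject_id, ]
  covs <- .usable_covariates(manifest, covariate_names)
  fam_of <- c(dwell = "dwell", total_dwell = "total_dwell",
              occurrence = "occurrence",
              transition = "path_transition", persistence = "path_transition",
              traj_entropy = "path_entropy")
  keys <- unique(dyn[, c("metric", "cap_from", "cap_to")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    key <- keys[i, ]
    sel <- dyn$metric == key$metric &
      dyn$cap_from == key$cap_from &
      (is.na(key$cap_to) & is.na(dyn$cap_to) |
         !is.na(key$cap_to) & !is.na(dyn$cap_to) & dyn$cap_to == key$cap_to)
    vals <- dyn$value[sel][match(manifest$subject_id, dyn$subject_id[sel])]
    res <- tryCatch(
      partial_pearson(vals, manifest[[score_col]], covs),
      error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(metric = key$metric, cap_from = key$cap_from, cap_to = key$cap_to,
               r = res$r, p = res$p, family = unname(fam_of[key$metric]),
               n = res$n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- NA_real_
  for (f in unique(out$family)) {
    idx <- out$family == f
    out$q[idx] <- fdr_bh(out$p[idx])
  }
  out
}
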