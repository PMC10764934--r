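#' Select discriminative dynamic features from a stat table
#'
#' Keeps the metric/path identifiers whose covariate-adjusted group contrast
#' has raw p below \code{alpha}, restricted by default to the four feature
#' families used for classification: dwell time, occurrence rate,
#' persistence probabilities and trajectory entropies (off-diagonal
#' transition probabilities enter only when explicitly requested).
#'
#' @param stat_table output of [group_contrast_table()].
#' @param alpha selection threshold on the raw p-value; default 0.05.
#' @param metrics metric families eligible for selection.
#' @return data.frame of selected rows (metric, cap_from, cap_to, p).
#' @export
select_features <- function(stat_table, alpha = 0.05,
                            metrics = c("dwell", "occurrence",
                                        "persistence", "traj_entropy")) {
  sel <- stat_table[stat_table$metric %in% metrics &
                      !is.na(stat_table$p) & stat_table$p < alpha,
                    c("metric", "cap_from", "cap_to", "p")]
  if (nrow(sel) == 0L)
    stop("no feature with p < ", alpha,
         "; relax alpha or verify the contrast has signal", call. = FALSE)
  rownames(sel) <- NULL
  sel
}

#' Build a subjects x features matrix for selected dynamic metrics
#'
#' @param dyn long-format table from [dynamics_table()].
#' @param features selection from [select_features()].
#' @param subject_ids subjects to include, in order.
#' @return numeric matrix, one column per selected feature, named
#'   \code{metric[from]} or \code{metric[from->to]}.
#' @export
feature_matrix <- function(dyn, features, subject_ids) {
  cols <- lapply(seq_len(nrow(features)), function(i) {
    key <- features[i, ]
    sel <- dyn$metric == key$metric &
      dyn$cap_from == key$cap_from &
      (is.na(key$cap_to) & is.na(dyn$cap_to) |
         !is.na(key$cap_to) & !is.na(dyn$cap_to) & dyn$cap_to == key$cap_to)
    dyn$value[sel][match(subject_ids, dyn$subject_id[sel])]
  })
  x <- do.call(cbind, cols)
  colnames(x) <- ifelse(is.na(features$cap_to),
                        sprintf("%s[%d]", features$metric, features$cap_from),
                        sprintf("%s[%d->%d]", features$metric,
                                features$cap_from, features$cap_to))
  rownames(x) <- subject_ids
  x
}

# Stratified fold assignment: within each class, subjects are shuffled and
# dealt round-robin, so every fold holds both classes whenever possible.
.stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# Area under the ROC curve from decision scores via the rank statistic
# (midpoint ranks, so ties contribute 1/2).
.auc_scores <- function(scores, labels_pos) {
  n_pos <- sum(labels_pos)
  n_neg <- sum(!labels_pos)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

.confusion_rates <- function(truth_pos, pred_pos) {
  tp <- sum(truth_pos & pred_pos); tn <- sum(!truth_pos & !pred_pos)
  fp <- sum(!truth_pos & pred_pos); fn <- sum(truth_pos & !pred_pos)
  c(accuracy = (tp + tn) / length(truth_pos),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_)
}

#' Nested cross-validated RBF-SVM classification
#'
#' Outer stratified K-fold cross-validation estimates performance; within
#' each outer training set an inner stratified K-fold grid search picks the
#' radial-basis-function SVM hyper-parameters (cost C and kernel width
#' gamma) by highest inner accuracy. Feature standardization (z-score) is
#' fitted on the outer training set only and applied to the held-out fold,
#' so no test information leaks into fitting.
#'
#' @param x subjects x features numeric matrix.
#' @param labels binary class labels (factor or coercible); the second
#'   level is treated as the positive class.
#' @param outer_folds,inner_folds number of outer and inner folds; default 5.
#' @param cost_grid,gamma_grid hyper-parameter grids; defaults span
#'   C in 2^\{-5, -3, ..., 15\} and gamma in 2^\{-15, -13, ..., 3\}.
#' @param seed integer seed fixing the fold assignment.
#' @return An object of class \code{classifier_report}: per-fold and mean
#'   accuracy, AUC, sensitivity, specificity, PPV, NPV, F1; chosen
#'   hyper-parameters per fold; the scaling parameters fitted per fold
#'   (\code{fold_scaling}) for leakage audits; fold assignment; seed.
#' @export
nested_cv_svm <- function(x, labels, outer_folds = 5L, inner_folds = 5L,
                          cost_grid = 2^seq(-5, 15, 2),
                          gamma_grid = 2^seq(-15, 3, 2),
                          seed = 1L) {
  x <- as.matrix(x)
  if (ncol(x) == 0L) stop("no features to classify on", call. = FALSE)
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("labels must be binary", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  fold <- .stratified_folds(labels, outer_folds)
  pos_level <- levels(labels)[2]
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid)
  fold_rows <- vector("list", outer_folds)
  fold_scaling <- vector("list", outer_folds)
  for (f in seq_len(outer_folds)) {
    tr <- fold != f; te <- !tr
    if (nlevels(droplevels(labels[tr])) != 2L)
      stop("a class is absent from outer training fold ", f, call. = FALSE)
    ctr <- colMeans(x[tr, , drop = FALSE])
    scl <- apply(x[tr, , drop = FALSE], 2L, stats::sd)
    scl[scl == 0] <- 1
    xtr <- scale(x[tr, , drop = FALSE], center = ctr, scale = scl)
    xte <- scale(x[te, , drop = FALSE], center = ctr, scale = scl)
    fold_scaling[[f]] <- list(center = ctr, scale = scl)
    inner <- .stratified_folds(labels[tr], inner_folds)
    acc <- vapply(seq_len(nrow(grid)), function(g) {
      hits <- 0L
      for (i in seq_len(inner_folds)) {
        itr <- inner != i
        if (nlevels(droplevels(labels[tr][itr])) != 2L) next
        fit <- e1071::svm(xtr[itr, , drop = FALSE], labels[tr][itr],
                          kernel = "radial", cost = grid$cost[g],
                          gamma = grid$gamma[g], scale = FALSE)
        hits <- hits + sum(stats::predict(fit, xtr[!itr, , drop = FALSE]) ==
                             labels[tr][!itr])
      }
      hits / sum(tabulate(inner))
    }, numeric(1))
    best <- which.max(acc)          # ties: first grid point (smallest cost)
    fit <- e1071::svm(xtr, labels[tr], kernel = "radial",
                      cost = grid$cost[best], gamma = grid$gamma[best],
                      scale = FALSE, decision.values = TRUE)
    pred <- stats::predict(fit, xte, decision.values = TRUE)
    dv <- attr(pred, "decision.values")[, 1]
    # decision values are signed towards the first class of "A/B"; orient
    # them so larger = more likely positive class
    if (!startsWith(colnames(attr(pred, "decision.values"))[1],
                    paste0(pos_level, "/")))
      dv <- -dv
    truth_pos <- labels[te] == pos_level
    rates <- .confusion_rates(truth_pos, pred == pos_level)
    fold_rows[[f]] <- data.frame(fold = f, t(rates),
                                 auc = .auc_scores(dv, truth_pos),
                                 cost = grid$cost[best], gamma = grid$gamma[best],
                                 n_test = sum(te))
  }
  folds_df <- do.call(rbind, fold_rows)
  metrics <- c("accuracy", "auc", "sensitivity", "specificity", "ppv", "npv", "f1")
  structure(
    list(folds = folds_df,
         mean = colMeans(folds_df[, metrics], na.rm = TRUE),
         fold_assignment = fold,
         fold_scaling = fold_scaling,
         grid = grid,
         positive = pos_level,
         seed = seed),
    class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("<classifier_report> positive class:", x$positive, "\n")
  print(round(x$mean, 4))
  invisible(x)
}

#' Permutation test of nested-CV classification performance
#'
#' Re-runs the full nested cross-validation pipeline on \code{n_perm}
#' label permutations and reports p = (1 + #\{null >= observed\}) /
#' (n_perm + 1) for mean accuracy and mean AUC.
#'
#' @inheritParams nested_cv_svm
#' @param n_perm number of permutations (>= 100); default 1000.
#' @param ... further arguments passed to [nested_cv_svm()]
#'   (fold counts, grids).
#' @return list with \code{observed} (classifier_report), \code{p_accuracy},
#'   \code{p_auc}, and the null distributions \code{null_accuracy},
#'   \code{null_auc}.
#' @export
permutation_test <- function(x, labels, n_perm = 1000L, seed = 1L, ...) {
  if (n_perm < 100L) stop("n_perm must be at least 100", call. = FALSE)
  observed <- nested_cv_svm(x, labels, seed = seed, ...)
  null_acc <- null_auc <- numeric(n_perm)
  set.seed(seed + 1L)
  perm_seeds <- sample.int(.Machine$integer.max, n_perm)
  for (b in seq_len(n_perm)) {
    set.seed(perm_seeds[b])
    rep_b <- nested_cv_svm(x, sample(labels), seed = perm_seeds[b], ...)
    null_acc[b] <- rep_b$mean["accuracy"]
    null_auc[b] <- rep_b$mean["auc"]
  }
  list(observed = observed,
       p_accuracy = (1 + sum(null_acc >= observed$mean["accuracy"])) / (n_perm + 1),
       p_auc = (1 + sum(null_auc >= observed$mean["auc"])) / (n_perm + 1),
       null_accuracy = null_acc,
       null_auc = null_auc)
}
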