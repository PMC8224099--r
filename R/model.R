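#' Information gain of one feature for a binary label
#'
#' Reduction of label entropy (base 2) after discretizing the feature
#' into `n_bins` equal-frequency bins:
#' `H(label) - sum_b p(b) H(label | bin b)`. Lies in `[0, H(label)]`.
#'
#' @param feature_values Numeric vector.
#' @param labels Binary vector (factor, character or 0/1) of equal length.
#' @param n_bins Number of equal-frequency bins (default 10).
#' @return A single number (bits).
#' @export
information_gain <- function(feature_values, labels, n_bins = 10L) {
  y <- as.integer(factor(labels))
  if (length(unique(y)) < 2) stop("labels must contain two classes")
  if (length(feature_values) != length(y)) stop("length mismatch")
  ent <- function(v) {
    p <- tabulate(v) / length(v)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  br <- unique(stats::quantile(feature_values,
                               probs = seq(0, 1, length.out = n_bins + 1),
                               na.rm = TRUE, names = FALSE))
  if (length(br) < 2) return(0)  # constant feature carries no information
  bins <- cut(feature_values, breaks = br, include.lowest = TRUE)
  h0 <- ent(y)
  hc <- 0
  for (b in levels(bins)) {
    idx <- which(bins == b)
    if (length(idx)) hc <- hc + length(idx) / length(y) * ent(y[idx])
  }
  max(0, h0 - hc)
}

#' Rank features by information gain
#'
#' @param X Numeric feature matrix (rows = samples).
#' @param y Binary labels.
#' @param n_bins Bins for [information_gain()].
#' @return A list of class `feature_ranking` with `features` (names, most
#'   to least important), `method` and `scores`.
#' @export
rank_infogain <- function(X, y, n_bins = 10L) {
  sc <- apply(X, 2, information_gain, labels = y, n_bins = n_bins)
  ord <- order(sc, decreasing = TRUE)
  structure(list(features = colnames(X)[ord], method = "infogain",
                 scores = sc[ord]), class = "feature_ranking")
}

#' SVM recursive feature elimination
#'
#' Repeatedly fits a linear-kernel maximum-margin classifier (balanced
#' class weights), scores each remaining feature by its squared weight
#' `w_j^2`, removes the `elimination_step` lowest-scoring features and
#' records the removal order; the ranking is that order reversed.
#' Deterministic given the data. The final classifier of the analysis
#' uses an RBF kernel; elimination uses the standard linear-weight
#' criterion.
#'
#' @param X Standardized numeric feature matrix.
#' @param y Binary labels.
#' @param elimination_step Features removed per iteration (default 1).
#' @param cost Linear SVM cost parameter used during elimination.
#' @return A `feature_ranking` (method `"svmrfe"`, no scores).
#' @export
rank_svmrfe <- function(X, y, elimination_step = 1L, cost = 1) {
  y <- factor(y)
  stopifnot(nlevels(y) == 2)
  remaining <- colnames(X)
  removed <- character(0)
  while (length(remaining) > 0) {
    fit <- e1071::svm(X[, remaining, drop = FALSE], y, kernel = "linear",
                      cost = cost, scale = FALSE,
                      class.weights = balanced_weights(y))
    w <- t(fit$coefs) %*% fit$SV
    score <- as.numeric(w)^2
    k <- min(elimination_step, length(remaining))
    drop_idx <- order(score)[seq_len(k)]
    removed <- c(removed, remaining[drop_idx])
    remaining <- remaining[-drop_idx]
  }
  structure(list(features = rev(removed), method = "svmrfe", scores = NULL),
            class = "feature_ranking")
}

balanced_weights <- function(y) {
  tb <- table(y)
  w <- length(y) / (length(tb) * tb)
  stats::setNames(as.numeric(w), names(tb))
}

#' Subject-wise stratified k-fold split
#'
#' Partitions *subjects* (never segments) into `k` folds, stratified by
#' label, so that every segment of a subject falls into exactly one fold
#' and no subject contributes to both training and test data.
#'
#' @param subjects Data.frame with columns `subject_id` and `label` (one
#'   row per subject).
#' @param k Number of folds (default 5, must be >= 2).
#' @param seed Integer seed for the fold assignment.
#' @return A list of `k` character vectors of held-out subject IDs.
#' @export
subject_kfold <- function(subjects, k = 5L, seed = 1L) {
  if (k < 2) stop("k must be at least 2 (a held-out set is required)")
  labs <- unique(subjects$label)
  for (l in labs)
    if (sum(subjects$label == l) < k)
      stop("each class needs at least k subjects")
  with_seed(seed, {
    folds <- vector("list", k)
    for (l in labs) {
      ids <- sample(subjects$subject_id[subjects$label == l])
      fi <- rep(seq_len(k), length.out = length(ids))
      for (f in seq_len(k))
        folds[[f]] <- c(folds[[f]], ids[fi == f])
    }
    folds
  })
}

#' Classification metrics from a confusion
#'
#' Sensitivity `TP / (TP + FN)`, specificity `TN / (TN + FP)` and accuracy
#' `(TP + TN) / total`, in percent, with CAD as the positive class.
#'
#' @param truth,pred Label vectors (`"CAD"` / `"non-CAD"`).
#' @return Named numeric vector `c(Acc, Se, Sp)` in percent.
#' @export
classification_metrics <- function(truth, pred) {
  tp <- sum(truth == "CAD" & pred == "CAD")
  fn <- sum(truth == "CAD" & pred != "CAD")
  tn <- sum(truth != "CAD" & pred != "CAD")
  fp <- sum(truth != "CAD" & pred == "CAD")
  c(Acc = 100 * (tp + tn) / (tp + tn + fp + fn),
    Se = 100 * tp / (tp + fn),
    Sp = 100 * tn / (tn + fp))
}

#' Hyper-parameter grid of the RBF SVM
#'
#' Powers of two from `2^-5` to `2^5` for both `C` and `gamma`.
#'
#' @param lo,hi Exponent range (defaults -5, 5).
#' @param by Exponent step (default 1, i.e. factor-2 spacing).
#' @return List with numeric vectors `cost` and `gamma`.
#' @export
svm_grid <- function(lo = -5, hi = 5, by = 1) {
  list(cost = 2^seq(lo, hi, by = by), gamma = 2^seq(lo, hi, by = by))
}

# grid search by inner cross-validated accuracy; returns the refitted model
svm_grid_train <- function(X, y, grid = svm_grid(), inner_k = 5L, seed = 1L) {
  y <- factor(y)
  best <- NULL; best_acc <- -Inf
  for (cst in grid$cost) {
    for (gm in grid$gamma) {
      acc <- with_seed(seed, {
        fit <- e1071::svm(X, y, kernel = "radial", cost = cst, gamma = gm,
                          scale = FALSE, class.weights = balanced_weights(y),
                          cross = inner_k)
        fit$tot.accuracy
      })
      if (acc > best_acc) { best_acc <- acc; best <- c(cst, gm) }
    }
  }
  e1071::svm(X, y, kernel = "radial", cost = best[1], gamma = best[2],
             scale = FALSE, class.weights = balanced_weights(y))
}

rank_features <- function(X, y, selector, rfe_step = 10L) {
  switch(selector,
         infogain = rank_infogain(X, y),
         svmrfe = rank_svmrfe(X, y, elimination_step = rfe_step),
         stop("unknown selector"))
}

#' Subject-wise cross-validated SVM evaluation
#'
#' Evaluates one feature set at one (or several) feature counts under
#' subject-wise k-fold CV. Within each training fold the features are
#' standardized with training statistics only, ranked with the chosen
#' selector (no selection leakage into the test fold), the top-`n` kept,
#' and an RBF SVM tuned over the `C`/`gamma` grid by inner
#' cross-validated accuracy and refitted. Metrics are averaged over the
#' outer folds.
#'
#' @param table Feature table (metadata columns plus feature columns).
#' @param spec A [feature_set_spec()].
#' @param selector `"infogain"` or `"svmrfe"`.
#' @param n_features Feature counts to evaluate (values above the set
#'   size are truncated).
#' @param k Outer folds (default 5).
#' @param seed Seed controlling fold assignment and inner CV.
#' @param grid SVM hyper-parameter grid, see [svm_grid()].
#' @param inner_k Inner CV folds for the grid search (default 5).
#' @param rfe_step Elimination step for SVM-RFE (default 10).
#' @param global_ranking Rank once on the full table instead of per fold
#'   (the optimistic protocol; default `FALSE`).
#' @param folds Optional list of held-out subject-ID vectors; by default
#'   a fresh [subject_kfold()] split is drawn with `seed`.
#' @return A data.frame of class `eval_result`: one row per
#'   (n_features, fold) plus summary rows are available via
#'   [summarize_eval()]. Per-fold rankings are attached as attribute
#'   `rankings`.
#' @export
evaluate_feature_set <- function(table, spec, selector = "infogain",
                                 n_features = NULL, k = 5L, seed = 1L,
                                 grid = svm_grid(), inner_k = 5L,
                                 rfe_step = 10L, global_ranking = FALSE,
                                 folds = NULL) {
  tab <- build_feature_set(table, spec)
  fcols <- setdiff(names(tab), c("subject_id", "label", "segment_index"))
  ok <- stats::complete.cases(tab[, fcols])
  tab <- tab[ok, ]
  if (is.null(n_features)) n_features <- length(fcols)
  n_features <- pmin(n_features, length(fcols))
  subjects <- unique(tab[, c("subject_id", "label")])
  if (is.null(folds)) folds <- subject_kfold(subjects, k = k, seed = seed)
  k <- length(folds)
  glob_rank <- if (global_ranking)
    rank_features(as.matrix(scale(tab[, fcols])), tab$label, selector, rfe_step)
  rows <- list(); rankings <- list()
  for (f in seq_len(k)) {
    test_ids <- folds[[f]]
    tr <- tab[!(tab$subject_id %in% test_ids), ]
    te <- tab[tab$subject_id %in% test_ids, ]
    Xtr <- as.matrix(tr[, fcols]); Xte <- as.matrix(te[, fcols])
    mu <- colMeans(Xtr); sg <- apply(Xtr, 2, stats::sd)
    sg[sg == 0] <- 1
    Xtr <- sweep(sweep(Xtr, 2, mu), 2, sg, "/")
    Xte <- sweep(sweep(Xte, 2, mu), 2, sg, "/")
    rk <- if (global_ranking) glob_rank
          else rank_features(Xtr, tr$label, selector, rfe_step)
    rankings[[f]] <- rk$features
    for (n in n_features) {
      sel <- rk$features[seq_len(n)]
      fit <- svm_grid_train(Xtr[, sel, drop = FALSE], tr$label,
                            grid = grid, inner_k = inner_k,
                            seed = seed + 7L * f)
      pred <- as.character(stats::predict(fit, Xte[, sel, drop = FALSE]))
      m <- classification_metrics(te$label, pred)
      rows[[length(rows) + 1L]] <- data.frame(
        set = spec$id,
        channel = if (is.null(spec$channel)) NA_integer_ else spec$channel,
        selector = selector, n_features = n, fold = f,
        Acc = m["Acc"], Se = m["Se"], Sp = m["Sp"], row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "rankings") <- rankings
  class(out) <- c("eval_result", class(out))
  out
}

#' Feature-count sweep
#'
#' Runs [evaluate_feature_set()] at counts `step, 2 step, ...` up to the
#' feature-set size (single-channel sets are conventionally swept at step
#' 2, multi-channel sets at step 10).
#'
#' @inheritParams evaluate_feature_set
#' @param step Feature-count increment.
#' @return An `eval_result` data.frame over all counts.
#' @export
evaluate_sweep <- function(table, spec, selector = "infogain", step = 10L,
                           k = 5L, seed = 1L, grid = svm_grid(),
                           inner_k = 5L, rfe_step = 10L,
                           global_ranking = FALSE) {
  total <- length(feature_set_columns(spec))
  ns <- unique(pmin(seq(step, total + step - 1, by = step), total))
  evaluate_feature_set(table, spec, selector, n_features = ns, k = k,
                       seed = seed, grid = grid, inner_k = inner_k,
                       rfe_step = rfe_step, global_ranking = global_ranking)
}

#' Summarize per-fold results as mean +/- SD per feature count
#'
#' @param res An `eval_result` from [evaluate_feature_set()].
#' @return Data.frame with one row per (set, selector, n_features) and
#'   mean/SD columns for Acc, Se and Sp.
#' @export
summarize_eval <- function(res) {
  agg <- function(v) c(mean = mean(v), sd = stats::sd(v))
  sp <- split(res, list(res$set, res$selector, res$n_features), drop = TRUE)
  rows <- lapply(sp, function(d) {
    data.frame(set = d$set[1], selector = d$selector[1],
               n_features = d$n_features[1],
               Acc_mean = mean(d$Acc), Acc_sd = stats::sd(d$Acc),
               Se_mean = mean(d$Se), Se_sd = stats::sd(d$Se),
               Sp_mean = mean(d$Sp), Sp_sd = stats::sd(d$Sp))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$set, out$selector, out$n_features), ]
}
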