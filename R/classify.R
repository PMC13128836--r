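#' Bagged-tree classifier configuration
#'
#' @param ntree trees in the ensemble.
#' @param folds cross-validation folds.
#' @param mtry features tried per split; default `floor(sqrt(d))`.
#' @param sample_fraction bootstrap fraction per tree.
#' @param nodesize minimum terminal-node size; 1 grows trees fully (the
#'   classical bagged-tree default), larger values smooth the decision
#'   surface toward the Bayes rule.
#' @param seed integer seed.
#' @return list of class `bag_config`.
#' @export
bag_config <- function(ntree = 100, folds = 10, mtry = NULL,
                       sample_fraction = 1, nodesize = 1, seed = 1L) {
  stopifnot(ntree >= 1, folds >= 2, sample_fraction > 0,
            sample_fraction <= 1, nodesize >= 1)
  structure(list(ntree = ntree, folds = folds, mtry = mtry,
                 sample_fraction = sample_fraction, nodesize = nodesize,
                 seed = as.integer(seed)),
            class = "bag_config")
}

.check_feature_matrix <- function(x) {
  bad <- vapply(seq_len(ncol(x)), function(j) any(!is.finite(x[, j])),
                logical(1))
  if (any(bad))
    stop("non-finite values in feature column(s): ",
         paste(colnames(x)[bad], collapse = ", "))
}

.as_feature_matrix <- function(features, subset = NULL) {
  if (is.data.frame(features)) {
    cols <- intersect(feature_names(), names(features))
    if (length(cols) == 0) cols <- setdiff(names(features),
                                           c("label", "event_id", "batch"))
    x <- as.matrix(features[, cols, drop = FALSE])
  } else x <- as.matrix(features)
  if (!is.null(subset)) x <- x[, subset, drop = FALSE]
  x
}

.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Train a bagged decision-tree classifier
#'
#' Fits an ensemble of `ntree` decision trees on bootstrap resamples
#' (fraction `sample_fraction`, with replacement) with `floor(sqrt(d))`
#' candidate features per split, and records stratified k-fold
#' cross-validation accuracy (10-fold by default). Reproducible under the
#' config seed.
#'
#' @param features data.frame or matrix of event features.
#' @param labels factor/character of class labels.
#' @param config a [bag_config()].
#' @param feature_subset optional character vector restricting the model
#'   to named features.
#' @return object of class `bag_model`: the fitted ensemble, feature
#'   subset, class labels, `cv_accuracy`, and config.
#' @export
train_bagged_trees <- function(features, labels, config = bag_config(),
                               feature_subset = NULL) {
  y <- droplevels(factor(labels))
  if (nlevels(y) < 2) stop("need >= 2 classes to train a classifier")
  x <- .as_feature_matrix(features, feature_subset)
  stopifnot(nrow(x) == length(y))
  .check_feature_matrix(x)
  set.seed(config$seed)
  mtry <- if (is.null(config$mtry)) max(1, floor(sqrt(ncol(x)))) else config$mtry
  sampsize <- max(1, round(config$sample_fraction * nrow(x)))
  folds <- min(config$folds, min(table(y)))
  if (folds < 2) stop("need >= 2 rows per class for cross-validation")
  fold <- .stratified_folds(y, folds)
  correct <- 0L
  for (f in seq_len(folds)) {
    tr <- fold != f
    fit <- randomForest::randomForest(
      x = x[tr, , drop = FALSE], y = y[tr], ntree = config$ntree,
      mtry = min(mtry, ncol(x)), replace = TRUE,
      nodesize = config$nodesize,
      sampsize = max(1, round(config$sample_fraction * sum(tr))))
    pred <- stats::predict(fit, x[!tr, , drop = FALSE])
    correct <- correct + sum(pred == y[!tr])
  }
  model <- randomForest::randomForest(
    x = x, y = y, ntree = config$ntree, mtry = min(mtry, ncol(x)),
    replace = TRUE, sampsize = sampsize, nodesize = config$nodesize,
    importance = TRUE)
  structure(list(forest = model, features = colnames(x),
                 classes = levels(y),
                 cv_accuracy = correct / length(y),
                 cv_folds = folds, config = config),
            class = "bag_model")
}

#' @export
print.bag_model <- function(x, ...) {
  cat(sprintf("<bag_model> %d trees, %d features, %d classes, %d-fold CV accuracy %.3f\n",
              x$config$ntree, length(x$features), length(x$classes),
              x$cv_folds, x$cv_accuracy))
  invisible(x)
}

#' Predict a test set and build the confusion matrix
#'
#' @param model a [train_bagged_trees()] model.
#' @param features test feature table (must contain the model's feature
#'   subset).
#' @param labels true test labels.
#' @return list: `predictions` (factor), `confusion` (true x predicted
#'   counts), `accuracy`.
#' @export
predict_and_confuse <- function(model, features, labels) {
  stopifnot(inherits(model, "bag_model"))
  x <- .as_feature_matrix(features)
  missing <- setdiff(model$features, colnames(x))
  if (length(missing))
    stop("test set missing feature(s): ", paste(missing, collapse = ", "))
  if (nrow(x) == 0) stop("empty test set")
  x <- x[, model$features, drop = FALSE]
  y <- factor(labels, levels = union(model$classes, unique(as.character(labels))))
  pred <- stats::predict(model$forest, x)
  pred <- factor(as.character(pred), levels = levels(y))
  confusion <- table(true = y, predicted = pred)
  list(predictions = pred, confusion = confusion,
       accuracy = sum(diag(confusion)) / sum(confusion))
}

#' Permutation importance of every feature
#'
#' Out-of-bag permutation importance (mean decrease in accuracy) from the
#' fitted ensemble, floored at zero.
#'
#' @param model a [train_bagged_trees()] model.
#' @return named numeric vector, one non-negative score per feature.
#' @export
rank_feature_importance <- function(model) {
  stopifnot(inherits(model, "bag_model"))
  imp <- randomForest::importance(model$forest, type = 1, scale = FALSE)
  scores <- pmax(imp[, 1], 0)
  names(scores) <- rownames(imp)
  scores
}

#' Greedy forward feature selection by cross-validated accuracy
#'
#' Starting from the empty set, at each step adds the feature whose
#' inclusion maximizes k-fold CV accuracy of the bagged-tree model (ties
#' broken by lower canonical feature index), recording the accuracy
#' curve. This reproduces the "highest accuracy at any given dimension"
#' ordering used when shortlisting features.
#'
#' @param features feature table.
#' @param labels class labels.
#' @param max_dim number of dimensions to grow to (clamped, with a
#'   warning, to the number of available features).
#' @param train_size optional per-class subsample size drawn before
#'   selection (few-shot scenarios).
#' @param config a [bag_config()].
#' @return list of class `selection_result`: `order` (features in
#'   addition order), `accuracy` (CV accuracy at each dimension),
#'   `shortlist` (features up to the accuracy maximum).
#' @export
greedy_forward_selection <- function(features, labels, max_dim = NULL,
                                     train_size = NULL,
                                     config = bag_config()) {
  y <- droplevels(factor(labels))
  x <- .as_feature_matrix(features)
  if (ncol(x) < 1) stop("need >= 1 feature")
  set.seed(config$seed)
  if (!is.null(train_size)) {
    idx <- unlist(lapply(levels(y), function(cl) {
      i <- which(y == cl)
      sample(i, min(train_size, length(i)))
    }))
    x <- x[idx, , drop = FALSE]
    y <- droplevels(y[idx])
  }
  if (is.null(max_dim)) max_dim <- ncol(x)
  if (max_dim > ncol(x)) {
    warning("max_dim exceeds available features; clamping to ", ncol(x))
    max_dim <- ncol(x)
  }
  canonical <- colnames(x)
  selected <- character(0)
  acc_curve <- numeric(0)
  cfg <- config
  for (step in seq_len(max_dim)) {
    candidates <- setdiff(canonical, selected)
    best_acc <- -Inf
    best_feat <- NULL
    for (cand in candidates) {   # canonical order = tie-break by index
      cfg$seed <- config$seed + step   # same folds for all candidates
      m <- train_bagged_trees(x[, c(selected, cand), drop = FALSE], y,
                              config = cfg)
      if (m$cv_accuracy > best_acc + 1e-12) {
        best_acc <- m$cv_accuracy
        best_feat <- cand
      }
    }
    selected <- c(selected, best_feat)
    acc_curve <- c(acc_curve, best_acc)
  }
  structure(list(order = selected, accuracy = acc_curve,
                 shortlist = selected[seq_len(which.max(acc_curve))]),
            class = "selection_result")
}

#' Shortlist features across training-set scales
#'
#' Runs greedy forward selection at several per-class training sizes and
#' unions the selected features, capped at `cap` by combined (summed)
#' rank. Features that matter at every data scale survive.
#'
#' @param features feature table.
#' @param labels labels.
#' @param train_sizes per-class training sizes to scan.
#' @param cap maximum shortlist size.
#' @param max_dim dimensions to grow each selection to.
#' @param config a [bag_config()].
#' @return character vector of shortlisted feature names.
#' @export
shortlist_features <- function(features, labels,
                               train_sizes = c(20, 200, 2000), cap = 21,
                               max_dim = NULL, config = bag_config()) {
  ranks <- list()
  for (ts in train_sizes) {
    sel <- greedy_forward_selection(features, labels, max_dim = max_dim,
                                    train_size = ts, config = config)
    ranks[[as.character(ts)]] <- stats::setNames(seq_along(sel$order),
                                                 sel$order)
  }
  all_feats <- unique(unlist(lapply(ranks, names)))
  worst <- max(vapply(ranks, length, integer(1))) + 1
  combined <- vapply(all_feats, function(f)
    sum(vapply(ranks, function(r) if (f %in% names(r)) r[[f]] else worst,
               numeric(1))), numeric(1))
  head(all_feats[order(combined)], cap)
}

#' Recall of a target analyte under concentrated interference
#'
#' Builds a test set with `n_target` target events and `R * n_target`
#' interferent events (sampled from a Gaussian feature library), predicts
#' with the supplied model, and returns the fraction of target events
#' correctly identified.
#'
#' @param model a [train_bagged_trees()] model.
#' @param flib a [default_feature_library()] for sampling test events.
#' @param target target analyte label.
#' @param interferents labels of the interfering analytes (their
#'   `R * n_target` events are split evenly).
#' @param ratio interferent-to-target concentration ratio R (>= 0).
#' @param n_target number of target events (> 0).
#' @param seed integer seed.
#' @return target recall in [0, 1].
#' @export
interference_recall <- function(model, flib, target, interferents,
                                ratio, n_target = 100, seed = 1L) {
  if (n_target <= 0) stop("n_target must be positive")
  if (ratio < 0) stop("ratio must be >= 0")
  set.seed(seed)
  draw <- function(lbl, n) {
    a <- match(lbl, flib$labels)
    if (is.na(a)) stop("label '", lbl, "' not in feature library")
    m <- matrix(stats::rnorm(n * length(flib$features),
                             mean = rep(flib$mean[a, ], each = n),
                             sd = rep(flib$sd[a, ], each = n)), nrow = n)
    colnames(m) <- flib$features
    m
  }
  x <- draw(target, n_target)
  n_int <- round(ratio * n_target)
  if (n_int > 0) {
    per <- diff(round(seq(0, n_int, length.out = length(interferents) + 1)))
    for (i in seq_along(interferents))
      if (per[i] > 0) x <- rbind(x, draw(interferents[i], per[i]))
  }
  pred <- stats::predict(model$forest, x[, model$features, drop = FALSE])
  mean(pred[seq_len(n_target)] == target)
}

#' Blockade-only Gaussian-mixture baseline
#'
#' Ensemble-analysis mimic: fits a k-component 1-D Gaussian mixture by EM
#' to the base-condition blockade values only and assigns each event to
#' its maximum-responsibility component. EM restarts (up to 5 seeds) on
#' non-convergence or component collapse.
#'
#' @param blockades numeric vector of `blockade@lp2000` values (%).
#' @param k number of mixture components (>= 1).
#' @param seed integer seed.
#' @param max_iter,tol EM controls.
#' @return list: `assignments` (integer component per event, components
#'   ordered by increasing mean), `means`, `sds`, `weights`, `loglik`,
#'   `iterations`.
#' @export
blockade_only_baseline <- function(blockades, k, seed = 1L,
                                   max_iter = 500, tol = 1e-8) {
  if (k < 1) stop("k must be >= 1")
  x <- as.numeric(blockades)
  n <- length(x)
  if (n < k) stop("fewer observations than components")
  if (k == 1) {
    return(list(assignments = rep(1L, n), means = mean(x),
                sds = stats::sd(x), weights = 1, loglik = NA_real_,
                iterations = 0L))
  }
  for (attempt in seq_len(5)) {
    set.seed(seed + attempt - 1L)
    # init: jittered quantile means, pooled sd
    mu <- stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
    mu <- mu + stats::rnorm(k, 0, stats::sd(x) / (10 * k))
    sg <- rep(stats::sd(x) / k, k)
    w <- rep(1 / k, k)
    ll_old <- -Inf
    ll <- NA_real_
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      dens <- vapply(seq_len(k), function(j)
        w[j] * stats::dnorm(x, mu[j], sg[j]), numeric(n))
      tot <- rowSums(dens)
      if (any(tot == 0) || any(!is.finite(tot))) break
      r <- dens / tot
      nk <- colSums(r)
      if (any(nk < 1e-8)) break
      w <- nk / n
      mu <- colSums(r * x) / nk
      sg <- sqrt(colSums(r * (x - rep(mu, each = n))^2) / nk)
      sg <- pmax(sg, 1e-6 * stats::sd(x))
      ll <- sum(log(tot))
      if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
        ok <- TRUE
        break
      }
      ll_old <- ll
      # exhausting the iteration budget on a finite likelihood is a slow
      # (heavily overlapped) fit, not a breakdown: accept it
      if (it == max_iter && is.finite(ll)) ok <- TRUE
    }
    if (ok) {
      ord <- order(mu)
      dens <- vapply(seq_len(k), function(j)
        w[j] * stats::dnorm(x, mu[j], sg[j]), numeric(n))
      assign_raw <- max.col(dens, ties.method = "first")
      remap <- match(seq_len(k), ord)
      return(list(assignments = remap[assign_raw],
                  means = mu[ord], sds = sg[ord], weights = w[ord],
                  loglik = sum(log(rowSums(dens))), iterations = it))
    }
  }
  stop("EM failed to converge after 5 restarts")
}

#' Flag events outside the analyte library
#'
#' An event is out-of-library when its standardized distance (root mean
#' squared z-score over the chosen features, a diagonal Mahalanobis
#' distance) to *every* library class exceeds `threshold_sigma`.
#' Probe-tethered non-PFCA carboxylic acids with PFCA-like blockades but
#' alien dwell or noise signatures are caught this way before counting.
#'
#' @param features feature table (43 columns, or at least
#'   `feature_subset`).
#' @param flib a `feature_library` of per-class Gaussian parameters.
#' @param threshold_sigma flagging threshold (default 3).
#' @param feature_subset features used for the distance (default: all in
#'   the library).
#' @return logical vector, TRUE = out-of-library.
#' @export
flag_unknown_signals <- function(features, flib, threshold_sigma = 3,
                                 feature_subset = NULL) {
  stopifnot(inherits(flib, "feature_library"))
  if (length(flib$labels) == 0) stop("empty analyte library")
  feats <- if (is.null(feature_subset)) flib$features else feature_subset
  x <- .as_feature_matrix(features)[, feats, drop = FALSE]
  dists <- vapply(seq_along(flib$labels), function(a) {
    z <- sweep(sweep(x, 2, flib$mean[a, feats], "-"), 2,
               flib$sd[a, feats], "/")
    sqrt(rowMeans(z^2))
  }, numeric(nrow(x)))
  if (nrow(x) == 1) dists <- matrix(dists, nrow = 1)
  apply(dists, 1, min) > threshold_sigma
}
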