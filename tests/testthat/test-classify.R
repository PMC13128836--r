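test_that("bagged trees separate separable classes and respect Bayes error", {
  # perfectly separated classes -> CV accuracy 1
  flib <- planted_feature_library(sep = 12)
  tb <- sample_feature_table(flib, 40, seed = 1)
  m <- train_bagged_trees(tb[, flib$features], tb$label,
                          bag_config(ntree = 30, folds = 5, seed = 2))
  expect_equal(m$cv_accuracy, 1)
  expect_equal(m$cv_folds, 5)

  # two 1-D Gaussians, means 2 sigma apart: Bayes accuracy = pnorm(1);
  # leaf-size smoothing brings the ensemble to the Bayes rule
  set.seed(8)
  n <- 600
  x <- data.frame(v = c(rnorm(n, 0), rnorm(n, 2)))
  y <- rep(c("a", "b"), each = n)
  m1 <- train_bagged_trees(x, y, bag_config(ntree = 60, folds = 5,
                                            nodesize = 15, seed = 3))
  expect_lt(abs(m1$cv_accuracy - pnorm(1)), 0.02)
})

test_that("degenerate classifier inputs raise informative errors", {
  tb <- sample_feature_table(planted_feature_library(), 20, seed = 4)
  expect_error(train_bagged_trees(tb[, 1:4], rep("one", nrow(tb))),
               "2 classes")
  bad <- tb
  bad$inf1[3] <- NaN
  expect_error(train_bagged_trees(bad[, planted_feature_library()$features],
                                  bad$label), "inf1")
})

test_that("confusion matrices conserve counts and recompute accuracy", {
  flib <- planted_feature_library(sep = 10)
  tb <- sample_feature_table(flib, 50, seed = 5)
  m <- train_bagged_trees(tb[, flib$features], tb$label,
                          bag_config(ntree = 30, folds = 3, seed = 6))
  te <- sample_feature_table(flib, 30, seed = 7)
  pc <- predict_and_confuse(m, te[, flib$features], te$label)
  # row sums = per-class test counts; total = test size
  expect_equal(unname(rowSums(pc$confusion)[flib$labels]), rep(30, 3))
  expect_equal(sum(pc$confusion), nrow(te))
  # arithmetic oracle
  expect_equal(pc$accuracy,
               sum(as.character(pc$predictions) == as.character(te$label)) /
                 nrow(te))
  # separable -> identity structure
  expect_equal(unname(diag(pc$confusion[flib$labels, flib$labels])),
               rep(30, 3))
  expect_error(predict_and_confuse(m, te[0, flib$features], character(0)),
               "empty")
})

test_that("permutation importance ranks planted features above noise", {
  flib <- planted_feature_library(n_noise = 5, sep = 3)
  tb <- sample_feature_table(flib, 80, seed = 9)
  m <- train_bagged_trees(tb[, flib$features], tb$label,
                          bag_config(ntree = 80, folds = 3, seed = 10))
  imp <- rank_feature_importance(m)
  expect_length(imp, length(flib$features))
  expect_true(all(imp >= 0))
  expect_gt(min(imp[c("inf1", "inf2")]), max(imp[paste0("noise", 1:5)]))
})

test_that("greedy forward selection finds the informative features first", {
  flib <- planted_feature_library(n_noise = 4, sep = 3)
  tb <- sample_feature_table(flib, 60, seed = 11)
  sel <- greedy_forward_selection(tb[, flib$features], tb$label,
                                  config = bag_config(ntree = 25, folds = 3,
                                                      seed = 12))
  expect_length(sel$accuracy, length(flib$features))
  expect_true(all(c("inf1", "inf2") %in% sel$order[1:3]))
  # plateau: accuracy beyond dimension 2 never improves much on dim-2
  expect_lt(max(sel$accuracy[3:6]) - max(sel$accuracy[1:2]), 0.08)

  one <- greedy_forward_selection(tb[, "inf1", drop = FALSE], tb$label,
                                  config = bag_config(ntree = 25, folds = 3))
  expect_equal(one$order, "inf1")
  expect_length(one$accuracy, 1)
  expect_warning(
    greedy_forward_selection(tb[, flib$features], tb$label, max_dim = 99,
                             config = bag_config(ntree = 10, folds = 2)),
    "clamp")
})

test_that("selection and training are reproducible under a fixed seed", {
  flib <- planted_feature_library(n_noise = 3)
  tb <- sample_feature_table(flib, 40, seed = 13)
  cfg <- bag_config(ntree = 20, folds = 3, seed = 77)
  m1 <- train_bagged_trees(tb[, flib$features], tb$label, cfg)
  m2 <- train_bagged_trees(tb[, flib$features], tb$label, cfg)
  expect_identical(m1$cv_accuracy, m2$cv_accuracy)
  expect_identical(rank_feature_importance(m1), rank_feature_importance(m2))
  s1 <- greedy_forward_selection(tb[, flib$features], tb$label, max_dim = 3,
                                 config = cfg)
  s2 <- greedy_forward_selection(tb[, flib$features], tb$label, max_dim = 3,
                                 config = cfg)
  expect_identical(s1$order, s2$order)
  expect_identical(s1$accuracy, s2$accuracy)
})

test_that("interference recall uses the configured ratio grid", {
  lib <- build_default_library(pfca_analytes(c("FTA", "C5", "C6")))
  flib <- default_feature_library(lib)
  tb <- simulate_feature_table(flib, 150, seed = 14)
  m <- train_bagged_trees(tb[, feature_names()], tb$label,
                          bag_config(ntree = 50, folds = 3, seed = 15))
  expect_error(interference_recall(m, flib, "FTA", c("C5", "C6"),
                                   ratio = 1, n_target = 0), "n_target")
  # R = 0: recall equals the per-class recall on a pure target sample
  r0 <- interference_recall(m, flib, "FTA", c("C5", "C6"), ratio = 0,
                            n_target = 200, seed = 16)
  expect_gt(r0, 0.8)
  # the ratio grid of the interference experiment runs end to end
  rec <- vapply(c(1, 10, 100, 1000), function(R)
    interference_recall(m, flib, "FTA", c("C5", "C6"), ratio = R,
                        n_target = 30, seed = 17), numeric(1))
  expect_true(all(rec >= 0 & rec <= 1))
  # recall is a per-event property: unaffected (within noise) by imbalance
  expect_gt(mean(rec), 0.6)
})

test_that("the blockade-only mixture baseline recovers known 1-D mixtures", {
  set.seed(18)
  x <- c(rnorm(300, 30, 0.2), rnorm(300, 36, 0.2))
  fit <- blockade_only_baseline(x, k = 2, seed = 1)
  expect_equal(fit$means, c(30, 36), tolerance = 0.05)
  expect_equal(fit$assignments, rep(1:2, each = 300))

  # weights within multinomial CI
  set.seed(19)
  n <- 1200
  w_true <- 0.3
  x <- c(rnorm(round(n * w_true), 30, 0.3), rnorm(round(n * (1 - w_true)), 32, 0.3))
  fit <- blockade_only_baseline(x, k = 2, seed = 2)
  expect_lt(abs(fit$weights[1] - w_true), 3 * sqrt(w_true * (1 - w_true) / n))

  # single component and degenerate sizes
  one <- blockade_only_baseline(rnorm(50, 10, 1), k = 1)
  expect_equal(one$assignments, rep(1L, 50))
  expect_error(blockade_only_baseline(c(1, 2), k = 3), "fewer")
})

test_that("the in-package EM agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))   # Mclust needs its namespace attached
  set.seed(20)
  x <- c(rnorm(400, 30, 0.3), rnorm(200, 31.5, 0.3))
  ours <- blockade_only_baseline(x, k = 2, seed = 3)
  ref <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(ours$means), sort(as.numeric(ref$parameters$mean)),
               tolerance = 0.05)
  expect_gt(mean(ours$assignments == ref$classification), 0.95)
})

test_that("multi-feature classification dominates the blockade-only baseline", {
  # classes separable only in tau_on / I_sigma, same blockade
  lib <- build_default_library(pfca_analytes(c("C5", "C6")))
  lib$blockade_mean <- c(33, 33.1)       # nearly indistinguishable blockades
  lib$dwell_log_mean <- c(log(1.5), log(4))
  flib <- default_feature_library(lib)
  diffs <- numeric(10)
  for (s in seq_len(10)) {
    tb <- simulate_feature_table(flib, 80, seed = 100 + s)
    te <- simulate_feature_table(flib, 60, seed = 200 + s)
    m <- train_bagged_trees(tb[, feature_names()], tb$label,
                            bag_config(ntree = 40, folds = 3, seed = s))
    multi <- predict_and_confuse(m, te[, feature_names()], te$label)$accuracy
    em <- blockade_only_baseline(te[["blockade@lp2000"]], k = 2, seed = s)
    # best label permutation for the EM assignment
    truth <- as.integer(te$label)
    em_acc <- max(mean(em$assignments == truth),
                  mean(3L - em$assignments == truth))
    diffs[s] <- multi - em_acc
  }
  expect_lt(wilcox.test(diffs, alternative = "greater",
                        exact = FALSE)$p.value, 0.01)
  expect_gt(mean(diffs), 0.2)
})

test_that("out-of-library signals are flagged, members are not", {
  lib <- build_default_library(pfca_analytes(c("C2", "C5", "C9")))
  flib <- default_feature_library(lib)
  tb <- simulate_feature_table(flib, 60, seed = 23)
  flags <- flag_unknown_signals(tb, flib)
  expect_lt(mean(flags), 0.02)

  # planted fatty-acid conjugate: PFCA-like blockade, 10x dwell
  fat <- lib[2, ]
  fat$label <- "FAT"
  fat$dwell_log_mean <- fat$dwell_log_mean + log(10)
  ftab <- simulate_feature_table(default_feature_library(fat), 40, seed = 24)
  flags <- flag_unknown_signals(ftab, flib)
  expect_gt(mean(flags), 0.95)

  empty <- structure(list(labels = character(), features = feature_names(),
                          mean = NULL, sd = NULL),
                     class = "feature_library")
  expect_error(flag_unknown_signals(tb, empty), "empty")
})
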