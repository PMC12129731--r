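# Balanced accuracy, SMOTE, cross-validated scoring, RFE and the MCTS
# subset search behave per contract and recover planted structure.

test_that("balanced accuracy is the mean per-class recall", {
  expect_equal(balanced_accuracy(c("a", "b", "c"), c("a", "b", "c")), 1)
  y <- c(rep("a", 4), rep("b", 4), rep("c", 4))
  pred <- c(rep("a", 4), rep("b", 4), rep("a", 4))  # class c fully wrong
  expect_equal(balanced_accuracy(y, pred), 2 / 3)
  y2 <- c(rep("a", 10), rep("b", 5), rep("c", 5))
  expect_equal(balanced_accuracy(y2, rep("a", 20)), 1 / 3)
  # predictions outside the true label set count as errors
  expect_equal(balanced_accuracy(c("a", "a"), c("z", "a")), 0.5)
  expect_error(balanced_accuracy(character(), character()),
               class = "invalid_request")
})

test_that("SMOTE balances classes by convex interpolation", {
  withr::with_seed(41, {
    X <- rbind(matrix(rnorm(8), 4, 2), matrix(rnorm(4) + 5, 2, 2))
  })
  colnames(X) <- c("x", "y")
  y <- c(rep("maj", 4), rep("min", 2))
  out <- smote_oversample(X, y, k = 1, seed = 5)
  expect_identical(as.vector(table(out$y)), c(4L, 4L))
  # originals unchanged and first
  expect_identical(out$X[1:6, ], X)
  expect_identical(attr(out, "synthetic"), c(rep(FALSE, 6), rep(TRUE, 2)))
  # each synthetic point lies on the segment between the two minority rows
  a <- X[5, ]; b <- X[6, ]
  for (i in 7:8) {
    s <- out$X[i, ]
    u <- (s - a) / (b - a)
    expect_equal(u[["x"]], u[["y"]], tolerance = 1e-10)
    expect_gte(u[["x"]], 0); expect_lte(u[["x"]], 1)
  }
  # determinism and the already-balanced identity
  expect_identical(out, smote_oversample(X, y, k = 1, seed = 5))
  bal <- smote_oversample(X[c(1:2, 5:6), ], y[c(1:2, 5:6)], seed = 1)
  expect_identical(bal$X, X[c(1:2, 5:6), ])
  # singleton class refuses silent duplication
  expect_error(smote_oversample(X[1:5, ], c(rep("maj", 4), "solo"), seed = 1),
               class = "invalid_request")
})

test_that("cross-validated scoring is leakage-free and deterministic", {
  full <- informative_data(n_per_class = 12, delta = 5, seed = 42)
  keep <- c(1:12, 13:20, 25:30)  # imbalanced classes (12 / 8 / 6)
  dat <- list(X = full$X[keep, ], y = full$y[keep],
              informative = full$informative, noise = full$noise)
  spec <- classifier_spec("svm", kernel = "linear")
  # linearly separable planted data scores perfectly
  expect_equal(cv_evaluate(dat$X, dat$y, dat$informative, spec, seed = 3), 1)
  # fold bookkeeping: test folds contain only original rows, no synthetics
  det <- cv_evaluate(dat$X, dat$y, dat$informative, spec, seed = 3,
                     details = TRUE)
  all_test <- sort(unlist(lapply(det$folds, `[[`, "test_idx")))
  expect_identical(all_test, seq_len(nrow(dat$X)))
  expect_true(all(vapply(det$folds, `[[`, 0L, "n_test_synthetic") == 0L))
  expect_true(any(vapply(det$folds, `[[`, 0L, "n_train_synthetic") > 0L))
  # memoization
  cache <- new.env(parent = emptyenv())
  s1 <- cv_evaluate(dat$X, dat$y, dat$noise[1:3], spec, seed = 3, cache = cache)
  s2 <- cv_evaluate(dat$X, dat$y, dat$noise[1:3], spec, seed = 3, cache = cache)
  expect_identical(s1, s2)
  expect_identical(attr(cache, "hits"), 1L)
  expect_error(cv_evaluate(dat$X, dat$y, "GHOST", spec),
               class = "invalid_request")
})

test_that("under label permutation cv scores sit at the chance level", {
  dat <- informative_data(n_per_class = 10, delta = 3, seed = 43)
  spec <- classifier_spec("svm", kernel = "linear")
  scores <- vapply(1:30, function(i) {
    yp <- withr::with_seed(500 + i, sample(dat$y))
    cv_evaluate(dat$X, yp, colnames(dat$X)[1:5], spec, seed = i)
  }, 0)
  expect_gte(mean(scores), 0.25)
  expect_lte(mean(scores), 0.42)
})

test_that("grid search returns the best spec with declaration-order ties", {
  dat <- informative_data(n_per_class = 12, n_noise = 5, delta = 6, seed = 44)
  single <- list(list(model = "svm", grid = list(kernel = "linear", cost = 1)))
  best <- grid_search_model(dat$X, dat$y, single, seed = 2)
  expect_identical(best$model, "svm")
  expect_equal(attr(best, "cv_score"), 1)
  # two identical candidates: the first one wins
  twice <- c(single, single)
  best2 <- grid_search_model(dat$X, dat$y, twice, seed = 2)
  lb <- attr(best2, "leaderboard")
  expect_identical(nrow(lb), 2L)
  expect_identical(lb$score[1], lb$score[2])
  expect_error(grid_search_model(dat$X, dat$y,
                                 list(list(model = "svm", grid = list()))),
               class = "config_error")
})

test_that("RFE converges on informative features and drops noise", {
  spec <- classifier_spec("svm", kernel = "linear")
  for (s in 1:3) {
    dat <- informative_data(n_per_class = 12, n_informative = 5,
                            n_noise = 45, delta = 2.5, seed = 100 + s)
    sel <- rfecv_select(dat$X, dat$y, spec, seed = s)
    # the retained set is dominated by planted features (ties between
    # equal-scoring sets resolve toward the smaller set, so redundant
    # informative features may be dropped, but noise must not dominate)
    expect_gte(mean(sel %in% dat$informative), 0.8)
    # and never scores worse than the full feature set
    full_score <- cv_evaluate(dat$X, dat$y, colnames(dat$X), spec, seed = s)
    expect_gte(attr(sel, "cv_score"), full_score)
  }
  # one feature in, one feature out
  dat <- informative_data(n_per_class = 8, n_informative = 1, n_noise = 0,
                          delta = 3, seed = 45)
  sel <- rfecv_select(dat$X, dat$y, spec, seed = 1)
  expect_identical(as.character(sel), "V001")
})

test_that("MCTS finds a constructed optimum and stops", {
  # one feature perfectly separates the two classes; the rest is noise
  dat <- informative_data(n_per_class = 12, n_informative = 1, n_noise = 7,
                          delta = 6, seed = 46, classes = c("A", "B"))
  cfg <- mcts_config(seed = 9)
  res <- mcts_feature_search(dat$X, dat$y, colnames(dat$X),
                             classifier_spec("svm", kernel = "linear"), cfg)
  expect_true(dat$informative %in% res$features)
  expect_equal(res$balanced_accuracy, 1)
  # determinism of the full trace and a warm cache
  res2 <- mcts_feature_search(dat$X, dat$y, colnames(dat$X),
                              classifier_spec("svm", kernel = "linear"), cfg)
  expect_identical(res$search_trace, res2$search_trace)
  expect_identical(res$features, res2$features)
  expect_gt(res$cache_hits, 0)
  expect_error(mcts_feature_search(dat$X, dat$y, character()),
               class = "invalid_request")
})

test_that("MCTS attains the exhaustive optimum under an additive reward", {
  # deterministic memoized reward over 8 candidate features
  feats <- sprintf("f%d", 1:8)
  X <- matrix(0, 4, 8, dimnames = list(NULL, feats))
  y <- rep(c("A", "B"), 2)
  for (s in 1:3) {
    w <- withr::with_seed(600 + s,
                          setNames(runif(8, -0.1, 0.2), feats))
    reward <- function(subset) 0.3 + sum(w[subset])
    cfg <- mcts_config(depth = 3, seed = s)
    res <- mcts_feature_search(X, y, feats, cfg = cfg, reward_fn = reward)
    # exhaustive enumeration over all 255 non-empty subsets
    best <- max(vapply(1:255, function(mask) {
      reward(feats[bitwAnd(mask, 2^(0:7)) > 0])
    }, 0))
    expect_equal(res$balanced_accuracy, best, tolerance = 1e-12)
  }
})

test_that("refinement seeds from subset frequency and never loses score", {
  dat <- informative_data(n_per_class = 10, n_informative = 3, n_noise = 5,
                          delta = 3, seed = 47)
  spec <- classifier_spec("svm", kernel = "linear")
  cfg <- mcts_config(accept_threshold = 0.6, seed = 4)
  res <- mcts_feature_search(dat$X, dat$y, colnames(dat$X), spec, cfg)
  expect_gt(nrow(res$qualifying_subsets), 0)
  refined <- refine_signature(res, dat$X, dat$y, colnames(dat$X), spec, cfg)
  expect_gte(refined$balanced_accuracy, res$balanced_accuracy)
  # a feature present in every qualifying subset must seed the refinement
  freq <- table(unlist(strsplit(res$qualifying_subsets$subset, "+",
                                fixed = TRUE)))
  always <- names(freq)[freq == nrow(res$qualifying_subsets)]
  if (length(always))
    expect_true(any(always %in% refined$refine_initial))
  # empty qualifying set falls back to the plain best subset
  none <- res; none$qualifying_subsets <- res$qualifying_subsets[0, ]
  expect_message(fb <- refine_signature(none, dat$X, dat$y, colnames(dat$X),
                                        spec, cfg), "no qualifying")
  expect_identical(fb$features, res$features)
})

test_that("signature evaluation produces calibrated AUCs and PCA", {
  dat <- informative_data(n_per_class = 12, delta = 5, seed = 48)
  ev <- evaluate_signature(dat$X, dat$y, dat$informative,
                           classifier_spec("svm", kernel = "linear"), seed = 2)
  expect_equal(ev$balanced_accuracy, 1)
  expect_true(all(unlist(ev$per_class_auc) == 1))
  expect_identical(nrow(ev$pca), nrow(dat$X))
  expect_true(all(c("PC1", "PC2") %in% names(ev$pca)))
  # negating the decision scores flips each AUC to its complement
  for (cl in unique(dat$y)) {
    a <- as.numeric(pROC::auc(pROC::roc(
      response = as.integer(dat$y == cl), predictor = ev$held_out_prob[, cl],
      levels = c(0, 1), direction = "<", quiet = TRUE)))
    b <- as.numeric(pROC::auc(pROC::roc(
      response = as.integer(dat$y == cl), predictor = -ev$held_out_prob[, cl],
      levels = c(0, 1), direction = "<", quiet = TRUE)))
    expect_equal(b, 1 - a, tolerance = 1e-12)
  }
})

test_that("random scores give chance-level AUC on balanced binary labels", {
  aucs <- vapply(1:10, function(s) {
    withr::with_seed(700 + s, {
      X <- matrix(rnorm(40 * 4), 40, 4,
                  dimnames = list(NULL, sprintf("V%d", 1:4)))
      y <- rep(c("pos", "neg"), each = 20)
    })
    ev <- evaluate_signature(X, y, colnames(X),
                             classifier_spec("svm", kernel = "linear"),
                             seed = s)
    ev$per_class_auc[["pos"]]
  }, 0)
  expect_gte(mean(aucs), 0.4)
  expect_lte(mean(aucs), 0.6)
})
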