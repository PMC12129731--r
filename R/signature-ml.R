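# Classifier selection and minimal-signature machinery: balanced
# accuracy, SMOTE oversampling strictly inside training folds,
# cross-validated subset scoring with memoization, grid search,
# backwards recursive feature elimination, a UCB1 Monte Carlo tree
# search over add-feature/STOP actions, frequency-based refinement, and
# one-vs-rest ROC / PCA signature evaluation.

#' MCTS search configuration
#'
#' @param depth Lookahead depth of each search round (default 5).
#' @param trees_factor Tree evaluations per round as a multiple of the
#'   candidate count (default 10).
#' @param accept_threshold Balanced-accuracy threshold above which a
#'   subset qualifies for refinement (default 0.90, strict).
#' @param improvement_epsilon Minimal one-step score improvement to keep
#'   growing the subset (default 1e-3).
#' @param ucb_c UCB1 exploration constant (default `sqrt(2)`).
#' @param refine_init Number of top-frequency features seeding the
#'   refinement round (default = `depth`).
#' @param seed Integer seed for rollouts and CV folds.
#' @return A list of class `mcts_config`.
#' @export
mcts_config <- function(depth = 5L, trees_factor = 10L,
                        accept_threshold = 0.90,
                        improvement_epsilon = 1e-3,
                        ucb_c = sqrt(2), refine_init = depth, seed = 1L) {
  if (depth < 1 || trees_factor < 1)
    abort_phosphosig("depth and trees_factor must be >= 1", "config_error")
  if (accept_threshold <= 0 || accept_threshold >= 1)
    abort_phosphosig("accept_threshold must lie in (0, 1)", "config_error")
  structure(list(depth = as.integer(depth),
                 trees_factor = as.integer(trees_factor),
                 accept_threshold = accept_threshold,
                 improvement_epsilon = improvement_epsilon,
                 ucb_c = ucb_c, refine_init = as.integer(refine_init),
                 seed = as.integer(seed)),
            class = "mcts_config")
}

#' Classifier specification
#'
#' @param model One of `"svm"` (maximum-margin classifier, via e1071),
#'   `"rf"` (random forest) or `"gbt"` (gradient boosting); the latter
#'   two require the suggested randomForest / xgboost packages.
#' @param kernel SVM kernel, `"linear"` or `"radial"`.
#' @param cost SVM regularization constant.
#' @param gamma RBF width (`NULL` = 1/n_features).
#' @param ... Further model parameters (e.g. `ntree`, `nrounds`).
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(model = c("svm", "rf", "gbt"),
                            kernel = "linear", cost = 1, gamma = NULL, ...) {
  model <- match.arg(model)
  structure(list(model = model, kernel = kernel, cost = cost, gamma = gamma,
                 extra = list(...)),
            class = "classifier_spec")
}

spec_key <- function(spec) {
  paste(spec$model, spec$kernel, spec$cost,
        spec$gamma %||% "auto",
        paste(names(spec$extra), unlist(spec$extra), collapse = ","),
        sep = "|")
}

# Fit/predict wrappers. Features are standardized with training-fold
# statistics inside fit (no leakage); zero-variance columns get sd 1.
fit_model <- function(spec, X, y, probability = FALSE) {
  y <- factor(y)
  mu <- colMeans(X)
  sd_ <- apply(X, 2, sd)
  sd_[sd_ == 0] <- 1
  Xs <- scale(X, center = mu, scale = sd_)
  fit <- switch(spec$model,
    svm = e1071::svm(Xs, y, kernel = spec$kernel, cost = spec$cost,
                     gamma = spec$gamma %||% (1 / ncol(Xs)),
                     scale = FALSE, probability = probability),
    rf = {
      if (!requireNamespace("randomForest", quietly = TRUE))
        abort_phosphosig("randomForest not installed", "config_error")
      randomForest::randomForest(Xs, y,
        ntree = spec$extra$ntree %||% 200L)
    },
    gbt = {
      if (!requireNamespace("xgboost", quietly = TRUE))
        abort_phosphosig("xgboost not installed", "config_error")
      xgboost::xgboost(data = Xs, label = as.integer(y) - 1L,
        nrounds = spec$extra$nrounds %||% 50L,
        params = list(objective = "multi:softprob",
                      num_class = nlevels(y),
                      max_depth = spec$extra$max_depth %||% 3L,
                      eta = spec$extra$eta %||% 0.3),
        verbose = 0)
    })
  list(spec = spec, fit = fit, levels = levels(y), mu = mu, sd = sd_,
       probability = probability)
}

predict_model <- function(model, X, type = c("class", "prob")) {
  type <- match.arg(type)
  Xs <- scale(X, center = model$mu, scale = model$sd)
  if (model$spec$model == "svm") {
    if (type == "class") return(as.character(predict(model$fit, Xs)))
    pr <- predict(model$fit, Xs, probability = TRUE)
    p <- attr(pr, "probabilities")
    return(p[, model$levels, drop = FALSE])
  }
  if (model$spec$model == "rf") {
    if (type == "class")
      return(as.character(predict(model$fit, Xs)))
    return(predict(model$fit, Xs, type = "prob")[, model$levels, drop = FALSE])
  }
  p <- matrix(predict(model$fit, Xs), ncol = length(model$levels),
              byrow = TRUE, dimnames = list(NULL, model$levels))
  if (type == "class") model$levels[max.col(p)] else p
}

#' Balanced accuracy (mean per-class recall)
#'
#' @param y_true,y_pred Equal-length label vectors; every true class
#'   must be non-empty. Predicted labels outside the true set count as
#'   wrong.
#' @return Mean over true classes of the within-class recall.
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  if (!length(y_true) || length(y_true) != length(y_pred))
    abort_phosphosig("label vectors must be non-empty and equal length",
                     "invalid_request")
  classes <- unique(as.character(y_true))
  mean(vapply(classes, function(cl) {
    idx <- y_true == cl
    mean(y_pred[idx] == cl)
  }, 0))
}

#' SMOTE oversampling
#'
#' Brings every class up to the majority-class count by interpolating
#' between same-class nearest neighbours: each synthetic point is
#' `x + u * (neighbour - x)` with `u ~ U(0, 1)` and the neighbour drawn
#' among the `k` nearest same-class points. Original rows are unchanged
#' and come first in the output; the attribute `synthetic` flags the
#' appended rows.
#'
#' @param X Numeric feature matrix (rows = samples).
#' @param y Class labels.
#' @param k Neighbours per minority point (default 5; clamped to class
#'   size minus one).
#' @param seed Integer seed.
#' @return List with elements `X`, `y` and attribute-carried provenance.
#' @export
smote_oversample <- function(X, y, k = 5L, seed = 1L) {
  y <- as.character(y)
  counts <- table(y)
  if (any(counts < 2))
    abort_phosphosig(paste0(
      "SMOTE requires every class to have >= 2 samples (got a singleton '",
      names(counts)[which.min(counts)],
      "'); merge classes or drop the singleton"), "invalid_request")
  target <- max(counts)
  withr::with_seed(derive_seed(seed, 6L), {
    synth_X <- list(); synth_y <- character()
    for (cl in names(counts)) {
      need <- target - counts[[cl]]
      if (need == 0) next
      idx <- which(y == cl)
      Xc <- X[idx, , drop = FALSE]
      kc <- min(k, nrow(Xc) - 1L)
      d <- as.matrix(dist(Xc))
      diag(d) <- Inf
      nn <- apply(d, 1, function(z) order(z)[seq_len(kc)], simplify = FALSE)
      if (is.matrix(nn)) nn <- asplit(nn, 2)  # kc > 1 returns a matrix
      base_i <- sample.int(nrow(Xc), need, replace = TRUE)
      rows <- matrix(NA_real_, need, ncol(X))
      for (s in seq_len(need)) {
        i <- base_i[s]
        j <- nn[[i]][sample.int(kc, 1L)]
        u <- runif(1)
        rows[s, ] <- Xc[i, ] + u * (Xc[j, ] - Xc[i, ])
      }
      synth_X[[cl]] <- rows
      synth_y <- c(synth_y, rep(cl, need))
    }
    Xout <- rbind(X, do.call(rbind, synth_X))
    yout <- c(y, synth_y)
    structure(list(X = Xout, y = yout),
              synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, length(synth_y))))
  })
}

# Stratified k-fold assignment, deterministic given seed.
stratified_folds <- function(y, n_folds, seed) {
  y <- as.character(y)
  fold <- integer(length(y))
  withr::with_seed(derive_seed(seed, 7L), {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

#' Cross-validated balanced accuracy of a feature subset
#'
#' Stratified k-fold cross-validation in which SMOTE is applied to the
#' training portion only; the classifier is fitted on the oversampled
#' training rows restricted to the subset and scored by balanced
#' accuracy on the untouched test portion. Results are memoized in
#' `cache` keyed by (subset, classifier, seed).
#'
#' @param X Feature matrix with column names.
#' @param y Class labels.
#' @param feature_subset Non-empty character vector of column names.
#' @param spec A [classifier_spec()].
#' @param n_folds Folds (default 5).
#' @param seed Integer seed fixing folds and SMOTE draws (folds are
#'   shared across subsets for paired evaluation).
#' @param cache Optional environment used as a memo table.
#' @param details Return fold bookkeeping alongside the score.
#' @param n_reps Number of repeated cross-validations (distinct fold
#'   assignments derived from `seed`) averaged into the score; repeats
#'   stabilize subset selection against fold-assignment noise
#'   (default 1).
#' @return The mean balanced accuracy, or (with `details = TRUE`) a list
#'   with `score`, `fold` assignment and per-fold test indices plus
#'   synthetic-row counts.
#' @export
cv_evaluate <- function(X, y, feature_subset, spec, n_folds = 5L, seed = 1L,
                        cache = NULL, details = FALSE, n_reps = 1L) {
  if (!length(feature_subset))
    abort_phosphosig("feature subset must be non-empty", "invalid_request")
  unknown <- setdiff(feature_subset, colnames(X))
  if (length(unknown))
    abort_phosphosig(sprintf("unknown feature(s): %s",
                             paste(unknown, collapse = ", ")), "invalid_request")
  key <- paste(paste(sort(feature_subset), collapse = "+"),
               spec_key(spec), n_folds, seed, n_reps, sep = "#")
  if (!details && !is.null(cache) && !is.null(cache[[key]])) {
    attr(cache, "hits") <- (attr(cache, "hits") %||% 0L) + 1L
    return(cache[[key]])
  }
  if (n_reps > 1L) {
    score <- mean(vapply(seq_len(n_reps), function(r)
      cv_evaluate(X, y, feature_subset, spec, n_folds,
                  seed = derive_seed(seed, 300L + r)), 0))
    if (!is.null(cache)) cache[[key]] <- score
    return(score)
  }
  fold <- stratified_folds(y, n_folds, seed)
  scores <- numeric(n_folds)
  book <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    Xtr <- X[train_idx, feature_subset, drop = FALSE]
    res <- smote_oversample(Xtr, y[train_idx], seed = derive_seed(seed, 100L + f))
    model <- fit_model(spec, res$X, res$y)
    pred <- predict_model(model, X[test_idx, feature_subset, drop = FALSE])
    scores[f] <- balanced_accuracy(as.character(y[test_idx]), pred)
    book[[f]] <- list(test_idx = test_idx,
                      n_train_synthetic = sum(attr(res, "synthetic")),
                      n_test_synthetic = 0L)  # test rows are original by construction
  }
  score <- mean(scores)
  if (!is.null(cache)) cache[[key]] <- score
  if (details) list(score = score, fold = fold, folds = book) else score
}

#' Grid search over candidate classifiers
#'
#' Evaluates every (model, hyperparameter) combination on the full
#' feature set by [cv_evaluate()] and returns the best specification;
#' ties are broken by declaration order.
#'
#' @param X,y Data.
#' @param candidates List of candidate entries, each a list with
#'   `model` and a `grid` (named list of parameter value vectors).
#' @param n_folds,seed Cross-validation settings.
#' @return The winning [classifier_spec()] with its score in attribute
#'   `cv_score` and the full leaderboard in `leaderboard`.
#' @export
grid_search_model <- function(X, y, candidates = default_candidates(),
                              n_folds = 5L, seed = 1L) {
  specs <- list()
  for (cand in candidates) {
    grid <- cand$grid
    if (!length(grid))
      abort_phosphosig("empty hyperparameter grid", "config_error")
    combos <- expand.grid(grid, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(combos))) {
      args <- c(list(model = cand$model), as.list(combos[i, , drop = FALSE]))
      args <- args[!vapply(args, function(a) is.na(a %||% NA), TRUE) |
                     names(args) == "model"]
      specs[[length(specs) + 1L]] <- do.call(classifier_spec, args)
    }
  }
  cache <- new.env(parent = emptyenv())
  scores <- vapply(specs, function(s)
    cv_evaluate(X, y, colnames(X), s, n_folds, seed, cache = cache), 0)
  best <- which.max(scores)  # first maximum = declaration order tie-break
  out <- specs[[best]]
  attr(out, "cv_score") <- scores[best]
  attr(out, "leaderboard") <- data.frame(
    spec = vapply(specs, spec_key, ""), score = scores,
    stringsAsFactors = FALSE)
  out
}

#' Default classifier candidates
#'
#' A maximum-margin classifier over linear and RBF kernels with a small
#' regularization/width grid; random forest and gradient boosting are
#' appended when their packages are installed.
#' @return A candidates list for [grid_search_model()].
#' @export
default_candidates <- function() {
  cands <- list(
    list(model = "svm", grid = list(kernel = c("linear", "radial"),
                                    cost = c(0.1, 1, 10))))
  if (requireNamespace("randomForest", quietly = TRUE))
    cands <- c(cands, list(list(model = "rf", grid = list(ntree = c(200L)))))
  if (requireNamespace("xgboost", quietly = TRUE))
    cands <- c(cands, list(list(model = "gbt", grid = list(nrounds = c(50L)))))
  cands
}

# Per-feature importance for RFE: aggregated absolute hyperplane
# weights for linear kernels, single-pass permutation importance
# otherwise.
feature_importance <- function(spec, X, y, seed = 1L) {
  model <- fit_model(spec, X, y)
  if (spec$model == "svm" && spec$kernel == "linear") {
    W <- t(model$fit$coefs) %*% model$fit$SV  # pairwise hyperplanes x features
    imp <- colSums(abs(W))
    names(imp) <- colnames(X)
    return(imp)
  }
  base <- balanced_accuracy(y, predict_model(model, X))
  withr::with_seed(derive_seed(seed, 8L), {
    vapply(colnames(X), function(f) {
      Xp <- X
      Xp[, f] <- sample(Xp[, f])
      base - balanced_accuracy(y, predict_model(model, Xp))
    }, 0)
  })
}

#' Backwards recursive feature elimination with cross-validation
#'
#' Starts from the ANOVA-significant features (raw screen p below
#' `anova_p_cutoff`), then iteratively drops the lowest-importance 10%
#' of the remaining features, scoring each working set by
#' [cv_evaluate()], and returns the best-scoring set seen. Score ties
#' prefer the smaller set, then the lexicographically first.
#'
#' @param X,y Data (X columns named).
#' @param spec A [classifier_spec()].
#' @param n_folds,seed Cross-validation settings.
#' @param anova_p Optional named vector of pre-computed screen p-values;
#'   by default a one-way ANOVA across the classes of `y` is run on `X`.
#' @param anova_p_cutoff Raw-p cutoff for the pre-selection (default 0.05).
#' @param step_frac Fraction of remaining features dropped per
#'   iteration (default 0.1, at least one).
#' @return Character vector of selected features with the score in
#'   attribute `cv_score` and the elimination path in `path`.
#' @export
rfecv_select <- function(X, y, spec, n_folds = 5L, seed = 1L,
                         anova_p = NULL, anova_p_cutoff = 0.05,
                         step_frac = 0.1) {
  if (is.null(anova_p)) {
    values <- t(X)
    dimnames(values) <- list(colnames(X),
                             rownames(X) %||% sprintf("s%03d", seq_len(nrow(X))))
    scr <- anova_screen_matrix(values, as.character(y))
    anova_p <- setNames(scr$p, scr$feature_id)
  }
  current <- colnames(X)[colnames(X) %in% names(anova_p)[anova_p < anova_p_cutoff]]
  if (!length(current)) {
    warning("no feature passes the ANOVA pre-selection; using all features")
    current <- colnames(X)
  }
  cache <- new.env(parent = emptyenv())
  best <- NULL; best_score <- -Inf
  path <- list()
  while (length(current) >= 1) {
    score <- cv_evaluate(X, y, current, spec, n_folds, seed, cache = cache)
    path[[length(path) + 1L]] <- list(n = length(current), score = score)
    better <- score > best_score ||
      (score == best_score && length(current) < length(best)) ||
      (score == best_score && length(current) == length(best) &&
         paste(sort(current), collapse = "") < paste(sort(best), collapse = ""))
    if (better) { best <- current; best_score <- score }
    if (length(current) == 1) break
    imp <- feature_importance(spec, X[, current, drop = FALSE], y, seed)
    n_drop <- max(1L, floor(step_frac * length(current)))
    # drop lowest-importance features; ties resolved lexicographically
    ord <- order(imp, names(imp), method = "radix")
    current <- setdiff(current, names(imp)[ord[seq_len(n_drop)]])
  }
  if (is.null(best))
    abort_phosphosig("all features eliminated before any score was computed",
                     "invalid_request")
  structure(sort(best), cv_score = best_score, path = path)
}

# Internal matrix-level one-way ANOVA (features in rows). Bypasses the
# sample-sheet group validation so it works on arbitrary class labels.
anova_screen_matrix <- function(values, groups) {
  tab <- intensity_table(values, scale = "log2")
  sheet <- data.frame(sample_id = colnames(values), group = groups,
                      stringsAsFactors = FALSE)
  class(sheet) <- c("sample_sheet", "data.frame")
  anova_screen(tab, sheet)
}

subset_key <- function(features) paste(sort(features), collapse = "+")

#' Monte Carlo tree search for a minimal discriminative feature subset
#'
#' For each candidate first feature, grows a working subset by repeated
#' search rounds. Each round runs `trees_factor x |candidates|` tree
#' evaluations over add-feature actions plus an explicit STOP node,
#' with random rollouts of lookahead depth at most `depth`; node values
#' are updated by UCB1 with exploration constant `ucb_c`, and the
#' reward of a rollout is the cross-validated balanced accuracy of the
#' visited subset. After the budget the best child feature is appended,
#' or the chain halts when STOP wins or the best one-step improvement
#' falls below `improvement_epsilon`. Every evaluated subset scoring
#' strictly above `accept_threshold` is collected.
#'
#' @param X,y Data (X columns named).
#' @param candidate_features Non-empty character vector of candidate
#'   feature columns.
#' @param spec A [classifier_spec()] fixed for all rewards.
#' @param cfg An [mcts_config()].
#' @param n_folds CV folds for the reward (default 5).
#' @param reward_fn Optional `function(features) -> score` replacing the
#'   cross-validated reward (used for oracle testing); memoized
#'   internally either way.
#' @param initial_features Features forced into every subset (used by
#'   refinement); not counted as candidates.
#' @param n_reps Repeated-CV count for the reward (see [cv_evaluate()]).
#' @return A list of class `signature_result`: `features` (best subset),
#'   `balanced_accuracy`, `qualifying_subsets`, `search_trace`,
#'   `evaluations` (memo table as a data frame) and `cache_hits`.
#' @export
mcts_feature_search <- function(X, y, candidate_features, spec = classifier_spec(),
                                cfg = mcts_config(), n_folds = 5L,
                                reward_fn = NULL,
                                initial_features = character(), n_reps = 1L) {
  if (!length(candidate_features))
    abort_phosphosig("candidate set must be non-empty", "invalid_request")
  budget <- cfg$trees_factor * length(candidate_features)
  if (budget <= 0)
    abort_phosphosig("tree-evaluation budget must be positive", "config_error")
  cache <- new.env(parent = emptyenv())
  evals <- new.env(parent = emptyenv())
  reward <- function(features) {
    key <- subset_key(features)
    if (!is.null(evals[[key]])) {
      attr(evals, "hits") <- (attr(evals, "hits") %||% 0L) + 1L
      return(evals[[key]])
    }
    r <- if (is.null(reward_fn)) {
      cv_evaluate(X, y, features, spec, n_folds, cfg$seed, cache = cache,
                  n_reps = n_reps)
    } else {
      reward_fn(features)
    }
    evals[[key]] <- r
    r
  }
  trace <- list()
  starts <- if (length(initial_features)) list(initial_features) else
    as.list(candidate_features)
  for (chain_i in seq_along(starts)) {
    S <- unique(c(initial_features, starts[[chain_i]]))
    s_score <- reward(S)
    round_i <- 0L
    repeat {
      round_i <- round_i + 1L
      remaining <- setdiff(candidate_features, S)
      if (!length(remaining)) break
      actions <- c(remaining, ".STOP")
      n_act <- length(actions)
      visits <- numeric(n_act); value <- numeric(n_act)
      rng_seed <- derive_seed(cfg$seed, 1000L * chain_i + round_i)
      withr::with_seed(rng_seed, {
        for (it in seq_len(budget)) {
          a <- if (any(visits == 0)) {
            which(visits == 0)[1L]  # expand untried actions in order
          } else {
            ucb <- value / visits +
              cfg$ucb_c * sqrt(log(sum(visits)) / visits)
            which.max(ucb)
          }
          if (actions[a] == ".STOP") {
            r <- s_score
          } else {
            # rollout: chosen action plus random additions, path <= depth
            path <- actions[a]
            extra_pool <- setdiff(remaining, path)
            n_extra <- sample.int(cfg$depth, 1L) - 1L
            n_extra <- min(n_extra, length(extra_pool))
            if (n_extra > 0)
              path <- c(path, sample(extra_pool, n_extra))
            r <- reward(c(S, path))
          }
          visits[a] <- visits[a] + 1
          value[a] <- value[a] + r
        }
      })
      mean_value <- value / pmax(visits, 1)
      stop_i <- which(actions == ".STOP")
      best_a <- which.max(mean_value)
      # decide on the one-step move: compare the best child's immediate
      # reward against the current subset's own score
      if (best_a == stop_i) {
        trace[[length(trace) + 1L]] <- data.frame(
          chain = chain_i, round = round_i, action = "STOP",
          reward = s_score, stringsAsFactors = FALSE)
        break
      }
      cand_feat <- actions[best_a]
      one_step <- reward(c(S, cand_feat))
      trace[[length(trace) + 1L]] <- data.frame(
        chain = chain_i, round = round_i, action = cand_feat,
        reward = one_step, stringsAsFactors = FALSE)
      if (one_step - s_score < cfg$improvement_epsilon) break
      S <- c(S, cand_feat)
      s_score <- one_step
    }
  }
  eval_keys <- ls(evals)
  eval_df <- data.frame(
    subset = eval_keys,
    size = lengths(strsplit(eval_keys, "+", fixed = TRUE)),
    score = vapply(eval_keys, function(k) evals[[k]], 0),
    stringsAsFactors = FALSE, row.names = NULL)
  qualifying <- eval_df[eval_df$score > cfg$accept_threshold, , drop = FALSE]
  # best subset: highest score, then smallest, then lexicographic
  ord <- order(-eval_df$score, eval_df$size, eval_df$subset, method = "radix")
  best_row <- eval_df[ord[1L], ]
  structure(list(
    features = strsplit(best_row$subset, "+", fixed = TRUE)[[1L]],
    balanced_accuracy = best_row$score,
    qualifying_subsets = qualifying,
    search_trace = if (length(trace)) do.call(rbind, trace) else
      data.frame(chain = integer(), round = integer(), action = character(),
                 reward = numeric(), stringsAsFactors = FALSE),
    evaluations = eval_df,
    cache_hits = attr(evals, "hits") %||% 0L,
    seed = cfg$seed
  ), class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat(sprintf("signature_result: %d feature(s), balanced accuracy %.3f\n",
              length(x$features), x$balanced_accuracy))
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  if (!is.null(x$per_class_auc)) {
    auc <- vapply(x$per_class_auc, identity, 0)
    cat("  one-vs-rest AUC:",
        paste(sprintf("%s %.3f", names(auc), auc), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Frequency-based refinement of qualifying subsets
#'
#' Ranks features by how often they appear across the qualifying
#' subsets, seeds a second MCTS whose initial subset is the
#' top-frequency features (`cfg$refine_init`, default 5), and returns
#' the highest-scoring subset found, never worse than the seed set's
#' own score. With no qualifying subsets it falls back to the best
#' subset from the first search.
#'
#' @param result A `signature_result` from [mcts_feature_search()].
#' @param X,y Data.
#' @param candidate_features Candidate pool of the first search.
#' @param spec,cfg,n_folds,reward_fn,n_reps As in [mcts_feature_search()].
#' @return A refined `signature_result`.
#' @export
refine_signature <- function(result, X, y, candidate_features,
                             spec = classifier_spec(), cfg = mcts_config(),
                             n_folds = 5L, reward_fn = NULL, n_reps = 1L) {
  qs <- result$qualifying_subsets
  if (!nrow(qs)) {
    message("no qualifying subset; keeping the best subset from the search")
    return(result)
  }
  freq <- sort(table(unlist(strsplit(qs$subset, "+", fixed = TRUE))),
               decreasing = TRUE)
  ord <- order(-as.vector(freq), names(freq), method = "radix")
  init <- names(freq)[ord][seq_len(min(cfg$refine_init, length(freq)))]
  refined <- mcts_feature_search(X, y, candidate_features, spec, cfg,
                                 n_folds, reward_fn,
                                 initial_features = init, n_reps = n_reps)
  # merge qualifying sets and pick the overall best
  all_eval <- rbind(result$evaluations, refined$evaluations)
  all_eval <- all_eval[!duplicated(all_eval$subset), ]
  ord2 <- order(-all_eval$score, all_eval$size, all_eval$subset,
                method = "radix")
  best_row <- all_eval[ord2[1L], ]
  refined$features <- strsplit(best_row$subset, "+", fixed = TRUE)[[1L]]
  refined$balanced_accuracy <- best_row$score
  refined$evaluations <- all_eval
  refined$qualifying_subsets <-
    all_eval[all_eval$score > cfg$accept_threshold, , drop = FALSE]
  refined$refine_initial <- init
  refined
}

#' Cross-validated signature evaluation (one-vs-rest ROC, PCA)
#'
#' Scores the fixed feature set by stratified cross-validation: SMOTE on
#' each training portion, class-probability predictions on the held-out
#' portion, pooled into per-class one-vs-rest ROC AUCs and an overall
#' balanced accuracy. Also returns a 2-component PCA projection of the
#' standardized signature features for plotting.
#'
#' @param X,y Data.
#' @param features Signature feature names (columns of X).
#' @param spec A [classifier_spec()].
#' @param n_folds,seed Cross-validation settings.
#' @return A `signature_result` with `per_class_auc` and `pca` entries.
#' @export
evaluate_signature <- function(X, y, features, spec = classifier_spec(),
                               n_folds = 5L, seed = 1L) {
  unknown <- setdiff(features, colnames(X))
  if (length(unknown))
    abort_phosphosig(sprintf("unknown feature(s): %s",
                             paste(unknown, collapse = ", ")), "invalid_request")
  y <- as.character(y)
  fold <- stratified_folds(y, n_folds, seed)
  classes <- sort(unique(y))
  if (any(vapply(classes, function(cl)
    any(tabulate(fold[y == cl], n_folds) == 0), TRUE)))
    abort_phosphosig("a class is absent from some fold; reduce n_folds",
                     "design_error")
  prob <- matrix(NA_real_, nrow(X), length(classes),
                 dimnames = list(NULL, classes))
  pred <- character(nrow(X))
  for (f in seq_len(n_folds)) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    res <- smote_oversample(X[train_idx, features, drop = FALSE], y[train_idx],
                            seed = derive_seed(seed, 200L + f))
    model <- fit_model(spec, res$X, res$y, probability = TRUE)
    p <- predict_model(model, X[test_idx, features, drop = FALSE], type = "prob")
    prob[test_idx, colnames(p)] <- p
    pred[test_idx] <- colnames(p)[max.col(p)]
  }
  auc <- lapply(classes, function(cl) {
    as.numeric(pROC::auc(pROC::roc(
      response = as.integer(y == cl), predictor = prob[, cl],
      levels = c(0, 1), direction = "<", quiet = TRUE)))
  })
  names(auc) <- classes
  Xs <- scale(X[, features, drop = FALSE])
  Xs[, apply(Xs, 2, function(z) anyNA(z))] <- 0
  pca <- prcomp(Xs, center = FALSE, scale. = FALSE)
  coords <- data.frame(sample = rownames(X) %||% seq_len(nrow(X)),
                       class = y,
                       PC1 = pca$x[, 1],
                       PC2 = if (ncol(pca$x) >= 2) pca$x[, 2] else 0)
  structure(list(
    features = features,
    balanced_accuracy = balanced_accuracy(y, pred),
    per_class_auc = auc,
    predictions = data.frame(truth = y, predicted = pred,
                             stringsAsFactors = FALSE),
    held_out_prob = prob,
    pca = coords,
    seed = seed
  ), class = "signature_result")
}
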