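#' The eleven classifier families
#'
#' Identifiers of the model families entered in the selection sweep:
#' logistic regression (LR), k-nearest neighbors (KNN), support-vector
#' machine (SVM), gradient boosting (GB), extremely randomized trees (ET),
#' decision tree (DT), random forest (RF), Gaussian naive Bayes (NB),
#' AdaBoost (AB), quadratic discriminant analysis (QDA) and Gaussian
#' process (GP).
#'
#' @return Character vector of the 11 algorithm ids.
#' @export
algorithm_ids <- function() {
  c("LR", "KNN", "SVM", "GB", "ET", "DT", "RF", "NB", "AB", "QDA", "GP")
}

.positive_class <- "retrieval"
.class_levels <- c("encoding", "retrieval")

#' Randomized hyperparameter search spaces
#'
#' One documented sampler per algorithm; each randomized-search iteration
#' draws one configuration from the family's space. QDA has no tunable
#' hyperparameters (its space is empty, so its search collapses to a single
#' fit).
#'
#' @param id Algorithm id, or NULL for the full named list of samplers.
#' @return A sampler function (no arguments, returns a named parameter
#'   list), or the list of all samplers.
#' @export
search_space <- function(id = NULL) {
  spaces <- list(
    LR = function() list(alpha = sample(c(0, 0.5, 1), 1),
                         lambda = 10^stats::runif(1, -4, 1)),
    KNN = function() list(k = sample(seq(1L, 25L, 2L), 1)),
    SVM = function() list(cost = 10^stats::runif(1, -2, 2),
                          gamma = 10^stats::runif(1, -4, 0),
                          kernel = sample(c("radial", "linear"), 1)),
    GB = function() list(nrounds = sample(20:150, 1),
                         eta = 10^stats::runif(1, -2, -0.3),
                         max_depth = sample(1:6, 1),
                         subsample = stats::runif(1, 0.5, 1)),
    ET = function() list(num.trees = sample(c(100L, 200L, 300L, 500L), 1),
                         mtry_frac = stats::runif(1, 0.1, 1),
                         min.node.size = sample(1:10, 1)),
    DT = function() list(cp = 10^stats::runif(1, -4, -1),
                         maxdepth = sample(1:10, 1),
                         minsplit = sample(2:20, 1)),
    RF = function() list(num.trees = sample(c(100L, 200L, 300L, 500L), 1),
                         mtry_frac = stats::runif(1, 0.1, 1),
                         min.node.size = sample(1:10, 1)),
    NB = function() list(laplace = stats::runif(1, 0, 2)),
    AB = function() list(n_estimators = sample(20:100, 1),
                         maxdepth = sample(1:3, 1)),
    QDA = function() list(),
    GP = function() list(sigma = 10^stats::runif(1, -3, 1))
  )
  if (is.null(id)) return(spaces)
  if (!id %in% names(spaces)) stop_invalid("algorithm", paste("unknown id:", id))
  spaces[[id]]
}

# Draw n seeded configurations; empty spaces collapse to a single draw.
.draw_params <- function(id, n, seed) {
  sampler <- search_space(id)
  with_seed(seed, {
    draws <- replicate(n, sampler(), simplify = FALSE)
    if (all(vapply(draws, length, 0L) == 0L)) draws <- draws[1L]
    draws
  })
}

.fit_algorithm <- function(id, X, y, params, seed = 1L) {
  with_seed(seed, {
    obj <- switch(id,
      LR = {
        Xp <- if (ncol(X) < 2L) cbind(X, .pad = 0) else X
        glmnet::glmnet(Xp, y, family = "binomial",
                       alpha = params$alpha, lambda = params$lambda)
      },
      KNN = list(X = X, y = y, k = min(params$k, nrow(X))),
      SVM = e1071::svm(X, y, cost = params$cost, gamma = params$gamma,
                       kernel = params$kernel, scale = FALSE),
      GB = xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = params$eta,
                      max_depth = params$max_depth,
                      subsample = params$subsample, nthread = 1,
                      seed = seed),
        data = xgboost::xgb.DMatrix(X, label = as.numeric(y == .positive_class)),
        nrounds = params$nrounds, verbose = 0),
      ET = ranger::ranger(
        x = as.data.frame(X), y = y,
        num.trees = params$num.trees,
        mtry = max(1L, floor(params$mtry_frac * ncol(X))),
        min.node.size = params$min.node.size,
        splitrule = "extratrees", num.random.splits = 1,
        replace = FALSE, sample.fraction = 1,
        seed = seed, num.threads = 1),
      DT = {
        df <- data.frame(.label = y, X, check.names = FALSE)
        rpart::rpart(.label ~ ., df, method = "class",
                     control = rpart::rpart.control(
                       cp = params$cp, maxdepth = params$maxdepth,
                       minsplit = params$minsplit, xval = 0))
      },
      RF = ranger::ranger(
        x = as.data.frame(X), y = y,
        num.trees = params$num.trees,
        mtry = max(1L, floor(params$mtry_frac * ncol(X))),
        min.node.size = params$min.node.size,
        seed = seed, num.threads = 1),
      NB = e1071::naiveBayes(X, y, laplace = params$laplace %||% 0),
      AB = .fit_adaboost(X, y, params$n_estimators, params$maxdepth),
      QDA = MASS::qda(X, grouping = y),
      GP = kernlab::gausspr(x = X, y = y, kernel = "rbfdot",
                            kpar = list(sigma = params$sigma)),
      stop_invalid("algorithm", paste("unknown id:", id))
    )
    list(id = id, obj = obj, params = params)
  })
}

.predict_algorithm <- function(fit, X) {
  id <- fit$id
  obj <- fit$obj
  pred <- switch(id,
    LR = {
      Xp <- if (ncol(X) < 2L) cbind(X, .pad = 0) else X
      as.character(stats::predict(obj, newx = Xp, s = fit$params$lambda,
                                  type = "class")[, 1L])
    },
    KNN = as.character(class::knn(obj$X, X, obj$y, k = obj$k)),
    SVM = as.character(stats::predict(obj, X)),
    GB = ifelse(stats::predict(obj, xgboost::xgb.DMatrix(X)) > 0.5,
                .positive_class, .class_levels[1L]),
    ET = as.character(stats::predict(obj, data = as.data.frame(X))$predictions),
    DT = as.character(stats::predict(obj, data.frame(X, check.names = FALSE),
                                     type = "class")),
    RF = as.character(stats::predict(obj, data = as.data.frame(X))$predictions),
    NB = as.character(stats::predict(obj, X)),
    AB = .predict_adaboost(obj, X),
    QDA = as.character(stats::predict(obj, X)$class),
    GP = as.character(kernlab::predict(obj, X))
  )
  factor(pred, levels = .class_levels)
}

# SAMME AdaBoost over rpart weak learners (binary case).
.fit_adaboost <- function(X, y, n_estimators, maxdepth) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  df <- data.frame(.label = y, X, check.names = FALSE)
  stumps <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_estimators)) {
    fit <- rpart::rpart(.label ~ ., df, weights = w, method = "class",
                        control = rpart::rpart.control(
                          maxdepth = maxdepth, cp = 0, minsplit = 2, xval = 0))
    pred <- stats::predict(fit, df, type = "class")
    err <- sum(w[pred != y]) / sum(w)
    if (err <= 0) {
      stumps[[length(stumps) + 1L]] <- fit
      alphas <- c(alphas, 10)
      break
    }
    if (err >= 0.5) {
      if (length(stumps) == 0L) {
        stumps[[1L]] <- fit
        alphas <- 1e-10
      }
      break
    }
    alpha <- log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
  }
  list(stumps = stumps, alphas = alphas)
}

.predict_adaboost <- function(obj, X) {
  df <- data.frame(X, check.names = FALSE)
  score <- numeric(nrow(X))
  for (m in seq_along(obj$stumps)) {
    pred <- stats::predict(obj$stumps[[m]], df, type = "class")
    score <- score + obj$alphas[m] * ifelse(pred == .positive_class, 1, -1)
  }
  ifelse(score > 0, .positive_class, .class_levels[1L])
}

#' Participant-level train/test split
#'
#' Holds out `n_test` whole participants, stratified by study group
#' (stress/control) as evenly as possible, so no participant's trials appear
#' on both sides. Seeded and reproducible.
#'
#' @param table A `feature_table`.
#' @param n_test Number of test participants.
#' @param seed Integer seed.
#' @return List with `train` and `test` feature tables.
#' @export
split_by_participant <- function(table, n_test = 5L, seed = 1L) {
  info <- unique(table[, c("participant", "group")])
  if (nrow(info) < n_test + 1L) {
    stop_invalid("split", sprintf("need at least %d participants, got %d",
                                  n_test + 1L, nrow(info)))
  }
  test_ids <- with_seed(seed, {
    ids <- character(0)
    groups <- split(info$participant, info$group)
    # proportional allocation, largest remainder
    quota <- n_test * vapply(groups, length, 0L) / nrow(info)
    take <- floor(quota)
    rem <- n_test - sum(take)
    if (rem > 0) {
      extra <- order(quota - take, decreasing = TRUE)[seq_len(rem)]
      take[extra] <- take[extra] + 1L
    }
    for (g in seq_along(groups)) {
      ids <- c(ids, sample(as.character(groups[[g]]), take[g]))
    }
    ids
  })
  is_test <- as.character(table$participant) %in% test_ids
  list(train = table[!is_test, , drop = FALSE],
       test = table[is_test, , drop = FALSE])
}

#' Filter a feature table to a condition group
#'
#' Group SN keeps all rows; groups N and S keep only trials recorded under
#' normal or stressor conditions respectively.
#'
#' @param table A `feature_table`.
#' @param group One of "SN", "N", "S".
#' @return The filtered table.
#' @export
filter_group <- function(table, group = c("SN", "N", "S")) {
  group <- match.arg(group)
  if (group == "SN") return(table)
  table[table$condition == group, , drop = FALSE]
}

#' Rank features by ANOVA F-value
#'
#' One-way ANOVA of each feature against the encoding/retrieval label over
#' the selected condition group's rows: F = MS(between) / MS(within), which
#' for two classes equals the squared pooled two-sample t statistic.
#' Features are ordered by decreasing F; ties break by feature index.
#'
#' @param table A `feature_table` (training rows).
#' @param group Condition group to rank within ("SN", "N", "S").
#' @param features Feature columns to rank (default: all).
#' @return A `ranked_features` object: ordered feature names plus F-values.
#' @export
anova_rank <- function(table, group = "SN", features = feature_columns(table)) {
  tbl <- filter_group(table, group)
  y <- tbl$label
  if (length(unique(y)) < 2L) {
    stop_invalid("anova", "both classes must be present")
  }
  X <- as.matrix(tbl[, features, drop = FALSE])
  f <- anova_f(X, y)
  ord <- order(-f, seq_along(f))
  structure(list(features = features[ord], f_values = f[ord]),
            class = "ranked_features")
}

#' Vectorized one-way ANOVA F statistic
#'
#' @param X Numeric matrix (rows = observations).
#' @param y Class labels (any number of groups).
#' @return Named vector of F values (0 where both between- and
#'   within-class variation vanish).
#' @export
anova_f <- function(X, y) {
  y <- as.factor(y)
  n <- nrow(X)
  k <- nlevels(y)
  grand <- colMeans(X)
  ssb <- 0
  ssw <- 0
  for (lev in levels(y)) {
    rows <- y == lev
    m <- colMeans(X[rows, , drop = FALSE])
    ssb <- ssb + sum(rows) * (m - grand)^2
    ssw <- ssw + colSums((X[rows, , drop = FALSE] -
                            matrix(m, sum(rows), ncol(X), byrow = TRUE))^2)
  }
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  f <- ifelse(msw > 0, msb / msw, ifelse(msb > 0, Inf, 0))
  stats::setNames(f, colnames(X))
}

#' Select the top fraction of ranked features
#'
#' Keeps the best `round(n_features * pct / 100)` features (at least one).
#' At 2% of 651 features this is 13 features.
#'
#' @param ranked A `ranked_features`.
#' @param pct Integer percentage in 1..100.
#' @return Character vector of selected feature names, best first.
#' @export
select_top_fraction <- function(ranked, pct) {
  if (length(pct) != 1L || is.na(pct) || pct < 1 || pct > 100) {
    stop_invalid("fraction", "pct must lie in 1..100")
  }
  n <- max(1L, round(length(ranked$features) * pct / 100))
  ranked$features[seq_len(n)]
}

#' Drop highly correlated features
#'
#' The first selection stage: walks the features in column order and drops
#' any feature whose absolute Pearson correlation with an already-kept
#' feature exceeds the threshold (the later feature of the pair is removed).
#' When no pair exceeds the threshold the table passes through unchanged.
#'
#' @param table A `feature_table` (training rows).
#' @param threshold Absolute correlation cutoff (default 0.95).
#' @param features Candidate feature columns.
#' @return List with `kept` and `dropped` feature-name vectors.
#' @export
drop_correlated <- function(table, threshold = 0.95,
                            features = feature_columns(table)) {
  X <- as.matrix(table[, features, drop = FALSE])
  C <- suppressWarnings(abs(stats::cor(X)))
  C[!is.finite(C)] <- 0
  keep <- logical(length(features))
  for (j in seq_along(features)) {
    keep[j] <- !any(C[j, which(keep[seq_len(j - 1L)])] > threshold)
  }
  list(kept = features[keep], dropped = features[!keep])
}

# Participant-grouped CV fold assignment (fold id per row).
.cv_folds <- function(table, n_folds, seed) {
  parts <- unique(table$participant)
  with_seed(seed, {
    if (length(parts) >= n_folds) {
      shuffled <- sample(parts)
      fold_of <- stats::setNames(rep(seq_len(n_folds), length.out = length(parts)),
                                 shuffled)
      unname(fold_of[as.character(table$participant)])
    } else {
      sample(rep(seq_len(n_folds), length.out = nrow(table)))
    }
  })
}

.metrics_from_preds <- function(truth, pred) {
  truth <- factor(truth, levels = .class_levels)
  pred <- factor(pred, levels = .class_levels)
  tp <- sum(pred == .positive_class & truth == .positive_class)
  fp <- sum(pred == .positive_class & truth != .positive_class)
  fn <- sum(pred != .positive_class & truth == .positive_class)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  structure(list(accuracy = mean(pred == truth),
                 precision = precision, recall = recall,
                 f1 = f1_score(precision, recall)),
            class = "eval_metrics")
}

#' F1 score from precision and recall
#'
#' The harmonic mean `2 P R / (P + R)` (0 when P + R = 0), the model-selection
#' criterion under the dataset's encoding/retrieval imbalance.
#'
#' @param precision,recall Values in [0, 1].
#' @return F1 in [0, 1].
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Tune and train one classifier
#'
#' Randomized search: `n_iters` seeded draws from the algorithm's
#' hyperparameter space, each scored by participant-grouped k-fold
#' cross-validated F1 (retrieval = positive class) on the training rows; the
#' best configuration is refit on all training rows. Draws whose fit fails
#' (e.g., a rank-deficient QDA fold) score -Inf and are skipped.
#'
#' @param algorithm One of [algorithm_ids()].
#' @param train Training `feature_table` rows.
#' @param features Feature subset (column names) to train on.
#' @param config A [pipeline_config()] (supplies `n_search_iters`,
#'   `n_cv_folds` defaults).
#' @param seed Integer seed; same seed, same chosen hyperparameters.
#' @param n_iters,n_folds Optional overrides of the config values.
#' @return A `nirs_model` (algorithm, chosen params, fitted object, feature
#'   list, CV F1).
#' @export
tune_and_train <- function(algorithm, train, features,
                           config = pipeline_config(), seed = 1L,
                           n_iters = config$n_search_iters,
                           n_folds = config$n_cv_folds) {
  if (!algorithm %in% algorithm_ids()) {
    stop_invalid("algorithm", paste("unknown id:", algorithm))
  }
  missing_cols <- setdiff(features, names(train))
  if (length(missing_cols)) {
    stop_invalid("features", paste("missing column(s):",
                                   paste(missing_cols[1:min(3, length(missing_cols))],
                                         collapse = ", ")))
  }
  X <- as.matrix(train[, features, drop = FALSE])
  y <- factor(train$label, levels = .class_levels)
  folds <- .cv_folds(train, n_folds, seed)
  params_list <- .draw_params(algorithm, n_iters, seed)
  fit_seeds <- derive_seeds(seed, length(params_list) + 1L)

  scores <- vapply(seq_along(params_list), function(i) {
    p <- params_list[[i]]
    fold_f1 <- vapply(sort(unique(folds)), function(f) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2L) return(NA_real_)
      fit <- tryCatch(
        .fit_algorithm(algorithm, X[tr, , drop = FALSE], y[tr], p, fit_seeds[i]),
        error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      pred <- tryCatch(.predict_algorithm(fit, X[!tr, , drop = FALSE]),
                       error = function(e) NULL)
      if (is.null(pred)) return(NA_real_)
      .metrics_from_preds(y[!tr], pred)$f1
    }, 0)
    if (all(is.na(fold_f1))) -Inf else mean(fold_f1, na.rm = TRUE)
  }, 0)

  if (all(!is.finite(scores))) {
    stop_invalid("tuning", sprintf("all %s candidate fits failed", algorithm))
  }
  best <- which.max(scores)
  final <- .fit_algorithm(algorithm, X, y, params_list[[best]],
                          fit_seeds[length(fit_seeds)])
  structure(list(algorithm = algorithm, params = params_list[[best]],
                 fit = final, features = features,
                 cv_f1 = scores[best], levels = .class_levels,
                 positive = .positive_class),
            class = "nirs_model")
}

#' @export
predict.nirs_model <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$features, colnames(newdata))
  if (length(missing_cols)) {
    stop_invalid("predict", "feature columns of new data do not match the model")
  }
  X <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  .predict_algorithm(object$fit, X)
}

#' Evaluate a fitted model on held-out rows
#'
#' Accuracy, precision, recall and F1 with retrieval as the positive class.
#'
#' @param model A `nirs_model`.
#' @param test Test `feature_table` rows.
#' @return An `eval_metrics` list.
#' @export
evaluate_model <- function(model, test) {
  pred <- predict(model, test)
  .metrics_from_preds(test$label, pred)
}

#' Accuracy of the trivial majority-class predictor
#'
#' @param table A `feature_table`.
#' @return The larger class fraction — the floor any useful model must beat.
#' @export
majority_class_accuracy <- function(table) {
  max(table(factor(table$label, levels = .class_levels))) / nrow(table)
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%  F1 %.3f  precision %.3f  recall %.3f\n",
              100 * x$accuracy, x$f1, x$precision, x$recall))
  invisible(x)
}

#' Sweep classifier families over feature fractions
#'
#' The model-selection workflow on Group SN: drop correlated features, rank
#' the survivors by ANOVA F, then for every (algorithm, feature-fraction)
#' combination run randomized search with cross-validation, refit, and
#' evaluate on the held-out participants. With 11 algorithms and a 1..100%
#' fraction grid the full sweep trains and optimizes 1100 models; the grid
#' and iteration counts can be reduced for quick runs while the leaderboard
#' records the sweep dimensions either way.
#'
#' @param train,test Feature tables from [split_by_participant()].
#' @param config A [pipeline_config()].
#' @param algorithms Algorithm ids to sweep (default all 11).
#' @param fractions Feature percentages to sweep (default the config grid).
#' @param n_iters Randomized-search iterations per combination.
#' @param seed Integer seed.
#' @return A `sweep_leaderboard` data frame (algorithm, pct, n_features,
#'   cv_f1, accuracy, precision, recall, f1) sorted by test F1 (ties: higher
#'   accuracy, then smaller pct), with the ranking, the chosen best
#'   combination and the sweep dimensions in attributes.
#' @export
sweep_models <- function(train, test, config = pipeline_config(),
                         algorithms = algorithm_ids(),
                         fractions = config$feature_fraction_grid,
                         n_iters = config$n_search_iters,
                         seed = 1L) {
  dropout <- drop_correlated(train, config$corr_dropout_threshold)
  ranked <- anova_rank(train, "SN", features = dropout$kept)
  subsets <- lapply(fractions, function(p) select_top_fraction(ranked, p))
  combos <- expand.grid(algorithm = algorithms, pct = fractions,
                        stringsAsFactors = FALSE)
  seeds <- derive_seeds(seed, nrow(combos))
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    alg <- combos$algorithm[i]
    pct <- combos$pct[i]
    feats <- subsets[[match(pct, fractions)]]
    model <- tryCatch(
      tune_and_train(alg, train, feats, config, seed = seeds[i],
                     n_iters = n_iters),
      error = function(e) NULL)
    if (is.null(model)) {
      return(data.frame(algorithm = alg, pct = pct, n_features = length(feats),
                        cv_f1 = NA_real_, accuracy = NA_real_,
                        precision = NA_real_, recall = NA_real_, f1 = NA_real_))
    }
    m <- evaluate_model(model, test)
    data.frame(algorithm = alg, pct = pct, n_features = length(feats),
               cv_f1 = model$cv_f1, accuracy = m$accuracy,
               precision = m$precision, recall = m$recall, f1 = m$f1)
  })
  lb <- do.call(rbind, rows)
  lb <- lb[order(-lb$f1, -lb$accuracy, lb$pct, na.last = TRUE), , drop = FALSE]
  rownames(lb) <- NULL
  structure(lb,
            class = c("sweep_leaderboard", "data.frame"),
            ranked = ranked, dropped = dropout$dropped,
            n_algorithms = length(algorithms), n_fractions = length(fractions),
            total_models = length(algorithms) * length(fractions),
            best = list(algorithm = lb$algorithm[1L], pct = lb$pct[1L],
                        features = subsets[[match(lb$pct[1L], fractions)]]))
}

#' Condition-group transfer matrix
#'
#' Trains the chosen algorithm/feature combination separately on each
#' condition group's training rows (SN = all, N = no-stress, S = stress) and
#' evaluates each model on each group's test rows — a 3 x 3 grid probing how
#' well a model trained under one environmental condition transfers to
#' another. By default all three models reuse the feature subset derived
#' from the Group SN ranking; `rerank = TRUE` re-derives the subset from
#' each training group instead.
#'
#' @param train,test Feature tables from [split_by_participant()].
#' @param algorithm Algorithm id (the sweep winner).
#' @param pct Feature percentage (the sweep winner's).
#' @param config A [pipeline_config()].
#' @param seed Integer seed.
#' @param features Optional explicit SN-derived feature subset; computed
#'   from `train` when NULL.
#' @param rerank Re-derive the subset per training group.
#' @param n_iters Randomized-search iterations.
#' @return A `transfer_matrix`: 3 x 3 list of `eval_metrics`, the three
#'   fitted models, and the feature subsets used.
#' @export
transfer_matrix <- function(train, test, algorithm, pct,
                            config = pipeline_config(), seed = 1L,
                            features = NULL, rerank = FALSE,
                            n_iters = config$n_search_iters) {
  groups <- c("SN", "N", "S")
  if (is.null(features)) {
    dropout <- drop_correlated(train, config$corr_dropout_threshold)
    features <- select_top_fraction(anova_rank(train, "SN", dropout$kept), pct)
  }
  seeds <- derive_seeds(seed, length(groups))
  models <- list()
  feats_by_group <- list()
  cells <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    tr <- filter_group(train, g)
    if (!nrow(tr)) stop_invalid("transfer", paste("empty training group", g))
    feats <- if (rerank) {
      select_top_fraction(anova_rank(tr, "SN"), pct)
    } else {
      features
    }
    feats_by_group[[g]] <- feats
    models[[g]] <- tune_and_train(algorithm, tr, feats, config,
                                  seed = seeds[gi], n_iters = n_iters)
    cells[[g]] <- list()
    for (h in groups) {
      te <- filter_group(test, h)
      if (!nrow(te)) stop_invalid("transfer", paste("empty testing group", h))
      cells[[g]][[h]] <- evaluate_model(models[[g]], te)
    }
  }
  structure(list(metrics = cells, models = models, algorithm = algorithm,
                 pct = pct, features = feats_by_group, groups = groups),
            class = "transfer_matrix")
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat(sprintf("<transfer_matrix> %s at %d%% features (train rows x test cols)\n",
              x$algorithm, x$pct))
  for (g in x$groups) {
    line <- vapply(x$groups, function(h) {
      m <- x$metrics[[g]][[h]]
      sprintf("%5.2f%% / F1 %.3f", 100 * m$accuracy, m$f1)
    }, "")
    cat(sprintf("  %-3s: %s\n", g, paste(line, collapse = "   ")))
  }
  invisible(x)
}

#' @export
as.data.frame.transfer_matrix <- function(x, ...) {
  rows <- list()
  for (g in x$groups) {
    for (h in x$groups) {
      m <- x$metrics[[g]][[h]]
      rows[[length(rows) + 1L]] <- data.frame(
        train_group = g, test_group = h, accuracy = m$accuracy,
        precision = m$precision, recall = m$recall, f1 = m$f1)
    }
  }
  do.call(rbind, rows)
}
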