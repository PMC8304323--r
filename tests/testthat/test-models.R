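test_that("participant split is disjoint, stratified and seeded", {
  tbl <- toy_feature_table(n_participants = 31)
  sp <- split_by_participant(tbl, n_test = 5, seed = 4)
  expect_equal(length(unique(sp$train$participant)), 26L)
  expect_equal(length(unique(sp$test$participant)), 5L)
  expect_length(intersect(unique(sp$train$participant),
                          unique(sp$test$participant)), 0L)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(tbl))
  # stratification: test groups within 1 of proportional
  expect_lte(abs(sum(unique(sp$test[, c("participant", "group")])$group == "stress") - 2.5), 1.5)
  sp2 <- split_by_participant(tbl, n_test = 5, seed = 4)
  expect_identical(sp$test$participant, sp2$test$participant)
  expect_error(split_by_participant(toy_feature_table(n_participants = 5),
                                    n_test = 5), "at least")
})

test_that("ANOVA F matches the hand-worked example and the t-squared identity", {
  # two classes [1,2,3] vs [2,3,4]: SSB = 1.5, MSW = 1 -> F = 1.5
  X <- cbind(f = c(1, 2, 3, 2, 3, 4))
  y <- rep(c("encoding", "retrieval"), each = 3)
  expect_equal(unname(anova_f(X, y)), 1.5, tolerance = 1e-12)

  # F equals the pooled two-sample t statistic squared on random features
  set.seed(20)
  X <- matrix(rnorm(40 * 8), 40, 8)
  y <- rep(c("encoding", "retrieval"), each = 20)
  f <- anova_f(X, y)
  for (j in 1:8) {
    t_stat <- t.test(X[y == "encoding", j], X[y == "retrieval", j],
                     var.equal = TRUE)$statistic
    expect_equal(unname(f[j]), unname(t_stat^2), tolerance = 1e-10)
  }
  # cross-check against R's own one-way ANOVA
  a <- anova(aov(X[, 1] ~ factor(y)))
  expect_equal(unname(f[1]), a$`F value`[1], tolerance = 1e-10)
  # a feature identical across classes has F = 0
  X0 <- cbind(rep(c(1, 2), 20))
  expect_equal(unname(anova_f(X0, y)), 0)
})

test_that("ranking orders by decreasing F with index tie-breaks", {
  tbl <- toy_feature_table(n_signal = 3, shift = 3)
  rk <- anova_rank(tbl, "SN")
  expect_s3_class(rk, "ranked_features")
  expect_length(rk$features, 30L)
  expect_true(all(diff(rk$f_values) <= 1e-12))
  expect_setequal(head(rk$features, 3), c("f001", "f002", "f003"))
  one_class <- tbl[tbl$label == "encoding", ]
  expect_error(anova_rank(one_class), "both classes")
})

test_that("top-fraction selection uses round(n * pct / 100) with a floor of 1", {
  fake <- structure(list(features = sprintf("f%03d", 1:651),
                         f_values = seq(651, 1)), class = "ranked_features")
  expect_length(select_top_fraction(fake, 2), 13L)    # round(13.02)
  expect_length(select_top_fraction(fake, 1), 7L)     # round(6.51)
  expect_length(select_top_fraction(fake, 100), 651L)
  small <- structure(list(features = c("a", "b"), f_values = c(2, 1)),
                     class = "ranked_features")
  expect_identical(select_top_fraction(small, 1), "a")  # floor of 1
  expect_error(select_top_fraction(fake, 0), "1..100")
  expect_error(select_top_fraction(fake, 101), "1..100")
})

test_that("correlated-feature dropout removes later duplicates, else passes through", {
  tbl <- toy_feature_table(n_features = 10, n_signal = 0, seed = 3)
  res <- drop_correlated(tbl)
  expect_length(res$dropped, 0L)  # independent noise: pass-through
  expect_identical(res$kept, feature_columns(tbl))
  tbl$f010 <- tbl$f001 * 2 + 1e-8 * rnorm(nrow(tbl))
  res <- drop_correlated(tbl)
  expect_identical(res$dropped, "f010")
})

test_that("every model family fits a separable toy set with perfect CV F1", {
  tbl <- toy_feature_table(n_participants = 10, n_features = 2, n_signal = 2,
                           shift = 6, seed = 5)
  for (alg in algorithm_ids()) {
    m <- tune_and_train(alg, tbl, c("f001", "f002"), seed = 1, n_iters = 3)
    expect_s3_class(m, "nirs_model")
    expect_gte(m$cv_f1, 0.95)
  }
  # the separable case is exactly solvable by a random forest
  rf <- tune_and_train("RF", tbl, c("f001", "f002"), seed = 1, n_iters = 3)
  expect_equal(rf$cv_f1, 1.0)
})

test_that("tuning is deterministic under a fixed seed", {
  tbl <- toy_feature_table(seed = 6)
  feats <- feature_columns(tbl)[1:8]
  a <- tune_and_train("RF", tbl, feats, seed = 7, n_iters = 5)
  b <- tune_and_train("RF", tbl, feats, seed = 7, n_iters = 5)
  expect_identical(a$params, b$params)
  expect_identical(a$cv_f1, b$cv_f1)
  expect_identical(predict(a, tbl), predict(b, tbl))
})

test_that("label-shuffled data scores within the permutation band of chance", {
  tbl <- toy_feature_table(n_participants = 8, n_features = 10, n_signal = 0,
                           seed = 8)
  shuffled <- tbl
  set.seed(30)
  shuffled$label <- sample(shuffled$label)
  m <- tune_and_train("DT", shuffled, feature_columns(tbl), seed = 9,
                      n_iters = 5)
  # null distribution of best-of-5 CV F1 under prevalence-matched random
  # prediction, simulated model-free
  set.seed(31)
  n <- nrow(shuffled)
  p_pos <- mean(shuffled$label == "retrieval")
  null_best <- replicate(400, {
    max(replicate(5, {
      truth <- sample(shuffled$label)
      pred <- ifelse(runif(n) < p_pos, "retrieval", "encoding")
      tp <- sum(pred == "retrieval" & truth == "retrieval")
      fp <- sum(pred == "retrieval" & truth != "retrieval")
      fn <- sum(pred != "retrieval" & truth == "retrieval")
      P <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
      R <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
      f1_score(P, R)
    }))
  })
  expect_lte(m$cv_f1, quantile(null_best, 0.975) + 0.05)
})

test_that("evaluation metrics satisfy the published worked examples and identities", {
  # harmonic-mean identity on printed precision/recall pairs
  expect_equal(round(f1_score(0.760, 0.950), 3), 0.844)
  expect_equal(round(f1_score(0.722, 0.975), 3), 0.830)
  expect_equal(f1_score(0, 0), 0)

  tbl <- toy_feature_table(n_participants = 6, n_features = 2, n_signal = 2,
                           shift = 6, seed = 10)
  m <- tune_and_train("SVM", tbl, c("f001", "f002"), seed = 2, n_iters = 3)
  ev <- evaluate_model(m, tbl)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$f1, 1)
  # harmonic-mean identity holds on every evaluation
  expect_equal(ev$f1, f1_score(ev$precision, ev$recall))
  expect_error(evaluate_model(m, tbl[, 1:5]), "match")
})

test_that("majority-class accuracy equals the larger class fraction", {
  tbl <- toy_feature_table(n_participants = 4, trials_per_class = 3)
  expect_equal(majority_class_accuracy(tbl), 0.5)
  tbl2 <- tbl[c(1:6, 4:6), ]  # unbalanced
  expect_equal(majority_class_accuracy(tbl2),
               max(table(tbl2$label)) / nrow(tbl2))
})

test_that("the sweep covers algorithms x fractions, sorted by test F1", {
  tbl <- toy_feature_table(n_participants = 8, n_features = 12, n_signal = 4,
                           shift = 3, seed = 12)
  sp <- split_by_participant(tbl, n_test = 2, seed = 1)
  lb <- sweep_models(sp$train, sp$test, algorithms = c("RF", "DT", "NB"),
                     fractions = c(25, 50), n_iters = 2, seed = 5)
  expect_equal(nrow(lb), 6L)
  expect_equal(attr(lb, "total_models"), 6L)
  f1s <- lb$f1[!is.na(lb$f1)]
  expect_true(all(diff(f1s) <= 1e-12))
  expect_true(attr(lb, "best")$algorithm %in% c("RF", "DT", "NB"))
})

test_that("transfer matrix trains per group and fills all 9 cells", {
  tbl <- toy_feature_table(n_participants = 10, n_features = 8, n_signal = 4,
                           shift = 4, seed = 13)
  sp <- split_by_participant(tbl, n_test = 3, seed = 2)
  tm <- transfer_matrix(sp$train, sp$test, "DT", pct = 50, seed = 3,
                        n_iters = 2)
  expect_s3_class(tm, "transfer_matrix")
  df <- as.data.frame(tm)
  expect_equal(nrow(df), 9L)
  expect_true(all(df$accuracy >= 0 & df$accuracy <= 1))
  expect_true(all(abs(df$f1 - f1_score(df$precision, df$recall)) < 1e-12))
  # signal is condition-invariant in the toy table: cells should agree broadly
  expect_lt(max(df$f1) - min(df$f1), 0.35)
})

test_that("no participant leaks across the train/test boundary in the workflow", {
  tbl <- toy_feature_table(n_participants = 10)
  sp <- split_by_participant(tbl, n_test = 3, seed = 7)
  for (g in c("SN", "N", "S")) {
    tr <- filter_group(sp$train, g)
    te <- filter_group(sp$test, g)
    expect_length(intersect(unique(tr$participant), unique(te$participant)), 0L)
  }
})

test_that("unknown algorithm ids are rejected", {
  tbl <- toy_feature_table(n_participants = 4)
  expect_error(tune_and_train("MLP", tbl, "f001"), "unknown id")
  expect_error(search_space("XX"), "unknown id")
})
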