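test_that("hyperparameter grids match the printed domains", {
  g <- grid_spec()
  expect_equal(length(unique(g$tree$max_depth)), 61)
  expect_equal(range(g$tree$max_depth), c(5, 305))
  expect_equal(nrow(g$tree), 2 * 2 * 61)
  # invalid solver/penalty combinations are pruned
  expect_equal(nrow(g$logistic), 9)
  expect_false(any(g$logistic$solver == "lbfgs" & g$logistic$penalty == "l1"))
  expect_false(any(g$logistic$solver == "liblinear" & g$logistic$penalty == "none"))
  expect_false(any(g$logistic$solver == "sag" & g$logistic$penalty == "l1"))
  expect_equal(nrow(g$mlp), 3 * 4)
  expect_equal(nrow(g$linear_svm), 2 * 7)
  expect_equal(nrow(g$knn), 6 * 30 * 2)
  expect_equal(nrow(grid_spec(full_knn_leaf = TRUE)$knn), 50 * 30 * 2)
})

test_that("per-participant z-scoring centres and scales within participants", {
  tab <- random_table(n_participants = 3, windows_per = 15, n_features = 4,
                      seed = 1)
  tab$f04 <- 7                       # constant column
  z <- normalize_features(tab, "per_participant_z")
  for (p in unique(z$participant_id)) {
    blk <- as.matrix(z[z$participant_id == p, feature_columns(z)])
    expect_lt(max(abs(colMeans(blk))), 1e-9)
    sds <- apply(blk, 2, sd)
    expect_true(all(abs(sds - 1) < 1e-9 | sds == 0))
  }
  expect_true(all(z$f04 == 0))
})

test_that("min-max normalization fits on training rows and clips the rest", {
  tab <- random_table(n_participants = 1, windows_per = 4, n_features = 1,
                      seed = 2)
  tab$f01 <- c(0, 10, 5, 20)
  out <- normalize_features(tab, "train_fit_minmax", train_idx = 1:2)
  expect_equal(out$f01, c(0, 1, 0.5, 1))   # 20 clipped to 1
})

test_that("weighted F1 matches brute-force confusion-matrix computation", {
  expect_equal(weighted_f1(c("a", "b", "a"), c("a", "b", "a")), 1)
  # binary truths 3 pos / 1 neg, all predicted pos
  got <- weighted_f1(rep("pos", 4), c("pos", "pos", "pos", "neg"))
  expect_equal(got, 0.75 * (6 / 7) + 0.25 * 0, tolerance = 1e-12)
  # independent implementation: full confusion matrix, explicit P/R
  oracle_f1 <- function(pred, truth) {
    cls <- unique(truth)
    cm <- table(factor(truth, cls), factor(pred, union(cls, unique(pred))))
    f1 <- sapply(cls, function(cl) {
      tp <- cm[cl, cl]
      prec <- if (sum(cm[, cl]) == 0) 0 else tp / sum(cm[, cl])
      rec <- if (sum(cm[cl, ]) == 0) 0 else tp / sum(cm[cl, ])
      if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    })
    w <- rowSums(cm)[cls] / length(truth)
    sum(f1 * w)
  }
  set.seed(3)
  for (i in 1:200) {
    k <- sample(2:5, 1)
    truth <- sample(letters[1:k], 40, replace = TRUE)
    pred <- sample(letters[1:k], 40, replace = TRUE)
    expect_equal(weighted_f1(pred, truth), oracle_f1(pred, truth),
                 tolerance = 1e-12)
  }
  expect_error(weighted_f1(character(0), character(0)), "non-empty")
})

test_that("every classifier family separates linearly separable classes", {
  set.seed(4)
  n <- 60
  y <- factor(rep(c("low", "high"), each = n / 2), levels = c("low", "high"))
  X <- cbind(x1 = rnorm(n) + ifelse(y == "high", 6, 0),
             x2 = rnorm(n))
  X <- cogload:::minmax_block(X, seq_len(n))
  configs <- list(
    tree = list(criterion = "gini", splitter = "best", max_depth = 5),
    logistic = list(solver = "lbfgs", penalty = "l2"),
    mlp = list(activation = "relu", hidden_size = 10),
    knn = list(leaf_size = 1, n_neighbors = 5, p = 2),
    linear_svm = list(penalty = "l2", C = 1))
  for (fam in names(configs)) {
    pred <- cogload:::fit_predict(fam, configs[[fam]], X, y, X, seed = 1)
    expect_gte(weighted_f1(pred, y), 0.95)
  }
  # all MLP activations and both SVM penalties learn the same easy boundary
  for (act in c("logistic", "tanh", "relu")) {
    pred <- cogload:::fit_predict("mlp", list(activation = act, hidden_size = 10),
                                  X, y, X, seed = 1)
    expect_gte(weighted_f1(pred, y), 0.9)
  }
  pred <- cogload:::fit_predict("linear_svm", list(penalty = "l1", C = 1),
                                X, y, X, seed = 1)
  expect_gte(weighted_f1(pred, y), 0.9)
})

test_that("hand-rolled KNN agrees with the reference Euclidean implementation", {
  skip_if_not_installed("class")
  set.seed(5)
  Xtr <- matrix(rnorm(40 * 3), 40, 3)
  ytr <- factor(sample(c("a", "b"), 40, replace = TRUE))
  Xte <- matrix(rnorm(25 * 3), 25, 3)
  for (k in c(1, 3, 7)) {
    mine <- cogload:::knn_predict(Xtr, ytr, Xte, k = k, p = 2)
    ref <- as.character(class::knn(Xtr, Xte, ytr, k = k))
    # ties are broken differently; compare only where a majority exists
    maj <- sapply(seq_len(nrow(Xte)), function(i) {
      d <- sqrt(colSums((t(Xtr) - Xte[i, ])^2))
      votes <- table(ytr[order(d)[1:k]])
      max(votes) > k / 2
    })
    expect_equal(mine[maj], ref[maj])
  }
})

test_that("LOO-CV builds one fold per participant and is deterministic", {
  tab <- random_table(n_participants = 5, windows_per = 16, n_features = 6,
                      signal = 2, seed = 6)
  p2 <- classification_problem(2)
  fs <- structure(sprintf("f%02d", 1:6), set_name = "custom")
  cv <- loo_cv(tab, p2, fs, reduced_grid_spec("logistic"), seed = 1)
  expect_s3_class(cv, "cogload_cv")
  expect_equal(cv$n_folds, 5)
  expect_equal(sort(unique(cv$folds$fold_name)), sprintf("P%02d", 1:5))
  expect_true(all(cv$summary$min_f1 <= cv$summary$mean_f1 + 1e-12))
  expect_true(all(cv$summary$mean_f1 <= cv$summary$max_f1 + 1e-12))
  cv2 <- loo_cv(tab, p2, fs, reduced_grid_spec("logistic"), seed = 1)
  expect_equal(cv$summary, cv2$summary)
  # a strong linear signal is learnable across participants
  expect_gt(max(cv$summary$mean_f1), 0.85)
  expect_error(loo_cv(tab[tab$participant_id == "P01", ], p2, fs,
                      reduced_grid_spec("logistic")), "2 participants")
})

test_that("imputation and scaling are fitted without test-fold leakage", {
  # a feature equal to the label on one participant's rows only (noise on
  # all others) must not help when that participant is held out
  set.seed(7)
  tab <- random_table(n_participants = 5, windows_per = 16, n_features = 3,
                      signal = 0, seed = 7)
  cheat <- rnorm(nrow(tab))
  hold <- tab$participant_id == "P03"
  cheat[hold] <- tab$workload_response[hold]
  tab$f01 <- cheat
  p2 <- classification_problem(2)
  fs <- structure(sprintf("f%02d", 1:3), set_name = "custom")
  cv <- loo_cv(tab, p2, fs,
               list(logistic = data.frame(solver = "lbfgs", penalty = "l2")),
               seed = 1, z_normalize = FALSE)
  f1_hold <- cv$folds$weighted_f1[cv$folds$fold_name == "P03"]
  expect_lt(f1_hold, 0.8)
})

test_that("personalised CV reduces to leave-one-window-out at k = n", {
  tab <- random_table(n_participants = 2, windows_per = 20, n_features = 4,
                      signal = 3, seed = 8)
  p2 <- classification_problem(2)
  fs <- structure(sprintf("f%02d", 1:4), set_name = "custom")
  # 20 windows -> 8 binary windows per participant (responses 1,2,4,5 of 1..5)
  n_binary <- sum(!is.na(map_labels(tab$workload_response, p2)) &
                    tab$participant_id == "P01")
  cv <- personal_cv(tab, p2, fs,
                    list(knn = data.frame(leaf_size = 1, n_neighbors = 3, p = 2)),
                    k = n_binary, seed = 1)
  expect_equal(unique(table(cv$folds$fold_name)), as.integer(1))
  cv2 <- personal_cv(tab, p2, fs,
                     list(knn = data.frame(leaf_size = 1, n_neighbors = 3, p = 2)),
                     k = n_binary, seed = 1)
  expect_equal(cv$summary, cv2$summary)
})

test_that("activity features do not change F1 when labels ignore activity", {
  diffs <- sapply(1:20, function(s) {
    tab <- random_table(n_participants = 2, windows_per = 30, n_features = 4,
                        signal = 2, seed = 100 + s)
    p2 <- classification_problem(2)
    fs <- structure(sprintf("f%02d", 1:4), set_name = "custom")
    g <- list(logistic = data.frame(solver = "lbfgs", penalty = "l2"))
    on <- personal_cv(tab, p2, fs, g, k = 4, seed = s, with_activity = TRUE)
    off <- personal_cv(tab, p2, fs, g, k = 4, seed = s, with_activity = FALSE)
    on$summary$mean_f1 - off$summary$mean_f1
  })
  expect_lt(abs(mean(diffs)), 0.05)
})

test_that("the report artifact summarises min/mean/max and round-trips", {
  tab <- random_table(n_participants = 4, windows_per = 16, n_features = 5,
                      signal = 1, seed = 9)
  p2 <- classification_problem(2)
  fs <- structure(sprintf("f%02d", 1:5), set_name = "custom")
  g <- reduced_grid_spec(c("tree", "logistic"))
  r1 <- loo_cv(tab, p2, fs, g, seed = 1)
  r2 <- personal_cv(tab, p2, fs, g, k = 3, seed = 1)
  out <- withr::local_tempfile()
  rows <- cv_report(list(r1, r2), out)
  expect_equal(nrow(rows), 2 * 2)        # 2 reports x 2 families
  expect_true(all(rows$min_f1 <= rows$mean_f1 & rows$mean_f1 <= rows$max_f1))
  back <- jsonlite::read_json(paste0(out, ".json"), simplifyVector = TRUE)
  expect_equal(back$mean_f1, rows$mean_f1, tolerance = 1e-12)
  expect_true(file.exists(paste0(out, ".csv")))
})
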