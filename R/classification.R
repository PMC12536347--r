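#' Hyperparameter grids for the five classifier families
#'
#' The printed grids: decision tree criterion (gini, entropy) x splitter
#' (best, random) x max_depth 5..305 in steps of 5 (61 depths); logistic
#' regression solver (lbfgs, liblinear, sag, saga) x penalty (l1, l2, none)
#' with invalid solver/penalty combinations pruned; MLP activation
#' (logistic, tanh, relu) x hidden size (3, 10, 30, 50); KNN leaf size
#' (sampled at 1, 10, 20, 30, 40, 50 by default since leaf size never
#' changes predictions; `full_knn_leaf = TRUE` restores 1..50) x neighbours
#' 1..30 x Minkowski p (1, 2); linear SVM penalty (l1, l2) x C (0.001 ..
#' 1000).
#'
#' @param families Subset of `c("tree", "logistic", "mlp", "knn",
#'   "linear_svm")`.
#' @param full_knn_leaf Use the full 1..50 leaf-size range.
#' @return Named list of data frames, one per family.
#' @export
grid_spec <- function(families = c("tree", "logistic", "mlp", "knn", "linear_svm"),
                      full_knn_leaf = FALSE) {
  valid_logistic <- rbind(
    expand.grid(solver = "lbfgs", penalty = c("l2", "none")),
    expand.grid(solver = "liblinear", penalty = c("l1", "l2")),
    expand.grid(solver = "sag", penalty = c("l2", "none")),
    expand.grid(solver = "saga", penalty = c("l1", "l2", "none")))
  g <- list(
    tree = expand.grid(criterion = c("gini", "entropy"),
                       splitter = c("best", "random"),
                       max_depth = seq(5, 305, by = 5),
                       stringsAsFactors = FALSE),
    logistic = data.frame(lapply(valid_logistic, as.character),
                          stringsAsFactors = FALSE),
    mlp = expand.grid(activation = c("logistic", "tanh", "relu"),
                      hidden_size = c(3, 10, 30, 50),
                      stringsAsFactors = FALSE),
    knn = expand.grid(leaf_size = if (full_knn_leaf) 1:50
                                  else c(1, 10, 20, 30, 40, 50),
                      n_neighbors = 1:30, p = c(1, 2)),
    linear_svm = expand.grid(penalty = c("l1", "l2"),
                             C = c(0.001, 0.01, 0.1, 1, 10, 100, 1000),
                             stringsAsFactors = FALSE))
  g <- lapply(g, function(d) { d[] <- lapply(d, function(c)
    if (is.factor(c)) as.character(c) else c); d })
  g[families]
}

#' Small screening grid
#'
#' A few representative configurations per family, used for quick
#' simulation studies where the full grids are unnecessary.
#'
#' @inheritParams grid_spec
#' @export
reduced_grid_spec <- function(families = c("tree", "logistic", "mlp", "knn",
                                           "linear_svm")) {
  g <- list(
    tree = data.frame(criterion = c("gini", "gini"), splitter = "best",
                      max_depth = c(5, 15), stringsAsFactors = FALSE),
    logistic = data.frame(solver = c("lbfgs", "saga"), penalty = c("l2", "l1"),
                          stringsAsFactors = FALSE),
    mlp = data.frame(activation = "relu", hidden_size = 30,
                     stringsAsFactors = FALSE),
    knn = data.frame(leaf_size = 1, n_neighbors = 9, p = 1),
    linear_svm = data.frame(penalty = "l2", C = c(0.01, 1),
                            stringsAsFactors = FALSE))
  g[families]
}

## ---- normalization -------------------------------------------------------

#' Normalize feature columns
#'
#' Two stages mirror the evaluation pipeline. `per_participant_z`: each
#' participant's feature column is centred and scaled over that
#' participant's windows (constant columns become 0). `train_fit_minmax`:
#' min/max are fitted on the training rows only, applied to all rows, and
#' test values are clipped to \[0, 1\]. Missing values are median-imputed
#' within the fitting scope before scaling.
#'
#' @param table A feature table.
#' @param stage `"per_participant_z"` or `"train_fit_minmax"`.
#' @param feature_cols Feature columns (default all).
#' @param train_idx Row indices defining the fitting scope for the min-max
#'   stage (default: all rows).
#' @return The table with normalized feature columns.
#' @export
normalize_features <- function(table,
                               stage = c("per_participant_z", "train_fit_minmax"),
                               feature_cols = NULL, train_idx = NULL) {
  stage <- match.arg(stage)
  if (is.null(feature_cols)) feature_cols <- feature_columns(table)
  X <- as.matrix(table[feature_cols])
  if (stage == "per_participant_z") {
    for (p in unique(table$participant_id)) {
      i <- table$participant_id == p
      X[i, ] <- zscore_block(X[i, , drop = FALSE])
    }
  } else {
    if (is.null(train_idx)) train_idx <- seq_len(nrow(X))
    X <- impute_median(X, train_idx)
    X <- minmax_block(X, train_idx)
  }
  table[feature_cols] <- as.data.frame(X, check.names = FALSE)
  table
}

zscore_block <- function(X) {
  X <- impute_median(X, seq_len(nrow(X)))
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  X <- sweep(X, 2, mu)
  nz <- sd > 0 & is.finite(sd)
  X[, nz] <- sweep(X[, nz, drop = FALSE], 2, sd[nz], "/")
  X[, !nz] <- 0
  X
}

impute_median <- function(X, train_idx) {
  for (j in seq_len(ncol(X))) {
    bad <- !is.finite(X[, j])
    if (any(bad)) {
      med <- stats::median(X[train_idx, j], na.rm = TRUE)
      if (!is.finite(med)) med <- 0
      X[bad, j] <- med
    }
  }
  X
}

minmax_block <- function(X, train_idx) {
  lo <- apply(X[train_idx, , drop = FALSE], 2, min)
  hi <- apply(X[train_idx, , drop = FALSE], 2, max)
  rng <- hi - lo
  rng[rng == 0 | !is.finite(rng)] <- 1
  X <- sweep(sweep(X, 2, lo), 2, rng, "/")
  X[X < 0] <- 0; X[X > 1] <- 1
  X
}

## ---- metrics -------------------------------------------------------------

#' Weighted F1 score
#'
#' Per-class F1 (harmonic mean of precision and recall; 0 where undefined)
#' averaged with weights proportional to each class's support in the truth.
#'
#' @param predictions,truths Equal-length label vectors.
#' @return Scalar in \[0, 1\].
#' @export
weighted_f1 <- function(predictions, truths) {
  if (!length(truths) || length(predictions) != length(truths))
    stopf("predictions and truths must be non-empty and of equal length")
  predictions <- as.character(predictions); truths <- as.character(truths)
  classes <- unique(truths)
  f1s <- vapply(classes, function(cl) {
    tp <- sum(predictions == cl & truths == cl)
    fp <- sum(predictions == cl & truths != cl)
    fn <- sum(predictions != cl & truths == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  support <- vapply(classes, function(cl) sum(truths == cl), numeric(1))
  sum(f1s * support) / sum(support)
}

## ---- model backends ------------------------------------------------------

fit_predict <- function(family, params, Xtr, ytr, Xte, seed) {
  lv <- levels(ytr)
  if (length(unique(ytr)) < 2L)
    return(factor(rep(as.character(ytr[1]), nrow(Xte)), levels = lv))
  pred <- tryCatch(switch(family,
    tree = {
      df <- data.frame(Xtr, check.names = TRUE)
      te <- data.frame(Xte, check.names = TRUE)
      names(te) <- names(df)
      df$.y <- ytr
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
        parms = list(split = if (params$criterion == "entropy") "information" else "gini"),
        control = rpart::rpart.control(maxdepth = min(params$max_depth, 30),
                                       minsplit = 2, cp = 0, xval = 0))
      as.character(stats::predict(fit, te, type = "class"))
    },
    logistic = {
      fam <- if (length(lv) == 2) "binomial" else "multinomial"
      alpha <- if (params$penalty == "l1") 1 else 0
      lambda <- if (params$penalty == "none") 1e-8 else 1 / nrow(Xtr)
      # glmnet warns about small class counts on per-participant folds;
      # true degeneracy is flagged separately via the fold report
      fit <- suppressWarnings(
        glmnet::glmnet(Xtr, ytr, family = fam, alpha = alpha,
                       lambda = lambda, standardize = FALSE))
      p <- stats::predict(fit, Xte, type = "class")
      as.character(p[, 1])
    },
    mlp = mlp_fit_predict(Xtr, ytr, Xte, activation = params$activation,
                          hidden = params$hidden_size, seed = seed),
    knn = knn_predict(Xtr, ytr, Xte, k = params$n_neighbors, p = params$p),
    linear_svm = linsvm_fit_predict(Xtr, ytr, Xte, penalty = params$penalty,
                                    C = params$C)),
    error = function(e) {
      # degenerate fit: fall back to the majority class
      rep(names(which.max(table(ytr))), nrow(Xte))
    })
  factor(pred, levels = lv)
}

# Single-hidden-layer perceptron with softmax output, trained full-batch
# with Adam on the cross-entropy loss; deterministic under `seed`.
mlp_fit_predict <- function(Xtr, ytr, Xte, activation = "relu", hidden = 30,
                            seed = 1, epochs = 300, lr = 0.01) {
  act <- switch(activation,
    logistic = list(f = function(z) 1 / (1 + exp(-z)),
                    df = function(z, a) a * (1 - a)),
    tanh = list(f = tanh, df = function(z, a) 1 - a^2),
    relu = list(f = function(z) pmax(z, 0), df = function(z, a) (z > 0) * 1),
    stopf("unknown activation '%s'", activation))
  lv <- levels(ytr)
  K <- length(lv); d <- ncol(Xtr); n <- nrow(Xtr)
  Y <- outer(as.integer(ytr), seq_len(K), `==`) * 1
  with_local_seed(seed, {
    W1 <- matrix(stats::rnorm(d * hidden, sd = 1 / sqrt(d)), d, hidden)
    b1 <- numeric(hidden)
    W2 <- matrix(stats::rnorm(hidden * K, sd = 1 / sqrt(hidden)), hidden, K)
    b2 <- numeric(K)
  })
  ms <- lapply(list(W1, b1, W2, b2), function(p) p * 0)
  vs <- ms
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  for (it in seq_len(epochs)) {
    Z1 <- sweep(Xtr %*% W1, 2, b1, `+`)
    A1 <- act$f(Z1)
    Z2 <- sweep(A1 %*% W2, 2, b2, `+`)
    Z2 <- Z2 - apply(Z2, 1, max)
    P <- exp(Z2); P <- P / rowSums(P)
    dZ2 <- (P - Y) / n
    gW2 <- t(A1) %*% dZ2; gb2 <- colSums(dZ2)
    dA1 <- dZ2 %*% t(W2)
    dZ1 <- dA1 * act$df(Z1, A1)
    gW1 <- t(Xtr) %*% dZ1; gb1 <- colSums(dZ1)
    grads <- list(gW1, gb1, gW2, gb2)
    pars <- list(W1, b1, W2, b2)
    for (i in 1:4) {
      ms[[i]] <- beta1 * ms[[i]] + (1 - beta1) * grads[[i]]
      vs[[i]] <- beta2 * vs[[i]] + (1 - beta2) * grads[[i]]^2
      mhat <- ms[[i]] / (1 - beta1^it)
      vhat <- vs[[i]] / (1 - beta2^it)
      pars[[i]] <- pars[[i]] - lr * mhat / (sqrt(vhat) + eps)
    }
    W1 <- pars[[1]]; b1 <- pars[[2]]; W2 <- pars[[3]]; b2 <- pars[[4]]
  }
  A1 <- act$f(sweep(Xte %*% W1, 2, b1, `+`))
  S <- sweep(A1 %*% W2, 2, b2, `+`)
  lv[max.col(S, ties.method = "first")]
}

# Exact k-nearest-neighbour prediction under the Minkowski metric
# (p = 1 Manhattan, p = 2 Euclidean); majority vote, ties broken by the
# smallest summed distance then by class order.
knn_predict <- function(Xtr, ytr, Xte, k = 5, p = 2) {
  lv <- levels(ytr)
  k <- min(k, nrow(Xtr))
  out <- character(nrow(Xte))
  for (i in seq_len(nrow(Xte))) {
    d <- if (p == 1) colSums(abs(t(Xtr) - Xte[i, ]))
         else sqrt(colSums((t(Xtr) - Xte[i, ])^2))
    nb <- order(d)[seq_len(k)]
    votes <- table(factor(as.character(ytr[nb]), levels = lv))
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      dist_by <- vapply(top, function(cl)
        sum(d[nb][as.character(ytr[nb]) == cl]), numeric(1))
      top <- top[order(dist_by, top)][1]
    }
    out[i] <- top
  }
  out
}

# One-vs-rest linear SVM with squared-hinge loss; l2 penalty by gradient
# descent, l1 by proximal (soft-threshold) steps.
linsvm_fit_predict <- function(Xtr, ytr, Xte, penalty = "l2", C = 1,
                               iters = 300) {
  lv <- levels(ytr)
  n <- nrow(Xtr); d <- ncol(Xtr)
  # Lipschitz-style step size for the squared-hinge gradient
  lip <- 2 * C * max(colSums(Xtr^2)) * 2 + 1
  step <- 1 / lip
  scores <- matrix(0, nrow(Xte), length(lv))
  for (ki in seq_along(lv)) {
    y <- ifelse(as.character(ytr) == lv[ki], 1, -1)
    w <- numeric(d); b <- 0
    for (it in seq_len(iters)) {
      f <- as.numeric(Xtr %*% w) + b
      m <- pmax(0, 1 - y * f)
      gw <- -2 * C * as.numeric(t(Xtr) %*% (y * m))
      gb <- -2 * C * sum(y * m)
      if (penalty == "l2") {
        w <- w - step * (gw + w)
      } else {
        w <- w - step * gw
        w <- sign(w) * pmax(0, abs(w) - step)   # prox of ||w||_1
      }
      b <- b - step * gb
    }
    scores[, ki] <- as.numeric(Xte %*% w) + b
  }
  if (length(lv) == 2) {
    # binary: single decision value, matching the one-vs-rest of two classes
    lv[ifelse(scores[, 2] - scores[, 1] > 0, 2, 1)]
  } else lv[max.col(scores, ties.method = "first")]
}

## ---- cross-validation ----------------------------------------------------

prepare_problem <- function(table, problem, feature_set,
                            with_activity = FALSE, z_normalize = TRUE) {
  keep <- table$activity %in% classification_activities
  y <- map_labels(table$workload_response, problem)
  keep <- keep & !is.na(y)
  tab <- table[keep, , drop = FALSE]
  y <- droplevels(y[keep])
  y <- factor(as.character(y), levels = problem$levels)
  if (z_normalize)
    tab <- normalize_features(tab, "per_participant_z")
  cols <- intersect(as.character(feature_set), names(tab))
  if (!length(cols)) stopf("feature set has no columns present in the table")
  X <- as.matrix(tab[cols])
  if (with_activity) X <- cbind(X, one_hot_activity(tab$activity))
  list(X = X, y = y, pid = tab$participant_id, activity = tab$activity)
}

eval_folds <- function(X, y, folds, family, params, seed) {
  res <- lapply(seq_along(folds), function(fi) {
    te <- folds[[fi]]
    tr <- setdiff(seq_len(nrow(X)), te)
    Xi <- impute_median(X, tr)
    Xi <- minmax_block(Xi, tr)
    degenerate <- length(unique(y[tr])) < length(levels(y)) ||
      !all(levels(droplevels(y[te])) %in% unique(as.character(y[tr])))
    pred <- fit_predict(family, params, Xi[tr, , drop = FALSE], y[tr],
                        Xi[te, , drop = FALSE], seed = seed + fi)
    data.frame(fold = fi, n_test = length(te),
               accuracy = mean(as.character(pred) == as.character(y[te])),
               weighted_f1 = weighted_f1(pred, y[te]),
               degenerate = degenerate)
  })
  do.call(rbind, res)
}

config_label <- function(params)
  paste(sprintf("%s=%s", names(params), unlist(lapply(params, as.character))),
        collapse = ", ")

# Tie-break helper: smaller models first (sum of numeric hyperparameter
# magnitudes), then lexicographic configuration label.
config_size <- function(params) {
  v <- suppressWarnings(as.numeric(unlist(params)))
  sum(abs(v[is.finite(v)]))
}

run_cv <- function(X, y, folds, fold_names, grid, seed, mode, problem_name,
                   set_name) {
  all_res <- list()
  for (family in names(grid)) {
    cfgs <- grid[[family]]
    for (ci in seq_len(nrow(cfgs))) {
      params <- as.list(cfgs[ci, , drop = FALSE])
      r <- eval_folds(X, y, folds, family, params, seed)
      r$family <- family
      r$config <- config_label(params)
      r$config_size <- config_size(params)
      r$fold_name <- fold_names[r$fold]
      all_res[[length(all_res) + 1L]] <- r
    }
  }
  res <- do.call(rbind, all_res)
  agg <- do.call(rbind, lapply(split(res, list(res$family, res$config), drop = TRUE),
    function(g) data.frame(family = g$family[1], config = g$config[1],
                           config_size = g$config_size[1],
                           min_f1 = min(g$weighted_f1),
                           mean_f1 = mean(g$weighted_f1),
                           max_f1 = max(g$weighted_f1),
                           mean_accuracy = mean(g$accuracy),
                           n_degenerate = sum(g$degenerate))))
  rownames(agg) <- NULL
  best <- do.call(rbind, lapply(split(agg, agg$family), function(g) {
    g[order(-g$mean_f1, g$config_size, g$config), ][1, ]
  }))
  rownames(best) <- NULL
  structure(list(mode = mode, problem = problem_name, feature_set = set_name,
                 folds = res, summary = agg, best = best,
                 n_windows = nrow(X), n_folds = length(folds)),
            class = "cogload_cv")
}

#' Leave-one-participant-out evaluation (generalised models)
#'
#' For every hyperparameter configuration each participant is held out in
#' turn; the model is fitted on the remaining participants (median
#' imputation and min-max scaling fitted on the training rows only, test
#' values clipped) and scored on the held-out participant with accuracy and
#' weighted F1. Per configuration the held-out scores are aggregated as
#' min/mean/max; the best configuration per family maximises mean weighted
#' F1 (ties: smaller hyperparameter magnitudes, then lexicographic label).
#' Eyes-closed windows and, for the binary problem, response-3 windows are
#' excluded. Per-participant z-scoring is applied before splitting (set
#' `z_normalize = FALSE` to disable).
#'
#' @param table A feature table.
#' @param problem A [classification_problem()].
#' @param feature_set Character vector of feature names (see
#'   [reduced_feature_set()]).
#' @param grid Named list of per-family configuration data frames (see
#'   [grid_spec()], [reduced_grid_spec()]).
#' @param seed Integer seed (stochastic learners, fold-local seeds).
#' @param with_activity Append one-hot activity features.
#' @param z_normalize Apply the per-participant z stage first.
#' @return A `cogload_cv` object.
#' @export
loo_cv <- function(table, problem, feature_set = reduced_feature_set("All"),
                   grid = reduced_grid_spec("logistic"), seed = 1,
                   with_activity = FALSE, z_normalize = TRUE) {
  pp <- prepare_problem(table, problem, feature_set, with_activity, z_normalize)
  pids <- unique(pp$pid)
  if (length(pids) < 2L) stopf("leave-one-participant-out needs >= 2 participants")
  folds <- lapply(pids, function(p) which(pp$pid == p))
  run_cv(pp$X, pp$y, folds, pids, grid, seed, mode = "loo",
         problem_name = sprintf("%d-class", problem$n_classes),
         set_name = attr(feature_set, "set_name") %||% "custom")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stratified_folds <- function(y, k, seed) {
  idx <- with_local_seed(seed, {
    out <- vector("list", k)
    for (cl in levels(droplevels(y))) {
      ci <- sample(which(y == cl))
      for (j in seq_along(ci))
        out[[(j - 1) %% k + 1]] <- c(out[[(j - 1) %% k + 1]], ci[j])
    }
    out
  })
  idx[vapply(idx, length, integer(1)) > 0]
}

#' Personalised stratified k-fold evaluation
#'
#' Fits and scores each configuration within each participant's own windows
#' using stratified k-fold cross-validation, optionally appending one-hot
#' activity features. Participants with fewer than `k * n_classes` windows
#' are skipped with a notice. Per configuration the per-participant
#' (min/mean/max over folds) triples are averaged across participants.
#'
#' @inheritParams loo_cv
#' @param k Number of folds (default 5).
#' @return A `cogload_cv` object (summary rows are cross-participant
#'   averages).
#' @export
personal_cv <- function(table, problem, feature_set = reduced_feature_set("All"),
                        grid = reduced_grid_spec("logistic"), k = 5, seed = 1,
                        with_activity = FALSE, z_normalize = TRUE) {
  pp <- prepare_problem(table, problem, feature_set, with_activity, z_normalize)
  pids <- unique(pp$pid)
  per_part <- list(); all_folds <- list()
  for (p in pids) {
    rows <- which(pp$pid == p)
    yp <- droplevels(pp$y[rows])
    if (length(rows) < max(k, 2L * length(levels(yp))) ||
        length(levels(yp)) < 2L) {
      message(sprintf("personal_cv: skipping participant %s (%d windows)",
                      p, length(rows)))
      next
    }
    folds <- stratified_folds(pp$y[rows], k, child_seed(seed, match(p, pids)))
    cv <- run_cv(pp$X[rows, , drop = FALSE],
                 factor(as.character(pp$y[rows]), levels = levels(yp)),
                 folds, paste0(p, "_f", seq_along(folds)), grid,
                 child_seed(seed, 1000 + match(p, pids)), mode = "personal",
                 problem_name = sprintf("%d-class", problem$n_classes),
                 set_name = attr(feature_set, "set_name") %||% "custom")
    cv$summary$participant <- p
    cv$folds$participant <- p
    per_part[[p]] <- cv$summary
    all_folds[[p]] <- cv$folds
  }
  if (!length(per_part)) stopf("no participant had enough windows for %d-fold CV", k)
  pooled <- do.call(rbind, per_part)
  agg <- do.call(rbind, lapply(split(pooled, list(pooled$family, pooled$config),
                                     drop = TRUE),
    function(g) data.frame(family = g$family[1], config = g$config[1],
                           config_size = g$config_size[1],
                           min_f1 = mean(g$min_f1), mean_f1 = mean(g$mean_f1),
                           max_f1 = mean(g$max_f1),
                           mean_accuracy = mean(g$mean_accuracy),
                           n_degenerate = sum(g$n_degenerate))))
  rownames(agg) <- NULL
  best <- do.call(rbind, lapply(split(agg, agg$family), function(g)
    g[order(-g$mean_f1, g$config_size, g$config), ][1, ]))
  rownames(best) <- NULL
  structure(list(mode = "personal",
                 problem = sprintf("%d-class", problem$n_classes),
                 feature_set = attr(feature_set, "set_name") %||% "custom",
                 folds = do.call(rbind, all_folds), summary = agg, best = best,
                 n_windows = nrow(pp$X),
                 n_participants = length(per_part)),
            class = "cogload_cv")
}

#' Permutation-null distribution of the LOO-CV mean weighted F1
#'
#' Re-runs the leave-one-participant-out evaluation of a single
#' configuration after permuting the class labels across windows, yielding
#' the chance-level distribution of the mean weighted F1.
#'
#' @inheritParams loo_cv
#' @param family,params One configuration (e.g. `family = "logistic"`,
#'   `params = list(solver = "lbfgs", penalty = "l2")`).
#' @param n_perm Number of permutations (default 50).
#' @return List: `null_f1` (vector of permuted means), `band` (2.5% and
#'   97.5% quantiles).
#' @export
loo_cv_null <- function(table, problem, feature_set, family = "logistic",
                        params = list(solver = "lbfgs", penalty = "l2"),
                        n_perm = 50, seed = 1, z_normalize = TRUE) {
  pp <- prepare_problem(table, problem, feature_set, FALSE, z_normalize)
  pids <- unique(pp$pid)
  folds <- lapply(pids, function(p) which(pp$pid == p))
  perm_seeds <- vapply(seq_len(n_perm), function(i) child_seed(seed, i), integer(1))
  null_f1 <- vapply(seq_len(n_perm), function(i) {
    yp <- with_local_seed(perm_seeds[i], sample(pp$y))
    mean(eval_folds(pp$X, yp, folds, family, params, seed)$weighted_f1)
  }, numeric(1))
  list(null_f1 = null_f1,
       band = stats::quantile(null_f1, c(0.025, 0.975), names = FALSE))
}

## ---- reporting -----------------------------------------------------------

#' @export
print.cogload_cv <- function(x, ...) {
  cat(sprintf("<%s CV: %s, feature set %s, %d windows, %d folds>\n",
              x$mode, x$problem, x$feature_set, x$n_windows,
              x$n_folds %||% NA))
  cat("best configuration per family (by mean weighted F1):\n")
  print(x$best[, c("family", "config", "min_f1", "mean_f1", "max_f1")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
summary.cogload_cv <- function(object, ...) {
  object$summary[order(-object$summary$mean_f1), ]
}

#' @export
plot.cogload_cv <- function(x, ...) {
  b <- x$best
  ylim <- c(0, 1)
  mid <- graphics::barplot(b$mean_f1, names.arg = b$family, ylim = ylim,
                           ylab = "weighted F1",
                           main = sprintf("%s CV, %s (%s)", x$mode, x$problem,
                                          x$feature_set), ...)
  graphics::arrows(mid, b$min_f1, mid, b$max_f1, angle = 90, code = 3,
                   length = 0.05)
  invisible(x)
}

#' Write a summary artifact over several CV reports
#'
#' One row per model family, problem and feature set with min/mean/max
#' weighted F1 and the best configuration; written as both JSON and CSV.
#'
#' @param reports List of `cogload_cv` objects.
#' @param out_path Output path without extension (`.json` and `.csv` are
#'   appended).
#' @return The summary data frame, invisibly.
#' @export
cv_report <- function(reports, out_path) {
  if (!length(reports)) stopf("no reports to summarise")
  rows <- do.call(rbind, lapply(reports, function(r) {
    b <- r$best
    data.frame(mode = r$mode, problem = r$problem, feature_set = r$feature_set,
               family = b$family, best_config = b$config,
               min_f1 = b$min_f1, mean_f1 = b$mean_f1, max_f1 = b$max_f1,
               mean_accuracy = b$mean_accuracy)
  }))
  rownames(rows) <- NULL
  jsonlite::write_json(rows, paste0(out_path, ".json"), digits = NA,
                       dataframe = "rows")
  utils::write.csv(rows, paste0(out_path, ".csv"), row.names = FALSE)
  invisible(rows)
}

#' Optional validation against a real recorded dataset
#'
#' Runs the full pipeline on locally downloaded real recordings laid out as
#' one directory per participant-session in the packaged export dialects.
#' The dataset is not bundled and must be obtained separately; this path is
#' informational and no packaged result depends on it.
#'
#' @param root Directory containing session subdirectories.
#' @param problem A [classification_problem()].
#' @param grid Hyperparameter grid.
#' @param seed Integer seed.
#' @return A `cogload_cv` object.
#' @export
validate_real_data <- function(root, problem = classification_problem(2),
                               grid = reduced_grid_spec(), seed = 1) {
  if (!dir.exists(root))
    stopf(paste0("real-data root '%s' not found; download the study dataset ",
                 "and point `root` at its session directories"), root)
  dirs <- list.dirs(root, recursive = FALSE)
  if (!length(dirs)) stopf("no session directories under '%s'", root)
  sessions <- lapply(dirs, read_session)
  tab <- build_feature_table(sessions)
  loo_cv(tab, problem, reduced_feature_set("All"), grid, seed = seed)
}
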