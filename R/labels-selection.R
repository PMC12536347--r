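#' Define a classification problem over the 5-point workload scale
#'
#' The five-class problem keeps the questionnaire response as the label.
#' Three classes merge responses 1-2 into `low`, keep 3 as `neutral`
#' ("neither low nor high") and merge 4-5 into `high`. The binary problem
#' keeps the two poles (`low` from 1-2, `high` from 4-5) and excludes
#' response-3 windows entirely.
#'
#' @param n_classes 2, 3 or 5.
#' @return List of class `cogload_problem` with the response mapping.
#' @export
classification_problem <- function(n_classes) {
  if (!n_classes %in% c(2, 3, 5)) stopf("n_classes must be 2, 3 or 5")
  mapping <- switch(as.character(n_classes),
    "5" = c("1", "2", "3", "4", "5"),
    "3" = c("low", "low", "neutral", "high", "high"),
    "2" = c("low", "low", NA, "high", "high"))
  levels <- switch(as.character(n_classes),
    "5" = c("1", "2", "3", "4", "5"),
    "3" = c("low", "neutral", "high"),
    "2" = c("low", "high"))
  structure(list(n_classes = n_classes, mapping = mapping, levels = levels),
            class = "cogload_problem")
}

#' Map questionnaire responses to class labels
#'
#' @param response Integer vector of responses in 1..5.
#' @param problem A [classification_problem()].
#' @return Factor with the problem's class levels; excluded responses
#'   (response 3 in the binary problem) become `NA` and their windows are
#'   dropped by the evaluators.
#' @export
map_labels <- function(response, problem) {
  if (any(!response %in% 1:5)) stopf("responses must lie in 1..5")
  factor(problem$mapping[response], levels = problem$levels)
}

classification_activities <- c("Relaxation", "Load", "Summary", "Reading", "Game")

#' One-hot encoding of the task activity
#'
#' Fixed ordering (Relaxation, Load, Summary, Reading, Game); eyes-closed
#' baselines are excluded from classification and are rejected here.
#'
#' @param activity Character vector of activities.
#' @return Numeric matrix with one indicator column per activity
#'   (`activity_Relaxation`, ...); each row sums to 1.
#' @export
one_hot_activity <- function(activity) {
  bad <- setdiff(unique(activity), classification_activities)
  if (length(bad))
    stopf("activity outside the classification vocabulary: %s",
          paste(bad, collapse = ", "))
  m <- sapply(classification_activities, function(a) as.numeric(activity == a))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  colnames(m) <- paste0("activity_", classification_activities)
  m
}

#' Correlate features with workload labels
#'
#' Pearson or Spearman (rank-transform then Pearson) correlation of each
#' feature column with the label, either pooled over all windows or per
#' participant with the absolute coefficients averaged across participants.
#' Constant features (or too few windows) yield `NA` coefficients.
#'
#' @param table A feature table (see [extract_features()]).
#' @param labels Numeric label per row (e.g. the workload response).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param scope `"pooled"` or `"per_participant"`.
#' @param feature_cols Feature column names (default: all non-metadata
#'   columns).
#' @param feature_matrix If TRUE also return the feature-by-feature
#'   correlation matrix (pooled).
#' @return List of class `cogload_corr`: `coefficients` (named; signed for
#'   pooled scope, mean absolute for per-participant scope), `method`,
#'   `scope`, and optionally `feature_matrix`.
#' @export
correlate_features <- function(table, labels,
                               method = c("spearman", "pearson"),
                               scope = c("pooled", "per_participant"),
                               feature_cols = NULL, feature_matrix = FALSE) {
  method <- match.arg(method)
  scope <- match.arg(scope)
  if (length(unique(labels[!is.na(labels)])) < 2L)
    stopf("labels are constant: correlation analysis is undefined")
  if (is.null(feature_cols)) feature_cols <- feature_columns(table)
  X <- as.matrix(table[feature_cols])
  y <- as.numeric(labels)
  tr <- function(v) if (method == "spearman") rank(v, na.last = "keep") else v
  corr_one <- function(X, y) {
    yr <- tr(y)
    apply(X, 2, function(col) {
      ok <- is.finite(col) & is.finite(y)
      if (sum(ok) < 3L || stats::sd(col[ok]) == 0 || stats::sd(y[ok]) == 0)
        return(NA_real_)
      stats::cor(tr(col[ok]), tr(y[ok]))
    })
  }
  if (scope == "pooled") {
    co <- corr_one(X, y)
  } else {
    pids <- unique(table$participant_id)
    per <- sapply(pids, function(p) {
      i <- table$participant_id == p
      if (sum(i) < 3L) return(rep(NA_real_, ncol(X)))
      abs(corr_one(X[i, , drop = FALSE], y[i]))
    })
    co <- rowMeans(per, na.rm = TRUE)
    names(co) <- feature_cols
  }
  out <- list(coefficients = co, method = method, scope = scope)
  if (feature_matrix)
    out$feature_matrix <- suppressWarnings(
      stats::cor(X, use = "pairwise.complete.obs",
                 method = if (method == "spearman") "spearman" else "pearson"))
  structure(out, class = "cogload_corr")
}

feature_set_manifest <- function() {
  path <- system.file("extdata", "feature_sets.json", package = "cogload")
  if (path == "") path <- file.path("inst", "extdata", "feature_sets.json")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Reduced feature sets
#'
#' Membership of the pinned reduced sets: `BothModalities` (20 features: the
#' twelve wavelet members plus eight wristband features), `MuseS` (20: the
#' twelve wavelet members plus eight spectral/index features), `EmpaticaE4`
#' (the 18 wristband features) and `All` (the full 754-entry bank). The
#' twelve wavelet members are pinned in the package manifest
#' (`extdata/feature_sets.json`).
#'
#' @param name One of `"BothModalities"`, `"MuseS"`, `"EmpaticaE4"`, `"All"`.
#' @return Character vector of feature names, attribute `set_name`.
#' @export
reduced_feature_set <- function(name = c("BothModalities", "MuseS",
                                         "EmpaticaE4", "All")) {
  name <- match.arg(name)
  man <- feature_set_manifest()
  members <- switch(name,
    BothModalities = c(man$dwt_twelve, man$e4_shared),
    MuseS = c(man$dwt_twelve, man$muse_spectral),
    EmpaticaE4 = e4_feature_names,
    All = all_feature_names())
  structure(members, set_name = name)
}

#' Select the top-k features by correlation strength
#'
#' Orders features by absolute correlation coefficient (averaged absolute
#' coefficient for per-participant reports); ties are broken by lexicographic
#' feature name so the selection is deterministic.
#'
#' @param report A `cogload_corr` from [correlate_features()].
#' @param k Number of features to keep.
#' @return Character vector of k feature names, attribute `set_name = "TopK"`.
#' @export
select_top_features <- function(report, k) {
  co <- abs(report$coefficients)
  co[!is.finite(co)] <- -Inf
  if (k > length(co)) stopf("k = %d exceeds the %d available features", k, length(co))
  ord <- order(-co, names(co))
  structure(names(co)[ord][seq_len(k)], set_name = "TopK")
}
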