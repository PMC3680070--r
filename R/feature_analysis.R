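# Information-gain feature ranking with correlation signs, decision-tree
# difficulty prediction, and the non-kernel interaction-classifier
# baseline harness.

#' Shannon entropy of a label vector, in bits
#'
#' @param labels non-empty vector (factor, character or logical).
#' @return entropy of the empirical label distribution.
#' @export
entropy_of_labels <- function(labels) {
  if (!length(labels)) stop("empty label vector")
  entropy_bits(table(labels))
}

#' Supervised discretization of a continuous feature
#'
#' Binary split maximizing information gain against the labels, recursing
#' once on each side (at most four bins). Features with few distinct
#' values are used as-is. Deterministic.
#'
#' @param x numeric feature column.
#' @param labels aligned label vector.
#' @param max_distinct treat `x` as already discrete when it has at most
#'   this many distinct values.
#' @return factor of bin memberships.
#' @export
discretize_feature <- function(x, labels, max_distinct = 8) {
  ux <- unique(x[!is.na(x)])
  if (length(ux) <= max_distinct) {
    return(factor(ifelse(is.na(x), "(missing)", as.character(x))))
  }
  split_once <- function(idx) {
    xs <- x[idx]; ys <- labels[idx]
    cand <- sort(unique(xs))
    if (length(cand) < 2) return(NULL)
    cuts <- (cand[-1] + cand[-length(cand)]) / 2
    if (length(cuts) > 64) {
      cuts <- stats::quantile(xs, probs = seq(0.02, 0.98, length.out = 64),
                              names = FALSE, type = 1)
      cuts <- sort(unique(cuts))
    }
    base <- entropy_bits(table(ys))
    best <- NULL; best_ig <- -Inf
    for (cc in cuts) {
      left <- xs <= cc
      if (!any(left) || all(left)) next
      h <- mean(left) * entropy_bits(table(ys[left])) +
        mean(!left) * entropy_bits(table(ys[!left]))
      ig <- base - h
      if (ig > best_ig + 1e-12) { best_ig <- ig; best <- cc }
    }
    best
  }
  n <- length(x)
  obs <- which(!is.na(x))
  bin <- rep("(missing)", n)
  c0 <- split_once(obs)
  if (is.null(c0)) {
    bin[obs] <- "all"
    return(factor(bin))
  }
  for (side in list(obs[x[obs] <= c0], obs[x[obs] > c0])) {
    c1 <- split_once(side)
    if (is.null(c1)) {
      bin[side] <- sprintf("bin@%g", mean(x[side]))
    } else {
      bin[side[x[side] <= c1]] <- sprintf("le%g", c1)
      bin[side[x[side] > c1]] <- sprintf("gt%g", c1)
    }
  }
  factor(bin)
}

#' Information gain of a feature for a label
#'
#' `IG = H(label) - sum_v p(v) H(label | feature = v)` after supervised
#' discretization of continuous features. The sign is the sign of the
#' Pearson (point-biserial) correlation between the numeric feature and
#' the binary class indicator.
#'
#' @param feature_column numeric (or discrete) feature values.
#' @param labels aligned labels; for the sign, logical/binary labels are
#'   used directly and factors are compared against their first level.
#' @param discretize whether to apply [discretize_feature()] to numeric
#'   input.
#' @return list with `IG` (bits), `sign` (`"+"` or `"-"`).
#' @export
information_gain <- function(feature_column, labels, discretize = TRUE) {
  if (length(unique(labels)) < 2) {
    return(list(IG = 0, sign = "+"))
  }
  v <- if (is.numeric(feature_column) && discretize) {
    discretize_feature(feature_column, labels)
  } else {
    factor(feature_column)
  }
  base <- entropy_bits(table(labels))
  cond <- 0
  for (lev in levels(v)) {
    sel <- v == lev
    if (!any(sel)) next
    cond <- cond + mean(sel) * entropy_bits(table(labels[sel]))
  }
  ig <- max(base - cond, 0)
  sgn <- "+"
  if (is.numeric(feature_column)) {
    y <- if (is.logical(labels)) as.numeric(labels) else
      as.numeric(factor(labels) == levels(factor(labels))[1])
    ok <- !is.na(feature_column)
    if (stats::sd(feature_column[ok]) > 0 && stats::sd(y[ok]) > 0) {
      r <- stats::cor(feature_column[ok], y[ok])
      sgn <- if (!is.na(r) && r < 0) "-" else "+"
    }
  }
  list(IG = ig, sign = sgn)
}

#' Rank features by information gain against a class indicator
#'
#' @param ft feature table from [feature_table()] (metadata columns are
#'   skipped), or any data.frame of numeric feature columns.
#' @param class_labels binary indicator (logical) of the target difficulty
#'   class, aligned to the table rows.
#' @param k number of top features to return (all when `k` exceeds the
#'   feature count; 0 gives an empty ranking).
#' @return data.frame with `rank`, `feature`, `sign`, `IG`, ordered by
#'   descending IG with deterministic name tie-break.
#' @export
rank_features <- function(ft, class_labels, k = 10) {
  meta <- c("pair_id", "sentence_id", "document_id", "corpus", "gold")
  cols <- setdiff(names(ft), meta)
  cols <- cols[vapply(ft[cols], is.numeric, TRUE)]
  entries <- lapply(cols, function(cl) {
    e <- information_gain(ft[[cl]], class_labels)
    data.frame(feature = cl, sign = e$sign, IG = e$IG,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, entries)
  if (is.null(out)) {
    return(data.frame(rank = integer(), feature = character(),
                      sign = character(), IG = numeric()))
  }
  out <- out[order(-out$IG, out$feature), ]
  out <- utils::head(out, k)
  if (nrow(out)) out <- cbind(rank = seq_len(nrow(out)), out)
  else out <- cbind(rank = integer(), out)
  rownames(out) <- NULL
  out
}

# ---- difficulty prediction ------------------------------------------------

feature_matrix_for_learning <- function(ft) {
  meta <- c("pair_id", "sentence_id", "document_id", "corpus", "gold")
  cols <- setdiff(names(ft), meta)
  cols <- cols[vapply(ft[cols], is.numeric, TRUE)]
  X <- ft[cols]
  # median-impute missing parse features; the has_* flags keep the signal
  for (cl in cols) {
    nas <- is.na(X[[cl]])
    if (any(nas)) {
      med <- stats::median(X[[cl]], na.rm = TRUE)
      X[[cl]][nas] <- if (is.finite(med)) med else 0
    }
  }
  X
}

#' Train a decision tree predicting pair difficulty class
#'
#' CART-style tree (information-gain splitting) over the surface/parse
#' feature space, predicting `{D, N, E}`. Defaults: minimum leaf size 25,
#' maximum depth 12, no cost-complexity pruning.
#'
#' @param ft feature table from [feature_table()].
#' @param classes data.frame with `pair_id`, `class` (see
#'   [combine_settings()]).
#' @param minbucket,maxdepth tree hyperparameters.
#' @param seed integer seed (tree fitting in `rpart` is deterministic; the
#'   seed is recorded in the metadata and used by evaluation protocols).
#' @return object of class `difficulty_model`: list with `fit` (rpart),
#'   `features`, `meta`.
#' @export
train_difficulty_model <- function(ft, classes, minbucket = 25,
                                   maxdepth = 12, seed = 1L) {
  cl <- stats::setNames(classes$class, classes$pair_id)[ft$pair_id]
  if (length(unique(cl)) < 2) stop("single-class training set")
  X <- feature_matrix_for_learning(ft)
  df <- cbind(.class = factor(cl, c("D", "N", "E")), X)
  fit <- rpart::rpart(
    .class ~ ., data = df, method = "class",
    parms = list(split = "information"),
    control = rpart::rpart.control(minbucket = minbucket, maxdepth = maxdepth,
                                   cp = 0, xval = 0))
  structure(list(fit = fit, features = names(X),
                 meta = list(minbucket = minbucket, maxdepth = maxdepth,
                             seed = seed)),
            class = "difficulty_model")
}

#' Predict difficulty classes
#'
#' @param object a `difficulty_model`.
#' @param newdata feature table.
#' @param ... unused.
#' @return character vector over `{D, N, E}`.
#' @export
predict.difficulty_model <- function(object, newdata, ...) {
  X <- feature_matrix_for_learning(newdata)
  miss <- setdiff(object$features, names(X))
  for (m in miss) X[[m]] <- 0
  as.character(predict(object$fit, X, type = "class"))
}

#' Evaluate difficulty prediction under a stated protocol
#'
#' `mode = "cv"` runs document-level k-fold cross-validation (folds are
#' derived from the pair ids' document component) and pools the confusion
#' matrix; `mode = "resubstitution"` trains and evaluates on the full
#' table.
#'
#' @param ft feature table.
#' @param classes difficulty class assignment (see
#'   [train_difficulty_model()]).
#' @param mode `"cv"` or `"resubstitution"`.
#' @param n_folds number of folds for `"cv"`.
#' @param seed integer seed controlling the fold assignment.
#' @param ... passed to [train_difficulty_model()].
#' @return a [multiclass_eval()] report.
#' @export
evaluate_difficulty_model <- function(ft, classes, mode = c("cv", "resubstitution"),
                                      n_folds = 10, seed = 1L, ...) {
  mode <- match.arg(mode)
  cl <- stats::setNames(classes$class, classes$pair_id)[ft$pair_id]
  if (mode == "resubstitution") {
    model <- train_difficulty_model(ft, classes, seed = seed, ...)
    pred <- predict(model, ft)
    return(multiclass_eval(pred, cl))
  }
  docs <- unique(ft$document_id)
  set.seed(seed)
  doc_fold <- stats::setNames(sample(rep(seq_len(n_folds),
                                         length.out = length(docs))), docs)
  fold <- doc_fold[ft$document_id]
  pred <- character(nrow(ft))
  for (f in seq_len(n_folds)) {
    test <- fold == f
    if (!any(test) || !any(!test)) next
    model <- train_difficulty_model(ft[!test, , drop = FALSE], classes,
                                    seed = seed, ...)
    pred[test] <- predict(model, ft[test, , drop = FALSE])
  }
  keep <- nzchar(pred)
  multiclass_eval(pred[keep], cl[keep])
}

# ---- interaction baselines ------------------------------------------------

#' Baseline learner specification
#'
#' @param kind one of `"decision-tree"`, `"naive-bayes"`, `"logistic"`,
#'   `"rule"` (single-feature OneR-style rule), `"nearest-neighbor"`,
#'   `"majority"`.
#' @param seed integer seed.
#' @param k neighbors for `"nearest-neighbor"`.
#' @return list of class `baseline_spec`.
#' @export
baseline_spec <- function(kind = c("decision-tree", "naive-bayes", "logistic",
                                   "rule", "nearest-neighbor", "majority"),
                          seed = 1L, k = 5L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, seed = seed, k = k), class = "baseline_spec")
}

fit_predict_baseline <- function(spec, X_train, y_train, X_test) {
  switch(spec$kind,
    "majority" = rep(mean(y_train) >= 0.5, nrow(X_test)),
    "decision-tree" = {
      df <- cbind(.y = factor(y_train, c(FALSE, TRUE)), X_train)
      fit <- rpart::rpart(.y ~ ., df, method = "class",
                          parms = list(split = "information"),
                          control = rpart::rpart.control(minbucket = 10,
                                                         cp = 0.001, xval = 0))
      predict(fit, X_test, type = "class") == "TRUE"
    },
    "naive-bayes" = {
      fit <- e1071::naiveBayes(X_train, factor(y_train, c(FALSE, TRUE)))
      predict(fit, X_test) == "TRUE"
    },
    "logistic" = {
      keep <- vapply(X_train, function(v) stats::sd(v) > 0, TRUE)
      df <- cbind(.y = y_train, X_train[keep])
      fit <- suppressWarnings(
        stats::glm(.y ~ ., data = df, family = stats::binomial()))
      suppressWarnings(
        predict(fit, X_test[keep], type = "response")) >= 0.5
    },
    "rule" = fit_predict_oner(X_train, y_train, X_test),
    "nearest-neighbor" = {
      mu <- vapply(X_train, mean, 0)
      sg <- vapply(X_train, stats::sd, 0); sg[sg == 0] <- 1
      zt <- scale(as.matrix(X_train), mu, sg)
      zs <- scale(as.matrix(X_test), mu, sg)
      as.character(class::knn(zt, zs, factor(y_train, c(FALSE, TRUE)),
                              k = spec$k)) == "TRUE"
    })
}

# OneR-style rule: pick the single discretized feature with the highest
# training accuracy and predict each bin's majority label.
fit_predict_oner <- function(X_train, y_train, X_test) {
  best_acc <- -1; best_col <- NULL; best_map <- NULL; best_cut <- NULL
  for (cl in names(X_train)) {
    x <- X_train[[cl]]
    if (stats::sd(x) == 0) next
    cuts <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 1)
    cuts <- unique(cuts)
    bins <- findInterval(x, cuts)
    map <- tapply(y_train, bins, function(g) mean(g) >= 0.5)
    acc <- mean(map[as.character(bins)] == y_train, na.rm = TRUE)
    if (!is.na(acc) && acc > best_acc) {
      best_acc <- acc; best_col <- cl; best_map <- map; best_cut <- cuts
    }
  }
  if (is.null(best_col)) return(rep(mean(y_train) >= 0.5, nrow(X_test)))
  bins <- as.character(findInterval(X_test[[best_col]], best_cut))
  out <- best_map[bins]
  out[is.na(out)] <- mean(y_train) >= 0.5
  unname(out)
}

#' Train and evaluate non-kernel interaction baselines
#'
#' Surface-feature classifiers for the binary interaction label, evaluated
#' with document-level cross-validation: every learner is trained and
#' tested strictly across document boundaries (a shared document between
#' train and test folds is a hard error).
#'
#' @param ft feature table from [feature_table()].
#' @param gold named logical vector of gold labels.
#' @param specs list of [baseline_spec()] objects.
#' @param folds named integer vector document id -> fold (see
#'   [read_folds()] / [assign_folds()]).
#' @return data.frame: one row per learner per corpus (plus pooled
#'   `"(all)"`), with `learner`, `corpus`, `P`, `R`, `F`.
#' @export
train_interaction_baselines <- function(ft, gold, specs, folds) {
  miss <- setdiff(unique(ft$document_id), names(folds))
  if (length(miss)) stop("document without fold assignment: ", miss[1])
  # a document listed under more than one fold would leak across the
  # train/test boundary
  conflicts <- tapply(unname(folds), names(folds),
                      function(v) length(unique(v)))
  if (any(conflicts > 1)) {
    stop("fold leakage: document ", names(conflicts)[conflicts > 1][1],
         " assigned to more than one fold")
  }
  folds <- folds[!duplicated(names(folds))]
  X <- feature_matrix_for_learning(ft)
  y <- unname(gold[ft$pair_id])
  fold <- folds[ft$document_id]
  if (length(unique(fold)) < 2) {
    stop("fold assignment leaves no held-out documents")
  }
  out <- list()
  for (spec in specs) {
    set.seed(spec$seed)
    pred <- logical(nrow(ft))
    for (f in sort(unique(fold))) {
      test <- fold == f
      if (!any(test) || !any(!test)) next
      pred[test] <- fit_predict_baseline(
        spec, X[!test, , drop = FALSE], y[!test], X[test, , drop = FALSE])
    }
    pv <- stats::setNames(pred, ft$pair_id)
    gv <- stats::setNames(y, ft$pair_id)
    rep_ <- ensemble_eval(pv, gv,
                          stats::setNames(ft$corpus, ft$pair_id))
    rep_$learner <- spec$kind
    out[[spec$kind]] <- rep_
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[c("learner", "corpus", "P", "R", "F")]
}
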