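# Confusion counts, precision/recall/F1, expected-correctness bookkeeping
# on difficulty strata, multiclass reports, relabel-and-rescore, and
# majority-vote ensembles.

#' Round half away from zero
#'
#' Presentation rounding used throughout the stratum reports: `0.5` rounds
#' to `1`, `-0.5` to `-1` (base `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Confusion counts on a pair subset
#'
#' @param predictions named logical vector of predicted labels (one
#'   classifier).
#' @param gold named logical vector of gold labels.
#' @param subset pair ids to evaluate; default all of `gold`.
#' @return list with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(predictions, gold, subset = names(gold)) {
  missing <- setdiff(subset, names(predictions))
  if (length(missing)) {
    stop("pair outside prediction coverage: ", missing[1])
  }
  p <- predictions[subset]; g <- gold[subset]
  list(TP = sum(p & g), FP = sum(p & !g),
       TN = sum(!p & !g), FN = sum(!p & g))
}

#' Precision, recall and F1 from confusion counts
#'
#' Percent scale. Zero-denominator cases (no predicted positives, no gold
#' positives, or P + R = 0) are defined as 0.
#'
#' @param counts list with `TP`, `FP`, `TN`, `FN` (see [confusion()]).
#' @return list with `P`, `R`, `F` in `[0, 100]` (unrounded).
#' @export
prf <- function(counts) {
  P <- if (counts$TP + counts$FP > 0) 100 * counts$TP / (counts$TP + counts$FP) else 0
  R <- if (counts$TP + counts$FN > 0) 100 * counts$TP / (counts$TP + counts$FN) else 0
  F <- if (P + R > 0) 2 * P * R / (P + R) else 0
  list(P = P, R = R, F = F)
}

#' Positive-prediction rate of a classifier
#'
#' The fraction (percent) of a pair population that a classifier labels
#' positive. The default population is every pair covered by the
#' prediction set (pooled over corpora, per setting).
#'
#' @param predictions a [prediction_set()].
#' @param classifier classifier id in the roster.
#' @param population pair ids; default all covered pairs.
#' @return list with `classifier` and `r` (percent).
#' @export
positive_rate <- function(predictions, classifier,
                          population = rownames(predictions$table)) {
  if (!length(population)) stop("population must be non-empty")
  col <- predictions$table[population, classifier]
  list(classifier = classifier, r = 100 * mean(col))
}

#' Expected number of correct labels on a stratum
#'
#' If a classifier labels a fraction `r` percent of pairs positive
#' independently of difficulty, it is expected to label
#' `(1 - r/100) * size` pairs of an all-negative stratum correctly (true
#' negatives), and `(r/100) * size` of an all-positive stratum (true
#' positives). Rounded to the nearest integer, halves away from zero.
#'
#' @param stratum_size number of pairs in the stratum.
#' @param r positive-prediction rate in percent.
#' @param polarity `"negative"` or `"positive"` (the stratum's gold label).
#' @return expected correct count (integer-valued numeric).
#' @export
expected_correct <- function(stratum_size, r, polarity = c("negative", "positive")) {
  polarity <- match.arg(polarity)
  stopifnot(r >= 0, r <= 100, stratum_size >= 0)
  frac <- if (polarity == "negative") 1 - r / 100 else r / 100
  round_half_away(frac * stratum_size)
}

#' Observed-versus-expected report for one classifier on one stratum
#'
#' For a single-polarity stratum (e.g. the negative-difficult pairs), the
#' observed correct count is the true-negative (negative polarity) or
#' true-positive (positive polarity) count; the expected count comes from
#' the classifier's positive-prediction rate via [expected_correct()].
#'
#' @param predictions a [prediction_set()].
#' @param classifier classifier id.
#' @param gold named logical vector of gold labels.
#' @param stratum pair ids of the stratum (must share one gold label).
#' @param polarity `"negative"` or `"positive"`; must match the stratum's
#'   gold labels.
#' @param r optional positive rate (percent) to use instead of computing it
#'   from the prediction set's full population.
#' @return list with `classifier`, `stratum_size`, `r`, `observed`, `e`,
#'   `ratio_e` (observed / e) and `ratio_size` (observed / size), ratios
#'   rounded to two decimals (half away from zero); `ratio_e` is `NA` when
#'   `e` is 0.
#' @export
stratum_report <- function(predictions, classifier, gold, stratum,
                           polarity = c("negative", "positive"), r = NULL) {
  polarity <- match.arg(polarity)
  g <- gold[stratum]
  want <- polarity == "positive"
  if (any(g != want)) {
    stop("stratum gold labels inconsistent with polarity ", polarity)
  }
  if (is.null(r)) r <- positive_rate(predictions, classifier)$r
  cc <- confusion(stats::setNames(predictions$table[, classifier],
                                  rownames(predictions$table)),
                  gold, stratum)
  observed <- if (want) cc$TP else cc$TN
  stratum_bookkeeping(classifier, length(stratum), r, observed, polarity)
}

#' Expected-correctness bookkeeping from explicit counts
#'
#' The arithmetic core of [stratum_report()], usable directly on printed
#' rates and counts: derives `e` and the two ratio columns from a positive
#' rate, an observed correct count and a stratum size.
#'
#' @param classifier classifier id.
#' @param stratum_size stratum size.
#' @param r positive rate in percent.
#' @param observed observed correct count (TN or TP).
#' @param polarity `"negative"` or `"positive"`.
#' @return same shape as [stratum_report()].
#' @export
stratum_bookkeeping <- function(classifier, stratum_size, r, observed,
                                polarity = c("negative", "positive")) {
  polarity <- match.arg(polarity)
  e <- expected_correct(stratum_size, r, polarity)
  list(classifier = classifier, stratum_size = stratum_size, r = r,
       observed = observed, e = e,
       ratio_e = if (e > 0) round_half_away(observed / e, 2) else NA_real_,
       ratio_size = round_half_away(observed / stratum_size, 2))
}

#' Stratum report for every classifier in a roster
#'
#' @inheritParams stratum_report
#' @param stratum_name label for the stratum (e.g. `"ND"`).
#' @return data.frame with one row per classifier, sorted by observed
#'   correct count (descending).
#' @export
stratum_table <- function(predictions, gold, stratum, polarity,
                          stratum_name = polarity) {
  rows <- lapply(predictions$roster, function(cl)
    as.data.frame(stratum_report(predictions, cl, gold, stratum, polarity),
                  stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$stratum <- stratum_name
  out[order(-out$observed, out$classifier), ]
}

# ---- multiclass -----------------------------------------------------------

#' Multiclass evaluation over the D/N/E difficulty classes
#'
#' Builds the 3x3 confusion matrix (actual rows, predicted columns),
#' per-class one-vs-rest precision/recall/F1, and a support-weighted total
#' row (weights are the actual class supports).
#'
#' @param predicted,actual factors/characters over `{D, N, E}`, or pass a
#'   3x3 confusion matrix as `confusion_matrix`.
#' @param confusion_matrix optional 3x3 matrix (actual rows D/N/E,
#'   predicted columns D/N/E) used instead of label vectors.
#' @return object of class `multiclass_report`: list with `confusion`
#'   (matrix), `per_class` (data.frame class/P/R/F/support, unrounded) and
#'   `total` (list P/R/F, support-weighted).
#' @export
multiclass_eval <- function(predicted = NULL, actual = NULL,
                            confusion_matrix = NULL) {
  classes <- c("D", "N", "E")
  if (is.null(confusion_matrix)) {
    bad <- setdiff(unique(c(predicted, actual)), classes)
    if (length(bad)) stop("label outside {D, N, E}: ", bad[1])
    confusion_matrix <- table(factor(actual, classes),
                              factor(predicted, classes))
    confusion_matrix <- matrix(as.numeric(confusion_matrix), 3,
                               dimnames = list(classes, classes))
  } else {
    stopifnot(all(dim(confusion_matrix) == c(3, 3)))
    dimnames(confusion_matrix) <- list(classes, classes)
  }
  per <- lapply(classes, function(k) {
    tp <- confusion_matrix[k, k]
    fp <- sum(confusion_matrix[, k]) - tp
    fn <- sum(confusion_matrix[k, ]) - tp
    m <- prf(list(TP = tp, FP = fp, FN = fn, TN = 0))
    data.frame(class = k, P = m$P, R = m$R, F = m$F,
               support = sum(confusion_matrix[k, ]),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  w <- per$support / sum(per$support)
  total <- list(P = sum(w * per$P), R = sum(w * per$R), F = sum(w * per$F))
  structure(list(confusion = confusion_matrix, per_class = per,
                 total = total),
            class = "multiclass_report")
}

#' @export
print.multiclass_report <- function(x, ...) {
  df <- x$per_class
  df[c("P", "R", "F")] <- lapply(df[c("P", "R", "F")], round_half_away, 1)
  print(df, row.names = FALSE)
  cat(sprintf("total (weighted): P %.1f  R %.1f  F %.1f\n",
              round_half_away(x$total$P, 1), round_half_away(x$total$R, 1),
              round_half_away(x$total$F, 1)))
  invisible(x)
}

# ---- relabel and rescore --------------------------------------------------

#' Rescore predictions after flipping gold labels
#'
#' Inverts the gold interaction label of the listed pairs (a curated
#' relabeling, e.g. suspected annotation errors among the hardest pairs)
#' and recomputes precision/recall/F1 of the *fixed* predictions — no
#' retraining is involved.
#'
#' @param predictions a [prediction_set()].
#' @param gold named logical vector of gold labels.
#' @param flip_ids pair ids whose gold label is inverted.
#' @return list with `n_flipped`, `fraction_flipped`, and `report`: a
#'   data.frame per classifier with before/after P, R, F.
#' @export
relabel_and_rescore <- function(predictions, gold, flip_ids) {
  flip_ids <- normalize_pair_id(flip_ids)
  ids <- normalize_pair_id(names(gold))
  names(gold) <- ids
  unknown <- setdiff(flip_ids, ids)
  if (length(unknown)) stop("unknown pair id in flip list: ", unknown[1])
  gold2 <- gold
  gold2[flip_ids] <- !gold2[flip_ids]
  rn <- normalize_pair_id(rownames(predictions$table))
  tab <- predictions$table
  rownames(tab) <- rn
  rows <- lapply(predictions$roster, function(cl) {
    pv <- stats::setNames(tab[, cl], rn)
    before <- prf(confusion(pv, gold))
    after <- prf(confusion(pv, gold2))
    data.frame(classifier = cl,
               P_before = before$P, R_before = before$R, F_before = before$F,
               P_after = after$P, R_after = after$R, F_after = after$F,
               stringsAsFactors = FALSE)
  })
  list(n_flipped = length(flip_ids),
       fraction_flipped = length(flip_ids) / length(gold),
       report = do.call(rbind, rows))
}

# ---- ensembles ------------------------------------------------------------

#' Majority-vote ensemble over a classifier committee
#'
#' @param predictions a [prediction_set()].
#' @param committee classifier ids (subset of the roster).
#' @param tie_rule tie handling for even committees: `"error"`,
#'   `"positive"` or `"negative"`.
#' @return named logical vector of ensemble labels over the covered pairs.
#' @export
majority_vote <- function(predictions, committee = predictions$roster,
                          tie_rule = c("error", "positive", "negative")) {
  tie_rule <- match.arg(tie_rule)
  missing <- setdiff(committee, predictions$roster)
  if (length(missing)) stop("committee member not in roster: ", missing[1])
  votes <- rowSums(predictions$table[, committee, drop = FALSE])
  half <- length(committee) / 2
  out <- votes > half
  ties <- votes == half
  if (any(ties)) {
    out[ties] <- switch(tie_rule,
      error = stop("tie encountered with tie_rule = 'error' (pair ",
                   rownames(predictions$table)[ties][1], ")"),
      positive = TRUE,
      negative = FALSE)
  }
  stats::setNames(out, rownames(predictions$table))
}

#' Evaluate ensemble predictions per corpus
#'
#' @param ensemble_predictions named logical vector (e.g. from
#'   [majority_vote()]).
#' @param gold named logical vector of gold labels.
#' @param corpus_of_pair named character vector pair id -> corpus name;
#'   default derives the corpus from the long-form pair-id prefix.
#' @return data.frame with one row per corpus plus a pooled `"(all)"` row:
#'   `corpus`, `P`, `R`, `F` (unrounded percent).
#' @export
ensemble_eval <- function(ensemble_predictions, gold,
                          corpus_of_pair = NULL) {
  ids <- names(gold)
  if (is.null(corpus_of_pair)) {
    corpus_of_pair <- stats::setNames(sub("\\..*$", "", ids), ids)
  }
  groups <- split(ids, corpus_of_pair[ids])
  rows <- lapply(names(groups), function(nm) {
    m <- prf(confusion(ensemble_predictions, gold, groups[[nm]]))
    data.frame(corpus = nm, P = m$P, R = m$R, F = m$F,
               stringsAsFactors = FALSE)
  })
  all_m <- prf(confusion(ensemble_predictions, gold, ids))
  rows[[length(rows) + 1L]] <- data.frame(corpus = "(all)", P = all_m$P,
                                          R = all_m$R, F = all_m$F,
                                          stringsAsFactors = FALSE)
  do.call(rbind, rows)
}
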