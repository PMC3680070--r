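# Success levels, ~10% difficulty/easy cutoffs, D/PD/ND/NE/PE combination
# across evaluation settings, and chi-square overlap testing.

#' Compute per-pair classification success levels
#'
#' The success level of a pair is the number of classifiers in the
#' setting's roster that predict its gold label correctly; it ranges from 0
#' to the roster size.
#'
#' @param gold named logical vector of gold labels (or a [ppi_corpus()] /
#'   list of corpora, from which gold labels are taken).
#' @param predictions a [prediction_set()] covering all pairs in `gold` for
#'   its full roster.
#' @return object of class `success_table`: list with `setting`, `roster`
#'   and `levels` (named integer vector, pair id -> success level).
#' @export
compute_success_levels <- function(gold, predictions) {
  if (!is.logical(gold)) gold <- gold_labels(gold)
  missing <- setdiff(names(gold), rownames(predictions$table))
  if (length(missing)) {
    stop("missing prediction cell for pair ", missing[1],
         " (all classifiers)")
  }
  m <- predictions$table[names(gold), , drop = FALSE]
  s <- as.integer(rowSums(m == gold))
  structure(list(setting = predictions$setting,
                 roster = predictions$roster,
                 levels = stats::setNames(s, names(gold))),
            class = "success_table")
}

#' Histogram of success levels
#'
#' @param x a `success_table` from [compute_success_levels()], or a named
#'   integer vector of levels.
#' @param max_level highest possible level (roster size); inferred from a
#'   `success_table`.
#' @return integer vector of pair counts, names `"0"` .. `"max_level"`.
#' @export
success_histogram <- function(x, max_level = NULL) {
  if (inherits(x, "success_table")) {
    if (is.null(max_level)) max_level <- length(x$roster)
    x <- x$levels
  }
  if (is.null(max_level)) max_level <- max(x)
  counts <- tabulate(x + 1L, nbins = max_level + 1L)
  stats::setNames(counts, as.character(0:max_level))
}

#' Cut the difficult side of a success-level histogram
#'
#' Selects the non-empty level prefix (levels `0..t`) whose total size is
#' closest to `fraction` of the corpus, ties broken toward the smaller
#' (more stringent) set. An alternative `"at_least"` rule selects the
#' smallest non-empty prefix reaching at least the target.
#'
#' @param histogram integer vector of pair counts indexed by success level
#'   (names `"0"`, `"1"`, ...).
#' @param corpus_size total pair count; defaults to `sum(histogram)`.
#' @param fraction target fraction, default 0.10.
#' @param rule `"closest"` (default) or `"at_least"`.
#' @return list with `side = "difficult"`, `threshold` (highest included
#'   level), `size`, `levels` (included levels) and `rule`.
#' @export
cut_difficult <- function(histogram, corpus_size = sum(histogram),
                          fraction = 0.10, rule = c("closest", "at_least")) {
  rule <- match.arg(rule)
  if (corpus_size <= 0) stop("corpus_size must be positive")
  cum <- cumsum(histogram)
  nonempty <- which(cum > 0)
  target <- fraction * corpus_size
  sel <- switch(rule,
    closest = nonempty[which.min(abs(cum[nonempty] - target))],
    at_least = {
      reach <- nonempty[cum[nonempty] >= target]
      if (length(reach)) reach[1] else nonempty[length(nonempty)]
    })
  list(side = "difficult", threshold = unname(sel) - 1L,
       size = unname(cum[sel]), levels = 0:(sel - 1L), rule = rule)
}

#' Cut the easy side of a success-level histogram
#'
#' Selects the smallest non-empty level suffix (levels `t..max`) whose
#' total size is at least `fraction` of the corpus (default rule), or the
#' suffix closest to the target (`"closest"`).
#'
#' @inheritParams cut_difficult
#' @return list with `side = "easy"`, `threshold` (lowest included level),
#'   `size`, `levels` and `rule`.
#' @export
cut_easy <- function(histogram, corpus_size = sum(histogram),
                     fraction = 0.10, rule = c("at_least", "closest")) {
  rule <- match.arg(rule)
  if (corpus_size <= 0) stop("corpus_size must be positive")
  K <- length(histogram)
  cum <- rev(cumsum(rev(histogram)))   # cum[i] = size of suffix starting at i
  has_mass <- cum > 0
  target <- fraction * corpus_size
  sel <- switch(rule,
    at_least = {
      reach <- which(cum >= target & has_mass)
      if (length(reach)) reach[length(reach)] else which(has_mass)[1]
    },
    closest = {
      cand <- which(has_mass)
      cand[which.min(abs(cum[cand] - target))[1]]
    })
  # ties under "closest" break toward the smaller set (larger start level)
  if (rule == "closest") {
    cand <- which(has_mass & abs(cum - target) == abs(cum[sel] - target))
    sel <- cand[length(cand)]
  }
  list(side = "easy", threshold = unname(sel) - 1L,
       size = unname(cum[sel]), levels = (sel - 1L):(K - 1L), rule = rule)
}

#' Difficult and easy pair sets for one corpus and setting
#'
#' Applies [cut_difficult()] and [cut_easy()] to the success-level
#' histogram of a corpus and materializes the pair-id sets. When the two
#' configurable cutoff rules disagree on a side, the result carries a
#' `rules_disagree` flag for that side.
#'
#' @param success a `success_table` from [compute_success_levels()].
#' @param fraction target fraction of the corpus on each side.
#' @param difficult_rule,easy_rule cutoff rules, see [cut_difficult()] and
#'   [cut_easy()].
#' @return object of class `difficulty_sets`: list with `setting`,
#'   `fraction`, `difficult` / `easy` (each with `ids`, `threshold`,
#'   `size`, `rules_disagree`).
#' @export
difficulty_sets <- function(success, fraction = 0.10,
                            difficult_rule = "closest",
                            easy_rule = "at_least") {
  hist <- success_histogram(success)
  n <- sum(hist)
  dcut <- cut_difficult(hist, n, fraction, difficult_rule)
  ecut <- cut_easy(hist, n, fraction, easy_rule)
  dalt <- cut_difficult(hist, n, fraction,
                        setdiff(c("closest", "at_least"), difficult_rule))
  ealt <- cut_easy(hist, n, fraction,
                   setdiff(c("at_least", "closest"), easy_rule))
  lv <- success$levels
  structure(list(
    setting = success$setting,
    fraction = fraction,
    difficult = list(ids = names(lv)[lv <= dcut$threshold],
                     threshold = dcut$threshold, size = dcut$size,
                     rule = dcut$rule,
                     rules_disagree = dcut$size != dalt$size),
    easy = list(ids = names(lv)[lv >= ecut$threshold],
                threshold = ecut$threshold, size = ecut$size,
                rule = ecut$rule,
                rules_disagree = ecut$size != ealt$size)
  ), class = "difficulty_sets")
}

#' Combine per-setting difficulty sets into D/N/E classes
#'
#' The universal difficult class is the intersection of the per-setting
#' difficult sets, `D = D_CV` \eqn{\cap} `D_CL`; likewise for easy. All
#' remaining pairs are neutral. With gold labels the signed subclasses
#' ND/PD/NE/PE (and `"neutral"`) are derived.
#'
#' @param difficult_cv,easy_cv,difficult_cl,easy_cl character vectors of
#'   pair ids (the four per-setting sets over one pair universe).
#' @param gold named logical vector of gold labels covering the universe.
#' @return data.frame with columns `pair_id`, `class` (`D`/`N`/`E`) and
#'   `subclass` (`PD`/`ND`/`PE`/`NE`/`neutral`).
#' @export
combine_settings <- function(difficult_cv, easy_cv, difficult_cl, easy_cl,
                             gold) {
  if (length(intersect(difficult_cv, easy_cv))) {
    stop("difficult and easy CV sets overlap")
  }
  if (length(intersect(difficult_cl, easy_cl))) {
    stop("difficult and easy CL sets overlap")
  }
  universe <- names(gold)
  outside <- setdiff(c(difficult_cv, easy_cv, difficult_cl, easy_cl),
                     universe)
  if (length(outside)) {
    stop("set member outside the pair universe: ", outside[1])
  }
  D <- intersect(difficult_cv, difficult_cl)
  E <- intersect(easy_cv, easy_cl)
  cls <- rep("N", length(universe))
  names(cls) <- universe
  cls[D] <- "D"; cls[E] <- "E"
  sub <- ifelse(cls == "N", "neutral",
                paste0(ifelse(gold[universe], "P", "N"), cls))
  data.frame(pair_id = universe, class = unname(cls),
             subclass = unname(sub), stringsAsFactors = FALSE)
}

#' Chi-square test for the overlap of two pair sets
#'
#' Tests whether two subsets of a common universe overlap more than
#' expected under random draws, via Pearson's chi-square on the 2x2
#' membership table without continuity correction. The reported `p` is the
#' upper chi-square(1) tail; `p_one_sided` halves it on the enrichment
#' side. A result is significant when `p < 0.001` and the observed overlap
#' exceeds expectation (enrichment, not depletion).
#'
#' @param A,B character vectors (subsets of the universe) or set sizes when
#'   `overlap` is given.
#' @param N universe size.
#' @param overlap optional observed overlap; when supplied, `A` and `B` are
#'   interpreted as set sizes.
#' @return object of class `overlap_test`: list with `n_a`, `n_b`,
#'   `overlap`, `N`, `expected`, `chi2`, `p`, `p_one_sided`, `significant`.
#' @export
overlap_chi2 <- function(A, B, N, overlap = NULL) {
  if (is.null(overlap)) {
    overlap <- length(intersect(A, B))
    n_a <- length(unique(A)); n_b <- length(unique(B))
  } else {
    n_a <- A; n_b <- B
  }
  if (N <= 0) stop("universe size N must be positive")
  if (n_a == 0 || n_b == 0 || n_a == N || n_b == N) {
    stop("degenerate 2x2 table: a set is empty or equals the universe")
  }
  if (overlap > min(n_a, n_b)) stop("overlap exceeds the smaller set")
  a <- overlap
  b <- n_a - overlap
  c_ <- n_b - overlap
  d <- N - n_a - n_b + overlap
  if (d < 0) stop("sets larger than the universe")
  expected <- n_a * n_b / N
  obs <- c(a, b, c_, d)
  exp_ <- c(expected, n_a - expected, n_b - expected,
            N - n_a - n_b + expected)
  chi2 <- sum((obs - exp_)^2 / exp_)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  p_one <- if (a >= expected) p / 2 else 1 - p / 2
  structure(list(n_a = n_a, n_b = n_b, overlap = a, N = N,
                 expected = expected, chi2 = chi2, p = p,
                 p_one_sided = p_one,
                 significant = (p < 0.001) && (a > expected)),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "<overlap_test: |A|=%d |B|=%d overlap=%d (expected %.1f) chi2=%.2f p=%.3g%s>\n",
    x$n_a, x$n_b, x$overlap, x$expected, x$chi2, x$p,
    if (x$significant) " *" else ""))
  invisible(x)
}

#' Cross-tabulate CV and CL success levels
#'
#' @param success_cv,success_cl `success_table` objects over the same pair
#'   universe.
#' @return integer matrix of pair counts; rows are CV levels
#'   `0..|roster_CV|`, columns CL levels `0..|roster_CL|`.
#' @export
crosstab_cv_cl <- function(success_cv, success_cl) {
  ids <- names(success_cv$levels)
  if (!setequal(ids, names(success_cl$levels))) {
    stop("CV and CL success tables cover different pair universes")
  }
  k1 <- length(success_cv$roster); k2 <- length(success_cl$roster)
  m <- table(factor(success_cv$levels[ids], levels = 0:k1),
             factor(success_cl$levels[ids], levels = 0:k2))
  out <- matrix(as.integer(m), nrow = k1 + 1L,
                dimnames = list(CV = 0:k1, CL = 0:k2))
  out
}

#' Full difficulty-stratification report over a corpus collection
#'
#' Runs the per-corpus pipeline (success levels, difficult/easy cutoffs in
#' both settings, D/N/E combination, overlap tests) and returns the
#' combined classes together with the per-corpus overlap table.
#'
#' @param corpora named list of [ppi_corpus()] objects.
#' @param predictions_cv,predictions_cl [prediction_set()] objects pooled
#'   over the corpora.
#' @param fraction target per-side fraction, default 0.10.
#' @return list with `classes` (data.frame over all pairs: `pair_id`,
#'   `corpus`, `class`, `subclass`), `overlaps` (data.frame of per-corpus
#'   overlap tests for D and E) and `sets` (per-corpus per-setting
#'   [difficulty_sets()]).
#' @export
stratify_difficulty <- function(corpora, predictions_cv, predictions_cl,
                                fraction = 0.10) {
  classes <- list(); overlaps <- list(); sets <- list()
  for (nm in names(corpora)) {
    gold <- gold_labels(corpora[[nm]])
    scv <- compute_success_levels(gold, predictions_cv)
    scl <- compute_success_levels(gold, predictions_cl)
    dcv <- difficulty_sets(scv, fraction)
    dcl <- difficulty_sets(scl, fraction)
    sets[[nm]] <- list(CV = dcv, CL = dcl)
    cls <- combine_settings(dcv$difficult$ids, dcv$easy$ids,
                            dcl$difficult$ids, dcl$easy$ids, gold)
    cls$corpus <- nm
    classes[[nm]] <- cls
    N <- length(gold)
    ov <- lapply(list(D = list(dcv$difficult$ids, dcl$difficult$ids),
                      E = list(dcv$easy$ids, dcl$easy$ids)),
                 function(ab) {
                   res <- tryCatch(overlap_chi2(ab[[1]], ab[[2]], N),
                                   error = function(e) NULL)
                   res
                 })
    for (side in names(ov)) {
      if (is.null(ov[[side]])) next
      o <- ov[[side]]
      overlaps[[paste(nm, side)]] <- data.frame(
        corpus = nm, side = side, n_cv = o$n_a, n_cl = o$n_b,
        overlap = o$overlap, expected = o$expected, chi2 = o$chi2,
        p = o$p, significant = o$significant, stringsAsFactors = FALSE)
    }
  }
  list(classes = do.call(rbind, c(classes, list(make.row.names = FALSE))),
       overlaps = do.call(rbind, c(overlaps, list(make.row.names = FALSE))),
       sets = sets)
}
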