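# Instance-level classifier similarity, hierarchical clustering, and
# Newick dendrogram export.

#' Prediction agreement between two classifiers
#'
#' The fraction of commonly covered pairs on which two classifiers emit
#' the identical predicted label (gold labels play no role).
#'
#' @param predictions a [prediction_set()].
#' @param c1,c2 classifier ids.
#' @return agreement fraction in `[0, 1]`.
#' @export
pairwise_agreement <- function(predictions, c1, c2) {
  if (!nrow(predictions$table)) stop("no common pairs")
  mean(predictions$table[, c1] == predictions$table[, c2])
}

#' Full pairwise agreement matrix
#'
#' @param predictions a [prediction_set()] with at least two classifiers.
#' @return symmetric matrix of agreement fractions with unit diagonal,
#'   rows/columns ordered by classifier id.
#' @export
agreement_matrix <- function(predictions) {
  roster <- sort(predictions$roster)
  m <- predictions$table[, roster, drop = FALSE] * 1
  n <- nrow(m)
  agree <- (t(m) %*% m + t(1 - m) %*% (1 - m)) / n
  agree
}

#' Cluster classifiers by prediction agreement
#'
#' Agglomerative hierarchical clustering on the distance `1 - agreement`.
#' Classifiers are ordered lexicographically by id before clustering so
#' merge tie-breaking is deterministic.
#'
#' @param matrix agreement matrix from [agreement_matrix()].
#' @param linkage `"complete"` (default) or `"average"`.
#' @return an [stats::hclust] tree; merge heights are in distance units.
#' @export
cluster_classifiers <- function(matrix, linkage = c("complete", "average")) {
  linkage <- match.arg(linkage)
  if (nrow(matrix) < 2) stop("need at least two classifiers to cluster")
  ord <- order(rownames(matrix))
  d <- stats::as.dist(1 - matrix[ord, ord])
  stats::hclust(d, method = linkage)
}

#' Export a classifier dendrogram as a Newick string
#'
#' Branch lengths are height differences between merges, so leaf-to-root
#' path lengths equal the root merge height.
#'
#' @param tree an [stats::hclust] object (see [cluster_classifiers()]).
#' @return single Newick string (terminated by `;`).
#' @export
to_newick <- function(tree) {
  phy <- ape::as.phylo(tree)
  # as.phylo() halves merge heights (cophenetic convention); restore
  # height-difference branch lengths so a leaf merged at height h carries h
  phy$edge.length <- phy$edge.length * 2
  ape::write.tree(phy)
}
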