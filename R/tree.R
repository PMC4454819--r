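# Gain-ratio decision tree (C4.5-style) on binary surface-group features.
#
# Cluster membership is explained from the presence/absence of four surface
# functional groups (TMAT, phosphate, phosphatidylcholine, amine). Splits are
# chosen greedily by gain ratio (information gain divided by split
# information, in bits); induction stops at pure nodes or when no split has
# positive gain. With four binary features and two classes the tree is at
# most four levels deep and pessimistic pruning buys nothing, so no pruning
# is applied.

entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Induce a gain-ratio decision tree on binary features
#'
#' Greedy top-down induction: at each node the unused feature with the
#' largest gain ratio (among features with positive information gain and a
#' non-degenerate split) becomes the split; recursion stops at pure nodes or
#' when no admissible split remains, leaving a majority-label leaf (ties
#' label "A"). Each feature is used at most once per root-to-leaf path.
#'
#' @param features Data.frame or matrix of logical/0-1 features, rownames (or
#'   `ids`) identifying the materials.
#' @param labels Character/factor vector of class labels (e.g. "A"/"B")
#'   aligned with `features` rows.
#' @param ids Optional character vector of ids; defaults to rownames.
#' @return An object of class `ez_tree` (nested list of `split`/`leaf`
#'   nodes).
#' @export
build_tree <- function(features, labels, ids = NULL) {
  features <- as.data.frame(features)
  if (is.null(ids)) ids <- rownames(features)
  labels <- as.character(labels)
  if (nrow(features) < 1 || length(labels) != nrow(features)) {
    stop("features and labels must be nonempty and aligned", call. = FALSE)
  }
  for (f in names(features)) features[[f]] <- parse_flag(features[[f]], f)
  classes <- sort(unique(labels))
  grow <- function(rows, avail) {
    labs <- labels[rows]
    counts <- table(factor(labs, levels = classes))
    majority <- names(counts)[which.max(counts)]  # ties: first = "A" side
    if (length(unique(labs)) == 1 || length(avail) == 0) {
      return(list(type = "leaf", label = majority, counts = counts))
    }
    h_parent <- entropy_bits(as.numeric(counts))
    best_f <- NULL; best_ratio <- 0
    for (f in avail) {
      on <- rows[features[[f]][rows]]
      off <- setdiff(rows, on)
      if (length(on) == 0 || length(off) == 0) next
      p_on <- length(on) / length(rows)
      h_split <- p_on * entropy_bits(table(labels[on])) +
        (1 - p_on) * entropy_bits(table(labels[off]))
      gain <- h_parent - h_split
      if (gain <= 1e-12) next
      split_info <- entropy_bits(c(length(on), length(off)))
      ratio <- gain / split_info
      if (ratio > best_ratio + 1e-12) { best_ratio <- ratio; best_f <- f }
    }
    if (is.null(best_f)) {
      return(list(type = "leaf", label = majority, counts = counts))
    }
    on <- rows[features[[best_f]][rows]]
    off <- setdiff(rows, on)
    list(type = "split", feature = best_f, counts = counts,
         branch_false = grow(off, setdiff(avail, best_f)),
         branch_true = grow(on, setdiff(avail, best_f)))
  }
  structure(list(root = grow(seq_len(nrow(features)), names(features)),
                 features = names(features), classes = classes),
            class = "ez_tree")
}

#' Predict class labels from a gain-ratio tree
#'
#' @param object An `ez_tree` from [build_tree()].
#' @param newdata Data.frame of the same binary features.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.ez_tree <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  for (f in object$features) {
    if (!f %in% names(newdata)) {
      stop("newdata lacks feature '", f, "'", call. = FALSE)
    }
    newdata[[f]] <- parse_flag(newdata[[f]], f)
  }
  one <- function(node, row) {
    if (node$type == "leaf") return(node$label)
    if (newdata[[node$feature]][row]) one(node$branch_true, row)
    else one(node$branch_false, row)
  }
  vapply(seq_len(nrow(newdata)), function(r) one(object$root, r), "")
}

#' Maximum depth of a tree (root at depth 0)
#' @param tree An `ez_tree`.
#' @return Integer depth.
#' @export
tree_depth <- function(tree) {
  dep <- function(node) {
    if (node$type == "leaf") return(0L)
    1L + max(dep(node$branch_false), dep(node$branch_true))
  }
  dep(tree$root)
}

#' Cross-validated accuracy of the surface-group classifier
#'
#' Evaluates [build_tree()] by leave-one-out or stratified k-fold
#' cross-validation: for each fold a tree is grown on the training split and
#' the held-out materials are predicted. A training fold containing a single
#' class simply yields a majority-leaf tree. Leave-one-out is deterministic
#' and needs no seed; k-fold stratifies fold assignment within each class
#' from `seed`.
#'
#' @inheritParams build_tree
#' @param scheme `"loo"` (default) or `"kfold"`.
#' @param k Number of folds for `scheme = "kfold"` (default 10).
#' @param seed Integer seed for stratified fold assignment (k-fold only).
#' @return List of class `ez_cv`: `scheme`, `k`, `accuracy`, `misclassified`
#'   (material ids), `n`, `seed`.
#' @export
cross_validate <- function(features, labels, scheme = c("loo", "kfold"),
                           k = 10, seed = NULL, ids = NULL) {
  scheme <- match.arg(scheme)
  features <- as.data.frame(features)
  labels <- as.character(labels)
  n <- nrow(features)
  if (is.null(ids)) ids <- rownames(features)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (scheme == "loo") {
    fold <- seq_len(n)
    k_used <- n
  } else {
    if (n < k) stop("need at least k observations for k-fold CV",
                    call. = FALSE)
    fold <- integer(n)
    if (!is.null(seed)) set.seed(seed)
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    k_used <- k
  }
  pred <- character(n)
  for (f in unique(fold)) {
    test <- which(fold == f)
    train <- setdiff(seq_len(n), test)
    tr <- build_tree(features[train, , drop = FALSE], labels[train])
    pred[test] <- predict(tr, features[test, , drop = FALSE])
  }
  wrong <- ids[pred != labels]
  structure(list(scheme = scheme, k = k_used,
                 accuracy = 1 - length(wrong) / n,
                 misclassified = wrong, n = n, seed = seed),
            class = "ez_cv")
}
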