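# Clustering of EZ concentration profiles.
#
# Materials are clustered on their score vectors over a common concentration
# grid with agglomerative Ward linkage on Euclidean distances, implemented
# through the Lance-Williams recurrence. Merge heights are reported as the
# Ward merge cost, i.e. the increase in within-cluster sum of squares caused
# by the merge (dendrogram software disagrees on height conventions; the
# two-cluster cut used downstream is convention-independent). Ties are broken
# deterministically by the smallest active pair of row indices.

#' Align concentration profiles on a common grid
#'
#' Builds the materials-by-concentrations score matrix used for clustering.
#' Cells absent from a profile are handled per `fill`: `"error"` rejects the
#' input, `"zero"` fills 0 with a warning, `"interpolate"` fills interior
#' gaps linearly on the log10-concentration axis (gaps at the grid edge are
#' an error).
#'
#' @param profiles Named list of `ez_profile` objects.
#' @param grid Ordered treatment concentrations (ppm) to align on; defaults
#'   to the sorted union of all treatment concentrations observed.
#' @param fill Missing-cell policy: `"error"` (default), `"zero"`, or
#'   `"interpolate"`.
#' @return Numeric matrix, one row per material (rownames = material ids),
#'   one column per grid concentration.
#' @export
profile_matrix <- function(profiles, grid = NULL,
                           fill = c("error", "zero", "interpolate")) {
  fill <- match.arg(fill)
  if (is.null(grid)) {
    grid <- sort(unique(unlist(lapply(profiles, function(p)
      p$concentration[p$concentration > 0]))))
  }
  grid <- sort(unique(as.numeric(grid)))
  if (any(grid <= 0)) stop("grid concentrations must be positive",
                           call. = FALSE)
  rows <- lapply(profiles, function(p) {
    treat <- p[p$concentration > 0, , drop = FALSE]
    v <- treat$score[match(grid, treat$concentration)]
    miss <- which(is.na(v))
    if (length(miss) > 0) {
      if (fill == "error") {
        stop("material '", attr(p, "material_id"),
             "' lacks score(s) at concentration(s): ",
             paste(grid[miss], collapse = ", "), call. = FALSE)
      } else if (fill == "zero") {
        warning("filling ", length(miss), " missing cell(s) with 0 for '",
                attr(p, "material_id"), "'")
        v[miss] <- 0
      } else {
        if (any(miss == 1) || any(miss == length(grid)) ||
            nrow(treat) < 2) {
          stop("cannot interpolate a gap at the grid edge for '",
               attr(p, "material_id"), "'", call. = FALSE)
        }
        v[miss] <- stats::approx(log10(treat$concentration), treat$score,
                                 xout = log10(grid[miss]))$y
      }
    }
    v
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- names(profiles)
  colnames(mat) <- as.character(grid)
  mat
}

#' Agglomerative Ward clustering of profile rows
#'
#' Ward-linkage hierarchical clustering on Euclidean distances between the
#' rows of a profile matrix, via the Lance-Williams recurrence on the exact
#' Ward merge cost: initial pair costs are half the squared Euclidean
#' distance, and each reported height is the increase in total within-cluster
#' sum of squares caused by that merge. At every step the cheapest merge is
#' taken; cost ties resolve to the smallest (first, then second) active
#' cluster index, so the result is deterministic and row-order invariant up
#' to relabeling when costs are distinct.
#'
#' @param x Numeric matrix (materials x grid), no missing values.
#' @return An `hclust`-compatible object (also class `ez_dendrogram`) whose
#'   `height` component holds the Ward merge costs; usable with
#'   [stats::cutree()], `plot()`, and [write_dendrogram_newick()].
#' @export
ward_cluster <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 rows to cluster", call. = FALSE)
  if (any(!is.finite(x))) stop("profile matrix has non-finite entries",
                               call. = FALSE)
  labs <- rownames(x)
  if (is.null(labs)) labs <- as.character(seq_len(n))
  D <- as.matrix(stats::dist(x))^2 / 2  # Ward cost of merging two singletons
  size <- rep(1, n)
  code <- -seq_len(n)                   # hclust coding of active clusters
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (k in seq_len(n - 1)) {
    act <- which(active)
    best_i <- 0L; best_j <- 0L; best <- Inf
    for (ai in seq_len(length(act) - 1)) {
      i <- act[ai]
      for (aj in (ai + 1):length(act)) {
        j <- act[aj]
        if (D[i, j] < best) { best <- D[i, j]; best_i <- i; best_j <- j }
      }
    }
    i <- best_i; j <- best_j
    pair <- c(code[i], code[j])
    # hclust convention: singletons (negative) before merged clusters,
    # otherwise ascending
    pair <- pair[order(pair >= 0, abs(pair))]
    merge[k, ] <- pair
    height[k] <- best
    ni <- size[i]; nj <- size[j]
    for (m in act) {
      if (m == i || m == j) next
      nm <- size[m]
      D[i, m] <- D[m, i] <-
        ((ni + nm) * D[i, m] + (nj + nm) * D[j, m] - nm * best) /
        (ni + nj + nm)
    }
    size[i] <- ni + nj
    active[j] <- FALSE
    code[i] <- k
  }
  # leaf ordering by left-to-right traversal of the merge tree
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  structure(list(merge = merge, height = height,
                 order = if (n == 2) 1:2 else expand(n - 1),
                 labels = labs, method = "ward",
                 dist.method = "euclidean", call = match.call()),
            class = c("ez_dendrogram", "hclust"))
}

#' Members of each subtree of a dendrogram node
#'
#' Returns the dendrogram as a nested node list: each node carries its
#' member labels, its merge height (0 at leaves), and its two children.
#'
#' @param hc An `hclust`-compatible object from [ward_cluster()].
#' @return Nested list with fields `members`, `height`, `children`.
#' @export
dendrogram_tree <- function(hc) {
  node <- function(code) {
    if (code < 0) {
      list(members = hc$labels[-code], height = 0, children = NULL)
    } else {
      left <- node(hc$merge[code, 1])
      right <- node(hc$merge[code, 2])
      list(members = c(left$members, right$members),
           height = hc$height[code], children = list(left, right))
    }
  }
  node(nrow(hc$merge))
}

#' Export a dendrogram as Newick
#'
#' Serializes the clustering through [ape::as.phylo()] (branch lengths derive
#' from merge-height differences).
#'
#' @param hc An `hclust`-compatible object from [ward_cluster()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  class(hc) <- "hclust"
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Cut a dendrogram into its two top-level clusters
#'
#' Splits at the root merge and labels the two subtrees A and B, with B
#' assigned to the cluster of larger mean summed EZ score (the more toxic
#' group). If the means tie exactly, B goes to the cluster containing the
#' lexicographically smallest material id, with a warning. Per-cluster
#' summaries of the summed scores (min, quartiles, mean, max) are returned
#' alongside.
#'
#' @param hc An `hclust`-compatible object from [ward_cluster()].
#' @param sumez Named numeric vector of summed EZ scores (see [sum_ez()]),
#'   names covering the dendrogram labels.
#' @return List with `assignment` (named character vector of "A"/"B"),
#'   `summary` (data.frame of per-cluster sumEZ statistics) and `means`
#'   (named numeric).
#' @export
cut_two <- function(hc, sumez) {
  if (length(hc$labels) < 2) stop("degenerate dendrogram", call. = FALSE)
  missing <- setdiff(hc$labels, names(sumez))
  if (length(missing) > 0) {
    stop("sumez lacks value(s) for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ct <- stats::cutree(structure(unclass(hc), class = "hclust"), k = 2)
  g1 <- names(ct)[ct == 1]
  g2 <- names(ct)[ct == 2]
  m1 <- mean(sumez[g1]); m2 <- mean(sumez[g2])
  if (m1 == m2) {
    warning("cluster mean sumEZ tie; labeling by smallest material id")
    b_first <- min(g1) < min(g2)
    groups <- if (b_first) list(B = g1, A = g2) else list(B = g2, A = g1)
  } else {
    groups <- if (m2 > m1) list(A = g1, B = g2) else list(A = g2, B = g1)
  }
  assignment <- c(
    stats::setNames(rep("A", length(groups$A)), groups$A),
    stats::setNames(rep("B", length(groups$B)), groups$B)
  )[hc$labels]
  summ <- do.call(rbind, lapply(c("A", "B"), function(lab) {
    v <- sumez[groups[[lab]]]
    data.frame(cluster = lab, n = length(v), min = min(v),
               q1 = unname(stats::quantile(v, 0.25)),
               median = stats::median(v),
               q3 = unname(stats::quantile(v, 0.75)),
               mean = mean(v), max = max(v), stringsAsFactors = FALSE)
  }))
  list(assignment = assignment, summary = summ,
       means = c(A = mean(sumez[groups$A]), B = mean(sumez[groups$B])))
}
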