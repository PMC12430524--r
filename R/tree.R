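#' Gini impurity of a two-class count vector
#'
#' \code{1 - sum(p_k^2)}: the probability that a randomly drawn element of
#' the node is misclassified by a random draw from the node's label
#' distribution. For two classes the value lies in [0, 0.5].
#'
#' @param class_counts nonnegative counts per class, not all zero.
#' @return impurity value.
#' @export
#' @examples
#' gini_impurity(c(3, 1))  # 0.375
gini_impurity <- function(class_counts) {
  if (any(class_counts < 0) || sum(class_counts) == 0) {
    stop("gini_impurity(): counts must be nonnegative and not all zero")
  }
  p <- class_counts / sum(class_counts)
  1 - sum(p^2)
}

#' Best Gini split of one feature column
#'
#' Exhaustive scan over the midpoints of consecutive distinct sorted
#' values, returning the threshold that minimises the sample-weighted mean
#' Gini impurity of the two children. Ties are broken toward the smaller
#' threshold. A constant column has no admissible split and returns the
#' no-split sentinel (\code{NULL}).
#'
#' @param values numeric feature column.
#' @param labels 0/1 class labels, same length.
#' @param min_leaf smallest admissible child size (default 1).
#' @return list with \code{threshold} and \code{impurity} (weighted child
#'   Gini), or \code{NULL} if no admissible split exists.
#' @export
best_split <- function(values, labels, min_leaf = 1L) {
  n <- length(values)
  stopifnot(n == length(labels), n >= 2L)
  ord <- order(values)
  v <- values[ord]
  y <- labels[ord]
  cut_after <- which(v[-n] < v[-1])           # boundaries between distinct values
  if (length(cut_after) == 0L) return(NULL)   # constant column
  nl <- cut_after
  nr <- n - nl
  ok <- nl >= min_leaf & nr >= min_leaf
  if (!any(ok)) return(NULL)
  c1l <- cumsum(y)[cut_after]                 # class-1 count left of boundary
  c0l <- nl - c1l
  c1r <- sum(y) - c1l
  c0r <- nr - c1r
  # weighted child Gini w = 1 - score/n with score = Al/nl + Ar/nr,
  # A = c0^2 + c1^2. Ranking by the rational (Al*nr + Ar*nl)/(nl*nr) keeps
  # integer arithmetic exact (counts <= n, products < 2^53), so
  # mathematically tied splits compare as exactly equal doubles and the
  # first maximum is the smallest threshold.
  num <- (c0l^2 + c1l^2) * nr + (c0r^2 + c1r^2) * nl
  score <- num / (nl * nr)
  score[!ok] <- -Inf
  i <- which.max(score)
  list(threshold = (v[cut_after[i]] + v[cut_after[i] + 1L]) / 2,
       impurity = 1 - score[i] / n)
}

#' Fit a Gini decision tree on a dihedral matrix
#'
#' Recursive binary partitioning on the labeled rows of \code{matrix}. At
#' each node every allowed feature is scanned exhaustively with
#' \code{\link{best_split}}; the (feature, threshold) pair with the
#' smallest weighted child impurity wins, with ties broken by the canonical
#' feature order (ascending residue number, phi before psi). Splitting
#' stops at \code{max_depth}, node purity, node size below
#' \code{2 * min_leaf}, or when no split reduces impurity.
#'
#' @param matrix a \code{DihedralMatrix} (or a plain list with an
#'   \code{angles} matrix and \code{class} vector).
#' @param features character vector of allowed feature names (default: all
#'   columns).
#' @param max_depth maximum tree depth in splits (default 2, matching the
#'   two-angles-per-tree selection design).
#' @param min_leaf minimum frames per leaf (default 5).
#' @param mtry number of features sampled at each node (default: all).
#'   Sampling uses the current RNG stream; seed externally for
#'   reproducibility.
#' @return object of class \code{DecisionTree}: a nested node list with
#'   \code{feature}, \code{threshold}, \code{counts} (class 0/1 counts),
#'   \code{left}/\code{right} or \code{leaf = TRUE} with majority
#'   \code{label}.
#' @export
fit_tree <- function(matrix, features = NULL, max_depth = 2L, min_leaf = 5L,
                     mtry = NULL) {
  ang <- matrix$angles
  cls <- matrix$class
  keep <- !is.na(cls)
  ang <- ang[keep, , drop = FALSE]
  cls <- cls[keep]
  if (length(cls) == 0L) stop("fit_tree(): no labeled rows")
  if (is.null(features)) features <- colnames(ang)
  miss <- setdiff(features, colnames(ang))
  if (length(miss) > 0) {
    stop(sprintf("fit_tree(): unknown feature(s): %s",
                 paste(miss, collapse = ", ")))
  }
  features <- canonical_feature_order(features)
  node <- grow_node(ang, cls, features, depth = 0L, max_depth = max_depth,
                    min_leaf = min_leaf, mtry = mtry)
  structure(list(root = node, features = features, max_depth = max_depth,
                 min_leaf = min_leaf),
            class = "DecisionTree")
}

grow_node <- function(ang, cls, features, depth, max_depth, min_leaf, mtry) {
  counts <- c(sum(cls == 0L), sum(cls == 1L))
  leaf <- function() {
    list(leaf = TRUE, counts = counts,
         label = if (counts[2] > counts[1]) 1L else 0L)
  }
  if (depth >= max_depth || min(counts) == 0L ||
      sum(counts) < 2L * min_leaf) {
    return(leaf())
  }
  cand <- features
  if (!is.null(mtry) && mtry < length(features)) {
    cand <- features[sort(sample.int(length(features), mtry))]
    cand <- canonical_feature_order(cand)
  }
  parent_g <- gini_impurity(counts)
  best <- NULL
  for (f in cand) {           # canonical order; strict improvement keeps ties on first
    s <- best_split(ang[, f], cls, min_leaf = min_leaf)
    if (!is.null(s) && (is.null(best) || s$impurity < best$impurity)) {
      best <- c(s, list(feature = f))
    }
  }
  if (is.null(best) || best$impurity >= parent_g) return(leaf())
  go_left <- ang[, best$feature] <= best$threshold
  list(
    leaf = FALSE, feature = best$feature, threshold = best$threshold,
    counts = counts, impurity = parent_g, child_impurity = best$impurity,
    left = grow_node(ang[go_left, , drop = FALSE], cls[go_left], features,
                     depth + 1L, max_depth, min_leaf, mtry),
    right = grow_node(ang[!go_left, , drop = FALSE], cls[!go_left], features,
                      depth + 1L, max_depth, min_leaf, mtry)
  )
}

#' Predict class labels with a decision tree
#'
#' @param object a \code{DecisionTree}.
#' @param newdata numeric matrix with named columns covering the tree's
#'   features, or a \code{DihedralMatrix}.
#' @param ... unused.
#' @return integer vector of 0/1 labels, one per row.
#' @export
predict.DecisionTree <- function(object, newdata, ...) {
  ang <- if (inherits(newdata, "DihedralMatrix")) newdata$angles else newdata
  out <- integer(nrow(ang))
  recurse <- function(node, idx) {
    if (length(idx) == 0L) return()
    if (isTRUE(node$leaf)) {
      out[idx] <<- node$label
      return()
    }
    go_left <- ang[idx, node$feature] <= node$threshold
    recurse(node$left, idx[go_left])
    recurse(node$right, idx[!go_left])
  }
  recurse(object$root, seq_len(nrow(ang)))
  out
}

#' Features a decision tree splits on
#'
#' @param tree a \code{DecisionTree}.
#' @return character vector of distinct split feature names, in canonical
#'   order.
#' @export
tree_split_features <- function(tree) {
  feats <- character(0)
  walk <- function(node) {
    if (isTRUE(node$leaf)) return()
    feats <<- c(feats, node$feature)
    walk(node$left); walk(node$right)
  }
  walk(tree$root)
  canonical_feature_order(unique(feats))
}

#' @export
print.DecisionTree <- function(x, ...) {
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (isTRUE(node$leaf)) {
      cat(sprintf("%sleaf: label=%d counts=(%d S, %d R)\n", pad, node$label,
                  node$counts[1], node$counts[2]))
    } else {
      cat(sprintf("%s%s <= %.4f  [gini %.4f -> %.4f]\n", pad, node$feature,
                  node$threshold, node$impurity, node$child_impurity))
      show(node$left, indent + 1L)
      show(node$right, indent + 1L)
    }
  }
  cat("DecisionTree\n")
  show(x$root, 1L)
  invisible(x)
}

#' Training accuracy of a tree on its matrix
#'
#' @param tree a \code{DecisionTree}.
#' @param matrix the \code{DihedralMatrix} it was fit on.
#' @return fraction of labeled frames predicted correctly.
#' @export
tree_training_accuracy <- function(tree, matrix) {
  keep <- !is.na(matrix$class)
  mean(predict(tree, matrix$angles[keep, , drop = FALSE]) ==
         matrix$class[keep])
}
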