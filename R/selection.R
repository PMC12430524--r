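#' Iterative decision-tree feature selection
#'
#' The selection mechanism of the pipeline: fit a shallow Gini tree on all
#' remaining features, harvest the distinct dihedrals it splits on, remove
#' them from the pool, and repeat. Each round's harvest is one small set of
#' discriminative angles; the per-round sets are pairwise disjoint by
#' construction.
#'
#' @param matrix a \code{DihedralMatrix} with both classes present.
#' @param n_rounds number of trees/rounds to fit (>= 1).
#' @param max_depth depth of each selection tree (default 2, giving up to
#'   about two distinct angles per round).
#' @param min_leaf minimum frames per leaf (default 5).
#' @param features optional starting feature pool (default: all columns).
#' @return object of class \code{SelectionResult}: list of rounds, each
#'   with the fitted \code{tree}, the \code{selected} feature names, the
#'   training \code{gini_before}/\code{gini_after} and training
#'   \code{accuracy}; plus the cumulative \code{excluded} set.
#' @export
iterative_selection <- function(matrix, n_rounds = 3L, max_depth = 2L,
                                min_leaf = 5L, features = NULL) {
  stopifnot(n_rounds >= 1L)
  if (length(unique(stats::na.omit(matrix$class))) < 2L) {
    stop("iterative_selection(): both classes must be present")
  }
  pool <- if (is.null(features)) colnames(matrix$angles) else features
  pool <- canonical_feature_order(pool)
  rounds <- list()
  excluded <- character(0)
  for (r in seq_len(n_rounds)) {
    if (length(pool) == 0L) {
      warning(sprintf("iterative_selection(): feature pool exhausted after %d round(s)",
                      r - 1L))
      break
    }
    tree <- fit_tree(matrix, features = pool, max_depth = max_depth,
                     min_leaf = min_leaf)
    sel <- tree_split_features(tree)
    if (length(sel) == 0L) {
      warning(sprintf("iterative_selection(): round %d tree found no admissible split; stopping",
                      r))
      break
    }
    rounds[[r]] <- list(
      round = r,
      tree = tree,
      selected = sel,
      gini_before = gini_impurity(tree$root$counts),
      gini_after = leaf_weighted_gini(tree),
      accuracy = tree_training_accuracy(tree, matrix)
    )
    excluded <- c(excluded, sel)
    pool <- setdiff(pool, sel)
  }
  structure(list(rounds = rounds, excluded = excluded),
            class = "SelectionResult")
}

# Sample-weighted Gini impurity over the leaves of a fitted tree.
leaf_weighted_gini <- function(tree) {
  total <- sum(tree$root$counts)
  acc <- 0
  walk <- function(node) {
    if (isTRUE(node$leaf)) {
      acc <<- acc + sum(node$counts) / total * gini_impurity(node$counts)
    } else {
      walk(node$left); walk(node$right)
    }
  }
  walk(tree$root)
  acc
}

#' Selected features of chosen rounds
#'
#' @param selection a \code{SelectionResult}.
#' @param rounds integer vector of round indices (default: all).
#' @return character vector, union of the rounds' selected features in
#'   canonical order.
#' @export
selected_features <- function(selection, rounds = NULL) {
  if (is.null(rounds)) rounds <- seq_along(selection$rounds)
  if (any(rounds < 1L | rounds > length(selection$rounds))) {
    stop("selected_features(): round index out of range")
  }
  canonical_feature_order(unique(unlist(
    lapply(selection$rounds[rounds], `[[`, "selected"))))
}

#' @export
print.SelectionResult <- function(x, ...) {
  cat(sprintf("SelectionResult: %d round(s)\n", length(x$rounds)))
  for (r in x$rounds) {
    cat(sprintf("  round %d: %s  (gini %.4f -> %.4f, training accuracy %.3f)\n",
                r$round, paste(r$selected, collapse = ", "),
                r$gini_before, r$gini_after, r$accuracy))
  }
  invisible(x)
}

#' Serialize a SelectionResult to JSON
#'
#' @param selection a \code{SelectionResult}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_selection_json <- function(selection, path) {
  payload <- lapply(selection$rounds, function(r) {
    list(round = r$round, selected = r$selected,
         gini_before = r$gini_before, gini_after = r$gini_after,
         accuracy = r$accuracy, splits = flatten_splits(r$tree$root))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

flatten_splits <- function(node) {
  if (isTRUE(node$leaf)) return(list())
  c(list(list(feature = node$feature, threshold = node$threshold)),
    flatten_splits(node$left), flatten_splits(node$right))
}
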