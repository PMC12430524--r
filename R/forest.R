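#' Train a random forest on a fixed dihedral feature list
#'
#' An ensemble of Gini decision trees fit on bootstrap resamples of the
#' labeled frames, each restricted to the declared feature list with
#' per-node feature subsampling (\code{mtry}). A frame's prediction is the
#' majority vote over trees; exact vote ties go to the sensitive class (0),
#' the non-flagging call. Fully reproducible for a fixed seed.
#'
#' @param matrix a \code{DihedralMatrix} with both classes among labeled
#'   rows.
#' @param features feature list the forest may use (nonempty).
#' @param n_trees trees in the ensemble (default 100).
#' @param seed integer seed (required: every training run is stochastic).
#' @param max_depth per-tree depth cap (default 5).
#' @param min_leaf minimum frames per leaf (default 5).
#' @param mtry features sampled per node (default
#'   \code{max(1, floor(sqrt(p)))}).
#' @param bootstrap resample rows with replacement (default TRUE; with
#'   \code{n_trees = 1} and \code{bootstrap = FALSE} the forest equals the
#'   single fitted tree).
#' @return object of class \code{ForestModel}.
#' @export
train_forest <- function(matrix, features, n_trees = 100L, seed,
                         max_depth = 5L, min_leaf = 5L, mtry = NULL,
                         bootstrap = TRUE) {
  if (missing(seed)) stop("train_forest(): a seed is required")
  if (length(features) == 0L) stop("train_forest(): empty feature list")
  miss <- setdiff(features, colnames(matrix$angles))
  if (length(miss) > 0) {
    stop(sprintf("train_forest(): feature(s) not in matrix: %s",
                 paste(miss, collapse = ", ")))
  }
  keep <- which(!is.na(matrix$class))
  if (length(unique(matrix$class[keep])) < 2L) {
    stop("train_forest(): training rows must contain both classes")
  }
  features <- canonical_feature_order(features)
  # restrict to the declared feature columns once: bootstraps then copy
  # only the small feature block, not the full dihedral matrix
  ang <- matrix$angles[keep, features, drop = FALSE]
  cls <- matrix$class[keep]
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(length(features))))
  set.seed(seed)
  n <- nrow(ang)
  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    rows <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
    trees[[t]] <- fit_tree(list(angles = ang[rows, , drop = FALSE],
                                class = cls[rows]),
                           features = features,
                           max_depth = max_depth, min_leaf = min_leaf,
                           mtry = mtry)
  }
  structure(list(trees = trees, features = features, n_trees = n_trees,
                 seed = seed, max_depth = max_depth, min_leaf = min_leaf,
                 mtry = mtry, bootstrap = bootstrap),
            class = "ForestModel")
}

#' @export
print.ForestModel <- function(x, ...) {
  cat(sprintf("ForestModel: %d trees on {%s} (max_depth %d, mtry %d, seed %d)\n",
              x$n_trees, paste(x$features, collapse = ", "), x$max_depth,
              x$mtry, x$seed))
  invisible(x)
}

#' Fraction of trees voting resistant, per frame
#'
#' The forest's continuous output: for each row, the fraction of member
#' trees voting class 1 (resistant). The hard frame label is
#' \code{vote > 0.5} (exact ties go sensitive).
#'
#' @param model a \code{ForestModel}.
#' @param newdata numeric matrix with named columns, or a
#'   \code{DihedralMatrix}.
#' @return numeric vector in [0, 1], one value per row.
#' @export
forest_vote_fraction <- function(model, newdata) {
  ang <- if (inherits(newdata, "DihedralMatrix")) newdata$angles else newdata
  votes <- numeric(nrow(ang))
  for (tr in model$trees) votes <- votes + predict(tr, ang)
  votes / length(model$trees)
}

#' Predict frame labels with a forest
#'
#' @param object a \code{ForestModel}.
#' @param newdata matrix or \code{DihedralMatrix}.
#' @param ... unused.
#' @return integer 0/1 labels per row (majority of trees; ties -> 0).
#' @export
predict.ForestModel <- function(object, newdata, ...) {
  as.integer(forest_vote_fraction(object, newdata) > 0.5)
}

#' Aggregate one variant's frame votes to a variant-level call
#'
#' Majority vote over the variant's frames; an exact 50/50 split is called
#' sensitive (a resistant call should require a strict majority, as it
#' triggers clinical action) and flagged low-confidence.
#'
#' @param model a \code{ForestModel}.
#' @param frames the variant's frames: \code{FrameSet},
#'   \code{DihedralMatrix} rows, or plain matrix.
#' @param variant variant name (taken from the FrameSet if absent).
#' @return object of class \code{VariantPrediction}: list with
#'   \code{variant}, \code{label} ("S"/"R"), \code{vote_fraction} (fraction
#'   of frames supporting the call, in [0.5, 1]), \code{frame_labels} and
#'   \code{low_confidence}.
#' @export
predict_variant <- function(model, frames, variant = NULL) {
  if (inherits(frames, "FrameSet")) {
    if (is.null(variant)) variant <- frames$variant
    frames <- as_angles(frames)$angles
  } else if (inherits(frames, "DihedralMatrix")) {
    if (is.null(variant)) variant <- unique(frames$variant)[1]
    frames <- frames$angles
  }
  if (nrow(frames) == 0L) stop("predict_variant(): zero frames")
  fl <- predict(model, frames)
  n_r <- sum(fl == 1L)
  n <- length(fl)
  label <- if (n_r > n / 2) "R" else "S"
  frac <- max(n_r, n - n_r) / n
  structure(list(variant = variant %||% "unknown", label = label,
                 vote_fraction = frac, frame_labels = fl,
                 low_confidence = (2 * n_r == n)),
            class = "VariantPrediction")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.VariantPrediction <- function(x, ...) {
  cat(sprintf("VariantPrediction '%s': %s (%.1f%% of %d frames%s)\n",
              x$variant, x$label, 100 * x$vote_fraction,
              length(x$frame_labels),
              if (x$low_confidence) "; tie, low confidence" else ""))
  invisible(x)
}

#' Leave-one-variant-out evaluation
#'
#' For every known-label variant in turn: train a forest on all other
#' variants' frames, predict every frame of the held-out variant, and
#' aggregate to a variant-level call. No frame of the held-out variant
#' enters training, so there is no frame-level leakage. Overall accuracy
#' is the fraction of variants called correctly.
#'
#' @param matrix a \code{DihedralMatrix}; unlabeled rows are ignored.
#' @param features forest feature list.
#' @param n_trees,seed,max_depth,min_leaf,mtry,bootstrap forwarded to
#'   \code{\link{train_forest}} (each fold uses a seed derived from
#'   \code{seed} and the fold index).
#' @return object of class \code{LovoResult}: \code{per_variant}
#'   data.frame (variant, truth, predicted, vote_fraction),
#'   \code{accuracy} (variant-level), \code{features}.
#' @export
lovo_evaluate <- function(matrix, features, n_trees = 100L, seed,
                          max_depth = 5L, min_leaf = 5L, mtry = NULL,
                          bootstrap = TRUE) {
  if (missing(seed)) stop("lovo_evaluate(): a seed is required")
  miss <- setdiff(features, colnames(matrix$angles))
  if (length(miss) > 0) {
    stop(sprintf("lovo_evaluate(): feature(s) not in matrix: %s",
                 paste(miss, collapse = ", ")))
  }
  keep <- which(!is.na(matrix$class))
  # work on the feature block only; folds then copy small matrices
  m <- dihedral_matrix(matrix$angles[keep, features, drop = FALSE],
                       matrix$variant[keep], matrix$class[keep],
                       matrix$trajectory[keep], matrix$frame[keep])
  variants <- unique(m$variant)
  vclass <- vapply(variants, function(v) m$class[m$variant == v][1], integer(1))
  if (sum(vclass == 0L) < 2L || sum(vclass == 1L) < 2L) {
    stop(paste("lovo_evaluate(): each class needs at least 2 variants,",
               "otherwise some training fold would be single-class;",
               "add variants or evaluate differently"))
  }
  res <- data.frame(variant = variants,
                    truth = ifelse(vclass == 1L, "R", "S"),
                    predicted = NA_character_,
                    vote_fraction = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(variants)) {
    hold <- m$variant == variants[i]
    train <- subset_matrix(m, which(!hold))
    # structural no-leakage guard: held-out frames never enter training
    stopifnot(!any(train$variant == variants[i]),
              nrow(train$angles) + sum(hold) == nrow(m$angles))
    fold_model <- train_forest(train, features, n_trees = n_trees,
                               seed = seed + i, max_depth = max_depth,
                               min_leaf = min_leaf, mtry = mtry,
                               bootstrap = bootstrap)
    pred <- predict_variant(fold_model, subset_matrix(m, which(hold)),
                            variant = variants[i])
    res$predicted[i] <- pred$label
    res$vote_fraction[i] <- pred$vote_fraction
  }
  structure(list(per_variant = res,
                 accuracy = mean(res$predicted == res$truth),
                 features = features),
            class = "LovoResult")
}

#' @export
print.LovoResult <- function(x, ...) {
  cat(sprintf("LovoResult on {%s}: variant-level accuracy %.4f\n",
              paste(x$features, collapse = ", "), x$accuracy))
  print(x$per_variant, row.names = FALSE)
  invisible(x)
}

#' Compare feature subsets drawn from selection rounds
#'
#' For each requested set of round indices, takes the union of those
#' rounds' selected features and runs a leave-one-variant-out evaluation,
#' reporting one row per subset — the layout of the per-drug feature/
#' accuracy comparison tables.
#'
#' @param matrix a \code{DihedralMatrix}.
#' @param selection a \code{SelectionResult}.
#' @param subsets list of integer vectors of round indices; duplicated
#'   subsets are evaluated once (first occurrence kept).
#' @param ... forwarded to \code{\link{lovo_evaluate}} (seed required).
#' @return data.frame with columns features, rounds, accuracy.
#' @export
subset_comparison <- function(matrix, selection, subsets, ...) {
  key <- vapply(subsets, function(s) paste(sort(unique(s)), collapse = ","),
                character(1))
  first <- !duplicated(key)
  subsets <- subsets[first]
  key <- key[first]
  rows <- list()
  for (i in seq_along(subsets)) {
    feats <- tryCatch(selected_features(selection, subsets[[i]]),
                      error = function(e) stop(e))
    if (length(feats) == 0L) {
      warning(sprintf("subset_comparison(): rounds {%s} select no features; skipped",
                      key[i]))
      next
    }
    lv <- lovo_evaluate(matrix, feats, ...)
    rows[[length(rows) + 1L]] <- data.frame(
      features = paste(feats, collapse = ", "),
      rounds = key[i],
      accuracy = lv$accuracy,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Predict unknown-significance variants
#'
#' Trains one forest on every known-label frame, then aggregates each
#' unknown variant's frames to a variant-level call.
#'
#' @param matrix \code{DihedralMatrix} of the known-label variants.
#' @param features forest feature list.
#' @param vus list of \code{FrameSet}s (or a \code{DihedralMatrix} with
#'   class NA rows) holding the unknown variants' frames.
#' @param n_trees,seed,... forwarded to \code{\link{train_forest}}.
#' @return named list of \code{VariantPrediction}, one per unknown variant
#'   (empty list if there are none).
#' @export
predict_unknowns <- function(matrix, features, vus, n_trees = 100L, seed, ...) {
  if (missing(seed)) stop("predict_unknowns(): a seed is required")
  model <- train_forest(matrix, features, n_trees = n_trees, seed = seed, ...)
  if (inherits(vus, "DihedralMatrix")) {
    vn <- unique(vus$variant[is.na(vus$class)])
    vus <- lapply(vn, function(v) {
      idx <- which(vus$variant == v & is.na(vus$class))
      frame_set(v, angles = vus$angles[idx, , drop = FALSE],
                trajectory = vus$trajectory[idx], frame = vus$frame[idx])
    })
  }
  out <- lapply(vus, function(f) predict_variant(model, f))
  names(out) <- vapply(out, function(p) p$variant, character(1))
  out
}
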