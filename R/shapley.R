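#' Exact interventional Shapley attribution for one frame
#'
#' Attributes the forest's continuous output (fraction of trees voting
#' resistant) for a single frame to its features by exhaustive coalition
#' enumeration. The value function is interventional: v(S) is the mean
#' model output over the background rows with the features in S replaced by
#' the frame's values. Shapley weights |S|! (k-|S|-1)! / k! are applied
#' exactly, so the attribution satisfies the efficiency axiom to machine
#' precision: base + sum(values) = model output of the frame.
#'
#' Positive values push the prediction toward the resistant class (1),
#' negative toward sensitive (0).
#'
#' @param model a \code{ForestModel} (or any object accepted by
#'   \code{output_fn}).
#' @param frame named numeric vector (or 1-row matrix) of the frame's
#'   feature values; must cover the model's features.
#' @param background numeric matrix of background rows (named columns
#'   covering the features); nonempty.
#' @param output_fn function(model, matrix) -> numeric per row; defaults to
#'   \code{\link{forest_vote_fraction}}.
#' @return list with \code{values} (named per-feature Shapley values),
#'   \code{base} (expected output over the background) and \code{output}
#'   (model output for the frame).
#' @export
exact_shapley <- function(model, frame, background,
                          output_fn = forest_vote_fraction) {
  feats <- model$features
  k <- length(feats)
  if (k > 16L) {
    stop("exact_shapley(): more than 16 features; coalition enumeration is intractable (a sampling approximation is out of scope)")
  }
  if (is.matrix(frame)) frame <- frame[1L, ]
  if (!all(feats %in% names(frame))) {
    stop("exact_shapley(): frame does not cover the model's features")
  }
  if (is.null(dim(background)) || nrow(background) == 0L) {
    stop("exact_shapley(): background must be a nonempty matrix")
  }
  bg <- background[, feats, drop = FALSE]
  nb <- nrow(bg)
  # v(S) for every coalition S, encoded as a bitmask over feats
  n_coal <- bitwShiftL(1L, k)
  v <- numeric(n_coal)
  for (mask in 0:(n_coal - 1L)) {
    hybrid <- bg
    for (j in seq_len(k)) {
      if (bitwAnd(mask, bitwShiftL(1L, j - 1L)) != 0L) {
        hybrid[, j] <- frame[feats[j]]
      }
    }
    v[mask + 1L] <- mean(output_fn(model, hybrid))
  }
  fact <- factorial(0:k)
  values <- stats::setNames(numeric(k), feats)
  for (j in seq_len(k)) {
    bit <- bitwShiftL(1L, j - 1L)
    for (mask in 0:(n_coal - 1L)) {
      if (bitwAnd(mask, bit) == 0L) {
        s <- sum(bitwAnd(mask, bitwShiftL(1L, 0:(k - 1L))) != 0L)
        w <- fact[s + 1L] * fact[k - s] / fact[k + 1L]
        values[j] <- values[j] + w * (v[mask + bit + 1L] - v[mask + 1L])
      }
    }
  }
  list(values = values, base = v[1L], output = v[n_coal])
}

#' Shapley summary over a set of frames
#'
#' Runs \code{\link{exact_shapley}} for every requested row and assembles
#' the beeswarm-style export: per (frame, feature) the raw feature value
#' and its Shapley value, plus the mean |Shapley| feature ranking.
#'
#' @param model a \code{ForestModel}.
#' @param matrix a \code{DihedralMatrix} (or plain matrix) of frames to
#'   attribute.
#' @param background background rows (matrix or \code{DihedralMatrix});
#'   defaults to up to 100 training-scale rows sampled from \code{matrix}
#'   with \code{seed}.
#' @param rows integer row indices to attribute (default: all, capped at
#'   \code{max_rows}).
#' @param max_rows cap on attributed rows when \code{rows} is NULL
#'   (default 200; exact enumeration is quadratic-ish in practice).
#' @param seed seed for the background/row subsamples.
#' @return object of class \code{ShapSummary}: \code{table} (data.frame
#'   frame, feature, value, shapley), \code{ranking} (named mean |Shapley|
#'   per feature, decreasing), \code{base}, \code{local_accuracy_error}
#'   (max |base + sum - output| over frames).
#' @export
shap_summary <- function(model, matrix, background = NULL, rows = NULL,
                         max_rows = 200L, seed = 1L) {
  ang <- if (inherits(matrix, "DihedralMatrix")) matrix$angles else matrix
  set.seed(seed)
  if (is.null(background)) {
    idx <- sample.int(nrow(ang), min(100L, nrow(ang)))
    background <- ang[idx, , drop = FALSE]
  } else if (inherits(background, "DihedralMatrix")) {
    background <- background$angles
  }
  if (is.null(rows)) {
    rows <- if (nrow(ang) > max_rows) {
      sort(sample.int(nrow(ang), max_rows))
    } else {
      seq_len(nrow(ang))
    }
  }
  feats <- model$features
  shap <- matrix(NA_real_, nrow = length(rows), ncol = length(feats),
                 dimnames = list(NULL, feats))
  base <- NA_real_
  err <- 0
  for (i in seq_along(rows)) {
    ex <- exact_shapley(model, ang[rows[i], ], background)
    shap[i, ] <- ex$values
    base <- ex$base
    err <- max(err, abs(ex$base + sum(ex$values) - ex$output))
  }
  tab <- data.frame(
    frame = rep(rows, times = length(feats)),
    feature = rep(feats, each = length(rows)),
    value = as.vector(ang[rows, feats, drop = FALSE]),
    shapley = as.vector(shap),
    stringsAsFactors = FALSE)
  ranking <- sort(colMeans(abs(shap)), decreasing = TRUE)
  structure(list(table = tab, ranking = ranking, base = base,
                 local_accuracy_error = err),
            class = "ShapSummary")
}

#' @export
print.ShapSummary <- function(x, ...) {
  cat(sprintf("ShapSummary: %d frames, base value %.4f, local accuracy error %.2e\n",
              length(unique(x$table$frame)), x$base, x$local_accuracy_error))
  cat("  mean |Shapley| ranking:\n")
  for (f in names(x$ranking)) {
    cat(sprintf("    %-8s %.4f\n", f, x$ranking[[f]]))
  }
  invisible(x)
}

#' Export a ShapSummary
#'
#' Writes the (frame, feature, raw value, shapley) table as TSV and the
#' mean |Shapley| ranking as JSON.
#'
#' @param x a \code{ShapSummary}.
#' @param tsv_path,json_path output paths (either may be NULL to skip).
#' @return invisibly, NULL.
#' @export
write_shap_summary <- function(x, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(x$table, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(as.list(x$ranking), json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(NULL)
}
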