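#' Optimal superposition and RMSD of two matched point sets
#'
#' Kabsch algorithm: centroids removed, least-squares optimal rotation via
#' SVD with a proper-rotation correction (determinant +1), RMSD computed
#' from the superposed sets.
#'
#' @param X,Y numeric n x 3 matrices of matched points (n >= 3).
#' @return list with \code{rotation} (3 x 3, applied to centred Y to match
#'   centred X), \code{rmsd} (Angstrom).
#' @export
kabsch_rmsd <- function(X, Y) {
  if (!is.matrix(X) || !is.matrix(Y) || !identical(dim(X), dim(Y)) ||
      ncol(X) != 3L) {
    stop("kabsch_rmsd(): X and Y must be matched n x 3 matrices")
  }
  if (nrow(X) < 3L) stop("kabsch_rmsd(): need at least 3 points")
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  H <- crossprod(Yc, Xc)
  sv <- svd(H)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1)) {
    stop("kabsch_rmsd(): rank-deficient (collinear) configuration; rotation is not unique")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  Yr <- Yc %*% t(R)
  list(rotation = R, rmsd = sqrt(mean(rowSums((Xc - Yr)^2))))
}

#' RMSD series of a coordinate FrameSet against a reference frame
#'
#' @param x FrameSet holding coordinates.
#' @param reference frame index of the reference (default 1).
#' @param atoms "CA" (default) or "backbone" (N, CA, C).
#' @return object of class \code{RmsdSeries}: data.frame with columns
#'   trajectory, frame, rmsd.
#' @export
rmsd_series <- function(x, reference = 1L, atoms = c("CA", "backbone")) {
  atoms <- match.arg(atoms)
  if (is.null(x$coords)) stop("rmsd_series(): FrameSet holds no coordinates")
  n <- dim(x$coords)[1] %/% 3L
  sel <- if (atoms == "CA") 3L * (seq_len(n) - 1L) + 2L else seq_len(3L * n)
  nf <- dim(x$coords)[3]
  ref <- x$coords[sel, , reference]
  r <- vapply(seq_len(nf), function(f) {
    kabsch_rmsd(ref, x$coords[sel, , f])$rmsd
  }, numeric(1))
  structure(data.frame(trajectory = x$trajectory, frame = x$frame, rmsd = r),
            class = c("RmsdSeries", "data.frame"))
}

#' Detect the RMSD plateau (convergence) point
#'
#' Scans rolling windows of the series and reports the earliest index from
#' which every subsequent window is flat: absolute fitted slope below
#' \code{tol_slope} and window SD below \code{tol_sd}. Emulates the visual
#' "levelled off" convergence call on an RMSD trace.
#'
#' @param series numeric RMSD vector, or an \code{RmsdSeries} (single
#'   trajectory).
#' @param window rolling window length in frames (>= 2; default 500).
#' @param tol_slope max |slope| within a converged window
#'   (units per frame; default 1e-4).
#' @param tol_sd max SD within a converged window (default 0.1).
#' @return the first converged frame index (start of the stable tail), or
#'   \code{NA} with a warning if the series never stabilises or is shorter
#'   than the window.
#' @export
rmsd_plateau <- function(series, window = 500L, tol_slope = 1e-4,
                         tol_sd = 0.1) {
  if (inherits(series, "RmsdSeries")) series <- series$rmsd
  if (window < 2L) stop("rmsd_plateau(): window must be >= 2")
  n <- length(series)
  if (n < window) {
    warning("rmsd_plateau(): series shorter than the window; no plateau call")
    return(NA_integer_)
  }
  starts <- seq_len(n - window + 1L)
  t0 <- seq_len(window) - mean(seq_len(window))
  sxx <- sum(t0^2)
  ok <- logical(length(starts))
  for (i in starts) {
    w <- series[i:(i + window - 1L)]
    slope <- sum(t0 * (w - mean(w))) / sxx
    ok[i] <- abs(slope) <= tol_slope && stats::sd(w) <= tol_sd
  }
  # earliest start whose every subsequent window is also flat
  good_tail <- rev(cumprod(rev(ok))) == 1
  if (!any(good_tail)) {
    warning("rmsd_plateau(): no stable tail found")
    return(NA_integer_)
  }
  which(good_tail)[1L]
}

#' Ramachandran histogram distance between two frame windows
#'
#' Pools (phi, psi) pairs over all residues within each window, bins them
#' on a fixed grid covering (-180, 180]^2, and returns the Jensen–Shannon
#' distance (base-2, square root of the divergence) between the two
#' normalised histograms: 0 for identical distributions, 1 for disjoint
#' support.
#'
#' @param matrix a \code{DihedralMatrix}.
#' @param window_a,window_b integer row-index vectors; nonempty and
#'   disjoint.
#' @param bin_width bin width in degrees (default 10; must divide 360).
#' @return distance in [0, 1].
#' @export
ramachandran_window_agreement <- function(matrix, window_a, window_b,
                                          bin_width = 10) {
  if (length(window_a) == 0L || length(window_b) == 0L) {
    stop("ramachandran_window_agreement(): empty window")
  }
  if (length(intersect(window_a, window_b)) > 0L) {
    stop("ramachandran_window_agreement(): windows must be disjoint")
  }
  if (360 %% bin_width != 0) {
    stop("ramachandran_window_agreement(): bin_width must divide 360")
  }
  h_a <- rama_histogram(matrix, window_a, bin_width)
  h_b <- rama_histogram(matrix, window_b, bin_width)
  js_distance(h_a, h_b)
}

# 2-D (phi, psi) histogram over all residues of the given rows, as a
# normalised probability vector on the fixed grid.
rama_histogram <- function(matrix, rows, bin_width) {
  info <- parse_feature_names(colnames(matrix$angles))
  resid <- intersect(info$resid[info$kind == "phi"],
                     info$resid[info$kind == "psi"])
  if (length(resid) == 0L) {
    stop("rama_histogram(): no residue has both phi and psi")
  }
  nb <- as.integer(360 / bin_width)
  bin_of <- function(x) {
    # (-180, 180] -> 1..nb; wrap_angle guarantees the range
    pmin(nb, floor((wrap_angle(x) + 180) / bin_width) + 1L)
  }
  counts <- numeric(nb * nb)
  for (r in resid) {
    bp <- bin_of(matrix$angles[rows, sprintf("phi%d", r)])
    bs <- bin_of(matrix$angles[rows, sprintf("psi%d", r)])
    idx <- (bs - 1L) * nb + bp
    tab <- tabulate(idx, nbins = nb * nb)
    counts <- counts + tab
  }
  counts / sum(counts)
}

# Jensen-Shannon distance between two probability vectors, base-2 logs.
js_distance <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  sqrt(pmax(0, (kl(p, m) + kl(q, m)) / 2))
}

#' Stability of feature selection across frame windows
#'
#' Re-runs the iterative tree selection on each frame window and reports
#' the pairwise Jaccard overlap of the selected feature sets, and each
#' window's overlap with the full-retention selection — the windowed
#' re-analysis used to argue that the retained ensemble is equilibrated.
#'
#' @param matrix a \code{DihedralMatrix}.
#' @param windows named list of integer row-index vectors (>= 2 windows).
#' @param n_rounds,max_depth,min_leaf forwarded to
#'   \code{\link{iterative_selection}}.
#' @param min_frames windows with fewer rows are skipped with a warning
#'   (default 50).
#' @return object of class \code{SelectionStability}: list with
#'   \code{selections} (features per window), \code{full} (features of the
#'   full run), \code{pairwise} (matrix of Jaccard overlaps),
#'   \code{vs_full} (named vector of overlaps with the full run).
#' @export
windowed_selection_stability <- function(matrix, windows, n_rounds = 3L,
                                         max_depth = 2L, min_leaf = 5L,
                                         min_frames = 50L) {
  if (length(windows) < 2L) {
    stop("windowed_selection_stability(): need at least 2 windows")
  }
  if (is.null(names(windows))) {
    names(windows) <- paste0("window", seq_along(windows))
  }
  usable <- vapply(windows, length, integer(1)) >= min_frames
  if (!all(usable)) {
    warning(sprintf("windowed_selection_stability(): window(s) %s too small; skipped",
                    paste(names(windows)[!usable], collapse = ", ")))
    windows <- windows[usable]
    if (length(windows) < 2L) {
      stop("windowed_selection_stability(): fewer than 2 usable windows remain")
    }
  }
  sel_of <- function(rows) {
    selected_features(iterative_selection(subset_matrix(matrix, rows),
                                          n_rounds = n_rounds,
                                          max_depth = max_depth,
                                          min_leaf = min_leaf))
  }
  sels <- lapply(windows, sel_of)
  full <- sel_of(seq_len(nrow(matrix$angles)))
  jac <- function(a, b) {
    u <- union(a, b)
    if (length(u) == 0L) return(1)
    length(intersect(a, b)) / length(u)
  }
  k <- length(sels)
  pw <- matrix(1, k, k, dimnames = list(names(sels), names(sels)))
  for (i in seq_len(k)) for (j in seq_len(k)) pw[i, j] <- jac(sels[[i]], sels[[j]])
  vs_full <- vapply(sels, jac, numeric(1), b = full)
  structure(list(selections = sels, full = full, pairwise = pw,
                 vs_full = vs_full),
            class = "SelectionStability")
}

#' @export
print.SelectionStability <- function(x, ...) {
  cat("SelectionStability\n")
  cat(sprintf("  full-run selection: %s\n", paste(x$full, collapse = ", ")))
  for (nm in names(x$selections)) {
    cat(sprintf("  %s: {%s}  Jaccard vs full = %.2f\n", nm,
                paste(x$selections[[nm]], collapse = ", "), x$vs_full[[nm]]))
  }
  invisible(x)
}
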