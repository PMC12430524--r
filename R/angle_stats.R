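#' Reference-ensemble magnitude threshold for angle differences
#'
#' Summarises the dispersion of a reference (wild-type) ensemble as a
#' single magnitude threshold in degrees: the per-dihedral circular SD over
#' the reference frames, averaged across dihedrals. Class-mean differences
#' smaller than this are within the reference variant's own breathing and
#' are not flagged.
#'
#' @param wt_matrix \code{DihedralMatrix} (or plain angle matrix) of the
#'   reference variant's frames.
#' @return threshold in degrees.
#' @export
wt_threshold <- function(wt_matrix) {
  ang <- if (inherits(wt_matrix, "DihedralMatrix")) wt_matrix$angles else wt_matrix
  if (is.null(dim(ang)) || nrow(ang) == 0L) {
    stop("wt_threshold(): reference ensemble is empty")
  }
  if (ncol(ang) < 2L) {
    stop("wt_threshold(): need at least 2 dihedrals to summarise dispersion across residues")
  }
  mean(circular_col_sds(ang))
}

#' Per-dihedral class-difference analysis
#'
#' For every dihedral column: the circular mean of the sensitive frames,
#' the circular mean of the resistant frames (frames pooled within class),
#' their wrapped signed difference, and a Welch two-sample t-test computed
#' on values unwrapped about the pooled circular mean (so the test
#' respects circularity). A dihedral is flagged when the absolute
#' difference exceeds the magnitude threshold AND the test is significant
#' at \code{alpha}.
#'
#' @param matrix a \code{DihedralMatrix} with both classes present.
#' @param threshold magnitude gate in degrees (default 15, the reference
#'   wild-type dispersion scale; compute a data-driven value with
#'   \code{\link{wt_threshold}}).
#' @param alpha significance level (default 0.05). No multiple-testing
#'   correction is applied by default — the magnitude gate is the
#'   effective filter; set \code{bonferroni = TRUE} to divide alpha by the
#'   number of dihedrals.
#' @param bonferroni apply Bonferroni correction to alpha.
#' @param per_variant_means average per-variant circular means within each
#'   class instead of pooling frames (default FALSE: pooled).
#' @return object of class \code{AngleDiffTable}: data.frame with columns
#'   feature, kind, resid, mean_S, mean_R, difference, t, p, flag.
#' @export
group_angle_analysis <- function(matrix, threshold = 15, alpha = 0.05,
                                 bonferroni = FALSE,
                                 per_variant_means = FALSE) {
  cls <- matrix$class
  if (!any(cls == 0L, na.rm = TRUE) || !any(cls == 1L, na.rm = TRUE)) {
    stop("group_angle_analysis(): both classes must be present")
  }
  s_rows <- which(cls == 0L)
  r_rows <- which(cls == 1L)
  ang <- matrix$angles
  info <- parse_feature_names(colnames(ang))
  if (per_variant_means) {
    vm <- function(rows) {
      vs <- split(rows, matrix$variant[rows])
      means <- vapply(vs, function(ix) circular_col_means(ang[ix, , drop = FALSE]),
                      numeric(ncol(ang)))
      apply(means, 1, function(a) circular_stats(a)$mean)
    }
    mean_s <- vm(s_rows)
    mean_r <- vm(r_rows)
  } else {
    mean_s <- circular_col_means(ang[s_rows, , drop = FALSE])
    mean_r <- circular_col_means(ang[r_rows, , drop = FALSE])
  }
  diff <- wrap_difference(mean_r, mean_s)
  eff_alpha <- if (bonferroni) alpha / ncol(ang) else alpha
  tstat <- numeric(ncol(ang))
  pval <- numeric(ncol(ang))
  for (j in seq_len(ncol(ang))) {
    pooled <- circular_stats(ang[c(s_rows, r_rows), j])$mean
    # unwrap about the pooled circular mean -> ordinary reals for Welch's t
    ds <- wrap_difference(ang[s_rows, j], pooled)
    dr <- wrap_difference(ang[r_rows, j], pooled)
    tt <- stats::t.test(dr, ds)
    tstat[j] <- unname(tt$statistic)
    pval[j] <- tt$p.value
  }
  out <- data.frame(
    feature = info$name, kind = info$kind, resid = info$resid,
    mean_S = mean_s, mean_R = mean_r, difference = diff,
    t = tstat, p = pval,
    flag = abs(diff) > threshold & pval < eff_alpha,
    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  attr(out, "alpha") <- eff_alpha
  class(out) <- c("AngleDiffTable", "data.frame")
  out
}

#' Per-residue difference profiles for plotting
#'
#' Splits an \code{AngleDiffTable} into phi and psi series over residue
#' number — the shape of the published per-residue difference profiles.
#'
#' @param table an \code{AngleDiffTable}.
#' @return list with data.frames \code{phi} and \code{psi} (resid,
#'   difference, flag).
#' @export
angle_diff_profiles <- function(table) {
  pick <- function(kind) {
    d <- table[table$kind == kind, c("resid", "difference", "flag")]
    d[order(d$resid), ]
  }
  list(phi = pick("phi"), psi = pick("psi"))
}
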