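#' Construct a FrameSet
#'
#' A FrameSet holds one variant's conformational sample: either per-frame
#' backbone coordinates (N, CA, C per residue) or per-frame dihedral
#' vectors, together with trajectory provenance. It is the normalized form
#' every reader and the synthetic generator produce.
#'
#' @param variant variant name (single string).
#' @param angles numeric matrix frames x dihedral features (degrees), with
#'   column names like \code{phi600}; or NULL if only coordinates are held.
#' @param coords 3-D array \code{[3N atoms, 3, frames]} of backbone
#'   coordinates, or NULL.
#' @param residue_numbers integer vector of biological residue numbers.
#' @param trajectory integer vector, trajectory id per frame.
#' @param frame integer vector, frame index within its trajectory.
#' @return object of class \code{FrameSet}.
#' @export
frame_set <- function(variant, angles = NULL, coords = NULL,
                      residue_numbers = NULL, trajectory = NULL,
                      frame = NULL) {
  if (is.null(angles) && is.null(coords)) {
    stop("frame_set(): need angles or coords")
  }
  nf <- if (!is.null(angles)) nrow(angles) else dim(coords)[3]
  if (is.null(trajectory)) trajectory <- rep(1L, nf)
  if (is.null(frame)) frame <- seq_len(nf)
  if (length(trajectory) != nf || length(frame) != nf) {
    stop("frame_set(): trajectory/frame metadata length must equal the frame count")
  }
  if (!is.null(angles)) {
    if (is.null(colnames(angles))) {
      stop("frame_set(): angle columns must be named (phi<resid>/psi<resid>)")
    }
    if (anyNA(angles) || !all(is.finite(angles))) {
      stop("frame_set(): non-finite angle values")
    }
  }
  structure(
    list(variant = variant, angles = angles, coords = coords,
         residue_numbers = residue_numbers,
         trajectory = as.integer(trajectory), frame = as.integer(frame)),
    class = "FrameSet"
  )
}

#' @export
print.FrameSet <- function(x, ...) {
  nf <- n_frames(x)
  what <- if (!is.null(x$angles)) {
    sprintf("%d dihedral features", ncol(x$angles))
  } else {
    sprintf("%d backbone atoms", dim(x$coords)[1])
  }
  cat(sprintf("FrameSet '%s': %d frames (%d trajectories), %s\n",
              x$variant, nf, length(unique(x$trajectory)), what))
  invisible(x)
}

#' Number of frames in a FrameSet
#' @param x a FrameSet.
#' @return integer frame count.
#' @export
n_frames <- function(x) {
  if (!is.null(x$angles)) nrow(x$angles) else dim(x$coords)[3]
}

# Subset a FrameSet by frame row indices, keeping provenance aligned.
subset_frames <- function(x, idx) {
  frame_set(
    variant = x$variant,
    angles = if (!is.null(x$angles)) x$angles[idx, , drop = FALSE],
    coords = if (!is.null(x$coords)) x$coords[, , idx, drop = FALSE],
    residue_numbers = x$residue_numbers,
    trajectory = x$trajectory[idx],
    frame = x$frame[idx]
  )
}

#' Ensure a FrameSet carries dihedral angles
#'
#' Computes phi/psi from coordinates if the set holds only coordinates.
#'
#' @param x a FrameSet.
#' @return FrameSet with a populated \code{angles} matrix.
#' @export
as_angles <- function(x) {
  if (!is.null(x$angles)) return(x)
  ang <- extract_phi_psi(x$coords, residue_numbers = x$residue_numbers)
  if (is.null(dim(ang))) ang <- matrix(ang, nrow = 1L,
                                       dimnames = list(NULL, names(ang)))
  frame_set(x$variant, angles = ang, coords = x$coords,
            residue_numbers = x$residue_numbers,
            trajectory = x$trajectory, frame = x$frame)
}

#' Construct a DihedralMatrix
#'
#' The frame-level data matrix of the analysis: one row per retained frame,
#' one column per named dihedral (degrees in (-180, 180]), with per-row
#' variant name, class label (0 = sensitive, 1 = resistant, NA = unknown),
#' trajectory id and frame index.
#'
#' @param angles numeric matrix frames x features, named columns.
#' @param variant character vector per row.
#' @param class integer vector per row (0, 1 or NA).
#' @param trajectory,frame integer vectors per row.
#' @return object of class \code{DihedralMatrix}.
#' @export
dihedral_matrix <- function(angles, variant, class, trajectory = NULL,
                            frame = NULL) {
  n <- nrow(angles)
  if (is.null(trajectory)) trajectory <- rep(1L, n)
  if (is.null(frame)) frame <- seq_len(n)
  if (anyDuplicated(colnames(angles))) {
    stop("dihedral_matrix(): duplicate feature names")
  }
  if (!all(length(variant) == n, length(class) == n,
           length(trajectory) == n, length(frame) == n)) {
    stop("dihedral_matrix(): metadata length mismatch")
  }
  if (!all(class %in% c(0L, 1L) | is.na(class))) {
    stop("dihedral_matrix(): class labels must be 0, 1 or NA")
  }
  structure(
    list(angles = angles, variant = as.character(variant),
         class = as.integer(class), trajectory = as.integer(trajectory),
         frame = as.integer(frame)),
    class = "DihedralMatrix"
  )
}

#' @export
print.DihedralMatrix <- function(x, ...) {
  cat(sprintf(
    "DihedralMatrix: %d frames x %d dihedrals; %d variants (%d labeled rows)\n",
    nrow(x$angles), ncol(x$angles), length(unique(x$variant)),
    sum(!is.na(x$class))))
  invisible(x)
}

#' @export
dim.DihedralMatrix <- function(x) dim(x$angles)

# Row-subset a DihedralMatrix.
subset_matrix <- function(x, idx) {
  dihedral_matrix(x$angles[idx, , drop = FALSE], x$variant[idx],
                  x$class[idx], x$trajectory[idx], x$frame[idx])
}

#' Re-center a dihedral matrix about reference circular means
#'
#' Rotates each angle column so that a reference ensemble's circular mean
#' maps to 0 degrees, mitigating wraparound artifacts in threshold-based
#' tree splits for angles whose distribution straddles +/-180. Off by
#' default throughout the pipeline: the raw signed degrees are the
#' canonical features.
#'
#' @param matrix a \code{DihedralMatrix}.
#' @param reference rows to derive the per-angle reference means from: a
#'   \code{DihedralMatrix}, a plain angle matrix, or a variant name found
#'   in \code{matrix} (e.g. "WT").
#' @return a \code{DihedralMatrix} with transformed angles (same metadata).
#' @export
recenter_matrix <- function(matrix, reference = "WT") {
  ref_angles <- if (inherits(reference, "DihedralMatrix")) {
    reference$angles
  } else if (is.matrix(reference)) {
    reference
  } else {
    idx <- which(matrix$variant == reference)
    if (length(idx) == 0L) {
      stop(sprintf("recenter_matrix(): no rows for reference variant '%s'",
                   reference))
    }
    matrix$angles[idx, , drop = FALSE]
  }
  mu <- circular_col_means(ref_angles)
  if (anyNA(mu)) {
    stop("recenter_matrix(): a reference column has an undefined circular mean")
  }
  shifted <- wrap_angle(sweep(matrix$angles, 2, mu))
  dihedral_matrix(shifted, matrix$variant, matrix$class, matrix$trajectory,
                  matrix$frame)
}

#' Apply the frame-retention rule to a FrameSet
#'
#' Keeps the final \code{retain_last} frames of each trajectory (by frame
#' index within trajectory), the retention scheme of the study design.
#'
#' @param x a FrameSet.
#' @param retain_last frames to keep per trajectory.
#' @return FrameSet restricted to the retained frames.
#' @export
retain_final_frames <- function(x, retain_last) {
  keep <- unlist(lapply(split(seq_along(x$frame), x$trajectory), function(ix) {
    ix[order(x$frame[ix])][max(1L, length(ix) - retain_last + 1L):length(ix)]
  }), use.names = FALSE)
  subset_frames(x, sort(keep))
}

#' Assemble the frame-level data matrix from variant ensembles
#'
#' Joins the retained frames of every labeled variant into one
#' \code{DihedralMatrix} for a given drug, mapping status S to class 0 and R
#' to class 1. Variants with unknown status are excluded (use
#' \code{include_unknown = TRUE} to build a prediction matrix of the
#' unknowns instead). If \code{retain_last} is given, the retention rule is
#' applied to each ensemble first (for raw-length trajectories).
#'
#' @param ensembles list of FrameSets.
#' @param labels label table: data.frame with columns variant, drug, status
#'   (status in S/R/Unknown), as from \code{\link{read_label_table}}.
#' @param drug drug name to look up in the label table.
#' @param retain_last optional retention count per trajectory.
#' @param include_unknown if TRUE, return the unknown-status variants
#'   (class NA) instead of the labeled ones.
#' @return a \code{DihedralMatrix}.
#' @export
build_data_matrix <- function(ensembles, labels, drug, retain_last = NULL,
                              include_unknown = FALSE) {
  vnames <- vapply(ensembles, function(e) e$variant, character(1))
  if (anyDuplicated(vnames)) {
    stop(sprintf("build_data_matrix(): duplicate variant name '%s'",
                 vnames[duplicated(vnames)][1]))
  }
  lab <- labels[tolower(labels$drug) == tolower(drug), , drop = FALSE]
  missing <- setdiff(vnames, lab$variant)
  if (length(missing) > 0) {
    stop(sprintf("build_data_matrix(): no '%s' label for variant(s): %s",
                 drug, paste(missing, collapse = ", ")))
  }
  status <- lab$status[match(vnames, lab$variant)]
  cls <- ifelse(toupper(status) == "S", 0L,
                ifelse(toupper(status) == "R", 1L, NA_integer_))
  want <- if (include_unknown) is.na(cls) else !is.na(cls)
  if (!any(want)) {
    stop("build_data_matrix(): no variants with the requested label status")
  }
  parts <- lapply(which(want), function(i) {
    e <- as_angles(ensembles[[i]])
    if (!is.null(retain_last)) e <- retain_final_frames(e, retain_last)
    list(e = e, cls = cls[i])
  })
  ref_cols <- colnames(parts[[1]]$e$angles)
  for (p in parts) {
    if (!identical(colnames(p$e$angles), ref_cols)) {
      stop(sprintf("build_data_matrix(): variant '%s' has a different feature set",
                   p$e$variant))
    }
  }
  dihedral_matrix(
    angles = do.call(rbind, lapply(parts, function(p) p$e$angles)),
    variant = unlist(lapply(parts, function(p) rep(p$e$variant, n_frames(p$e)))),
    class = unlist(lapply(parts, function(p) rep(p$cls, n_frames(p$e)))),
    trajectory = unlist(lapply(parts, function(p) p$e$trajectory)),
    frame = unlist(lapply(parts, function(p) p$e$frame))
  )
}
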