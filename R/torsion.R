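#' Signed torsion (dihedral) angle of four points
#'
#' Computes the signed dihedral angle defined by four 3-D points using the
#' IUPAC convention: 0 for cis (eclipsed), +/-180 for trans, with the sign
#' given by the right-hand rule about the central bond b2 = p3 - p2.
#' Implemented with the atan2 formulation, which is numerically stable near
#' 0 and 180.
#'
#' All four arguments may be matrices with one point per row, in which case
#' a vector of torsions is returned (rows are independent quadruples).
#'
#' @param p1,p2,p3,p4 numeric length-3 vectors, or n x 3 matrices.
#' @return torsion angle(s) in degrees, in (-180, 180].
#' @export
#' @examples
#' torsion_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))  # 0 (cis)
torsion_angle <- function(p1, p2, p3, p4) {
  as_mat <- function(p) if (is.matrix(p)) p else matrix(p, nrow = 1L)
  p1 <- as_mat(p1); p2 <- as_mat(p2); p3 <- as_mat(p3); p4 <- as_mat(p4)
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  cross <- function(a, b) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  }
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  n1n <- sqrt(rowSums(n1^2))
  n2n <- sqrt(rowSums(n2^2))
  b2n <- sqrt(rowSums(b2^2))
  if (any(b2n == 0)) stop("torsion_angle(): central bond p3 - p2 is zero")
  bad <- n1n < 1e-12 * pmax(1, b2n) | n2n < 1e-12 * pmax(1, b2n)
  if (any(bad)) {
    stop(sprintf(
      "torsion_angle(): collinear points leave the dihedral plane undefined (quadruple %d)",
      which(bad)[1]))
  }
  # x = n1.n2 scaled; y = (n1 x n2).b2hat: atan2(y, x) gives the signed angle
  x <- rowSums(n1 * n2)
  m <- cross(n1, n2)
  y <- rowSums(m * (b2 / b2n))
  wrap_angle(atan2(y, x) * 180 / pi)
}

#' Dihedral feature names for a residue range
#'
#' Features follow extraction order along the chain: for residue i, phi(i)
#' exists for i = 2..N and psi(i) for i = 1..N-1, named \code{phi<resid>} /
#' \code{psi<resid>} in biological residue numbering. A chain of N residues
#' therefore has 2N - 2 features.
#'
#' @param n_residues number of residues (>= 2).
#' @param residue_offset biological number of the first residue.
#' @return character vector of 2 * n_residues - 2 feature names.
#' @export
#' @examples
#' dihedral_feature_names(3, residue_offset = 448)
dihedral_feature_names <- function(n_residues, residue_offset = 1L) {
  if (n_residues < 2) stop("dihedral_feature_names(): need >= 2 residues")
  resid <- seq_len(n_residues) + residue_offset - 1L
  nm <- character(0)
  for (i in seq_len(n_residues)) {
    if (i >= 2L) nm <- c(nm, sprintf("phi%d", resid[i]))
    if (i <= n_residues - 1L) nm <- c(nm, sprintf("psi%d", resid[i]))
  }
  nm
}

#' Parse dihedral feature names into kind and residue number
#'
#' @param names character vector of names like "phi600" or "psi494".
#' @return data.frame with columns \code{name}, \code{kind} ("phi"/"psi"),
#'   \code{resid} (integer).
#' @export
parse_feature_names <- function(names) {
  ok <- grepl("^(phi|psi)[0-9]+$", names)
  if (!all(ok)) {
    stop(sprintf("parse_feature_names(): malformed feature name '%s'",
                 names[!ok][1]))
  }
  data.frame(
    name  = names,
    kind  = substr(names, 1, 3),
    resid = as.integer(sub("^(phi|psi)", "", names)),
    stringsAsFactors = FALSE
  )
}

#' Canonical ordering of dihedral feature names
#'
#' Ascending residue number with phi before psi; non phi/psi names fall
#' back to lexicographic order after all parseable names. This ordering is
#' the deterministic tie-break used throughout tree fitting.
#'
#' @param features character vector of feature names.
#' @return the same names, canonically ordered.
#' @export
canonical_feature_order <- function(features) {
  parseable <- grepl("^(phi|psi)[0-9]+$", features)
  out <- character(0)
  if (any(parseable)) {
    p <- parse_feature_names(features[parseable])
    ord <- order(p$resid, match(p$kind, c("phi", "psi")))
    out <- p$name[ord]
  }
  c(out, sort(features[!parseable]))
}

#' Extract phi/psi torsions from one backbone frame
#'
#' Given backbone coordinates (N, CA, C per residue) of a single
#' conformation, computes phi(i) = torsion(C(i-1), N(i), CA(i), C(i)) for
#' i = 2..N and psi(i) = torsion(N(i), CA(i), C(i), N(i+1)) for i = 1..N-1,
#' returning the 2N - 2 angles in chain order named by residue.
#'
#' @param coords numeric matrix with 3 * N rows (N1, CA1, C1, N2, ...) and 3
#'   columns, or a 3-D array \code{[atom, xyz, frame]} for multiple frames.
#' @param residue_numbers integer vector of biological residue numbers
#'   (default 1..N).
#' @return named numeric vector of 2N - 2 torsions (degrees), or a matrix
#'   with one row per frame when \code{coords} has a frame dimension.
#' @export
extract_phi_psi <- function(coords, residue_numbers = NULL) {
  if (is.matrix(coords)) {
    dim(coords) <- c(dim(coords), 1L)
    drop_frame <- TRUE
  } else {
    drop_frame <- FALSE
  }
  na <- dim(coords)[1]
  if (na %% 3L != 0L || ncol(coords) != 3L) {
    stop("extract_phi_psi(): coords must have 3*N rows (N, CA, C per residue) and 3 columns")
  }
  n <- na %/% 3L
  if (n < 2L) stop("extract_phi_psi(): need at least 2 residues")
  if (is.null(residue_numbers)) residue_numbers <- seq_len(n)
  nf <- dim(coords)[3]
  names_out <- dihedral_feature_names(n, residue_numbers[1])

  idxN <- 3L * (seq_len(n) - 1L) + 1L
  idxCA <- idxN + 1L
  idxC <- idxN + 2L

  out <- matrix(NA_real_, nrow = nf, ncol = 2L * n - 2L,
                dimnames = list(NULL, names_out))
  for (f in seq_len(nf)) {
    x <- coords[, , f]
    phi <- torsion_angle(x[idxC[-n], , drop = FALSE],
                         x[idxN[-1], , drop = FALSE],
                         x[idxCA[-1], , drop = FALSE],
                         x[idxC[-1], , drop = FALSE])
    psi <- torsion_angle(x[idxN[-n], , drop = FALSE],
                         x[idxCA[-n], , drop = FALSE],
                         x[idxC[-n], , drop = FALSE],
                         x[idxN[-1], , drop = FALSE])
    # interleave in chain order: psi(1), phi(2), psi(2), ..., phi(N)
    v <- numeric(2L * n - 2L)
    k <- 1L
    for (i in seq_len(n)) {
      if (i >= 2L) { v[k] <- phi[i - 1L]; k <- k + 1L }
      if (i <= n - 1L) { v[k] <- psi[i]; k <- k + 1L }
    }
    out[f, ] <- v
  }
  if (drop_frame && nf == 1L) out[1L, ] else out
}
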