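#' Standard peptide backbone geometry constants
#'
#' Idealised bond lengths (Angstrom) and bond angles (degrees) used by
#' \code{\link{build_backbone_from_torsions}}; the omega torsion is frozen
#' trans (180). Values are the conventional Engh–Huber-style averages.
#'
#' @return named list of geometry constants.
#' @export
peptide_geometry <- function() {
  list(
    b_n_ca  = 1.458,   # N-CA bond
    b_ca_c  = 1.525,   # CA-C bond
    b_c_n   = 1.329,   # C-N peptide bond
    a_n_ca_c = 111.2,  # N-CA-C angle
    a_ca_c_n = 116.2,  # CA-C-N angle
    a_c_n_ca = 121.7,  # C-N-CA angle
    omega    = 180.0   # peptide bond torsion, trans
  )
}

# Place one atom from three predecessors by internal coordinates
# (bond length to C, bond angle B-C-new, torsion A-B-C-new). Standard NeRF
# construction.
place_atom <- function(a, b, c, length, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- torsion_deg * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-length * cos(ang),
         length * sin(ang) * cos(tor),
         length * sin(ang) * sin(tor))
  c + d[1] * bc + d[2] * m + d[3] * n
}

#' Build backbone coordinates from phi/psi torsions
#'
#' Constructs N/CA/C coordinates of a polypeptide chain whose backbone
#' torsions equal the supplied phi/psi vector, using fixed standard peptide
#' geometry and a trans (180 degree) omega. The construction is the inverse
#' of \code{\link{extract_phi_psi}}: extracting torsions from the returned
#' coordinates reproduces the input within numerical tolerance, which makes
#' the pair a round-trip fixture for the torsion extractor.
#'
#' @param phi_psi numeric vector of length 2N - 2 in chain order
#'   (psi1, phi2, psi2, ..., phiN), optionally named as produced by
#'   \code{\link{dihedral_feature_names}}.
#' @param geometry list of constants as from \code{\link{peptide_geometry}}.
#' @return numeric matrix of 3N rows (N1, CA1, C1, N2, ...) x 3 columns.
#' @export
build_backbone_from_torsions <- function(phi_psi, geometry = peptide_geometry()) {
  len <- length(phi_psi)
  if (len < 2L || len %% 2L != 0L) {
    stop("build_backbone_from_torsions(): phi_psi must have length 2N - 2 for N >= 2 residues")
  }
  if (!all(is.finite(phi_psi))) {
    stop("build_backbone_from_torsions(): non-finite torsion supplied")
  }
  n <- (len + 2L) %/% 2L
  # split chain-ordered vector into phi(2..N) and psi(1..N-1)
  phi <- numeric(n); psi <- numeric(n)
  k <- 1L
  for (i in seq_len(n)) {
    if (i >= 2L) { phi[i] <- phi_psi[k]; k <- k + 1L }
    if (i <= n - 1L) { psi[i] <- phi_psi[k]; k <- k + 1L }
  }
  g <- geometry
  coords <- matrix(NA_real_, nrow = 3L * n, ncol = 3L)
  # seed residue 1 in a canonical pose
  coords[1L, ] <- c(0, 0, 0)                                   # N1
  coords[2L, ] <- c(g$b_n_ca, 0, 0)                            # CA1
  ang <- g$a_n_ca_c * pi / 180
  coords[3L, ] <- coords[2L, ] +
    g$b_ca_c * c(-cos(ang), sin(ang), 0)                       # C1
  for (i in seq_len(n - 1L)) {
    iN <- 3L * (i - 1L) + 1L
    # N(i+1): torsion psi(i) about CA(i)-C(i)
    coords[iN + 3L, ] <- place_atom(coords[iN, ], coords[iN + 1L, ],
                                    coords[iN + 2L, ],
                                    g$b_c_n, g$a_ca_c_n, psi[i])
    # CA(i+1): omega about C(i)-N(i+1)
    coords[iN + 4L, ] <- place_atom(coords[iN + 1L, ], coords[iN + 2L, ],
                                    coords[iN + 3L, ],
                                    g$b_n_ca, g$a_c_n_ca, g$omega)
    # C(i+1): phi(i+1) about N(i+1)-CA(i+1)
    coords[iN + 5L, ] <- place_atom(coords[iN + 2L, ], coords[iN + 3L, ],
                                    coords[iN + 4L, ],
                                    g$b_ca_c, g$a_n_ca_c, phi[i + 1L])
  }
  coords
}
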