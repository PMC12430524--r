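#' Read a conformational ensemble from file
#'
#' Supported formats: multi-model PDB (one MODEL per frame, backbone atoms
#' N/CA/C of a single protein chain) and angle TSV (one row per frame,
#' columns named \code{phi<resid>}/\code{psi<resid>}). PDB residue
#' numbering is authoritative for feature names.
#'
#' @param path file path.
#' @param format "pdb" or "tsv"; guessed from the extension by default.
#' @param variant variant name to attach; defaults to the file stem.
#' @return a \code{\link{frame_set}}.
#' @export
read_ensemble <- function(path, format = c("auto", "pdb", "tsv"),
                          variant = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("read_ensemble(): no such file: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "tsv"
  }
  if (is.null(variant)) variant <- sub("\\.[^.]*$", "", basename(path))
  switch(format,
         pdb = read_ensemble_pdb(path, variant),
         tsv = read_ensemble_tsv(path, variant))
}

read_ensemble_tsv <- function(path, variant) {
  df <- utils::read.delim(path, check.names = FALSE)
  angle_cols <- grepl("^(phi|psi)[0-9]+$", names(df))
  if (!any(angle_cols)) {
    stop(sprintf("read_ensemble(): no dihedral columns (phi<resid>/psi<resid>) in %s", path))
  }
  ang <- as.matrix(df[, angle_cols, drop = FALSE])
  if (!is.numeric(ang) || anyNA(ang)) {
    stop(sprintf("read_ensemble(): non-numeric or missing angle values in %s", path))
  }
  resid <- sort(unique(parse_feature_names(colnames(ang))$resid))
  frame_set(variant, angles = ang, residue_numbers = resid,
            trajectory = if ("trajectory" %in% names(df)) df$trajectory,
            frame = if ("frame" %in% names(df)) df$frame)
}

# Fixed-width multi-model PDB reader for backbone ensembles. Written
# in-package so malformed records can be reported with their line number and
# incomplete residues with their model and residue id; altlocs resolved by
# highest occupancy, then first listed.
read_ensemble_pdb <- function(path, variant) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  "
  is_model <- rec == "MODEL "
  is_end <- trimws(rec) == "ENDMDL"
  model_id <- cumsum(is_model)
  if (!any(is_model)) model_id <- rep(1L, length(lines))
  atom_lines <- which(is_atom)
  if (length(atom_lines) == 0) {
    stop(sprintf("read_ensemble(): no ATOM records in %s", path))
  }
  fw <- function(l, a, b) substr(lines[l], a, b)
  name <- trimws(fw(atom_lines, 13, 16))
  altloc <- fw(atom_lines, 17, 17)
  chain <- fw(atom_lines, 22, 22)
  resid_s <- trimws(fw(atom_lines, 23, 26))
  xs <- trimws(fw(atom_lines, 31, 38))
  ys <- trimws(fw(atom_lines, 39, 46))
  zs <- trimws(fw(atom_lines, 47, 54))
  occ_s <- trimws(fw(atom_lines, 55, 60))
  suppressWarnings({
    resid <- as.integer(resid_s)
    x <- as.numeric(xs); y <- as.numeric(ys); z <- as.numeric(zs)
    occ <- as.numeric(occ_s)
  })
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad) > 0) {
    stop(sprintf("read_ensemble(): malformed ATOM record at line %d of %s",
                 atom_lines[bad[1]], path))
  }
  occ[is.na(occ)] <- 1
  keep <- name %in% c("N", "CA", "C")
  name <- name[keep]; altloc <- altloc[keep]; chain <- chain[keep]
  resid <- resid[keep]; occ <- occ[keep]
  xyz <- cbind(x, y, z)[keep, , drop = FALSE]
  mid <- model_id[atom_lines][keep]
  if (length(unique(chain)) > 1) {
    stop(sprintf("read_ensemble(): multiple chains (%s) in %s; single-chain models only",
                 paste(unique(chain), collapse = ", "), path))
  }
  models <- sort(unique(mid))
  resseq <- sort(unique(resid))
  n <- length(resseq)
  if (n < 2) stop(sprintf("read_ensemble(): fewer than 2 residues in %s", path))
  coords <- array(NA_real_, dim = c(3L * n, 3L, length(models)))
  for (k in seq_along(models)) {
    sel <- mid == models[k]
    m_name <- name[sel]; m_resid <- resid[sel]; m_occ <- occ[sel]
    m_alt <- altloc[sel]; m_xyz <- xyz[sel, , drop = FALSE]
    if (!setequal(unique(m_resid), resseq)) {
      stop(sprintf("read_ensemble(): model %d of %s has an inconsistent residue set",
                   k, path))
    }
    for (i in seq_len(n)) {
      for (j in 1:3) {
        at <- c("N", "CA", "C")[j]
        hit <- which(m_resid == resseq[i] & m_name == at)
        if (length(hit) == 0) {
          stop(sprintf(
            "read_ensemble(): model %d, residue %d of %s is missing backbone atom %s",
            k, resseq[i], path, at))
        }
        if (length(hit) > 1) {
          # altloc: highest occupancy, first listed on ties
          hit <- hit[order(-m_occ[hit], m_alt[hit] != " ")][1]
        }
        coords[3L * (i - 1L) + j, , k] <- m_xyz[hit, ]
      }
    }
  }
  frame_set(variant, coords = coords, residue_numbers = resseq,
            trajectory = rep(1L, length(models)), frame = seq_along(models))
}

#' Write a FrameSet as a multi-model PDB
#'
#' One MODEL per frame, backbone atoms only (N, CA, C), poly-alanine
#' residue names, biological residue numbering preserved.
#'
#' @param x FrameSet holding coordinates.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_ensemble_pdb <- function(x, path) {
  if (is.null(x$coords)) {
    stop("write_ensemble_pdb(): FrameSet holds no coordinates")
  }
  nfrm <- dim(x$coords)[3]
  n <- dim(x$coords)[1] %/% 3L
  resid <- x$residue_numbers
  if (is.null(resid)) resid <- seq_len(n)
  con <- file(path, "w")
  on.exit(close(con))
  atn <- c(" N  ", " CA ", " C  ")
  for (f in seq_len(nfrm)) {
    writeLines(sprintf("MODEL %8d", f), con)
    serial <- 0L
    rows <- character(3L * n)
    for (i in seq_len(n)) {
      for (j in 1:3) {
        serial <- serial + 1L
        p <- x$coords[3L * (i - 1L) + j, , f]
        rows[serial] <- sprintf(
          "ATOM  %5d %s ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %1s",
          serial, atn[j], resid[i], p[1], p[2], p[3], 1, 0,
          substr(trimws(atn[j]), 1, 1))
      }
    }
    writeLines(rows, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a DihedralMatrix as TSV
#'
#' One row per frame; angle columns (6 decimal places) followed by the two
#' label columns \code{status} (S/R/Unknown) and \code{variant}, so a
#' 550-dihedral study writes 552 columns. Reading the file back recovers
#' the angle payload exactly at the declared precision.
#'
#' @param x a \code{DihedralMatrix}.
#' @param path output path.
#' @param provenance also write trajectory/frame columns (default FALSE,
#'   keeping the canonical 552-column layout).
#' @return invisibly, the path.
#' @export
write_matrix <- function(x, path, provenance = FALSE) {
  stopifnot(inherits(x, "DihedralMatrix"))
  if (nrow(x$angles) == 0) stop("write_matrix(): empty matrix")
  df <- as.data.frame(round(x$angles, 6), check.names = FALSE)
  df$status <- ifelse(is.na(x$class), "Unknown", ifelse(x$class == 1L, "R", "S"))
  df$variant <- x$variant
  if (provenance) {
    df$trajectory <- x$trajectory
    df$frame <- x$frame
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a DihedralMatrix TSV
#'
#' Inverse of \code{\link{write_matrix}}.
#'
#' @param path file path.
#' @return a \code{DihedralMatrix}.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  angle_cols <- grepl("^(phi|psi)[0-9]+$", names(df))
  if (!any(angle_cols)) {
    stop(sprintf("read_matrix(): no dihedral columns in %s", path))
  }
  ang <- as.matrix(df[, angle_cols, drop = FALSE])
  status <- if ("status" %in% names(df)) df$status else rep("Unknown", nrow(df))
  cls <- ifelse(toupper(status) == "S", 0L,
                ifelse(toupper(status) == "R", 1L, NA_integer_))
  dihedral_matrix(
    ang,
    variant = if ("variant" %in% names(df)) df$variant else rep("unknown", nrow(df)),
    class = cls,
    trajectory = if ("trajectory" %in% names(df)) df$trajectory,
    frame = if ("frame" %in% names(df)) df$frame
  )
}

#' Read / write a variant label table
#'
#' A label table maps variant name to drug-response status per drug:
#' TSV columns \code{variant}, \code{drug}, \code{status} (S, R or
#' Unknown).
#'
#' @param path file path.
#' @return data.frame with columns variant, drug, status.
#' @export
read_label_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant", "drug", "status")
  if (!all(need %in% names(df))) {
    stop(sprintf("read_label_table(): %s must have columns %s",
                 path, paste(need, collapse = ", ")))
  }
  if (!all(toupper(df$status) %in% c("S", "R", "UNKNOWN"))) {
    stop("read_label_table(): status values must be S, R or Unknown")
  }
  df[need]
}

#' @rdname read_label_table
#' @param x label table data.frame.
#' @export
write_label_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundled clinical label roster for the BRAF kinase-domain study design
#'
#' Variant names and drug-sensitive/resistant/unknown status per inhibitor,
#' used as the default roster of \code{\link{braf_study_spec}}.
#'
#' @return data.frame with columns variant, drug, status.
#' @export
variant_label_table <- function() {
  read_label_table(system.file("extdata", "variant_labels.tsv",
                               package = "torsionForest", mustWork = TRUE))
}

#' Bundled reference variant-level calls per inhibitor
#'
#' The known clinical status and the reference model's variant-level call
#' for each variant of the study roster (including unknown-significance
#' variants). Feeding the known-status rows through
#' \code{\link{confusion_and_metrics}} reproduces the reference performance
#' metrics.
#'
#' @param drug "dabrafenib" or "vemurafenib".
#' @param known_only drop the unknown-status rows (default TRUE).
#' @return data.frame with columns variant, status, predicted.
#' @export
reference_variant_calls <- function(drug = c("dabrafenib", "vemurafenib"),
                                    known_only = TRUE) {
  drug <- match.arg(drug)
  df <- utils::read.delim(
    system.file("extdata", paste0("reference_calls_", drug, ".tsv"),
                package = "torsionForest", mustWork = TRUE),
    stringsAsFactors = FALSE)
  if (known_only) df <- df[toupper(df$status) != "UNKNOWN", , drop = FALSE]
  df
}
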