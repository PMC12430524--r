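#' Specify one synthetic variant
#'
#' @param name variant name (e.g. "V600E").
#' @param label drug-response status: "S" (sensitive), "R" (resistant) or
#'   "Unknown".
#' @param mean_shift named numeric vector: per-dihedral offset (degrees)
#'   added to the baseline mean for this variant's class — the planted
#'   discriminative signal. Names must be dihedral feature names.
#' @param concentration von Mises concentration for every angle of this
#'   variant (> 0). The default of 8 gives a circular SD of about 21
#'   degrees, a typical equilibrated single-basin spread.
#' @param variant_jitter_sd SD (degrees) of the per-variant perturbation of
#'   mean angles, drawn once per variant so that variants within a class are
#'   exchangeable in distribution but not identical.
#' @return object of class \code{VariantSpec}.
#' @export
variant_spec <- function(name, label = c("S", "R", "Unknown"),
                         mean_shift = numeric(0), concentration = 8,
                         variant_jitter_sd = 5) {
  label <- match.arg(label)
  if (!all(is.finite(mean_shift))) {
    stop("variant_spec(): mean_shift offsets must be finite")
  }
  if (!is.finite(concentration) || concentration <= 0) {
    stop("variant_spec(): concentration must be finite and > 0")
  }
  if (!is.finite(variant_jitter_sd) || variant_jitter_sd < 0) {
    stop("variant_spec(): variant_jitter_sd must be finite and >= 0")
  }
  structure(list(name = name, label = label, mean_shift = mean_shift,
                 concentration = concentration,
                 variant_jitter_sd = variant_jitter_sd),
            class = "VariantSpec")
}

#' Specify a synthetic study
#'
#' Bundles the generator parameters that define a study: the chain, the
#' variant roster, and the trajectory/retention scheme (three independent
#' trajectories of 10,000 frames per variant, of which the final 1000 per
#' trajectory are retained, i.e. 3000 frames per variant).
#'
#' @param variants list of \code{\link{variant_spec}} objects.
#' @param n_residues chain length (>= 4; default 276).
#' @param residue_offset biological number of the first residue (default
#'   448, so feature names carry kinase-domain numbering like phi600).
#' @param frames_per_trajectory frames per trajectory (default 10000).
#' @param trajectories_per_variant independent trajectories per variant
#'   (default 3).
#' @param retain_last frames retained from the end of each trajectory
#'   (default 1000).
#' @param class_shift named numeric vector applied to the resistant class
#'   baseline: per-dihedral mean offsets (degrees) shared by all R variants
#'   — the class-level planted signal recovered by feature selection.
#' @param seed integer seed; generation is fully reproducible given it.
#' @return object of class \code{StudySpec}.
#' @export
study_spec <- function(variants, n_residues = 276, residue_offset = 448,
                       frames_per_trajectory = 10000,
                       trajectories_per_variant = 3, retain_last = 1000,
                       class_shift = numeric(0), seed = 1) {
  if (n_residues < 4) stop("study_spec(): n_residues must be >= 4")
  if (retain_last > frames_per_trajectory) {
    stop("study_spec(): retain_last cannot exceed frames_per_trajectory")
  }
  if (length(variants) == 0) stop("study_spec(): at least one variant required")
  if (!all(vapply(variants, inherits, logical(1), "VariantSpec"))) {
    stop("study_spec(): variants must be VariantSpec objects")
  }
  feats <- dihedral_feature_names(n_residues, residue_offset)
  bad <- setdiff(names(class_shift),  feats)
  for (v in variants) bad <- union(bad, setdiff(names(v$mean_shift), feats))
  if (length(bad) > 0) {
    stop(sprintf("study_spec(): shifted dihedral(s) not in the feature set: %s",
                 paste(bad, collapse = ", ")))
  }
  if (!all(is.finite(class_shift))) stop("study_spec(): class_shift must be finite")
  structure(list(variants = variants, n_residues = as.integer(n_residues),
                 residue_offset = as.integer(residue_offset),
                 frames_per_trajectory = as.integer(frames_per_trajectory),
                 trajectories_per_variant = as.integer(trajectories_per_variant),
                 retain_last = as.integer(retain_last),
                 class_shift = class_shift, seed = as.integer(seed),
                 features = feats),
            class = "StudySpec")
}

#' Generate the synthetic conformational ensembles of a study
#'
#' Draws, for every variant, \code{trajectories_per_variant} trajectories
#' whose retained tail (\code{retain_last} frames each) is returned as the
#' variant's ensemble. Every dihedral of every frame is an independent von
#' Mises draw centred on the variant's mean angle for that dihedral:
#' a per-study baseline, plus the resistant-class shift for R-labelled
#' variants, plus the variant's own planted shifts, plus a per-variant
#' jitter drawn once per (variant, dihedral). Angles are wrapped to
#' (-180, 180]. Identical seeds give identical ensembles.
#'
#' Because the per-frame draws are exchangeable, only the retained frames
#' are materialised (indices \code{frames_per_trajectory - retain_last + 1}
#' onward), keeping paper-scale generation fast; set
#' \code{full_trajectories = TRUE} to materialise whole trajectories for
#' convergence analyses.
#'
#' @param spec a \code{\link{study_spec}}.
#' @param full_trajectories materialise all frames, not just the retained
#'   tail.
#' @return named list of \code{FrameSet} objects, one per variant, each
#'   carrying a \code{label} attribute.
#' @export
generate_study <- function(spec, full_trajectories = FALSE) {
  stopifnot(inherits(spec, "StudySpec"))
  labels <- vapply(spec$variants, function(v) v$label, character(1))
  known <- labels[labels != "Unknown"]
  if (length(spec$class_shift) > 0 && !all(c("S", "R") %in% known)) {
    stop("generate_study(): a class-separating signal is planted but one class has zero variants")
  }
  set.seed(spec$seed)
  p <- length(spec$features)
  # study-wide baseline mean per dihedral: phi in the broad alpha/beta
  # region, psi spread wider — loosely Ramachandran-like, fixed per study
  is_phi <- startsWith(spec$features, "phi")
  baseline <- numeric(p)
  baseline[is_phi] <- wrap_angle(stats::rnorm(sum(is_phi), mean = -90, sd = 40))
  baseline[!is_phi] <- wrap_angle(stats::runif(sum(!is_phi), -180, 180))
  names(baseline) <- spec$features

  nf_keep <- if (full_trajectories) spec$frames_per_trajectory else spec$retain_last
  first_idx <- if (full_trajectories) 1L else
    spec$frames_per_trajectory - spec$retain_last + 1L

  out <- vector("list", length(spec$variants))
  names(out) <- vapply(spec$variants, function(v) v$name, character(1))
  for (vi in seq_along(spec$variants)) {
    v <- spec$variants[[vi]]
    mu <- baseline
    if (v$label == "R" && length(spec$class_shift) > 0) {
      mu[names(spec$class_shift)] <- mu[names(spec$class_shift)] + spec$class_shift
    }
    if (length(v$mean_shift) > 0) {
      mu[names(v$mean_shift)] <- mu[names(v$mean_shift)] + v$mean_shift
    }
    jitter <- stats::rnorm(p, 0, v$variant_jitter_sd)
    mu <- wrap_angle(mu + jitter)
    ntot <- nf_keep * spec$trajectories_per_variant
    ang <- matrix(rvonmises(ntot * p, rep(mu, each = ntot), v$concentration),
                  nrow = ntot, ncol = p,
                  dimnames = list(NULL, spec$features))
    fs <- frame_set(
      variant = v$name, angles = ang,
      residue_numbers = seq_len(spec$n_residues) + spec$residue_offset - 1L,
      trajectory = rep(seq_len(spec$trajectories_per_variant), each = nf_keep),
      frame = rep(seq(first_idx, spec$frames_per_trajectory), times = spec$trajectories_per_variant)
    )
    attr(fs, "label") <- v$label
    out[[vi]] <- fs
  }
  out
}

#' Label table of a study spec
#'
#' @param spec a \code{\link{study_spec}}.
#' @param drug drug name to record in the table.
#' @return data.frame with columns variant, drug, status.
#' @export
study_label_table <- function(spec, drug = "drug") {
  data.frame(
    variant = vapply(spec$variants, function(v) v$name, character(1)),
    drug = drug,
    status = vapply(spec$variants, function(v) v$label, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Default study roster emulating the published BRAF design
#'
#' Builds a \code{\link{study_spec}} whose variant roster and labels follow
#' the clinical classification table for the requested inhibitor
#' (12 known-status variants for dabrafenib, 11 for vemurafenib, plus the
#' unknown-significance variants), with the class-level signal planted on
#' the discriminative dihedrals reported for that drug. Chain and retention
#' parameters default to the study design (276 residues numbered from 448,
#' 3 x 10,000-frame trajectories, final 1000 retained).
#'
#' @param drug "dabrafenib" or "vemurafenib".
#' @param planted_shift degrees of class-mean separation planted on each
#'   discriminative dihedral (default 60).
#' @param planted feature names carrying the class signal (default: the
#'   drug's reported discriminative dihedrals; override when using a
#'   scaled-down chain that does not cover their residue numbers).
#' @param concentration per-angle von Mises concentration (default 8).
#' @param variant_jitter_sd per-variant jitter SD in degrees (default 5).
#' @param include_unknown include the unknown-significance variants.
#' @param seed integer seed.
#' @param ... further arguments passed to \code{\link{study_spec}}
#'   (e.g. \code{frames_per_trajectory}, \code{retain_last}).
#' @return a \code{StudySpec}.
#' @export
braf_study_spec <- function(drug = c("dabrafenib", "vemurafenib"),
                            planted_shift = 60, concentration = 8,
                            variant_jitter_sd = 5, include_unknown = TRUE,
                            seed = 1, planted = NULL, ...) {
  drug <- match.arg(drug)
  lab <- variant_label_table()
  lab <- lab[tolower(lab$drug) == drug, , drop = FALSE]
  if (!include_unknown) lab <- lab[toupper(lab$status) != "UNKNOWN", , drop = FALSE]
  if (is.null(planted)) planted <- discriminative_features(drug)
  shift <- rep(planted_shift, length(planted))
  names(shift) <- planted
  variants <- lapply(seq_len(nrow(lab)), function(i) {
    variant_spec(lab$variant[i],
                 label = if (toupper(lab$status[i]) == "UNKNOWN") "Unknown" else lab$status[i],
                 concentration = concentration,
                 variant_jitter_sd = variant_jitter_sd)
  })
  study_spec(variants, class_shift = shift, seed = seed, ...)
}

#' Discriminative dihedrals reported for each inhibitor
#'
#' The small feature sets that the iterative decision-tree selection
#' identified as sufficient to separate resistant from sensitive variants;
#' used as the default planted signal of \code{\link{braf_study_spec}}.
#'
#' @param drug "dabrafenib" or "vemurafenib".
#' @return character vector of dihedral feature names.
#' @export
discriminative_features <- function(drug = c("dabrafenib", "vemurafenib")) {
  drug <- match.arg(drug)
  switch(drug,
    dabrafenib  = c("psi494", "phi600", "phi644", "phi663", "psi675", "phi677"),
    vemurafenib = c("psi450", "phi484", "phi495", "phi518", "phi622", "psi622")
  )
}
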