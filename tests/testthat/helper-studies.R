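# Shared scaled-down study fixtures, built in code at test time.

# A small two-class study: 12 variants (7 S, 5 R) on a short chain with the
# class signal planted on two angles. Mirrors the full design's structure at
# a fraction of its size.
small_study <- function(seed = 42, n_residues = 12, frames = 60,
                        retain = 30, planted = c("phi3", "psi7"),
                        shift = 60, concentration = 12, jitter = 4,
                        n_s = 7, n_r = 5) {
  variants <- c(
    lapply(seq_len(n_s), function(i) {
      variant_spec(sprintf("S%02d", i), "S", concentration = concentration,
                   variant_jitter_sd = jitter)
    }),
    lapply(seq_len(n_r), function(i) {
      variant_spec(sprintf("R%02d", i), "R", concentration = concentration,
                   variant_jitter_sd = jitter)
    })
  )
  shifts <- stats::setNames(rep(shift, length(planted)), planted)
  study_spec(variants, n_residues = n_residues, residue_offset = 1,
             frames_per_trajectory = frames, retain_last = retain,
             class_shift = shifts, seed = seed)
}

small_matrix <- function(...) {
  spec <- small_study(...)
  ens <- generate_study(spec)
  build_data_matrix(ens, study_label_table(spec, "drug"), "drug")
}

# Tiny deterministic two-feature matrix where featA separates the classes
# perfectly and featB is noise; 4 variants, n frames each.
toy_matrix <- function(n = 20, seed = 5) {
  set.seed(seed)
  per <- rep(n, 4)
  variant <- rep(c("sa", "sb", "ra", "rb"), times = per)
  cls <- rep(c(0L, 0L, 1L, 1L), times = per)
  angA <- ifelse(cls == 0L, -60, 60) + stats::rnorm(sum(per), 0, 5)
  angB <- stats::runif(sum(per), -180, 180)
  dihedral_matrix(cbind(phi2 = angA, psi2 = angB), variant, cls)
}
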