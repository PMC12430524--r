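test_that("generated ensembles follow the retention scheme and wrap range", {
  spec <- small_study(seed = 21, frames = 40, retain = 15)
  ens <- generate_study(spec)
  expect_length(ens, 12)
  for (e in ens) {
    expect_equal(n_frames(e), 3 * 15)
    expect_true(all(e$angles > -180 & e$angles <= 180))
    expect_equal(sort(unique(e$trajectory)), 1:3)
    # retained tail: frame indices are the final retain_last of each trajectory
    expect_true(all(e$frame >= 40 - 15 + 1 & e$frame <= 40))
  }
  expect_equal(ncol(ens[[1]]$angles), 2 * 12 - 2)
})

test_that("generation is deterministic in the seed", {
  a <- generate_study(small_study(seed = 33))
  b <- generate_study(small_study(seed = 33))
  c <- generate_study(small_study(seed = 34))
  expect_identical(a[[1]]$angles, b[[1]]$angles)
  expect_false(identical(a[[1]]$angles, c[[1]]$angles))
})

test_that("planted class shift appears in the class-conditional circular means", {
  spec <- small_study(seed = 22, frames = 1100, retain = 1000,
                      planted = "phi3", shift = 60, concentration = 25,
                      jitter = 0)
  ens <- generate_study(spec)
  mat <- build_data_matrix(ens, study_label_table(spec, "drug"), "drug")
  m_s <- circular_stats(mat$angles[mat$class == 0L, "phi3"])$mean
  m_r <- circular_stats(mat$angles[mat$class == 1L, "phi3"])$mean
  # n = 3000 per class group and kappa = 25: sampling error well under 2 deg
  expect_equal(abs(wrap_difference(m_r, m_s)), 60, tolerance = 2)
  # an unplanted angle shows no class difference
  m_s0 <- circular_stats(mat$angles[mat$class == 0L, "psi5"])$mean
  m_r0 <- circular_stats(mat$angles[mat$class == 1L, "psi5"])$mean
  expect_lt(abs(wrap_difference(m_r0, m_s0)), 3)
})

test_that("zero planted shifts give identical class distributions in expectation", {
  spec <- small_study(seed = 23, frames = 600, retain = 500,
                      planted = character(0), shift = numeric(0), jitter = 0)
  ens <- generate_study(spec)
  mat <- build_data_matrix(ens, study_label_table(spec, "drug"), "drug")
  d <- wrap_difference(
    circular_col_means(mat$angles[mat$class == 1L, , drop = FALSE]),
    circular_col_means(mat$angles[mat$class == 0L, , drop = FALSE]))
  expect_lt(max(abs(d)), 5)
})

test_that("invalid study parameters are rejected", {
  expect_error(variant_spec("x", "S", concentration = 0), "concentration")
  expect_error(variant_spec("x", "S", mean_shift = c(phi2 = Inf)), "finite")
  expect_error(study_spec(list(variant_spec("x", "S")), n_residues = 3),
               "n_residues")
  expect_error(
    study_spec(list(variant_spec("x", "S")), n_residues = 10,
               frames_per_trajectory = 10, retain_last = 20),
    "retain_last")
  expect_error(
    study_spec(list(variant_spec("x", "S")), n_residues = 10,
               residue_offset = 1, class_shift = c(phi99 = 60)),
    "not in the feature set")
  # class signal planted but only one class on the roster
  spec <- study_spec(list(variant_spec("a", "S"), variant_spec("b", "S")),
                     n_residues = 10, residue_offset = 1,
                     frames_per_trajectory = 10, retain_last = 5,
                     class_shift = c(phi2 = 60))
  expect_error(generate_study(spec), "zero variants")
})

test_that("the default roster matches the per-drug study designs", {
  dab <- braf_study_spec("dabrafenib", include_unknown = FALSE)
  expect_length(dab$variants, 12)
  expect_length(dab$features, 550)
  expect_equal(names(dab$class_shift),
               c("psi494", "phi600", "phi644", "phi663", "psi675", "phi677"))
  vem <- braf_study_spec("vemurafenib", include_unknown = FALSE)
  expect_length(vem$variants, 11)
  labs <- vapply(vem$variants, function(v) v$label, character(1))
  expect_equal(sum(labs == "S"), 6)
  expect_equal(sum(labs == "R"), 5)
})
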