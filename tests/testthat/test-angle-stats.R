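test_that("the reference threshold is the mean per-angle circular SD", {
  set.seed(111)
  # identical dispersion c for every angle -> threshold = c
  kappa <- 12
  m <- sapply(1:6, function(j) rvonmises(4000, runif(1, -180, 180), kappa))
  colnames(m) <- dihedral_feature_names(4, 1)
  expected_sd <- sqrt(-2 * log(besselI(kappa, 1) / besselI(kappa, 0))) * 180 / pi
  expect_equal(wt_threshold(m), expected_sd, tolerance = 0.5)
  expect_error(wt_threshold(m[0, , drop = FALSE]), "empty")
  expect_error(wt_threshold(m[, 1, drop = FALSE]), "at least 2 dihedrals")
})

test_that("planted class offsets are flagged; identical classes are not", {
  mat <- small_matrix(seed = 112, planted = "phi3", shift = 60,
                      concentration = 25, jitter = 0,
                      frames = 120, retain = 60)
  tab <- group_angle_analysis(mat, threshold = 15)
  expect_s3_class(tab, "AngleDiffTable")
  row <- tab[tab$feature == "phi3", ]
  expect_true(row$flag)
  expect_equal(abs(row$difference), 60, tolerance = 4)
  expect_lt(row$p, 1e-6)
  # identical class ensembles: copy S rows as fake R rows
  s_rows <- which(mat$class == 0L)
  half <- seq_len(length(s_rows) %/% 2)
  ang <- mat$angles[s_rows, ]
  cls <- rep(0L, length(s_rows)); cls[half] <- 1L
  null_mat <- dihedral_matrix(ang, mat$variant[s_rows], cls)
  tab0 <- group_angle_analysis(null_mat, threshold = 15)
  expect_false(any(tab0$flag))
  expect_lt(max(abs(tab0$difference)), 10)
})

test_that("under the null the magnitude gate suppresses alpha-level flags", {
  set.seed(113)
  n <- 200
  p <- 110
  ang <- sapply(seq_len(p), function(j) rvonmises(n, runif(1, -180, 180), 15))
  colnames(ang) <- dihedral_feature_names(p / 2 + 1, 1)
  cls <- rep(0:1, each = n / 2)
  mat <- dihedral_matrix(ang, rep(c("a", "b", "c", "d"), each = n / 4), cls)
  tab <- group_angle_analysis(mat, threshold = 15)
  raw_sig <- mean(tab$p < 0.05)
  expect_lt(raw_sig, 0.15)          # about alpha before the gate
  expect_lt(mean(tab$flag), 0.02)   # essentially none after the 15 deg gate
})

test_that("the analysis is invariant to a global +350 degree rotation", {
  mat <- small_matrix(seed = 114, planted = "phi3", shift = 50,
                      concentration = 20, frames = 60, retain = 30)
  tab1 <- group_angle_analysis(mat, threshold = 15)
  shifted <- dihedral_matrix(wrap_angle(mat$angles + 350), mat$variant,
                             mat$class, mat$trajectory, mat$frame)
  tab2 <- group_angle_analysis(shifted, threshold = 15)
  expect_equal(tab2$difference, tab1$difference, tolerance = 1e-9)
  expect_equal(tab2$flag, tab1$flag)
  expect_equal(tab2$p, tab1$p, tolerance = 1e-9)
})

test_that("flag counts decrease monotonically in the threshold", {
  mat <- small_matrix(seed = 115, planted = c("phi3", "psi7"), shift = 45,
                      concentration = 15, frames = 60, retain = 30)
  counts <- vapply(c(0, 10, 20, 40, 90), function(th) {
    sum(group_angle_analysis(mat, threshold = th)$flag)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("per-variant-mean mode agrees with pooling on balanced data", {
  mat <- small_matrix(seed = 116, planted = "phi3", shift = 60,
                      concentration = 25, jitter = 1,
                      frames = 60, retain = 30)
  pooled <- group_angle_analysis(mat, threshold = 15)
  byvar <- group_angle_analysis(mat, threshold = 15, per_variant_means = TRUE)
  expect_equal(byvar$difference[byvar$feature == "phi3"],
               pooled$difference[pooled$feature == "phi3"], tolerance = 5)
})

test_that("profiles split by angle kind over residues", {
  mat <- small_matrix(seed = 117, planted = "phi3", frames = 30, retain = 15)
  tab <- group_angle_analysis(mat, threshold = 15)
  prof <- angle_diff_profiles(tab)
  expect_named(prof, c("phi", "psi"))
  expect_equal(nrow(prof$phi) + nrow(prof$psi), nrow(tab))
  expect_false(is.unsorted(prof$phi$resid))
})

test_that("re-centering maps the reference means to zero and preserves signal", {
  mat <- small_matrix(seed = 118, planted = "phi3", shift = 60,
                      concentration = 20, frames = 60, retain = 30)
  rc <- recenter_matrix(mat, reference = "S01")
  s01 <- which(rc$variant == "S01")
  mu <- circular_col_means(rc$angles[s01, , drop = FALSE])
  expect_lt(max(abs(mu)), 1e-9)
  # class separation on the planted angle is unchanged by the rotation
  d0 <- wrap_difference(
    circular_stats(mat$angles[mat$class == 1L, "phi3"])$mean,
    circular_stats(mat$angles[mat$class == 0L, "phi3"])$mean)
  d1 <- wrap_difference(
    circular_stats(rc$angles[rc$class == 1L, "phi3"])$mean,
    circular_stats(rc$angles[rc$class == 0L, "phi3"])$mean)
  expect_equal(d1, d0, tolerance = 1e-9)
  expect_error(recenter_matrix(mat, reference = "nope"), "no rows")
})
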