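test_that("Kabsch superposition is exact under rigid motion", {
  set.seed(121)
  X <- matrix(rnorm(30, sd = 5), 10, 3)
  expect_equal(kabsch_rmsd(X, X)$rmsd, 0, tolerance = 1e-12)
  for (i in 1:10) {
    Y <- random_rigid(X)
    expect_lt(kabsch_rmsd(X, Y)$rmsd, 1e-9)
    # symmetry in the arguments
    expect_equal(kabsch_rmsd(X, Y)$rmsd, kabsch_rmsd(Y, X)$rmsd,
                 tolerance = 1e-9)
  }
  R <- kabsch_rmsd(X, random_rigid(X))$rotation
  expect_equal(det(R), 1, tolerance = 1e-9)  # proper rotation enforced
})

test_that("Kabsch RMSD matches a numerical-optimizer oracle", {
  set.seed(122)
  X <- matrix(rnorm(30, sd = 3), 10, 3)
  Y <- X
  Y[4, ] <- Y[4, ] + c(1, 0, 0)  # one point displaced 1 Angstrom
  got <- kabsch_rmsd(X, Y)$rmsd
  expect_equal(got, oracle_rmsd(X, Y), tolerance = 1e-6)
  # also on a noisy pair
  Z <- random_rigid(X + matrix(rnorm(30, sd = 0.3), 10, 3))
  expect_equal(kabsch_rmsd(X, Z)$rmsd, oracle_rmsd(X, Z), tolerance = 1e-6)
})

test_that("degenerate point sets are rejected", {
  expect_error(kabsch_rmsd(matrix(0, 2, 3), matrix(0, 2, 3)), "3 points")
  line <- cbind(1:5, 0, 0) * 1.0
  expect_error(kabsch_rmsd(line, line), "rank-deficient")
})

test_that("rmsd_series is zero at the reference and nonnegative", {
  set.seed(123)
  n <- 6
  frames <- lapply(1:4, function(i) {
    build_backbone_from_torsions(runif(2 * n - 2, -179, 180))
  })
  co <- array(unlist(frames), c(3 * n, 3, 4))
  fs <- frame_set("v", coords = co, residue_numbers = 1:n)
  rs <- rmsd_series(fs)
  expect_equal(rs$rmsd[1], 0, tolerance = 1e-9)
  expect_true(all(rs$rmsd >= 0))
})

test_that("plateau detection finds the start of a constant tail", {
  set.seed(124)
  rising <- c(seq(0, 2, length.out = 300), rep(2, 700)) + rnorm(1000, 0, 0.01)
  idx <- rmsd_plateau(rising, window = 100, tol_slope = 1e-3, tol_sd = 0.05)
  expect_gte(idx, 250)
  expect_lte(idx, 320)
  # monotonically rising series: no plateau
  expect_warning(
    none <- rmsd_plateau(seq(0, 5, length.out = 500), window = 100,
                         tol_slope = 1e-3, tol_sd = 0.05),
    "no stable tail")
  expect_true(is.na(none))
  expect_warning(short <- rmsd_plateau(1:5, window = 10), "shorter")
  expect_true(is.na(short))
})

test_that("Ramachandran window distance is 0 for identical, ~1 for disjoint", {
  mat <- small_matrix(seed = 125, planted = "phi3", frames = 40, retain = 20)
  n <- nrow(mat$angles)
  a <- 1:(n %/% 2); b <- (n %/% 2 + 1):n
  # duplicated windows: literally the same rows copied into disjoint slots
  dup <- dihedral_matrix(rbind(mat$angles[a, ], mat$angles[a, ]),
                         rep("v", 2 * length(a)), rep(0L, 2 * length(a)))
  expect_equal(
    ramachandran_window_agreement(dup, a, a + length(a)), 0, tolerance = 1e-12)
  # disjoint angle modes: shift one window's angles by 180
  disj <- dihedral_matrix(rbind(mat$angles[a, ],
                                wrap_angle(mat$angles[a, ] + 180)),
                          rep("v", 2 * length(a)), rep(0L, 2 * length(a)))
  expect_gt(ramachandran_window_agreement(disj, a, a + length(a)), 0.9)
  expect_error(ramachandran_window_agreement(mat, integer(0), b), "empty")
  expect_error(ramachandran_window_agreement(mat, a, a), "disjoint")
})

test_that("stationary same-generator windows sit near zero distance", {
  # enough pooled (phi, psi) points that sampling noise sits well below
  # any real distributional change
  mat <- small_matrix(seed = 126, planted = "phi5", concentration = 8,
                      frames = 600, retain = 600, n_residues = 30)
  one <- which(mat$variant == "S01")
  half <- length(one) %/% 2
  d <- ramachandran_window_agreement(mat, one[1:half],
                                     one[(half + 1):length(one)])
  # at this reduced size (25k points/window) the multinomial noise floor is
  # near 0.1; the full-scale null (274k points/window) is checked in the
  # acceptance suite at its tighter bound
  expect_lt(d, 0.15)
  # and stationary windows sit nowhere near the disjoint-support bound
  expect_lt(d, 0.5)
})

test_that("windowed selection is stable under stationarity, degraded by drift", {
  mat <- small_matrix(seed = 127, planted = c("phi3", "psi7"), shift = 60,
                      concentration = 20, frames = 200, retain = 200,
                      n_residues = 12)
  # windows are frame-index ranges so each contains every variant
  w <- list(which(mat$frame <= 66),
            which(mat$frame > 66 & mat$frame <= 133),
            which(mat$frame > 133))
  st <- windowed_selection_stability(mat, w, n_rounds = 1)
  expect_true(all(st$vs_full >= 0.5))
  expect_equal(diag(st$pairwise), rep(1, 3), ignore_attr = TRUE)
  # identical windows have Jaccard 1
  st2 <- windowed_selection_stability(mat, list(a = w[[1]], b = w[[1]]),
                                      n_rounds = 1)
  expect_equal(st2$pairwise["a", "b"], 1)
  # drifted early window: swamp the planted signal on other angles
  drift <- mat
  early <- w[[1]]
  drift$angles[early, "psi5"] <-
    wrap_angle(drift$angles[early, "psi5"] +
                 ifelse(drift$class[early] == 1L, 120, -120))
  st3 <- windowed_selection_stability(drift, w, n_rounds = 1)
  expect_lt(st3$vs_full[[1]], 1)
  expect_lt(st3$pairwise[1, 2], st$pairwise[1, 2] + 1e-9)
  expect_error(windowed_selection_stability(mat, w[1]), "at least 2")
  expect_warning(
    windowed_selection_stability(mat, list(a = w[[1]], b = w[[2]], c = 1:3)),
    "too small")
})
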