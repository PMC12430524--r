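test_that("forests are deterministic in the seed and separate separable data", {
  mat <- toy_matrix(n = 25, seed = 71)
  m1 <- train_forest(mat, c("phi2", "psi2"), n_trees = 20, seed = 9)
  m2 <- train_forest(mat, c("phi2", "psi2"), n_trees = 20, seed = 9)
  expect_identical(predict(m1, mat), predict(m2, mat))
  expect_equal(mean(predict(m1, mat) == mat$class), 1)
  m3 <- train_forest(mat, c("phi2", "psi2"), n_trees = 20, seed = 10)
  expect_false(identical(m1$trees, m3$trees))
})

test_that("a 1-tree unbootstrapped forest equals the single fitted tree", {
  mat <- small_matrix(seed = 72, planted = "phi3", concentration = 10,
                      frames = 60, retain = 30)
  forest <- train_forest(mat, c("phi3", "psi5"), n_trees = 1, seed = 1,
                         bootstrap = FALSE, max_depth = 2,
                         mtry = 2)
  tree <- fit_tree(mat, c("phi3", "psi5"), max_depth = 2)
  expect_identical(predict(forest, mat), predict(tree, mat$angles))
})

test_that("forest votes respect the tie-to-sensitive rule", {
  mat <- toy_matrix(n = 25, seed = 73)
  model <- train_forest(mat, c("phi2"), n_trees = 10, seed = 2)
  # hand-built predictions: 1600 of 3000 frames resistant
  fake <- model
  p <- predict_variant(model, mat$angles[mat$class == 1L, , drop = FALSE],
                       variant = "allR")
  expect_equal(p$label, "R")
  expect_equal(p$vote_fraction, 1.0)
  # exact 50/50 split -> sensitive, flagged
  half <- rbind(mat$angles[mat$class == 1L, ][1:10, ],
                mat$angles[mat$class == 0L, ][1:10, ])
  ph <- predict_variant(model, half, variant = "tie")
  expect_equal(ph$label, "S")
  expect_true(ph$low_confidence)
  expect_equal(ph$vote_fraction, 0.5)
  expect_error(predict_variant(model, mat$angles[0, , drop = FALSE]),
               "zero frames")
})

test_that("variant aggregation reports the majority fraction", {
  set.seed(74)
  mat <- toy_matrix(n = 25, seed = 74)
  model <- train_forest(mat, c("phi2"), n_trees = 11, seed = 3)
  # 1600 R-like of 3000 frames -> R at ~0.533
  n_r <- 1600; n_s <- 1400
  frames <- rbind(
    cbind(phi2 = rnorm(n_r, 60, 5), psi2 = runif(n_r, -180, 180)),
    cbind(phi2 = rnorm(n_s, -60, 5), psi2 = runif(n_s, -180, 180)))
  p <- predict_variant(model, frames, variant = "mix")
  expect_equal(p$label, "R")
  expect_equal(p$vote_fraction, n_r / (n_r + n_s), tolerance = 0.02)
})

test_that("LOVO evaluation is leak-free, order-invariant and accurate on planted signal", {
  mat <- small_matrix(seed = 75, planted = c("phi3", "psi7"), shift = 60,
                      concentration = 20, frames = 60, retain = 30)
  lv <- lovo_evaluate(mat, c("phi3", "psi7"), n_trees = 15, seed = 4)
  expect_equal(lv$accuracy, 1)
  expect_equal(nrow(lv$per_variant), 12)
  # frame order must not change variant calls
  set.seed(76)
  perm <- sample(nrow(mat$angles))
  mat_perm <- dihedral_matrix(mat$angles[perm, ], mat$variant[perm],
                              mat$class[perm], mat$trajectory[perm],
                              mat$frame[perm])
  lv2 <- lovo_evaluate(mat_perm, c("phi3", "psi7"), n_trees = 15, seed = 4)
  ord <- match(lv$per_variant$variant, lv2$per_variant$variant)
  expect_equal(lv$per_variant$predicted, lv2$per_variant$predicted[ord])
})

test_that("LOVO refuses folds whose training set would be single-class", {
  spec <- small_study(seed = 77, n_s = 1, n_r = 1, frames = 30, retain = 15,
                      planted = "phi3")
  ens <- generate_study(spec)
  mat <- build_data_matrix(ens, study_label_table(spec, "drug"), "drug")
  expect_error(lovo_evaluate(mat, "phi3", n_trees = 5, seed = 1),
               "at least 2 variants")
})

test_that("subset comparison unions rounds, deduplicates, and ranks signal subsets", {
  mat <- small_matrix(seed = 78, planted = c("phi3", "psi7"), shift = 60,
                      concentration = 20, frames = 60, retain = 30)
  sel <- iterative_selection(mat, n_rounds = 2)
  tab <- subset_comparison(mat, sel, list(1, 2, c(1, 2), c(2, 1)),
                           n_trees = 15, seed = 5)
  expect_equal(nrow(tab), 3)  # duplicated {1,2} evaluated once
  expect_equal(tab$rounds, c("1", "2", "1,2"))
  # only round 1 carries planted signal: subsets containing it dominate
  acc <- setNames(tab$accuracy, tab$rounds)
  expect_gte(acc[["1"]], acc[["2"]])
  expect_gte(acc[["1,2"]], acc[["2"]])
})

test_that("unknown variants get exactly one call each; none is fine", {
  spec <- small_study(seed = 79, planted = "phi3", shift = 60,
                      concentration = 20, frames = 60, retain = 30)
  # add unknowns: one drawn like an S variant, by reusing the S baseline
  ens <- generate_study(spec)
  lab <- study_label_table(spec, "drug")
  mat <- build_data_matrix(ens, lab, "drug")
  model_frames <- ens[["S01"]]
  vus <- frame_set("VUS1", angles = model_frames$angles,
                   trajectory = model_frames$trajectory,
                   frame = model_frames$frame)
  preds <- predict_unknowns(mat, "phi3", list(vus), n_trees = 15, seed = 6)
  expect_length(preds, 1)
  # distributionally identical to a training sensitive variant -> S
  expect_equal(preds[["VUS1"]]$label, "S")
  empty <- predict_unknowns(mat, "phi3", list(), n_trees = 15, seed = 6)
  expect_length(empty, 0)
  expect_error(train_forest(mat, character(0), n_trees = 5, seed = 1),
               "empty feature list")
})

test_that("forest decisions agree with an established implementation on separable data", {
  skip_if_not_installed("randomForest")
  mat <- toy_matrix(n = 40, seed = 80)
  ours <- train_forest(mat, c("phi2", "psi2"), n_trees = 50, seed = 7)
  rf <- randomForest::randomForest(
    x = as.data.frame(mat$angles), y = factor(mat$class), ntree = 50)
  set.seed(81)
  test <- cbind(phi2 = c(rnorm(20, -60, 5), rnorm(20, 60, 5)),
                psi2 = runif(40, -180, 180))
  want <- rep(c(0L, 1L), each = 20)
  expect_equal(predict(ours, test), want)
  expect_equal(as.integer(as.character(
    predict(rf, as.data.frame(test)))), want)
})
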