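test_that("Shapley axioms hold on toy forests", {
  mat <- toy_matrix(n = 25, seed = 101)
  model <- train_forest(mat, c("phi2", "psi2"), n_trees = 25, seed = 1,
                        mtry = 2)
  bg <- mat$angles[1:40, ]
  # null player: psi2 is noise the trees never use when phi2 separates
  frame <- mat$angles[1, ]
  ex <- exact_shapley(model, frame, bg)
  expect_equal(ex$base + sum(ex$values), ex$output, tolerance = 1e-9)
  # constant model: every attribution is exactly 0
  const_fn <- function(model, m) rep(0.7, nrow(m))
  ex0 <- exact_shapley(model, frame, bg, output_fn = const_fn)
  expect_equal(unname(ex0$values), c(0, 0))
  expect_equal(ex0$base, 0.7)
})

test_that("single-feature attribution equals output minus base", {
  mat <- toy_matrix(n = 25, seed = 102)
  model <- train_forest(mat, "phi2", n_trees = 15, seed = 2)
  bg <- mat$angles[sample(nrow(mat$angles), 30), , drop = FALSE]
  frame <- mat$angles[3, ]
  ex <- exact_shapley(model, frame, bg)
  expect_equal(unname(ex$values[["phi2"]]), ex$output - ex$base,
               tolerance = 1e-12)
})

test_that("coalition enumeration equals the permutation-enumeration oracle", {
  set.seed(103)
  n <- 60
  ang <- cbind(phi2 = rnorm(n, ifelse(rep(0:1, each = n / 2), 40, -40), 10),
               psi2 = runif(n, -180, 180),
               phi3 = rnorm(n, ifelse(rep(0:1, each = n / 2), -20, 20), 15))
  mat <- dihedral_matrix(ang, rep(c("a", "b", "c", "d"), each = n / 4),
                         rep(0:1, each = n / 2))
  model <- train_forest(mat, c("phi2", "psi2", "phi3"), n_trees = 20,
                        seed = 3, mtry = 2)
  bg <- ang[seq(1, n, by = 3), ]
  for (row in c(1, 17, 42)) {
    ours <- exact_shapley(model, ang[row, ], bg)
    theirs <- oracle_shapley(model, as.list(ang[row, ]), bg)
    expect_equal(ours$values, theirs, tolerance = 1e-12)
  }
})

test_that("symmetric players in the value function get equal attribution", {
  # the axiom concerns the model, not the data: use a model that treats the
  # two duplicated angles exactly symmetrically
  set.seed(104)
  n <- 40
  a <- c(rnorm(n / 2, -60, 5), rnorm(n / 2, 60, 5))
  ang <- cbind(phi2 = a, phi3 = a)
  sym_model <- structure(list(features = c("phi2", "phi3")),
                         class = "ForestModel")
  sym_fn <- function(model, m) ((m[, "phi2"] > 0) + (m[, "phi3"] > 0)) / 2
  ex <- exact_shapley(sym_model, ang[n, ], ang, output_fn = sym_fn)
  expect_equal(ex$values[["phi2"]], ex$values[["phi3"]], tolerance = 1e-12)
  expect_equal(ex$base + sum(ex$values), ex$output, tolerance = 1e-12)
})

test_that("summary ranks the determining angle first with correct signs", {
  mat <- small_matrix(seed = 105, planted = "phi3", shift = 80,
                      concentration = 25, jitter = 2,
                      frames = 60, retain = 30)
  model <- train_forest(mat, c("phi3", "psi5"), n_trees = 25, seed = 5,
                        mtry = 2)
  sm <- shap_summary(model, mat, max_rows = 60, seed = 6)
  expect_equal(names(sm$ranking)[1], "phi3")
  expect_lt(sm$local_accuracy_error, 1e-9)
  # frames of the sensitive mode push toward S (negative values)
  s_frames <- which(mat$class == 0L)
  tab <- sm$table
  s_shap <- tab$shapley[tab$feature == "phi3" & tab$frame %in% s_frames]
  r_shap <- tab$shapley[tab$feature == "phi3" & !(tab$frame %in% s_frames)]
  expect_lt(mean(s_shap), 0)
  expect_gt(mean(r_shap), 0)
})

test_that("too many features for exact enumeration is a clear error", {
  mat <- small_matrix(seed = 106, n_residues = 12, frames = 20, retain = 10,
                      planted = "phi3")
  feats <- colnames(mat$angles)[1:17]
  model <- structure(list(features = feats), class = "ForestModel")
  expect_error(exact_shapley(model, mat$angles[1, ], mat$angles),
               "16 features")
})

test_that("shap tables export as TSV and JSON", {
  mat <- toy_matrix(n = 10, seed = 107)
  model <- train_forest(mat, c("phi2", "psi2"), n_trees = 10, seed = 7)
  sm <- shap_summary(model, mat, max_rows = 10, seed = 8)
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_shap_summary(sm, tsv, js)
  tab <- read.delim(tsv)
  expect_named(tab, c("frame", "feature", "value", "shapley"))
  j <- jsonlite::read_json(js)
  expect_setequal(names(j), c("phi2", "psi2"))
})
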