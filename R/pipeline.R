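#' Build and validate a pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one validated
#' object. Unknown keys are rejected; a seed is mandatory because every
#' stage past featurization is stochastic.
#'
#' @param config named list or path to a YAML file with (a subset of) the
#'   keys of the defaults below; values given here override the file.
#' @param ... individual key overrides.
#' @return object of class \code{PipelineConfig} (a validated named list).
#' @export
pipeline_config <- function(config = list(), ...) {
  defaults <- list(
    drug = "dabrafenib",          # roster/labels to use
    label_table = NULL,           # TSV path; NULL = bundled roster
    n_residues = 276L,
    residue_offset = 448L,
    frames_per_trajectory = 10000L,
    trajectories_per_variant = 3L,
    retain_last = 1000L,
    planted = NULL,               # planted feature names; NULL = drug default
    planted_shift = 60,           # degrees, class separation of planted angles
    concentration = 8,            # von Mises kappa per angle
    variant_jitter_sd = 5,        # degrees
    selection_rounds = 3L,
    selection_depth = 2L,
    min_leaf = 5L,
    n_trees = 100L,
    forest_depth = 5L,
    shap_frames = 100L,           # frames attributed in the SHAP summary
    threshold = 15,               # degrees, angle-difference magnitude gate
    alpha = 0.05,
    bin_width = 10,               # degrees, Ramachandran bins
    seed = NULL,                  # REQUIRED
    out_dir = NULL                # NULL = tables returned, not written
  )
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop(sprintf("pipeline_config(): no such config file: %s", config))
    }
    config <- yaml::read_yaml(config)
  }
  config <- utils::modifyList(config, list(...))
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop(sprintf("pipeline_config(): unknown key(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$seed)) stop("pipeline_config(): a seed is required")
  cfg$seed <- as.integer(cfg$seed)
  if (!cfg$drug %in% c("dabrafenib", "vemurafenib")) {
    stop("pipeline_config(): drug must be 'dabrafenib' or 'vemurafenib'")
  }
  if (!is.null(cfg$label_table) && !file.exists(cfg$label_table)) {
    stop(sprintf("pipeline_config(): label table not found: %s", cfg$label_table))
  }
  structure(cfg, class = "PipelineConfig")
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Executes the workflow end to end: generate the synthetic ensembles for
#' the configured drug roster, assemble the frame-level dihedral matrix,
#' run the iterative tree selection, evaluate the selected features by
#' leave-one-variant-out classification (plus the round-subset comparison
#' and unknown-variant predictions), compute the performance metrics,
#' Shapley attributions, the per-dihedral class-difference table, and the
#' Ramachandran window agreement. With \code{out_dir} set, every table is
#' written (TSV/JSON) together with a manifest recording the config, seed
#' and per-file checksums; identical configs reproduce identical outputs.
#'
#' @param config a \code{\link{pipeline_config}} (or anything accepted by
#'   it).
#' @return named list with elements \code{config}, \code{matrix},
#'   \code{selection}, \code{lovo}, \code{subset_table}, \code{metrics},
#'   \code{vus}, \code{shap}, \code{angle_table}, \code{rama_distance},
#'   and \code{manifest} (NULL unless written).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "PipelineConfig")) config else pipeline_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  labels <- stage("labels", {
    if (is.null(cfg$label_table)) variant_label_table()
    else read_label_table(cfg$label_table)
  })
  spec <- stage("simulate", braf_study_spec(
    drug = cfg$drug, planted = cfg$planted, planted_shift = cfg$planted_shift,
    concentration = cfg$concentration,
    variant_jitter_sd = cfg$variant_jitter_sd, seed = cfg$seed,
    n_residues = cfg$n_residues, residue_offset = cfg$residue_offset,
    frames_per_trajectory = cfg$frames_per_trajectory,
    trajectories_per_variant = cfg$trajectories_per_variant,
    retain_last = cfg$retain_last))
  ensembles <- stage("simulate", generate_study(spec))
  mat <- stage("extract", build_data_matrix(ensembles, labels, cfg$drug))
  vus_mat <- stage("extract", tryCatch(
    build_data_matrix(ensembles, labels, cfg$drug, include_unknown = TRUE),
    error = function(e) NULL))
  sel <- stage("select", iterative_selection(
    mat, n_rounds = cfg$selection_rounds, max_depth = cfg$selection_depth,
    min_leaf = cfg$min_leaf))
  feats <- selected_features(sel)
  lovo <- stage("classify", lovo_evaluate(
    mat, feats, n_trees = cfg$n_trees, seed = cfg$seed,
    max_depth = cfg$forest_depth, min_leaf = cfg$min_leaf))
  nr <- length(sel$rounds)
  subsets <- c(list(seq_len(nr)),
               if (nr > 1) lapply(seq_len(nr), function(d) setdiff(seq_len(nr), d)))
  subset_table <- stage("classify", subset_comparison(
    mat, sel, subsets, n_trees = cfg$n_trees, seed = cfg$seed,
    max_depth = cfg$forest_depth, min_leaf = cfg$min_leaf))
  metrics <- stage("evaluate", confusion_and_metrics(
    lovo$per_variant$truth, lovo$per_variant$predicted))
  vus <- stage("classify", {
    if (is.null(vus_mat)) list()
    else predict_unknowns(mat, feats, vus_mat, n_trees = cfg$n_trees,
                          seed = cfg$seed, max_depth = cfg$forest_depth,
                          min_leaf = cfg$min_leaf)
  })
  model <- stage("attribute", train_forest(
    mat, feats, n_trees = cfg$n_trees, seed = cfg$seed,
    max_depth = cfg$forest_depth, min_leaf = cfg$min_leaf))
  shap <- stage("attribute", shap_summary(
    model, mat, max_rows = cfg$shap_frames, seed = cfg$seed))
  angle_table <- stage("anglediff", group_angle_analysis(
    mat, threshold = cfg$threshold, alpha = cfg$alpha))
  rama <- stage("converge", {
    half <- cfg$retain_last %/% 2L
    early <- which(mat$frame <= cfg$frames_per_trajectory - half)
    late <- which(mat$frame > cfg$frames_per_trajectory - half)
    ramachandran_window_agreement(mat, early, late, bin_width = cfg$bin_width)
  })
  result <- list(config = cfg, matrix = mat, selection = sel, lovo = lovo,
                 subset_table = subset_table, metrics = metrics, vus = vus,
                 shap = shap, angle_table = angle_table,
                 rama_distance = rama, manifest = NULL)
  if (!is.null(cfg$out_dir)) {
    result$manifest <- write_pipeline_outputs(result, cfg$out_dir)
  }
  result
}

# Write every pipeline table under out_dir and return the manifest.
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  utils::write.table(result$subset_table, p("subset_comparison.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$lovo$per_variant, p("variant_predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(result$vus) > 0) {
    vdf <- data.frame(
      variant = names(result$vus),
      predicted = vapply(result$vus, function(x) x$label, character(1)),
      vote_fraction = vapply(result$vus, function(x) x$vote_fraction, numeric(1)))
    utils::write.table(vdf, p("vus_predictions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_metrics_tsv(result$metrics, p("metrics.tsv"))
  write_selection_json(result$selection, p("selection.json"))
  write_shap_summary(result$shap, p("shap_values.tsv"), p("shap_ranking.json"))
  utils::write.table(as.data.frame(result$angle_table), p("angle_differences.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(rama_distance = result$rama_distance),
                       p("convergence.json"), auto_unbox = TRUE, digits = NA)
  files <- sort(list.files(out_dir, full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  cfg_plain <- unclass(result$config)
  cfg_file <- tempfile()
  writeLines(yaml::as.yaml(cfg_plain), cfg_file)
  manifest <- list(
    config = cfg_plain,
    config_md5 = unname(tools::md5sum(cfg_file)),
    seed = result$config$seed,
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files))))
  unlink(cfg_file)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest
}
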