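#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run. The defaults reproduce the
#' reference configuration for a real dataset and a 1000-wide backbone:
#' class balancing to 700 per class, 512 x 512 working resolution, ReliefF
#' with 10 neighbors, a full ranked-prefix sweep (`step = 1`,
#' `max_prefix = NULL` meaning all columns), cubic SVM (degree 3, box
#' constraint 1, automatic kernel scale, standardization) under 10-fold
#' cross-validation. Desk-scale runs override `target_per_class`,
#' `backbone_args`, `step` and `max_prefix`.
#'
#' @param input_dir dataset root in the class-per-subdirectory layout;
#'   mutually exclusive with `phantom`.
#' @param phantom a [phantom_spec()] to generate inputs synthetically.
#' @param target_per_class per-class record count after augmentation
#'   balancing; `NULL` skips balancing.
#' @param image_side working resolution (default 512).
#' @param backbone backbone registry name (default `"stub"`).
#' @param backbone_args arguments for the backbone factory (for the stub:
#'   `output_dim`, `seed`, `grid`).
#' @param k_neighbors ReliefF neighbors (default 10).
#' @param step,max_prefix ranked-prefix sweep controls (see
#'   [iterative_select()]).
#' @param svm an [svm_config()].
#' @param n_folds cross-validation folds (default 10).
#' @param seed master seed; per-stage seeds are derived from it
#'   deterministically so stages can be re-run in isolation.
#' @param output_dir optional directory for artifacts (manifest CSV,
#'   feature CSV for small matrices, ranking/selection/report JSON, config
#'   snapshot).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, phantom = NULL,
                            target_per_class = 700L, image_side = 512L,
                            backbone = "stub",
                            backbone_args = list(output_dim = 32L),
                            k_neighbors = 10L, step = 1L,
                            max_prefix = NULL, svm = svm_config(),
                            n_folds = 10L, seed = 1L, output_dir = NULL) {
  if (is.null(input_dir) && is.null(phantom))
    stop("provide input_dir or a phantom spec")
  if (!is.null(input_dir) && !is.null(phantom))
    stop("input_dir and phantom are mutually exclusive")
  structure(list(input_dir = input_dir, phantom = phantom,
                 target_per_class = target_per_class,
                 image_side = as.integer(image_side), backbone = backbone,
                 backbone_args = backbone_args,
                 k_neighbors = as.integer(k_neighbors),
                 step = as.integer(step), max_prefix = max_prefix,
                 svm = svm, n_folds = as.integer(n_folds),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

stage_log <- function(fmt, ...) message(sprintf(paste0("[pyrads] ", fmt), ...))

config_snapshot <- function(config) {
  snap <- config
  snap$svm <- unclass(snap$svm)
  if (!is.null(snap$phantom)) snap$phantom <- unclass(snap$phantom)
  unclass(snap)
}

resolve_extractor <- function(config) {
  args <- config$backbone_args
  if (identical(config$backbone, "stub") && is.null(args$seed))
    args$seed <- derive_seed(config$seed, "extract")
  do.call(get_backbone, c(list(config$backbone), args))
}

#' Run the full pipeline: prepare, extract, select, evaluate
#'
#' Stages, in order: (1) load or synthesize the dataset and balance class
#' sizes by seeded augmentation; (2) build the 21-image pyramid per case
#' and extract concatenated backbone features; (3) min-max normalize,
#' weight features with ReliefF, and pick the loss-minimizing ranked
#' prefix with the cross-validated cubic-SVM loss; (4) evaluate the
#' selected subset under stratified cross-validation with pooled confusion
#' counts. Any stage error aborts with the stage name. All randomness is
#' derived from the master seed.
#'
#' @param config a [pipeline_config()].
#' @return object of class `pipeline_result`: list with `manifest`,
#'   `features`, `ranked`, `selection`, `report`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))

  t0 <- Sys.time()
  manifest <- with_stage("prepare", {
    m <- if (!is.null(config$input_dir)) load_dataset(config$input_dir)
         else generate_phantoms(config$phantom)
    if (!is.null(config$target_per_class))
      m <- balance_by_augmentation(m, config$target_per_class,
                                   rng_seed = derive_seed(config$seed,
                                                          "prepare"))
    m
  })
  cc <- class_counts(manifest)
  stage_log("prepare: %d records (%s) [%.1fs]", length(manifest),
            paste(sprintf("%s=%d", names(cc), cc), collapse = ", "),
            as.numeric(Sys.time() - t0, units = "secs"))

  t0 <- Sys.time()
  fm <- with_stage("extract", {
    extractor <- resolve_extractor(config)
    extract_dataset(extractor, manifest, side = config$image_side,
                    pyramidal = TRUE)
  })
  stage_log("extract: %d x %d feature matrix [%.1fs]", nrow(fm$values),
            ncol(fm$values), as.numeric(Sys.time() - t0, units = "secs"))

  t0 <- Sys.time()
  sel <- with_stage("select", {
    normed <- minmax_normalize(fm)
    ranked <- relieff_rank(normed, k_neighbors = config$k_neighbors)
    folds <- stratified_folds(fm$labels, n_folds = config$n_folds,
                              seed = derive_seed(config$seed, "select"))
    evaluator <- function(Xs, y) cv_svm_loss(Xs, y, config$svm, folds)
    list(ranked = ranked,
         selection = iterative_select(fm, ranked = ranked,
                                      evaluator = evaluator,
                                      max_prefix = config$max_prefix,
                                      step = config$step))
  })
  stage_log("select: best prefix %d of %d (loss %.4f) [%.1fs]",
            sel$selection$best_size, ncol(fm$values),
            min(sel$selection$loss_curve),
            as.numeric(Sys.time() - t0, units = "secs"))

  t0 <- Sys.time()
  report <- with_stage("evaluate", {
    evaluate(fm$values[, sel$selection$selected_columns, drop = FALSE],
             fm$labels, config = config$svm, n_folds = config$n_folds,
             seed = derive_seed(config$seed, "evaluate"))
  })
  stage_log("evaluate: accuracy %.4f [%.1fs]", report$metrics["accuracy"],
            as.numeric(Sys.time() - t0, units = "secs"))

  result <- structure(list(manifest = manifest, features = fm,
                           ranked = sel$ranked, selection = sel$selection,
                           report = report, config = config),
                      class = "pipeline_result")
  if (!is.null(config$output_dir)) write_artifacts(result)
  result
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

write_artifacts <- function(result) {
  dir.create(result$config$output_dir, showWarnings = FALSE,
             recursive = TRUE)
  out <- function(f) file.path(result$config$output_dir, f)
  man <- do.call(rbind, lapply(result$manifest$records, function(r)
    data.frame(source_id = r$source_id, label = r$label,
               is_augmented = r$is_augmented,
               transform_log = as.character(
                 jsonlite::toJSON(r$transform_log, auto_unbox = TRUE)))))
  utils::write.csv(man, out("manifest.csv"), row.names = FALSE)
  if (length(result$features$values) <= 2e6)
    write_feature_csv(result$features, out("features.csv"))
  jsonlite::write_json(list(weights = result$ranked$weights,
                            order = result$ranked$order,
                            priors = as.list(result$ranked$priors)),
                       out("ranking.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(prefix_sizes = result$selection$prefix_sizes,
                            loss_curve = unname(result$selection$loss_curve),
                            best_size = result$selection$best_size,
                            selected_columns =
                              result$selection$selected_columns),
                       out("selection.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(counts = unclass(result$report$counts),
                            metrics = as.list(result$report$metrics),
                            seed = result$report$seed,
                            positive_class = result$report$positive_class),
                       out("report.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(config_snapshot(result$config),
                       out("config.json"), auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(result$config$output_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n  ")
  print(x$report)
  cat(sprintf("  selected %d / %d features\n", x$selection$best_size,
              ncol(x$features$values)))
  invisible(x)
}

#' Backbone x classifier accuracy grid, plain and pyramidal
#'
#' Prepares the dataset once, extracts features for every backbone in both
#' modes (plain: original image only; pyramidal: the 21-image pyramid,
#' whose feature width is 21x the plain width) and tabulates pooled CV
#' accuracy per classifier. Per-cell failures are recorded as `NA` with a
#' warning and the run continues.
#'
#' @param config a [pipeline_config()].
#' @param backbones named list of `backbone_extractor` objects; defaults to
#'   the stub resolved from `config`.
#' @param classifiers named list of classifier functions (see
#'   [grid_benchmark()]); defaults to the cubic SVM.
#' @return data frame with columns `feature_set` (rows named
#'   `<backbone>_plain` / `<backbone>_pyramidal`) and one accuracy column
#'   per classifier; written to `grid.csv` under `output_dir` when set.
#' @export
run_grid <- function(config, backbones = NULL, classifiers = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(backbones))
    backbones <- stats::setNames(list(resolve_extractor(config)),
                                 config$backbone)
  if (is.null(classifiers))
    classifiers <- list(cubic_svm = classifier_cubic_svm(config$svm))
  manifest <- with_stage("prepare", {
    m <- if (!is.null(config$input_dir)) load_dataset(config$input_dir)
         else generate_phantoms(config$phantom)
    if (!is.null(config$target_per_class))
      m <- balance_by_augmentation(m, config$target_per_class,
                                   rng_seed = derive_seed(config$seed,
                                                          "prepare"))
    m
  })
  feature_sets <- list()
  for (bb in names(backbones)) {
    feature_sets[[paste0(bb, "_plain")]] <-
      extract_dataset(backbones[[bb]], manifest, side = config$image_side,
                      pyramidal = FALSE)
    feature_sets[[paste0(bb, "_pyramidal")]] <-
      extract_dataset(backbones[[bb]], manifest, side = config$image_side,
                      pyramidal = TRUE)
  }
  tab <- grid_benchmark(feature_sets, classifiers,
                        n_folds = config$n_folds,
                        seed = derive_seed(config$seed, "grid"))
  tab <- cbind(data.frame(feature_set = rownames(tab)), tab)
  rownames(tab) <- NULL
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(config$output_dir, "grid.csv"),
                     row.names = FALSE)
  }
  tab
}
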