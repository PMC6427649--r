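#' Pipeline configuration
#'
#' Nested stage configurations for [run_pipeline()].
#'
#' @param matching A [matching_config()] (default: SGM, 15x15 window,
#'   128 px range).
#' @param rectify_policy Output sizing policy for
#'   [build_rectification()].
#' @param target_count Down-sampling budget (default 4096).
#' @param K Mixture components (default 10).
#' @param gmm_seed Seed for the mixture fit (default 0).
#' @param knn_k,knn_alpha Outlier-filter parameters (defaults 10 and 1).
#' @param crop_rule Crop selection rule for [select_crop_component()].
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(matching = matching_config("sgm"),
                            rectify_policy = "preserve_all",
                            target_count = 4096, K = 10, gmm_seed = 0,
                            knn_k = 10, knn_alpha = 1,
                            crop_rule = "lowest_mean_z") {
  structure(list(matching = matching, rectify_policy = rectify_policy,
                 target_count = target_count, K = K, gmm_seed = gmm_seed,
                 knn_k = knn_k, knn_alpha = knn_alpha,
                 crop_rule = crop_rule),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full seedling-recognition pipeline
#'
#' Executes, in order: epipolar rectification, stereo matching, 3D
#' reconstruction, invalid-point removal, non-uniform grid
#' down-sampling, Gaussian-mixture clustering, crop-component selection
#' by height advantage, and KNN outlier filtering. When `output_dir` is
#' given every intermediate artifact is persisted (rectified images,
#' disparity map + mask, dense/sparse/crop clouds as PLY, and a JSON
#' report), so later analyses can start from any stage.
#'
#' @param left,right The stereo pair (`[0, 1]` RGB arrays or PNG paths).
#' @param calib A [stereo_calibration()] or path to a calibration YAML.
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory for artifacts.
#' @param verbose Print stage progress (default `FALSE`).
#' @return List of class `seedling_pipeline`: `crop` (filtered crop
#'   [point_cloud()]), `report` (stage point counts, crop weight,
#'   envelope box, wall time), and the intermediates `geometry`,
#'   `rectified`, `disparity`, `dense`, `finite`, `sparse`, `gmm`,
#'   `selection`.
#' @export
run_pipeline <- function(left, right, calib, config = pipeline_config(),
                         output_dir = NULL, verbose = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  if (is.character(left)) left <- read_image(left)
  if (is.character(right)) right <- read_image(right)
  if (is.character(calib)) calib <- read_calibration(calib)
  say <- function(...) if (verbose) message(sprintf(...))

  say("rectifying...")
  geom <- stage("rectify", build_rectification(
    calib, c(dim(left)[2], dim(left)[1]), policy = config$rectify_policy))
  rect <- stage("rectify", rectify_pair(left, right, geom))

  say("matching (%s)...", config$matching$algorithm)
  d <- stage("match", if (config$matching$algorithm == "sgm")
    sgm_match(rect$left, rect$right, config$matching)
    else block_match(rect$left, rect$right, config$matching))

  say("reconstructing...")
  dense <- stage("reconstruct", reproject(d, geom, rect$left))
  finite <- stage("remove_invalid", remove_invalid(dense))

  say("down-sampling %d -> %d...", finite$count, config$target_count)
  sparse <- stage("downsample", suppressWarnings(
    nonuniform_grid_sample(finite, config$target_count)))

  say("clustering (K = %d)...", config$K)
  fit <- stage("gmm", gmm_fit(sparse, K = config$K,
                              seed = config$gmm_seed))
  sel <- stage("select_crop",
               select_crop_component(fit, sparse, rule = config$crop_rule))
  crop <- stage("knn_filter", suppressWarnings(
    knn_outlier_filter(sel$points, config$knn_k, config$knn_alpha)))

  box <- envelope_box(crop)
  report <- list(
    counts = list(dense = dense$count,
                  after_invalid_removal = finite$count,
                  sparse = sparse$count,
                  crop_component = sel$points$count,
                  crop_filtered = crop$count),
    rectified_size = c(width = geom$width, height = geom$height),
    crop_component = sel$component,
    crop_pi = sel$weight,
    envelope_box = list(length = box$length, width = box$width,
                        height = box$height, volume = box$volume),
    gmm = list(log_likelihood = fit$log_likelihood,
               iterations = fit$iterations, converged = fit$converged),
    timing = list(total_seconds = proc.time()[["elapsed"]] - t0))

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_image(rect$left, file.path(output_dir, "left_rectified.png"))
    write_image(rect$right, file.path(output_dir, "right_rectified.png"))
    write_disparity(d, file.path(output_dir, "disparity.png"))
    write_cloud(finite, file.path(output_dir, "dense.ply"))
    write_cloud(sparse, file.path(output_dir, "sparse.ply"))
    write_cloud(crop, file.path(output_dir, "crop.ply"))
    jsonlite::write_json(report, file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(list(crop = crop, report = report, geometry = geom,
                 rectified = rect, disparity = d, dense = dense,
                 finite = finite, sparse = sparse, gmm = fit,
                 selection = sel),
            class = "seedling_pipeline")
}

#' @export
print.seedling_pipeline <- function(x, ...) {
  r <- x$report
  cat("Seedling recognition pipeline\n")
  cat(sprintf("  dense %d -> finite %d -> sparse %d -> crop %d -> filtered %d\n",
              r$counts$dense, r$counts$after_invalid_removal,
              r$counts$sparse, r$counts$crop_component,
              r$counts$crop_filtered))
  cat(sprintf("  crop component %d (pi = %.4f); envelope %.0fx%.0fx%.0f mm\n",
              r$crop_component, r$crop_pi, r$envelope_box$length,
              r$envelope_box$width, r$envelope_box$height))
  cat(sprintf("  %.2f s total\n", r$timing$total_seconds))
  invisible(x)
}
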