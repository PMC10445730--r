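#' Draw a per-nucleus spot specification for a simulated condition
#'
#' Places `spots_per_nucleus` probe spots in every nucleus with true
#' normalized radial positions drawn from a normal distribution truncated to
#' \[0.02, 0.98\] (a spot exactly on the boundary or centre is degenerate for
#' recovery scoring).
#'
#' @param n_nuclei number of nuclei in the scene.
#' @param spots_per_nucleus spots per nucleus.
#' @param r_mean,r_sd mean and sd of the true normalized radial position
#'   (1 = centre, 0 = periphery).
#' @param amplitude peak spot counts.
#' @param seed integer seed.
#' @return A `spots_spec` tibble for [scene_params()].
#' @export
draw_spots_spec <- function(n_nuclei, spots_per_nucleus = 1L,
                            r_mean = 0.3, r_sd = 0.05,
                            amplitude = 500, seed = NULL) {
  with_seed(seed, {
    n <- n_nuclei * spots_per_nucleus
    r <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        v <- rnorm(1, r_mean, r_sd)
        if (v >= 0.02 && v <= 0.98) break
      }
      r[i] <- v
    }
    tibble(nucleus = rep(seq_len(n_nuclei), each = spots_per_nucleus),
           r = r, amplitude = amplitude)
  })
}

#' Elliptical spline ROI from a projected nucleus outline
#'
#' Builds control points on the ellipse that a nucleus projects to in the
#' maximum projection — the synthetic stand-in for manually tracing the
#' nucleus contour.
#'
#' @param nucleus nucleus id.
#' @param center_yx_px ellipse centre (y, x) in pixels (1-based).
#' @param semiaxes_yx_px ellipse semi-axes (y, x) in pixels.
#' @param n_points number of control points (>= 5).
#' @return A [spline_roi()].
#' @export
roi_from_ellipse <- function(nucleus, center_yx_px, semiaxes_yx_px,
                             n_points = 12L) {
  theta <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
  spline_roi(nucleus, cbind(
    y = center_yx_px[1] + semiaxes_yx_px[1] * sin(theta),
    x = center_yx_px[2] + semiaxes_yx_px[2] * cos(theta)))
}

#' Read spline ROIs from JSON
#'
#' Expects an array of objects with fields `nucleus` and `control_points`
#' (an array of \[y, x\] pixel pairs).
#'
#' @param path JSON file path.
#' @return List of [spline_roi()] objects.
#' @export
read_rois <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  purrr::map(seq_len(nrow(raw)), function(i) {
    spline_roi(raw$nucleus[i], matrix(unlist(raw$control_points[[i]]),
                                      ncol = 2, byrow = TRUE))
  })
}

config_defaults <- list(
  condition = "condition",
  seed = 1L,
  readout = "2d",
  output_dir = NULL,
  bins = 20L,
  scene = NULL,
  input = NULL,
  segmentation = list(),
  probe_detection = list(),
  lamin_detection = list(candidate_mode = "dense",
                         com_window_zyx = c(3L, 5L, 5L))
)

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a named list), fills defaults, rejects unknown
#' keys and reports every schema violation at once.
#'
#' Recognised top-level keys: `condition`, `seed`, `readout` ("2d" or "3d"),
#' `output_dir`, `bins`, `scene` (arguments of [scene_params()], plus an
#' optional `spots` block with arguments of [draw_spots_spec()]), `input`
#' (`stack` TIFF path and, for the 2D readout, `rois` JSON path),
#' `segmentation` ([segmentation_params()]), `probe_detection` and
#' `lamin_detection` ([dog_params()]). Exactly one of `scene` / `input` must
#' be given.
#'
#' @param config path to a YAML file, or a named list.
#' @return A validated `pipeline_config` object.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a file path or a named list")
  errors <- character()
  unknown <- setdiff(names(config), names(config_defaults))
  if (length(unknown) > 0)
    errors <- c(errors, paste0("unknown key(s): ",
                               paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(config_defaults, config)
  if (!cfg$readout %in% c("2d", "3d"))
    errors <- c(errors, "readout: must be \"2d\" or \"3d\"")
  if (is.null(cfg$scene) == is.null(cfg$input))
    errors <- c(errors, "exactly one of scene:/input: must be given")
  if (!is.null(cfg$input)) {
    if (is.null(cfg$input$stack) || !file.exists(cfg$input$stack))
      errors <- c(errors, "input.stack: file missing")
    if (cfg$readout == "2d" &&
        (is.null(cfg$input$rois) || !file.exists(cfg$input$rois)))
      errors <- c(errors, "input.rois: file missing (required for 2d readout)")
  }
  scene_spots <- NULL
  if (!is.null(cfg$scene)) {
    scene_spots <- cfg$scene$spots
    cfg$scene$spots <- NULL
    bad <- setdiff(names(cfg$scene), names(formals(scene_params)))
    if (length(bad) > 0)
      errors <- c(errors, paste0("scene: unknown key(s): ",
                                 paste(bad, collapse = ", ")))
    if (!is.null(scene_spots)) {
      bad <- setdiff(names(scene_spots),
                     setdiff(names(formals(draw_spots_spec)),
                             c("seed", "n_nuclei")))
      if (length(bad) > 0)
        errors <- c(errors, paste0("scene.spots: unknown key(s): ",
                                   paste(bad, collapse = ", ")))
    }
  }
  bad <- setdiff(names(cfg$segmentation), names(formals(segmentation_params)))
  if (length(bad) > 0)
    errors <- c(errors, paste0("segmentation: unknown key(s): ",
                               paste(bad, collapse = ", ")))
  for (blk in c("probe_detection", "lamin_detection")) {
    bad <- setdiff(names(cfg[[blk]]), names(formals(dog_params)))
    if (length(bad) > 0)
      errors <- c(errors, paste0(blk, ": unknown key(s): ",
                                 paste(bad, collapse = ", ")))
  }
  # constructor-level validation (value ranges), collected rather than thrown
  objs <- list()
  add_err <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      errors <<- c(errors, paste0(label, ": ", conditionMessage(e)))
      NULL
    })
  }
  objs$segmentation <- add_err("segmentation",
    do.call(segmentation_params, cfg$segmentation))
  objs$probe_detection <- add_err("probe_detection",
    do.call(dog_params, cfg$probe_detection))
  objs$lamin_detection <- add_err("lamin_detection",
    do.call(dog_params, cfg$lamin_detection))
  if (length(errors) > 0)
    abort(paste0("invalid pipeline config:\n  - ",
                 paste(errors, collapse = "\n  - ")))
  structure(list(condition = cfg$condition, seed = as.integer(cfg$seed),
                 readout = cfg$readout, output_dir = cfg$output_dir,
                 bins = as.integer(cfg$bins),
                 scene = cfg$scene, scene_spots = scene_spots,
                 input = cfg$input,
                 segmentation = objs$segmentation,
                 probe_detection = objs$probe_detection,
                 lamin_detection = objs$lamin_detection),
            class = "pipeline_config")
}

#' Run the full locus-position pipeline
#'
#' Simulate (or read) a 3-channel stack, segment nuclei, detect and refine
#' probe spots, and score each locus by the chosen readout: the 3D shortest
#' distance to the lamin point cloud (micrometres) or the 2D normalized
#' radial position from spline-contour distance maps. Deterministic for a
#' fixed seed. When `output_dir` is set, writes the per-nucleus table, the
#' spot table, the distance records and a JSON run manifest with per-stage
#' counts.
#'
#' @param config a `pipeline_config` from [validate_config()], a named list,
#'   or a YAML path.
#' @return A `pipeline_result`: list with `summary` (condition, n nuclei,
#'   n spots, median/mean/sd of the readout), `records`, `spots`, `labels`,
#'   `histogram` and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  stage <- "setup"
  manifest <- list(condition = config$condition, seed = config$seed,
                   readout = config$readout,
                   package_version = as.character(utils::packageVersion("perifish")),
                   stages = list())
  result <- tryCatch({
    truth <- NULL; rois <- NULL; sim_nuclei <- NULL
    stage <- "scene"
    if (!is.null(config$scene)) {
      sargs <- config$scene
      sargs$seed <- sargs$seed %||% config$seed
      n_nuc <- sargs$n_nuclei %||% formals(scene_params)$n_nuclei
      spot_args <- config$scene_spots %||% list()
      spot_args$n_nuclei <- as.integer(n_nuc)
      spot_args$seed <- config$seed + 1L
      sargs$spots_spec <- do.call(draw_spots_spec, spot_args)
      params <- do.call(scene_params, sargs)
      scene <- generate_scene(params)
      stack <- scene$stack; truth <- scene$truth
      sim_nuclei <- scene$nuclei
    } else {
      stack <- read_stack(config$input$stack)
      if (config$readout == "2d") rois <- read_rois(config$input$rois)
    }
    manifest$stages$scene <- list(shape_zyx = dim(stack$channels$dna))

    stage <- "segmentation"
    labels <- segment_nuclei(stack, config$segmentation)
    manifest$stages$segmentation <- list(n_nuclei = nrow(labels$nuclei),
                                         threshold = labels$threshold)
    if (is.null(rois) && config$readout == "2d" && !is.null(config$scene)) {
      # simulated run: stand in for manual tracing with the true projected
      # outline of each segmented nucleus (matched by centroid, since
      # segmentation labels are in scan order)
      vs <- stack$voxel_size_zyx
      rois <- purrr::map(seq_len(nrow(labels$nuclei)), function(k) {
        cen_um <- c(labels$nuclei$cy[k] - 1, labels$nuclei$cx[k] - 1) * vs[2:3]
        j <- which.min((sim_nuclei$y_um - cen_um[1])^2 +
                         (sim_nuclei$x_um - cen_um[2])^2)
        roi_from_ellipse(k,
          c(sim_nuclei$y_um[j] / vs[2] + 1, sim_nuclei$x_um[j] / vs[3] + 1),
          c(sim_nuclei$ay_um[j] / vs[2], sim_nuclei$ax_um[j] / vs[3]))
      })
    }

    stage <- "spot detection"
    spots <- localize_spots(stack, "probe", labels, config$probe_detection)
    n_assigned <- sum(!is.na(spots$nucleus))
    manifest$stages$spots <- list(detected = nrow(spots),
                                  assigned = n_assigned,
                                  unassigned = nrow(spots) - n_assigned)

    stage <- "distance"
    if (config$readout == "3d") {
      cloud <- lamin_point_cloud(stack, labels, config$lamin_detection)
      records <- spot_lamin_distances(spots, cloud,
                                      condition = config$condition)
      value_col <- "distance_3d_um"
      manifest$stages$lamin <- list(cloud_points = nrow(cloud),
        excluded_nuclei = attr(cloud, "excluded_nuclei"))
    } else {
      sp2d <- spots[!is.na(spots$nucleus),
                    c("nucleus", "yr", "xr"), drop = FALSE]
      names(sp2d) <- c("nucleus", "y", "x")
      records <- radial_positions(sp2d, rois,
                                  dim(stack$channels$dna)[2:3],
                                  condition = config$condition)
      value_col <- "normalized_position"
    }
    manifest$stages$distance <- list(records = nrow(records))

    stage <- "summary"
    v <- records[[value_col]]
    hist <- if (length(v) > 0) {
      if (value_col == "normalized_position") {
        pdf_histogram(v, bins = config$bins, condition = config$condition)
      } else {
        pdf_histogram(v, bin_edges = fd_bin_edges(v),
                      condition = config$condition)
      }
    } else NULL
    summary <- tibble(condition = config$condition,
                      readout = value_col,
                      n_nuclei = nrow(labels$nuclei),
                      n_spots = nrow(spots),
                      n_records = length(v),
                      median = if (length(v)) median(v) else NA_real_,
                      mean = if (length(v)) mean(v) else NA_real_,
                      sd = if (length(v)) sd(v) else NA_real_)
    manifest$complete <- TRUE
    list(summary = summary, records = records, spots = spots,
         labels = labels, truth = truth, histogram = hist,
         manifest = manifest)
  }, error = function(e) {
    abort(paste0("pipeline failed at stage `", stage, "`: ",
                 conditionMessage(e)))
  })
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$output_dir, f)
    write.csv(result$labels$nuclei, p("nuclei.csv"), row.names = FALSE)
    write.csv(result$spots, p("spots.csv"), row.names = FALSE)
    write.csv(result$records, p("distances.csv"), row.names = FALSE)
    jsonlite::write_json(result$manifest, p("manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  structure(result, class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$summary)
  invisible(x)
}

#' @rdname run_pipeline
#' @param x,object a `pipeline_result`.
#' @param ... unused.
#' @method tidy pipeline_result
#' @export
tidy.pipeline_result <- function(x, ...) x$records

#' @rdname run_pipeline
#' @method glance pipeline_result
#' @export
glance.pipeline_result <- function(x, ...) x$summary
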