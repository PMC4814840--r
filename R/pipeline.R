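#' Save or load a projection model as JSON
#'
#' @param model A `projection_model`.
#' @param path JSON path.
#' @return `read_projection_model()` returns the model;
#'   `write_projection_model()` returns `path` invisibly.
#' @export
write_projection_model <- function(model, path) {
  stopifnot(inherits(model, "projection_model"))
  obj <- list(kind = model$kind, feature_names = model$feature_names,
              mean_vector = model$mean_vector,
              scale_vector = model$scale_vector,
              basis = model$basis, axis_scores = model$axis_scores,
              degenerate = isTRUE(model$degenerate),
              objective = model$objective)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_projection_model
#' @export
read_projection_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  basis <- as.matrix(o$basis)
  rownames(basis) <- o$feature_names
  new_projection_model(o$kind, o$mean_vector, o$scale_vector, basis,
                       o$axis_scores, o$feature_names,
                       degenerate = isTRUE(o$degenerate),
                       objective = o$objective)
}

pipeline_defaults <- function() {
  list(
    seed = 1L,
    output_dir = "specell_out",
    input = list(tiff = NULL, channels = NULL),
    simulate = NULL,
    background = list(enabled = TRUE, percentile = 5),
    denoise = list(enabled = TRUE, n_scales = 5, n_orientations = 6,
                   noise_threshold_k = 2, mult_factor = 2.5,
                   variance_stabilise = TRUE),
    segment = list(min_area_px = 50, split_touching = TRUE,
                   smooth_sigma = 2),
    unmix = list(enabled = FALSE, k = 3, n_restarts = 5),
    features = list(registry = "default18"),
    project = list(method = "pca"),
    test_groups = list(enabled = FALSE),
    subpop = list(enabled = FALSE, k_range = 1:5, min_cluster_size = 5)
  )
}

#' Validate and normalise a pipeline configuration
#'
#' Fills in stage defaults and rejects unknown stages or parameters
#' before any image is read, so misconfigured runs fail fast.
#'
#' @param config A named list, or path to a YAML file with the same
#'   structure as [pipeline_defaults idea][run_pipeline()].
#' @return The validated, completed configuration list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defs <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defs))
  if (length(unknown) > 0)
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (nm in names(config)) {
    if (is.list(defs[[nm]]) && !is.null(config[[nm]])) {
      bad <- setdiff(names(config[[nm]]), names(defs[[nm]]))
      if (nm == "simulate") bad <- character(0) # scene params checked later
      if (length(bad) > 0)
        stop("unknown parameter(s) in `", nm, "`: ",
             paste(bad, collapse = ", "), call. = FALSE)
      defs[[nm]][names(config[[nm]])] <- config[[nm]]
    } else {
      defs[[nm]] <- config[[nm]]
    }
  }
  if (is.null(defs$simulate) && is.null(defs$input$tiff))
    stop("config needs either `input$tiff` or a `simulate` section",
         call. = FALSE)
  reg <- defs$features$registry
  if (is.character(reg) && !reg %in% c("default18", "minimal") &&
      !file.exists(reg))
    stop("feature registry '", reg, "' is neither a preset nor a file",
         call. = FALSE)
  defs
}

#' Run the full characterisation pipeline
#'
#' Executes the stages in fixed order — (simulate or load) ->
#' background subtraction -> denoise -> segment -> optional unmix ->
#' features -> projection -> optional two-group test and subpopulation
#' detection — writing every artefact under the configured output
#' directory and a `manifest.json` recording each artefact's MD5
#' hash, the stage parameters, the seed and the package version.
#'
#' @param config Configuration list or YAML path (see
#'   [validate_config()]).
#' @return Invisibly, the manifest as a list; artefacts on disk.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  artefacts <- list()
  note <- function(path, stage) {
    artefacts[[length(artefacts) + 1]] <<-
      list(path = path, stage = stage,
           md5 = unname(tools::md5sum(path)))
  }
  log_stage <- function(stage, t_start, params) {
    message(sprintf("[%s] %.2fs  %s", stage,
                    as.numeric(Sys.time() - t_start, units = "secs"),
                    paste(names(params), unlist(params), sep = "=",
                          collapse = " ")))
  }

  # acquire
  ts <- Sys.time()
  if (!is.null(cfg$simulate)) {
    scene_args <- cfg$simulate
    scene_args$seed <- scene_args$seed %||% cfg$seed
    scene <- do.call(synth_scene, scene_args)
    rendered <- render_scene(scene)
    stack <- rendered$stack
    gt_csv <- file.path(out, "ground_truth_cells.csv")
    utils::write.csv(rendered$cells, gt_csv, row.names = FALSE)
    note(gt_csv, "simulate")
    stack_tif <- file.path(out, "stack.tif")
    write_stack(stack, stack_tif)
    note(stack_tif, "simulate")
    note(default_sidecar(stack_tif), "simulate")
  } else {
    stack <- read_stack(cfg$input$tiff, cfg$input$channels)
  }
  log_stage("acquire", ts, list(seed = cfg$seed))

  if (isTRUE(cfg$background$enabled)) {
    ts <- Sys.time()
    stack <- subtract_background(stack,
                                 percentile = cfg$background$percentile)
    log_stage("background", ts,
              list(percentile = cfg$background$percentile))
  }

  if (isTRUE(cfg$denoise$enabled)) {
    ts <- Sys.time()
    dp <- denoise_params(cfg$denoise$n_scales, cfg$denoise$n_orientations,
                         cfg$denoise$noise_threshold_k,
                         cfg$denoise$mult_factor,
                         cfg$denoise$variance_stabilise)
    stack <- denoise_stack(stack, dp)
    den_tif <- file.path(out, "denoised.tif")
    write_stack(stack, den_tif)
    note(den_tif, "denoise")
    log_stage("denoise", ts, cfg$denoise[-1])
  }

  ts <- Sys.time()
  seg <- segment_cells(stack, min_area_px = cfg$segment$min_area_px,
                       split_touching = cfg$segment$split_touching,
                       smooth_sigma = cfg$segment$smooth_sigma)
  lab_tif <- file.path(out, "labels.tif")
  write_labels(seg, lab_tif)
  note(lab_tif, "segment")
  cells_csv <- file.path(out, "cells.csv")
  utils::write.csv(seg$cells, cells_csv, row.names = FALSE)
  note(cells_csv, "segment")
  log_stage("segment", ts, cfg$segment)

  if (isTRUE(cfg$unmix$enabled)) {
    ts <- Sys.time()
    em <- unmix_stack(stack, k = cfg$unmix$k, seed = cfg$seed,
                      n_restarts = cfg$unmix$n_restarts)
    sp_csv <- file.path(out, "endmember_spectra.csv")
    utils::write.csv(as.data.frame(em$spectra), sp_csv, row.names = FALSE)
    note(sp_csv, "unmix")
    log_stage("unmix", ts, list(k = cfg$unmix$k))
  }

  ts <- Sys.time()
  reg <- cfg$features$registry
  registry <- if (is.character(reg) && reg %in% c("default18", "minimal"))
    feature_registry(reg, channels = stack$channels)
  else if (is.character(reg)) read_feature_registry(reg)
  else reg
  feats <- suppressMessages(
    extract_features(stack, seg, registry))
  if (!is.null(cfg$simulate) && nrow(feats) > 0 &&
      length(unique(rendered$cells$group)) > 1) {
    # attach ground-truth group by looking up the true label image at
    # each segmented cell's centroid
    ci <- match(feats$cell_id, seg$cells$cell_id)
    gt <- rendered$labels[cbind(round(seg$cells$centroid_row[ci]),
                                round(seg$cells$centroid_col[ci]))]
    feats <- tibble::add_column(
      feats, group = ifelse(gt > 0, rendered$cells$group[gt], NA),
      .after = "cell_id")
    feats <- feats[!is.na(feats$group), , drop = FALSE]
  }
  feats_csv <- file.path(out, "features.csv")
  utils::write.csv(feats, feats_csv, row.names = FALSE)
  note(feats_csv, "features")
  log_stage("features", ts, list(registry = if (is.character(reg)) reg
                                 else "inline", p = nrow(registry)))

  manifest <- list(version = as.character(utils::packageVersion("specell")),
                   seed = cfg$seed, config = cfg)
  if (nrow(feats) >= 3) {
    ts <- Sys.time()
    fm <- feature_matrix(feats)
    fm <- fm[, apply(fm, 2, stats::sd) > 0, drop = FALSE]  # drop constants
    model <- pca_fit(fm, standardise = TRUE)
    model_json <- file.path(out, "projection_model.json")
    write_projection_model(model, model_json)
    note(model_json, "project")
    scores <- pca_transform(model, feats)
    sc_csv <- file.path(out, "scores.csv")
    utils::write.csv(
      cbind(data.frame(cell_id = feats$cell_id), as.data.frame(scores)),
      sc_csv, row.names = FALSE)
    note(sc_csv, "project")
    log_stage("project", ts, cfg$project)

    if (isTRUE(cfg$subpop$enabled)) {
      ts <- Sys.time()
      D <- min(3, ncol(scores))
      asg <- detect_clusters(scores[, seq_len(D), drop = FALSE],
                             min_cluster_size = cfg$subpop$min_cluster_size,
                             k_range = cfg$subpop$k_range, seed = cfg$seed)
      cl_csv <- file.path(out, "clusters.csv")
      utils::write.csv(data.frame(cell_id = feats$cell_id,
                                  cluster = asg$labels),
                       cl_csv, row.names = FALSE)
      note(cl_csv, "subpop")
      log_stage("subpop", ts, list(K = asg$K))
    }
    if (isTRUE(cfg$test_groups$enabled) && "group" %in% names(feats)) {
      ts <- Sys.time()
      res <- discriminate_1d(feats, feats$group)
      tg_json <- file.path(out, "group_test.json")
      jsonlite::write_json(list(ks_statistic = res$ks_statistic,
                                p_value = res$p_value),
                           tg_json, auto_unbox = TRUE, digits = NA)
      note(tg_json, "test_groups")
      log_stage("test_groups", ts, list(p = signif(res$p_value, 3)))
    }
  }

  manifest$artefacts <- artefacts
  manifest$wall_time_s <- as.numeric(Sys.time() - t0, units = "secs")
  man_json <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, man_json, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(manifest)
}
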