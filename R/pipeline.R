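# End-to-end orchestration: load (or simulate) a two-channel scene, run
# segment -> assign -> measure -> summarize, and write the report bundle.

#' Load a registered two-channel image pair from TIFF files
#'
#' @param reporter_path,marker_path Paths to single-plane grayscale TIFFs of
#'   equal dimensions.
#' @param pixel_size_um Physical pixel size (um).
#' @return A [channel_pair()].
#' @export
load_channels <- function(reporter_path, marker_path, pixel_size_um) {
  reporter <- read_pixel_grid(reporter_path, pixel_size_um)
  marker <- read_pixel_grid(marker_path, pixel_size_um)
  channel_pair(reporter, marker)
}

#' Pipeline configuration
#'
#' Exactly one of `reporter_path`/`marker_path` (measured images) or
#' `scene` (a [scene_config()] to simulate) must be supplied.
#'
#' @param reporter_path,marker_path Input TIFF paths, or `NULL`.
#' @param scene A [scene_config()], or `NULL`.
#' @param pixel_size_um Pixel size for loaded images (ignored when
#'   simulating; the scene's own pixel size is used).
#' @param params A [segmentation_params()].
#' @param perimeter_edges,circularity_edges Histogram bin edges.
#' @param exclude_foci Exclude perimeter <= 15 um objects from condensate
#'   histograms.
#' @param out_dir Output directory for the report bundle.
#' @param seed Integer seed recorded in the run manifest.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(reporter_path = NULL,
                            marker_path = NULL,
                            scene = NULL,
                            pixel_size_um = 0.65,
                            params = segmentation_params(),
                            perimeter_edges = seq(0, 50, by = 2),
                            circularity_edges = seq(0, 1, by = 0.1),
                            exclude_foci = FALSE,
                            out_dir = tempfile("ceod_run_"),
                            seed = 1L) {
  have_paths <- !is.null(reporter_path) || !is.null(marker_path)
  have_scene <- !is.null(scene)
  if (have_paths == have_scene) {
    abort("Supply exactly one of {reporter_path + marker_path} or {scene}.")
  }
  if (have_paths && (is.null(reporter_path) || is.null(marker_path))) {
    abort("Both `reporter_path` and `marker_path` are required.")
  }
  if (have_scene) {
    scene <- validate_scene_config(scene)
    scene$rng_seed <- as.integer(seed)
  }
  structure(
    list(
      reporter_path = reporter_path, marker_path = marker_path,
      scene = scene, pixel_size_um = pixel_size_um, params = params,
      perimeter_edges = perimeter_edges,
      circularity_edges = circularity_edges,
      exclude_foci = isTRUE(exclude_foci),
      out_dir = out_dir, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Run the full condensate quantification pipeline
#'
#' Loads (or simulates) the two channels, segments droplets and condensates,
#' assigns each condensate to its mother droplet, measures morphology, and
#' aggregates the replicate summary. Writes to `config$out_dir`: per-object
#' and per-droplet CSV tables (units in the column names), label-map TIFFs,
#' the replicate summary JSON, a JSON run manifest (configuration, package
#' version, seed) and a plain-text log. Any stage error is re-raised with
#' the stage name and the partial output directory is removed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `droplet_records`, `condensate_records`,
#'   `parents`, `droplet_summaries`, `replicate`, and `paths`.
#' @export
run_quantify <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- character()
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                                       sprintf(fmt, ...)))
  }
  stage <- function(name, expr) {
    say("stage %s: start", name)
    tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, sprintf("stage %s FAILED: %s", name,
                                      conditionMessage(e))), log_path)
      unlink(list.files(config$out_dir, full.names = TRUE,
                        pattern = "\\.(csv|tif|json)$"))
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  channels <- stage("load", {
    if (!is.null(config$scene)) {
      simulate_scene(config$scene)$channels
    } else {
      load_channels(config$reporter_path, config$marker_path,
                    config$pixel_size_um)
    }
  })
  droplet_map <- stage("segment_droplets",
                       segment_droplets(channels$reporter, config$params))
  condensate_map <- stage("segment_condensates",
                          segment_condensates(channels$marker, config$params))
  parents <- stage("assign", assign_condensates(droplet_map, condensate_map))
  droplet_records <- stage("measure",
                           measure_objects(droplet_map, channels$reporter))
  condensate_records <- stage("measure",
                              measure_objects(condensate_map, channels$marker))
  droplet_summaries <- stage("summarize",
                             summarize_droplets(droplet_records,
                                                condensate_records, parents))
  replicate <- stage("summarize",
                     summarize_replicate(droplet_summaries, condensate_records,
                                         config$perimeter_edges,
                                         config$circularity_edges,
                                         config$exclude_foci))
  say("detected %d droplets, %d condensates", nrow(droplet_records),
      nrow(condensate_records))
  paths <- stage("write", {
    p <- c(
      objects = file.path(config$out_dir, "condensate_objects.csv"),
      droplets = file.path(config$out_dir, "droplet_summaries.csv"),
      summary = file.path(config$out_dir, "replicate_summary.json"),
      manifest = file.path(config$out_dir, "manifest.json"),
      droplet_labels = file.path(config$out_dir, "droplet_labels.tif"),
      condensate_labels = file.path(config$out_dir, "condensate_labels.tif")
    )
    obj <- dplyr::left_join(condensate_records,
                            dplyr::select(parents, "condensate_label",
                                          "parent_label"),
                            by = c(label = "condensate_label"))
    obj$perimeter_class <- as.character(classify_by_perimeter(
      pmax(obj$perimeter_um, 1e-9)))
    write.csv(obj, p[["objects"]], row.names = FALSE)
    write.csv(droplet_summaries, p[["droplets"]], row.names = FALSE)
    rep_out <- replicate
    rep_out$perimeter_histogram <- as.data.frame(rep_out$perimeter_histogram)
    rep_out$circularity_histogram <- as.data.frame(rep_out$circularity_histogram)
    jsonlite::write_json(unclass(rep_out), p[["summary"]],
                         auto_unbox = TRUE, digits = 10, na = "null")
    manifest <- list(
      package = "ceodr",
      version = as.character(packageVersion("ceodr")),
      seed = config$seed,
      mode = if (is.null(config$scene)) "images" else "simulation",
      scene = if (is.null(config$scene)) NULL else unclass(config$scene),
      reporter_path = config$reporter_path,
      marker_path = config$marker_path,
      params = unclass(config$params),
      exclude_foci = config$exclude_foci
    )
    jsonlite::write_json(manifest, p[["manifest"]], auto_unbox = TRUE,
                         digits = NA, null = "null")
    write_label_map(droplet_map, p[["droplet_labels"]])
    write_label_map(condensate_map, p[["condensate_labels"]])
    p
  })
  say("done")
  writeLines(log_lines, log_path)
  invisible(list(
    droplet_records = droplet_records,
    condensate_records = condensate_records,
    parents = parents,
    droplet_summaries = droplet_summaries,
    replicate = replicate,
    paths = paths
  ))
}
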