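#' Pipeline run configuration
#'
#' Bundles everything one segmentation-and-ratio run needs; serializable to
#' YAML ([write_run_config()]) and fully resolved into a JSON log by
#' [run_pipeline()], so every run is reproducible from its log alone.
#'
#' @param input Path(s) to the input TIFF (one interleaved file or one per
#'   channel). May be `NULL` when a stack is passed to [run_pipeline()]
#'   directly.
#' @param channel_order Channel roles in file order.
#' @param settings A [segmentation_settings()].
#' @param outdir Output directory (created if needed).
#' @param nearest Nearest-point projection convention (`"top"` or
#'   `"bottom"`, see [nearest_point_projection()]).
#' @param display_dilation Label-dilation iterations for the display copies
#'   (0 = off; measurements always use undilated labels).
#' @param bit_depth Optional bit-depth override for reading.
#' @param seed Seed for any stochastic fixture generation; the analysis path
#'   itself is deterministic.
#' @return An `fq_config` list.
#' @export
run_config <- function(input = NULL,
                       channel_order = c("DxDm", "DxAm", "AxAm"),
                       settings = segmentation_settings(),
                       outdir = ".",
                       nearest = c("top", "bottom"),
                       display_dilation = 0L,
                       bit_depth = NULL,
                       seed = 1L) {
  stopifnot(inherits(settings, "fq_settings"))
  nearest <- match.arg(nearest)
  if (display_dilation < 0) stopf("`display_dilation` must be >= 0")
  structure(list(input = input, channel_order = channel_order,
                 settings = settings, outdir = outdir, nearest = nearest,
                 display_dilation = as.integer(display_dilation),
                 bit_depth = if (is.null(bit_depth)) NULL else as.integer(bit_depth),
                 seed = as.integer(seed)),
            class = "fq_config")
}

config_to_list <- function(config) {
  out <- unclass(config)
  out$settings <- unclass(config$settings)
  out
}

list_to_config <- function(x) {
  s <- x$settings
  settings <- segmentation_settings(
    segmentation_channel = s$segmentation_channel %||% "AxAm",
    dog_sigma_small = s$dog_sigma_small %||% 1,
    dog_sigma_large = s$dog_sigma_large %||% 4,
    tophat_enabled = isTRUE(s$tophat_enabled),
    tophat_radius = s$tophat_radius %||% 5,
    threshold_method = s$threshold_method %||% "otsu",
    manual_threshold = s$manual_threshold,
    watershed_enabled = isTRUE(s$watershed_enabled %||% TRUE),
    connectivity = s$connectivity %||% 26L,
    min_voxels = s$min_voxels %||% 5L
  )
  run_config(input = x$input,
             channel_order = x$channel_order %||% c("DxDm", "DxAm", "AxAm"),
             settings = settings,
             outdir = x$outdir %||% ".",
             nearest = x$nearest %||% "top",
             display_dilation = x$display_dilation %||% 0L,
             bit_depth = x$bit_depth,
             seed = x$seed %||% 1L)
}

#' @rdname run_config
#' @param config An `fq_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "fq_config"))
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config '%s' does not exist", path)
  list_to_config(yaml::read_yaml(path))
}

#' Run the full segmentation-and-ratio pipeline
#'
#' Reads the stack (unless one is supplied), segments it, measures
#' per-nucleus statistics with saturation exclusion, and writes the five
#' standardized image products plus the results table and a fully resolved
#' settings log:
#'
#' * `threshold.tif` — 8-bit 0/255 threshold foreground
#' * `labels.tif` — 16-bit label map
#' * `ratio_stack.tif` — per-voxel emission ratios, x1000 16-bit convention
#' * `ratio_max_z.tif` — maximum Z projection of the ratio stack
#' * `ratio_nearest_z.tif` — nearest-point Z projection
#' * `results.csv` — one row per nucleus
#' * `<stem>_<timestamp>_settings.json` — resolved configuration log
#'
#' All configuration is validated before any output is written; the analysis
#' is deterministic, so identical configurations yield byte-identical
#' results tables.
#'
#' @param config An [run_config()].
#' @param stack Optional in-memory [multichannel_stack()]; otherwise
#'   `config$input` is read.
#' @return Invisibly, a list with `records`, `segmentation`, `paths`.
#' @export
run_pipeline <- function(config, stack = NULL) {
  stopifnot(inherits(config, "fq_config"))
  settings <- config$settings  # construction already validated them
  if (is.null(stack)) {
    if (is.null(config$input)) stopf("config has no `input` and no stack was supplied")
    stack <- read_stack(config$input, config$channel_order,
                        bit_depth = config$bit_depth)
  }

  seg <- segment(stack, settings)
  mask <- saturation_mask(stack)
  records <- measure_rois(seg$labels, stack, mask)
  records$category <- UNLABELLED
  rs <- ratio_stack(seg$labels, records)

  display_labels <- if (config$display_dilation > 0L) {
    dilate_labels_for_display(seg$labels, config$display_dilation)
  } else seg$labels

  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  paths <- list(threshold = p("threshold.tif"),
                labels = p("labels.tif"),
                ratio_stack = p("ratio_stack.tif"),
                ratio_max_z = p("ratio_max_z.tif"),
                ratio_nearest_z = p("ratio_nearest_z.tif"),
                results = p("results.csv"))

  write_mask_tiff(seg$binary, paths$threshold)
  write_label_tiff(display_labels, paths$labels)
  exp_stack <- export_ratio_image(rs)
  write_pages(volume_to_pages(exp_stack), paths$ratio_stack, 16L)
  write_pages(list(export_ratio_image(max_z_projection(rs))),
              paths$ratio_max_z, 16L)
  write_pages(list(export_ratio_image(
    nearest_point_projection(rs, seg$labels, config$nearest))),
    paths$ratio_nearest_z, 16L)
  write_results_table(records, paths$results)

  stem <- tools::file_path_sans_ext(basename(
    if (!is.null(config$input)) config$input[1L] else stack$source_name))
  log_name <- sprintf("%s_%s_settings.json", stem,
                      format(Sys.time(), "%Y%m%d-%H%M%S"))
  paths$log <- p(log_name)
  resolved <- config_to_list(config)
  resolved$settings <- unclass(seg$settings_used)
  resolved$n_objects <- seg$n_objects
  resolved$package_version <- as.character(packageVersion("fretquant"))
  jsonlite::write_json(resolved, paths$log, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)

  invisible(list(records = records, segmentation = seg, paths = paths))
}
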