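#' Segmentation settings
#'
#' Every tunable of the punctate-nucleus segmentation pipeline, serializable
#' into the per-run settings log. Kernel sizes are in voxels and are scaled
#' per axis when the stack carries an anisotropic `voxel_size`; thresholds are
#' applied to the difference-of-Gaussians response with a strict `>`
#' comparison.
#'
#' @param segmentation_channel Channel role to segment on; defaults to the
#'   acceptor-excited acceptor channel (`"AxAm"`), falling back to `"DxAm"`
#'   when absent.
#' @param dog_sigma_small,dog_sigma_large Difference-of-Gaussians standard
#'   deviations in voxels (`sigma_small < sigma_large`).
#' @param tophat_enabled Apply a white top-hat after the DoG?
#' @param tophat_radius Top-hat ball radius, voxels.
#' @param threshold_method `"otsu"` (default), `"triangle"`, `"yen"`,
#'   `"mean"` or `"manual"`.
#' @param manual_threshold Threshold value, required iff
#'   `threshold_method = "manual"`.
#' @param watershed_enabled Split touching objects with a marker-controlled
#'   3D watershed (recommended for dense tissue; switch off for sparse
#'   scenes)?
#' @param connectivity Voxel connectivity for component analysis: 6 (faces)
#'   or 26 (faces, edges, corners).
#' @param min_voxels Discard final objects smaller than this many voxels
#'   (hot-pixel guard), applied after lost-object merging.
#' @return An `fq_settings` list.
#' @export
segmentation_settings <- function(segmentation_channel = "AxAm",
                                  dog_sigma_small = 1,
                                  dog_sigma_large = 4,
                                  tophat_enabled = FALSE,
                                  tophat_radius = 5,
                                  threshold_method = "otsu",
                                  manual_threshold = NULL,
                                  watershed_enabled = TRUE,
                                  connectivity = 26L,
                                  min_voxels = 5L) {
  threshold_method <- match.arg(threshold_method,
                                c("otsu", "triangle", "yen", "mean", "manual"))
  if (!segmentation_channel %in% c("DxDm", "DxAm", "AxAm")) {
    stopf("`segmentation_channel` must be one of DxDm, DxAm, AxAm")
  }
  if (any(dog_sigma_small >= dog_sigma_large)) {
    stopf("`dog_sigma_small` must be < `dog_sigma_large`")
  }
  if (threshold_method == "manual" && is.null(manual_threshold)) {
    stopf("`manual_threshold` is required when threshold_method = \"manual\"")
  }
  if (!connectivity %in% c(6L, 26L)) stopf("`connectivity` must be 6 or 26")
  if (min_voxels < 0) stopf("`min_voxels` must be >= 0")
  structure(list(segmentation_channel = segmentation_channel,
                 dog_sigma_small = dog_sigma_small,
                 dog_sigma_large = dog_sigma_large,
                 tophat_enabled = isTRUE(tophat_enabled),
                 tophat_radius = tophat_radius,
                 threshold_method = threshold_method,
                 manual_threshold = manual_threshold,
                 watershed_enabled = isTRUE(watershed_enabled),
                 connectivity = as.integer(connectivity),
                 min_voxels = as.integer(min_voxels)),
            class = "fq_settings")
}

as_mask <- function(x, what = "mask") {
  x <- as_volume(x, what)
  if (!is.logical(x)) {
    storage.mode(x) <- "logical"
  }
  x
}

#' Label connected components in 3D
#'
#' Flood-fill connected-components analysis with 6- or 26-connectivity.
#' Labels are contiguous `1..L`, assigned in raster-scan order of each
#' component's first voxel, so results are deterministic.
#'
#' @param binary Logical 3D array.
#' @param connectivity 6 or 26.
#' @param min_voxels Discard components smaller than this (0 keeps all);
#'   surviving labels are renumbered contiguously.
#' @return Integer 3D label array (0 = background).
#' @export
label_components <- function(binary, connectivity = 26L, min_voxels = 0L) {
  binary <- as_mask(binary)
  if (!connectivity %in% c(6L, 26L)) stopf("`connectivity` must be 6 or 26")
  d <- dim(binary)
  lab <- cc_label_cpp(as.logical(binary), d, as.integer(connectivity))
  if (min_voxels > 0L) {
    nlab <- max(lab)
    if (nlab > 0L) {
      sizes <- tabulate(lab[lab > 0L], nbins = nlab)
      keep <- which(sizes >= min_voxels)
      remap <- integer(nlab)
      remap[keep] <- seq_along(keep)
      pos <- lab > 0L
      lab[pos] <- remap[lab[pos]]
    }
  }
  array(as.integer(lab), d)
}

#' Split touching objects with a marker-controlled 3D watershed
#'
#' Computes the exact Euclidean distance transform of the binary map, takes
#' its regional maxima (plateaus merged) as markers, and floods the negated
#' distance transform with Meyer's algorithm. Watershed-line voxels are set
#' to background, so touching objects come apart along ridge lines;
#' foreground never grows.
#'
#' @param binary Logical 3D array.
#' @param connectivity Flooding/marker connectivity (6 or 26).
#' @param marker_radius Chebyshev radius (voxels) of the regional-maximum
#'   window; larger values suppress spurious markers on ragged objects.
#' @return Logical 3D array, the split foreground (a subset of `binary`).
#' @export
watershed_split <- function(binary, connectivity = 26L, marker_radius = 1L) {
  binary <- as_mask(binary)
  d <- dim(binary)
  if (!any(binary)) return(binary)
  edt <- edt_cpp(as.logical(binary), d)
  maxima <- local_max_cpp(edt, as.logical(binary), d, as.integer(max(1, marker_radius)))
  markers <- cc_label_cpp(maxima, d, 26L)
  ws <- watershed_cpp(-edt, markers, as.logical(binary), d, as.integer(connectivity))
  array(ws > 0L, d)
}

#' Find objects lost to the watershed
#'
#' A connected component of the pre-watershed binary map is *lost* when no
#' voxel of it survives in the split map (the watershed erased it entirely).
#' Lost components are returned so they can be added back to the label map,
#' preventing the watershed from discarding small nuclei.
#'
#' @param binary Pre-watershed logical 3D array.
#' @param split Post-watershed logical 3D array; must be a subset of
#'   `binary`.
#' @param connectivity 6 or 26.
#' @return Logical 3D array: the union of lost components.
#' @export
find_lost_objects <- function(binary, split, connectivity = 26L) {
  binary <- as_mask(binary, "binary")
  split <- as_mask(split, "split")
  if (!same_dim(binary, split)) stopf("`binary` and `split` must have identical dim")
  if (any(split & !binary)) stopf("`split` must be a subset of `binary`")
  comp <- label_components(binary, connectivity)
  n <- max(comp)
  if (n == 0L) return(array(FALSE, dim(binary)))
  surviving <- unique(comp[split])
  lost_ids <- setdiff(seq_len(n), surviving)
  array(comp %in% lost_ids & binary, dim(binary))
}

#' Grow watershed-shrunken labels back to the threshold foreground
#'
#' Iterated conditional dilation: labels expand in 6-connected single-voxel
#' steps into unlabelled voxels only, masked by the original threshold map at
#' every step, until no unlabelled foreground voxel is adjacent to a label.
#' Existing labels are never overwritten and simultaneous claims on a voxel
#' resolve deterministically to the lowest label id. This restores objects
#' shrunk by the watershed to their full thresholded extent without merging
#' them ("split objects without object shrinkage").
#'
#' @param labels Integer 3D label array whose nonzero voxels lie inside
#'   `binary`.
#' @param binary The original (pre-watershed) threshold foreground.
#' @return Integer 3D label array covering every `binary` voxel reachable
#'   from a label.
#' @export
constrained_dilate_relabel <- function(labels, binary) {
  labels <- as_volume(labels, "labels")
  binary <- as_mask(binary, "binary")
  if (!same_dim(labels, binary)) stopf("`labels` and `binary` must have identical dim")
  if (any(labels > 0L & !binary)) {
    stopf("nonzero labels must lie inside the `binary` foreground")
  }
  d <- dim(labels)
  out <- cond_dilate_cpp(as.integer(labels), as.logical(binary), d)
  array(as.integer(out), d)
}

#' Append lost components to a label map
#'
#' Runs connected components on the lost-object map and appends them with
#' fresh ids `L+1, L+2, ...` (raster-scan order) after the existing maximum
#' label `L`; prior ids are unchanged.
#'
#' @param labels Integer 3D label array.
#' @param lost Logical 3D array of lost objects, disjoint from the labelled
#'   foreground.
#' @param connectivity 6 or 26.
#' @return Integer 3D label array.
#' @export
merge_lost_labels <- function(labels, lost, connectivity = 26L) {
  labels <- as_volume(labels, "labels")
  lost <- as_mask(lost, "lost")
  if (!same_dim(labels, lost)) stopf("`labels` and `lost` must have identical dim")
  if (any(lost & labels > 0L)) {
    stopf("`lost` overlaps the labelled foreground; lost objects must be disjoint")
  }
  lc <- label_components(lost, connectivity)
  offset <- max(labels)
  sel <- lc > 0L
  labels[sel] <- lc[sel] + offset
  labels
}

# Renumber labels to contiguous 1..L preserving first-occurrence order.
relabel_contiguous <- function(labels) {
  ids <- unique(labels[labels > 0L])
  if (!length(ids)) return(labels)
  remap <- integer(max(ids))
  remap[ids] <- seq_along(ids)
  sel <- labels > 0L
  labels[sel] <- remap[labels[sel]]
  labels
}

#' Segment punctate nuclei in a multichannel stack
#'
#' The full segmentation pipeline for nuclear-localized punctate signal:
#' difference-of-Gaussians filtering of the segmentation channel, optional
#' white top-hat, automatic or manual thresholding, optional
#' marker-controlled 3D watershed with lost-object recovery,
#' connected-components labelling, constrained-dilation relabelling back to
#' the full threshold foreground, and merging of lost objects. A minimum
#' object size filter is applied last. Every setting actually used (including
#' the resolved threshold value) is recorded in the result.
#'
#' When the stack carries a `voxel_size`, DoG sigmas are interpreted in the
#' units of the finest axis and scaled per axis, so one setting transfers
#' across anisotropic acquisitions.
#'
#' @param stack An [multichannel_stack()].
#' @param settings A [segmentation_settings()].
#' @return An `fq_segmentation` list: `labels` (integer 3D array), `binary`
#'   (threshold foreground), `lost_map`, `threshold`, `watershed_applied`,
#'   `settings_used`, `n_objects`.
#' @export
#' @examples
#' sp <- scene_spec(shape = c(16, 48, 48),
#'                  nuclei = random_nuclei(3, c(16, 48, 48), radius = 3,
#'                                         margin = 6, seed = 2),
#'                  background_level = 20, noise = "none")
#' sc <- generate_scene(sp)
#' seg <- segment(sc$stack, segmentation_settings())
#' seg$n_objects
segment <- function(stack, settings = segmentation_settings()) {
  stopifnot(inherits(stack, "fq_stack"), inherits(settings, "fq_settings"))
  chan <- settings$segmentation_channel
  if (!chan %in% names(stack$channels)) {
    if (chan == "AxAm" && "DxAm" %in% names(stack$channels)) {
      chan <- "DxAm"  # expression channel absent; FRET channel is the stand-in
    } else {
      stopf("segmentation channel '%s' not present in stack '%s'",
            chan, stack$source_name)
    }
  }
  vol <- get_channel(stack, chan)

  s_small <- settings$dog_sigma_small
  s_large <- settings$dog_sigma_large
  if (!is.null(stack$voxel_size)) {
    scale <- stack$voxel_size / min(stack$voxel_size)
    s_small <- (if (length(s_small) == 1L) rep(s_small, 3L) else s_small) / scale
    s_large <- (if (length(s_large) == 1L) rep(s_large, 3L) else s_large) / scale
  }
  filtered <- dog_filter(vol, s_small, s_large)
  if (settings$tophat_enabled) {
    filtered <- tophat_filter(filtered, settings$tophat_radius)
  }
  bin <- binarize(filtered, settings$threshold_method,
                  manual_threshold = settings$manual_threshold)
  binary <- bin$mask

  lost <- array(FALSE, dim(binary))
  if (settings$watershed_enabled) {
    split <- watershed_split(binary, settings$connectivity,
                             marker_radius = max(1, ceiling(max(s_small))))
    lost <- find_lost_objects(binary, split, settings$connectivity)
    labels <- label_components(split, settings$connectivity)
    labels <- constrained_dilate_relabel(labels, binary & !lost)
  } else {
    labels <- label_components(binary, settings$connectivity)
  }
  labels <- merge_lost_labels(labels, lost, settings$connectivity)

  if (settings$min_voxels > 0L) {
    sizes <- tabulate(labels[labels > 0L], nbins = max(labels, 1L))
    small <- which(sizes > 0L & sizes < settings$min_voxels)
    if (length(small)) labels[labels %in% small] <- 0L
  }
  labels <- relabel_contiguous(labels)

  used <- settings
  used$segmentation_channel <- chan
  used$threshold_value <- bin$threshold
  structure(list(labels = labels,
                 binary = binary,
                 lost_map = lost,
                 threshold = bin$threshold,
                 watershed_applied = settings$watershed_enabled,
                 settings_used = used,
                 n_objects = max(labels, 0L)),
            class = "fq_segmentation")
}

#' @export
print.fq_segmentation <- function(x, ...) {
  cat(sprintf("<fq_segmentation> %d object(s); threshold %.4g (%s); watershed %s; lost voxels %d\n",
              x$n_objects, x$threshold, x$settings_used$threshold_method,
              if (x$watershed_applied) "on" else "off", sum(x$lost_map)))
  invisible(x)
}
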