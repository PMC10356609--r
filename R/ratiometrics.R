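#' Saturated-voxel exclusion mask
#'
#' Voxels saturated in **either** the donor-excited donor channel (DxDm) or
#' the donor-excited acceptor channel (DxAm) are excluded from the intensity
#' statistics of **both** channels, since a clipped value in one channel
#' invalidates the ratio at that voxel.
#'
#' @param stack An [multichannel_stack()] with `DxDm` and `DxAm` channels.
#' @return Logical 3D array; `TRUE` marks excluded voxels.
#' @export
saturation_mask <- function(stack) {
  stopifnot(inherits(stack, "fq_stack"))
  for (ch in c("DxDm", "DxAm")) {
    if (!ch %in% names(stack$channels)) {
      stopf("saturation mask requires channel '%s'", ch)
    }
  }
  nmax <- max_value(stack$bit_depth)
  stack$channels$DxDm >= nmax | stack$channels$DxAm >= nmax
}

#' Measure per-nucleus intensities and emission ratios
#'
#' For each labelled object, computes its centroid and voxel count over all
#' of its voxels, and channel means over its *analysed* (unsaturated) voxels
#' only. The emission ratio is the ratio of channel means,
#' `mean(DxAm) / mean(DxDm)`, which pools voxels before dividing and is
#' robust to dim voxels. Objects whose analysed voxel set is empty (fully
#' saturated) or whose donor mean is non-positive get an undefined ratio:
#' `emission_ratio = NA` with `ratio_defined = FALSE` — flagged, never
#' silently dropped.
#'
#' @param labels Integer 3D label array (see [segment()]).
#' @param stack An [multichannel_stack()]; must match `labels` in shape.
#' @param mask Optional exclusion mask; defaults to [saturation_mask()].
#' @return Data frame with one row per label id: `source_name`, `roi_id`,
#'   `frame_index`, `centroid_z/y/x` (1-based voxel coordinates),
#'   `voxel_count`, `analysed_voxel_count`, `donor_intensity`,
#'   `acceptor_fret_intensity`, `acceptor_intensity` (NA when the AxAm
#'   channel is absent), `emission_ratio`, `ratio_defined`, `category`.
#' @export
measure_rois <- function(labels, stack, mask = NULL) {
  labels <- as_volume(labels, "labels")
  stopifnot(inherits(stack, "fq_stack"))
  if (!identical(dim(labels), stack_dim(stack))) {
    stopf("`labels` dim (%s) does not match stack dim (%s)",
          paste(dim(labels), collapse = ","),
          paste(stack_dim(stack), collapse = ","))
  }
  if (is.null(mask)) mask <- saturation_mask(stack)
  mask <- as_mask(mask)
  if (!same_dim(mask, labels)) stopf("`mask` dim does not match `labels`")

  nlab <- max(labels, 0L)
  empty <- data.frame(source_name = character(0), roi_id = integer(0),
                      frame_index = integer(0), centroid_z = numeric(0),
                      centroid_y = numeric(0), centroid_x = numeric(0),
                      voxel_count = integer(0), analysed_voxel_count = integer(0),
                      donor_intensity = numeric(0),
                      acceptor_fret_intensity = numeric(0),
                      acceptor_intensity = numeric(0),
                      emission_ratio = numeric(0), ratio_defined = logical(0),
                      category = character(0))
  if (nlab == 0L) return(empty)

  idx <- which(labels > 0L)
  lab <- labels[idx]
  f <- factor(lab, levels = seq_len(nlab))
  pos <- arrayInd(idx, dim(labels))
  voxel_count <- tabulate(lab, nbins = nlab)
  cz <- as.numeric(tapply(pos[, 1L], f, mean))
  cy <- as.numeric(tapply(pos[, 2L], f, mean))
  cx <- as.numeric(tapply(pos[, 3L], f, mean))

  ok <- !mask[idx]
  fa <- f[ok]
  analysed <- tabulate(lab[ok], nbins = nlab)
  ch_mean <- function(role) {
    if (!role %in% names(stack$channels)) return(rep(NA_real_, nlab))
    v <- stack$channels[[role]][idx][ok]
    s <- as.numeric(rowsum(as.numeric(v), fa, reorder = TRUE))
    out <- rep(NA_real_, nlab)
    present <- sort(unique(as.integer(fa)))
    out[present] <- s / analysed[present]
    out
  }
  donor <- ch_mean("DxDm")
  acceptor_fret <- ch_mean("DxAm")
  acceptor <- ch_mean("AxAm")

  ratio <- acceptor_fret / donor
  defined <- analysed > 0L & !is.na(donor) & donor > 0
  ratio[!defined] <- NA_real_

  data.frame(source_name = stack$source_name,
             roi_id = seq_len(nlab),
             frame_index = stack$frame_index,
             centroid_z = cz, centroid_y = cy, centroid_x = cx,
             voxel_count = voxel_count,
             analysed_voxel_count = analysed,
             donor_intensity = donor,
             acceptor_fret_intensity = acceptor_fret,
             acceptor_intensity = acceptor,
             emission_ratio = ratio,
             ratio_defined = defined,
             category = NA_character_)
}

#' Paint per-nucleus emission ratios into a volume
#'
#' Every voxel of object `k` carries object `k`'s emission ratio; background
#' and objects with undefined ratios carry 0 (the undefined flag survives in
#' the records table).
#'
#' @param labels Integer 3D label array.
#' @param records Output of [measure_rois()] covering all label ids.
#' @return Numeric 3D array of ratios.
#' @export
ratio_stack <- function(labels, records) {
  labels <- as_volume(labels, "labels")
  nlab <- max(labels, 0L)
  if (nlab > 0L && !all(seq_len(nlab) %in% records$roi_id)) {
    stopf("`records` must cover every label id 1..%d", nlab)
  }
  out <- array(0, dim(labels))
  if (nlab == 0L) return(out)
  lut <- numeric(nlab)
  r <- records$emission_ratio[match(seq_len(nlab), records$roi_id)]
  lut[] <- ifelse(is.na(r), 0, r)
  sel <- labels > 0L
  out[sel] <- lut[labels[sel]]
  out
}

#' Maximum-intensity Z projection
#'
#' @param volume Numeric 3D array `(z, y, x)`.
#' @return 2D `(y, x)` matrix of per-column maxima (0 where a column is all
#'   zero, since background is 0).
#' @export
max_z_projection <- function(volume) {
  volume <- as_volume(volume)
  apply(volume, c(2L, 3L), max)
}

#' Nearest-point Z projection
#'
#' For each `(y, x)` position, takes the ratio of the labelled voxel nearest
#' the viewer along Z — by default the smallest z index (first slice
#' acquired); `nearest = "bottom"` takes the largest. Columns without
#' labelled voxels are 0.
#'
#' @param volume Numeric 3D ratio array (see [ratio_stack()]).
#' @param labels Integer 3D label array defining which voxels are occupied.
#' @param nearest `"top"` (smallest z, default) or `"bottom"`.
#' @return 2D `(y, x)` matrix.
#' @export
nearest_point_projection <- function(volume, labels, nearest = c("top", "bottom")) {
  volume <- as_volume(volume)
  labels <- as_volume(labels, "labels")
  if (!same_dim(volume, labels)) stopf("`volume` and `labels` must share dim")
  nearest <- match.arg(nearest)
  d <- dim(volume)
  out <- matrix(0, d[2L], d[3L])
  zs <- if (nearest == "top") rev(seq_len(d[1L])) else seq_len(d[1L])
  for (z in zs) {
    sl <- volume[z, , , drop = TRUE]
    has <- labels[z, , , drop = TRUE] > 0L
    out[has] <- sl[has]
  }
  out
}

#' Export ratios as 16-bit integers (x1000 convention)
#'
#' Emission ratios are multiplied by 1000 and rounded (half away from zero)
#' so ratio images can be stored as 16-bit integers instead of 32-bit floats,
#' halving file size; values are clipped to 65535. [import_ratio_image()]
#' inverts the convention.
#'
#' @param ratio Numeric array/matrix of ratios (>= 0).
#' @return Integer array of stored values in `[0, 65535]`.
#' @export
#' @examples
#' export_ratio_image(0.5)   # 500
#' import_ratio_image(500L)  # 0.5
export_ratio_image <- function(ratio) {
  if (any(ratio < 0, na.rm = TRUE)) stopf("ratios must be >= 0 for export")
  v <- round_half_away(ratio * 1000)
  v[v > 65535] <- 65535
  storage.mode(v) <- "integer"
  v
}

#' @rdname export_ratio_image
#' @param stored Integer array of stored (x1000) values.
#' @export
import_ratio_image <- function(stored) {
  stored / 1000
}

#' Write a per-nucleus results table
#'
#' One row per object with a fixed column order (that of [measure_rois()]);
#' undefined ratios are written as empty cells alongside the `ratio_defined`
#' flag column, so no information is lost.
#'
#' @param records Output of [measure_rois()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  cols <- c("source_name", "roi_id", "frame_index",
            "centroid_z", "centroid_y", "centroid_x",
            "voxel_count", "analysed_voxel_count",
            "donor_intensity", "acceptor_fret_intensity", "acceptor_intensity",
            "emission_ratio", "ratio_defined", "category")
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols)) {
    stopf("records are missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  ok <- tryCatch({
    write.csv(records[, cols], path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stopf("failed to write results table '%s': %s", path, conditionMessage(ok))
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) stopf("results table '%s' does not exist", path)
  out <- read.csv(path, stringsAsFactors = FALSE)
  if ("ratio_defined" %in% names(out)) out$ratio_defined <- as.logical(out$ratio_defined)
  if ("category" %in% names(out)) out$category[out$category == ""] <- NA_character_
  out
}

#' Dilate labels for display
#'
#' Grows each label into background voxels for the given number of
#' iterations so small nuclei are easier to see in rendered figures. Labels
#' never overwrite each other (ties go to the lowest id). Display only —
#' measurements must always use the undilated map.
#'
#' @param labels Integer 3D label array.
#' @param iterations Number of single-voxel growth steps (>= 0).
#' @param connectivity 6 or 26.
#' @return Integer 3D label array.
#' @export
dilate_labels_for_display <- function(labels, iterations = 1L, connectivity = 6L) {
  labels <- as_volume(labels, "labels")
  if (iterations < 0) stopf("`iterations` must be >= 0")
  if (!connectivity %in% c(6L, 26L)) stopf("`connectivity` must be 6 or 26")
  if (iterations == 0L) return(labels)
  d <- dim(labels)
  out <- dilate_labels_cpp(as.integer(labels), d, as.integer(iterations),
                           as.integer(connectivity))
  array(as.integer(out), d)
}
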