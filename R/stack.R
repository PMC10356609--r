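#' Multichannel 3D image stack
#'
#' Container for aligned per-channel 3D voxel arrays with channel roles and
#' acquisition metadata. Channel roles follow the standard FRET nomenclature:
#' `DxDm` donor-excited donor emission, `DxAm` donor-excited acceptor (FRET)
#' emission, `AxAm` acceptor-excited acceptor emission (expression control,
#' typically used for segmentation).
#'
#' @param channels Named list of 3D arrays (identical `dim = c(z, y, x)`),
#'   names drawn from `DxDm`, `DxAm`, `AxAm`. Values must be non-negative
#'   counts representable at `bit_depth`.
#' @param bit_depth Integer, one of 8, 12, 16.
#' @param voxel_size Optional numeric length-3 physical voxel size `(z, y, x)`
#'   in any consistent unit; used to scale filter kernels anisotropically.
#' @param frame_index Integer frame (timepoint) identifier carried into
#'   results tables.
#' @param source_name Text identifier (for example the source file name)
#'   carried into results tables.
#'
#' @return An object of class `fq_stack`.
#' @export
#' @examples
#' a <- array(0L, c(4, 8, 8))
#' s <- multichannel_stack(list(DxDm = a, DxAm = a), bit_depth = 12)
#' channel_names(s)
multichannel_stack <- function(channels, bit_depth = 16L, voxel_size = NULL,
                               frame_index = 1L, source_name = "stack") {
  if (!is.list(channels) || length(channels) == 0L || is.null(names(channels))) {
    stopf("`channels` must be a non-empty named list of 3D arrays")
  }
  valid <- c("DxDm", "DxAm", "AxAm")
  bad <- setdiff(names(channels), valid)
  if (length(bad)) {
    stopf("unknown channel role(s): %s (valid: %s)",
          paste(bad, collapse = ", "), paste(valid, collapse = ", "))
  }
  if (!bit_depth %in% c(8L, 12L, 16L)) stopf("`bit_depth` must be 8, 12 or 16")
  channels <- lapply(channels, as_volume, what = "channel")
  d <- dim(channels[[1L]])
  for (nm in names(channels)) {
    if (!identical(dim(channels[[nm]]), d)) {
      stopf("channel '%s' has dim (%s); expected (%s)", nm,
            paste(dim(channels[[nm]]), collapse = ","), paste(d, collapse = ","))
    }
    v <- channels[[nm]]
    if (any(v < 0) || any(v > 2^bit_depth - 1)) {
      stopf("channel '%s' has values outside [0, 2^%d - 1]", nm, bit_depth)
    }
  }
  if (!is.null(voxel_size)) {
    voxel_size <- as.numeric(voxel_size)
    if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
      stopf("`voxel_size` must be 3 positive numbers (z, y, x)")
    }
  }
  structure(
    list(
      channels = channels,
      bit_depth = as.integer(bit_depth),
      voxel_size = voxel_size,
      frame_index = as.integer(frame_index),
      source_name = as.character(source_name)
    ),
    class = "fq_stack"
  )
}

#' @export
print.fq_stack <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("<fq_stack> '%s': %d channel(s) [%s], dim z=%d y=%d x=%d, %d-bit\n",
              x$source_name, length(x$channels),
              paste(names(x$channels), collapse = ", "),
              d[1L], d[2L], d[3L], x$bit_depth))
  invisible(x)
}

#' @rdname multichannel_stack
#' @param x An `fq_stack` object.
#' @export
channel_names <- function(x) names(x$channels)

#' Extract one channel of a stack
#'
#' @param x An `fq_stack`.
#' @param role Channel role (`"DxDm"`, `"DxAm"` or `"AxAm"`).
#' @return The channel's 3D array.
#' @export
get_channel <- function(x, role) {
  if (!role %in% names(x$channels)) {
    stopf("stack '%s' has no channel with role '%s' (has: %s)",
          x$source_name, role, paste(names(x$channels), collapse = ", "))
  }
  x$channels[[role]]
}

stack_dim <- function(x) dim(x$channels[[1L]])

max_value <- function(bit_depth) 2^bit_depth - 1
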