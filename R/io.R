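# Multichannel TIFF input/output.
#
# Two on-disk dialects are supported and round-trip voxel-identically:
#   * one interleaved multi-page file: page (z-1)*C + c, channels fastest,
#     channel order given by `channel_order`;
#   * one multi-page file per channel (a character vector of paths, one per
#     entry of `channel_order`).
# Values are stored as unsigned integers; 12-bit data travel in 16-bit files.

tiff_bits <- function(bit_depth) if (bit_depth <= 8L) 8L else 16L

write_pages <- function(pages, path, bit_depth) {
  bits <- tiff_bits(bit_depth)
  scale <- 2^bits - 1
  pages <- lapply(pages, function(p) p / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

volume_to_pages <- function(volume) {
  d <- dim(volume)
  lapply(seq_len(d[1L]), function(z) matrix(volume[z, , ], d[2L], d[3L]))
}

pages_to_volume <- function(pages) {
  d <- dim(pages[[1L]])
  out <- array(0L, c(length(pages), d[1L], d[2L]))
  for (z in seq_along(pages)) out[z, , ] <- pages[[z]]
  storage.mode(out) <- "integer"
  out
}

#' Write a multichannel stack as TIFF
#'
#' @param stack An [multichannel_stack()].
#' @param path Either a single file path (channels interleaved within each
#'   z plane) or one path per channel.
#' @param channel_order Channel roles in file order; defaults to the stack's
#'   channel order.
#' @return The path(s), invisibly.
#' @export
write_stack <- function(stack, path, channel_order = channel_names(stack)) {
  stopifnot(inherits(stack, "fq_stack"))
  missing_ch <- setdiff(channel_order, channel_names(stack))
  if (length(missing_ch)) {
    stopf("stack lacks channel(s): %s", paste(missing_ch, collapse = ", "))
  }
  if (length(path) == 1L) {
    d <- stack_dim(stack)
    pages <- vector("list", d[1L] * length(channel_order))
    i <- 0L
    for (z in seq_len(d[1L])) {
      for (ch in channel_order) {
        i <- i + 1L
        pages[[i]] <- matrix(stack$channels[[ch]][z, , ], d[2L], d[3L])
      }
    }
    write_pages(pages, path, stack$bit_depth)
  } else {
    if (length(path) != length(channel_order)) {
      stopf("%d paths given for %d channels", length(path), length(channel_order))
    }
    for (i in seq_along(channel_order)) {
      write_pages(volume_to_pages(stack$channels[[channel_order[i]]]),
                  path[i], stack$bit_depth)
    }
  }
  invisible(path)
}

read_tiff_pages <- function(path) {
  if (!file.exists(path)) stopf("TIFF '%s' does not exist", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # drop spurious sample dims
    p
  })
}

#' Read a multichannel stack from TIFF
#'
#' @param path Single interleaved multi-page file, or one file per channel
#'   (same length as `channel_order`).
#' @param channel_order Channel roles in file order, e.g.
#'   `c("DxDm", "DxAm", "AxAm")`.
#' @param bit_depth Optional override; by default taken from the file's
#'   bits-per-sample (12-bit data stored in 16-bit files need the override
#'   to be treated as 12-bit for saturation detection).
#' @param ... Passed to [multichannel_stack()] (`voxel_size`, `frame_index`).
#' @return An [multichannel_stack()]; `source_name` is the first file's base
#'   name.
#' @export
read_stack <- function(path, channel_order = c("DxDm", "DxAm", "AxAm"),
                       bit_depth = NULL, ...) {
  nch <- length(channel_order)
  if (length(path) == 1L) {
    pages <- read_tiff_pages(path)
    if (length(pages) %% nch != 0L) {
      stopf("'%s' has %d pages, not a multiple of the %d channel(s) in channel_order (%s)",
            path, length(pages), nch, paste(channel_order, collapse = ","))
    }
    nz <- length(pages) %/% nch
    channels <- lapply(seq_len(nch), function(c_i) {
      pages_to_volume(pages[(seq_len(nz) - 1L) * nch + c_i])
    })
    names(channels) <- channel_order
    bits_attr <- attr(pages[[1L]], "bits.per.sample")
  } else {
    if (length(path) != nch) {
      stopf("%d files given for %d channels in channel_order", length(path), nch)
    }
    channels <- lapply(path, function(p) pages_to_volume(read_tiff_pages(p)))
    names(channels) <- channel_order
    bits_attr <- attr(read_tiff_pages(path[1L])[[1L]], "bits.per.sample")
  }
  if (is.null(bit_depth)) {
    bit_depth <- if (!is.null(bits_attr)) as.integer(bits_attr) else {
      mx <- max(vapply(channels, max, 0))
      if (mx <= 255) 8L else 16L
    }
  }
  multichannel_stack(channels, bit_depth = bit_depth,
                     source_name = basename(path[1L]), ...)
}

#' Write a label map as a 16-bit TIFF
#'
#' @param labels Integer 3D label array (ids must fit in 16 bits).
#' @param path Output path.
#' @export
write_label_tiff <- function(labels, path) {
  labels <- as_volume(labels, "labels")
  if (max(labels) > 65535) stopf("label ids exceed the 16-bit range")
  write_pages(volume_to_pages(labels), path, 16L)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path) {
  pages_to_volume(read_tiff_pages(path))
}

#' Write a binary map as an 8-bit 0/255 TIFF
#'
#' @param mask Logical 3D array.
#' @param path Output path.
#' @export
write_mask_tiff <- function(mask, path) {
  mask <- as_mask(mask)
  write_pages(volume_to_pages(array(ifelse(mask, 255L, 0L), dim(mask))), path, 8L)
}
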