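# Preprocessing filters: 3D difference of Gaussians and white top-hat.

# Sampled, normalized 1D Gaussian kernel; radius covers +-3.5 sigma.
gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3.5 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable 3D Gaussian blur; sigma is length 1 or 3 (z, y, x), in voxels.
# sigma = 0 on an axis skips that axis.
gaussian_blur3 <- function(volume, sigma) {
  v <- as.numeric(volume)
  d <- dim(volume)
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  for (axis in 1:3) {
    if (sigma[axis] > 0) {
      v <- conv_axis_cpp(v, d, gaussian_kernel(sigma[axis]), axis - 1L)
    }
  }
  array(v, d)
}

#' Difference-of-Gaussians band-pass filter
#'
#' Smooths noise and removes broad background in one step:
#' `G(sigma_small) * volume - G(sigma_large) * volume`, computed in floating
#' point. Blob-like objects whose scale lies between the two sigmas are
#' enhanced; constant backgrounds are annihilated exactly.
#'
#' @param volume 3D array of counts, `dim = c(z, y, x)`.
#' @param sigma_small,sigma_large Gaussian standard deviations in voxels
#'   (length 1, or 3 for per-axis anisotropic kernels); elementwise
#'   `sigma_small < sigma_large` is required.
#' @return 3D array of signed filter responses.
#' @export
#' @examples
#' v <- array(0, c(9, 9, 9)); v[5, 5, 5] <- 1
#' r <- dog_filter(v, 1, 2)
#' which.max(r) == which.max(v)
dog_filter <- function(volume, sigma_small, sigma_large) {
  volume <- as_volume(volume)
  if (length(sigma_small) == 1L) sigma_small <- rep(sigma_small, 3L)
  if (length(sigma_large) == 1L) sigma_large <- rep(sigma_large, 3L)
  if (any(sigma_small >= sigma_large)) {
    stopf("`sigma_small` (%s) must be < `sigma_large` (%s) on every axis",
          paste(sigma_small, collapse = ","), paste(sigma_large, collapse = ","))
  }
  if (any(sigma_small < 0)) stopf("sigmas must be >= 0")
  gaussian_blur3(volume, sigma_small) - gaussian_blur3(volume, sigma_large)
}

# Offsets (k x 3 integer matrix) of a voxel ball of the given radius,
# optionally anisotropic (length-3 radius).
ball_offsets <- function(radius) {
  if (length(radius) == 1L) radius <- rep(radius, 3L)
  r <- pmax(1, radius)
  g <- expand.grid(dz = -floor(r[1L]):floor(r[1L]),
                   dy = -floor(r[2L]):floor(r[2L]),
                   dx = -floor(r[3L]):floor(r[3L]))
  keep <- (g$dz / r[1L])^2 + (g$dy / r[2L])^2 + (g$dx / r[3L])^2 <= 1
  as.matrix(g[keep, , drop = FALSE])
}

#' White top-hat background subtraction
#'
#' Subtracts the morphological opening (erosion then dilation with a ball
#' structuring element) from the volume, removing structures wider than the
#' element while keeping smaller, brighter features. The result is
#' non-negative.
#'
#' @param volume 3D array, `dim = c(z, y, x)`.
#' @param radius Ball radius in voxels (length 1 or 3), >= 1.
#' @return 3D array of background-subtracted values.
#' @export
tophat_filter <- function(volume, radius) {
  volume <- as_volume(volume)
  if (any(radius < 1)) stopf("`radius` must be >= 1")
  d <- dim(volume)
  offs <- ball_offsets(radius)
  storage.mode(offs) <- "integer"
  eroded <- morph_flat_cpp(as.numeric(volume), d, offs, FALSE)
  opened <- morph_flat_cpp(eroded, d, offs, TRUE)
  out <- as.numeric(volume) - opened
  out[out < 0] <- 0
  array(out, d)
}
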