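# Histogram-based automatic thresholding and binarization.

# Build a histogram (counts + upper bin edges) suitable for the automatic
# threshold criteria. Integer-valued data with a modest range get exact
# integer bins; otherwise `nbins` uniform bins are used.
threshold_histogram <- function(v, nbins = 4096L) {
  rng <- range(v)
  if (rng[1L] == rng[2L]) {
    return(list(counts = length(v), edges = rng[1L]))
  }
  intish <- all(v == floor(v)) && (rng[2L] - rng[1L]) <= 65535
  if (intish) {
    edges <- seq(rng[1L], rng[2L], by = 1)
  } else {
    edges <- seq(rng[1L], rng[2L], length.out = nbins + 1L)[-1L]
  }
  # bin i holds values in (edges[i-1], edges[i]]
  idx <- findInterval(v, edges, left.open = TRUE) + 1L
  idx[idx > length(edges)] <- length(edges)
  list(counts = tabulate(idx, nbins = length(edges)), edges = edges)
}

otsu_threshold <- function(counts, edges) {
  p <- counts / sum(counts)
  mids <- edges
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, length(p))
  sigma_b[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  mx <- max(sigma_b)
  # center of the argmax plateau: puts the cut mid-gap for well-separated modes
  plateau <- which(sigma_b >= mx - 1e-10 * abs(mx))
  edges[floor(mean(range(plateau)))]
}

triangle_threshold <- function(counts, edges) {
  peak <- which.max(counts)
  nz <- which(counts > 0)
  lo <- nz[1L]; hi <- nz[length(nz)]
  # work on the longer tail side of the peak
  if ((hi - peak) >= (peak - lo)) {
    idx <- peak:hi
  } else {
    idx <- peak:lo
  }
  x1 <- idx[1L]; y1 <- counts[peak]
  x2 <- idx[length(idx)]; y2 <- counts[x2]
  dx <- x2 - x1; dy <- y2 - y1
  norm <- sqrt(dx^2 + dy^2)
  if (norm == 0) return(edges[peak])
  dist <- abs(dy * (idx - x1) - dx * (counts[idx] - y1)) / norm
  edges[idx[which.max(dist)]]
}

yen_threshold <- function(counts, edges) {
  p <- counts / sum(counts)
  p1 <- cumsum(p)
  p1sq <- cumsum(p^2)
  p2sq <- p1sq[length(p1sq)] - p1sq
  crit <- ifelse(p1sq * p2sq > 0, -log(p1sq * p2sq), 0) +
    ifelse(p1 * (1 - p1) > 0, 2 * log(p1 * (1 - p1)), 0)
  edges[which.max(crit)]
}

#' Compute an automatic threshold value
#'
#' Standard histogram criteria operating on any numeric volume (including the
#' signed output of [dog_filter()]): Otsu's between-class variance maximum,
#' the triangle geometric method, Yen's maximum-correlation criterion, or the
#' sample mean.
#'
#' @param volume Numeric array or vector.
#' @param method One of `"otsu"`, `"triangle"`, `"yen"`, `"mean"`.
#' @param nbins Number of histogram bins for non-integer data.
#' @return The threshold value (foreground is strictly above it).
#' @export
auto_threshold <- function(volume, method = c("otsu", "triangle", "yen", "mean"),
                           nbins = 4096L) {
  method <- match.arg(method)
  v <- as.numeric(volume)
  v <- v[is.finite(v)]
  if (!length(v)) stopf("no finite values to threshold")
  if (method == "mean") return(mean(v))
  h <- threshold_histogram(v, nbins)
  if (length(h$edges) == 1L) return(h$edges)
  switch(method,
         otsu = otsu_threshold(h$counts, h$edges),
         triangle = triangle_threshold(h$counts, h$edges),
         yen = yen_threshold(h$counts, h$edges))
}

#' Binarize a volume
#'
#' Generates the binary foreground map used downstream by the watershed and
#' labelling stages. Foreground is every voxel **strictly above** the
#' threshold; the threshold value actually used is returned so it can be
#' recorded in the run log.
#'
#' @param volume 3D numeric array (typically a [dog_filter()] response).
#' @param method `"otsu"` (default), `"triangle"`, `"yen"`, `"mean"` or
#'   `"manual"`.
#' @param manual_threshold Threshold value, required iff `method = "manual"`.
#' @param nbins Histogram bins for the automatic criteria.
#' @return List with `mask` (logical 3D array) and `threshold` (numeric).
#' @export
#' @examples
#' v <- array(c(rep(10, 500), rep(100, 500)), c(10, 10, 10))
#' b <- binarize(v, "otsu")
#' b$threshold
binarize <- function(volume, method = c("otsu", "triangle", "yen", "mean", "manual"),
                     manual_threshold = NULL, nbins = 4096L) {
  volume <- as_volume(volume)
  method <- match.arg(method)
  if (method == "manual") {
    if (is.null(manual_threshold)) {
      stopf("`manual_threshold` is required when method = \"manual\"")
    }
    thr <- as.numeric(manual_threshold)
  } else {
    if (!is.null(manual_threshold)) {
      stopf("`manual_threshold` is only meaningful with method = \"manual\"")
    }
    thr <- auto_threshold(volume, method, nbins)
  }
  list(mask = volume > thr, threshold = thr)
}
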