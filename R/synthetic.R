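#' Specify one synthetic nucleus
#'
#' Nuclei are rendered as solid ellipsoids of constant expected intensity.
#' Inside a nucleus the donor-excitation channels take the nucleus values
#' (`DxDm = dxdm_intensity`, `DxAm = true_ratio * dxdm_intensity`,
#' `AxAm = axam_intensity`) so that the ground-truth emission ratio of every
#' nucleus is exactly `true_ratio` before noise; background applies only
#' outside nuclei.
#'
#' @param center Numeric length-3 voxel coordinates `(z, y, x)`, 1-based, may
#'   be fractional.
#' @param radii Numeric length-3 ellipsoid semi-axes in voxels `(z, y, x)`;
#'   a single number gives a sphere.
#' @param dxdm_intensity Expected donor-channel counts inside the nucleus.
#' @param true_ratio Ground-truth emission ratio (`DxAm/DxDm`), dimensionless.
#' @param axam_intensity Expected acceptor-excitation counts inside the
#'   nucleus (expression level).
#' @return A `fq_nucleus` list.
#' @export
nucleus_spec <- function(center, radii, dxdm_intensity = 1000,
                         true_ratio = 1, axam_intensity = dxdm_intensity) {
  center <- as.numeric(center)
  radii <- as.numeric(radii)
  if (length(radii) == 1L) radii <- rep(radii, 3L)
  if (length(center) != 3L) stopf("`center` must be length 3 (z, y, x)")
  if (length(radii) != 3L || any(radii <= 0)) stopf("`radii` must be positive (z, y, x)")
  if (dxdm_intensity < 0 || axam_intensity < 0) stopf("intensities must be >= 0")
  if (true_ratio < 0) stopf("`true_ratio` must be >= 0")
  structure(list(center = center, radii = radii,
                 dxdm_intensity = dxdm_intensity, true_ratio = true_ratio,
                 axam_intensity = axam_intensity),
            class = "fq_nucleus")
}

#' Specify a synthetic multichannel scene
#'
#' Describes a ground-truthed 3D scene of ellipsoidal "nuclei" carrying a
#' nuclear-localized ratiometric biosensor, with optional background
#' gradient, detector noise and saturated voxels. [generate_scene()] renders
#' it into an [multichannel_stack()] plus exact ground truth.
#'
#' @param shape Integer length-3 volume dimensions `(z, y, x)` in voxels.
#' @param nuclei List of [nucleus_spec()] objects.
#' @param background_level Expected background counts (>= 0).
#' @param background_gradient Additional counts per voxel added linearly along
#'   `gradient_axis` (0 disables).
#' @param gradient_axis Axis of the background gradient: `"z"`, `"y"` or `"x"`.
#' @param noise Noise model: `"none"`, `"gaussian"` (additive, sd =
#'   `noise_sd` counts) or `"poisson"` (counts drawn from the noiseless
#'   expectation).
#' @param noise_sd Gaussian noise standard deviation in counts.
#' @param bit_depth Image bit depth (8, 12 or 16); values are clipped to the
#'   representable range after noise.
#' @param saturate_fraction Fraction of nucleus voxels whose `DxAm` value is
#'   forced to the maximum representable value (simulates detector
#'   saturation).
#' @param with_axam Render the `AxAm` expression-control channel?
#' @param seed Integer seed; scenes are bit-identical for identical spec+seed.
#' @return A `fq_scene_spec` list.
#' @export
#' @examples
#' sp <- scene_spec(shape = c(8, 16, 16),
#'                  nuclei = list(nucleus_spec(c(4, 8, 8), 3, 100, 1.5)),
#'                  background_level = 0, noise = "none")
#' sc <- generate_scene(sp)
#' sc$truth$table
scene_spec <- function(shape, nuclei, background_level = 50,
                       background_gradient = 0, gradient_axis = "y",
                       noise = c("none", "gaussian", "poisson"), noise_sd = 0,
                       bit_depth = 16L, saturate_fraction = 0,
                       with_axam = TRUE, seed = 1L) {
  noise <- match.arg(noise)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stopf("`shape` must be 3 positive integers (z, y, x)")
  if (!is.list(nuclei) || !all(vapply(nuclei, inherits, TRUE, "fq_nucleus"))) {
    stopf("`nuclei` must be a list of nucleus_spec() objects")
  }
  for (i in seq_along(nuclei)) {
    ctr <- nuclei[[i]]$center
    if (any(ctr < 1) || any(ctr > shape)) {
      stopf("nucleus %d center (%s) lies outside the volume shape (%s)",
            i, paste(ctr, collapse = ","), paste(shape, collapse = ","))
    }
  }
  if (background_level < 0) stopf("`background_level` must be >= 0")
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  if (saturate_fraction < 0 || saturate_fraction > 1) stopf("`saturate_fraction` must be in [0, 1]")
  if (!bit_depth %in% c(8L, 12L, 16L)) stopf("`bit_depth` must be 8, 12 or 16")
  gradient_axis <- match.arg(gradient_axis, c("z", "y", "x"))
  structure(list(shape = shape, nuclei = nuclei,
                 background_level = background_level,
                 background_gradient = background_gradient,
                 gradient_axis = gradient_axis,
                 noise = noise, noise_sd = noise_sd,
                 bit_depth = as.integer(bit_depth),
                 saturate_fraction = saturate_fraction,
                 with_axam = isTRUE(with_axam),
                 seed = as.integer(seed)),
            class = "fq_scene_spec")
}

#' Render a synthetic scene with ground truth
#'
#' Renders the ellipsoids of a [scene_spec()] into `DxDm`/`DxAm` (and
#' optionally `AxAm`) channels, applies the requested noise model, rounds and
#' clips to the representable integer range, injects saturated voxels, and
#' returns the stack together with an exact ground-truth label map and
#' per-nucleus table. Where ellipsoids overlap, each voxel belongs to the
#' nucleus whose center is nearest in radii-scaled coordinates (deterministic,
#' order-independent; exact ties go to the lowest nucleus id).
#'
#' @param spec A [scene_spec()].
#' @return A list with elements `stack` (an [multichannel_stack()]) and
#'   `truth` (list: `label_map` 3D integer array, `table` data frame with
#'   columns `id`, `center_z/y/x`, `voxel_count`, `true_ratio`).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "fq_scene_spec"))
  d <- spec$shape
  nmax <- max_value(spec$bit_depth)
  nvox <- prod(d)

  bg <- array(spec$background_level, d)
  if (spec$background_gradient != 0) {
    ax <- match(spec$gradient_axis, c("z", "y", "x"))
    coord <- slice.index(bg, ax) - 1
    bg <- bg + spec$background_gradient * coord
  }

  label <- array(0L, d)
  best <- array(Inf, d)
  for (k in seq_along(spec$nuclei)) {
    nu <- spec$nuclei[[k]]
    lo <- pmax(1L, ceiling(nu$center - nu$radii))
    hi <- pmin(d, floor(nu$center + nu$radii))
    if (any(lo > hi)) next
    zz <- lo[1L]:hi[1L]; yy <- lo[2L]:hi[2L]; xx <- lo[3L]:hi[3L]
    dz2 <- ((zz - nu$center[1L]) / nu$radii[1L])^2
    dy2 <- ((yy - nu$center[2L]) / nu$radii[2L])^2
    dx2 <- ((xx - nu$center[3L]) / nu$radii[3L])^2
    d2 <- outer(outer(dz2, dy2, `+`), dx2, `+`)
    sub <- best[zz, yy, xx, drop = FALSE]
    take <- d2 <= 1 & d2 < sub
    if (any(take)) {
      lab_sub <- label[zz, yy, xx, drop = FALSE]
      lab_sub[take] <- k
      sub[take] <- d2[take]
      label[zz, yy, xx] <- lab_sub
      best[zz, yy, xx] <- sub
    }
  }

  dxdm <- bg
  dxam <- bg
  axam <- if (spec$with_axam) bg else NULL
  idx <- which(label > 0L)
  lab <- label[idx]
  dxdm_int <- vapply(spec$nuclei, `[[`, 0, "dxdm_intensity")
  ratio <- vapply(spec$nuclei, `[[`, 0, "true_ratio")
  axam_int <- vapply(spec$nuclei, `[[`, 0, "axam_intensity")
  dxdm[idx] <- dxdm_int[lab]
  dxam[idx] <- ratio[lab] * dxdm_int[lab]
  if (!is.null(axam)) axam[idx] <- axam_int[lab]

  quantize <- function(x) {
    x <- round_half_away(x)
    x[x < 0] <- 0
    x[x > nmax] <- nmax
    array(as.integer(x), d)
  }
  chans <- list(DxDm = dxdm, DxAm = dxam)
  if (!is.null(axam)) chans$AxAm <- axam

  chans <- with_seed(spec$seed, {
    out <- lapply(chans, function(x) {
      if (spec$noise == "gaussian" && spec$noise_sd > 0) {
        x <- x + rnorm(nvox, 0, spec$noise_sd)
      } else if (spec$noise == "poisson") {
        x <- array(rpois(nvox, pmax(x, 0)), d)
      }
      quantize(x)
    })
    if (spec$saturate_fraction > 0 && length(idx)) {
      nsat <- round(spec$saturate_fraction * length(idx))
      if (nsat > 0) {
        sat <- sample(idx, nsat)
        out$DxAm[sat] <- as.integer(nmax)
      }
    }
    out
  })

  counts <- tabulate(lab, nbins = length(spec$nuclei))
  pos <- arrayInd(idx, d)
  truth_table <- data.frame(
    id = seq_along(spec$nuclei),
    center_z = vapply(spec$nuclei, function(n) n$center[1L], 0),
    center_y = vapply(spec$nuclei, function(n) n$center[2L], 0),
    center_x = vapply(spec$nuclei, function(n) n$center[3L], 0),
    voxel_count = counts,
    true_ratio = ratio
  )
  # rendered centroids (of assigned voxels) for convenience
  if (length(idx)) {
    truth_table$centroid_z <- as.numeric(tapply(pos[, 1L], factor(lab, levels = truth_table$id), mean))
    truth_table$centroid_y <- as.numeric(tapply(pos[, 2L], factor(lab, levels = truth_table$id), mean))
    truth_table$centroid_x <- as.numeric(tapply(pos[, 3L], factor(lab, levels = truth_table$id), mean))
  }

  list(
    stack = multichannel_stack(chans, bit_depth = spec$bit_depth,
                               source_name = sprintf("synthetic_seed%d", spec$seed)),
    truth = list(label_map = label, table = truth_table)
  )
}

#' Place random non-overlapping spherical nuclei
#'
#' Rejection-samples `n` sphere centers so that spheres do not overlap and
#' stay `margin` voxels away from the volume border. Convenience builder for
#' benchmark scenes.
#'
#' @param n Number of nuclei.
#' @param shape Volume shape `(z, y, x)`.
#' @param radius Sphere radius in voxels (single number or range to sample).
#' @param dxdm_intensity,axam_intensity Channel intensities (see
#'   [nucleus_spec()]).
#' @param ratio_range Range of ground-truth emission ratios to sample
#'   uniformly.
#' @param margin Border margin in voxels.
#' @param min_gap Minimum surface-to-surface gap between spheres, voxels.
#' @param seed Integer seed.
#' @return List of [nucleus_spec()] objects.
#' @export
random_nuclei <- function(n, shape, radius = 4, dxdm_intensity = 1000,
                          axam_intensity = 1000, ratio_range = c(0.6, 1.8),
                          margin = radius + 2, min_gap = 2, seed = 1L) {
  stopifnot(n >= 1, length(shape) == 3L)
  margin <- max(margin)
  rr <- if (length(radius) == 1L) c(radius, radius) else range(radius)
  with_seed(seed, {
    centers <- matrix(0, 0, 3)
    radii <- numeric(0)
    tries <- 0L
    while (nrow(centers) < n && tries < 20000L) {
      tries <- tries + 1L
      r <- stats::runif(1, rr[1L], rr[2L])
      ctr <- vapply(1:3, function(a) {
        lo <- 1 + margin
        hi <- shape[a] - margin
        if (hi <= lo) {  # axis too thin for the margin: fall back to its middle
          mid <- (1 + shape[a]) / 2
          lo <- mid - 0.5
          hi <- mid + 0.5
        }
        stats::runif(1, lo, hi)
      }, 0)
      ok <- TRUE
      if (nrow(centers)) {
        dist <- sqrt(colSums((t(centers) - ctr)^2))
        ok <- all(dist > radii + r + min_gap)
      }
      if (ok) {
        centers <- rbind(centers, ctr)
        radii <- c(radii, r)
      }
    }
    if (nrow(centers) < n) {
      stopf("could not place %d non-overlapping nuclei in shape (%s)",
            n, paste(shape, collapse = ","))
    }
    # ratios on the 0.001 grid: ground truth is exactly representable in
    # integer channels (dxdm_intensity 1000) and in the x1000 export
    ratios <- round(stats::runif(n, ratio_range[1L], ratio_range[2L]) * 1000) / 1000
    lapply(seq_len(n), function(i) {
      nucleus_spec(centers[i, ], radii[i], dxdm_intensity, ratios[i], axam_intensity)
    })
  })
}

#' Single-site binding isotherm
#'
#' `R(c) = r_min + (r_max - r_min) * c^n / (kd^n + c^n)`; `c = 0` maps
#' exactly to `r_min` (no log transform anywhere).
#'
#' @param conc Ligand concentration(s), same units as `kd`.
#' @param r_min,r_max Emission ratio at zero and saturating ligand.
#' @param kd Dissociation constant (> 0).
#' @param n_hill Hill coefficient (1 = single independent site).
#' @return Numeric response(s).
#' @export
hill_response <- function(conc, r_min, r_max, kd, n_hill = 1) {
  stopifnot(kd > 0, all(conc >= 0))
  cn <- ifelse(conc == 0, 0, conc^n_hill)
  r_min + (r_max - r_min) * cn / (kd^n_hill + cn)
}

#' Simulate a biosensor titration
#'
#' Generates per-replicate emission ratios on a single-site (or general Hill)
#' isotherm with additive Gaussian noise, emulating a plate-reader serial
#' dilution read out as an emission-band ratio.
#'
#' @inheritParams hill_response
#' @param concentrations Ligand concentrations (>= 0; include 0 for the
#'   apo point).
#' @param noise_sd Gaussian noise sd on the ratio (>= 0).
#' @param replicates Replicates per concentration.
#' @param seed Integer seed; deterministic given seed.
#' @return Data frame with columns `concentration`, `replicate`, `ratio`.
#' @export
#' @examples
#' generate_titration(0.6, 1.0, kd = 1e-7,
#'                    concentrations = c(0, 10^seq(-9, -5, length.out = 7)))
generate_titration <- function(r_min, r_max, kd, n_hill = 1, concentrations,
                               noise_sd = 0, replicates = 1L, seed = 1L) {
  if (kd <= 0) stopf("`kd` must be > 0")
  if (any(concentrations < 0)) stopf("`concentrations` must be >= 0")
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  stopifnot(replicates >= 1)
  conc <- rep(concentrations, each = replicates)
  repl <- rep(seq_len(replicates), times = length(concentrations))
  mu <- hill_response(conc, r_min, r_max, kd, n_hill)
  ratio <- with_seed(seed, mu + if (noise_sd > 0) rnorm(length(mu), 0, noise_sd) else 0)
  data.frame(concentration = conc, replicate = repl, ratio = ratio)
}
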