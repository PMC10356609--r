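# Shared fixture builders and independent oracles.

# Solid sphere / ellipsoid masks built by direct coordinate arithmetic.
sphere_mask <- function(dim, center, radius) {
  g <- expand.grid(z = seq_len(dim[1]), y = seq_len(dim[2]), x = seq_len(dim[3]))
  array((g$z - center[1])^2 + (g$y - center[2])^2 + (g$x - center[3])^2 <= radius^2,
        dim)
}

# Two touching radius-5 spheres with centers 8 voxels apart along x.
dumbbell_mask <- function(dim = c(24, 24, 32), r = 5, gap = 8) {
  c1 <- c(12, 12, 12)
  c2 <- c(12, 12, 12 + gap)
  sphere_mask(dim, c1, r) | sphere_mask(dim, c2, r)
}

# Independent connected-components oracle: iterative minimum-label
# propagation (vectorized flood fill) until fixpoint. Completely separate
# from the package's BFS implementation.
cc_oracle <- function(mask, connectivity) {
  d <- dim(mask)
  lab <- array(Inf, d)
  lab[mask] <- which(mask)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  if (connectivity == 6) {
    offs <- offs[abs(offs$dz) + abs(offs$dy) + abs(offs$dx) == 1, ]
  }
  offs <- as.matrix(offs)
  shift <- function(a, o) {
    out <- array(Inf, d)
    zi <- seq(max(1, 1 - o[1]), min(d[1], d[1] - o[1]))
    yi <- seq(max(1, 1 - o[2]), min(d[2], d[2] - o[2]))
    xi <- seq(max(1, 1 - o[3]), min(d[3], d[3] - o[3]))
    if (length(zi) && length(yi) && length(xi)) {
      out[zi, yi, xi] <- a[zi + o[1], yi + o[2], xi + o[3]]
    }
    out
  }
  repeat {
    new <- lab
    for (i in seq_len(nrow(offs))) {
      new <- pmin(new, shift(lab, offs[i, ]))
    }
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  # compress to contiguous ids in order of first (raster) occurrence
  out <- array(0L, d)
  ids <- unique(lab[mask])
  out[mask] <- match(lab[mask], ids)
  out
}

# Two labelings describe the same partition of the foreground.
same_partition <- function(a, b) {
  fa <- a[a > 0L]
  fb <- b[b > 0L]
  if (length(fa) != length(fb)) return(FALSE)
  if (!identical(a > 0L, b > 0L)) return(FALSE)
  length(unique(fa)) == length(unique(fb)) &&
    length(unique(paste(fa, fb))) == length(unique(fa))
}

# Ground-truthed benchmark scene with n non-overlapping spherical nuclei.
make_scene <- function(n, shape = c(32, 128, 128), background = 50,
                       noise = "none", noise_sd = 0, seed = 7,
                       saturate_fraction = 0) {
  nuc <- random_nuclei(n, shape, radius = 4, seed = seed)
  generate_scene(scene_spec(shape, nuc, background_level = background,
                            noise = noise, noise_sd = noise_sd,
                            saturate_fraction = saturate_fraction,
                            seed = seed + 100))
}

# Match each measured ROI to its ground-truth nucleus by centroid proximity
# and return the relative emission-ratio errors.
ratio_errors <- function(records, truth) {
  vapply(seq_len(nrow(records)), function(i) {
    d2 <- (truth$center_z - records$centroid_z[i])^2 +
      (truth$center_y - records$centroid_y[i])^2 +
      (truth$center_x - records$centroid_x[i])^2
    k <- which.min(d2)
    abs(records$emission_ratio[i] - truth$true_ratio[k]) / truth$true_ratio[k]
  }, 0)
}
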