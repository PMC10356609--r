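make_simple_stack <- function(dxdm, dxam, axam = NULL, bit_depth = 16L) {
  ch <- list(DxDm = dxdm, DxAm = dxam)
  if (!is.null(axam)) ch$AxAm <- axam
  multichannel_stack(ch, bit_depth = bit_depth)
}

test_that("saturation masking follows the either-channel rule at any bit depth", {
  d <- c(4, 4, 4)
  dxdm <- array(100L, d)
  dxam <- array(200L, d)
  st <- make_simple_stack(dxdm, dxam)
  expect_false(any(saturation_mask(st)))

  dxam[2, 2, 2] <- 65535L
  st <- make_simple_stack(dxdm, dxam)
  m <- saturation_mask(st)
  expect_equal(which(m), which(array(seq_len(64), d) == 22))

  dxdm12 <- array(100L, d)
  dxdm12[1, 1, 1] <- 4095L
  st12 <- make_simple_stack(dxdm12, array(200L, d), bit_depth = 12L)
  expect_true(saturation_mask(st12)[1, 1, 1])
  expect_equal(sum(saturation_mask(st12)), 1L)
})

test_that("per-ROI ratios are ratios of means over unsaturated voxels", {
  d <- c(3, 5, 5)
  lab <- array(0L, d)
  lab[2, 2:4, 2:4] <- 1L          # 9 voxels
  dxdm <- array(0L, d); dxam <- array(0L, d)
  dxdm[lab == 1L] <- 100L
  dxam[lab == 1L] <- 150L
  rec <- measure_rois(lab, make_simple_stack(dxdm, dxam))
  expect_equal(rec$emission_ratio, 1.5)
  expect_true(rec$ratio_defined)
  expect_true(is.na(rec$acceptor_intensity))  # AxAm absent

  # 10-voxel ROI, one saturated; remaining nine have DxDm 200, DxAm 100
  lab2 <- array(0L, d)
  lab2[1, 1:2, 1:5] <- 1L
  dxdm2 <- array(0L, d); dxam2 <- array(0L, d)
  dxdm2[lab2 == 1L] <- 200L
  dxam2[lab2 == 1L] <- 100L
  dxdm2[1, 1, 1] <- 65535L
  rec2 <- measure_rois(lab2, make_simple_stack(dxdm2, dxam2))
  expect_equal(rec2$voxel_count, 10L)
  expect_equal(rec2$analysed_voxel_count, 9L)
  expect_equal(rec2$emission_ratio, 0.5)

  # fully saturated ROI: flagged undefined, never dropped
  dxdm3 <- array(65535L, d)
  rec3 <- measure_rois(lab, make_simple_stack(dxdm3, dxam))
  expect_equal(nrow(rec3), 1L)
  expect_equal(rec3$analysed_voxel_count, 0L)
  expect_true(is.na(rec3$emission_ratio))
  expect_false(rec3$ratio_defined)
})

test_that("saturating one voxel perturbs only its ROI, on a common voxel set", {
  sc <- make_scene(4, shape = c(16, 64, 64), background = 20,
                   noise = "gaussian", noise_sd = 50)
  lab <- sc$truth$label_map
  base <- measure_rois(lab, sc$stack)
  st <- sc$stack
  vox <- which(lab == 2L)[1]
  st$channels$DxAm[vox] <- 65535L
  pert <- measure_rois(lab, st)
  unchanged <- pert$roi_id != 2L
  expect_equal(pert$donor_intensity[unchanged], base$donor_intensity[unchanged])
  expect_equal(pert$acceptor_fret_intensity[unchanged],
               base$acceptor_fret_intensity[unchanged])
  expect_equal(pert$analysed_voxel_count[!unchanged],
               base$analysed_voxel_count[!unchanged] - 1L)
  # donor stats recomputed over the same reduced set even though DxDm itself
  # was untouched
  expect_false(pert$donor_intensity[!unchanged] ==
                 base$donor_intensity[!unchanged] &&
               pert$acceptor_fret_intensity[!unchanged] ==
                 base$acceptor_fret_intensity[!unchanged])
})

test_that("scaling DxAm scales every defined ratio exactly", {
  sc <- make_scene(5, shape = c(16, 64, 64), background = 10, noise = "none")
  lab <- sc$truth$label_map
  base <- measure_rois(lab, sc$stack)
  st <- sc$stack
  st$channels$DxAm <- st$channels$DxAm * 3L   # stays within 16-bit range
  scaled <- measure_rois(lab, st)
  expect_equal(scaled$emission_ratio, 3 * base$emission_ratio)
})

test_that("ratio stack paints per-ROI constants; projections stay within columns", {
  d <- c(6, 8, 8)
  lab <- array(0L, d)
  lab[2, 2:3, 2:3] <- 1L
  lab[5, 2:3, 2:3] <- 2L   # stacked above ROI 1 in z
  lab[3, 6, 6] <- 3L
  dxdm <- array(0L, d); dxam <- array(0L, d)
  dxdm[lab > 0] <- 100L
  dxam[lab == 1L] <- 80L   # ratio 0.8
  dxam[lab == 2L] <- 120L  # ratio 1.2
  dxam[lab == 3L] <- 100L  # ratio 1.0
  st <- make_simple_stack(dxdm, dxam)
  rec <- measure_rois(lab, st)
  rs <- ratio_stack(lab, rec)
  expect_setequal(unique(as.numeric(rs)), c(0, 0.8, 1.2, 1))
  expect_true(all(rs[lab == 0] == 0))

  mz <- max_z_projection(rs)
  expect_equal(mz[2, 2], 1.2)   # max over the stacked column
  np <- nearest_point_projection(rs, lab, "top")
  expect_equal(np[2, 2], 0.8)   # smallest z wins
  npb <- nearest_point_projection(rs, lab, "bottom")
  expect_equal(npb[2, 2], 1.2)
  expect_equal(np[1, 1], 0)     # empty column
  # projection containment: every nonzero projected value occurs in its column
  for (y in 1:8) for (x in 1:8) {
    if (mz[y, x] > 0) expect_true(mz[y, x] %in% rs[, y, x])
    if (np[y, x] > 0) expect_true(np[y, x] %in% rs[, y, x])
  }

  # undefined-ratio ROI paints 0 but keeps its flag in the table
  st2 <- make_simple_stack(array(65535L, d), dxam)
  rec2 <- measure_rois(lab, st2)
  rs2 <- ratio_stack(lab, rec2)
  expect_true(all(rs2 == 0))
  expect_false(any(rec2$ratio_defined))
})

test_that("x1000 export convention round-trips to within half a milliratiounit", {
  expect_identical(export_ratio_image(0.5), 500L)
  expect_identical(export_ratio_image(0), 0L)
  expect_identical(export_ratio_image(70), 65535L)  # clipped
  r <- seq(0, 65.535, length.out = 20001)
  back <- import_ratio_image(export_ratio_image(r))
  expect_lte(max(abs(r - back)), 0.0005 + 1e-12)
})

test_that("results tables round-trip through CSV", {
  sc <- make_scene(3, shape = c(12, 48, 48), background = 0, noise = "none")
  rec <- measure_rois(sc$truth$label_map, sc$stack)
  rec$category <- c("meristem", "unlabelled", "meristem")
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_results_table(rec, path)
  lines <- readLines(path)
  expect_length(lines, 4L)  # header + 3 rows
  back <- read_results_table(path)
  expect_equal(back$emission_ratio, rec$emission_ratio, tolerance = 1e-6)
  expect_equal(back$category, rec$category)
  expect_equal(back$ratio_defined, rec$ratio_defined)

  empty <- measure_rois(array(0L, c(2, 2, 2)),
                        make_simple_stack(array(0L, c(2, 2, 2)),
                                          array(0L, c(2, 2, 2))))
  write_results_table(empty, path)
  expect_length(readLines(path), 1L)  # header only
})

test_that("display dilation grows labels without merging them", {
  d <- c(7, 7, 7)
  lab <- array(0L, d)
  lab[4, 4, 4] <- 1L
  out <- dilate_labels_for_display(lab, 1, 6)
  expect_equal(sum(out == 1L), 7L)  # voxel + 6-neighborhood
  expect_identical(dilate_labels_for_display(lab, 0), lab)

  two <- array(0L, c(5, 5, 9))
  two[3, 3, 3] <- 1L
  two[3, 3, 6] <- 2L
  g1 <- dilate_labels_for_display(two, 2, 6)
  g2 <- dilate_labels_for_display(two, 2, 6)
  expect_identical(g1, g2)
  expect_true(all(g1[two > 0] == two[two > 0]))
  expect_setequal(unique(g1[g1 > 0]), 1:2)
})
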