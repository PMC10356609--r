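test_that("connected components count simple geometry correctly", {
  m <- array(FALSE, c(10, 10, 10))
  m[2:4, 2:4, 2:4] <- TRUE
  m[6:8, 6:8, 6:8] <- TRUE
  lab <- label_components(m, 26)
  expect_equal(max(lab), 2L)
  expect_equal(as.integer(table(lab[lab > 0])), c(27L, 27L))

  expect_equal(max(label_components(array(FALSE, c(5, 5, 5)), 26)), 0L)
})

test_that("corner-touching voxels join under 26- but not 6-connectivity", {
  m <- array(FALSE, c(4, 4, 4))
  m[2, 2, 2] <- TRUE
  m[3, 3, 3] <- TRUE
  expect_equal(max(label_components(m, 26)), 1L)
  expect_equal(max(label_components(m, 6)), 2L)
})

test_that("min_voxels filtering drops small components and renumbers contiguously", {
  m <- array(FALSE, c(8, 8, 8))
  m[2, 2, 2] <- TRUE            # 1 voxel
  m[5:6, 5:6, 5:6] <- TRUE      # 8 voxels
  lab <- label_components(m, 26, min_voxels = 5)
  expect_equal(max(lab), 1L)
  expect_equal(sum(lab > 0), 8L)
})

test_that("components agree with the flood-fill oracle on random volumes", {
  set.seed(101)
  for (i in 1:150) {
    d <- sample(4:16, 3, replace = TRUE)
    m <- array(stats::runif(prod(d)) < stats::runif(1, 0.1, 0.6), d)
    for (conn in c(6L, 26L)) {
      expect_true(same_partition(label_components(m, conn), cc_oracle(m, conn)),
                  label = sprintf("case %d conn %d", i, conn))
    }
  }
})

test_that("watershed splits a touching pair along the neck without growing foreground", {
  bin <- dumbbell_mask()
  expect_equal(max(label_components(bin, 26)), 1L)
  split <- watershed_split(bin, 26)
  expect_true(all(bin[split]))                       # split subset of input
  expect_equal(max(label_components(split, 26)), 2L) # two objects now
  # an isolated sphere is untouched in component count
  iso <- sphere_mask(c(16, 16, 16), c(8, 8, 8), 5)
  expect_equal(max(label_components(watershed_split(iso, 26), 26)), 1L)
})

test_that("watershed never decreases the component count on random blobs", {
  set.seed(77)
  for (i in 1:20) {
    d <- c(12, 16, 16)
    m <- array(FALSE, d)
    for (k in 1:3) {
      ctr <- sapply(d, function(s) sample(3:(s - 2), 1))
      m <- m | sphere_mask(d, ctr, sample(2:4, 1))
    }
    split <- watershed_split(m, 26)
    expect_true(all(m[split]))
    expect_gte(max(label_components(split, 26)), max(label_components(m, 26)))
  }
})

test_that("lost objects are exactly the components erased by the split map", {
  bin <- array(FALSE, c(8, 8, 16))
  bin[3:5, 3:5, 3:5] <- TRUE       # component A
  bin[3:5, 3:5, 10:12] <- TRUE     # component B
  split <- bin
  split[, , 10:12] <- FALSE        # B fully erased, A intact
  split[3, 3, 3] <- FALSE          # A partially eroded but surviving
  lost <- find_lost_objects(bin, split, 26)
  expected <- array(FALSE, c(8, 8, 16))
  expected[3:5, 3:5, 10:12] <- TRUE
  expect_equal(lost, expected)
  expect_equal(sum(find_lost_objects(bin, bin, 26)), 0)
  expect_equal(sum(find_lost_objects(array(FALSE, c(4, 4, 4)),
                                     array(FALSE, c(4, 4, 4)), 26)), 0)
  expect_error(find_lost_objects(split, bin, 26), "subset")
})

test_that("constrained dilation restores the full foreground without merging labels", {
  bin <- dumbbell_mask()
  split <- watershed_split(bin, 26)
  lab <- label_components(split, 26)
  out <- constrained_dilate_relabel(lab, bin)
  expect_equal(sum(out > 0), sum(bin))            # no shrinkage
  expect_equal(length(unique(out[out > 0])), 2L)  # still two objects
  # already-complete labels are a fixed point
  comp <- label_components(bin, 26)
  expect_identical(constrained_dilate_relabel(comp, bin), comp)
  # deterministic under repetition (lowest-id tie rule)
  expect_identical(out, constrained_dilate_relabel(lab, bin))
  expect_error(constrained_dilate_relabel(comp, array(FALSE, dim(bin))), "foreground")
})

test_that("lost labels are appended with fresh contiguous ids", {
  lab <- array(0L, c(6, 6, 12))
  lab[2:3, 2:3, 2:3] <- 1L
  lab[2:3, 2:3, 5:6] <- 2L
  lost <- array(FALSE, c(6, 6, 12))
  lost[2:3, 2:3, 9] <- TRUE
  lost[5, 5, 11] <- TRUE
  out <- merge_lost_labels(lab, lost, 26)
  expect_setequal(unique(out[out > 0]), 1:4)
  expect_true(all(out[lab > 0] == lab[lab > 0]))     # prior ids unchanged
  expect_identical(out, merge_lost_labels(lab, lost, 26))
  expect_identical(merge_lost_labels(lab, array(FALSE, dim(lab)), 26), lab)
  bad <- lost
  bad[2, 2, 2] <- TRUE
  expect_error(merge_lost_labels(lab, bad, 26), "disjoint")
})
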