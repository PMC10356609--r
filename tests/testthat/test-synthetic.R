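test_that("rendered scenes honour the nucleus specification exactly", {
  sp <- scene_spec(shape = c(10, 20, 20),
                   nuclei = list(nucleus_spec(c(5, 10, 10), 3,
                                              dxdm_intensity = 100,
                                              true_ratio = 1.5)),
                   background_level = 0, noise = "none")
  sc <- generate_scene(sp)
  inside <- sc$truth$label_map == 1L
  expect_true(all(sc$stack$channels$DxDm[inside] == 100L))
  expect_true(all(sc$stack$channels$DxAm[inside] == 150L))
  expect_true(all(sc$stack$channels$DxDm[!inside] == 0L))
  expect_equal(sc$truth$table$voxel_count, sum(inside))
})

test_that("a twenty-nucleus scene yields exactly twenty ground-truth labels", {
  sc <- make_scene(20, noise = "none", background = 0)
  expect_equal(nrow(sc$truth$table), 20L)
  expect_setequal(unique(sc$truth$label_map[sc$truth$label_map > 0]), 1:20)
  # conservation: table voxel counts sum to nonzero label voxels
  expect_equal(sum(sc$truth$table$voxel_count), sum(sc$truth$label_map > 0))
})

test_that("identical spec and seed reproduce bit-identical scenes", {
  sp <- scene_spec(shape = c(12, 24, 24),
                   nuclei = random_nuclei(3, c(12, 24, 24), radius = 2.5,
                                          margin = 4, seed = 3),
                   noise = "gaussian", noise_sd = 20,
                   saturate_fraction = 0.02, seed = 42)
  a <- generate_scene(sp)
  b <- generate_scene(sp)
  expect_identical(a$stack$channels, b$stack$channels)
  expect_identical(a$truth, b$truth)
})

test_that("overlapping nuclei are split by scaled-center proximity, not input order", {
  shape <- c(9, 9, 21)
  n1 <- nucleus_spec(c(5, 5, 8), 4, 100, 1.0)
  n2 <- nucleus_spec(c(5, 5, 14), 4, 100, 2.0)
  a <- generate_scene(scene_spec(shape, list(n1, n2), background_level = 0))
  b <- generate_scene(scene_spec(shape, list(n2, n1), background_level = 0))
  # strictly closer voxels follow proximity regardless of order:
  # x=10 is closer to n1 (scaled d 0.5 vs 1), x=12 closer to n2
  expect_equal(a$truth$label_map[5, 5, 10], 1L)
  expect_equal(b$truth$label_map[5, 5, 10], 2L)
  expect_equal(a$truth$label_map[5, 5, 12], 2L)
  expect_equal(b$truth$label_map[5, 5, 12], 1L)
  # exact midpoint ties resolve to the lowest nucleus id, deterministically
  expect_equal(a$truth$label_map[5, 5, 11], 1L)
  expect_equal(b$truth$label_map[5, 5, 11], 1L)
})

test_that("gaussian noise matches the requested sd and saturation hits DxAm", {
  sp <- scene_spec(shape = c(30, 30, 30),
                   nuclei = list(nucleus_spec(c(15, 15, 15), 11, 5000, 1.2, 5000)),
                   background_level = 1000, noise = "gaussian", noise_sd = 50,
                   seed = 9)
  sc <- generate_scene(sp)
  bgvox <- sc$truth$label_map == 0L
  expect_gt(sum(bgvox), 1e4)
  s <- stats::sd(as.numeric(sc$stack$channels$DxDm[bgvox]))
  expect_lt(abs(s - 50) / 50, 0.05)

  sat <- generate_scene(scene_spec(shape = c(10, 20, 20),
                                   nuclei = list(nucleus_spec(c(5, 10, 10), 4, 200, 1.0)),
                                   background_level = 0, noise = "none",
                                   saturate_fraction = 0.25, bit_depth = 12L))
  nvox <- sum(sat$truth$label_map == 1L)
  expect_equal(sum(sat$stack$channels$DxAm == 4095L), round(0.25 * nvox))
})

test_that("scene validation rejects out-of-bounds nuclei by index", {
  expect_error(
    scene_spec(shape = c(8, 8, 8),
               nuclei = list(nucleus_spec(c(4, 4, 4), 2),
                             nucleus_spec(c(4, 4, 20), 2))),
    "nucleus 2")
})

test_that("titration simulator obeys the single-site isotherm", {
  # zero ligand -> r_min; c = kd -> midpoint; hand-evaluated interior point
  expect_equal(hill_response(0, 0.5, 1.0, 100), 0.5)
  expect_equal(hill_response(100, 0.5, 1.0, 100), 0.75)
  expect_equal(hill_response(300, 0.5, 1.0, 100), 0.875)

  tt <- generate_titration(0.5, 1.0, kd = 100, concentrations = c(0, 100, 300),
                           noise_sd = 0, replicates = 2)
  expect_equal(tt$ratio, c(0.5, 0.5, 0.75, 0.75, 0.875, 0.875))
  t1 <- generate_titration(0.5, 1.0, 100, concentrations = c(0, 50),
                           noise_sd = 0.05, replicates = 3, seed = 5)
  t2 <- generate_titration(0.5, 1.0, 100, concentrations = c(0, 50),
                           noise_sd = 0.05, replicates = 3, seed = 5)
  expect_identical(t1, t2)
  expect_error(generate_titration(0.5, 1, 100, concentrations = 1, noise_sd = -1),
               "noise_sd")
  expect_error(generate_titration(0.5, 1, kd = 0, concentrations = 1), "kd")
})
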