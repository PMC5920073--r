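test_that("Otsu matches exhaustive between-class-variance search", {
  set.seed(5)
  for (i in 1:30) {
    v <- c(rnorm(400, 30, 8), rnorm(120, 150, 25))
    v <- pmax(v, 0)
    expect_equal(otsu_level(v), brute_otsu(v))
  }
  # perfectly bimodal: mask is exactly the bright voxels
  arr <- array(10, c(5, 5, 4))
  bright <- sample(length(arr), 10)
  arr[bright] <- 200
  m <- threshold_stack(is_stack(arr), "otsu")
  expect_identical(which(m), sort(bright))
  expect_error(otsu_level(array(3, c(2, 2, 2))), "constant")
})

test_that("fixed thresholding and mask semantics behave as value > level", {
  s <- is_stack(array(c(1, 2, 3, 4), c(1, 2, 2)))
  expect_true(all(threshold_stack(s, "fixed", value = 0)))
  expect_equal(sum(threshold_stack(s, "fixed", value = 2)), 2)
  expect_error(threshold_stack(s, "fixed"), "value")
})

test_that("connected components match the flood-fill oracle for all connectivities", {
  expect_equal(max(label_components(array(TRUE, c(2, 2, 2)))), 1)
  expect_equal(sum(label_components(array(TRUE, c(2, 2, 2))) == 1), 8)
  diag2 <- array(FALSE, c(2, 2, 2))
  diag2[1, 1, 1] <- diag2[2, 2, 2] <- TRUE
  expect_equal(max(label_components(diag2, 26)), 1)
  expect_equal(max(label_components(diag2, 6)), 2)

  set.seed(6)
  for (i in 1:25) {
    mask <- array(runif(10 * 10 * 10) < 0.2, c(10, 10, 10))
    for (conn in c(6, 18, 26)) {
      got <- label_components(mask, conn, cal = unit_cal())
      want <- flood_fill_labels(mask, conn)
      expect_identical(as.integer(got), as.integer(want))
    }
  }
})

test_that("size filtering removes only sub-threshold components and renumbers densely", {
  # one 8-voxel block and one isolated voxel at confocal calibration
  arr <- array(0L, c(6, 6, 6))
  arr[1:2, 1:2, 1:2] <- 1L
  arr[5, 5, 5] <- 2L
  labs <- label_volume(arr, calibration(0.159, 0.159, 0.38))
  kept <- filter_small(labs, 0.05)       # 8 * 0.0096 = 0.077 survives
  expect_identical(positive_labels(kept), 1L)
  expect_equal(sum(kept == 1), 8)

  expect_identical(as.integer(filter_small(labs, 0)), as.integer(labs))
  expect_equal(max(filter_small(labs, 1e6)), 0)

  # foreground is only removed, never added, and renumbering is dense
  set.seed(7)
  mask <- array(runif(8^3) < 0.25, c(8, 8, 8))
  labs2 <- label_components(mask, 6, cal = unit_cal())
  f <- filter_small(labs2, 3)            # drop components under 3 voxels
  expect_true(all(which(f > 0) %in% which(labs2 > 0)))
  ids <- positive_labels(f)
  expect_identical(ids, seq_along(ids))
})

test_that("watershed splitting separates tangent spheres and is the identity otherwise", {
  dims <- c(11, 11, 21)
  single <- brute_sphere_mask(c(5.5, 5.5, 10.5), 4, c(1, 1, 1), dims)
  labs <- label_components(single, 26, cal = unit_cal())
  expect_identical(as.integer(split_touching(labs, min_sep_um = 3)),
                   as.integer(labs))

  two <- two_sphere_mask(r = 4, gap_vox = 8, dims = dims)
  merged <- label_components(two$mask, 26, cal = unit_cal())
  expect_equal(max(merged), 1)           # tangent spheres merge into one blob
  split <- split_touching(merged, min_sep_um = 4)
  expect_equal(max(split), 2)
  counts <- tabulate(as.integer(split)[as.integer(split) > 0])
  expect_lt(max(abs(counts - sum(two$m1)) / sum(two$m1)), 0.15)

  # marker separation beyond the component diameter forces identity
  expect_identical(as.integer(split_touching(merged, min_sep_um = 50)),
                   as.integer(merged))
})

test_that("droplet segmentation recovers a noise-free synthetic field exactly", {
  spec <- preset_spec("noise_free", field_shape = c(24, 128, 128),
                      droplets_per_cell = 18, seed = 9)
  field <- generate_field(spec)
  truth <- field$truth
  labs <- segment_droplets(field$fluorescence)
  expect_equal(length(positive_labels(labs)), nrow(truth$droplets))
  expect_equal(sum(labs > 0), sum(truth$droplet_labels > 0))
  # voxel-for-voxel: every segmented droplet matches one truth droplet
  got_fg <- which(as.integer(labs) > 0)
  want_fg <- which(as.integer(truth$droplet_labels) > 0)
  expect_identical(got_fg, want_fg)
  # per-droplet Jaccard against the truth partition
  tv <- as.integer(truth$droplet_labels)[want_fg]
  gv <- as.integer(labs)[want_fg]
  tab <- table(tv, gv)
  expect_true(all(apply(tab > 0, 1, sum) == 1))  # one-to-one correspondence

  # rerun is bit-identical (determinism)
  expect_identical(as.integer(segment_droplets(field$fluorescence)),
                   as.integer(labs))
})

test_that("an empty field above a fixed threshold yields zero droplets", {
  s <- is_stack(array(5, c(4, 8, 8)))
  labs <- segment_droplets(s, list(segment = list(threshold_method = "fixed",
                                                  threshold_value = 50)))
  expect_equal(length(positive_labels(labs)), 0)
})
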