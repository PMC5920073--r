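test_that("droplet records carry exact physical geometry and strict size flags", {
  # single voxel at the confocal calibration
  one <- array(0L, c(3, 3, 3))
  one[2, 2, 2] <- 1L
  rec <- droplet_records(label_volume(one, calibration(0.159, 0.159, 0.38)))
  expect_equal(rec$volume_um3, 9.607e-3, tolerance = 1e-4)
  expect_false(rec$touches_border)
  expect_equal(rec$centroid_x_um, 1.5 * 0.159)

  # boundary cases of both size classes, via a calibration that makes a
  # 100-voxel droplet hit the thresholds exactly
  blob <- array(0L, c(4, 5, 5))
  blob[1:4, 1:5, 1:5] <- 1L
  r_large <- droplet_records(label_volume(blob, calibration(1, 1, 0.654498)))
  expect_equal(r_large$volume_um3, 65.4498, tolerance = 1e-4)
  expect_equal(r_large$eq_diameter_um, 5, tolerance = 1e-4)
  expect_false(r_large$is_large)            # strictly greater than 5 um

  r_small <- droplet_records(label_volume(blob, calibration(1, 1, 1)))
  expect_equal(r_small$volume_um3, 100)
  expect_equal(r_small$eq_diameter_um, 5.7588, tolerance = 1e-4)
  expect_false(r_small$is_small_class)      # strictly less than 100 um^3
  expect_true(r_small$touches_border)
})

test_that("per-cell records compute VLD/VSC with the voxel volume cancelling", {
  cells <- array(0L, c(10, 40, 40))
  cells[1:10, 1:25, 1:40] <- 1L             # 10 000 voxels
  cells[1:10, 30:34, 1:40] <- 2L            # droplet-free cell
  cells <- lv(cells, kind = "cell")
  drops <- array(0L, c(10, 40, 40))
  drops[1:10, 1:15, 1:10] <- 1L             # 1 500 voxels inside cell 1
  drops <- lv(drops)
  rec <- droplet_records(drops, assign_droplets(drops, cells))
  cr <- cell_records(cells, rec, integrated = integer(0))
  expect_equal(cr$vld_vsc_ratio[cr$cell_id == 1], 0.15)
  expect_equal(cr$tnld[cr$cell_id == 1], 1)
  expect_equal(cr$vld_um3[cr$cell_id == 2], 0)
  expect_equal(cr$vld_vsc_ratio[cr$cell_id == 2], 0)
  expect_equal(cr$tnld[cr$cell_id == 2], 0)

  bad <- rec
  bad$cell_id <- 99L
  expect_error(cell_records(cells, bad), "nonexistent")
})

test_that("the field summary reproduces the printed-scale VTSF and ratio bounds", {
  # full-size scanning field: 800 x 800 px, 70 slices at 0.159/0.38 um
  big <- label_volume(array(0L, c(70, 800, 800)),
                      calibration(0.159, 0.159, 0.38))
  fs <- field_summary(big)
  expect_equal(fs$vtsf_um3, 4.304e5, tolerance = 1e-3)
  expect_equal(fs$vtld_vtsf_ratio, 0)

  small <- array(1L, c(2, 2, 2))
  expect_equal(field_summary(lv(small))$vtld_vtsf_ratio, 1)
})

test_that("droplet volume is conserved between per-cell and field accounting", {
  field <- generate_field(preset_spec("noise_free", seed = 31,
                                      field_shape = c(20, 96, 96),
                                      n_cells = 4, droplets_per_cell = 15))
  truth <- field$truth
  q <- quantify_field(field$fluorescence, truth$cell_labels)
  unassigned <- sum(q$droplets$volume_um3[is.na(q$droplets$cell_id)])
  expect_equal(sum(q$cells$vld_um3) + unassigned, q$field$vtld_um3)
  expect_true(all(q$cells$vld_vsc_ratio >= 0 & q$cells$vld_vsc_ratio <= 1))
})

test_that("volumes scale exactly linearly in the slice spacing", {
  set.seed(32)
  arr <- array(sample(0:3, 6 * 8 * 8, TRUE), c(6, 8, 8))
  l1 <- label_volume(arr, calibration(0.159, 0.159, 0.38))
  l2 <- label_volume(arr, calibration(0.159, 0.159, 0.76))
  r1 <- droplet_records(l1)
  r2 <- droplet_records(l2)
  expect_equal(r2$volume_um3, 2 * r1$volume_um3)
  expect_equal(field_summary(l2)$vtsf_um3, 2 * field_summary(l1)$vtsf_um3)
  expect_equal(field_summary(l2)$vtld_vtsf_ratio,
               field_summary(l1)$vtld_vtsf_ratio)
})

test_that("digitized-sphere diameters converge to the true diameter", {
  errs <- sapply(c(3, 5, 9, 15), function(r) {
    dims <- rep(2 * r + 5, 3)
    m <- brute_sphere_mask(rep(r + 2.5, 3), r, c(1, 1, 1), dims)
    rec <- droplet_records(label_components(m, 26, cal = unit_cal()))
    abs(rec$eq_diameter_um - 2 * r) / (2 * r)
  })
  expect_lt(errs[2], 0.05)                 # r = 5: within 5% of 4/3 pi r^3
  expect_lt(errs[4], errs[1])              # error shrinks with radius
})

test_that("cell spacing matches the 1D slab oracle and honours the cutoff", {
  slabs <- array(0L, c(1, 3, 20))
  slabs[1, , 1:5] <- 1L
  slabs[1, , 11:20] <- 2L                  # 5 empty voxels between surfaces
  cs <- cell_spacing(lv(slabs, kind = "cell"), max_gap_um = 15)
  expect_equal(cs$pairs$min_dist_um, 6)
  expect_equal(cs$pairs$spacing_um, 5)
  expect_equal(cs$mean_spacing_um, 5)

  # an isolated third cell beyond the cutoff contributes no pairs
  iso <- array(0L, c(1, 3, 60))
  iso[1, , 1:5] <- 1L
  iso[1, , 11:15] <- 2L
  iso[1, , 55:60] <- 3L
  cs2 <- cell_spacing(lv(iso, kind = "cell"), max_gap_um = 15)
  expect_equal(nrow(cs2$pairs), 1)
  expect_identical(sort(unique(c(cs2$pairs$cell_a, cs2$pairs$cell_b))),
                   c(1L, 2L))

  lone <- array(0L, c(1, 3, 10))
  lone[1, , 3:5] <- 1L
  expect_true(is.na(cell_spacing(lv(lone, kind = "cell"))$mean_spacing_um))
})

test_that("the tessellation round-trips its wall width through cell spacing", {
  spec <- preset_spec("noise_free", seed = 33, wall_um = 4,
                      droplets_per_cell = 0)
  set.seed(33)
  cells <- generate_tessellation(spec)
  cs <- cell_spacing(cells, max_gap_um = 15)
  # corner-adjacent cells in a near-square tessellation meet near
  # sqrt(2) * wall; restrict the wall-width check to face pairs
  face <- cs$pairs$spacing_um[cs$pairs$spacing_um <= 1.3 * 4]
  expect_gte(length(face), 8)
  expect_lt(abs(mean(face) - 4) / 4, 0.2)
})

test_that("size distributions bin volumes and report class percentages", {
  rec <- data.frame(droplet_id = 1:3, cell_id = 1L,
                    volume_um3 = c(1, 2, 150),
                    is_large = c(FALSE, FALSE, TRUE),
                    is_small_class = c(TRUE, TRUE, FALSE))
  sd1 <- size_distribution(rec, bin_edges_um3 = 100, line_id = "HO1")
  expect_equal(unname(sd1$counts), c(2, 1))
  expect_equal(sd1$pct_small_class, 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(sd1$pct_large, 100 / 3, tolerance = 1e-9)
  expect_equal(nrow(sd1$long), 3)
  expect_equal(unique(sd1$long$line_id), "HO1")

  all_small <- rec[1:2, ]
  expect_equal(size_distribution(all_small, 100)$pct_small_class, 100)
  empty <- rec[0, ]
  sd0 <- size_distribution(empty, 100)
  expect_equal(unname(sd0$counts), c(0, 0))
  expect_true(is.na(sd0$pct_large))
  expect_error(size_distribution(rec, c(5, 5)), "increasing")
})
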