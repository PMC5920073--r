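test_that("field generation is deterministic and seed-sensitive", {
  spec <- preset_spec("ho_like", seed = 41, field_shape = c(12, 48, 48),
                      n_cells = 2, droplets_per_cell = 6,
                      diam_lognorm = c(meanlog = log(2), sdlog = 0.25),
                      diam_range_um = c(1.2, 3))
  a <- generate_field(spec)
  b <- generate_field(spec)
  expect_identical(as.numeric(a$fluorescence), as.numeric(b$fluorescence))
  expect_identical(as.numeric(a$brightfield), as.numeric(b$brightfield))
  expect_identical(as.integer(a$truth$droplet_labels),
                   as.integer(b$truth$droplet_labels))
  expect_identical(a$truth$droplets, b$truth$droplets)

  spec2 <- preset_spec("ho_like", seed = 42, field_shape = c(12, 48, 48),
                       n_cells = 2, droplets_per_cell = 6,
                       diam_lognorm = c(meanlog = log(2), sdlog = 0.25),
                       diam_range_um = c(1.2, 3))
  c2 <- generate_field(spec2)
  expect_false(identical(a$truth$droplets$center_x_um,
                         c2$truth$droplets$center_x_um))
})

test_that("tessellation honours cell count, wall width and the 1D construction", {
  one <- synthetic_spec(field_shape = c(6, 10, 10), n_cells = 1, wall_um = 0,
                        cal = unit_cal(), droplets_per_cell = 0,
                        diam_range_um = c(0.5, 2))
  set.seed(1)
  t1 <- generate_tessellation(one)
  expect_true(all(t1 == 1))              # single cell fills the field

  nine <- preset_spec("noise_free", seed = 44, droplets_per_cell = 0)
  set.seed(44)
  t9 <- generate_tessellation(nine)
  expect_identical(positive_labels(t9), 1:9)

  # 1D oracle: two cells on a line with a 5 um wall at unit pitch leave
  # ~5 background voxels between facing surfaces (plus the border margin)
  line <- synthetic_spec(field_shape = c(1, 1, 100), n_cells = 2, wall_um = 5,
                         cal = unit_cal(), droplets_per_cell = 0,
                         diam_range_um = c(0.5, 0.9))
  set.seed(45)
  tl <- generate_tessellation(line)
  v <- as.integer(tl)
  runs <- rle(v)
  inner_gap <- runs$lengths[runs$values == 0]
  inner_gap <- inner_gap[-c(1, length(inner_gap))]  # drop border margins
  expect_length(inner_gap, 1)
  expect_true(abs(inner_gap - 5) <= 1)

  # identical RNG state reproduces the same labels
  set.seed(45)
  expect_identical(as.integer(generate_tessellation(line)), as.integer(tl))

  tiny <- synthetic_spec(field_shape = c(4, 10, 10), n_cells = 4, wall_um = 9,
                         cal = unit_cal(), droplets_per_cell = 0,
                         diam_range_um = c(0.5, 0.9))
  set.seed(46)
  expect_error(generate_tessellation(tiny), "vanished")
})

test_that("placed droplets sit wholly inside cells, pairwise separated", {
  spec <- preset_spec("noise_free", seed = 47, field_shape = c(20, 96, 96),
                      n_cells = 4, droplets_per_cell = 12)
  field <- generate_field(spec)
  truth <- field$truth
  dl <- as.integer(truth$droplet_labels)
  cl <- as.integer(truth$cell_labels)
  # containment: every droplet voxel carries its cell's label
  for (i in seq_len(nrow(truth$droplets))) {
    vox <- dl == truth$droplets$droplet_id[i]
    expect_true(all(cl[vox] == truth$droplets$cell_id[i]))
  }
  # pairwise separation by at least min_gap_um of clear space
  ctr <- as.matrix(truth$droplets[, c("center_z_um", "center_y_um",
                                      "center_x_um")])
  r <- truth$droplets$diameter_um / 2
  dd <- as.matrix(dist(ctr))
  lim <- outer(r, r, `+`) + spec$min_gap_um
  diag(dd) <- Inf
  expect_true(all(dd >= lim - 1e-9))
  # stored fraction equals the fraction recomputed from the labels
  expect_identical(truth$true_field_fraction, mean(dl > 0))
  # truth voxel counts match the label volume exactly
  expect_equal(truth$droplets$voxel_count,
               unname(tabulate(dl[dl > 0])[truth$droplets$droplet_id]))
})

test_that("zero droplets per cell yields an empty truth", {
  spec <- preset_spec("noise_free", seed = 48, field_shape = c(10, 40, 40),
                      n_cells = 2, droplets_per_cell = 0,
                      diam_range_um = c(1.5, 4))
  field <- generate_field(spec)
  expect_equal(nrow(field$truth$droplets), 0)
  expect_equal(field$truth$true_field_fraction, 0)
})

test_that("sphere voxelization matches brute-force enumeration and its volume", {
  set.seed(49)
  for (i in 1:10) {
    dims <- c(14, 16, 16)
    sp <- c(runif(1, 0.4, 1), runif(1, 0.3, 0.8), runif(1, 0.3, 0.8))
    r <- runif(1, 1.2, 2.8)
    ctr <- c(runif(1, r + 0.5, dims[1] * sp[1] - r - 0.5),
             runif(1, r + 0.5, dims[2] * sp[2] - r - 0.5),
             runif(1, r + 0.5, dims[3] * sp[3] - r - 0.5))
    got <- sort(ld3d:::voxelize_sphere(ctr, r, sp, dims))
    want <- which(brute_sphere_mask(ctr, r, sp, dims))
    expect_identical(as.integer(got), want)
  }
  # discretized volume approaches (4/3) pi r^3 for a well-resolved sphere
  dims <- c(24, 24, 24)
  vox <- ld3d:::voxelize_sphere(c(12.5, 12.5, 12.5), 5, c(1, 1, 1), dims)
  expect_lt(abs(length(vox) - 4 / 3 * pi * 125) / (4 / 3 * pi * 125), 0.05)
})

test_that("rendering reduces to the exact two-level image without PSF or noise", {
  spec <- preset_spec("noise_free", seed = 50, field_shape = c(10, 40, 40),
                      n_cells = 2, droplets_per_cell = 5,
                      diam_lognorm = c(meanlog = log(1.8), sdlog = 0.2),
                      diam_range_um = c(1.2, 2.2))
  field <- generate_field(spec)
  mask <- as.integer(field$truth$droplet_labels) > 0
  v <- as.numeric(field$fluorescence)
  expect_true(all(v[mask] == spec$droplet_intensity))
  expect_true(all(v[!mask] == spec$background_intensity))
})

test_that("the mean of many noisy renders converges to the noise-free render", {
  spec <- preset_spec("ho_like", seed = 51, field_shape = c(6, 20, 20),
                      n_cells = 1, wall_um = 1, droplets_per_cell = 3,
                      diam_lognorm = c(meanlog = log(1.8), sdlog = 0.2),
                      diam_range_um = c(1.2, 2.5))
  set.seed(51)
  cells <- generate_tessellation(spec)
  truth <- place_droplets(cells, spec)
  clean_spec <- spec
  clean_spec$noise <- list(poisson_on = FALSE, gaussian_sd = 0)
  clean <- as.numeric(render_channels(truth, clean_spec)$fluorescence)
  acc <- 0
  n_rep <- 120
  for (i in seq_len(n_rep))
    acc <- acc + as.numeric(render_channels(truth, spec)$fluorescence)
  avg <- acc / n_rep
  # Monte-Carlo error ~ sd/sqrt(n); droplet voxels have sd ~ sqrt(180)
  expect_lt(max(abs(avg - clean)), 6 * sqrt(max(clean)) / sqrt(n_rep) + 0.5)
  expect_lt(abs(mean(avg) - mean(clean)), 0.2)
})

test_that("high-oil presets carry more lipid than low-oil presets at equal seed", {
  ho <- generate_field(preset_spec("ho_like", seed = 52,
                                   field_shape = c(16, 96, 96), n_cells = 4,
                                   droplets_per_cell = 15,
                                   diam_range_um = c(1.5, 6)))
  lo <- generate_field(preset_spec("lo_like", seed = 52,
                                   field_shape = c(16, 96, 96), n_cells = 4,
                                   droplets_per_cell = 7,
                                   diam_range_um = c(1.5, 6)))
  expect_gt(ho$truth$true_field_fraction, lo$truth$true_field_fraction)
})
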