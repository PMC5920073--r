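test_that("watershed recovers synthetic cells from the bright-field channel", {
  field <- generate_field(preset_spec("ho_like", seed = 21,
                                      field_shape = c(32, 192, 192),
                                      n_cells = 4, droplets_per_cell = 25))
  truth <- field$truth$cell_labels
  got <- segment_cells(field$brightfield)
  expect_equal(length(positive_labels(got)), 4)
  tv <- as.integer(truth)
  sv <- as.integer(got)
  for (id in positive_labels(truth)) {
    tidx <- tv == id
    hit <- sv[tidx]
    best <- as.integer(names(which.max(table(hit[hit > 0]))))
    jac <- sum(tidx & sv == best) / sum(tidx | sv == best)
    expect_gte(jac, 0.8)
  }
})

test_that("supplied seeds control the region count", {
  u <- is_stack(array(100, c(6, 12, 12)), channel = "brightfield")
  seeds <- rbind(c(3, 3, 3), c(3, 9, 9), c(4, 3, 9))
  got <- segment_cells(u, list(cells = list(wall_cutoff = -1)), seeds = seeds)
  expect_equal(length(positive_labels(got)), 3)

  # one seed, no wall cutoff: a single label floods the whole field
  got1 <- segment_cells(u, list(cells = list(wall_cutoff = -1)),
                        seeds = rbind(c(3, 6, 6)))
  expect_true(all(got1 == 1))
})

test_that("integrated cells are exactly those avoiding every field face", {
  full <- lv(array(1L, c(9, 9, 9)), kind = "cell")
  expect_length(integrated_cells(full), 0)

  centered <- array(0L, c(9, 9, 9))
  centered[4:6, 4:6, 4:6] <- 1L
  expect_identical(integrated_cells(lv(centered, kind = "cell")), 1L)

  # 3x3 in-plane grid spanning all of z: no cell avoids the z faces;
  # adding a z margin leaves only the in-plane center cell
  grid <- array(0L, c(9, 11, 11))
  id <- 0L
  for (gx in 0:2) for (gy in 0:2) {
    id <- id + 1L
    grid[, gy * 4 + 1:3, gx * 4 + 1:3] <- id
  }
  expect_length(integrated_cells(lv(grid, kind = "cell")), 0)
  margin <- grid
  margin[c(1, 9), , ] <- 0L
  expect_identical(integrated_cells(lv(margin, kind = "cell")), 5L)
})

test_that("cropping a field never adds an integrated cell", {
  set.seed(22)
  field <- generate_field(preset_spec("noise_free", seed = 22,
                                      field_shape = c(20, 96, 96),
                                      n_cells = 4, droplets_per_cell = 0))
  cells <- field$truth$cell_labels
  before <- integrated_cells(cells)
  d <- dim(cells)
  cropped <- label_volume(unclass(cells)[, , 1:(d[3] %/% 2)],
                          calibration_of(cells), "cell")
  after <- integrated_cells(cropped)
  expect_true(all(after %in% before))
})

test_that("droplets are assigned by majority overlap with stated tie-breaks", {
  cells <- array(0L, c(1, 1, 10))
  cells[1, 1, 1:5] <- 1L
  cells[1, 1, 6:10] <- 2L
  cells <- lv(cells, kind = "cell")

  wholly <- lv(array(c(0L, 3L, 3L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
                     c(1, 1, 10)))
  a <- assign_droplets(wholly, cells)
  expect_equal(a$cell_id[a$droplet_id == 3], 1)

  # 60/40 split across cells 1 and 2 -> majority cell 1
  maj <- lv(array(c(0L, 0L, 1L, 1L, 1L, 1L, 1L, 0L, 0L, 0L), c(1, 1, 10)))
  expect_equal(assign_droplets(maj, cells)$cell_id, 1)

  # 50/50 split -> smallest cell id
  tie <- lv(array(c(0L, 0L, 0L, 1L, 1L, 1L, 1L, 0L, 0L, 0L), c(1, 1, 10)))
  expect_equal(assign_droplets(tie, cells)$cell_id, 1)

  # strict majority on background -> unassigned
  bgcells <- array(0L, c(1, 1, 10))
  bgcells[1, 1, 10] <- 1L
  bg <- assign_droplets(maj, lv(bgcells, kind = "cell"))
  expect_true(is.na(bg$cell_id))

  # shape mismatch is an error, not a silent resample
  expect_error(assign_droplets(wholly, lv(array(0L, c(1, 1, 9)), kind = "cell")),
               "shape")
})

test_that("truth cell labels reproduce the true assignment exactly", {
  field <- generate_field(preset_spec("noise_free", seed = 23,
                                      field_shape = c(20, 96, 96),
                                      n_cells = 4, droplets_per_cell = 12))
  truth <- field$truth
  a <- assign_droplets(truth$droplet_labels, truth$cell_labels)
  expect_identical(a$droplet_id, truth$droplets$droplet_id)
  expect_identical(a$cell_id, as.integer(truth$droplets$cell_id))
  expect_true(all(a$frac_in_cell == 1))
})
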