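#' Specification of a synthetic confocal field
#'
#' Describes one ground-truthed synthetic field: a wall-separated cell
#' tessellation filled with spherical lipid droplets, rendered into a
#' Nile-Red-like fluorescence channel and a bright-field boundary channel.
#' The defaults emulate a cotyledon storage-tissue field: ~9 complete cells
#' in view, intercellular wall gaps of a few micrometers, tens of droplets
#' per cell with a right-skewed (lognormal) diameter distribution that
#' includes droplets above the 5 um "unusually large" threshold, PSF blur,
#' shot (Poisson) noise and Gaussian read noise.
#'
#' @param field_shape voxel counts `(nz, ny, nx)`.
#' @param cal voxel [calibration()]. The synthetic default (0.5 x 0.5 x
#'   0.65 um) trades in-plane resolution for field extent so that a full
#'   128 x 128 x 26 um cell layer fits in a quarter-million-voxel stack.
#' @param n_cells target number of cells.
#' @param wall_um intercellular gap width in micrometers (>= 0).
#' @param droplets_per_cell mean droplet count per cell (Poisson).
#' @param diam_lognorm `(meanlog, sdlog)` of the droplet diameter (um).
#' @param diam_range_um `(min, max)` truncation of the diameter draw.
#' @param droplet_intensity,background_intensity mean fluorescence signal
#'   levels (droplet must exceed background).
#' @param bf_cell_intensity,bf_wall_intensity bright-field levels for cell
#'   interiors and the intercellular matrix.
#' @param psf_sigma_um Gaussian PSF sigma `(z, y, x)` in micrometers;
#'   converted per-axis to voxels so calibration anisotropy does not
#'   distort the blur.
#' @param noise list with `poisson_on` (flag) and `gaussian_sd` (read-noise
#'   SD in intensity units).
#' @param min_gap_um minimum gap between droplet surfaces. The default
#'   (1 um, two in-plane voxels) guarantees that distinct droplets are
#'   never 26-adjacent after voxelization, so truth labels are unambiguous.
#' @param allow_contact if `TRUE`, droplets may touch or slightly overlap
#'   (surface gap down to -5% of the summed radii), to exercise watershed
#'   splitting downstream.
#' @param max_attempts rejection-sampling budget per droplet.
#' @param seed random seed driving all randomness in [generate_field()].
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(field_shape = c(40, 256, 256),
                           cal = calibration(0.5, 0.5, 0.65),
                           n_cells = 9,
                           wall_um = 4,
                           droplets_per_cell = 70,
                           diam_lognorm = c(meanlog = log(3.6), sdlog = 0.32),
                           diam_range_um = c(1.5, 8),
                           droplet_intensity = 180,
                           background_intensity = 20,
                           bf_cell_intensity = 160,
                           bf_wall_intensity = 30,
                           psf_sigma_um = c(0.35, 0.15, 0.15),
                           noise = list(poisson_on = TRUE, gaussian_sd = 3),
                           min_gap_um = 1,
                           allow_contact = FALSE,
                           max_attempts = 300,
                           seed = 1) {
  cal <- as_calibration(cal)
  spec <- list(field_shape = as.integer(field_shape), cal = cal,
               n_cells = as.integer(n_cells), wall_um = wall_um,
               droplets_per_cell = droplets_per_cell,
               diam_lognorm = diam_lognorm,
               diam_range_um = diam_range_um,
               droplet_intensity = droplet_intensity,
               background_intensity = background_intensity,
               bf_cell_intensity = bf_cell_intensity,
               bf_wall_intensity = bf_wall_intensity,
               psf_sigma_um = psf_sigma_um, noise = noise,
               min_gap_um = min_gap_um, allow_contact = allow_contact,
               max_attempts = max_attempts, seed = seed)
  extent <- spec$field_shape * cal_spacing_zyx(cal)
  if (length(spec$field_shape) != 3 || any(spec$field_shape < 1))
    stop("field_shape must be three positive voxel counts")
  if (wall_um < 0) stop("wall_um must be >= 0")
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (diam_range_um[1] <= 0 || diam_range_um[2] <= diam_range_um[1])
    stop("diam_range_um must be increasing and positive")
  if (diam_range_um[2] > min(extent))
    stop("diam_range_um exceeds the field extent")
  if (background_intensity < 0 || droplet_intensity <= background_intensity)
    stop("need droplet_intensity > background_intensity >= 0")
  class(spec) <- "synthetic_spec"
  spec
}

#' Preset synthetic fields
#'
#' Phenotype presets for the high-oil / low-oil contrast and a noise-free
#' variant for exact-recovery tests. `ho_like` fields have more droplets
#' per cell and narrower intercellular gaps (~4 um) than `lo_like` fields
#' (~6 um gaps, fewer droplets), mirroring the orderings observed between
#' high- and low-oil breeding lines; droplet counts per cell sit inside the
#' observed 29-124 range.
#'
#' @param name `"ho_like"`, `"lo_like"` or `"noise_free"`.
#' @param ... overrides passed to [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
preset_spec <- function(name = c("ho_like", "lo_like", "noise_free"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    ho_like = list(droplets_per_cell = 70, wall_um = 4,
                   diam_lognorm = c(meanlog = log(3.6), sdlog = 0.32)),
    lo_like = list(droplets_per_cell = 30, wall_um = 6,
                   diam_lognorm = c(meanlog = log(3.4), sdlog = 0.32)),
    noise_free = list(droplets_per_cell = 50,
                      psf_sigma_um = c(0, 0, 0),
                      noise = list(poisson_on = FALSE, gaussian_sd = 0)))
  do.call(synthetic_spec, modifyList(args, list(...)))
}

#' Jittered-seed Voronoi cell tessellation
#'
#' Partitions the field into `n_cells` convex regions around jittered grid
#' seeds, then carves the intercellular matrix: a voxel is background when
#' the difference between its distances to the two nearest seeds is below
#' `wall_um` (each region recedes `wall_um / 2` from the bisector, so
#' facing cell surfaces end up ~`wall_um` apart), or when it lies within
#' `wall_um / 2` of a field face (so every cell is fully in-field).
#' Distances are physical, so anisotropic voxels do not skew the walls.
#' Consumes the current RNG stream; seed it (or use [generate_field()])
#' for reproducibility.
#'
#' @param spec a [synthetic_spec()].
#' @return A cell [label_volume()] with labels `1..n_cells`.
#' @export
generate_tessellation <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dims <- spec$field_shape
  sp <- cal_spacing_zyx(spec$cal)
  extent <- dims * sp
  seeds <- tessellation_seeds(spec$n_cells, extent)
  zc <- (seq_len(dims[1]) - 0.5) * sp[1]
  yc <- (seq_len(dims[2]) - 0.5) * sp[2]
  xc <- (seq_len(dims[3]) - 0.5) * sp[3]
  best1 <- array(Inf, dims)
  best2 <- array(Inf, dims)
  lab <- array(0L, dims)
  for (s in seq_len(nrow(seeds))) {
    d2 <- outer(outer((zc - seeds[s, 1])^2, (yc - seeds[s, 2])^2, `+`),
                (xc - seeds[s, 3])^2, `+`)
    closer <- d2 < best1
    best2[closer] <- best1[closer]
    best1[closer] <- d2[closer]
    lab[closer] <- s
    mid <- !closer & d2 < best2
    best2[mid] <- d2[mid]
  }
  if (spec$wall_um > 0) {
    wall <- (sqrt(best2) - sqrt(best1)) < spec$wall_um
    # margin to the field faces; degenerate single-voxel axes are exempt
    bz <- if (dims[1] > 1) pmin(zc, extent[1] - zc) else rep(Inf, dims[1])
    by <- if (dims[2] > 1) pmin(yc, extent[2] - yc) else rep(Inf, dims[2])
    bx <- if (dims[3] > 1) pmin(xc, extent[3] - xc) else rep(Inf, dims[3])
    border <- outer(outer(bz, by, pmin), bx, pmin)
    lab[wall | border < spec$wall_um / 2] <- 0L
  }
  present <- tabulate(lab[lab > 0], nbins = spec$n_cells)
  if (any(present == 0))
    stop("wall_um too large: at least one cell region vanished")
  label_volume(lab, spec$cal, kind = "cell")
}

# near-square in-plane grid of jittered seed points (z, y, x in um)
tessellation_seeds <- function(n, extent) {
  gx <- ceiling(sqrt(n))
  gy <- ceiling(n / gx)
  ij <- expand.grid(ix = seq_len(gx), iy = seq_len(gy))[seq_len(n), ]
  px <- extent[3] / gx
  py <- extent[2] / gy
  cbind(z = extent[1] / 2 + runif(n, -0.1, 0.1) * extent[1],
        y = (ij$iy - 0.5) * py + runif(n, -0.2, 0.2) * py,
        x = (ij$ix - 0.5) * px + runif(n, -0.2, 0.2) * px)
}

#' Place spherical droplets inside cells
#'
#' Rejection-samples droplet centers inside cells and voxelizes each
#' accepted sphere by the center-in-sphere rule (a voxel belongs to the
#' droplet iff its center lies within the radius; distances in physical
#' units). Droplets are wholly contained in their cell and, by default,
#' pairwise separated by at least `min_gap_um` of clear space. Diameters
#' are lognormal, truncated to `diam_range_um`; per-cell counts are
#' Poisson with mean `droplets_per_cell`. A placement shortfall (attempt
#' budget exhausted) is reported as a warning, never silently dropped.
#' Consumes the current RNG stream.
#'
#' @param cells tessellation from [generate_tessellation()].
#' @param spec the [synthetic_spec()].
#' @return A list (the ground truth): `cell_labels`, `droplet_labels`,
#'   `droplets` (truth records: `droplet_id`, `cell_id`, `diameter_um`,
#'   center coordinates, `voxel_count`, `volume_um3`),
#'   `true_field_fraction` (droplet voxels / total voxels).
#' @export
place_droplets <- function(cells, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dims <- dim(cells)
  sp <- cal_spacing_zyx(spec$cal)
  vv <- voxel_volume(spec$cal)
  cellv <- as.integer(cells)
  ids <- positive_labels(cells)
  vox_by_cell <- split(which(cellv > 0), cellv[cellv > 0])
  droplet_lab <- integer(prod(dims))
  centers <- matrix(numeric(0), 0, 3)
  radii <- numeric(0)
  rec <- list()
  next_id <- 0L
  shortfall <- 0L
  for (id in ids) {
    n_want <- rpois(1, spec$droplets_per_cell)
    cell_vox <- vox_by_cell[[as.character(id)]]
    placed <- 0L
    while (placed < n_want) {
      ok <- FALSE
      for (att in seq_len(spec$max_attempts)) {
        diam <- draw_diameter(spec)
        r <- diam / 2
        ctr_vox <- cell_vox[sample.int(length(cell_vox), 1)]
        ctr <- (arrayInd(ctr_vox, dims) - 0.5 + runif(3, -0.5, 0.5)) * sp
        ctr <- as.numeric(ctr)
        # cheap overlap pre-check on center distances
        if (length(radii)) {
          dd <- sqrt(colSums((t(centers) - ctr)^2))
          lim <- if (spec$allow_contact) 0.95 * (radii + r)
                 else radii + r + spec$min_gap_um
          if (any(dd < lim)) next
        }
        vox <- voxelize_sphere(ctr, r, sp, dims)
        if (is.null(vox) || length(vox) == 0) next
        if (!all(cellv[vox] == id)) next          # wholly inside the cell
        if (spec$allow_contact && any(droplet_lab[vox] > 0)) {
          vox <- vox[droplet_lab[vox] == 0]
          if (length(vox) == 0) next
        }
        next_id <- next_id + 1L
        droplet_lab[vox] <- next_id
        centers <- rbind(centers, ctr)
        radii <- c(radii, r)
        rec[[next_id]] <- data.frame(
          droplet_id = next_id, cell_id = id, diameter_um = diam,
          center_z_um = ctr[1], center_y_um = ctr[2], center_x_um = ctr[3],
          voxel_count = length(vox), volume_um3 = length(vox) * vv)
        placed <- placed + 1L
        ok <- TRUE
        break
      }
      if (!ok) {
        shortfall <- shortfall + (n_want - placed)
        break
      }
    }
  }
  if (shortfall > 0)
    warning(sprintf("placement budget exhausted: %d droplet(s) not placed",
                    shortfall))
  droplets <- if (length(rec)) do.call(rbind, rec) else
    data.frame(droplet_id = integer(0), cell_id = integer(0),
               diameter_um = numeric(0), center_z_um = numeric(0),
               center_y_um = numeric(0), center_x_um = numeric(0),
               voxel_count = integer(0), volume_um3 = numeric(0))
  dl <- label_volume(array(droplet_lab, dims), spec$cal, kind = "droplet")
  structure(list(cell_labels = cells, droplet_labels = dl,
                 droplets = droplets,
                 true_field_fraction = sum(droplet_lab > 0) / prod(dims)),
            class = "ld3d_truth")
}

draw_diameter <- function(spec) {
  for (i in 1:100) {
    d <- rlnorm(1, spec$diam_lognorm[[1]], spec$diam_lognorm[[2]])
    if (d >= spec$diam_range_um[1] && d <= spec$diam_range_um[2]) return(d)
  }
  min(max(d, spec$diam_range_um[1]), spec$diam_range_um[2])
}

# linear voxel indices of a sphere (center-in-sphere rule); NULL when the
# sphere pokes out of the field
voxelize_sphere <- function(center, r, sp, dims) {
  rng <- lapply(1:3, function(a) {
    lo <- ceiling((center[a] - r) / sp[a] + 0.5)
    hi <- floor((center[a] + r) / sp[a] + 0.5)
    if (lo < 1 || hi > dims[a]) return(NULL)
    seq(lo, hi)
  })
  if (any(vapply(rng, is.null, TRUE))) return(NULL)
  g <- expand.grid(z = rng[[1]], y = rng[[2]], x = rng[[3]])
  d2 <- ((g$z - 0.5) * sp[1] - center[1])^2 +
        ((g$y - 0.5) * sp[2] - center[2])^2 +
        ((g$x - 0.5) * sp[3] - center[3])^2
  g <- g[d2 <= r^2, , drop = FALSE]
  g$z + dims[1] * ((g$y - 1) + dims[2] * (g$x - 1))
}

#' Render fluorescence and bright-field channels from ground truth
#'
#' The fluorescence channel is a two-level image (droplet vs background
#' intensity) blurred by the anisotropic Gaussian PSF, optionally Poisson
#' resampled (shot noise) and perturbed by additive Gaussian read noise,
#' clipped at zero and rounded to integer counts. The bright-field channel
#' renders cell interiors bright and the intercellular matrix dark, with
#' the same blur and noise treatment. Consumes the current RNG stream.
#'
#' @param truth output of [place_droplets()].
#' @param spec the [synthetic_spec()].
#' @return List with `fluorescence` and `brightfield` [intensity_stack()]s.
#' @export
render_channels <- function(truth, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dims <- dim(truth$droplet_labels)
  fluor <- render_one(unclass(truth$droplet_labels) > 0,
                      spec$droplet_intensity, spec$background_intensity,
                      spec, dims)
  bf <- render_one(unclass(truth$cell_labels) > 0,
                   spec$bf_cell_intensity, spec$bf_wall_intensity,
                   spec, dims)
  list(fluorescence = intensity_stack(fluor, spec$cal, "fluorescence"),
       brightfield = intensity_stack(bf, spec$cal, "brightfield"))
}

render_one <- function(mask, hi, lo, spec, dims) {
  img <- array(lo + (hi - lo) * as.numeric(mask), dims)
  sig_vox <- spec$psf_sigma_um / cal_spacing_zyx(spec$cal)
  if (any(sig_vox > 0))
    img <- array(gauss3d_cpp(as.numeric(img), dims, sig_vox), dims)
  if (isTRUE(spec$noise$poisson_on))
    img <- array(rpois(length(img), pmax(img, 0)), dims)
  if (spec$noise$gaussian_sd > 0)
    img <- img + rnorm(length(img), 0, spec$noise$gaussian_sd)
  array(pmin(round(pmax(img, 0)), 65535), dims)
}

#' Generate a complete synthetic field
#'
#' Seeds the RNG from `spec$seed`, then composes
#' [generate_tessellation()], [place_droplets()] and [render_channels()].
#' Identical spec and seed give byte-identical outputs.
#'
#' @param spec a [synthetic_spec()] or preset name for [preset_spec()].
#' @return List with `fluorescence`, `brightfield` (stacks) and `truth`
#'   (see [place_droplets()]).
#' @export
generate_field <- function(spec) {
  if (is.character(spec)) spec <- preset_spec(spec)
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  cells <- generate_tessellation(spec)
  truth <- place_droplets(cells, spec)
  channels <- render_channels(truth, spec)
  list(fluorescence = channels$fluorescence,
       brightfield = channels$brightfield, truth = truth)
}
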