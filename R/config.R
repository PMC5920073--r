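#' Default pipeline configuration
#'
#' Nested list of every tunable pipeline parameter, with the package
#' defaults. Any subset can be overridden via [merge_config()] or a JSON
#' config file; every run records the resolved configuration beside its
#' outputs so results are reproducible.
#'
#' Blocks and defaults:
#' * `preprocess`: `denoise_method` ("median"), `denoise_radius`
#'   (`c(0, 0, 0)` voxels, i.e. off), `illumination_sigma_um` (`NULL`, off).
#' * `segment`: `threshold_method` ("otsu"), `threshold_value` (`NULL`),
#'   `connectivity` (26), `min_volume_um3` (0.05), `split_enabled`
#'   (`FALSE`), `split_min_sep_um` (2).
#' * `cells`: `source` ("label_file"), `wall_cutoff` (`NULL` = Otsu),
#'   `seed_sigma_um` (1.5, below half the typical wall width so smoothing
#'   suppresses noise without erasing walls), `min_seed_sep_um` (12).
#' * `metrics`: `large_diam_um` (5), `small_class_um3` (100),
#'   `max_gap_um` (15).
#' * `report`: `test` ("welch").
#'
#' @return The configuration list.
#' @export
default_config <- function() {
  list(
    preprocess = list(denoise_method = "median",
                      denoise_radius = c(0, 0, 0),
                      illumination_sigma_um = NULL),
    segment = list(threshold_method = "otsu",
                   threshold_value = NULL,
                   connectivity = 26,
                   min_volume_um3 = 0.05,
                   split_enabled = FALSE,
                   split_min_sep_um = 2),
    cells = list(source = "label_file",
                 wall_cutoff = NULL,
                 seed_sigma_um = 1.5,
                 min_seed_sep_um = 12),
    metrics = list(large_diam_um = 5,
                   small_class_um3 = 100,
                   max_gap_um = 15),
    report = list(test = "welch"),
    seed = 1
  )
}

#' Merge a partial configuration over the defaults
#' @param config partial nested list (possibly `NULL`).
#' @return The fully resolved configuration.
#' @export
merge_config <- function(config = NULL) {
  base <- default_config()
  if (is.null(config)) return(base)
  for (block in names(base)) {
    if (is.list(base[[block]]) && !is.null(config[[block]]))
      base[[block]] <- modifyList(base[[block]], config[[block]],
                                  keep.null = TRUE)
    else if (!is.list(base[[block]]) && !is.null(config[[block]]))
      base[[block]] <- config[[block]]
  }
  base
}

#' Read / write a pipeline configuration as JSON
#' @param path JSON file path.
#' @return `read_config()` returns the resolved configuration list.
#' @export
read_config <- function(path) {
  merge_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(merge_config(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
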