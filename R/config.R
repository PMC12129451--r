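#' Pipeline configuration
#'
#' Creates the parameter set shared by every stage of the micronucleus (MN)
#' segmentation pipelines. Each argument is a named pipeline constant; defaults
#' are the published operating points of the method.
#'
#' @param rupture_ratio_threshold Maximum reporter MN/nucleus intensity ratio of
#'   a ruptured MN. An MN whose maximum reporter intensity is strictly less than
#'   this fraction of its nucleus' maximum is called ruptured. Default 0.16.
#' @param nucleus_min_area Connected components labeled as nucleus with an area
#'   strictly below this many pixels are reclassified as MN. Default 250.
#' @param mn_discard_radius MN strictly farther than this many pixels from every
#'   nucleus mask are discarded as likely false positives. Default 40.
#' @param native_vcs_resolution Acquisition resolution (px/um) of the rapid
#'   crop-classifier pipeline. Default 1.55.
#' @param working_resolution_range Two-element numeric; the px/um interval in
#'   which the tiled segmenter operates. Images outside the range must be
#'   linearly rescaled into it. Default `c(1.55, 2.8)`.
#' @param tile_size Side of the square sliding-window tile in pixels. Default 128.
#' @param tile_stride Advance of the sliding window in pixels; must not exceed
#'   `tile_size` so that every pixel is covered. Default 96.
#' @param vcs_crop_size Side of the nucleus-centered crop in pixels. Default 48.
#' @param vcs_net_input_size Side of the enlarged crop fed to the crop
#'   classifier. Default 96.
#' @param split_fractions Train/validation/test fractions at the field level;
#'   must sum to 1. Default `c(0.65, 0.07, 0.28)`.
#' @param focal_gamma Focusing exponent of the focal loss. Default 2.
#' @param focal_alpha Class weights of the focal loss: `"balanced"` (inverse
#'   class frequency, the default) or a numeric vector of length 3.
#' @param cell_seed_threshold Threshold on the summed distance + proximity maps
#'   above which pixels seed the cell watershed. Default 0.5.
#' @param proximity_skeleton_threshold Proximity level below which foreground
#'   pixels form the cell-cell interface band whose skeleton licenses watershed
#'   boundaries. Default 0.5.
#' @param seed Integer seed controlling all randomness downstream.
#' @return An object of class `mn_config` (a validated named list).
#' @examples
#' cfg <- mn_config()
#' cfg$rupture_ratio_threshold
#' @export
mn_config <- function(rupture_ratio_threshold = 0.16,
                      nucleus_min_area = 250L,
                      mn_discard_radius = 40L,
                      native_vcs_resolution = 1.55,
                      working_resolution_range = c(1.55, 2.8),
                      tile_size = 128L,
                      tile_stride = 96L,
                      vcs_crop_size = 48L,
                      vcs_net_input_size = 96L,
                      split_fractions = c(0.65, 0.07, 0.28),
                      focal_gamma = 2,
                      focal_alpha = "balanced",
                      cell_seed_threshold = 0.5,
                      proximity_skeleton_threshold = 0.5,
                      seed = 1L) {
  cfg <- list(
    rupture_ratio_threshold = rupture_ratio_threshold,
    nucleus_min_area = as.integer(nucleus_min_area),
    mn_discard_radius = as.integer(mn_discard_radius),
    native_vcs_resolution = native_vcs_resolution,
    working_resolution_range = as.numeric(working_resolution_range),
    tile_size = as.integer(tile_size),
    tile_stride = as.integer(tile_stride),
    vcs_crop_size = as.integer(vcs_crop_size),
    vcs_net_input_size = as.integer(vcs_net_input_size),
    split_fractions = as.numeric(split_fractions),
    focal_gamma = focal_gamma,
    focal_alpha = focal_alpha,
    cell_seed_threshold = cell_seed_threshold,
    proximity_skeleton_threshold = proximity_skeleton_threshold,
    seed = as.integer(seed)
  )
  class(cfg) <- "mn_config"
  validate_config(cfg)
  cfg
}

#' @export
print.mn_config <- function(x, ...) {
  cat("<mn_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-28s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

validate_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("invalid config field '%s': %s", field, msg), call. = FALSE)
  }
  num1 <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      fail(field, "must be a single finite number")
    }
    v
  }
  r <- num1("rupture_ratio_threshold")
  if (r <= 0 || r >= 1) fail("rupture_ratio_threshold", "must lie in (0, 1)")
  for (field in c("nucleus_min_area", "mn_discard_radius", "tile_size",
                  "tile_stride", "vcs_crop_size", "vcs_net_input_size")) {
    v <- num1(field)
    if (v <= 0 || v != round(v)) fail(field, "must be a positive integer")
  }
  if (cfg$tile_stride > cfg$tile_size) {
    fail("tile_stride", "must not exceed tile_size")
  }
  wr <- cfg$working_resolution_range
  if (!is.numeric(wr) || length(wr) != 2L || any(!is.finite(wr)) ||
      any(wr <= 0) || wr[1] > wr[2]) {
    fail("working_resolution_range",
         "must be two positive numbers with lower bound <= upper bound")
  }
  if (num1("native_vcs_resolution") <= 0) {
    fail("native_vcs_resolution", "must be positive")
  }
  sf <- cfg$split_fractions
  if (!is.numeric(sf) || length(sf) != 3L || any(sf < 0)) {
    fail("split_fractions", "must be three non-negative fractions")
  }
  if (abs(sum(sf) - 1) > 1e-9) {
    fail("split_fractions", sprintf("must sum to 1 (got %.12g)", sum(sf)))
  }
  if (num1("focal_gamma") < 0) fail("focal_gamma", "must be non-negative")
  fa <- cfg$focal_alpha
  if (!(identical(fa, "balanced") ||
        (is.numeric(fa) && length(fa) == 3L && all(fa > 0)))) {
    fail("focal_alpha", "must be \"balanced\" or three positive weights")
  }
  if (num1("cell_seed_threshold") <= 0) {
    fail("cell_seed_threshold", "must be positive")
  }
  p <- num1("proximity_skeleton_threshold")
  if (p <= 0 || p >= 1) fail("proximity_skeleton_threshold", "must lie in (0, 1)")
  num1("seed")
  invisible(cfg)
}

.config_known_keys <- function() names(formals(mn_config))

#' Load a pipeline configuration from a YAML or JSON file
#'
#' Reads a key/value document, applies `overrides` on top of it, fills any
#' absent key with its default, and validates all invariants before returning.
#' Unknown keys are rejected so that typos cannot silently disable a threshold.
#'
#' @param path Path to a YAML (`.yml`/`.yaml`) or JSON (`.json`) file, or `NULL`
#'   to start from defaults only.
#' @param overrides Named list of config values applied after the file.
#' @return An `mn_config` object.
#' @seealso [mn_config()], [write_config()]
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    vals <- tryCatch(
      if (grepl("\\.json$", path, ignore.case = TRUE)) {
        jsonlite::read_json(path, simplifyVector = TRUE)
      } else {
        yaml::read_yaml(path)
      },
      error = function(e) {
        stop("failed to parse config file '", path, "': ", conditionMessage(e),
             call. = FALSE)
      }
    )
    if (is.null(vals)) vals <- list()  # empty document -> all defaults
    if (!is.list(vals)) stop("config file must be a key/value mapping", call. = FALSE)
  }
  vals[names(overrides)] <- overrides
  unknown <- setdiff(names(vals), .config_known_keys())
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(mn_config, vals)
}

#' Write a pipeline configuration to disk
#'
#' @param cfg An `mn_config` object.
#' @param path Output path; format chosen by extension (`.json` else YAML).
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "mn_config"))
  vals <- unclass(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path)
  }
  invisible(path)
}
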