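#' Algorithm configuration
#'
#' All tunable constants of the airway pipeline, defaulting to the published
#' operating point: global air threshold -400 HU, adaptive band upper cap
#' -125 HU, bone threshold +200 HU, 2 mm^3 small-object removal, 1.5x
#' choanae width-drop ratio, 11 mm stenosis rule, +/-5% station windows at
#' 0/25/50/75/100% of the mid-nasal axis, and an in-plane 3x3 local-mean
#' neighbourhood.
#'
#' @param air_threshold_hu Global air/tissue threshold (HU); voxels strictly
#'   below it seed the initial segmentation.
#' @param soft_threshold_hu Upper HU cap of the adaptive expansion band.
#' @param bone_threshold_hu Bone threshold (HU, inclusive) used for
#'   pyriform-aperture detection and width measurement.
#' @param min_object_volume_mm3 Connected components smaller than this are
#'   removed from the initial segmentation.
#' @param choanae_width_ratio Width-drop factor identifying the choanae.
#' @param stenosis_width_mm Pyriform widths strictly below this raise the
#'   stenosis flag.
#' @param profile_window_pct Half-width (percent of the mid-nasal axis) of
#'   the station averaging window.
#' @param sample_stations_pct Station positions in percent of the mid-nasal
#'   axis.
#' @param connectivity 3-D neighbourhood for airway components: 6, 18 or 26.
#' @param local_mean_mode `"inplane"` for the in-plane (axial) 3x3
#'   local-mean neighbourhood, `"3d"` for a 3x3x3 block.
#' @param choanae_rule `"prev_over_current"` (default: the ratio of the more
#'   posterior slice's width to the current one, scanning posterior to
#'   anterior) or `"current_over_prev"` for the inverse reading.
#' @param tip_band_slices Axial half-band (slices) around the nasal tip used
#'   when scanning for pyriform bone.
#' @param bone_min_area_mm2 Noise guard: minimum bone area in a coronal
#'   slice's tip band for pyriform detection.
#' @param aperture_lower_fraction Fraction of the bony opening's vertical
#'   extent, measured from its inferior edge, over which the minimum width
#'   is taken.
#' @return A list of class `nasal_config`.
#' @export
nasal_config <- function(air_threshold_hu = -400,
                         soft_threshold_hu = -125,
                         bone_threshold_hu = 200,
                         min_object_volume_mm3 = 2,
                         choanae_width_ratio = 1.5,
                         stenosis_width_mm = 11,
                         profile_window_pct = 5,
                         sample_stations_pct = c(0, 25, 50, 75, 100),
                         connectivity = 26,
                         local_mean_mode = c("inplane", "3d"),
                         choanae_rule = c("prev_over_current", "current_over_prev"),
                         tip_band_slices = 1,
                         bone_min_area_mm2 = 2,
                         aperture_lower_fraction = 0.5) {
  local_mean_mode <- match.arg(local_mean_mode)
  choanae_rule <- match.arg(choanae_rule)
  cfg <- list(air_threshold_hu = air_threshold_hu,
              soft_threshold_hu = soft_threshold_hu,
              bone_threshold_hu = bone_threshold_hu,
              min_object_volume_mm3 = min_object_volume_mm3,
              choanae_width_ratio = choanae_width_ratio,
              stenosis_width_mm = stenosis_width_mm,
              profile_window_pct = profile_window_pct,
              sample_stations_pct = sample_stations_pct,
              connectivity = as.integer(connectivity),
              local_mean_mode = local_mean_mode,
              choanae_rule = choanae_rule,
              tip_band_slices = as.integer(tip_band_slices),
              bone_min_area_mm2 = bone_min_area_mm2,
              aperture_lower_fraction = aperture_lower_fraction)
  validate_config(cfg)
  structure(cfg, class = "nasal_config")
}

validate_config <- function(cfg) {
  if (!(cfg$air_threshold_hu < cfg$soft_threshold_hu &&
        cfg$soft_threshold_hu < cfg$bone_threshold_hu))
    stop("thresholds must satisfy air < soft < bone")
  if (cfg$choanae_width_ratio <= 1) stop("choanae_width_ratio must be > 1")
  if (!(cfg$connectivity %in% c(6L, 18L, 26L)))
    stop("connectivity must be 6, 18 or 26")
  if (cfg$min_object_volume_mm3 < 0) stop("min_object_volume_mm3 must be >= 0")
  invisible(cfg)
}

#' Read a configuration file
#'
#' Reads a YAML or JSON file whose keys override [nasal_config()] defaults.
#' Unknown keys are an error, so typos fail loudly.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `nasal_config` list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("config file must be .yaml/.yml or .json"))
  if (is.null(vals)) vals <- list()
  known <- names(formals(nasal_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(nasal_config, vals)
}

#' @export
print.nasal_config <- function(x, ...) {
  cat("<nasal_config>\n")
  for (nm in names(x))
    cat("  ", nm, ": ", paste(x[[nm]], collapse = ", "), "\n", sep = "")
  invisible(x)
}
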