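# Quantitative outputs: pyriform width + stenosis flag, regional volumes,
# surface area, cross-sectional-area profiles and station sampling.

#' Pyriform aperture width and stenosis flag
#'
#' On the pyriform coronal slice, measures for each axial row in the lower
#' portion of the bony opening the left-right gap between the medial bone
#' edges flanking the midline, and reports the minimum gap. Widths strictly
#' below the stenosis threshold raise the flag.
#'
#' @param volume A [ct_volume()].
#' @param landmarks A [landmark_set()].
#' @param config A [nasal_config()]; `aperture_lower_fraction` sets the
#'   inferior fraction of the opening over which the minimum is taken.
#' @return A list `width_mm`, `stenosis_flag`, `row_widths` (tibble of
#'   per-row gaps).
#' @export
pyriform_width <- function(volume, landmarks, config = nasal_config()) {
  v <- volume$voxels
  d <- dim(v)
  sp <- volume$spacing
  bone <- v[, landmarks$pyriform + 1L, ] >= config$bone_threshold_hu
  body <- v[, landmarks$pyriform + 1L, ] > config$air_threshold_hu
  bodycols <- which(colSums(body) > 0)
  if (!length(bodycols)) stop("no tissue on the pyriform slice")
  xc <- round(mean(range(bodycols)))  # head midline column
  rows <- integer(0); gaps <- numeric(0)
  for (z in seq_len(d[1])) {
    xs <- which(bone[z, ])
    if (!length(xs)) next
    left <- xs[xs <= xc]; right <- xs[xs > xc]
    if (!length(left) || !length(right)) next
    le <- max(left); re <- min(right)
    if (re - le <= 1L) next  # bone crosses the midline: no opening this row
    rows <- c(rows, z - 1L)
    gaps <- c(gaps, (re - le - 1L) * sp[3])
  }
  if (!length(rows)) stop("no bone flanking the aperture on the pyriform slice")
  # the bony opening is the contiguous run of two-sided rows at the airway
  # level (the one containing the nasal tip); stray notches in blurred or
  # noisy bone away from it are not part of the aperture
  runs <- split(seq_along(rows), cumsum(c(1L, diff(rows) > 1L)))
  pick <- which.min(vapply(runs, function(i) min(abs(rows[i] - landmarks$tip)), 0))
  sel <- runs[[pick]]
  rows <- rows[sel]; gaps <- gaps[sel]
  zmin <- min(rows); zmax <- max(rows)
  lower <- rows >= zmax - config$aperture_lower_fraction * (zmax - zmin)
  width <- min(gaps[lower])
  list(width_mm = width,
       stenosis_flag = width < config$stenosis_width_mm,
       row_widths = tibble::tibble(axial = rows, gap_mm = gaps, lower = lower))
}

#' Regional airway volumes
#'
#' Voxel-count volumes in cm^3 for the nares, mid-nasal and nasopharynx
#' regions of the main passage; the total is their exact sum. Isolated
#' components are reported separately and never contribute.
#'
#' @param regional A [partition_regions()] result.
#' @return A list with the four volumes, `isolated` (cm^3) and a tidy
#'   `table` tibble.
#' @export
regional_volumes <- function(regional) {
  vv <- prod(regional$mask$spacing) / 1000
  counts <- tabulate(regional$regions, nbins = 3L)
  nares <- counts[1] * vv; mid <- counts[2] * vv; naso <- counts[3] * vv
  iso <- sum(regional$mask$labels > 1L) * vv
  list(nares = nares, midnasal = mid, nasopharynx = naso,
       total = nares + mid + naso, isolated = iso,
       table = tibble::tibble(
         region = c("nares", "midnasal", "nasopharynx", "total", "isolated"),
         volume_cm3 = c(nares, mid, naso, nares + mid + naso, iso)))
}

#' Surface area of the main airway
#'
#' Extracts the 0.5-level iso-surface of the (lightly smoothed) binary
#' main-component mask by marching tetrahedra and reports the mesh area.
#' Smoothing with a sub-voxel Gaussian regularises the staircase surface of
#' the binary grid; face counting is avoided because it overestimates area
#' and does not converge with resolution.
#'
#' @param mask An `airway_mask`, or a logical array with `spacing` given.
#' @param spacing Voxel spacing in mm (taken from the mask object if
#'   available).
#' @param smooth_mm Gaussian smoothing applied before extraction, mm.
#' @return Surface area in cm^2.
#' @export
surface_area <- function(mask, spacing = NULL, smooth_mm = 0.3) {
  if (inherits(mask, "airway_mask")) {
    m <- main_mask(mask)
    spacing <- mask$spacing
  } else m <- mask
  if (is.null(spacing)) stop("`spacing` is required for plain arrays")
  if (!any(m)) return(0)
  d <- dim(m)
  field <- array(as.numeric(m), d)
  if (smooth_mm > 0)
    field <- array(.gauss_blur_3d(field, d, smooth_mm / spacing), d)
  .surface_area_mt(field, d, spacing, 0.5) / 100
}

#' Cross-sectional-area profile along the airway
#'
#' Per coronal slice, the combined area of the main passage (voxel count
#' times the axial-by-lateral pixel area), indexed three ways: by slice, by
#' percent of full cavity length (nostrils 0% to posterior nasopharyngeal
#' wall 100%) and by percent of the mid-nasal axis (pyriform 0% to choanae
#' 100%). Both percent curves are also resampled by linear interpolation
#' onto 101 evenly spaced points.
#'
#' @param mask An `airway_mask`.
#' @param landmarks A [landmark_set()].
#' @return A list of class `nasal_profile`: `by_slice` tibble (`coronal`,
#'   `area_mm2`, `pct_full`, `pct_midnasal`), `curves` tibble
#'   (`axis`, `pct`, `area_mm2`).
#' @export
cross_section_profile <- function(mask, landmarks) {
  m <- main_mask(mask)
  sp <- mask$spacing
  px <- sp[1] * sp[3]
  ys <- landmarks$anterior:landmarks$posterior
  areas <- vapply(ys, function(y) sum(m[, y + 1L, ]) * px, 0)
  by_slice <- tibble::tibble(
    coronal = ys,
    area_mm2 = areas,
    pct_full = (ys - landmarks$anterior) /
      (landmarks$posterior - landmarks$anterior) * 100,
    pct_midnasal = (ys - landmarks$pyriform) /
      (landmarks$choanae - landmarks$pyriform) * 100)
  grid <- seq(0, 100, length.out = 101L)
  curves <- dplyr::bind_rows(
    tibble::tibble(axis = "full", pct = grid,
                   area_mm2 = approx(by_slice$pct_full, areas, xout = grid)$y),
    tibble::tibble(axis = "midnasal", pct = grid,
                   area_mm2 = approx(by_slice$pct_midnasal, areas, xout = grid)$y))
  structure(list(by_slice = by_slice, curves = curves, landmarks = landmarks,
                 spacing = sp),
            class = "nasal_profile")
}

#' Sample the profile at mid-nasal stations
#'
#' Station values are means of per-slice areas whose mid-nasal percent
#' position falls within +/- the window half-width of the station, the
#' window clipped to `[0, 100]`. Stations whose window holds no slice are
#' `NA` and flagged.
#'
#' @param profile A [cross_section_profile()] result.
#' @param config A [nasal_config()]; stations and window width come from
#'   `sample_stations_pct` and `profile_window_pct`.
#' @return A tibble `station_pct`, `area_mm2`, `n_slices`, `undefined`.
#' @export
sample_stations <- function(profile, config = nasal_config()) {
  bs <- profile$by_slice
  w <- config$profile_window_pct
  res <- lapply(config$sample_stations_pct, function(p) {
    lo <- max(p - w, 0); hi <- min(p + w, 100)
    sel <- bs$pct_midnasal >= lo & bs$pct_midnasal <= hi
    n <- sum(sel)
    tibble::tibble(station_pct = p,
                   area_mm2 = if (n) mean(bs$area_mm2[sel]) else NA_real_,
                   n_slices = n, undefined = n == 0L)
  })
  dplyr::bind_rows(res)
}

#' Full morphometry report for one case
#'
#' @param volume A [ct_volume()].
#' @param mask The final `airway_mask`.
#' @param landmarks A [landmark_set()]; detected automatically when `NULL`.
#' @param config A [nasal_config()].
#' @param case_id Identifier used in the report row.
#' @return A list of class `morphometry_report`: `report` (one-row tibble
#'   with width, stenosis flag, volumes, surface area and station areas),
#'   `profile`, `landmarks`, `width` detail.
#' @export
morphometry_report <- function(volume, mask, landmarks = NULL,
                               config = nasal_config(), case_id = "case") {
  if (is.null(landmarks)) landmarks <- detect_landmarks(volume, mask, config)
  wd <- pyriform_width(volume, landmarks, config)
  regional <- partition_regions(mask, landmarks)
  vols <- regional_volumes(regional)
  sa <- surface_area(mask)
  prof <- cross_section_profile(mask, landmarks)
  st <- sample_stations(prof, config)
  row <- tibble::tibble(
    case_id = case_id,
    pyriform_width_mm = wd$width_mm,
    stenosis_flag = wd$stenosis_flag,
    nares_cm3 = vols$nares,
    midnasal_cm3 = vols$midnasal,
    nasopharynx_cm3 = vols$nasopharynx,
    total_cm3 = vols$total,
    isolated_cm3 = vols$isolated,
    surface_cm2 = sa)
  for (i in seq_len(nrow(st)))
    row[[paste0("area_", st$station_pct[i], "pct_mm2")]] <- st$area_mm2[i]
  structure(list(report = row, profile = prof, landmarks = landmarks,
                 width = wd, volumes = vols, stations = st),
            class = "morphometry_report")
}

#' @export
print.morphometry_report <- function(x, ...) {
  r <- x$report
  cat("<morphometry_report> ", r$case_id, "\n", sep = "")
  cat("  pyriform width ", round(r$pyriform_width_mm, 2), " mm",
      if (r$stenosis_flag) "  [stenosis suspected: < 11 mm]" else "", "\n", sep = "")
  cat("  volumes (cm^3): nares ", round(r$nares_cm3, 3),
      ", mid-nasal ", round(r$midnasal_cm3, 3),
      ", nasopharynx ", round(r$nasopharynx_cm3, 3),
      ", total ", round(r$total_cm3, 3), "\n", sep = "")
  cat("  surface area ", round(r$surface_cm2, 2), " cm^2\n", sep = "")
  invisible(x)
}

#' @export
tidy.morphometry_report <- function(x, ...) {
  tidyr::pivot_longer(x$report, -dplyr::all_of(c("case_id", "stenosis_flag")),
                      names_to = "parameter", values_to = "value")
}
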