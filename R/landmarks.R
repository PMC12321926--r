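# Landmark-plane detection: nasal tip, pyriform aperture, choanae, and the
# partition of the main airway into nares / mid-nasal / nasopharynx.

#' Landmark plane indices
#'
#' All indices are 0-based grid indices in the canonical frame; coronal
#' indices run along the anterior-posterior axis. The ordering invariant
#' `anterior < pyriform < choanae < posterior` is enforced.
#'
#' @param tip Axial index of the nasal tip.
#' @param pyriform,choanae Coronal indices of the landmark planes.
#' @param anterior,posterior Coronal extent of the airway (nostril plane and
#'   posterior nasopharyngeal wall).
#' @param terminus Axial index of the nasopharynx terminus.
#' @return A list of class `landmark_set`.
#' @export
landmark_set <- function(tip, pyriform, choanae, anterior, posterior,
                         terminus = NA_integer_) {
  if (!(anterior < pyriform && pyriform < choanae && choanae < posterior))
    stop("landmark ordering violated: need anterior < pyriform < choanae < posterior (got ",
         anterior, ", ", pyriform, ", ", choanae, ", ", posterior, ")")
  structure(list(tip = as.integer(tip), pyriform = as.integer(pyriform),
                 choanae = as.integer(choanae), anterior = as.integer(anterior),
                 posterior = as.integer(posterior),
                 terminus = as.integer(terminus)),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> tip(axial)=", x$tip, " coronal: anterior=", x$anterior,
      " pyriform=", x$pyriform, " choanae=", x$choanae,
      " posterior=", x$posterior, "\n", sep = "")
  invisible(x)
}

#' Detect the nasal tip slice
#'
#' Returns the axial slice whose body contour reaches furthest anterior
#' within the VOI; ties go to the more superior slice.
#'
#' @param volume A [ct_volume()].
#' @param voi A [select_voi()] result.
#' @param config A [nasal_config()].
#' @return 0-based axial index.
#' @export
detect_nasal_tip <- function(volume, voi, config = nasal_config()) {
  v <- volume$voxels
  d <- dim(v)
  zs <- voi$z_range[1]:(voi$z_range[2] - 1L)
  front <- vapply(zs, function(z) {
    B <- v[z + 1L, , ] > config$air_threshold_hu
    rows <- which(rowSums(B) > 0)
    if (!length(rows)) return(NA_real_)
    min(rows)
  }, 0)
  if (all(is.na(front))) {
    warning("degenerate body contour; falling back to the mid-VOI slice")
    return(as.integer(round(mean(voi$z_range)) - 1L))
  }
  zs[which.min(front)]
}

#' Detect the pyriform aperture coronal plane
#'
#' Scans coronal slices anterior to posterior and returns the most anterior
#' one containing bone (HU at or above the bone threshold) within the axial
#' band around the nasal tip, subject to a minimum-area noise guard.
#'
#' @param volume A [ct_volume()].
#' @param voi A [select_voi()] result.
#' @param tip Axial tip index from [detect_nasal_tip()].
#' @param config A [nasal_config()].
#' @return 0-based coronal index.
#' @export
detect_pyriform_slice <- function(volume, voi, tip, config = nasal_config()) {
  v <- volume$voxels
  d <- dim(v)
  band <- max(0L, tip - config$tip_band_slices):min(d[1] - 1L, tip + config$tip_band_slices)
  min_vox <- ceiling(config$bone_min_area_mm2 /
                     (volume$spacing[1] * volume$spacing[3]))
  for (y in 0:(d[2] - 1L)) {
    n_bone <- sum(v[band + 1L, y + 1L, ] >= config$bone_threshold_hu)
    if (n_bone >= min_vox) return(y)
  }
  stop("no pyriform bone found at the nasal-tip level")
}

slice_region_width <- function(slice_mask, d1, d3) {
  # width (in voxels, along right-left) of the largest 2-D region of an
  # in-slice mask; 8-connectivity in the coronal plane
  if (!any(slice_mask)) return(0L)
  lab <- .cc_label_3d(as.vector(slice_mask), c(d1, d3, 1L), 26L)
  sizes <- tabulate(lab)
  big <- which.max(sizes)
  xs <- ((which(lab == big) - 1L) %/% d1)
  max(xs) - min(xs) + 1L
}

#' Detect the choanae coronal plane
#'
#' Scans the main airway's coronal slices posterior to anterior, measuring
#' the left-right width of the largest in-slice region; returns the first
#' slice whose width has dropped by at least the configured ratio relative
#' to the previous (more posterior) slice — the division of the single
#' nasopharyngeal cavity into two nasal passages.
#'
#' @param mask An `airway_mask` with a designated main component.
#' @param config A [nasal_config()]; `choanae_rule` selects the ratio
#'   direction.
#' @return 0-based coronal index.
#' @export
detect_choanae_slice <- function(mask, config = nasal_config()) {
  m <- main_mask(mask)
  d <- dim(m)
  ys <- which(apply(m, 2, any)) - 1L
  if (!length(ys)) stop("no airway")
  widths <- vapply(ys, function(y) slice_region_width(m[, y + 1L, ], d[1], d[3]), 0L)
  ord <- order(ys, decreasing = TRUE)  # posterior -> anterior
  ys <- ys[ord]; widths <- widths[ord]
  for (i in seq_along(ys)[-1]) {
    prev <- widths[i - 1L]; cur <- widths[i]
    if (cur == 0L) next
    ratio <- if (config$choanae_rule == "prev_over_current") prev / cur
             else cur / prev
    if (ratio >= config$choanae_width_ratio) return(ys[i])
  }
  stop("choanae not found: no width drop of at least ",
       config$choanae_width_ratio, "x")
}

#' Detect all landmarks for a segmented case
#'
#' @param volume A [ct_volume()].
#' @param mask The final `airway_mask`.
#' @param config A [nasal_config()].
#' @return A [landmark_set()].
#' @export
detect_landmarks <- function(volume, mask, config = nasal_config()) {
  voi <- mask$voi
  tip <- detect_nasal_tip(volume, voi, config)
  pyr <- detect_pyriform_slice(volume, voi, tip, config)
  cho <- detect_choanae_slice(mask, config)
  m <- main_mask(mask)
  ys <- which(apply(m, 2, any)) - 1L
  landmark_set(tip = tip, pyriform = pyr, choanae = cho,
               anterior = min(ys), posterior = max(ys),
               terminus = voi$terminus)
}

#' Partition the main airway into anatomical regions
#'
#' Assigns every main-component voxel to exactly one region by its coronal
#' index: nares `[anterior, pyriform)`, mid-nasal `[pyriform, choanae)`,
#' nasopharynx `[choanae, posterior]`.
#'
#' @param mask The final `airway_mask`.
#' @param landmarks A [landmark_set()].
#' @return A list of class `regional_mask` with an integer `regions` array
#'   (0 none, 1 nares, 2 mid-nasal, 3 nasopharynx), the source mask and the
#'   landmarks.
#' @export
partition_regions <- function(mask, landmarks) {
  m <- main_mask(mask)
  d <- dim(m)
  ybands <- integer(d[2])
  yidx <- 0:(d[2] - 1L)
  ybands[yidx >= landmarks$anterior & yidx < landmarks$pyriform] <- 1L
  ybands[yidx >= landmarks$pyriform & yidx < landmarks$choanae] <- 2L
  ybands[yidx >= landmarks$choanae & yidx <= landmarks$posterior] <- 3L
  regions <- array(0L, d)
  for (j in which(ybands > 0L)) {
    sl <- m[, j, ]
    if (any(sl)) regions[, j, ][sl] <- ybands[j]
  }
  structure(list(regions = regions, mask = mask, landmarks = landmarks),
            class = "regional_mask")
}
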