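# Airway isolation pipeline: VOI selection, nostril closure, -400 HU global
# threshold with external-air/small-object/oropharynx removal, adaptive
# local-threshold expansion in the -400..-125 HU band, and 3-D connectivity
# filtering with isolated-region flagging.

largest_component <- function(mask, d, connectivity = 26L) {
  lab <- .cc_label_3d(mask, d, connectivity)
  sizes <- tabulate(lab)
  if (!length(sizes)) return(array(FALSE, d))
  array(lab == which.max(sizes), d)
}

# enclosed air: air voxels with body tissue on both lateral sides of their
# (axial, AP) row — external air fails this, nasal/nasopharyngeal air and
# any enclosed pocket passes it
enclosed_air <- function(air, body, d) {
  left <- body
  for (k in 2:d[3]) left[, , k] <- left[, , k] | left[, , k - 1]
  right <- body
  for (k in (d[3] - 1):1) right[, , k] <- right[, , k] | right[, , k + 1]
  air & left & right
}

#' Select the nasal volume of interest
#'
#' Finds the head, identifies enclosed (internal) air, picks the air
#' component reaching furthest anterior (the nasal column, entered through
#' the nostrils), and returns the axial slice range spanning it — from the
#' most superior internal-air slice down to the nasopharynx terminus —
#' together with a per-slice lateral crop covering the central third of the
#' head width.
#'
#' @param volume A [ct_volume()].
#' @param config A [nasal_config()].
#' @return A list of class `voi_bounds`: `z_range` (0-based, half-open),
#'   `slices` (tibble `z`, `x_lo`, `x_hi`, 0-based half-open lateral crop),
#'   `terminus` (0-based axial index of the nasopharynx terminus).
#' @export
select_voi <- function(volume, config = nasal_config()) {
  v <- volume$voxels
  d <- dim(v)
  body_any <- v > config$air_threshold_hu
  if (mean(body_any) < 0.01) stop("no body detected in volume")
  body <- largest_component(body_any, d)
  air <- v < config$air_threshold_hu
  enc <- enclosed_air(air, body, d)
  lab <- .cc_label_3d(enc, d, 26L)
  sizes <- tabulate(lab)
  keep <- which(sizes >= 50)
  if (!length(keep)) stop("no airway candidate: no internal air found")
  idx <- which(enc)
  labv <- lab[idx]
  yidx <- ((idx - 1L) %/% d[1]) %% d[2]
  miny <- vapply(keep, function(l) min(yidx[labv == l]), 0)
  nasal <- keep[order(miny, -sizes[keep])][1]
  sel <- idx[labv == nasal]
  zidx <- (sel - 1L) %% d[1]
  z0 <- min(zidx); z1 <- max(zidx) + 1L

  zs <- z0:(z1 - 1L)
  x_lo <- integer(length(zs)); x_hi <- integer(length(zs))
  for (i in seq_along(zs)) {
    sl <- body[zs[i] + 1L, , ]
    cols <- which(colSums(sl) > 0)
    if (!length(cols)) stop("head absent from an axial slice inside the VOI")
    w <- max(cols) - min(cols) + 1L
    ctr <- (max(cols) + min(cols)) / 2
    x_lo[i] <- max(0L, as.integer(round(ctr - w / 6)) - 1L)
    x_hi[i] <- min(d[3], x_lo[i] + as.integer(round(w / 3)))
  }
  structure(list(
    z_range = c(z0, z1),
    slices = tibble::tibble(z = zs, x_lo = x_lo, x_hi = x_hi),
    terminus = z1 - 1L,
    dim = d), class = "voi_bounds")
}

voi_indicator <- function(voi) {
  d <- voi$dim
  vi <- array(FALSE, d)
  s <- voi$slices
  for (i in seq_len(nrow(s)))
    vi[s$z[i] + 1L, , (s$x_lo[i] + 1L):s$x_hi[i]] <- TRUE
  vi
}

#' Close the nostrils with virtual straight lines
#'
#' For each axial slice in the VOI, the anterior face contour is traced per
#' lateral column; interruptions (nostril openings) are bridged by a
#' straight closure line between the two flanking face points, and every
#' voxel anterior to the face/closure line is marked excluded, separating
#' nasal air from external air.
#'
#' @param volume A [ct_volume()].
#' @param voi A [select_voi()] result.
#' @param config A [nasal_config()].
#' @return A list of class `nostril_closure`: `segments` (tibble of
#'   closure-line endpoints per slice, 0-based grid indices) and `excluded`
#'   (logical array).
#' @export
close_nostrils <- function(volume, voi, config = nasal_config()) {
  v <- volume$voxels
  d <- dim(v)
  sp <- volume$spacing
  excluded <- array(FALSE, d)
  segs <- list()
  win <- max(1L, as.integer(round(6 / sp[3])))
  deep <- max(2L, as.integer(round(1 / sp[2])))  # a real opening recedes >= 1 mm
  yseq <- seq_len(d[2])
  for (z in voi$z_range[1]:(voi$z_range[2] - 1L)) {
    B <- v[z + 1L, , ] > config$air_threshold_hu
    yf <- rep(NA_integer_, d[3])
    nb <- colSums(B) > 0
    yf[nb] <- apply(B[, nb, drop = FALSE], 2, function(col) which(col)[1])
    if (!any(nb)) next
    yfi <- ifelse(is.na(yf), Inf, yf)
    base <- yfi
    for (s in seq_len(win)) {
      base <- pmin(base, c(yfi[-seq_len(s)], rep(Inf, s)),
                   c(rep(Inf, s), yfi[seq_len(d[3] - s)]))
    }
    # any column whose face recedes behind the local face baseline is part
    # of an interruption and gets bridged by the straight line between the
    # flanking face points
    gap <- nb & is.finite(base) & (yfi > base)
    cutoff <- ifelse(nb, yf, 0)
    r <- rle(gap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      a <- starts[i]; b <- ends[i]
      if (a <= 1L || b >= d[3]) next
      if (!nb[a - 1L] || !nb[b + 1L] || gap[a - 1L] || gap[b + 1L]) next
      line <- approx(c(a - 1L, b + 1L), c(yf[a - 1L], yf[b + 1L]),
                     xout = a:b)$y
      cutoff[a:b] <- pmin(cutoff[a:b], line)
      # only openings deeper than the noise scale count as nostril segments
      if (max(yfi[a:b] - base[a:b]) >= deep)
        segs[[length(segs) + 1L]] <- data.frame(
          z = z, x1 = a - 2L, y1 = yf[a - 1L] - 1L,
          x2 = b, y2 = yf[b + 1L] - 1L)
    }
    excluded[z + 1L, , ] <- outer(yseq, cutoff, "<")
  }
  segments <- if (length(segs)) tibble::as_tibble(do.call(rbind, segs))
              else tibble::tibble(z = integer(), x1 = integer(), y1 = integer(),
                                  x2 = integer(), y2 = integer())
  structure(list(segments = segments, excluded = excluded),
            class = "nostril_closure")
}

new_airway_mask <- function(mask, labels, connected, provenance, voi,
                            spacing, stats = list()) {
  structure(list(mask = mask, labels = labels, connected = connected,
                 provenance = provenance, voi = voi, spacing = spacing,
                 stats = stats), class = "airway_mask")
}

#' @export
print.airway_mask <- function(x, ...) {
  n <- sum(x$mask)
  cat("<airway_mask> ", n, " voxels (",
      signif(n * prod(x$spacing) / 1000, 4), " cm^3), ",
      length(x$connected), " component(s), ",
      sum(!x$connected), " isolated\n", sep = "")
  invisible(x)
}

#' Main-passage mask of an `airway_mask`
#' @param mask An `airway_mask`.
#' @return Logical array selecting the main connected passage.
#' @export
main_mask <- function(mask) mask$labels == 1L & mask$mask

relabel_by_size <- function(labels, keep) {
  sizes <- tabulate(labels)
  out <- integer(length(sizes))
  kept <- intersect(order(sizes, decreasing = TRUE), keep)
  out[kept] <- seq_along(kept)
  map <- c(0L, out)
  array(map[labels + 1L], dim(labels))
}

#' Initial airway segmentation by global thresholding
#'
#' Thresholds the VOI at the global air threshold, removes
#' closure-excluded voxels, components that reach the VOI's outer faces
#' (surrounding external air), components centred inferior to the
#' nasopharynx terminus (oropharyngeal cavities), and small objects below
#' the minimum object volume.
#'
#' @param volume A [ct_volume()].
#' @param voi A [select_voi()] result.
#' @param closure A [close_nostrils()] result.
#' @param config A [nasal_config()].
#' @return An `airway_mask` holding the initial segmentation.
#' @export
global_threshold_segment <- function(volume, voi, closure,
                                     config = nasal_config()) {
  v <- volume$voxels
  d <- dim(v)
  vi <- voi_indicator(voi)
  cand <- (v < config$air_threshold_hu) & vi & !closure$excluded
  lab <- .cc_label_3d(cand, d, config$connectivity)
  sizes <- tabulate(lab)
  drop <- logical(length(sizes))

  # external air: components reaching the VOI's anterior/posterior faces or
  # the lateral crop columns (the axial ends are airway by construction)
  boundary <- array(FALSE, d)
  boundary[, c(1L, d[2]), ] <- TRUE
  s <- voi$slices
  for (i in seq_len(nrow(s))) {
    boundary[s$z[i] + 1L, , c(s$x_lo[i] + 1L, s$x_hi[i])] <- TRUE
  }
  ext <- unique(lab[boundary & cand])
  drop[ext[ext > 0L]] <- TRUE

  # oropharynx proxy: centroid inferior to the nasopharynx terminus
  idx <- which(cand)
  if (length(idx)) {
    labv <- lab[idx]
    zc <- (idx - 1L) %% d[1]
    cz <- rowsum(zc, labv) / sizes[sort(unique(labv))]
    below <- as.integer(rownames(cz))[cz[, 1] > voi$terminus]
    drop[below] <- TRUE
  }

  min_vox <- ceiling(config$min_object_volume_mm3 / prod(volume$spacing))
  drop[sizes < min_vox] <- TRUE

  keep <- which(!drop & sizes > 0)
  if (!length(keep)) {
    warning("global threshold produced an empty airway mask")
    empty <- array(FALSE, d)
    return(new_airway_mask(empty, array(0L, d), logical(0),
                           array(0L, d), voi, volume$spacing,
                           stats = list(initial_voxels = 0L)))
  }
  lab <- array(ifelse(lab %in% keep, lab, 0L), d)
  lab <- relabel_by_size(lab, keep = seq_len(max(lab)))
  mask <- lab > 0L
  prov <- array(0L, d); prov[mask] <- 1L
  new_airway_mask(mask, lab, rep(TRUE, max(lab)), prov, voi, volume$spacing,
                  stats = list(initial_voxels = sum(mask),
                               removed_external = length(ext[ext > 0L]),
                               excluded = closure$excluded))
}

#' Adaptive local-threshold expansion
#'
#' Grows the initial mask into the partial-volume band: voxels with HU in
#' `[air_threshold, soft_threshold)` are absorbed when strictly below the
#' mean of their 3x3 neighbours at or above the air threshold (air voxels
#' are excluded from the mean; a voxel whose neighbours are all air is not
#' absorbed) and 3-D connected, through absorbed voxels, to the initial
#' mask. Expansion runs to its fixed point, which is independent of
#' evaluation order because the eligibility test is static.
#'
#' @param volume A [ct_volume()].
#' @param mask An initial `airway_mask` from [global_threshold_segment()].
#' @param config A [nasal_config()].
#' @return An expanded `airway_mask`; added voxels carry provenance 2.
#' @export
adaptive_expand <- function(volume, mask, config = nasal_config()) {
  v <- volume$voxels
  d <- dim(v)
  vi <- voi_indicator(mask$voi)
  excl <- mask$stats$excluded
  allowed <- if (is.null(excl)) vi else vi & !excl
  lm <- .local_band_mean(v, d, config$air_threshold_hu,
                         if (config$local_mean_mode == "3d") 1L else 0L)
  added <- array(.adaptive_expand_core(v, mask$mask, allowed, lm, d,
                                       config$air_threshold_hu,
                                       config$soft_threshold_hu,
                                       config$connectivity), d)
  out <- mask
  out$mask <- mask$mask | added
  out$provenance[added] <- 2L
  out$labels <- NULL  # recomputed by filter_connected
  out$stats$added_voxels <- sum(added)
  out
}

#' Retain airway regions by 3-D connectivity to the central passage
#'
#' Labels the expanded mask, designates as the main passage the largest
#' component intersecting the central third of the airway's
#' anterior-posterior extent (ties broken toward the more anterior
#' centroid), and flags all other components as anatomically isolated; they
#' are kept in the label map but excluded from every measurement.
#'
#' @param mask An `airway_mask` (typically from [adaptive_expand()]).
#' @param voi The matching [select_voi()] result.
#' @param config A [nasal_config()].
#' @return An `airway_mask` with labels 1 (main), 2+ (isolated, by size).
#' @export
filter_connected <- function(mask, voi = mask$voi, config = nasal_config()) {
  d <- dim(mask$mask)
  lab <- .cc_label_3d(mask$mask, d, config$connectivity)
  sizes <- tabulate(lab)
  if (!length(sizes)) stop("no airway: the segmentation mask is empty")
  idx <- which(mask$mask)
  labv <- lab[idx]
  yv <- ((idx - 1L) %/% d[1]) %% d[2]
  ylo <- min(yv); yhi <- max(yv)
  band <- yv >= ylo + (yhi - ylo) / 3 & yv <= yhi - (yhi - ylo) / 3
  cands <- sort(unique(labv[band]))
  if (!length(cands)) stop("no airway: no component intersects the nasal ROI")
  ymean <- rowsum(as.numeric(yv), labv)[, 1] / sizes[sort(unique(labv))]
  names(ymean) <- sort(unique(labv))
  ord <- cands[order(-sizes[cands], ymean[as.character(cands)])]
  main <- ord[1]
  all_labs <- which(sizes > 0)
  others <- setdiff(all_labs, main)
  others <- others[order(sizes[others], decreasing = TRUE)]
  map <- integer(length(sizes))
  map[main] <- 1L
  map[others] <- seq_along(others) + 1L
  out <- mask
  out$labels <- array(c(0L, map)[lab + 1L], d)
  out$connected <- c(TRUE, rep(FALSE, length(others)))
  out$stats$n_isolated <- length(others)
  out$stats$excluded <- NULL
  out
}

#' Segment the nasal airway
#'
#' Runs the full isolation pipeline: VOI selection, nostril closure, global
#' -400 HU thresholding with external-air, oropharynx and small-object
#' removal, adaptive local-threshold expansion, and connectivity filtering.
#'
#' @param volume A [ct_volume()].
#' @param config A [nasal_config()].
#' @return An `airway_mask` with provenance (1 = global threshold,
#'   2 = adaptive expansion) and isolated-region flags; the VOI and closure
#'   segments ride along in `$voi` and `$stats`.
#' @export
segment_airway <- function(volume, config = nasal_config()) {
  voi <- select_voi(volume, config)
  closure <- close_nostrils(volume, voi, config)
  initial <- global_threshold_segment(volume, voi, closure, config)
  if (!any(initial$mask)) return(initial)
  expanded <- adaptive_expand(volume, initial, config)
  final <- filter_connected(expanded, voi, config)
  final$stats$closure_segments <- closure$segments
  final
}
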