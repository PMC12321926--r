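#' Parametric CT head phantom specification
#'
#' Describes a schematic neonatal head: a soft-tissue ellipsoid with a
#' protruding nose, two circular nasal passages running anterior to
#' posterior, a bony pyriform plate with a configurable aperture gap, a
#' choanae-level width step into a single rectangular nasopharynx duct, and
#' optional sealing of one nostril (producing an anatomically isolated air
#' segment). Tissue HU, additive Gaussian noise and a partial-volume
#' Gaussian blur are configurable. All lengths in mm.
#'
#' The geometry is deliberately schematic (tubes, ellipsoid, plate): its
#' purpose is analytic ground truth, not anatomical realism.
#'
#' @param aperture_gap Pyriform aperture width (left-right bone gap), mm.
#' @param aperture_height Vertical extent of the bony opening, mm.
#' @param aperture_thickness Bone plate thickness along the airway, mm.
#' @param gap_taper Widening of the bone gap per mm superior of the
#'   opening's inferior edge (0 = parallel-sided opening).
#' @param r_nares,dx_nares Radius and lateral offset of each nostril tube.
#' @param r_ap,dx_ap Radius and lateral offset to which passages converge
#'   while crossing the aperture plane.
#' @param taper_length Length of the linear radius/centreline taper on each
#'   side of the aperture.
#' @param r_mid Mid-nasal passage radius.
#' @param septum Tissue gap between the two mid-nasal passages.
#' @param nares_length,midnasal_length,naso_length Segment lengths.
#' @param naso_width,naso_height Rectangular nasopharynx duct dimensions.
#' @param head_semiaxes Ellipsoid semi-axes (SI, AP, RL), mm.
#' @param nose_halfwidth,nose_z_above,nose_z_below,nose_protrusion,stair_slope
#'   Nose prism geometry; the front face recedes by `stair_slope` mm per mm
#'   of axial distance from the nasal tip so the tip slice is unique.
#' @param face_y Anterior-most face position in grid coordinates, mm.
#' @param hu_soft,hu_bone,hu_air Tissue attenuation values in HU.
#' @param noise_sd Additive Gaussian noise (HU), applied after blurring.
#' @param blur_sd Gaussian partial-volume blur (mm) applied to the
#'   rasterised HU volume before noise.
#' @param sealed Character vector among `"left"`, `"right"`: sealed nostrils
#'   (a tissue plug at the opening and another ahead of the aperture,
#'   leaving an enclosed, anatomically isolated air segment).
#' @param oropharynx_pocket Add an enclosed air pocket inferior to the nasal
#'   airway, outside the nasal volume of interest (exercises the
#'   oropharynx-exclusion stage).
#' @param bone_speckle Add a single bone voxel anterior to the plate at the
#'   tip level (exercises the pyriform noise guard).
#' @param seed Seed for the noise generator; generation is deterministic
#'   given the spec.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(aperture_gap = 11.8,
                         aperture_height = 8,
                         aperture_thickness = 1.5,
                         gap_taper = 0,
                         r_nares = 2.6, dx_nares = 4.5,
                         r_ap = 1.3, dx_ap = 1.0,
                         taper_length = 3,
                         r_mid = 4.0, septum = 0.8,
                         nares_length = 10,
                         midnasal_length = 20,
                         naso_length = 15,
                         naso_width = 16, naso_height = 5.5,
                         head_semiaxes = c(20, 26, 33),
                         nose_halfwidth = 10,
                         nose_z_above = 8, nose_z_below = 12,
                         nose_protrusion = 6,
                         stair_slope = 0.6,
                         face_y = 6,
                         hu_soft = 40, hu_bone = 700, hu_air = -1000,
                         noise_sd = 0, blur_sd = 0,
                         sealed = character(0),
                         oropharynx_pocket = FALSE,
                         bone_speckle = FALSE,
                         seed = 0) {
  spec <- as.list(environment())
  if (spec$aperture_gap <= 0) stop("aperture_gap must be > 0")
  if (spec$r_nares <= 0 || spec$r_mid <= 0 || spec$r_ap <= 0)
    stop("passage radii must be positive")
  if (spec$aperture_gap < 2 * spec$dx_ap)
    stop("aperture_gap too narrow for the converged passage offset")
  if (length(spec$sealed) && !all(spec$sealed %in% c("left", "right")))
    stop("`sealed` must be a subset of c('left', 'right')")
  structure(spec, class = "phantom_spec")
}

frustum_volume <- function(len, r1, r2) pi * len * (r1^2 + r1 * r2 + r2^2) / 3

#' Generate a CT phantom and its analytic ground truth
#'
#' Rasterises a [phantom_spec()] onto a voxel grid (circular cross-sections
#' use 2x2 in-plane subsampling with majority inclusion, a crude
#' partial-volume model), then applies the partial-volume blur and additive
#' noise. The returned truth holds the exact pre-noise airway mask,
#' connected-component labels, analytic regional volumes, aperture width,
#' cross-sectional areas and designed landmark plane indices.
#'
#' @param spec A [phantom_spec()].
#' @param spacing Voxel spacing (SI, AP, RL) in mm.
#' @param grid_shape Optional grid dimensions; computed to fit the head with
#'   a 6 mm margin when `NULL`. The phantom must fit with >= 5 mm margin.
#' @return A list with elements `volume` (a [ct_volume()]) and `truth`
#'   (class `phantom_truth`).
#' @export
generate_phantom <- function(spec, spacing = c(0.5, 0.3, 0.3), grid_shape = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- as.numeric(spacing)
  snap2 <- function(y) round(y / sp[2]) * sp[2]

  hs <- spec$head_semiaxes
  need <- c(2 * hs[1] + 12, spec$face_y + spec$nose_protrusion + 2 * hs[2] + 6,
            2 * hs[3] + 12)
  if (is.null(grid_shape)) grid_shape <- ceiling(need / sp)
  d <- as.integer(grid_shape)
  if (any(d * sp < need - 1e-9 + (5 - 6)))  # >= 5 mm margin required
    stop("phantom geometry does not fit inside the grid with a 5 mm margin")

  zc <- (seq_len(d[1]) - 0.5) * sp[1]
  yc <- (seq_len(d[2]) - 0.5) * sp[2]
  xc <- (seq_len(d[3]) - 0.5) * sp[3]
  # tip level on a voxel centre; midline on a voxel boundary
  z0 <- (floor(d[1] / 2) + 0.5) * sp[1]
  x0 <- round(d[3] / 2) * sp[3]

  ze <- d[1] * sp[1] / 2
  ye <- spec$face_y + spec$nose_protrusion + hs[2]

  Y_P <- snap2(spec$face_y + spec$nares_length)
  th <- max(snap2(spec$aperture_thickness), sp[2])
  Y_M0 <- Y_P + th
  Y_C <- snap2(Y_M0 + spec$midnasal_length)
  Y_E <- snap2(Y_C + spec$naso_length)
  L_mid <- Y_C - Y_M0

  face_z <- spec$face_y + spec$stair_slope * abs(zc - z0)
  nose_zband <- zc >= z0 - spec$nose_z_above & zc <= z0 + spec$nose_z_below

  side_sign <- c(left = 1, right = -1)  # dim3 runs right -> left
  sealed <- side_sign[spec$sealed]

  # per-side centre offset and radius as functions of y (nares + taper)
  nares_dxr <- function(y) {
    if (y < Y_P - spec$taper_length) {
      c(spec$dx_nares, spec$r_nares)
    } else {
      f <- (y - (Y_P - spec$taper_length)) / spec$taper_length
      c(spec$dx_nares + f * (spec$dx_ap - spec$dx_nares),
        spec$r_nares + f * (spec$r_ap - spec$r_nares))
    }
  }
  dx_mid <- spec$r_mid + spec$septum
  mid_dxr <- function(y) {
    yy <- y - Y_M0
    if (yy < spec$taper_length) {
      f <- yy / spec$taper_length
      c(spec$dx_ap + f * (dx_mid - spec$dx_ap),
        spec$r_ap + f * (spec$r_mid - spec$r_ap))
    } else {
      c(dx_mid, spec$r_mid)
    }
  }

  # 5x5 in-cell subsampling with majority (>= 13/25) inclusion approximates
  # the half-coverage rule; for straight edges it reduces to the unbiased
  # centre rule. Restricted to a bounding box for speed.
  circle2d <- function(cz, cx, r) {
    out <- matrix(FALSE, d[1], d[3])
    iz <- which(abs(zc - cz) <= r + sp[1])
    ix <- which(abs(xc - cx) <= r + sp[3])
    if (!length(iz) || !length(ix)) return(out)
    acc <- matrix(0L, length(iz), length(ix))
    offs <- (-2:2) / 5
    for (oz in offs * sp[1])
      for (ox in offs * sp[3])
        acc <- acc + (outer((zc[iz] + oz - cz)^2, (xc[ix] + ox - cx)^2, "+") <= r^2)
    out[iz, ix] <- acc >= 13L
    out
  }
  # sub-voxel centreline drift (golden-ratio sequence) decorrelating the
  # lattice alignment across slices so rasterisation errors average out;
  # geometrically negligible (< half a voxel) and volume-preserving
  drift <- function(j) c(sp[1] * (((j * 0.6180339887) %% 1) - 0.5),
                         sp[3] * (((j * 0.7548776662) %% 1) - 0.5))

  vol <- array(spec$hu_air, d)
  mask <- array(FALSE, d)

  ell_z <- ((zc - ze) / hs[1])^2
  ell_x <- ((xc - x0) / hs[3])^2
  nose_x <- abs(xc - x0) <= spec$nose_halfwidth
  # gap taper anchored at the most inferior voxel row of the opening so the
  # designed gap is realised exactly on that row
  taper_anchor <- z0 + spec$aperture_height / 2 - sp[1] / 2
  gap_half <- function(z) {
    g <- spec$aperture_gap + spec$gap_taper * pmax(0, taper_anchor - z)
    # realise the designed gap as the nearest achievable voxel gap so the
    # rasterised width is within half an in-plane voxel of the design
    pmax(round(g / sp[3]), 1) * sp[3] / 2
  }

  for (j in seq_len(d[2])) {
    y <- yc[j]
    rem <- 1 - ((y - ye) / hs[2])^2
    solid <- if (rem > 0) outer(ell_z / 1, ell_x, "+") <= rem
             else matrix(FALSE, d[1], d[3])
    nose <- outer(nose_zband & (y >= face_z), nose_x, "&")
    solid <- solid | nose
    if (!any(solid)) next

    air <- matrix(FALSE, d[1], d[3])
    bone <- matrix(FALSE, d[1], d[3])

    dj <- drift(j)
    if (y < Y_P) {
      dxr <- nares_dxr(y)
      for (s in c(1, -1)) {
        if (s %in% sealed) {
          # plug at the opening and ahead of the aperture: air only in between
          open_from <- face_z + 2
          ok <- y >= open_from & y < snap2(Y_P - spec$taper_length - 2)
          if (!any(ok)) next
          circ <- circle2d(z0 + dj[1], x0 + s * dxr[1] + dj[2], dxr[2])
          circ[!ok, ] <- FALSE
          air <- air | circ
        } else {
          air <- air | circle2d(z0 + dj[1], x0 + s * dxr[1] + dj[2], dxr[2])
        }
      }
    } else if (y < Y_M0) {
      hh <- spec$aperture_height / 2
      zin <- zc >= z0 - hh & zc < z0 + hh
      slot <- outer(zin, rep(TRUE, d[3]), "&") &
        t(outer(abs(xc - x0), gap_half(zc), "<="))
      air <- slot
      plate <- outer(zc >= z0 - 12 & zc < z0 + 12,
                     xc >= x0 - 16 & xc < x0 + 16, "&")
      bone <- plate & !slot
    } else if (y < Y_C) {
      dxr <- mid_dxr(y)
      for (s in c(1, -1))
        air <- air | circle2d(z0 + dj[1], x0 + s * dxr[1] + dj[2], dxr[2])
    } else if (y < Y_E) {
      hh <- spec$naso_height / 2; hw <- spec$naso_width / 2
      air <- outer(zc >= z0 - hh & zc < z0 + hh,
                   xc >= x0 - hw & xc < x0 + hw, "&")
    }

    air <- air & solid & !bone
    slice <- matrix(spec$hu_air, d[1], d[3])
    slice[solid] <- spec$hu_soft
    slice[bone & solid] <- spec$hu_bone
    slice[air] <- spec$hu_air
    vol[, j, ] <- slice
    mask[, j, ] <- air
  }

  if (spec$oropharynx_pocket) {
    pk <- zc >= z0 + 9 & zc <= z0 + 12
    pj <- yc >= 30 & yc <= 40
    px <- abs(xc - x0) <= 5
    vol[pk, pj, px] <- spec$hu_air
  }
  if (spec$bone_speckle) {
    sk <- which.min(abs(zc - z0))
    sj <- which.min(abs(yc - (Y_P - 5)))
    sx <- which.min(abs(xc - (x0 + 6)))
    vol[sk, sj, sx] <- spec$hu_bone
  }

  if (spec$blur_sd > 0)
    vol <- array(.gauss_blur_3d(vol, d, spec$blur_sd / sp), d)
  if (spec$noise_sd > 0) {
    vol <- withr::with_seed(spec$seed, {
      vol + array(rnorm(prod(d), 0, spec$noise_sd), d)
    })
  }
  vol <- array(clamp_hu(vol), d)

  # ---- analytic truth ----
  stair_corr <- function(r) spec$stair_slope * (4 / 3) * r^3
  n_open <- 2 - length(sealed)
  v_nares_tube <- pi * spec$r_nares^2 * (Y_P - spec$taper_length - spec$face_y) -
    stair_corr(spec$r_nares) +
    frustum_volume(spec$taper_length, spec$r_nares, spec$r_ap)
  v_slot <- th * (spec$aperture_gap * spec$aperture_height +
                  spec$gap_taper * (spec$aperture_height - sp[1] / 2)^2 / 2)
  v_mid_tube <- frustum_volume(spec$taper_length, spec$r_ap, spec$r_mid) +
    pi * spec$r_mid^2 * (L_mid - spec$taper_length - sp[2])
  v_naso <- spec$naso_width * spec$naso_height * (Y_E - Y_C) +
    2 * pi * spec$r_mid^2 * sp[2]
  v_isolated <- if (length(sealed)) {
    length(sealed) * (pi * spec$r_nares^2 *
      (snap2(Y_P - spec$taper_length - 2) - (spec$face_y + 2)) -
      stair_corr(spec$r_nares))
  } else 0
  vols <- list(
    nares = n_open * v_nares_tube / 1000,
    midnasal = (v_slot + 2 * v_mid_tube) / 1000,
    nasopharynx = v_naso / 1000,
    isolated = v_isolated / 1000)
  vols$total <- vols$nares + vols$midnasal + vols$nasopharynx

  labels <- array(.cc_label_3d(mask, d, 26L), d)
  sizes <- tabulate(labels)
  if (length(sizes)) {
    relab <- integer(length(sizes))
    relab[order(sizes, decreasing = TRUE)] <- seq_along(sizes)
    labels[] <- ifelse(labels > 0L, relab[pmax(labels, 1L)], 0L)
  }

  truth <- structure(list(
    mask = mask,
    labels = labels,
    volumes_cm3 = vols,
    width_mm = spec$aperture_gap,
    areas_mm2 = list(
      nares = n_open * pi * spec$r_nares^2,
      aperture = spec$aperture_gap * spec$aperture_height +
        spec$gap_taper * (spec$aperture_height - sp[1] / 2)^2 / 2,
      midnasal = 2 * pi * spec$r_mid^2,
      nasopharynx = spec$naso_width * spec$naso_height),
    surface_cm2 = NA_real_,
    landmarks = list(
      tip = floor(d[1] / 2),
      pyriform = as.integer(round(Y_P / sp[2])),
      choanae = as.integer(round(Y_C / sp[2])) - 1L),
    spacing = sp,
    spec = spec), class = "phantom_truth")

  list(volume = ct_volume(vol, sp, meta = list(phantom = TRUE, seed = spec$seed)),
       truth = truth)
}

#' Series of phantoms differing only in pyriform aperture gap
#'
#' @param base_spec A [phantom_spec()] whose `aperture_gap` is replaced.
#' @param aperture_gaps_mm Vector of designed gaps, mm.
#' @param spacing,grid_shape Passed to [generate_phantom()].
#' @return A list of `list(volume, truth)` pairs, one per gap; the analytic
#'   widths equal the requested gaps.
#' @export
stenosis_series <- function(base_spec, aperture_gaps_mm,
                            spacing = c(0.5, 0.3, 0.3), grid_shape = NULL) {
  if (any(aperture_gaps_mm <= 0)) stop("gaps must be positive")
  lapply(aperture_gaps_mm, function(g) {
    s <- base_spec
    s$aperture_gap <- g
    generate_phantom(s, spacing = spacing, grid_shape = grid_shape)
  })
}

#' Spherical-cavity calibration phantom
#'
#' A soft-tissue block with one spherical air cavity; analytic volume
#' `4/3 pi r^3` and surface area `4 pi r^2`.
#'
#' @param radius Cavity radius, mm.
#' @param spacing Voxel spacing, mm.
#' @param margin Tissue margin around the cavity, mm.
#' @return A list with `volume`, `mask`, `volume_cm3`, `surface_cm2`,
#'   `spacing`.
#' @export
phantom_sphere <- function(radius = 5, spacing = c(0.4, 0.4, 0.4), margin = 4) {
  sp <- as.numeric(spacing)
  d <- as.integer(ceiling(2 * (radius + margin) / sp))
  ctr <- d * sp / 2 + 0.31 * sp  # off-lattice centre avoids symmetry artefacts
  zc <- (seq_len(d[1]) - 0.5) * sp[1]
  yc <- (seq_len(d[2]) - 0.5) * sp[2]
  xc <- (seq_len(d[3]) - 0.5) * sp[3]
  mask <- array(FALSE, d)
  offs <- (-2:2) / 5
  for (j in seq_len(d[2])) {
    if (abs(yc[j] - ctr[2]) > radius + sp[2]) next
    acc <- matrix(0L, d[1], d[3])
    for (oz in offs * sp[1])
      for (ox in offs * sp[3]) {
        r2 <- radius^2 - (yc[j] - ctr[2])^2
        if (r2 <= 0) next
        acc <- acc + (outer((zc + oz - ctr[1])^2, (xc + ox - ctr[3])^2, "+") <= r2)
      }
    mask[, j, ] <- acc >= 13L
  }
  vol <- array(40, d)
  vol[mask] <- -1000
  list(volume = ct_volume(vol, sp), mask = mask,
       volume_cm3 = 4 / 3 * pi * radius^3 / 1000,
       surface_cm2 = 4 * pi * radius^2 / 100,
       spacing = sp)
}

#' Twin-tube calibration phantom
#'
#' A soft-tissue block with `n_tubes` parallel, capped cylindrical air
#' passages running anterior to posterior. Analytic volume
#' `n pi r^2 L`, mantle-plus-caps surface `n (2 pi r L + 2 pi r^2)` and a
#' flat combined cross-section `n pi r^2`.
#'
#' @param radius Tube radius, mm.
#' @param length Tube length, mm.
#' @param n_tubes 1 or 2.
#' @param dx Lateral offset of each tube from the midline (two-tube case).
#' @param spacing Voxel spacing, mm.
#' @param margin Tissue margin, mm.
#' @return A list with `volume`, `mask`, analytic quantities and the tube
#'   voxel index range `y_range` (0-based, half-open).
#' @export
phantom_tubes <- function(radius = 2, length = 20, n_tubes = 2, dx = 3.5,
                          spacing = c(0.5, 0.3, 0.3), margin = 4) {
  sp <- as.numeric(spacing)
  y0 <- round(margin / sp[2]) * sp[2]
  y1 <- y0 + round(length / sp[2]) * sp[2]
  len <- y1 - y0
  ext <- c(2 * (radius + margin), y1 + margin,
           2 * (dx * (n_tubes > 1) + radius + margin))
  d <- as.integer(ceiling(ext / sp))
  zc <- (seq_len(d[1]) - 0.5) * sp[1]
  yc <- (seq_len(d[2]) - 0.5) * sp[2]
  xc <- (seq_len(d[3]) - 0.5) * sp[3]
  z0 <- d[1] * sp[1] / 2 + 0.27 * sp[1]
  x0 <- d[3] * sp[3] / 2
  laterals <- if (n_tubes == 2) c(-dx, dx) else 0
  sub <- (-2:2) / 5
  mask <- array(FALSE, d)
  inside <- yc >= y0 & yc < y1
  for (j in which(inside)) {
    dz <- sp[1] * (((j * 0.6180339887) %% 1) - 0.5)
    dxo <- sp[3] * (((j * 0.7548776662) %% 1) - 0.5)
    circ <- matrix(FALSE, d[1], d[3])
    for (o in laterals) {
      acc <- matrix(0L, d[1], d[3])
      for (oz in sub * sp[1])
        for (ox in sub * sp[3])
          acc <- acc + (outer((zc + oz - z0 - dz)^2,
                              (xc + ox - (x0 + o + dxo))^2, "+") <= radius^2)
      circ <- circ | (acc >= 13L)
    }
    mask[, j, ] <- circ
  }
  vol <- array(40, d)
  vol[mask] <- -1000
  list(volume = ct_volume(vol, sp), mask = mask,
       volume_cm3 = n_tubes * pi * radius^2 * len / 1000,
       surface_cm2 = n_tubes * (2 * pi * radius * len + 2 * pi * radius^2) / 100,
       area_mm2 = n_tubes * pi * radius^2,
       y_range = c(min(which(inside)) - 1L, max(which(inside))),
       spacing = sp)
}

#' Cohort of phantom specs mirroring a normal/moderate/severe study
#'
#' Generates per-case [phantom_spec()]s for `n_normal` controls and a
#' stenosis group split into moderate and severe subgroups. Aperture gaps
#' and mid-nasal volumes are drawn around the group means reported for
#' clinical cohorts of this condition (normal gap 11.8 +/- 0.8 mm, moderate
#' 4.5 +/- 0.9, severe 4.4 +/- 1.4; mid-nasal volumes 2.03/1.45/0.79 cm^3),
#' with moderate and severe mid-nasal draws truncated to disjoint ranges so
#' subgroup separation on that parameter is structural. The nostril-tube
#' radius is drawn from one common distribution whose quantiles are
#' interleaved between moderate and severe cases, making that parameter
#' identically distributed across subgroups by construction.
#'
#' @param seed Cohort seed.
#' @param n_normal,n_moderate,n_severe Group sizes.
#' @param noise_sd,blur_sd Imaging-condition parameters applied to every
#'   case.
#' @return A tibble with columns `case_id`, `group` and a `spec`
#'   list-column.
#' @export
cohort_specs <- function(seed = 0, n_normal = 12, n_moderate = 4, n_severe = 6,
                         noise_sd = 20, blur_sd = 0.4) {
  n_sten <- n_moderate + n_severe
  withr::with_seed(seed, {
    gap_n <- pmin(pmax(rnorm(n_normal, 11.8, 0.8), 11.1), 14)
    gap_m <- pmin(pmax(rnorm(n_moderate, 4.5, 0.9), 3.2), 6.5)
    gap_s <- pmin(pmax(rnorm(n_severe, 4.4, 1.4), 3.2), 7.0)
    vmid_n <- pmin(pmax(rnorm(n_normal, 2.03, 0.48), 1.30), 2.90)
    vmid_m <- pmin(pmax(rnorm(n_moderate, 1.45, 0.18), 1.20), 1.80)
    vmid_s <- pmin(pmax(rnorm(n_severe, 0.79, 0.40), 0.30), 1.10)
    r_from_v <- function(v) sqrt(1000 * v / (2 * pi * 20))
    rn_norm <- 2.6 + rnorm(n_normal, 0, 0.15)
    # common jitter for the stenosis cases, interleaved across subgroups
    jit <- qnorm(ppoints(n_sten), 0, 0.15)
    mod_ranks <- round(seq(2, n_sten - 1, length.out = n_moderate))
    rn_m <- 2.6 + jit[mod_ranks]
    rn_s <- 2.6 + jit[setdiff(seq_len(n_sten), mod_ranks)]
    nh <- pmax(5.5 + rnorm(n_normal + n_sten, 0, 0.35), 4)
  })
  groups <- c(rep("normal", n_normal), rep("moderate", n_moderate),
              rep("severe", n_severe))
  gaps <- c(gap_n, gap_m, gap_s)
  rmid <- r_from_v(c(vmid_n, vmid_m, vmid_s))
  rnar <- c(rn_norm, rn_m, rn_s)
  specs <- lapply(seq_along(groups), function(i) {
    phantom_spec(aperture_gap = gaps[i], r_mid = rmid[i], r_nares = rnar[i],
                 naso_height = nh[i], noise_sd = noise_sd, blur_sd = blur_sd,
                 seed = (seed %% 1000L) * 1000L + i)
  })
  tibble::tibble(
    case_id = sprintf("case_%02d", seq_along(groups)),
    group = groups,
    spec = specs)
}
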