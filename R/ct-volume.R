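#' Calibrated CT volume
#'
#' Container for a 3-D grid of Hounsfield units with physical voxel spacing
#' and a fixed anatomical axis convention: array dimension 1 runs superior to
#' inferior (axial slices), dimension 2 anterior to posterior, dimension 3
#' right to left. Voxel `i` (0-based) is centred at `(i + 0.5) * spacing`.
#'
#' @param voxels 3-D numeric array of Hounsfield units.
#' @param spacing Numeric length-3 vector of voxel edge lengths in mm,
#'   ordered (axial slice, anterior-posterior, right-left).
#' @param meta Optional list of free-form acquisition metadata.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, meta = list()) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3-D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive voxel edge lengths in mm")
  rng <- range(voxels)
  if (rng[1] < -1024 || rng[2] > 3071)
    stop("HU values must lie in [-1024, 3071] after calibration; got [",
         rng[1], ", ", rng[2], "]")
  structure(
    list(voxels = voxels, spacing = spacing,
         axes = c("superior-inferior", "anterior-posterior", "right-left"),
         meta = meta),
    class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat("<ct_volume> ", paste(d, collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm (SI x AP x RL)\n", sep = "")
  cat("  HU range [", min(x$voxels), ", ", max(x$voxels), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

#' Physical volume of one voxel in mm^3
#' @param x A `ct_volume` or any object with a numeric `spacing` field.
#' @return Voxel volume in mm^3.
#' @export
voxel_volume <- function(x) {
  sp <- if (is.list(x)) x$spacing else x
  prod(sp)
}

clamp_hu <- function(v) pmin(pmax(v, -1024), 3071)

#' Rigid reorientation about the anterior-posterior and right-left axes
#'
#' Head-tilt correction expressed as explicit rotation angles rather than an
#' interactive step. HU values are resampled with trilinear interpolation
#' (nearest neighbour for masks); spacing is unchanged and voxels rotated in
#' from outside the grid are filled with -1024 HU.
#'
#' @param volume A [ct_volume()].
#' @param ap_deg Rotation in degrees about the anterior-posterior axis
#'   (in the axial/coronal "roll" plane). Magnitude must be <= 45.
#' @param lr_deg Rotation in degrees about the right-left axis ("pitch").
#'   Magnitude must be <= 45.
#' @param method `"linear"` (HU volumes) or `"nearest"` (label/mask volumes).
#' @return A reoriented `ct_volume`.
#' @export
reorient <- function(volume, ap_deg = 0, lr_deg = 0, method = c("linear", "nearest")) {
  stopifnot(inherits(volume, "ct_volume"))
  method <- match.arg(method)
  if (abs(ap_deg) > 45 || abs(lr_deg) > 45)
    stop("rotation angles must satisfy |angle| <= 45 degrees")
  if (ap_deg == 0 && lr_deg == 0) return(volume)

  d <- dim(volume$voxels)
  sp <- volume$spacing
  a <- ap_deg * pi / 180
  b <- lr_deg * pi / 180
  # rotation about AP axis mixes (SI, RL); rotation about RL axis mixes (SI, AP)
  R_ap <- matrix(c(cos(a), 0, -sin(a),
                   0,      1,  0,
                   sin(a), 0,  cos(a)), 3, 3, byrow = TRUE)
  R_lr <- matrix(c(cos(b), -sin(b), 0,
                   sin(b),  cos(b), 0,
                   0,       0,      1), 3, 3, byrow = TRUE)
  R <- R_lr %*% R_ap
  Rinv <- t(R)  # orthogonal

  centre <- (d * sp) / 2
  i1 <- ((seq_len(d[1]) - 0.5) * sp[1]) - centre[1]
  i2 <- ((seq_len(d[2]) - 0.5) * sp[2]) - centre[2]
  i3 <- ((seq_len(d[3]) - 0.5) * sp[3]) - centre[3]
  g1 <- rep(i1, times = d[2] * d[3])
  g2 <- rep(rep(i2, each = d[1]), times = d[3])
  g3 <- rep(i3, each = d[1] * d[2])

  s1 <- Rinv[1, 1] * g1 + Rinv[1, 2] * g2 + Rinv[1, 3] * g3 + centre[1]
  s2 <- Rinv[2, 1] * g1 + Rinv[2, 2] * g2 + Rinv[2, 3] * g3 + centre[2]
  s3 <- Rinv[3, 1] * g1 + Rinv[3, 2] * g2 + Rinv[3, 3] * g3 + centre[3]
  rm(g1, g2, g3)

  # continuous voxel coordinates (0-based, at voxel centres)
  f1 <- s1 / sp[1] - 0.5
  f2 <- s2 / sp[2] - 0.5
  f3 <- s3 / sp[3] - 0.5
  out <- rep(-1024, prod(d))
  v <- volume$voxels

  if (method == "nearest") {
    n1 <- round(f1); n2 <- round(f2); n3 <- round(f3)
    ok <- n1 >= 0 & n1 <= d[1] - 1 & n2 >= 0 & n2 <= d[2] - 1 & n3 >= 0 & n3 <= d[3] - 1
    idx <- n1[ok] + d[1] * (n2[ok] + d[2] * n3[ok]) + 1
    out[ok] <- v[idx]
  } else {
    ok <- f1 >= 0 & f1 <= d[1] - 1 & f2 >= 0 & f2 <= d[2] - 1 & f3 >= 0 & f3 <= d[3] - 1
    a1 <- floor(pmin(f1[ok], d[1] - 1 - 1e-9)); t1 <- f1[ok] - a1
    a2 <- floor(pmin(f2[ok], d[2] - 1 - 1e-9)); t2 <- f2[ok] - a2
    a3 <- floor(pmin(f3[ok], d[3] - 1 - 1e-9)); t3 <- f3[ok] - a3
    b1 <- pmin(a1 + 1, d[1] - 1); b2 <- pmin(a2 + 1, d[2] - 1); b3 <- pmin(a3 + 1, d[3] - 1)
    at <- function(x, y, z) v[x + d[1] * (y + d[2] * z) + 1]
    out[ok] <-
      (1 - t1) * (1 - t2) * (1 - t3) * at(a1, a2, a3) +
      t1       * (1 - t2) * (1 - t3) * at(b1, a2, a3) +
      (1 - t1) * t2       * (1 - t3) * at(a1, b2, a3) +
      t1       * t2       * (1 - t3) * at(b1, b2, a3) +
      (1 - t1) * (1 - t2) * t3       * at(a1, a2, b3) +
      t1       * (1 - t2) * t3       * at(b1, a2, b3) +
      (1 - t1) * t2       * t3       * at(a1, b2, b3) +
      t1       * t2       * t3       * at(b1, b2, b3)
  }
  ct_volume(array(clamp_hu(out), d), sp, meta = volume$meta)
}
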