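# Validation metrics and group-comparison statistics.

as_mask_array <- function(x) {
  if (inherits(x, "airway_mask")) return(main_mask(x))
  if (is.list(x) && !is.null(x$mask)) return(x$mask)
  x
}

#' Dice overlap coefficient
#'
#' `2|A n B| / (|A| + |B|)`; symmetric, 1 iff the masks are identical.
#' Two empty masks are defined to agree perfectly (Dice 1).
#'
#' @param mask_a,mask_b Logical arrays of equal shape (or `airway_mask`s,
#'   whose main component is used).
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  a <- as_mask_array(mask_a); b <- as_mask_array(mask_b)
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Segmentation sensitivity
#'
#' Fraction of reference-mask voxels recovered by the automatic mask:
#' `|auto n ref| / |ref|`. Asymmetric; the reference must be non-empty.
#'
#' @param mask_auto,mask_ref Logical arrays of equal shape (or
#'   `airway_mask`s).
#' @return Sensitivity in `[0, 1]`.
#' @export
sensitivity <- function(mask_auto, mask_ref) {
  a <- as_mask_array(mask_auto); r <- as_mask_array(mask_ref)
  if (!identical(dim(a), dim(r))) stop("mask shapes differ")
  nr <- sum(r)
  if (nr == 0) stop("reference mask is empty")
  sum(a & r) / nr
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test: exact distribution for combined samples of at
#' most 20 without ties, tie-corrected normal approximation otherwise. The
#' U statistic is reported for the first group; swapping the groups maps
#' `U` to `n1*n2 - U` with an identical p-value.
#'
#' @param group_x,group_y Numeric vectors, each non-empty.
#' @return A one-row tibble `U`, `p_value`, `n_x`, `n_y`, `method`.
#' @export
mann_whitney <- function(group_x, group_y) {
  if (!length(group_x) || !length(group_y)) stop("both groups must be non-empty")
  if (length(unique(c(group_x, group_y))) == 1L) {
    # fully tied data carry no ordering information: no separation, p = 1
    return(tibble::tibble(U = length(group_x) * length(group_y) / 2,
                          p_value = 1, n_x = length(group_x),
                          n_y = length(group_y), method = "degenerate"))
  }
  ties <- any(duplicated(c(group_x, group_y)))
  exact <- !ties && (length(group_x) + length(group_y)) <= 20
  wt <- suppressWarnings(
    wilcox.test(group_x, group_y, exact = exact, correct = TRUE))
  tibble::tibble(U = unname(wt$statistic), p_value = wt$p.value,
                 n_x = length(group_x), n_y = length(group_y),
                 method = if (exact) "exact" else "normal approximation")
}

#' Validation metrics for one automatic/reference mask pair
#'
#' @param mask_auto Automatic `airway_mask` or logical array.
#' @param mask_ref Reference mask (phantom truth or manual segmentation).
#' @param width_auto_mm,width_ref_mm Optional aperture widths for the
#'   agreement statistics.
#' @return A one-row tibble with Dice, sensitivity and width differences
#'   (mm and percent).
#' @export
validation_metrics <- function(mask_auto, mask_ref,
                               width_auto_mm = NA_real_, width_ref_mm = NA_real_) {
  tibble::tibble(
    dice = dice(mask_auto, mask_ref),
    sensitivity = sensitivity(mask_auto, mask_ref),
    width_difference_mm = width_auto_mm - width_ref_mm,
    width_difference_pct = 100 * (width_auto_mm - width_ref_mm) / width_ref_mm)
}

#' Group comparison of morphometry parameters
#'
#' For every numeric parameter in the case reports, computes group means
#' and standard deviations for the normal/moderate/severe groups and the
#' three Mann-Whitney contrasts: `p_a` moderate vs normal, `p_b` severe vs
#' normal, `p_c` severe vs moderate — the diagnostic contrasts against
#' controls and the severity contrast within stenosis cases. Raw two-sided
#' p-values are reported per contrast without multiplicity correction.
#'
#' @param reports Tibble of case reports (one row per case, as produced by
#'   [morphometry_report()], bound together), with a `case_id` column.
#' @param groups Tibble with `case_id` and `group` in
#'   `c("normal", "moderate", "severe")`.
#' @param alpha Significance level for the convenience flags.
#' @return A tibble of class `group_comparison`, one row per parameter.
#' @export
compare_groups <- function(reports, groups, alpha = 0.05) {
  if (!all(groups$group %in% c("normal", "moderate", "severe")))
    stop("unknown group label: ",
         paste(setdiff(unique(groups$group), c("normal", "moderate", "severe")),
               collapse = ", "))
  missing <- setdiff(groups$case_id, reports$case_id)
  if (length(missing))
    stop("groups reference missing case(s): ", paste(missing, collapse = ", "))
  dat <- dplyr::inner_join(reports, groups, by = "case_id")
  params <- setdiff(names(dat)[vapply(dat, is.numeric, TRUE)], "case_id")
  pull <- function(p, g) dat[[p]][dat$group == g & !is.na(dat[[p]])]
  contrast <- function(x, y) {
    if (!length(x) || !length(y)) return(c(NA_real_, NA_real_))
    mw <- mann_whitney(x, y)
    c(mw$U, mw$p_value)
  }
  rows <- lapply(params, function(p) {
    no <- pull(p, "normal"); mo <- pull(p, "moderate"); se <- pull(p, "severe")
    ca <- contrast(mo, no); cb <- contrast(se, no); cc <- contrast(se, mo)
    tibble::tibble(
      parameter = p,
      mean_normal = if (length(no)) mean(no) else NA_real_,
      sd_normal = if (length(no) > 1) sd(no) else NA_real_,
      mean_moderate = if (length(mo)) mean(mo) else NA_real_,
      sd_moderate = if (length(mo) > 1) sd(mo) else NA_real_,
      mean_severe = if (length(se)) mean(se) else NA_real_,
      sd_severe = if (length(se) > 1) sd(se) else NA_real_,
      U_a = ca[1], p_a = ca[2],
      U_b = cb[1], p_b = cb[2],
      U_c = cc[1], p_c = cc[2],
      sig_a = !is.na(ca[2]) & ca[2] < alpha,
      sig_b = !is.na(cb[2]) & cb[2] < alpha,
      sig_c = !is.na(cc[2]) & cc[2] < alpha)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("group_comparison", class(out))
  attr(out, "n_groups") <- c(table(groups$group))
  out
}

#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(
    n_parameters = nrow(x),
    n_significant_a = sum(x$sig_a, na.rm = TRUE),
    n_significant_b = sum(x$sig_b, na.rm = TRUE),
    n_significant_c = sum(x$sig_c, na.rm = TRUE))
}
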