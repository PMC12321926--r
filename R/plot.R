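# ggplot2 displays for profiles and cohorts.

#' @importFrom rlang .data
NULL

#' Plot a cross-sectional-area profile
#'
#' Combined cross-sectional area of the airway against percent of cavity
#' length, with the pyriform and choanae planes marked on the full-cavity
#' axis.
#'
#' @param object A `nasal_profile` from [cross_section_profile()].
#' @param axis `"full"` (nostrils to posterior nasopharyngeal wall) or
#'   `"midnasal"` (pyriform to choanae).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nasal_profile <- function(object, axis = c("full", "midnasal"), ...) {
  axis <- match.arg(axis)
  dat <- dplyr::filter(object$curves, .data$axis == !!axis)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$pct, y = .data$area_mm2)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#1f5d99") +
    ggplot2::labs(x = paste0("Position along ",
                             if (axis == "full") "cavity" else "mid-nasal axis",
                             " (%)"),
                  y = expression("Cross-sectional area" ~ (mm^2))) +
    ggplot2::theme_minimal()
  if (axis == "full") {
    lm <- object$landmarks
    marks <- object$by_slice$pct_full[match(c(lm$pyriform, lm$choanae),
                                            object$by_slice$coronal)]
    p <- p + ggplot2::geom_vline(xintercept = marks, linetype = "dashed",
                                 colour = "grey40")
  }
  p
}

#' @rdname autoplot.nasal_profile
#' @param profile A `nasal_profile`.
#' @export
plot_profile <- function(profile, axis = "full") autoplot(profile, axis = axis)

#' Group-mean cross-sectional-area profiles
#'
#' Mean +/- one standard deviation of the full-cavity percent profile per
#' group, on the common 101-point percent grid.
#'
#' @param cohort A `nasal_cohort` from [run_cohort()].
#' @param axis `"full"` or `"midnasal"`.
#' @return A ggplot object.
#' @export
plot_group_profiles <- function(cohort, axis = "full") {
  dat <- dplyr::bind_rows(lapply(names(cohort$profiles), function(id) {
    cv <- cohort$profiles[[id]]$curves
    cv <- dplyr::filter(cv, .data$axis == !!axis)
    cv$case_id <- id
    cv
  }))
  dat <- dplyr::inner_join(dat, cohort$groups, by = "case_id")
  summ <- dat |>
    dplyr::group_by(.data$group, .data$pct) |>
    dplyr::summarise(mean_area = mean(.data$area_mm2, na.rm = TRUE),
                     sd_area = sd(.data$area_mm2, na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$pct, y = .data$mean_area,
                                     colour = .data$group, fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_area - .data$sd_area,
                                      ymax = .data$mean_area + .data$sd_area),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::labs(x = "Position along cavity (%)",
                  y = expression("Cross-sectional area" ~ (mm^2)),
                  colour = "Group", fill = "Group") +
    ggplot2::theme_minimal()
}
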