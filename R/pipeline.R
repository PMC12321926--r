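# End-to-end drivers: one case (segment -> landmarks -> morphometry) and a
# labelled cohort with group statistics.

read_any_volume <- function(x) {
  if (inherits(x, "ct_volume")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (dir.exists(x)) return(read_dicom_series(x))
    if (file.exists(x)) return(read_nifti(x))
    stop("input volume not found: ", x)
  }
  stop("expected a ct_volume, a NIfTI path or a DICOM directory")
}

input_hash <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x) && !dir.exists(x))
    return(unname(tools::md5sum(x)))
  NA_character_
}

#' Run the full pipeline on one case
#'
#' Segments the airway, detects landmarks, and computes the morphometry
#' report. When `output_dir` is given, the label mask, report (JSON and
#' CSV), profile CSV, profile plot and a run manifest are written there;
#' partial outputs are removed if any stage fails.
#'
#' @param volume A [ct_volume()], a NIfTI path or a DICOM directory.
#' @param config A [nasal_config()] or a config file path.
#' @param case_id Case identifier.
#' @param output_dir Optional output directory.
#' @return A list of class `nasal_case`: `mask`, `landmarks`, `morphometry`
#'   (a [morphometry_report()]), `report` (its one-row tibble), `manifest`.
#' @export
run_case <- function(volume, config = nasal_config(), case_id = "case",
                     output_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  t0 <- proc.time()[["elapsed"]]
  vol <- read_any_volume(volume)
  timings <- c(load = proc.time()[["elapsed"]] - t0)

  stage <- function(name, expr) {
    t <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    timings[[name]] <<- proc.time()[["elapsed"]] - t
    out
  }
  mask <- stage("segment", segment_airway(vol, config))
  landmarks <- stage("landmarks", detect_landmarks(vol, mask, config))
  morpho <- stage("morphometry",
                  morphometry_report(vol, mask, landmarks, config, case_id))

  manifest <- list(
    package_version = as.character(utils::packageVersion("neonasal")),
    case_id = case_id,
    input = if (is.character(volume)) volume else "<in-memory volume>",
    input_md5 = input_hash(volume),
    config = unclass(config),
    timings_s = as.list(round(unlist(timings), 3)),
    landmarks = unclass(landmarks))
  out <- structure(list(mask = mask, landmarks = landmarks,
                        morphometry = morpho, report = morpho$report,
                        manifest = manifest),
                   class = "nasal_case")
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    written <- character(0)
    tryCatch({
      p <- file.path(output_dir, paste0(case_id, "_labels.nii.gz"))
      write_mask(mask, p); written <- c(written, p)
      p <- file.path(output_dir, paste0(case_id, "_report.json"))
      jsonlite::write_json(c(as.list(morpho$report),
                             list(landmarks = unclass(landmarks))),
                           p, auto_unbox = TRUE, digits = NA)
      written <- c(written, p)
      p <- file.path(output_dir, paste0(case_id, "_report.csv"))
      utils::write.csv(morpho$report, p, row.names = FALSE)
      written <- c(written, p)
      p <- file.path(output_dir, paste0(case_id, "_profile.csv"))
      utils::write.csv(morpho$profile$curves, p, row.names = FALSE)
      written <- c(written, p)
      p <- file.path(output_dir, paste0(case_id, "_profile.png"))
      grDevices::png(p, width = 900, height = 500)
      print(autoplot(morpho$profile))
      grDevices::dev.off()
      written <- c(written, p)
      manifest$outputs <- written
      out$manifest <- manifest
      jsonlite::write_json(manifest,
                           file.path(output_dir, paste0(case_id, "_manifest.json")),
                           auto_unbox = TRUE, digits = NA, null = "null")
    }, error = function(e) {
      unlink(written)
      stop("writing outputs failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  out
}

#' @export
print.nasal_case <- function(x, ...) {
  cat("<nasal_case> ", x$report$case_id, "\n", sep = "")
  print(x$morphometry)
  invisible(x)
}

#' @export
tidy.nasal_case <- function(x, ...) tidy(x$morphometry)

#' Run the pipeline on a labelled cohort
#'
#' Runs [run_case()] on every case, binds the per-case reports, and when at
#' least two groups are present computes the group comparison. Failed cases
#' are reported with a warning and the statistics are computed on the
#' successes.
#'
#' @param cases Named list of inputs accepted by [run_case()] (names become
#'   case ids), or a tibble with columns `case_id` and `volume`.
#' @param groups Tibble with `case_id` and `group`.
#' @param config A [nasal_config()].
#' @param output_dir Optional directory for per-case outputs.
#' @return A list of class `nasal_cohort`: `reports` (tibble), `comparison`
#'   (or `NULL` for a single group), `profiles` (per-case profile list),
#'   `failures`.
#' @export
run_cohort <- function(cases, groups, config = nasal_config(),
                       output_dir = NULL) {
  if (is.data.frame(cases)) {
    ids <- cases$case_id
    inputs <- cases$volume
  } else {
    ids <- names(cases)
    if (is.null(ids)) ids <- sprintf("case_%02d", seq_along(cases))
    inputs <- cases
  }
  missing <- setdiff(groups$case_id, ids)
  if (length(missing))
    stop("group labels reference missing case(s): ",
         paste(missing, collapse = ", "))
  results <- vector("list", length(inputs))
  failures <- character(0)
  for (i in seq_along(inputs)) {
    results[[i]] <- tryCatch(
      run_case(inputs[[i]], config, case_id = ids[i], output_dir = output_dir),
      error = function(e) {
        warning("case ", ids[i], " failed: ", conditionMessage(e), call. = FALSE)
        failures <<- c(failures, ids[i])
        NULL
      })
  }
  ok <- !vapply(results, is.null, TRUE)
  if (!any(ok)) stop("all cases failed")
  reports <- dplyr::bind_rows(lapply(results[ok], `[[`, "report"))
  groups_ok <- dplyr::filter(groups, .data$case_id %in% reports$case_id)
  comparison <- if (length(unique(groups_ok$group)) >= 2)
    compare_groups(reports, groups_ok) else NULL
  profiles <- setNames(lapply(results[ok], function(r) r$morphometry$profile),
                       reports$case_id)
  structure(list(reports = reports, comparison = comparison,
                 profiles = profiles, groups = groups_ok,
                 failures = failures),
            class = "nasal_cohort")
}

#' @export
print.nasal_cohort <- function(x, ...) {
  cat("<nasal_cohort> ", nrow(x$reports), " case(s)",
      if (length(x$failures)) paste0(", ", length(x$failures), " failed") else "",
      "\n", sep = "")
  if (!is.null(x$comparison)) {
    cat("groups:", paste(names(attr(x$comparison, "n_groups")),
                         attr(x$comparison, "n_groups"), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.nasal_cohort <- function(x, ...) {
  if (is.null(x$comparison)) stop("cohort has a single group; no comparison")
  x$comparison
}

#' @export
glance.nasal_cohort <- function(x, ...) {
  tibble::tibble(n_cases = nrow(x$reports),
                 n_failed = length(x$failures),
                 n_groups = length(unique(x$groups$group)))
}
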