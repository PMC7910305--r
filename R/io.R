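#' Write a confusion-matrix report to JSON
#'
#' @param cm a [validate()] result.
#' @param path output path (`confusion.json` by convention).
#' @export
write_confusion_json <- function(cm, path) {
  stopifnot(inherits(cm, "confusion_matrix"))
  obj <- list(
    counts = as.data.frame.matrix(cm$table),
    overall_accuracy = cm$overall_accuracy,
    producers_accuracy = as.list(cm$producers_accuracy),
    users_accuracy = as.list(cm$users_accuracy),
    mean_class_accuracy = cm$mean_class_accuracy,
    kappa = cm$kappa,
    n = cm$n
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Write a threshold scheme to JSON
#'
#' @param scheme a [threshold_scheme()].
#' @param path output path (`scheme.json` by convention).
#' @export
write_scheme_json <- function(scheme, path) {
  stopifnot(inherits(scheme, "threshold_scheme"))
  obj <- list(intervals = scheme$intervals, cuts = scheme$cuts,
              merged = list(b_water = scheme$b_water,
                            b_woody = scheme$b_woody))
  jsonlite::write_json(obj, path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write batch regime-shift results to JSON and a segments CSV
#'
#' @param batch a [batch_dynamics()] result.
#' @param json_path output JSON path (`regime_shifts.json`).
#' @param segments_csv optional CSV path for per-site segments
#'   (site, seg_start, seg_end, mean, var, modal_class).
#' @export
write_regime_json <- function(batch, json_path, segments_csv = NULL) {
  stopifnot(inherits(batch, "batch_dynamics"))
  per_site <- lapply(batch$results, function(r) {
    if (inherits(r, "regime_shift_failure"))
      return(list(id = r$id, error = r$error))
    list(id = r$id,
         shift_date = if (is.na(r$shift_date)) NULL else format(r$shift_date),
         shift_index = if (is.na(r$shift_index)) NULL else r$shift_index,
         pre_class = r$pre_class, post_class = r$post_class,
         return_fraction = r$return_fraction)
  })
  jsonlite::write_json(list(sites = per_site,
                            shift_years = as.list(batch$shift_years)),
                       json_path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  if (!is.null(segments_csv)) {
    segs <- do.call(rbind, lapply(names(batch$changepoints), function(id) {
      cp <- batch$changepoints[[id]]
      if (is.null(cp)) return(NULL)
      r <- batch$results[[id]]
      modal <- if (inherits(r, "regime_shift_failure")) NA_character_
               else r$segment_classes
      data.frame(site = id, seg_start = cp$segments$start,
                 seg_end = cp$segments$end, mean = cp$segments$mean,
                 var = cp$segments$var, modal_class = modal,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(segs, segments_csv, row.names = FALSE, quote = FALSE)
  }
  invisible(json_path)
}

#' Write a nest-relation fit report to JSON
#'
#' @param fit a [nest_evi_fit()] result.
#' @param path output path (`fit_report.json` by convention).
#' @export
write_fit_report_json <- function(fit, path) {
  stopifnot(inherits(fit, "nest_evi_fit"))
  cand <- lapply(fit$fits, function(f)
    list(form = f$form,
         intercept = unname(f$coefficients[1]),
         slope = unname(f$coefficients[2]),
         r_squared = f$r_squared, p_slope = f$p_slope,
         log_shift = if (is.na(f$log_shift)) NULL else f$log_shift))
  obj <- list(candidates = cand, selected = fit$selected$form,
              mean_subsample_p = fit$bootstrap$mean_p,
              settings = fit$bootstrap[c("n_boot", "subsample_fraction",
                                         "seed", "n_skipped")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Write a multi-year nesting summary to JSON
#'
#' @param table a `nest_table`.
#' @param path output path (`nesting_summary.json` by convention).
#' @export
write_nesting_summary_json <- function(table, path) {
  stopifnot(inherits(table, "nest_table"))
  years <- sort(unique(table$year))
  jsonlite::write_json(lapply(years, function(y) summarize_year(table, y)),
                       path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}
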