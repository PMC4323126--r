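# Comparison report across surface-coil correction modes: the statistics
# used to compare No-SCIC, PD-SCIC and SSFP-SCIC on one study, and paired
# t-tests across a group of studies.

#' Build the mode-comparison report for one study
#'
#' For each quantified mode, computes the myocardial CoV of the corrected
#' reference image, MBF spatial heterogeneity, sector means, the
#' septal-lateral difference, and (when a territory assignment is given)
#' remote/ischaemic territory MBF and their difference. Paired t-tests need
#' several studies and are attached by [compare_reports()]; a single-study
#' report carries an explanatory note instead.
#'
#' @param runs Named list (names among `"none"`, `"pd"`, `"ssfp"`), each
#'   element a quantified run: `list(reference, myo_mask, map, labels)` with
#'   a 2D reference image (corrected for the fitted modes, uncorrected for
#'   `"none"`), the myocardial [roi_mask()], an `mbf_map_result` and
#'   [segment_labels()]. [quantify_study()] returns this shape.
#' @param assignment Optional [territory_assignment()].
#' @return Object of class `comparison_report`.
#' @export
build_report <- function(runs, assignment = NULL) {
  known <- c("none", "pd", "ssfp")
  if (length(runs) == 0L || is.null(names(runs)) ||
      !all(names(runs) %in% known))
    stop("runs must be a named list with names among none/pd/ssfp")
  notes <- character(0)
  missing_modes <- setdiff(known, names(runs))
  if (length(missing_modes))
    notes <- c(notes, paste0("modes not run: ",
                             paste(missing_modes, collapse = ", "),
                             "; their contrasts are omitted"))
  per_mode <- lapply(runs, function(r) {
    sm <- sector_stats(r$map, r$labels)
    out <- list(
      cov_reference_pct = cov_si(r$reference, r$myo_mask),
      heterogeneity_pct = heterogeneity(r$map),
      sector_means = as.list(sm),
      septal_lateral_diff = septal_lateral_difference(sm))
    if (!is.null(assignment)) {
      ri <- remote_ischaemic_difference(sm, assignment)
      out$remote_mbf <- ri$remote
      out$ischaemic_mbf <- ri$ischaemic
      out$remote_ischaemic_diff <- ri$difference
    }
    out
  })
  notes <- c(notes,
             "paired t-tests require a group of studies; see compare_reports()")
  structure(list(modes = names(runs), per_mode = per_mode,
                 diseased = if (is.null(assignment)) NULL else
                   assignment$diseased,
                 paired_tests = NULL, notes = notes),
            class = "comparison_report")
}

#' Paired t-tests across a group of study reports
#'
#' For every statistic shared by a pair of modes, runs the paired t-test
#' across studies and attaches `(t, df, p)` to a group-level report.
#'
#' @param reports List of `comparison_report`s over the same modes (one per
#'   study, >= 2).
#' @return Object of class `comparison_report` with group means and
#'   `paired_tests` filled in; p-values are also rounded to 3 decimals in
#'   `p_3dp` for display.
#' @export
compare_reports <- function(reports) {
  if (length(reports) < 2L) stop("need at least 2 study reports")
  modes <- Reduce(intersect, lapply(reports, function(r) r$modes))
  if (length(modes) == 0L) stop("reports share no modes")
  stat_names <- c("cov_reference_pct", "heterogeneity_pct",
                  "septal_lateral_diff", "remote_ischaemic_diff")
  pull <- function(mode, stat)
    vapply(reports, function(r) {
      v <- r$per_mode[[mode]][[stat]]
      if (is.null(v)) NA_real_ else v
    }, numeric(1))
  per_mode <- lapply(setNames(modes, modes), function(m) {
    vals <- lapply(setNames(stat_names, stat_names), function(s) {
      v <- pull(m, s)
      if (all(is.na(v))) NULL else
        list(mean = mean(v), sd = sd(v), n = sum(!is.na(v)))
    })
    vals[!vapply(vals, is.null, logical(1))]
  })
  tests <- list()
  if (length(modes) >= 2L) {
    pairs <- utils::combn(modes, 2, simplify = FALSE)
    for (pr in pairs) for (s in stat_names) {
      a <- pull(pr[1], s); b <- pull(pr[2], s)
      if (any(is.na(a)) || any(is.na(b))) next
      tt <- paired_t_test(a, b)
      tests[[paste(s, pr[1], "vs", pr[2], sep = "_")]] <-
        list(t = tt$t, df = tt$df, p = tt$p, p_3dp = round(tt$p, 3))
    }
  }
  structure(list(modes = modes, n_studies = length(reports),
                 per_mode = per_mode, paired_tests = tests,
                 notes = character(0)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> modes:", paste(x$modes, collapse = ", "), "\n")
  for (m in x$modes) {
    pm <- x$per_mode[[m]]
    h <- pm$heterogeneity_pct
    if (is.list(h)) h <- h$mean
    if (!is.null(h)) cat(sprintf("  %-5s heterogeneity %.1f%%\n", m, h))
  }
  invisible(x)
}

#' Write a comparison report to JSON (and optionally CSV)
#'
#' @param report A `comparison_report`.
#' @param path_json Output JSON path.
#' @param path_csv Optional CSV path (one row per mode and statistic).
#' @return `path_json`, invisibly.
#' @export
write_report <- function(report, path_json, path_csv = NULL) {
  jsonlite::write_json(unclass(report), path_json, auto_unbox = TRUE,
                       digits = NA, null = "null")
  if (!is.null(path_csv)) {
    rows <- list()
    for (m in report$modes) {
      pm <- report$per_mode[[m]]
      for (s in names(pm)) {
        v <- pm[[s]]
        if (is.list(v) && !is.null(v$mean)) v <- v$mean
        if (is.list(v)) next  # sector_means handled below
        rows[[length(rows) + 1L]] <-
          data.frame(mode = m, statistic = s, value = as.double(v))
      }
      if (!is.null(pm$sector_means))
        for (s in names(pm$sector_means))
          rows[[length(rows) + 1L]] <-
            data.frame(mode = m, statistic = paste0("sector_mean_", s),
                       value = as.double(pm$sector_means[[s]]))
    }
    write.csv(do.call(rbind, rows), path_csv, row.names = FALSE)
  }
  invisible(path_json)
}
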