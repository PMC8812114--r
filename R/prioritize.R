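# Mapping bioactive fractions to chromatographic retention-time windows and
# selecting the annotated features that co-elute with the bioactivity.
#
# Each fraction covers a 13.5 s interval of the LC run. An error margin of
# 6.5 s (about half the fraction length) on both sides absorbs the small
# mechanical offset between the MS instrument and the fraction collector, so
# an unclipped selection window is 26.5 s long.

#' Retention-time window of a fraction
#'
#' @param i Fraction index 1-80.
#' @param duration Fraction length in seconds (default 13.5).
#' @param margin Error margin in seconds added on both sides (default 6.5).
#' @param t0 Fractionation start offset in seconds (default 0).
#' @param run_end Upper clip bound in seconds (default `Inf`: selection
#'   windows are clipped at 0 only).
#' @return A one-row data.frame: `fraction`, `core_start_s`, `core_end_s`,
#'   `midpoint_s`, `sel_start_s`, `sel_end_s`.
#' @examples
#' fraction_window(1)   # core 0-13.5 s, midpoint 6.75 s
#' fraction_window(80)  # core ends at 1080 s
#' @export
fraction_window <- function(i, duration = 13.5, margin = 6.5, t0 = 0,
                            run_end = Inf) {
  if (any(is.na(i)) || any(i < 1) || any(i > 80)) stop("fraction index out of 1-80")
  core_start <- t0 + (i - 1) * duration
  core_end <- t0 + i * duration
  data.frame(
    fraction = as.integer(i),
    core_start_s = core_start,
    core_end_s = core_end,
    midpoint_s = (core_start + core_end) / 2,
    sel_start_s = pmax(0, core_start - margin),
    sel_end_s = pmin(run_end, core_end + margin)
  )
}

#' Windows for a set of bioactive fractions
#'
#' @param fractions Integer vector of bioactive fraction indices.
#' @inheritParams fraction_window
#' @return data.frame with one row per fraction (see [fraction_window()]).
#' @export
fraction_windows <- function(fractions, duration = 13.5, margin = 6.5, t0 = 0,
                             run_end = Inf) {
  fraction_window(fractions, duration, margin, t0, run_end)
}

#' Select annotated features inside bioactive retention-time windows
#'
#' A feature is selected when its retention time lies inside at least one
#' selection window (closed interval: boundary features belong to both
#' adjacent windows, so a compound eluting on a fraction break is reported
#' under both fractions). Selected features are ranked by confidence level,
#' then by mean intensity (descending).
#'
#' @param annotations An `annotation_table` (see [annotate_table()]); only
#'   primary annotations are used unless `primary_only = FALSE`.
#' @param windows data.frame of windows from [fraction_windows()].
#' @param primary_only Keep only primary candidates (default TRUE).
#' @return data.frame: the selected annotation rows with an added `fraction`
#'   column (one row per feature x window hit) and a `rank` column.
#' @export
select_features <- function(annotations, windows, primary_only = TRUE) {
  empty <- annotations[0, , drop = FALSE]
  empty$fraction <- integer(0); empty$rank <- integer(0)
  if (!nrow(windows) || !nrow(annotations)) return(empty)
  ann <- if (primary_only) annotations[annotations$primary_flag, , drop = FALSE]
         else annotations
  if (!nrow(ann)) return(empty)
  hits <- list()
  for (w in seq_len(nrow(windows))) {
    inside <- ann$rt_s >= windows$sel_start_s[w] & ann$rt_s <= windows$sel_end_s[w]
    if (any(inside)) {
      h <- ann[inside, , drop = FALSE]
      h$fraction <- windows$fraction[w]
      hits[[length(hits) + 1L]] <- h
    }
  }
  if (!length(hits)) return(empty)
  out <- do.call(rbind, hits)
  out <- out[order(level_rank(out$level), -out$mean_intensity, out$feature_id), ,
             drop = FALSE]
  out$rank <- seq_len(nrow(out))
  stopifnot(all(vapply(seq_len(nrow(out)), function(k) {
    w <- windows[windows$fraction == out$fraction[k], ]
    out$rt_s[k] >= w$sel_start_s && out$rt_s[k] <= w$sel_end_s
  }, logical(1))))
  rownames(out) <- NULL
  out
}

#' Build the prioritization report
#'
#' Per-fraction breakdown in the shape of a bioactive-fraction summary table:
#' total feature count, names of level 1 / 2a / 2b annotations, counts of
#' level 3 / 4* / 4 / 5 annotations with summed isomer counts for the
#' formula-level classes, plus polyhalogenated-risk flags and the active
#' regions.
#'
#' @param prioritized Output of [select_features()].
#' @param hit_result Output of [call_hits()] (optional; adds regions and
#'   per-fraction responses).
#' @return A `prioritization_report`: list with `per_fraction` (data.frame),
#'   `names_by_level` (nested list), `polyhalo_features` (character),
#'   `regions`.
#' @export
build_report <- function(prioritized, hit_result = NULL) {
  fracs <- sort(unique(prioritized$fraction))
  per_fraction <- do.call(rbind, lapply(fracs, function(f) {
    p <- prioritized[prioritized$fraction == f, , drop = FALSE]
    cnt <- function(lv) sum(p$level == lv)
    iso <- function(lv) sum(p$isomer_count[p$level == lv], na.rm = TRUE)
    data.frame(fraction = f, n = nrow(p),
               level_1 = cnt("1"), level_2a = cnt("2a"), level_2b = cnt("2b"),
               level_3 = cnt("3"),
               level_4s = cnt("4*"), level_4s_isomers = iso("4*"),
               level_4 = cnt("4"), level_4_isomers = iso("4"),
               level_5 = cnt("5"),
               polyhalo_flags = sum(p$polyhalo_risk %in% TRUE))
  }))
  if (is.null(per_fraction))
    per_fraction <- data.frame(fraction = integer(0), n = integer(0))
  names_by_level <- lapply(fracs, function(f) {
    p <- prioritized[prioritized$fraction == f, , drop = FALSE]
    lapply(stats::setNames(nm = c("1", "2a", "2b")),
           function(lv) p$suspect[p$level == lv & !is.na(p$suspect)])
  })
  names(names_by_level) <- as.character(fracs)
  structure(list(
    per_fraction = per_fraction,
    names_by_level = names_by_level,
    polyhalo_features = unique(prioritized$feature_id[prioritized$polyhalo_risk %in% TRUE]),
    regions = if (!is.null(hit_result)) hit_result$regions else NULL,
    fraction_responses = if (!is.null(hit_result)) hit_result$fractions else NULL
  ), class = "prioritization_report")
}

#' @export
print.prioritization_report <- function(x, ...) {
  cat("<prioritization_report>\n")
  print(x$per_fraction)
  if (length(x$polyhalo_features))
    cat("polyhalogenated-risk features:",
        paste(x$polyhalo_features, collapse = ", "), "\n")
  invisible(x)
}

#' Write a prioritization report to CSV + JSON
#'
#' @param report A `prioritization_report`.
#' @param csv_path,json_path Output paths (either may be NULL to skip).
#' @return Invisibly, the report.
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(report$per_fraction, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(per_fraction = report$per_fraction,
           names_by_level = report$names_by_level,
           polyhalo_features = report$polyhalo_features,
           regions = report$regions),
      json_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}
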