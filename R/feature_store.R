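# Feature tables and suspect lists: the data model of the screening workflow.
#
# A feature table is a data.frame of class `feature_table` with columns
#   feature_id (unique), ion_mode ("+"/"-"), mz (Da), rt (seconds),
#   blank_intensity (NA when no blank is available), msms_recorded (logical),
#   intensity_1 .. intensity_k (per-injection peak areas)
# plus optional in-memory list-columns `msms` (msms_spectrum) and
# `isotope_peaks` (isotope_pattern) attached by the simulator or the MGF
# linker; these are not serialized to CSV.

.intensity_cols <- function(df) grep("^intensity_[0-9]+$", names(df), value = TRUE)

#' Construct a feature table
#'
#' @param df data.frame with the schema columns (see Details).
#' @param ion_mode Single ion mode of the table; defaults to the `ion_mode`
#'   column value.
#' @param label Optional table label (matrix / injection tag).
#' @return A `feature_table` (data.frame subclass).
#' @export
feature_table <- function(df, ion_mode = NULL, label = "") {
  req <- c("feature_id", "ion_mode", "mz", "rt")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop(sprintf("missing required column '%s'", miss[1]))
  if (anyDuplicated(df$feature_id)) stop("duplicate feature_id in table")
  if (length(unique(df$ion_mode)) > 1) stop("a feature table holds a single ion mode")
  if (any(df$mz <= 0)) stop("mz must be > 0")
  if (any(df$rt < 0)) stop("rt must be >= 0")
  if (!"blank_intensity" %in% names(df)) df$blank_intensity <- NA_real_
  if (!"msms_recorded" %in% names(df)) df$msms_recorded <- FALSE
  ic <- .intensity_cols(df)
  if (!length(ic)) stop("missing required column 'intensity_1'")
  if (any(unlist(df[ic]) < 0, na.rm = TRUE)) stop("intensities must be >= 0")
  attr(df, "label") <- label
  attr(df, "mode") <- if (is.null(ion_mode)) as.character(df$ion_mode[1]) else ion_mode
  class(df) <- unique(c("feature_table", class(df)))
  df
}

#' Read / write feature-table CSVs
#'
#' The CSV schema is `feature_id, ion_mode, mz, rt, blank_intensity,
#' msms_recorded, intensity_1..intensity_k`, plus an optional `isotopes`
#' column holding the measured isotope envelope as semicolon-separated
#' `mz:relative_intensity` pairs (parsed into the `isotope_peaks`
#' list-column). Retention time is stored internally in seconds; declare
#' `rt_unit = "min"` when the file carries minutes.
#'
#' @param path CSV path.
#' @param rt_unit `"s"` (default) or `"min"`.
#' @return `read_feature_table()`: a `feature_table`.
#' @export
read_feature_table <- function(path, rt_unit = c("s", "min")) {
  rt_unit <- match.arg(rt_unit)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("feature_id", "ion_mode", "mz", "rt")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop(sprintf("missing required column '%s' in %s", miss[1], path))
  if (rt_unit == "min") df$rt <- df$rt * 60
  if ("msms_recorded" %in% names(df)) df$msms_recorded <- as.logical(df$msms_recorded)
  iso <- NULL
  if ("isotopes" %in% names(df)) {
    iso <- lapply(df$isotopes, .parse_isotope_text)
    df$isotopes <- NULL
  }
  out <- feature_table(df, label = basename(path))
  if (!is.null(iso)) out$isotope_peaks <- iso
  out
}

.parse_isotope_text <- function(txt) {
  if (is.na(txt) || !nzchar(txt)) return(NULL)
  parts <- strsplit(strsplit(txt, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  as_isotope_pattern(vapply(parts, function(p) as.numeric(p[1]), numeric(1)),
                     vapply(parts, function(p) as.numeric(p[2]), numeric(1)))
}

.isotope_text <- function(pattern) {
  if (is.null(pattern) || !nrow(pattern)) return("")
  paste(sprintf("%.6f:%.6g", pattern$mz, pattern$rel_intensity), collapse = ";")
}

#' @rdname read_feature_table
#' @param table A `feature_table`.
#' @export
write_feature_table <- function(table, path) {
  cols <- c("feature_id", "ion_mode", "mz", "rt", "blank_intensity",
            "msms_recorded", .intensity_cols(table))
  df <- as.data.frame(table)[cols]
  if ("isotope_peaks" %in% names(table))
    df$isotopes <- vapply(table$isotope_peaks, .isotope_text, character(1))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a suspect-list CSV
#'
#' Columns: `name`, `formula` (Hill notation), `list_class` (`SL` spectral
#' library / `AL` analyte suspect list / `AL+` in-house standards with
#' recorded retention times), optional `rt_min` (expected RT in minutes),
#' optional `adducts` (semicolon-separated, default both protonated forms),
#' optional `spectra_file` (MSP with library spectra keyed by `name`).
#'
#' @param path CSV path.
#' @param name List name; default file stem.
#' @param rank Position in the hierarchical application order.
#' @return A `suspect_list`: list with `name`, `rank`, `entries` (list of
#'   `suspect_entry`).
#' @export
read_suspect_list <- function(path, name = NULL, rank = 1L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("name", "formula", "list_class")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop(sprintf("missing required column '%s' in %s", miss[1], path))
  spectra <- list()
  if ("spectra_file" %in% names(df)) {
    for (f in unique(stats::na.omit(df$spectra_file))) {
      if (nzchar(f)) spectra <- c(spectra, read_msp(file.path(dirname(path), f)))
    }
  }
  entries <- lapply(seq_len(nrow(df)), function(i) {
    suspect_entry(
      name = df$name[i],
      formula = parse_formula(df$formula[i]),
      list_class = df$list_class[i],
      expected_rt = if ("rt_min" %in% names(df) && !is.na(df$rt_min[i]))
        df$rt_min[i] * 60 else NA_real_,
      adducts = if ("adducts" %in% names(df) && !is.na(df$adducts[i]) && nzchar(df$adducts[i]))
        strsplit(df$adducts[i], ";")[[1]] else c("[M+H]+", "[M-H]-"),
      library_spectra = spectra[names(spectra) == df$name[i]]
    )
  })
  suspect_list(if (is.null(name)) sub("\\.csv$", "", basename(path)) else name,
               entries, rank = rank)
}

#' Construct a suspect entry
#'
#' @param name Compound name.
#' @param formula `element_composition`.
#' @param list_class `"SL"`, `"AL"` or `"AL+"`.
#' @param expected_rt Expected retention time in seconds (NA when unknown).
#' @param adducts Character vector of adduct ids to consider.
#' @param library_spectra List of `msms_spectrum` (possibly empty).
#' @return A `suspect_entry`.
#' @export
suspect_entry <- function(name, formula, list_class,
                          expected_rt = NA_real_,
                          adducts = c("[M+H]+", "[M-H]-"),
                          library_spectra = list()) {
  if (!list_class %in% c("SL", "AL", "AL+"))
    stop(sprintf("unknown list_class '%s'", list_class))
  structure(list(name = name, formula = formula, list_class = list_class,
                 expected_rt = expected_rt, adducts = adducts,
                 library_spectra = library_spectra),
            class = "suspect_entry")
}

#' Construct a suspect list
#'
#' @param name List name.
#' @param entries List of `suspect_entry`.
#' @param rank Hierarchy rank (lower = applied earlier; unique per hierarchy).
#' @return A `suspect_list`.
#' @export
suspect_list <- function(name, entries, rank = 1L) {
  stopifnot(all(vapply(entries, inherits, logical(1), "suspect_entry")))
  structure(list(name = name, rank = as.integer(rank), entries = entries),
            class = "suspect_list")
}

#' Group replicate-injection feature tables
#'
#' Tolerance-based grouping of features across injections of the same sample:
#' features whose m/z agrees within `mz_tol_ppm` and retention time within
#' `rt_tol_s` are merged into one feature carrying a per-injection intensity
#' vector (0 where the feature was absent), the mean m/z, and the mean RT.
#' This assumes near-aligned inputs (exported tables are RT-aligned upstream);
#' it is a grouper, not an alignment algorithm.
#'
#' @param tables List of single-injection `feature_table`s, same ion mode.
#' @param mz_tol_ppm m/z tolerance in ppm (default 10).
#' @param rt_tol_s RT tolerance in seconds (default 6).
#' @return A merged `feature_table` with one intensity column per input table.
#' @export
group_replicates <- function(tables, mz_tol_ppm = 10, rt_tol_s = 6) {
  if (!length(tables)) stop("need at least one table")
  modes <- vapply(tables, function(t) attr(t, "mode"), character(1))
  if (length(unique(modes)) > 1) stop("mixed ion modes across tables")
  n_inj <- length(tables)
  # seed groups from the first table, then greedily attach nearest matches
  groups <- lapply(seq_len(nrow(tables[[1]])), function(i) {
    list(mz = tables[[1]]$mz[i], rt = tables[[1]]$rt[i],
         id = tables[[1]]$feature_id[i],
         blank = tables[[1]]$blank_intensity[i],
         msms = tables[[1]]$msms_recorded[i],
         intens = c(tables[[1]][[.intensity_cols(tables[[1]])[1]]][i],
                    rep(0, n_inj - 1L)))
  })
  if (n_inj > 1) for (t in 2:n_inj) {
    tab <- tables[[t]]
    icol <- .intensity_cols(tab)[1]
    gmz <- vapply(groups, `[[`, numeric(1), "mz")
    grt <- vapply(groups, `[[`, numeric(1), "rt")
    taken <- logical(length(groups))
    for (i in seq_len(nrow(tab))) {
      dppm <- abs(gmz - tab$mz[i]) / gmz * 1e6
      drt <- abs(grt - tab$rt[i])
      ok <- which(!taken & dppm <= mz_tol_ppm & drt <= rt_tol_s)
      if (length(ok)) {
        j <- ok[which.min(dppm[ok] / mz_tol_ppm + drt[ok] / max(rt_tol_s, 1e-9))]
        taken[j] <- TRUE
        g <- groups[[j]]
        k <- sum(g$intens > 0)
        g$mz <- (g$mz * k + tab$mz[i]) / (k + 1)
        g$rt <- (g$rt * k + tab$rt[i]) / (k + 1)
        g$msms <- g$msms || isTRUE(tab$msms_recorded[i])
        if (is.na(g$blank)) g$blank <- tab$blank_intensity[i]
        g$intens[t] <- tab[[icol]][i]
        groups[[j]] <- g
      } else {
        groups[[length(groups) + 1L]] <- list(
          mz = tab$mz[i], rt = tab$rt[i], id = tab$feature_id[i],
          blank = tab$blank_intensity[i], msms = tab$msms_recorded[i],
          intens = replace(rep(0, n_inj), t, tab[[icol]][i]))
        gmz <- c(gmz, tab$mz[i]); grt <- c(grt, tab$rt[i]); taken <- c(taken, TRUE)
      }
    }
  }
  intens <- do.call(rbind, lapply(groups, `[[`, "intens"))
  colnames(intens) <- paste0("intensity_", seq_len(n_inj))
  out <- data.frame(
    feature_id = vapply(groups, `[[`, character(1), "id"),
    ion_mode = modes[1],
    mz = vapply(groups, `[[`, numeric(1), "mz"),
    rt = vapply(groups, `[[`, numeric(1), "rt"),
    blank_intensity = vapply(groups, function(g) as.numeric(g$blank), numeric(1)),
    msms_recorded = vapply(groups, function(g) isTRUE(g$msms), logical(1)),
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(intens))
  if (anyDuplicated(out$feature_id))
    out$feature_id <- make.unique(out$feature_id, sep = "_rep")
  feature_table(out, ion_mode = modes[1], label = "grouped")
}

#' Blank-ratio inclusion filter
#'
#' A feature passes when its aggregated sample intensity is at least `ratio`
#' times the blank intensity (inclusive, so exactly 3x blank passes at the
#' default). Returns `NA` when no blank intensity is available.
#'
#' @param intensities Per-injection sample intensities.
#' @param blank_intensity Blank intensity (NA if absent).
#' @param ratio Required sample/blank ratio (default 3).
#' @param aggregate `"mean"` (default) or `"max"` across injections.
#' @return `TRUE`, `FALSE` or `NA` (not evaluable).
#' @export
blank_ratio_pass <- function(intensities, blank_intensity, ratio = 3,
                             aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  if (is.na(blank_intensity)) return(NA)
  agg <- if (aggregate == "mean") mean(intensities) else max(intensities)
  if (blank_intensity == 0) return(agg > 0)
  agg >= ratio * blank_intensity
}

#' Replicate-CV inclusion filter
#'
#' Coefficient of variation (sample SD / mean, in %) over the injections in
#' which the feature was detected. Requires at least two nonzero injections;
#' single-injection data are not evaluable (returned as `NA`), matching how
#' single-injection processing skips this criterion.
#'
#' @param intensities Per-injection intensities.
#' @param max_cv Maximum CV in percent (default 20).
#' @return `TRUE`, `FALSE` or `NA`.
#' @export
cv_pass <- function(intensities, max_cv = 20) {
  x <- intensities[intensities > 0]
  if (length(x) < 2) return(NA)
  cv <- stats::sd(x) / mean(x) * 100
  cv <= max_cv
}

#' Replicate CV in percent
#' @inheritParams cv_pass
#' @return CV in percent over nonzero injections, or `NA` when fewer than two.
#' @export
replicate_cv <- function(intensities) {
  x <- intensities[intensities > 0]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / mean(x) * 100
}
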