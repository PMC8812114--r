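# Hierarchical suspect annotation with a total annotation quality (TAQ) code
# and Schymanski-style identification confidence levels.
#
# Default matching thresholds: mass deviation <= 10 ppm, RT deviation
# <= 0.2 min, isotopic fit mSigma <= 100, MS/MS library score >= 600. The
# TAQ code additionally records the feature-inclusion criteria (sample >= 3x
# blank; replicate CV <= 20%).

#' Default annotation thresholds
#'
#' @return Named list: `ppm` (10), `ppm_strict` (5), `rt_min` (0.2),
#'   `rt_min_strict` (0.1), `msigma` (100), `msigma_strict` (25),
#'   `msms_score` (600), `blank_ratio` (3), `max_cv` (20).
#' @export
annotation_thresholds <- function() {
  list(ppm = 10, ppm_strict = 5,
       rt_min = 0.2, rt_min_strict = 0.1,
       msigma = 100, msigma_strict = 25,
       msms_score = 600, blank_ratio = 3, max_cv = 20)
}

#' Confidence-level ordering
#'
#' Schymanski-style scale: 1 (confirmed by reference standard) > 2a (library
#' spectrum match) > 2b (diagnostic evidence) > 3 (tentative candidate) >
#' 4* (molecular formula, MS/MS recorded) > 4 (molecular formula) > 5 (exact
#' mass only).
#'
#' @return Character vector of levels, best first.
#' @export
confidence_levels <- function() c("1", "2a", "2b", "3", "4*", "4", "5")

#' Numeric rank of a confidence level (1 = best)
#' @param level Character level(s).
#' @return Integer rank(s); smaller is stronger evidence.
#' @export
level_rank <- function(level) {
  r <- match(level, confidence_levels())
  if (anyNA(r)) stop(sprintf("unknown confidence level '%s'", level[is.na(r)][1]))
  r
}

#' Match one feature against one suspect entry
#'
#' Tries every configured adduct compatible with the feature's ion mode and
#' keeps the one with the smallest absolute mass error. No match when every
#' adduct is off by more than the ppm threshold. RT is compared only when the
#' suspect has a recorded expected RT; the isotopic fit is computed only when
#' the feature carries a measured isotope envelope; the MS/MS score is the
#' maximum over the suspect's library spectra.
#'
#' @param mz,rt,ion_mode Feature m/z (Da), RT (s), ion mode.
#' @param suspect A `suspect_entry`.
#' @param isotope_peaks Optional measured `isotope_pattern` of the feature.
#' @param msms Optional measured `msms_spectrum`.
#' @param msms_recorded Was an MS/MS spectrum recorded for the feature?
#' @param intensities,blank_intensity Feature intensity data for the
#'   inclusion criteria.
#' @param thresholds See [annotation_thresholds()].
#' @return A `match_evidence` list, or `NULL` when no adduct matches:
#'   `adduct`, `ppm_error`, `rt_dev_min` (NA when no expected RT), `msigma`
#'   (NA without envelope), `msms_score` (NA without both spectra),
#'   `msms_recorded`, `blank_pass`, `cv_pass`.
#' @export
match_feature <- function(mz, rt, ion_mode, suspect,
                          isotope_peaks = NULL, msms = NULL,
                          msms_recorded = FALSE,
                          intensities = numeric(0), blank_intensity = NA_real_,
                          thresholds = annotation_thresholds()) {
  tbl <- adduct_table()
  adducts <- intersect(suspect$adducts, tbl$adduct)
  adducts <- adducts[tbl$charge_sign[match(adducts, tbl$adduct)] ==
                       (if (ion_mode == "+") 1L else -1L)]
  if (!length(adducts)) return(NULL)
  theo <- vapply(adducts, function(a) adduct_mz(suspect$formula, a), numeric(1))
  errs <- ppm_error(mz, theo)
  best <- which.min(abs(errs))
  if (abs(errs[best]) > thresholds$ppm) return(NULL)

  rt_dev <- if (!is.na(suspect$expected_rt)) abs(rt - suspect$expected_rt) / 60 else NA_real_
  msig <- if (!is.null(isotope_peaks) && nrow(isotope_peaks)) {
    theo_pat <- isotope_pattern(suspect$formula)
    theo_pat$mz <- theo_pat$mz +
      adduct_table()$delta_mass[match(adducts[best], adduct_table()$adduct)]
    msigma(isotope_peaks, theo_pat, tol_ppm = 2 * thresholds$ppm)
  } else NA_real_
  score <- NA_real_
  if (!is.null(msms) && length(suspect$library_spectra)) {
    compatible <- Filter(function(s) s$ion_mode == ion_mode, suspect$library_spectra)
    if (length(compatible))
      score <- max(vapply(compatible, function(s)
        spectral_match_score(msms, s, tol_ppm = thresholds$ppm), numeric(1)))
  }
  structure(list(
    adduct = adducts[best],
    ppm_error = unname(errs[best]),
    rt_dev_min = rt_dev,
    msigma = msig,
    msms_score = score,
    msms_recorded = isTRUE(msms_recorded) || !is.null(msms),
    blank_pass = if (length(intensities))
      blank_ratio_pass(intensities, blank_intensity, thresholds$blank_ratio) else NA,
    cv_pass = if (length(intensities)) cv_pass(intensities, thresholds$max_cv) else NA
  ), class = "match_evidence")
}

#' Total annotation quality (TAQ) code
#'
#' Six symbols, one per criterion in fixed order (mass, RT, isotope fit,
#' MS/MS, blank ratio, replicate CV). Each symbol is `2` (strict pass), `1`
#' (loose pass), `0` (fail) or `-` (not evaluable). Tiers: mass 2 at
#' |ppm| <= 5, 1 at <= 10; RT 2 at <= 0.1 min, 1 at <= 0.2 min; isotope fit 2
#' at mSigma <= 25, 1 at <= 100; MS/MS 2 when recorded with library score
#' >= 600, 1 when recorded without a qualifying library match, 0 when not
#' recorded; blank and CV are pass/fail only.
#'
#' @param ev A `match_evidence`.
#' @param thresholds See [annotation_thresholds()].
#' @return Six-character TAQ string, e.g. `"221122"`.
#' @export
taq_code <- function(ev, thresholds = annotation_thresholds()) {
  tier <- function(value, strict, loose, absent_symbol = "-") {
    if (is.na(value)) return(absent_symbol)
    if (value <= strict) "2" else if (value <= loose) "1" else "0"
  }
  mass <- tier(abs(ev$ppm_error), thresholds$ppm_strict, thresholds$ppm, "0")
  rt <- tier(ev$rt_dev_min, thresholds$rt_min_strict, thresholds$rt_min)
  iso <- tier(ev$msigma, thresholds$msigma_strict, thresholds$msigma)
  msms <- if (!isTRUE(ev$msms_recorded)) "0"
    else if (!is.na(ev$msms_score) && ev$msms_score >= thresholds$msms_score) "2"
    else "1"
  pf <- function(x) if (is.na(x)) "-" else if (isTRUE(x)) "2" else "0"
  paste0(mass, rt, iso, msms, pf(ev$blank_pass), pf(ev$cv_pass))
}

.taq_at <- function(taq, i) substr(taq, i, i)
.taq_ge <- function(sym, v) sym %in% c("1", "2") && as.integer(sym) >= v

#' Assign an identification confidence level from a TAQ code
#'
#' Rules: level 1 = AL+ entry with mass, RT and isotope fit at least loosely
#' passing and a qualifying library MS/MS match; 2a = spectral-library (SL)
#' entry with passing mass and a qualifying MS/MS match; 2b = AL+ with
#' passing mass, RT and isotope fit but no qualifying MS/MS match (diagnostic
#' evidence); 4* = molecular-formula evidence (mass + isotope fit) with MS/MS
#' recorded; 4 = the same without MS/MS; 5 = exact mass only. Level 3 is
#' reached only by [boost_level()]. Entries whose class-specific evidence is
#' incomplete fall through to the formula/mass rules.
#'
#' @param taq Six-character TAQ string.
#' @param list_class `"SL"`, `"AL"` or `"AL+"`.
#' @return A confidence level string.
#' @export
assign_level <- function(taq, list_class) {
  stopifnot(nchar(taq) == 6)
  mass <- .taq_at(taq, 1); rt <- .taq_at(taq, 2); iso <- .taq_at(taq, 3)
  msms <- .taq_at(taq, 4)
  mass1 <- .taq_ge(mass, 1); rt1 <- .taq_ge(rt, 1); iso1 <- .taq_ge(iso, 1)
  if (list_class == "AL+" && mass1 && rt1 && iso1)
    return(if (msms == "2") "1" else "2b")
  if (list_class == "SL" && mass1 && msms == "2")
    return("2a")
  if (mass1 && iso1)
    return(if (msms %in% c("1", "2")) "4*" else "4")
  "5"
}

#' Annotate a feature table against a suspect-list hierarchy
#'
#' Applies every list in the hierarchy to every feature. Each matching
#' feature x suspect pair yields an annotation with evidence, TAQ code and
#' confidence level; the annotation with the highest level is flagged as the
#' primary candidate (ties broken by a composite evidence score, then by
#' suspect name). Features matching nothing are emitted as level-5 records.
#'
#' @param table A `feature_table` (optionally with `msms` / `isotope_peaks`
#'   list-columns).
#' @param hierarchy List of `suspect_list` objects (applied in rank order).
#' @param thresholds See [annotation_thresholds()].
#' @return data.frame of class `annotation_table` with columns `feature_id`,
#'   `mode`, `mz`, `rt_s`, `mean_intensity`, `suspect`, `list`, `list_class`,
#'   `adduct`, `ppm`, `rt_dev_min`, `msigma`, `msms_score`, `taq`, `level`,
#'   `isomer_count`, `polyhalo_risk`, `primary_flag`.
#' @export
annotate_table <- function(table, hierarchy, thresholds = annotation_thresholds()) {
  if (!length(hierarchy)) stop("hierarchy must contain at least one suspect list")
  stopifnot(all(vapply(hierarchy, inherits, logical(1), "suspect_list")))
  hierarchy <- hierarchy[order(vapply(hierarchy, `[[`, integer(1), "rank"))]
  ic <- .intensity_cols(table)
  rows <- list()
  for (i in seq_len(nrow(table))) {
    intens <- as.numeric(table[i, ic])
    iso_meas <- if ("isotope_peaks" %in% names(table)) table$isotope_peaks[[i]] else NULL
    msms_i <- if ("msms" %in% names(table)) table$msms[[i]] else NULL
    polyhalo <- if (!is.null(iso_meas) && nrow(iso_meas) > 0)
      !monoisotopic_is_base(iso_meas) else NA
    cand <- list()
    for (sl in hierarchy) {
      for (entry in sl$entries) {
        ev <- match_feature(table$mz[i], table$rt[i], as.character(table$ion_mode[i]),
                            entry, isotope_peaks = iso_meas, msms = msms_i,
                            msms_recorded = isTRUE(table$msms_recorded[i]),
                            intensities = intens,
                            blank_intensity = table$blank_intensity[i],
                            thresholds = thresholds)
        if (is.null(ev)) next
        taq <- taq_code(ev, thresholds)
        cand[[length(cand) + 1L]] <- data.frame(
          feature_id = table$feature_id[i], mode = as.character(table$ion_mode[i]),
          mz = table$mz[i], rt_s = table$rt[i], mean_intensity = mean(intens),
          suspect = entry$name, list = sl$name, list_class = entry$list_class,
          adduct = ev$adduct, ppm = ev$ppm_error, rt_dev_min = ev$rt_dev_min,
          msigma = ev$msigma, msms_score = ev$msms_score,
          taq = taq, level = assign_level(taq, entry$list_class),
          isomer_count = count_isomers(entry, sl),
          polyhalo_risk = polyhalo, primary_flag = FALSE,
          stringsAsFactors = FALSE)
      }
    }
    if (!length(cand)) {
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = table$feature_id[i], mode = as.character(table$ion_mode[i]),
        mz = table$mz[i], rt_s = table$rt[i], mean_intensity = mean(intens),
        suspect = NA_character_, list = NA_character_, list_class = NA_character_,
        adduct = NA_character_, ppm = NA_real_, rt_dev_min = NA_real_,
        msigma = NA_real_, msms_score = NA_real_, taq = NA_character_,
        level = "5", isomer_count = NA_integer_,
        polyhalo_risk = polyhalo, primary_flag = TRUE,
        stringsAsFactors = FALSE)
    } else {
      df <- do.call(rbind, cand)
      comp <- .composite_evidence_score(df)
      ord <- order(level_rank(df$level), comp, df$suspect, df$list)
      df$primary_flag[ord[1]] <- TRUE
      rows[[length(rows) + 1L]] <- df
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("annotation_table", "data.frame")
  out
}

# Composite evidence score for equal-level tie-breaks: smaller is better.
# Absent components contribute 0 so evidence that was never evaluable is
# neither rewarded nor punished.
.composite_evidence_score <- function(df) {
  z <- function(x) ifelse(is.na(x), 0, x)
  z(abs(df$ppm)) / 10 + z(df$rt_dev_min) / 0.2 + z(df$msigma) / 100 -
    z(df$msms_score) / 1000
}

#' Count same-formula isomers of a suspect within its list
#'
#' @param suspect A `suspect_entry`.
#' @param list A `suspect_list` (non-empty).
#' @return Number of entries with the identical molecular formula (>= 1,
#'   includes the suspect itself).
#' @export
count_isomers <- function(suspect, list) {
  if (!length(list$entries)) stop("empty suspect list")
  target <- formula_string(suspect$formula)
  sum(vapply(list$entries, function(e) formula_string(e$formula) == target,
             logical(1)))
}

#' Reduce isomer candidates with retention-prediction boxes
#'
#' Keeps candidates whose predicted retention time falls in applicability-
#' domain box 1 (experimental and predicted RT match with the smallest
#' error). The reduction fraction is `1 - n_box1 / (n_total - n_box4)`:
#' box-4 candidates (outliers whose retention behaviour the predictor cannot
#' estimate) are excluded from the denominator but flagged for
#' reconsideration should no box-1 candidate be confirmed; candidates with no
#' prediction stay in the denominator.
#'
#' @param candidates data.frame with columns `candidate` and `box` (`1:4` or
#'   `NA` for unpredicted); optional `predicted_rt_s`.
#' @return List: `kept` (box-1 subset of `candidates`), `reduction_fraction`
#'   (`NA` and `undefined = TRUE` when every candidate is box 4),
#'   `reconsider` (box-4 subset).
#' @export
reduce_candidates <- function(candidates) {
  if (!nrow(candidates)) stop("need at least one candidate")
  box <- candidates$box
  n_all <- nrow(candidates)
  n_box4 <- sum(!is.na(box) & box == 4)
  n_box1 <- sum(!is.na(box) & box == 1)
  denom <- n_all - n_box4
  list(
    kept = candidates[!is.na(box) & box == 1, , drop = FALSE],
    reduction_fraction = if (denom > 0) 1 - n_box1 / denom else NA_real_,
    undefined = denom == 0,
    reconsider = candidates[!is.na(box) & box == 4, , drop = FALSE]
  )
}

#' Boost a level-4* annotation to level 3
#'
#' A tentative-candidate (level 3) call requires converging orthogonal
#' evidence: the candidate's predicted retention time must fall in
#' applicability-domain box 1 and at least `min_matched` measured fragments
#' must match its in-silico fragments (default 2, the two most intense
#' fragments).
#'
#' @param level Current confidence level; must be `"4*"`.
#' @param box Applicability-domain box of the candidate (1-4, NA if
#'   unpredicted).
#' @param frag A `fragment_match` result.
#' @param min_matched Minimum matched fragments (default 2).
#' @return `"3"` when boosted, otherwise `"4*"` unchanged.
#' @export
boost_level <- function(level, box, frag, min_matched = 2) {
  if (!identical(level, "4*"))
    stop("boost_level applies only to level 4* annotations")
  if (!is.na(box) && box == 1 && frag$n_matched_peaks >= min_matched) "3" else "4*"
}
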