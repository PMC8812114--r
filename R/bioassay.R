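# 96-well micro-fraction plate processing. The LC eluate is fractionated into
# 80 wells (positions A3-H12) of the assay plate; columns 1-2 hold controls.
# Fraction indexing is row-major from A3: A3 -> 1, A12 -> 10, ..., H12 -> 80.

#' Map a well position to its fraction index
#'
#' @param well Well id like `"B7"`; must lie in A3-H12.
#' @return Fraction index 1-80 (row-major from A3).
#' @examples
#' well_to_fraction("A3")   # 1
#' well_to_fraction("H12")  # 80
#' @export
well_to_fraction <- function(well) {
  vapply(well, function(w) {
    m <- regmatches(w, regexec("^([A-H])([0-9]{1,2})$", w))[[1]]
    if (length(m) == 0L) stop(sprintf("malformed well id '%s'", w))
    row <- match(m[2], LETTERS[1:8])
    col <- as.integer(m[3])
    if (col < 3 || col > 12)
      stop(sprintf("well '%s' is not a fraction well (columns 1-2 are controls)", w))
    (row - 1L) * 10L + (col - 2L)
  }, integer(1), USE.NAMES = FALSE)
}

#' Map a fraction index back to its well position
#'
#' Inverse of [well_to_fraction()].
#' @param fraction Fraction index 1-80.
#' @return Well id.
#' @export
fraction_to_well <- function(fraction) {
  vapply(fraction, function(f) {
    if (is.na(f) || f < 1 || f > 80) stop(sprintf("fraction index %s out of 1-80", f))
    f <- as.integer(f)
    sprintf("%s%d", LETTERS[1:8][(f - 1L) %/% 10L + 1L], (f - 1L) %% 10L + 3L)
  }, character(1), USE.NAMES = FALSE)
}

#' Read a plate-readout CSV
#'
#' Columns: `well`, `role` (`fraction`, `pb_fraction`, `solvent_control`,
#' `assay_control`), `replicate`, `raw_response`.
#'
#' @param path CSV path.
#' @return data.frame with an added `fraction` column (NA for control wells).
#' @export
read_plate <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("well", "role", "replicate", "raw_response")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop(sprintf("missing required column '%s' in %s", miss[1], path))
  df$fraction <- NA_integer_
  fr <- df$role %in% c("fraction", "pb_fraction")
  df$fraction[fr] <- well_to_fraction(df$well[fr])
  df
}

#' Normalize raw plate responses
#'
#' Growth assay (bacterial growth inhibition): percent viability =
#' `100 * raw / mean(solvent controls)`. Binding assay (competitive
#' fluorescence displacement): percent inhibition =
#' `100 * (1 - raw / mean(controls))`. Both are invariant to a uniform
#' detector gain.
#'
#' @param plate data.frame from [read_plate()].
#' @param assay `"growth"` or `"binding"`.
#' @param control_role Role of the normalization controls
#'   (default `"solvent_control"`).
#' @return data.frame of `fraction_result`s: one row per fraction x replicate
#'   with `fraction`, `replicate`, `response` (% viability or % inhibition),
#'   plus the per-fraction mean in attribute-free long form.
#' @export
normalize_plate <- function(plate, assay = c("growth", "binding"),
                            control_role = "solvent_control") {
  assay <- match.arg(assay)
  ctrl <- plate$raw_response[plate$role == control_role]
  if (!length(ctrl)) stop(sprintf("no control wells with role '%s'", control_role))
  cm <- mean(ctrl)
  if (!is.finite(cm) || cm == 0) stop("control mean is zero or undefined")
  fr <- plate[plate$role %in% c("fraction", "pb_fraction"), , drop = FALSE]
  resp <- if (assay == "growth") 100 * fr$raw_response / cm
          else 100 * (1 - fr$raw_response / cm)
  out <- data.frame(fraction = fr$fraction, replicate = fr$replicate,
                    role = fr$role, response = resp, stringsAsFactors = FALSE)
  out[order(out$fraction, out$replicate), , drop = FALSE]
}

#' Growth-assay hit threshold from the procedure blank
#'
#' The antibiotic-assay hit threshold is the mean procedure-blank response
#' minus three sample standard deviations of the procedure-blank responses
#' over all fractions.
#'
#' @param pb_responses Normalized procedure-blank responses (>= 3 values).
#' @return Threshold (same units as the responses).
#' @export
antibiotic_hit_threshold <- function(pb_responses) {
  if (length(pb_responses) < 3) stop("need at least 3 procedure-blank values")
  mean(pb_responses) - 3 * stats::sd(pb_responses)
}

#' Call bioactive fractions and group active regions
#'
#' Growth assay: a fraction is a hit when its mean response (viability) falls
#' below the procedure-blank-derived threshold. Binding assay: a hit when its
#' mean percent inhibition is at least `threshold` (default 20). Contiguous
#' hit fractions are grouped into active regions.
#'
#' @param responses Either a data.frame with `fraction` and `response`
#'   columns (replicates averaged), or a numeric vector of per-fraction mean
#'   responses for fractions `1..length`.
#' @param assay `"growth"` or `"binding"`.
#' @param threshold Hit threshold; required for growth (use
#'   [antibiotic_hit_threshold()]), default 20 for binding.
#' @return List: `fractions` (data.frame `fraction`, `mean_response`,
#'   `is_hit`), `hits` (hit fraction indices), `regions` (data.frame
#'   `region`, `first_fraction`, `last_fraction`).
#' @export
call_hits <- function(responses, assay = c("growth", "binding"),
                      threshold = NULL) {
  assay <- match.arg(assay)
  if (is.null(threshold)) {
    if (assay == "binding") threshold <- 20
    else stop("growth assay requires an explicit threshold (see antibiotic_hit_threshold)")
  }
  if (is.data.frame(responses)) {
    agg <- tapply(responses$response, responses$fraction, mean)
    frac <- as.integer(names(agg))
    mean_resp <- as.numeric(agg)
  } else {
    frac <- seq_along(responses)
    mean_resp <- as.numeric(responses)
  }
  is_hit <- if (assay == "growth") mean_resp < threshold else mean_resp >= threshold
  o <- order(frac)
  frac <- frac[o]; mean_resp <- mean_resp[o]; is_hit <- is_hit[o]
  hits <- frac[is_hit]
  regions <- data.frame(region = integer(0), first_fraction = integer(0),
                        last_fraction = integer(0))
  if (length(hits)) {
    grp <- cumsum(c(1L, as.integer(diff(hits) > 1L)))
    regions <- data.frame(
      region = seq_len(max(grp)),
      first_fraction = as.integer(tapply(hits, grp, min)),
      last_fraction = as.integer(tapply(hits, grp, max)))
  }
  list(fractions = data.frame(fraction = frac, mean_response = mean_resp,
                              is_hit = is_hit),
       hits = hits, regions = regions)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' `response = bottom + (top - bottom) / (1 + (x / ic50)^slope)`, fitted by
#' Levenberg-Marquardt nonlinear least squares with quartile-based
#' initialization. Non-convergence (or a non-positive fitted IC50) is flagged,
#' never silently defaulted.
#'
#' @param concentration Concentrations (or enrichment factors); >= 4 distinct
#'   positive values.
#' @param response Responses at those concentrations (same length).
#' @param expect_decreasing For inhibition-type readouts the response must
#'   fall with concentration; a fitted curve violating this is flagged as
#'   non-converged (default TRUE).
#' @return List: `converged` flag, `ic50`, `top`, `bottom`, `slope`,
#'   `residual_se`, and the `fit` object (NULL on failure).
#' @export
fit_ic50 <- function(concentration, response, expect_decreasing = TRUE) {
  if (length(concentration) != length(response)) stop("length mismatch")
  if (length(unique(concentration)) < 4)
    stop("need at least 4 distinct concentrations")
  if (any(concentration <= 0)) stop("concentrations must be > 0")
  top0 <- max(response); bot0 <- min(response)
  mid <- (top0 + bot0) / 2
  ic0 <- stats::median(concentration[order(abs(response - mid))][1:2])
  dr <- data.frame(x = concentration, y = response)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + (x / ic50)^slope),
      data = dr,
      start = list(top = top0, bottom = bot0, ic50 = ic0, slope = 1),
      lower = c(-Inf, -Inf, 1e-12, -50), upper = c(Inf, Inf, Inf, 50),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) {
    return(list(converged = FALSE, ic50 = NA_real_, top = NA_real_,
                bottom = NA_real_, slope = NA_real_, residual_se = NA_real_,
                fit = NULL))
  }
  p <- stats::coef(fit)
  # a flat or inverted curve gives an uninformative IC50: flag it
  informative <- is.finite(p[["ic50"]]) && p[["ic50"]] > 0 &&
    abs(p[["top"]] - p[["bottom"]]) > 1e-8 &&
    p[["ic50"]] <= max(concentration) * 100 && p[["ic50"]] >= min(concentration) / 100
  if (expect_decreasing && informative)
    informative <- p[["top"]] > p[["bottom"]] && p[["slope"]] > 0
  list(converged = informative,
       ic50 = p[["ic50"]], top = p[["top"]], bottom = p[["bottom"]],
       slope = p[["slope"]], residual_se = summary(fit)$sigma, fit = fit)
}

#' Back-calculate the minimum sample concentration for a half-maximal effect
#'
#' Divides a mass-concentration IC50 by the enrichment factor of the tested
#' plate: the concentration the original sample must have held for the well
#' to reach a 50% response.
#'
#' @param ic50_mass IC50 as a mass concentration (ug/L).
#' @param enrichment_factor Fold-concentration of the sample in the well
#'   (> 0).
#' @return Minimum sample concentration in ug/L.
#' @examples
#' # PFOA: IC50 1.1 uM -> ~455 ug/L; enrichment factor 12.5 -> ~36.4 ug/L
#' min_sample_conc(micromolar_to_mass_conc(1.1, parse_formula("C8HF15O2")), 12.5)
#' @export
min_sample_conc <- function(ic50_mass, enrichment_factor) {
  if (any(enrichment_factor <= 0)) stop("enrichment_factor must be > 0")
  ic50_mass / enrichment_factor
}

#' Spiking concentration
#'
#' @param amount_ug Spiked amount in ug.
#' @param volume_mL Sample volume in mL.
#' @return Concentration in ug/L.
#' @examples
#' spike_concentration(0.5, 500)  # 1.0 ug/L
#' @export
spike_concentration <- function(amount_ug, volume_mL) {
  if (any(volume_mL <= 0)) stop("volume must be > 0")
  amount_ug / (volume_mL / 1000)
}
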