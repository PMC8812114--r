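#' Parse a molecular formula
#'
#' Parses a Hill-style molecular formula string into an element-composition
#' object. Deuterium is written `D` and carbon-13 labels `[13C]`, so the
#' formulas of isotope-labelled internal standards (e.g. ciprofloxacin-d8,
#' `"C17H10D8FN3O3"`) parse directly.
#'
#' @param formula_text Formula string, e.g. `"C8HF15O2"`.
#' @return An object of class `element_composition`: a named integer vector of
#'   per-element atom counts in canonical Hill order.
#' @examples
#' parse_formula("H2O")
#' parse_formula("C17H10D8FN3O3")  # ciprofloxacin-d8
#' @export
parse_formula <- function(formula_text) {
  if (!is.character(formula_text) || length(formula_text) != 1L || is.na(formula_text))
    stop("formula_text must be a single string")
  s <- gsub("[[:space:]]", "", formula_text)
  if (!nzchar(s)) stop("empty formula string")
  counts <- integer(0)
  pos <- 1L
  n <- nchar(s)
  while (pos <= n) {
    rest <- substr(s, pos, n)
    m <- regmatches(rest, regexec("^(\\[13C\\]|[A-Z][a-z]?)([0-9]*)", rest))[[1]]
    if (length(m) == 0L || !nzchar(m[2]))
      stop(sprintf("malformed formula near '%s' in '%s'", substr(rest, 1, 4), formula_text))
    sym <- m[2]
    if (!sym %in% names(.ISOTOPES)) {
      # two-letter guesses like "Cl" already handled; reject unknown symbols
      stop(sprintf("unknown element symbol '%s' in '%s'", sym, formula_text))
    }
    cnt <- if (nzchar(m[3])) as.integer(m[3]) else 1L
    counts[sym] <- if (sym %in% names(counts)) counts[[sym]] + cnt else cnt
    pos <- pos + nchar(m[1])
  }
  element_composition(counts)
}

#' Construct an element composition
#'
#' @param counts Named integer vector or list of atom counts; names are element
#'   symbols from the supported set (`C H N O S P F Cl Br I Na K D [13C]`).
#' @return An `element_composition` object (named integer vector, Hill order).
#' @export
element_composition <- function(counts) {
  counts <- unlist(counts)
  if (length(counts)) {
    if (is.null(names(counts)) || any(!nzchar(names(counts))))
      stop("counts must be named by element symbol")
    bad <- setdiff(names(counts), names(.ISOTOPES))
    if (length(bad)) stop(sprintf("unknown element symbol '%s'", bad[1]))
    if (any(counts < 0) || any(counts != round(counts)))
      stop("atom counts must be non-negative integers")
    counts <- counts[counts > 0]
  }
  ord <- .HILL_ORDER[.HILL_ORDER %in% names(counts)]
  out <- as.integer(counts[ord])
  names(out) <- ord
  class(out) <- "element_composition"
  out
}

#' Serialize a composition back to a Hill-order formula string
#'
#' @param comp An `element_composition`.
#' @return Canonical formula string; round-trips through [parse_formula()].
#' @export
formula_string <- function(comp) {
  stopifnot(inherits(comp, "element_composition"))
  if (!length(comp)) return("")
  paste0(names(comp), ifelse(unclass(comp) > 1L, unclass(comp), ""), collapse = "")
}

#' @export
print.element_composition <- function(x, ...) {
  cat("<element_composition> ", formula_string(x), "\n", sep = "")
  invisible(x)
}

#' Molecular mass of a composition
#'
#' @param comp An `element_composition` (non-empty).
#' @param kind `"monoisotopic"` (sum of lightest-isotope masses) or
#'   `"average"` (sum of standard atomic weights).
#' @return Mass in Da (g/mol).
#' @examples
#' formula_mass(parse_formula("H2O"))                 # 18.01056
#' formula_mass(parse_formula("C8HF15O2"), "average") # PFOA, 414.07
#' @export
formula_mass <- function(comp, kind = c("monoisotopic", "average")) {
  stopifnot(inherits(comp, "element_composition"))
  kind <- match.arg(kind)
  if (!length(comp)) stop("empty composition has no mass")
  if (kind == "monoisotopic") {
    m <- vapply(names(comp), function(el) min(.ISOTOPES[[el]]$mass), numeric(1))
  } else {
    m <- .ATOMIC_WEIGHTS[names(comp)]
  }
  sum(m * unclass(comp))
}

#' Adduct m/z of a neutral composition
#'
#' Singly charged ESI adducts: m/z is the monoisotopic mass plus the adduct's
#' mass offset (a proton for `[M+H]+` / minus a proton for `[M-H]-`).
#'
#' @param comp An `element_composition`.
#' @param adduct Adduct identifier from [adduct_table()].
#' @return m/z in Da.
#' @export
adduct_mz <- function(comp, adduct = "[M+H]+") {
  tbl <- adduct_table()
  i <- match(adduct, tbl$adduct)
  if (is.na(i)) stop(sprintf("unknown adduct '%s'", adduct))
  formula_mass(comp, "monoisotopic") + tbl$delta_mass[i]
}

#' Charge sign of an adduct
#' @param adduct Adduct identifier.
#' @return +1 or -1.
#' @export
adduct_charge_sign <- function(adduct) {
  tbl <- adduct_table()
  i <- match(adduct, tbl$adduct)
  if (is.na(i)) stop(sprintf("unknown adduct '%s'", adduct))
  tbl$charge_sign[i]
}

#' Signed mass error in ppm
#'
#' @param measured_mz,theoretical_mz m/z values in Da; `theoretical_mz > 0`.
#' @return `(measured - theoretical) / theoretical * 1e6`, signed.
#' @export
ppm_error <- function(measured_mz, theoretical_mz) {
  if (any(theoretical_mz <= 0)) stop("theoretical_mz must be > 0")
  (measured_mz - theoretical_mz) / theoretical_mz * 1e6
}

#' Theoretical isotope pattern of a composition
#'
#' Convolves the per-element isotope distributions into the full isotopologue
#' distribution, merges isotopologues falling within `resolution_bin` of each
#' other (abundance-weighted centroid — no fine structure is resolved below
#' the bin width), drops peaks below `prune` of the base peak, and
#' renormalizes so the base peak has relative intensity 1.
#'
#' @param comp Non-empty `element_composition`.
#' @param resolution_bin Merge width in Da (default 0.01, QTOF-realistic).
#' @param prune Relative-intensity cutoff in (0,1) (default 1e-4).
#' @return An `isotope_pattern`: data.frame with columns `mz` (ascending) and
#'   `rel_intensity` (base peak = 1).
#' @examples
#' isotope_pattern(parse_formula("C6H4Br2"))  # M+2 is the base peak
#' @export
isotope_pattern <- function(comp, resolution_bin = 0.01, prune = 1e-4) {
  stopifnot(inherits(comp, "element_composition"))
  if (!length(comp)) stop("empty composition")
  if (!(prune > 0 && prune < 1)) stop("prune must be in (0,1)")
  if (resolution_bin <= 0) stop("resolution_bin must be > 0")

  dist <- list(mass = 0, abund = 1)
  for (el in names(comp)) {
    iso <- .ISOTOPES[[el]]
    for (k in seq_len(comp[[el]])) {
      mass <- as.vector(outer(dist$mass, iso$mass, `+`))
      abund <- as.vector(outer(dist$abund, iso$abund, `*`))
      # exact-mass compaction only (no binning yet): keeps the convolution
      # identical to exhaustive isotopologue enumeration
      key <- round(mass, 9)
      grp <- match(key, unique(key))
      mass <- vapply(split(mass * abund, grp), sum, numeric(1)) /
        vapply(split(abund, grp), sum, numeric(1))
      abund <- vapply(split(abund, grp), sum, numeric(1))
      keep <- abund > 1e-13
      if (!any(keep)) keep <- abund == max(abund)
      dist <- list(mass = mass[keep], abund = abund[keep])
    }
  }
  .bin_pattern(dist$mass, dist$abund, resolution_bin, prune)
}

# Merge peaks whose consecutive gap is <= bin (single linkage), weighted
# centroid; prune relative to base; renormalize.
.bin_pattern <- function(mass, abund, resolution_bin, prune) {
  o <- order(mass)
  mass <- mass[o]; abund <- abund[o]
  grp <- cumsum(c(1, as.integer(diff(mass) > resolution_bin)))
  mz <- vapply(split(mass * abund, grp), sum, numeric(1)) /
    vapply(split(abund, grp), sum, numeric(1))
  int <- vapply(split(abund, grp), sum, numeric(1))
  rel <- int / max(int)
  keep <- rel > prune
  out <- data.frame(mz = unname(mz[keep]), rel_intensity = unname(rel[keep]))
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("isotope_pattern", "data.frame")
  out
}

#' Construct an isotope pattern from raw peaks
#'
#' Normalizes intensities to base peak = 1 and sorts by m/z; used for measured
#' isotope envelopes.
#'
#' @param mz,intensity Numeric vectors of equal length.
#' @return An `isotope_pattern`.
#' @export
as_isotope_pattern <- function(mz, intensity) {
  if (length(mz) != length(intensity) || !length(mz)) stop("mz and intensity must be equal-length, non-empty")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  o <- order(mz)
  out <- data.frame(mz = mz[o], rel_intensity = intensity[o] / max(intensity))
  out <- out[out$rel_intensity > 0, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("isotope_pattern", "data.frame")
  out
}

#' Isotopic-fit score (mSigma-style)
#'
#' Scores the agreement between a measured and a theoretical isotope pattern
#' as 1000 times the root-mean-square difference of base-normalized
#' intensities over the theoretical peaks. Measured peaks are paired to the
#' nearest theoretical peak within `tol_ppm`; a theoretical peak with no
#' measured partner contributes its full intensity as residual. 0 is a perfect
#' fit; the conventional acceptance cutoff is 100 and a strict fit is <= 25.
#'
#' @param measured,theoretical `isotope_pattern` objects.
#' @param tol_ppm Pairing tolerance in ppm (default 10).
#' @return Non-negative score.
#' @export
msigma <- function(measured, theoretical, tol_ppm = 10) {
  if (is.null(theoretical) || !nrow(theoretical)) stop("no theoretical peaks")
  if (is.null(measured) || !nrow(measured)) stop("no measured peaks")
  resid <- numeric(nrow(theoretical))
  used <- rep(FALSE, nrow(measured))
  for (i in seq_len(nrow(theoretical))) {
    dmz <- abs(measured$mz - theoretical$mz[i])
    ok <- which(!used & dmz <= tol_ppm * 1e-6 * theoretical$mz[i])
    if (length(ok)) {
      j <- ok[which.min(dmz[ok])]
      used[j] <- TRUE
      resid[i] <- measured$rel_intensity[j] - theoretical$rel_intensity[i]
    } else {
      resid[i] <- theoretical$rel_intensity[i]
    }
  }
  1000 * sqrt(mean(resid^2))
}

#' Is the monoisotopic peak the base peak?
#'
#' For multihalogenated compounds (>= 2 Br/Cl) a heavier isotopologue can be
#' the most intense peak; peak-picking software that assumes the base peak is
#' the monoisotopic mass then reports the wrong m/z. A `FALSE` here triggers a
#' polyhalogenated-risk flag in reports.
#'
#' @param pattern An `isotope_pattern`.
#' @return `TRUE` iff the lowest-mass peak is the base peak.
#' @export
monoisotopic_is_base <- function(pattern) {
  if (is.null(pattern) || !nrow(pattern)) stop("empty pattern")
  pattern$rel_intensity[which.min(pattern$mz)] >= max(pattern$rel_intensity)
}

#' Convert a molar to a mass concentration
#'
#' @param conc_uM Concentration in micromolar (>= 0).
#' @param comp Non-empty `element_composition`.
#' @return Concentration in ug/L (uses the average molecular mass).
#' @examples
#' micromolar_to_mass_conc(1.1, parse_formula("C8HF15O2"))  # PFOA, ~455 ug/L
#' @export
micromolar_to_mass_conc <- function(conc_uM, comp) {
  if (any(conc_uM < 0)) stop("conc_uM must be >= 0")
  conc_uM * formula_mass(comp, "average")
}

#' @rdname micromolar_to_mass_conc
#' @param conc_ug_L Concentration in ug/L.
#' @export
mass_conc_to_micromolar <- function(conc_ug_L, comp) {
  if (any(conc_ug_L < 0)) stop("conc_ug_L must be >= 0")
  conc_ug_L / formula_mass(comp, "average")
}
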