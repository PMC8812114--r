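#' Construct an MS/MS spectrum
#'
#' @param mz,intensity Peak m/z values (Da) and intensities (arbitrary counts,
#'   >= 0); at least one peak.
#' @param precursor_mz Precursor m/z in Da.
#' @param ion_mode `"+"` or `"-"`.
#' @param meta Optional named list of extra header fields (preserved by the
#'   MGF/MSP writers).
#' @return An object of class `msms_spectrum`.
#' @export
msms_spectrum <- function(mz, intensity, precursor_mz = NA_real_,
                          ion_mode = c("+", "-"), meta = list()) {
  ion_mode <- match.arg(ion_mode)
  if (length(mz) != length(intensity) || !length(mz))
    stop("mz and intensity must be equal-length and non-empty")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  o <- order(mz)
  structure(
    list(precursor_mz = precursor_mz, ion_mode = ion_mode,
         peaks = data.frame(mz = mz[o], intensity = intensity[o]),
         meta = meta),
    class = "msms_spectrum"
  )
}

#' @export
print.msms_spectrum <- function(x, ...) {
  cat(sprintf("<msms_spectrum> %d peaks, precursor %.4f, mode %s\n",
              nrow(x$peaks), x$precursor_mz, x$ion_mode))
  invisible(x)
}

#' Relative-intensity peak filter
#'
#' Retains peaks whose intensity is strictly greater than
#' `rel_threshold` times the base-peak intensity. The 1%-of-base-peak default
#' mirrors the common practice of exporting only peaks with relative
#' abundance higher than 1% before in-silico fragment matching.
#'
#' @param spec An `msms_spectrum`.
#' @param rel_threshold Fraction of the base peak in `[0, 1)`.
#' @return Filtered `msms_spectrum` (idempotent).
#' @export
relative_intensity_filter <- function(spec, rel_threshold = 0.01) {
  stopifnot(inherits(spec, "msms_spectrum"))
  if (!(rel_threshold >= 0 && rel_threshold < 1)) stop("rel_threshold must be in [0,1)")
  if (!nrow(spec$peaks)) stop("empty spectrum")
  base <- max(spec$peaks$intensity)
  keep <- if (rel_threshold == 0) spec$peaks$intensity > 0
          else spec$peaks$intensity > rel_threshold * base
  out <- spec
  out$peaks <- spec$peaks[keep, , drop = FALSE]
  rownames(out$peaks) <- NULL
  out
}

# Greedy injective peak pairing within ppm tolerance: candidate pairs sorted
# by absolute mass error, accepted while both partners are unused.
# Deterministic and order-independent.
.pair_peaks <- function(mz_a, mz_b, tol_ppm) {
  pairs <- NULL
  for (i in seq_along(mz_a)) {
    tol <- tol_ppm * 1e-6 * mz_a[i]
    j <- which(abs(mz_b - mz_a[i]) <= tol)
    if (length(j))
      pairs <- rbind(pairs, cbind(i = i, j = j, err = abs(mz_b[j] - mz_a[i])))
  }
  if (is.null(pairs)) return(data.frame(i = integer(0), j = integer(0)))
  pairs <- pairs[order(pairs[, "err"], pairs[, "i"], pairs[, "j"]), , drop = FALSE]
  used_a <- logical(length(mz_a)); used_b <- logical(length(mz_b))
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    a <- pairs[k, "i"]; b <- pairs[k, "j"]
    if (!used_a[a] && !used_b[b]) {
      keep[k] <- TRUE; used_a[a] <- TRUE; used_b[b] <- TRUE
    }
  }
  data.frame(i = pairs[keep, "i"], j = pairs[keep, "j"])
}

#' MS/MS spectral similarity score
#'
#' Cosine similarity of square-root-transformed intensities over greedily
#' best-paired peaks within a ppm tolerance, scaled to 0-1000. Symmetric in
#' its arguments and invariant to uniform intensity scaling. Library matches
#' with a score of at least 600 (the conventional acceptance value on this
#' scale) count as spectral-library-level identification evidence.
#'
#' @param query,library Non-empty `msms_spectrum` objects of the same ion mode.
#' @param tol_ppm Peak-pairing tolerance in ppm (default 10).
#' @return Score in `[0, 1000]`.
#' @export
spectral_match_score <- function(query, library, tol_ppm = 10) {
  stopifnot(inherits(query, "msms_spectrum"), inherits(library, "msms_spectrum"))
  if (query$ion_mode != library$ion_mode) stop("ion-mode mismatch between spectra")
  qa <- sqrt(query$peaks$intensity)
  la <- sqrt(library$peaks$intensity)
  pairs <- .pair_peaks(query$peaks$mz, library$peaks$mz, tol_ppm)
  if (!nrow(pairs)) return(0)
  num <- sum(qa[pairs$i] * la[pairs$j])
  den <- sqrt(sum(qa^2)) * sqrt(sum(la^2))
  if (den == 0) return(0)
  1000 * num / den
}

#' Match in-silico fragments against a measured MS/MS spectrum
#'
#' Applies the relative-intensity filter, then pairs each retained peak with
#' at most one candidate fragment (nearest within `tol_ppm`, injective
#' assignment). The 5 ppm default is the conventional relative mass deviation
#' for matching predicted fragments to measured m/z values.
#'
#' @param spec An `msms_spectrum`.
#' @param candidate_fragments Non-empty numeric vector of fragment m/z (Da).
#' @param tol_ppm Match tolerance in ppm (default 5).
#' @param rel_threshold Intensity prefilter (default 0.01).
#' @return A `fragment_match` list: `n_candidate_fragments`,
#'   `n_matched_peaks`, `matched_pairs` (data.frame measured_mz, fragment_mz,
#'   ppm), `matched_intensity_fraction`.
#' @export
fragment_match <- function(spec, candidate_fragments, tol_ppm = 5,
                           rel_threshold = 0.01) {
  if (!length(candidate_fragments)) stop("empty candidate fragment list")
  filt <- relative_intensity_filter(spec, rel_threshold)
  pairs <- .pair_peaks(filt$peaks$mz, candidate_fragments, tol_ppm)
  matched <- data.frame(
    measured_mz = filt$peaks$mz[pairs$i],
    fragment_mz = candidate_fragments[pairs$j],
    ppm = ppm_error(filt$peaks$mz[pairs$i], candidate_fragments[pairs$j])
  )
  total <- sum(filt$peaks$intensity)
  structure(
    list(n_candidate_fragments = length(candidate_fragments),
         n_matched_peaks = nrow(matched),
         matched_pairs = matched,
         matched_intensity_fraction =
           if (total > 0) sum(filt$peaks$intensity[pairs$i]) / total else 0),
    class = "fragment_match"
  )
}
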