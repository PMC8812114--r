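# MGF and MSP text readers/writers. Both formats are simple line-oriented
# dialects; unknown header fields are kept in `meta` and written back on
# round-trip.

#' Read/write MGF spectral files
#'
#' MGF blocks are delimited by `BEGIN IONS`/`END IONS`; `PEPMASS`, `CHARGE`
#' and `TITLE` are interpreted, other `KEY=VALUE` headers are preserved in
#' `meta`. Charge strings ending in `-` (e.g. `1-`) map to negative ion mode.
#'
#' @param path File path.
#' @return `read_mgf()`: a named list of `msms_spectrum` (names from `TITLE`).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "BEGIN IONS") {
      hdr <- list(); mz <- numeric(0); int <- numeric(0)
      i <- i + 1L
      while (i <= length(lines) && trimws(lines[i]) != "END IONS") {
        ln <- trimws(lines[i])
        if (grepl("=", ln, fixed = TRUE)) {
          key <- toupper(sub("=.*", "", ln))
          hdr[[key]] <- sub("^[^=]*=", "", ln)
        } else if (nzchar(ln)) {
          parts <- strsplit(ln, "[[:space:]]+")[[1]]
          mz <- c(mz, as.numeric(parts[1]))
          int <- c(int, as.numeric(parts[2]))
        }
        i <- i + 1L
      }
      mode <- if (!is.null(hdr$CHARGE) && grepl("-", hdr$CHARGE)) "-" else "+"
      prec <- if (!is.null(hdr$PEPMASS))
        as.numeric(strsplit(trimws(hdr$PEPMASS), "[[:space:]]+")[[1]][1]) else NA_real_
      title <- if (!is.null(hdr$TITLE)) hdr$TITLE else sprintf("spectrum_%d", length(out) + 1L)
      meta <- hdr[setdiff(names(hdr), c("PEPMASS", "CHARGE", "TITLE"))]
      if (!length(mz)) stop(sprintf("MGF block '%s' has no peaks", title))
      out[[title]] <- msms_spectrum(mz, int, precursor_mz = prec,
                                    ion_mode = mode, meta = meta)
    }
    i <- i + 1L
  }
  out
}

#' @rdname read_mgf
#' @param spectra Named list of `msms_spectrum`.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (title in names(spectra)) {
    s <- spectra[[title]]
    writeLines("BEGIN IONS", con)
    writeLines(sprintf("TITLE=%s", title), con)
    if (!is.na(s$precursor_mz)) writeLines(sprintf("PEPMASS=%.6f", s$precursor_mz), con)
    writeLines(sprintf("CHARGE=1%s", s$ion_mode), con)
    for (k in names(s$meta)) writeLines(sprintf("%s=%s", k, s$meta[[k]]), con)
    writeLines(sprintf("%.6f %.6g", s$peaks$mz, s$peaks$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Read/write MSP spectral libraries
#'
#' NIST-style MSP: records start at `Name:`, `PrecursorMZ:`/`Ion_mode:` are
#' interpreted, any other `Key: value` header is preserved, and `Num Peaks:`
#' precedes the peak list.
#'
#' @param path File path.
#' @return `read_msp()`: a named list of `msms_spectrum` (names from `Name:`).
#' @export
read_msp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  hdr <- NULL; mz <- numeric(0); int <- numeric(0)
  flush_record <- function() {
    if (is.null(hdr)) return()
    nm <- if (!is.null(hdr$NAME)) hdr$NAME else sprintf("spectrum_%d", length(out) + 1L)
    mode <- if (!is.null(hdr$ION_MODE) && grepl("^N", toupper(hdr$ION_MODE))) "-" else "+"
    prec <- if (!is.null(hdr$PRECURSORMZ)) as.numeric(hdr$PRECURSORMZ) else NA_real_
    meta <- hdr[setdiff(names(hdr), c("NAME", "ION_MODE", "PRECURSORMZ", "NUM PEAKS"))]
    if (!length(mz)) stop(sprintf("MSP record '%s' has no peaks", nm))
    out[[nm]] <<- msms_spectrum(mz, int, precursor_mz = prec,
                                ion_mode = mode, meta = meta)
  }
  for (ln in c(lines, "")) {
    ln <- trimws(ln)
    if (grepl("^Name:", ln, ignore.case = TRUE)) {
      flush_record()
      hdr <- list(NAME = trimws(sub("^[Nn]ame:", "", ln)))
      mz <- numeric(0); int <- numeric(0)
    } else if (grepl("^[A-Za-z][A-Za-z_ ]*:", ln)) {
      key <- toupper(trimws(sub(":.*", "", ln)))
      hdr[[key]] <- trimws(sub("^[^:]*:", "", ln))
    } else if (nzchar(ln)) {
      parts <- strsplit(ln, "[[:space:];]+")[[1]]
      mz <- c(mz, as.numeric(parts[1]))
      int <- c(int, as.numeric(parts[2]))
    }
  }
  flush_record()
  out
}

#' @rdname read_msp
#' @param spectra Named list of `msms_spectrum`.
#' @export
write_msp <- function(spectra, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (nm in names(spectra)) {
    s <- spectra[[nm]]
    writeLines(sprintf("Name: %s", nm), con)
    if (!is.na(s$precursor_mz)) writeLines(sprintf("PrecursorMZ: %.6f", s$precursor_mz), con)
    writeLines(sprintf("Ion_mode: %s", if (s$ion_mode == "-") "Negative" else "Positive"), con)
    for (k in names(s$meta)) writeLines(sprintf("%s: %s", k, s$meta[[k]]), con)
    writeLines(sprintf("Num Peaks: %d", nrow(s$peaks)), con)
    writeLines(sprintf("%.6f %.6g", s$peaks$mz, s$peaks$intensity), con)
    writeLines("", con)
  }
  invisible(path)
}
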