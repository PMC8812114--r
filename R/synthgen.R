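# Synthetic-study generator: builds complete, internally consistent input
# sets (suspect lists, feature tables, spectra, bioassay plates, boxed
# candidates, fragment lists) with known ground truth, for end-to-end
# validation of the screening workflow.
#
# Statistical choices (documented in the methods vignette): feature
# intensities are lognormal, replicate noise is multiplicative Gaussian at a
# target CV, retention times are uniform over the run, and plate noise is
# additive Gaussian. MS/MS spectra are recorded DDA-style for the top-N
# most intense features only.

#' Default spiked compounds of the synthetic study
#'
#' Three isotope-labelled antibiotics (positive mode, growth assay) at known
#' retention times, mirroring a spiked-effluent design.
#'
#' @return data.frame: `name`, `formula`, `ion_mode`, `rt_s`,
#'   `effect` (response drop in the assay, response units), `potency_uM`.
#' @export
default_spikes <- function() {
  data.frame(
    name = c("ciprofloxacin-d8", "azithromycin-13Cd3", "clarithromycin-13Cd3"),
    formula = c("C17H10D8FN3O3", "C37H69D3N2O12[13C]", "C37H66D3NO13[13C]"),
    ion_mode = "+",
    rt_s = c(130, 215, 380),
    effect = c(55, 50, 60),
    potency_uM = c(0.05, 0.1, 0.08),
    stringsAsFactors = FALSE
  )
}

#' Synthetic-study configuration
#'
#' @param seed Integer seed fixing every random draw.
#' @param n_background_features Background (non-spike) features per ion mode.
#' @param spikes data.frame as in [default_spikes()].
#' @param n_injections Technical replicate injections (default 3).
#' @param run_end_s LC run length in seconds (default 1080 = 80 x 13.5).
#' @param intensity_meanlog,intensity_sdlog Lognormal intensity parameters.
#' @param replicate_cv Target replicate CV as a fraction (default 0.10).
#' @param blank_contamination_rate Fraction of background features also
#'   present in the blank at comparable intensity (default 0.05).
#' @param plate_noise_sd Gaussian plate noise SD in response units
#'   (default 4).
#' @param plate_baseline Clean-well response (default 100, percent scale).
#' @param fraction_duration,margin Fraction length and window margin in s.
#' @param dda_top_n MS/MS recorded for the top-N intensity features per mode.
#' @param annotatable_fraction Fraction of background features drawn from the
#'   suspect-list formulas (annotatable at formula level).
#' @return A `study_config` list.
#' @export
study_config <- function(seed = 1L,
                         n_background_features = 300L,
                         spikes = default_spikes(),
                         n_injections = 3L,
                         run_end_s = 1080,
                         intensity_meanlog = 11,
                         intensity_sdlog = 1.2,
                         replicate_cv = 0.10,
                         blank_contamination_rate = 0.05,
                         plate_noise_sd = 4,
                         plate_baseline = 100,
                         fraction_duration = 13.5,
                         margin = 6.5,
                         dda_top_n = 100L,
                         annotatable_fraction = 0.3) {
  cfg <- list(seed = as.integer(seed),
              n_background_features = as.integer(n_background_features),
              spikes = spikes, n_injections = as.integer(n_injections),
              run_end_s = run_end_s,
              intensity_meanlog = intensity_meanlog,
              intensity_sdlog = intensity_sdlog,
              replicate_cv = replicate_cv,
              blank_contamination_rate = blank_contamination_rate,
              plate_noise_sd = plate_noise_sd,
              plate_baseline = plate_baseline,
              fraction_duration = fraction_duration, margin = margin,
              dda_top_n = as.integer(dda_top_n),
              annotatable_fraction = annotatable_fraction)
  if (any(unlist(cfg[c("n_background_features", "n_injections", "dda_top_n")]) < 0))
    stop("counts must be >= 0")
  if (nrow(spikes) && any(spikes$rt_s < 0 | spikes$rt_s > run_end_s))
    stop("spike rt outside the run")
  class(cfg) <- "study_config"
  cfg
}

# Deterministic pseudo-fragment spectrum for a composition: fragments at
# fixed fractions of the precursor mass. Not a fragmentation model - just a
# reproducible spectrum unique to the formula.
.pseudo_spectrum <- function(comp, adduct, ion_mode) {
  prec <- adduct_mz(comp, adduct)
  fr <- c(0.32, 0.45, 0.61, 0.78, 0.9)
  mz <- round(prec * fr, 4)
  intensity <- c(250, 900, 400, 1000, 150)
  msms_spectrum(c(mz, round(prec, 4)), c(intensity, 300),
                precursor_mz = prec, ion_mode = ion_mode)
}

# Background formula pool for annotatable features (plausible small-molecule
# compositions, including isomer-rich groups).
.background_formulas <- function() {
  c("C9H13NO3", "C9H13NO3", "C9H13NO3",     # isomer triplet
    "C16H25NO2", "C16H25NO2",
    "C10H14N2", "C12H17NO", "C8H10N4O2", "C14H18N2O5", "C7H8N4O2",
    "C13H18O2", "C15H22O3", "C6H8O7", "C10H12O4", "C18H34O2",
    "C12H22O11", "C8H9NO2", "C11H12N2O2", "C17H19NO3", "C20H25NO3")
}

#' Generate a complete synthetic study
#'
#' Deterministic under the configured seed. Spiked features satisfy the
#' inclusion criteria by construction (blank-free, replicate CV at target),
#' carry measured isotope envelopes and MS/MS spectra, and drive plate
#' activity in exactly the fractions whose core window contains the spike
#' retention time.
#'
#' @param cfg A [study_config()].
#' @return A `synthetic_study` list: `config`, `tables` (named by ion mode),
#'   `hierarchy` (list of `suspect_list`), `plates` (list with `sample`,
#'   `procedure_blank`), `boxed_candidates`, `fragment_lists`,
#'   `ground_truth` (per-spike data.frame with `active_fractions`
#'   list-column), `feature_truth` (feature_id -> is_spike).
#' @export
generate_study <- function(cfg = study_config()) {
  stopifnot(inherits(cfg, "study_config"))
  set.seed(cfg$seed)
  modes <- c("+", "-")
  spikes <- cfg$spikes
  pool <- .background_formulas()

  # --- suspect lists ------------------------------------------------------
  al_plus_entries <- lapply(seq_len(nrow(spikes)), function(i) {
    suspect_entry(spikes$name[i], parse_formula(spikes$formula[i]), "AL+",
                  expected_rt = spikes$rt_s[i],
                  adducts = if (spikes$ion_mode[i] == "+") "[M+H]+" else "[M-H]-")
  })
  sl_formulas <- c("C8H10N4O2", "C13H18O2")  # library compounds
  sl_entries <- lapply(seq_along(sl_formulas), function(i) {
    comp <- parse_formula(sl_formulas[i])
    suspect_entry(sprintf("library_compound_%d", i), comp, "SL",
                  adducts = "[M+H]+",
                  library_spectra = list(.pseudo_spectrum(comp, "[M+H]+", "+")))
  })
  al_entries <- list()
  for (i in seq_along(pool)) {
    al_entries[[i]] <- suspect_entry(sprintf("cec_candidate_%02d", i),
                                     parse_formula(pool[i]), "AL",
                                     adducts = c("[M+H]+", "[M-H]-"))
  }
  hierarchy <- list(
    suspect_list("library", sl_entries, rank = 1L),
    suspect_list("cecscreen", al_entries, rank = 2L),
    suspect_list("standards", al_plus_entries, rank = 3L)
  )

  # --- feature tables -----------------------------------------------------
  tables <- list()
  feature_truth <- list()
  for (mode in modes) {
    nbg <- cfg$n_background_features
    n_ann <- round(cfg$annotatable_fraction * nbg)
    ann_formula <- sample(pool, n_ann, replace = TRUE)
    adduct <- if (mode == "+") "[M+H]+" else "[M-H]-"
    ann_mz <- vapply(ann_formula, function(f) adduct_mz(parse_formula(f), adduct),
                     numeric(1))
    mz <- c(ann_mz * (1 + stats::rnorm(n_ann, 0, 1e-6)),
            stats::runif(nbg - n_ann, 100, 900))
    rt <- stats::runif(nbg, 0, cfg$run_end_s)
    base_int <- stats::rlnorm(nbg, cfg$intensity_meanlog, cfg$intensity_sdlog)
    blank <- rep(0, nbg)
    contaminated <- stats::runif(nbg) < cfg$blank_contamination_rate
    blank[contaminated] <- base_int[contaminated] * stats::runif(sum(contaminated), 0.5, 1.5)

    sp <- spikes[spikes$ion_mode == mode, , drop = FALSE]
    nsp <- nrow(sp)
    if (nsp) {
      sp_comp <- lapply(sp$formula, parse_formula)
      sp_adduct <- ifelse(sp$ion_mode == "+", "[M+H]+", "[M-H]-")
      sp_mz <- mapply(function(c, a) adduct_mz(c, a), sp_comp, sp_adduct)
      mz <- c(mz, sp_mz * (1 + stats::rnorm(nsp, 0, 5e-7)))
      rt <- c(rt, sp$rt_s + stats::rnorm(nsp, 0, 1))
      base_int <- c(base_int, stats::rlnorm(nsp, cfg$intensity_meanlog + 4, 0.2))
      blank <- c(blank, rep(0, nsp))
    }
    n <- nbg + nsp
    ids <- sprintf("%s_%04d", if (mode == "+") "P" else "N", seq_len(n))
    intens <- matrix(0, n, cfg$n_injections)
    for (j in seq_len(cfg$n_injections))
      intens[, j] <- base_int * pmax(0.05, 1 + stats::rnorm(n, 0, cfg$replicate_cv))
    if (nsp && cfg$n_injections >= 2) {
      # spikes meet the CV criterion by construction: standardized residuals
      # give a realized replicate CV equal to the target exactly
      for (k in nbg + seq_len(nsp)) {
        r <- stats::rnorm(cfg$n_injections)
        r <- (r - mean(r)) / stats::sd(r)
        intens[k, ] <- base_int[k] * (1 + cfg$replicate_cv * r)
      }
    }
    colnames(intens) <- paste0("intensity_", seq_len(cfg$n_injections))

    dda <- rank(-rowMeans(intens), ties.method = "first") <= cfg$dda_top_n
    df <- data.frame(feature_id = ids, ion_mode = rep(mode, n), mz = mz,
                     rt = pmax(0, rt),
                     blank_intensity = blank, msms_recorded = dda,
                     stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(intens))
    tab <- feature_table(df, ion_mode = mode, label = sprintf("synthetic_%s", mode))

    # measured isotope envelopes for annotatable + spike features (theoretical
    # pattern plus small intensity noise), MS/MS for DDA'd known compounds
    iso_col <- vector("list", n)
    msms_col <- vector("list", n)
    known_formula <- c(ann_formula, if (nsp) sp$formula)
    known_idx <- c(seq_len(n_ann), if (nsp) (nbg + seq_len(nsp)))
    for (k in seq_along(known_idx)) {
      idx <- known_idx[k]
      comp <- parse_formula(known_formula[k])
      pat <- isotope_pattern(comp)
      delta <- adduct_table()$delta_mass[match(adduct, adduct_table()$adduct)]
      noisy <- pmax(1e-6, pat$rel_intensity * (1 + stats::rnorm(nrow(pat), 0, 0.01)))
      iso_col[[idx]] <- as_isotope_pattern(pat$mz + delta, noisy)
      if (df$msms_recorded[idx])
        msms_col[[idx]] <- .pseudo_spectrum(comp, adduct, mode)
    }
    tab$isotope_peaks <- iso_col
    tab$msms <- msms_col
    tables[[mode]] <- tab
    feature_truth[[mode]] <- data.frame(
      feature_id = ids,
      is_spike = c(rep(FALSE, nbg), rep(TRUE, nsp)),
      stringsAsFactors = FALSE)
  }

  # --- ground truth -------------------------------------------------------
  active_fractions <- lapply(spikes$rt_s, function(rt) {
    f <- floor(rt / cfg$fraction_duration) + 1
    f[f >= 1 & f <= 80]
  })
  ground_truth <- data.frame(
    name = spikes$name, formula = spikes$formula, ion_mode = spikes$ion_mode,
    rt_s = spikes$rt_s, effect = spikes$effect,
    expected_level = rep("2b", nrow(spikes)), stringsAsFactors = FALSE)
  ground_truth$active_fractions <- active_fractions

  # --- bioassay plates (growth assay) -------------------------------------
  truth_active <- sort(unique(unlist(active_fractions)))
  make_plate <- function(active, effect_by_fraction, n_rep) {
    rows <- list()
    for (rep in seq_len(n_rep)) {
      resp <- cfg$plate_baseline -
        ifelse(seq_len(80) %in% active,
               effect_by_fraction[as.character(seq_len(80))], 0)
      resp[is.na(resp)] <- cfg$plate_baseline
      raw <- resp + stats::rnorm(80, 0, cfg$plate_noise_sd)
      rows[[rep]] <- data.frame(
        well = fraction_to_well(seq_len(80)),
        role = if (n_rep > 1) "fraction" else "pb_fraction",
        replicate = rep, raw_response = raw * 500,
        fraction = seq_len(80), stringsAsFactors = FALSE)
    }
    ctrl <- data.frame(
      well = paste0(LETTERS[1:8], 1),
      role = "solvent_control", replicate = 1L,
      raw_response = (cfg$plate_baseline + stats::rnorm(8, 0, cfg$plate_noise_sd)) * 500,
      fraction = NA_integer_, stringsAsFactors = FALSE)
    do.call(rbind, c(rows, list(ctrl)))
  }
  eff <- stats::setNames(rep(0, 80), as.character(seq_len(80)))
  for (i in seq_len(nrow(spikes)))
    for (f in active_fractions[[i]])
      eff[as.character(f)] <- eff[as.character(f)] + spikes$effect[i]
  plates <- list(
    sample = make_plate(truth_active, eff, n_rep = 3L),
    procedure_blank = make_plate(integer(0), eff, n_rep = 1L)
  )

  # --- boxed candidates + fragment lists (for the boosting stage) ---------
  boxed <- make_isomer_set("C9H13NO3", 3, n_box1 = 1, n_box2 = 1, n_box3 = 1,
                           n_box4 = 0, n_unpredicted = 0,
                           predicted_rt_s = c(118, 250, 410))
  frag_target <- .pseudo_spectrum(parse_formula("C9H13NO3"), "[M+H]+", "+")
  fragment_lists <- list(
    "C9H13NO3_iso1" = frag_target$peaks$mz[c(2, 4)],  # the two most intense
    "C9H13NO3_iso2" = frag_target$peaks$mz[2] + 0.05  # off by ~270 ppm: no match
  )

  structure(list(config = cfg, tables = tables, hierarchy = hierarchy,
                 plates = plates, boxed_candidates = boxed,
                 fragment_lists = fragment_lists,
                 ground_truth = ground_truth,
                 feature_truth = do.call(rbind, feature_truth)),
            class = "synthetic_study")
}

#' Construct a boxed-candidate isomer set with a prescribed box histogram
#'
#' @param formula Shared molecular formula of the isomer set.
#' @param n_isomers Total number of candidates.
#' @param n_box1,n_box2,n_box3,n_box4,n_unpredicted Counts per applicability-
#'   domain box; must sum to `n_isomers`.
#' @param predicted_rt_s Optional predicted RTs (recycled NA when absent).
#' @return data.frame: `candidate`, `formula`, `box` (NA = unpredicted),
#'   `predicted_rt_s`.
#' @export
make_isomer_set <- function(formula, n_isomers, n_box1 = 0, n_box2 = 0,
                            n_box3 = 0, n_box4 = 0, n_unpredicted = 0,
                            predicted_rt_s = NULL) {
  counts <- c(n_box1, n_box2, n_box3, n_box4, n_unpredicted)
  if (sum(counts) != n_isomers)
    stop(sprintf("box counts sum to %d, not n_isomers = %d", sum(counts), n_isomers))
  box <- rep(c(1L, 2L, 3L, 4L, NA_integer_), counts)
  out <- data.frame(
    candidate = sprintf("%s_iso%d", formula, seq_len(n_isomers)),
    formula = formula, box = box,
    predicted_rt_s = if (is.null(predicted_rt_s)) NA_real_ else predicted_rt_s,
    stringsAsFactors = FALSE)
  out
}

#' Write a synthetic study to disk
#'
#' Emits the CSV/MGF/MSP dialects the rest of the package reads, plus a
#' `study.json` manifest carrying the seed and ground truth.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (mode in names(study$tables)) {
    tag <- if (mode == "+") "pos" else "neg"
    write_feature_table(study$tables[[mode]],
                        file.path(dir, sprintf("features_%s.csv", tag)))
    msms <- study$tables[[mode]]$msms
    names(msms) <- study$tables[[mode]]$feature_id
    msms <- Filter(Negate(is.null), msms)
    if (length(msms)) write_mgf(msms, file.path(dir, sprintf("msms_%s.mgf", tag)))
  }
  for (sl in study$hierarchy) {
    rows <- lapply(sl$entries, function(e) data.frame(
      name = e$name, formula = formula_string(e$formula),
      list_class = e$list_class,
      rt_min = if (is.na(e$expected_rt)) NA_real_ else e$expected_rt / 60,
      adducts = paste(e$adducts, collapse = ";"),
      spectra_file = if (length(e$library_spectra))
        sprintf("spectra_%s.msp", sl$name) else "",
      stringsAsFactors = FALSE))
    utils::write.csv(do.call(rbind, rows),
                     file.path(dir, sprintf("suspects_%s.csv", sl$name)),
                     row.names = FALSE, na = "")
    spectra <- list()
    for (e in sl$entries)
      if (length(e$library_spectra)) spectra[[e$name]] <- e$library_spectra[[1]]
    if (length(spectra))
      write_msp(spectra, file.path(dir, sprintf("spectra_%s.msp", sl$name)))
  }
  utils::write.csv(study$plates$sample, file.path(dir, "plate_sample.csv"),
                   row.names = FALSE)
  utils::write.csv(study$plates$procedure_blank,
                   file.path(dir, "plate_procedure_blank.csv"), row.names = FALSE)
  utils::write.csv(study$boxed_candidates, file.path(dir, "boxed_candidates.csv"),
                   row.names = FALSE, na = "")
  frag <- do.call(rbind, lapply(names(study$fragment_lists), function(nm)
    data.frame(candidate = nm, fragment_mz = study$fragment_lists[[nm]],
               stringsAsFactors = FALSE)))
  utils::write.csv(frag, file.path(dir, "fragments.csv"), row.names = FALSE)
  gt <- study$ground_truth
  jsonlite::write_json(
    list(seed = study$config$seed,
         spikes = lapply(seq_len(nrow(gt)), function(i) list(
           name = gt$name[i], formula = gt$formula[i], ion_mode = gt$ion_mode[i],
           rt_s = gt$rt_s[i], effect = gt$effect[i],
           expected_level = gt$expected_level[i],
           active_fractions = gt$active_fractions[[i]])),
         feature_truth = study$feature_truth),
    file.path(dir, "study.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
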