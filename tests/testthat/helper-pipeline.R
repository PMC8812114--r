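# Run the full screening pipeline on an in-memory synthetic study:
# inclusion filters -> annotation -> hit calling -> windows -> selection.
run_pipeline <- function(study) {
  cfg <- study$config
  annotations <- do.call(rbind, lapply(study$tables, function(tab)
    annotate_table(tab, study$hierarchy)))

  sample_norm <- normalize_plate(study$plates$sample, "growth")
  pb_norm <- normalize_plate(study$plates$procedure_blank, "growth")
  threshold <- antibiotic_hit_threshold(pb_norm$response)
  hits <- call_hits(sample_norm, "growth", threshold = threshold)

  windows <- if (length(hits$hits))
    fraction_windows(hits$hits, duration = cfg$fraction_duration,
                     margin = cfg$margin)
  else fraction_windows(integer(0))[0, ]

  selected <- select_features(annotations, windows)
  list(annotations = annotations, hits = hits, windows = windows,
       selected = selected, threshold = threshold)
}
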