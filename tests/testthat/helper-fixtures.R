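# Minimal annotation-table fixture used by the window/report tests.
make_annotations <- function(rt, level = "4*", id = sprintf("F%03d", seq_along(rt)),
                             intensity = rep(1000, length(rt))) {
  data.frame(feature_id = id, mode = "+", mz = 300, rt_s = rt,
             mean_intensity = intensity, suspect = paste0("s_", id),
             list = "cec", list_class = "AL", adduct = "[M+H]+",
             ppm = 1, rt_dev_min = NA_real_, msigma = 10, msms_score = NA_real_,
             taq = "2-11--", level = level, isomer_count = 1L,
             polyhalo_risk = FALSE, primary_flag = TRUE,
             stringsAsFactors = FALSE)
}
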