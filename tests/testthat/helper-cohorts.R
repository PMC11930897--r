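# Compact cohort builder for tests: one single-nodule patient per row.
make_cohort <- function(gvr, diameter, suspicious = FALSE, pathology = NA,
                        label = "test") {
  n <- max(length(gvr), length(diameter))
  ggn_cohort(data.frame(
    nodule_id = sprintf("N%03d", seq_len(n)),
    patient_id = sprintf("P%03d", seq_len(n)),
    mean_diameter_mm = rep_len(diameter, n),
    gvr = rep_len(gvr, n),
    suspicious_features = rep_len(suspicious, n),
    pathology = rep_len(as.character(pathology), n),
    stringsAsFactors = FALSE
  ), label = label)
}

training_clung_cells <- list(tp = 131, fp = 14, fn = 7, tn = 17)
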