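#!/usr/bin/env Rscript
# Generate the synthetic study cohort: three models across passages
# P0/P1/P4/P10 (one with pure-mouse outgrowth at P4/P10), plus the
# 5-sample x 3-replicate mouse panel, and validate the cohort design.

source("analysis/00_config.R")

cfg <- xm_config()
lay <- xm_layout(cfg)
cohort <- xm_cohort(cfg)
panel <- xm_panel(cfg)

write_chip_layout(lay, file.path(RESULTS_DIR, "layout.tsv"))
write_sample_sheet(rbind(cohort$annotations, panel$annotations),
                   file.path(RESULTS_DIR, "samples.csv"))

report <- validate_cohort(cohort$tables, cohort$annotations, lay)
message("cohort: ", length(cohort$tables), " arrays; mouse panel: ",
        length(panel$tables), " arrays")
if (length(report$warnings) > 0) {
  message("design warnings: ", paste(report$warnings, collapse = "; "))
} else {
  message("replicate design complete: 2-3 P0 and 5 per in vivo passage")
}

# ground truth table for downstream scoring
truth <- do.call(rbind, lapply(names(cohort$truth$drifting), function(m) {
  eff <- cohort$truth$drifting[[m]]
  if (length(eff) == 0) return(NULL)
  data.frame(model_name = m, probe_set_id = names(eff),
             log2_drift = unname(eff))
}))
write_tsv(truth, "truth_drift.tsv")
write_tsv(data.frame(probe_set_id = cohort$truth$crosshyb_ids),
          "truth_crosshyb.tsv")
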