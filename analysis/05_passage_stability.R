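#!/usr/bin/env Rscript
# Per-model passage-stability metric: transcripts changed >3-fold
# (p < 0.05) between P1 and P4 and between P1 and P10, models ranked
# most-stable-first. The outgrowth model's late passages are pure mouse
# signal, so its counts are expected to dwarf the others' — the same
# pattern that motivates excluding outgrown passages from release data.

source("analysis/00_config.R")

cfg <- xm_config()
cohort <- xm_cohort(cfg)
expr <- xm_expression(cfg)

reports <- lapply(cfg$model_names, function(m) {
  stability_metric(expr, cohort$annotations, m)
})
ranked <- rank_models_by_stability(reports)
print(ranked)

truth_n <- lengths(cohort$truth$drifting)[ranked$model_name]
message("injected drifting sets per model: ",
        paste(sprintf("%s=%d", names(truth_n), truth_n), collapse = ", "))

write_tsv(ranked, "stability_ranking.tsv")

# trajectory view for one injected drifting probe set of the top model
m1 <- cfg$model_names[1]
other <- unlist(lapply(cohort$truth$drifting[-1], names))
drift_ids <- setdiff(names(cohort$truth$drifting[[m1]]), other)
if (length(drift_ids) > 0) {
  traj <- transcript_trajectory(drift_ids[1], expr, cohort$annotations)
  message("trajectory of ", drift_ids[1], " (injected ",
          round(cohort$truth$drifting[[m1]][1], 2), " log2 in ", m1, "):")
  print(traj)
  write_tsv(traj, "example_trajectory.tsv")
}
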