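#!/usr/bin/env Rscript
# The in vitro -> in vivo transition, two ways:
#  (a) the published prostate worked example from the shipped fixture:
#      apply the stringency-1 mask to the printed top-50 list;
#  (b) the synthetic cohort: per-model P0 -> P1 fold changes, class
#      averaging, and the two-block (pre/post-mask) report.

source("analysis/00_config.R")

# (a) worked example
tbl <- read_transition_fixture(
  system.file("extdata", "prostate_transition_top50.tsv", package = "xenomine"))
res <- apply_mask(tbl, tbl$probe_set_id[tbl$n_mouse_samples >= 1])
message(sprintf(
  "worked example: %d of %d probe sets removed as mouse artifacts;",
  nrow(res$removed), nrow(tbl)))
message(sprintf("top retained entry: %s (%s), average fold change %.3f",
                res$retained$probe_set_id[1], res$retained$gene_symbol[1],
                res$retained$fold_change[1]))
write_tsv(res$retained, "worked_example_postmask.tsv")

# (b) synthetic cohort
cfg <- xm_config()
cohort <- xm_cohort(cfg)
expr <- xm_expression(cfg)
mask <- xm_mask(cfg)

human_models <- setdiff(cfg$model_names, cfg$outgrowth_models)
fc <- lapply(human_models, function(m) {
  average_fold_change(expr, cohort$annotations, m)
})
names(fc) <- human_models
cls <- class_fold_change(fc)
rep <- transition_report(cls, mask, n = 50, stringency = 1)
n_flagged <- sum(rep$pre_mask$n_mouse_samples >= 1)
message(sprintf(
  "synthetic class table: %d of the top 50 flagged as cross-hybridizing",
  n_flagged))
write_tsv(rep$pre_mask, "transition_pre_mask.tsv")
write_tsv(rep$post_mask, "transition_post_mask.tsv")
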