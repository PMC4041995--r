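#!/usr/bin/env Rscript
# Cohort QC: control-probe profile correlations, PCA outlier flagging
# (expected to isolate the outgrowth model's P4/P10 arrays), model
# co-clustering, and the in-silico species-composition score.

source("analysis/00_config.R")

cfg <- xm_config()
lay <- xm_layout(cfg)
cohort <- xm_cohort(cfg)
expr <- xm_expression(cfg)
mask <- xm_mask(cfg)

qc <- qc_report(expr, lay, mask_set = mask_at_stringency(mask, 1))

message("control-probe correlations: min ",
        round(min(qc$control$correlation), 4))
message("PCA outliers: ",
        paste(names(which(qc$pca$flagged)), collapse = ", "))
message("species-score flags: ",
        paste(qc$species$sample_id[qc$species$flagged], collapse = ", "))

# co-clustering on the models' baseline signatures at the published
# 100-fold filter scale
cl <- hierarchical_cocluster(expr, cohort$annotations, fold_cutoff = 100)
message("co-cluster purity: ",
        paste(sprintf("%s=%.2f", names(cl$purity), cl$purity),
              collapse = ", "),
        " (", cl$n_probe_sets_used, " probe sets used)")

write_tsv(qc$flags, "qc_flags.tsv")
write_tsv(qc$species, "species_scores.tsv")
write_tsv(data.frame(model_name = names(cl$purity),
                     purity = unname(cl$purity)), "cocluster_purity.tsv")
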