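# Shared study configuration for the analysis scripts.
#
# One synthetic cohort stands in for the raw-array cohort: three human
# tumor models (one with host-cell outgrowth at late passages), serial
# passages P0/P1/P4/P10, and a 5 x 3 mouse-RNA panel for mask building.
# Every script re-derives what it needs deterministically from this
# configuration, so the scripts can be run in any order.

library(xenomine)

RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

XM_SEED <- 2014L

xm_config <- function() {
  cohort_config(
    model_names = c("COLON-A", "PROSTATE-A", "GLIO-A"),
    n_probe_sets = 500,
    n_signature_sets = 25,
    n_drifting_sets = 20,
    drift_log2_range = c(2, 3),
    n_transition_sets = 15,
    outgrowth_models = "GLIO-A",
    crosshyb_fraction = 0.1,
    noise_sd = 0.25,
    seed = XM_SEED
  )
}

xm_layout <- function(cfg = xm_config()) {
  generate_chip_layout(cfg$n_probe_sets, cfg$probe_pairs_per_set,
                       cfg$n_controls, cfg$seed)
}

xm_cohort <- function(cfg = xm_config()) {
  simulate_cohort(cfg, xm_layout(cfg))
}

xm_panel <- function(cfg = xm_config()) {
  simulate_mouse_panel(cfg, xm_layout(cfg))
}

xm_expression <- function(cfg = xm_config()) {
  path <- file.path(RESULTS_DIR, "expression.tsv")
  if (file.exists(path)) return(read_expression_matrix(path))
  rma(xm_cohort(cfg)$tables, xm_layout(cfg))
}

xm_mask <- function(cfg = xm_config()) {
  path <- file.path(RESULTS_DIR, "crosshyb_mask.tsv")
  lay <- xm_layout(cfg)
  if (file.exists(path)) {
    return(read_crosshyb_mask(path, universe = lay$probe_set_ids))
  }
  panel <- xm_panel(cfg)
  build_crosshyb_table(detection_calls(panel$tables, lay),
                       panel$annotations)
}

write_tsv <- function(df, name) {
  path <- file.path(RESULTS_DIR, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  message("wrote ", path)
  path
}
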