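## End-to-end orchestration: simulate -> preprocess -> qc -> mask ->
## drift -> transition, with a reproducible run manifest. Each stage is
## independently consumable through its module functions; this composite
## exists for whole-cohort runs and determinism checks.

#' Pipeline configuration
#'
#' @param config a [cohort_config()] describing the synthetic cohort
#'   (or NULL when `expression` is supplied directly).
#' @param output_dir directory all stage outputs are written under.
#' @param stages character subset of
#'   `c("simulate", "preprocess", "qc", "mask", "drift", "transition")`.
#' @param stringency mask stringency for the transition stage.
#' @param fc_cutoff,p_cutoff stability-metric cutoffs.
#' @param top_n transition report block size.
#' @param seed integer seed recorded in the manifest; the cohort
#'   config's own seed governs simulation.
#' @export
pipeline_config <- function(config = cohort_config(),
                            output_dir = tempfile("xenomine_run_"),
                            stages = c("simulate", "preprocess", "qc",
                                       "mask", "drift", "transition"),
                            stringency = 1L, fc_cutoff = 3,
                            p_cutoff = 0.05, top_n = 50L, seed = 1L) {
  allowed <- c("simulate", "preprocess", "qc", "mask", "drift",
               "transition")
  bad <- setdiff(stages, allowed)
  if (length(bad) > 0L) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  }
  structure(
    list(config = config, output_dir = output_dir, stages = stages,
         stringency = as.integer(stringency), fc_cutoff = fc_cutoff,
         p_cutoff = p_cutoff, top_n = as.integer(top_n),
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the synthetic-cohort pipeline
#'
#' Executes the configured stages and writes each stage's outputs as the
#' package's plain-text formats under `output_dir`. Re-running with the
#' same configuration reproduces all outputs bit-identically (the
#' manifest's `timestamp` excepted).
#'
#' @param pcfg a [pipeline_config()].
#' @return the run manifest: parameters, per-stage output paths and
#'   their md5 digests.
#' @export
run_pipeline <- function(pcfg = pipeline_config()) {
  stopifnot(inherits(pcfg, "pipeline_config"))
  dir.create(pcfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(pcfg$output_dir, ...)
  manifest <- list(
    package_version = as.character(utils::packageVersion("xenomine")),
    seed = pcfg$seed,
    parameters = pcfg[c("stringency", "fc_cutoff", "p_cutoff", "top_n")],
    stages = list(),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  cfg <- pcfg$config
  layout <- generate_chip_layout(cfg$n_probe_sets,
                                 cfg$probe_pairs_per_set,
                                 cfg$n_controls, cfg$seed)
  cohort <- NULL
  panel <- NULL
  expr <- NULL
  mask <- NULL

  if ("simulate" %in% pcfg$stages) {
    cohort <- simulate_cohort(cfg, layout)
    panel <- simulate_mouse_panel(cfg, layout)
    write_chip_layout(layout, out("layout.tsv"))
    write_sample_sheet(rbind(cohort$annotations, panel$annotations),
                       out("samples.csv"))
    manifest$stages$simulate <- list(
      outputs = c("layout.tsv", "samples.csv"),
      n_cohort_tables = length(cohort$tables),
      n_panel_tables = length(panel$tables)
    )
  }
  if ("preprocess" %in% pcfg$stages) {
    if (is.null(cohort)) stop("preprocess stage needs the simulate stage")
    expr <- rma(cohort$tables, layout)
    write_expression_matrix(expr, out("expression.tsv"))
    manifest$stages$preprocess <- list(outputs = "expression.tsv",
                                       dim = dim(expr))
  }
  if ("mask" %in% pcfg$stages) {
    if (is.null(panel)) stop("mask stage needs the simulate stage")
    calls <- detection_calls(panel$tables, layout)
    mask <- build_crosshyb_table(calls, panel$annotations)
    write_crosshyb_mask(mask, out("crosshyb_mask.tsv"))
    manifest$stages$mask <- list(
      outputs = "crosshyb_mask.tsv",
      n_flagged_s1 = sum(mask >= 1L),
      n_flagged_s4 = sum(mask >= 4L)
    )
  }
  if ("qc" %in% pcfg$stages) {
    if (is.null(expr)) stop("qc stage needs the preprocess stage")
    mask_set <- if (!is.null(mask)) {
      mask_at_stringency(mask, pcfg$stringency)
    } else {
      NULL
    }
    qc <- qc_report(expr, layout, mask_set = mask_set)
    utils::write.table(qc$flags, out("qc_flags.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$stages$qc <- list(outputs = "qc_flags.tsv",
                               n_flagged = nrow(qc$flags))
  }
  if ("drift" %in% pcfg$stages) {
    if (is.null(expr)) stop("drift stage needs the preprocess stage")
    reports <- lapply(cfg$model_names, function(m) {
      stability_metric(expr, cohort$annotations, m,
                       fc_cutoff = pcfg$fc_cutoff,
                       p_cutoff = pcfg$p_cutoff)
    })
    ranked <- rank_models_by_stability(reports)
    utils::write.table(ranked, out("stability.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$stages$drift <- list(outputs = "stability.tsv",
                                  n_models = nrow(ranked))
  }
  if ("transition" %in% pcfg$stages) {
    if (is.null(expr)) stop("transition stage needs preprocess")
    fc <- lapply(cfg$model_names, function(m) {
      average_fold_change(expr, cohort$annotations, m)
    })
    names(fc) <- cfg$model_names
    tbl <- class_fold_change(fc)
    rep <- transition_report(tbl, if (is.null(mask)) character() else mask,
                             n = pcfg$top_n,
                             stringency = pcfg$stringency)
    utils::write.table(rep$pre_mask, out("transition_pre_mask.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(rep$post_mask, out("transition_post_mask.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$transition <- list(
      outputs = c("transition_pre_mask.tsv", "transition_post_mask.tsv"))
  }
  files <- unlist(lapply(manifest$stages, `[[`, "outputs"))
  manifest$digests <- tools::md5sum(file.path(pcfg$output_dir, files))
  names(manifest$digests) <- files
  manifest
}
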