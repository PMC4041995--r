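## Synthetic cohort generator with a ground-truth channel.
##
## The generator emulates the study design it is meant to exercise: human
## tumor models profiled in vitro (P0) and across serial in vivo passages
## (P1, P4, P10) with five tumors per passage, a five-sample x three-
## replicate mouse-RNA panel on human arrays for cross-hybridization mask
## building, per-model passage drift, mouse RNA admixture that signals only
## through a cross-hybridizing probe-set subset, and a "mouse outgrowth"
## scenario in which late passages carry 100% mouse signal.

#' Configuration for the synthetic xenograft cohort generator
#'
#' Signal model, per probe set j and sample with mouse fraction f:
#' human log2 abundance `a_j ~ Normal(8, 2)`; a drifting probe set in model
#' m gains a passage-dependent log2 effect `e_{m,j}(t)`; the true signal is
#' `s = (1 - f) * 2^(a_j + e) + f * affinity_j * 2^(a_j)`; probe pairs then
#' measure `PM = s * 2^eps + bg` and `MM = mm_leak * s * 2^eps' + bg` with
#' `eps, eps' ~ Normal(0, noise_sd)` and `bg ~ Exponential(mean =
#' background_mean)` (multiplicative log-normal noise plus additive
#' exponential background, the standard microarray error structure).
#'
#' @param model_names character vector of model (cell line) names.
#' @param n_probe_sets number of non-control probe sets.
#' @param probe_pairs_per_set probe pairs per probe set (platform norm 11).
#' @param n_controls number of `AFFX-` control probe sets.
#' @param replicates_per_passage tumors harvested per in vivo passage.
#' @param n_p0_replicates in vitro (P0) replicates.
#' @param n_signature_sets number of probe sets per model given a
#'   constant (all-passage, P0 included) baseline up-shift — the model's
#'   identity signature, what distinguishes one cell line's transcriptome
#'   from another's. Default 0: the recovery and null-calibration suites
#'   are defined on the shared-baseline cohort; enable for co-clustering
#'   analyses.
#' @param signature_log2_range range of the signature log2 offsets
#'   (default 100-fold to 1024-fold, the scale at which cell lines
#'   separate).
#' @param n_drifting_sets number of probe sets per model given a passage
#'   drift effect (ground truth channel).
#' @param drift_log2_range range of |log2 effect| for drifting sets;
#'   effects are drawn uniformly in this range.
#' @param drift_frac_up fraction of drifting sets shifted upward.
#' @param drift_onset `"linear"` (effect grows linearly over the in vivo
#'   passage index P1 -> P4 -> P10, so about half the P1->P10 change is
#'   present at P4) or `"step_p4"` (full effect from P4 on).
#' @param n_transition_sets number of probe sets per model given a P0->P1
#'   (in vitro -> in vivo) log2 effect.
#' @param transition_log2_range range of |log2 effect| for transition sets.
#' @param mouse_fraction mouse RNA admixture fraction for ordinary in vivo
#'   samples (P0 samples are always pure human).
#' @param outgrowth_models models whose P4/P10 samples are 100% mouse
#'   signal (host outgrowth scenario).
#' @param crosshyb_fraction fraction of probe sets given nonzero mouse
#'   affinity.
#' @param crosshyb_affinity_range range of affinity weights in (0, 1] for
#'   cross-hybridizing probe sets.
#' @param mouse_expressed_fraction per mouse biological sample, the
#'   probability that a transcript is expressed at all.
#' @param n_mouse_samples,mouse_replicates mouse panel design (5 biological
#'   samples x 3 replicates in the study).
#' @param noise_sd standard deviation of the additive log2 noise.
#' @param mm_leak fraction of true signal leaking into MM probes, in [0,1).
#' @param background_mean mean of the exponential additive background.
#' @param seed integer seed; all generators are deterministic given it.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(model_names = "MODEL-1",
                          n_probe_sets = 500,
                          probe_pairs_per_set = 11,
                          n_controls = 10,
                          replicates_per_passage = 5,
                          n_p0_replicates = 3,
                          n_signature_sets = 0,
                          signature_log2_range = c(log2(100), 10),
                          n_drifting_sets = 0,
                          drift_log2_range = c(2, 3),
                          drift_frac_up = 0.5,
                          drift_onset = c("linear", "step_p4"),
                          n_transition_sets = 0,
                          transition_log2_range = c(1.5, 3),
                          mouse_fraction = 0.05,
                          outgrowth_models = character(),
                          crosshyb_fraction = 0.1,
                          crosshyb_affinity_range = c(0.3, 1),
                          mouse_expressed_fraction = 0.7,
                          n_mouse_samples = 5,
                          mouse_replicates = 3,
                          noise_sd = 0.25,
                          mm_leak = 0.3,
                          background_mean = 5,
                          seed = 1) {
  drift_onset <- match.arg(drift_onset)
  cfg <- list(
    model_names = as.character(model_names),
    n_probe_sets = as.integer(n_probe_sets),
    probe_pairs_per_set = as.integer(probe_pairs_per_set),
    n_controls = as.integer(n_controls),
    replicates_per_passage = as.integer(replicates_per_passage),
    n_p0_replicates = as.integer(n_p0_replicates),
    n_signature_sets = as.integer(n_signature_sets),
    signature_log2_range = as.numeric(signature_log2_range),
    n_drifting_sets = as.integer(n_drifting_sets),
    drift_log2_range = as.numeric(drift_log2_range),
    drift_frac_up = as.numeric(drift_frac_up),
    drift_onset = drift_onset,
    n_transition_sets = as.integer(n_transition_sets),
    transition_log2_range = as.numeric(transition_log2_range),
    mouse_fraction = as.numeric(mouse_fraction),
    outgrowth_models = as.character(outgrowth_models),
    crosshyb_fraction = as.numeric(crosshyb_fraction),
    crosshyb_affinity_range = as.numeric(crosshyb_affinity_range),
    mouse_expressed_fraction = as.numeric(mouse_expressed_fraction),
    n_mouse_samples = as.integer(n_mouse_samples),
    mouse_replicates = as.integer(mouse_replicates),
    noise_sd = as.numeric(noise_sd),
    mm_leak = as.numeric(mm_leak),
    background_mean = as.numeric(background_mean),
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

#' @rdname cohort_config
#' @param config a `cohort_config` list.
#' @export
validate_cohort_config <- function(config) {
  with(config, {
    if (probe_pairs_per_set < 1L) stop("probe_pairs_per_set must be >= 1")
    if (n_probe_sets < 1L) stop("n_probe_sets must be >= 1")
    if (n_drifting_sets > n_probe_sets) {
      stop("n_drifting_sets exceeds n_probe_sets")
    }
    if (n_signature_sets > n_probe_sets) {
      stop("n_signature_sets exceeds n_probe_sets")
    }
    if (n_transition_sets > n_probe_sets) {
      stop("n_transition_sets exceeds n_probe_sets")
    }
    for (f in c(mouse_fraction, crosshyb_fraction, drift_frac_up,
                mouse_expressed_fraction)) {
      if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
    }
    if (mm_leak < 0 || mm_leak >= 1) stop("mm_leak must lie in [0, 1)")
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    if (background_mean < 0) stop("background_mean must be >= 0")
    if (!all(outgrowth_models %in% model_names)) {
      stop("outgrowth_models must be a subset of model_names")
    }
  })
  invisible(config)
}

#' Generate a chip layout for the synthetic cohort
#'
#' Probe-set identifiers follow the platform's suffix convention
#' (`<number>_at`); control sets are prefixed `AFFX-`. Deterministic for a
#' fixed seed.
#'
#' @param n_probe_sets number of non-control probe sets.
#' @param probe_pairs_per_set probe pairs per set.
#' @param n_controls number of control probe sets.
#' @param seed integer seed.
#' @return a [chip_layout()].
#' @export
generate_chip_layout <- function(n_probe_sets, probe_pairs_per_set,
                                 n_controls = 0, seed = 1) {
  if (probe_pairs_per_set < 1) stop("probe_pairs_per_set must be >= 1")
  if (n_probe_sets < 1) stop("n_probe_sets must be >= 1")
  set.seed(seed)
  ids <- c(
    sprintf("%06d_at", sample.int(899999, n_probe_sets) + 100000L),
    if (n_controls > 0) sprintf("AFFX-Ctrl%03d_at", seq_len(n_controls))
  )
  chip_layout(rep(ids, each = probe_pairs_per_set))
}

## Passage-effect multiplier for the drift onset model: fraction of the
## full P1->P10 effect present at each passage.
.drift_weight <- function(passage, onset) {
  w <- switch(onset,
    linear = c(P0 = 0, P1 = 0, P4 = 0.5, P10 = 1),
    step_p4 = c(P0 = 0, P1 = 0, P4 = 1, P10 = 1)
  )
  unname(w[passage])
}

## Draw probe-pair level intensities for one sample given true per-set
## linear signal s (named by probe set id).
.measure_sample <- function(signal, layout, config) {
  per_pair <- signal[layout$probe_set_of]
  n <- layout$n_probe_pairs
  eps <- stats::rnorm(n, 0, config$noise_sd)
  eps2 <- stats::rnorm(n, 0, config$noise_sd)
  # background is spatially smooth on a chip, so a pair's PM and MM cells
  # share one draw (the ideal-mismatch assumption); a zero-signal probe
  # set then has PM = MM exactly and is called Absent, never Present.
  bg <- if (config$background_mean > 0) {
    stats::rexp(n, rate = 1 / config$background_mean)
  } else {
    numeric(n)
  }
  list(
    pm = per_pair * 2^eps + bg,
    mm = config$mm_leak * per_pair * 2^eps2 + bg
  )
}

## Shared truth scaffolding: abundances, drifting / transition /
## cross-hybridizing probe-set assignments. Controls get a fixed high
## abundance and never drift or cross-hybridize.
.draw_truth <- function(config, layout) {
  ids <- layout$probe_set_ids
  ctrl <- layout$control_ids
  target <- setdiff(ids, ctrl)
  abundance <- stats::setNames(stats::rnorm(length(ids), 8, 2), ids)
  if (length(ctrl) > 0) {
    # spike-in style controls: a fixed graded series, so each good chip
    # shows the same structured control profile
    abundance[ctrl] <- seq(7, 13, length.out = length(ctrl))
  }
  n_xhyb <- round(config$crosshyb_fraction * length(target))
  xhyb_ids <- sample(target, n_xhyb)
  affinity <- stats::setNames(numeric(length(ids)), ids)
  affinity[xhyb_ids] <- stats::runif(n_xhyb,
                                     config$crosshyb_affinity_range[1],
                                     config$crosshyb_affinity_range[2])
  drifting <- list()
  transition <- list()
  signature <- list()
  for (m in config$model_names) {
    s_ids <- sample(target, config$n_signature_sets)
    signature[[m]] <- stats::setNames(
      stats::runif(length(s_ids), config$signature_log2_range[1],
                   config$signature_log2_range[2]), s_ids)
    d_ids <- sample(target, config$n_drifting_sets)
    sign_up <- stats::rbinom(length(d_ids), 1, config$drift_frac_up) * 2 - 1
    d_eff <- sign_up * stats::runif(length(d_ids),
                                    config$drift_log2_range[1],
                                    config$drift_log2_range[2])
    drifting[[m]] <- stats::setNames(d_eff, d_ids)
    t_ids <- sample(target, config$n_transition_sets)
    t_sign <- stats::rbinom(length(t_ids), 1, 0.5) * 2 - 1
    t_eff <- t_sign * stats::runif(length(t_ids),
                                   config$transition_log2_range[1],
                                   config$transition_log2_range[2])
    transition[[m]] <- stats::setNames(t_eff, t_ids)
  }
  list(abundance = abundance, affinity = affinity,
       crosshyb_ids = sort(xhyb_ids), drifting = drifting,
       transition = transition, signature = signature)
}

#' Simulate a xenograft cohort at probe level
#'
#' Generates P0/P1/P4/P10 samples for each configured model under the
#' documented signal model, together with the ground truth needed to score
#' downstream recovery (drifting set ids and effects, transition effects,
#' cross-hybridization affinities, per-sample species mix).
#'
#' @param config a [cohort_config()].
#' @param layout a [chip_layout()] (typically from
#'   [generate_chip_layout()]).
#' @return list with `tables` (list of [probe_intensity_table()]),
#'   `annotations` (sample-sheet data.frame) and `truth`.
#' @export
simulate_cohort <- function(config, layout) {
  validate_cohort_config(config)
  stopifnot(inherits(layout, "chip_layout"))
  set.seed(config$seed)
  truth <- .draw_truth(config, layout)
  ids <- layout$probe_set_ids
  tables <- list()
  ann <- list()
  mix <- list()
  for (m in config$model_names) {
    for (p in c("P0", "P1", "P4", "P10")) {
      n_rep <- if (p == "P0") config$n_p0_replicates else
        config$replicates_per_passage
      for (r in seq_len(n_rep)) {
        f <- if (p == "P0") {
          0
        } else if (m %in% config$outgrowth_models && p %in% c("P4", "P10")) {
          1
        } else {
          config$mouse_fraction
        }
        e <- numeric(length(ids))
        names(e) <- ids
        if (length(truth$signature[[m]]) > 0) {
          e[names(truth$signature[[m]])] <- truth$signature[[m]]
        }
        dw <- .drift_weight(p, config$drift_onset)
        if (dw > 0 && length(truth$drifting[[m]]) > 0) {
          e[names(truth$drifting[[m]])] <-
            e[names(truth$drifting[[m]])] + dw * truth$drifting[[m]]
        }
        if (p != "P0" && length(truth$transition[[m]]) > 0) {
          e[names(truth$transition[[m]])] <-
            e[names(truth$transition[[m]])] + truth$transition[[m]]
        }
        human <- 2^(truth$abundance + e)
        mouse <- truth$affinity * 2^truth$abundance
        s <- (1 - f) * human + f * mouse
        meas <- .measure_sample(s, layout, config)
        sid <- sprintf("%s_%s_r%d", m, p, r)
        tables[[sid]] <- probe_intensity_table(sid, meas$pm, meas$mm, layout)
        ann[[sid]] <- data.frame(
          sample_id = sid, model_name = m, passage = p, replicate_index = r,
          rna_species = "human", tumor_class = "synthetic",
          stringsAsFactors = FALSE
        )
        mix[[sid]] <- f
      }
    }
  }
  annotations <- do.call(rbind, ann)
  rownames(annotations) <- NULL
  truth$species_mix <- unlist(mix)
  list(tables = unname(tables), annotations = annotations, truth = truth)
}

#' Simulate the mouse-RNA-on-human-array panel
#'
#' Mouse biological samples (default 5, e.g. universal RNA, tumor, host
#' skin) each express a random transcript subset; signal reaches the human
#' probes only through probe sets with nonzero cross-hybridization
#' affinity. Each biological sample is measured in replicate (default 3).
#'
#' @inheritParams simulate_cohort
#' @return list with `tables` (n_mouse_samples x mouse_replicates
#'   [probe_intensity_table()]s), `annotations`, and `truth` including
#'   `expected_detected`: per biological sample, the probe sets carrying
#'   above-background signal (affinity > 0 and transcript expressed).
#' @export
simulate_mouse_panel <- function(config, layout) {
  validate_cohort_config(config)
  stopifnot(inherits(layout, "chip_layout"))
  # the truth scaffold (abundances, cross-hybridization affinities) is a
  # property of the chip and cohort, so it is drawn from the same seed
  # as simulate_cohort; only the panel's own sampling diverges after
  set.seed(config$seed)
  truth <- .draw_truth(config, layout)
  set.seed(config$seed + 1L)
  ids <- layout$probe_set_ids
  tables <- list()
  ann <- list()
  expected <- list()
  for (s in seq_len(config$n_mouse_samples)) {
    msid <- sprintf("MOUSE-%d", s)
    expressed <- ids[stats::runif(length(ids)) <
                       config$mouse_expressed_fraction]
    carrying <- intersect(expressed, names(which(truth$affinity > 0)))
    expected[[msid]] <- sort(carrying)
    signal <- stats::setNames(numeric(length(ids)), ids)
    signal[carrying] <- truth$affinity[carrying] *
      2^truth$abundance[carrying]
    for (r in seq_len(config$mouse_replicates)) {
      meas <- .measure_sample(signal, layout, config)
      sid <- sprintf("%s_r%d", msid, r)
      tables[[sid]] <- probe_intensity_table(sid, meas$pm, meas$mm, layout)
      ann[[sid]] <- data.frame(
        sample_id = sid, model_name = msid, passage = "MOUSE_PANEL",
        replicate_index = r, rna_species = "mouse",
        tumor_class = "mouse panel", stringsAsFactors = FALSE
      )
    }
  }
  annotations <- do.call(rbind, ann)
  rownames(annotations) <- NULL
  truth$expected_detected <- expected
  list(tables = unname(tables), annotations = annotations, truth = truth)
}
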