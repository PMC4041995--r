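test_that("pairwise DE finds nothing between splits of identical replicates", {
  ann <- tiny_annotations(passages = c(P1 = 6))
  m <- expr_from_annotations(ann, n_sets = 40, seed = 14)
  m[] <- rep(rnorm(40, 8, 1), times = 6)  # identical columns
  res <- pairwise_de(m, ann$sample_id[1:3], ann$sample_id[4:6],
                     fc_cutoff = 1.01)
  expect_equal(nrow(res), 0)
})

test_that("pairwise DE matches the textbook pooled-t computation", {
  # constructed probe set: means 4 vs 6, sd 0.05, n = 5 per group
  a_vals <- 4 + c(-0.05, -0.025, 0, 0.025, 0.05)
  b_vals <- 6 + c(-0.05, -0.025, 0, 0.025, 0.05)
  m <- matrix(c(a_vals, b_vals), 1, 10,
              dimnames = list("PS1", paste0("s", 1:10)))
  res <- pairwise_de(m, paste0("s", 1:5), paste0("s", 6:10),
                     fc_cutoff = 3, p_cutoff = 0.05, pct = 0)
  expect_equal(res$fold_change, 4, tolerance = 1e-12)
  expect_equal(res$direction, "up")
  expect_lt(res$p_value, 1e-6)
  # textbook pooled t on the same numbers
  oracle <- t.test(b_vals, a_vals, var.equal = TRUE)$p.value
  expect_equal(res$p_value, oracle, tolerance = 1e-12)
})

test_that("two-group ANOVA equals the pooled t-test, and aov agrees", {
  set.seed(15)
  m <- matrix(rnorm(20 * 8, 8, 1), 20, 8,
              dimnames = list(sprintf("PS%02d", 1:20), paste0("s", 1:8)))
  full <- pairwise_de(m, paste0("s", 1:4), paste0("s", 5:8),
                      pct = 0, full = TRUE)
  grp <- factor(rep(c("a", "b"), each = 4))
  for (i in c(1, 7, 13)) {
    p_aov <- summary(aov(m[i, ] ~ grp))[[1]][["Pr(>F)"]][1]
    p_t <- t.test(m[i, 1:4], m[i, 5:8], var.equal = TRUE)$p.value
    expect_equal(full$p_value[i], p_aov, tolerance = 1e-10)
    expect_equal(full$p_value[i], p_t, tolerance = 1e-10)
  }
})

test_that("pairwise DE rejects malformed groups", {
  ann <- tiny_annotations(passages = c(P1 = 4))
  m <- expr_from_annotations(ann, n_sets = 10, seed = 16)
  expect_error(pairwise_de(m, ann$sample_id[1:2], ann$sample_id[2:3]),
               "overlap")
  expect_error(pairwise_de(m, ann$sample_id[1], ann$sample_id[2:3]),
               "group_a")
})

test_that("stability metric recovers injected drift and is null-calibrated", {
  # background 0 isolates the estimator from the documented fold-change
  # compression that additive background causes for low-abundance sets
  cfg <- cohort_config(n_probe_sets = 300, n_drifting_sets = 15,
                       drift_log2_range = c(2, 2.5), noise_sd = 0.1,
                       mouse_fraction = 0, background_mean = 0, seed = 17)
  lay <- generate_chip_layout(300, 11, 5, seed = 17)
  co <- simulate_cohort(cfg, lay)
  e <- rma(co$tables, lay)
  rep <- stability_metric(e, co$annotations, "MODEL-1")
  truth_n <- length(co$truth$drifting[["MODEL-1"]])
  expect_equal(rep$n_changed_P1_P10, truth_n, tolerance = 0.2)
  # linear onset: at P4 only half the effect is present, below the
  # 3-fold cutoff for these effect sizes
  expect_lt(rep$n_changed_P1_P4, rep$n_changed_P1_P10)

  # null cohort: no counts at the 3-fold cutoff
  cfg0 <- cohort_config(n_probe_sets = 300, n_drifting_sets = 0,
                        noise_sd = 0.1, mouse_fraction = 0,
                        background_mean = 0, seed = 18)
  co0 <- simulate_cohort(cfg0, lay)
  e0 <- rma(co0$tables, lay)
  rep0 <- stability_metric(e0, co0$annotations, "MODEL-1")
  expect_equal(rep0$n_changed_P1_P10, 0)

  expect_error(
    stability_metric(e, co$annotations[co$annotations$passage != "P4", ],
                     "MODEL-1"),
    "lacks passage")
})

test_that("stability counts respect cutoff monotonicity and shift invariance", {
  cfg <- cohort_config(n_probe_sets = 150, n_drifting_sets = 10,
                       drift_log2_range = c(1, 3), noise_sd = 0.2,
                       mouse_fraction = 0, seed = 19)
  lay <- generate_chip_layout(150, 6, 0, seed = 19)
  co <- simulate_cohort(cfg, lay)
  e <- rma(co$tables, lay)
  n_loose <- stability_metric(e, co$annotations, "MODEL-1",
                              fc_cutoff = 2)$n_changed_P1_P10
  n_default <- stability_metric(e, co$annotations, "MODEL-1",
                                fc_cutoff = 3)$n_changed_P1_P10
  n_strict_p <- stability_metric(e, co$annotations, "MODEL-1",
                                 fc_cutoff = 3,
                                 p_cutoff = 0.01)$n_changed_P1_P10
  expect_gte(n_loose, n_default)
  expect_gte(n_default, n_strict_p)

  shifted <- stability_metric(e + 5, co$annotations, "MODEL-1")
  expect_equal(shifted$n_changed_P1_P10, n_default)

  # order of samples is immaterial
  perm <- sample(ncol(e))
  resh <- stability_metric(e[, perm], co$annotations, "MODEL-1")
  expect_equal(resh$n_changed_P1_P10, n_default)

  # degenerate completeness: no cutoffs, count = retained probe sets
  all_in <- stability_metric(e, co$annotations, "MODEL-1",
                             fc_cutoff = 1, p_cutoff = 1, pct = 0)
  expect_equal(all_in$n_changed_P1_P10, nrow(e))
})

test_that("model ranking sorts ascending with the documented tie-breaks", {
  reports <- list(
    data.frame(model_name = "A", n_changed_P1_P4 = 9, n_changed_P1_P10 = 10),
    data.frame(model_name = "C", n_changed_P1_P4 = 3, n_changed_P1_P10 = 5),
    data.frame(model_name = "B", n_changed_P1_P4 = 2, n_changed_P1_P10 = 5)
  )
  ranked <- rank_models_by_stability(reports)
  expect_equal(ranked$model_name, c("B", "C", "A"))
  expect_equal(ranked$rank, 1:3)
  # shuffled input gives the same order
  expect_equal(rank_models_by_stability(rev(reports))$model_name,
               ranked$model_name)
  expect_equal(rank_models_by_stability(reports[2])$rank, 1)
  expect_error(rank_models_by_stability(c(reports, reports[1])),
               "duplicate model")
})

test_that("trajectories recover per-model injected drift", {
  ann <- rbind(tiny_annotations("X"), tiny_annotations("Y"))
  m <- expr_from_annotations(ann, n_sets = 20, seed = 20, sd = 0.01)
  # inject +2 log2 drift on PS005 in model X only
  m["PS005_at", ann$model_name == "X" & ann$passage == "P10"] <-
    m["PS005_at", ann$model_name == "X" & ann$passage == "P10"] + 2

  traj <- transcript_trajectory("PS005_at", m, ann)
  expect_equal(traj$delta_P1_P10[traj$model_name == "X"], 2,
               tolerance = 0.05)
  expect_equal(traj$delta_P1_P10[traj$model_name == "Y"], 0,
               tolerance = 0.05)

  # constant probe set: all deltas 0
  m["PS001_at", ] <- 8
  traj0 <- transcript_trajectory("PS001_at", m, ann)
  expect_equal(traj0$delta_P1_P10, c(0, 0))

  # missing P10 for one model: delta is NA, never silently 0
  sub <- ann$sample_id[!(ann$model_name == "Y" & ann$passage == "P10")]
  traj_na <- transcript_trajectory("PS005_at", m[, sub],
                                   ann[ann$sample_id %in% sub, ])
  expect_true(is.na(traj_na$delta_P1_P10[traj_na$model_name == "Y"]))

  expect_error(transcript_trajectory("nope", m, ann), "unknown probe set")
})

test_that("expression ranking is descending with alphabetical tie-break", {
  ann <- rbind(tiny_annotations("B", c(P1 = 2)),
               tiny_annotations("A", c(P1 = 2)),
               tiny_annotations("C", c(P1 = 2)))
  m <- matrix(c(8, 8, 6, 6, 8, 8), 1, 6,
              dimnames = list("PS1", ann$sample_id))
  ranked <- rank_models_by_expression("PS1", m, ann, "P1")
  expect_equal(ranked$model_name, c("B", "C", "A"))
  expect_equal(ranked$mean_log2, c(8, 8, 6))

  # injected +3 log2 puts a model first
  m2 <- matrix(rnorm(6, 7, 0.01), 1, 6,
               dimnames = list("PS1", ann$sample_id))
  m2[1, ann$model_name == "C"] <- m2[1, ann$model_name == "C"] + 3
  expect_equal(rank_models_by_expression("PS1", m2, ann)$model_name[1], "C")
})
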