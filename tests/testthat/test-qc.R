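test_that("control-probe QC flags profiles decorrelated from the cohort", {
  lay <- tiny_layout(3, 2, n_controls = 8)
  set.seed(5)
  ctrl_profile <- rnorm(8, 10, 2)
  m <- matrix(rnorm(11 * 6, 8, 0.1), 11, 6,
              dimnames = list(lay$probe_set_ids, paste0("s", 1:6)))
  m[lay$control_ids, ] <- ctrl_profile + rnorm(48, 0, 0.05)

  ok <- control_probe_profile(m, lay)
  expect_true(ok$evaluable)
  expect_false(any(ok$flagged))

  # one sample with shuffled control values decorrelates and is flagged
  bad <- m
  bad[lay$control_ids, "s3"] <- sample(bad[lay$control_ids, "s3"])
  res <- control_probe_profile(bad, lay)
  expect_true(res$flagged[["s3"]])
  expect_false(any(res$flagged[names(res$flagged) != "s3"]))

  # cohort of one: not evaluable, nothing flagged
  single <- control_probe_profile(m[, 1, drop = FALSE], lay)
  expect_false(single$evaluable)
  expect_false(any(single$flagged))

  no_ctrl <- tiny_layout(3, 2, n_controls = 0)
  expect_error(control_probe_profile(m, no_ctrl), "control probe")
})

test_that("PCA outlier detection flags displaced samples only", {
  set.seed(6)
  base <- matrix(rnorm(50 * 22, 8, 0.5), 50, 22,
                 dimnames = list(sprintf("PS%02d", 1:50),
                                 sprintf("s%02d", 1:22)))
  # identical samples: zero variance, no outliers
  same <- base
  same[] <- 8
  res0 <- pca_outliers(same)
  expect_true(res0$evaluable)
  expect_false(any(res0$flagged))

  # two samples displaced 50 sigma along a random direction
  dir <- rnorm(50)
  dir <- dir / sqrt(sum(dir^2))
  shifted <- base
  shifted[, 21] <- shifted[, 21] + 50 * 0.5 * dir
  shifted[, 22] <- shifted[, 22] + 50 * 0.5 * dir
  res <- pca_outliers(shifted)
  expect_setequal(names(which(res$flagged)), c("s21", "s22"))

  # invariance to adding a constant to all expression values
  res_shift <- pca_outliers(shifted + 100)
  expect_equal(res$z, res_shift$z, tolerance = 1e-8)

  expect_false(pca_outliers(base[, 1:2])$evaluable)
})

test_that("co-clustering recovers block-diagonal model structure", {
  # 3 models x (2 P0 + 3 P1), disjoint high-fold signatures
  ann <- do.call(rbind, lapply(c("A", "B", "C"), function(m) {
    tiny_annotations(m, passages = c(P0 = 2, P1 = 3))
  }))
  set.seed(9)
  m <- expr_from_annotations(ann, n_sets = 60, seed = 9, sd = 0.1)
  sig <- split(1:30, rep(c("A", "B", "C"), each = 10))
  for (mod in names(sig)) {
    m[sig[[mod]], ann$model_name == mod] <-
      m[sig[[mod]], ann$model_name == mod] + 8
  }
  res <- hierarchical_cocluster(m, ann, fold_cutoff = 100)
  expect_equal(unname(res$purity[c("A", "B", "C")]), c(1, 1, 1))

  # duplicated sample: distance 0, merged first
  dup_ann <- rbind(ann, data.frame(
    sample_id = "A_P1_r99", model_name = "A", passage = "P1",
    replicate_index = 99, rna_species = "human", tumor_class = "synthetic"))
  m2 <- cbind(m, A_P1_r99 = m[, "A_P1_r1"])
  res2 <- hierarchical_cocluster(m2, dup_ann, fold_cutoff = 100)
  first <- res2$hclust$merge[1, ]
  leaves <- colnames(m2)[-first]
  expect_setequal(leaves, c("A_P1_r1", "A_P1_r99"))

  # two models sharing one signature co-cluster: purity < 1, not an error
  shared_ann <- do.call(rbind, lapply(c("X", "Y", "Z"), function(mm) {
    tiny_annotations(mm, passages = c(P0 = 2, P1 = 3))
  }))
  ms <- expr_from_annotations(shared_ann, n_sets = 60, seed = 10, sd = 0.1)
  ms[1:10, shared_ann$model_name %in% c("X", "Y")] <-
    ms[1:10, shared_ann$model_name %in% c("X", "Y")] + 8
  ms[11:20, shared_ann$model_name == "Z"] <-
    ms[11:20, shared_ann$model_name == "Z"] + 8
  res3 <- hierarchical_cocluster(ms, shared_ann, fold_cutoff = 100)
  expect_lt(res3$purity[["X"]], 1)
  expect_lt(res3$purity[["Y"]], 1)

  # an over-aggressive filter is an actionable error
  expect_error(hierarchical_cocluster(m, ann, fold_cutoff = 1e9),
               "lower fold_cutoff")
})

test_that("species-composition score orders samples by mouse admixture", {
  set.seed(12)
  ids <- sprintf("PS%03d", 1:200)
  masked <- ids[1:20]
  human_level <- rnorm(200, 8, 1)
  score_of <- function(f) {
    # mouse fraction f: masked sets keep signal, unmasked fade out
    x <- human_level
    x[!(ids %in% masked)] <- log2((1 - f) * 2^x[!(ids %in% masked)] +
                                    2^rnorm(180, 2, 0.3))
    matrix(x, dimnames = list(ids, "s"))
  }
  fractions <- c(0, 0.25, 0.5, 0.75, 1)
  scores <- vapply(fractions, function(f) {
    species_composition_score(score_of(f), masked)$score
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))

  # pure-mouse sample scores highest in a mixed cohort and is flagged
  cohort <- cbind(score_of(0), score_of(0), score_of(1))
  colnames(cohort) <- c("h1", "h2", "mouse")
  res <- species_composition_score(cohort, masked)
  expect_equal(res$sample_id[which.max(res$score)], "mouse")
  expect_true(res$flagged[res$sample_id == "mouse"])
  expect_false(any(res$flagged[res$sample_id != "mouse"]))

  # degenerate masks are not evaluable
  expect_false(isTRUE(species_composition_score(cohort, ids)$evaluable))
  expect_false(isTRUE(species_composition_score(cohort, character())$evaluable))
})
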