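make_panel_calls <- function(call_matrix, n_bio = 5, n_rep = 3) {
  samples <- colnames(call_matrix)
  ann <- data.frame(
    sample_id = samples,
    model_name = rep(sprintf("MOUSE-%d", seq_len(n_bio)), each = n_rep),
    passage = "MOUSE_PANEL",
    replicate_index = rep(seq_len(n_rep), n_bio),
    rna_species = "mouse", tumor_class = "mouse panel",
    stringsAsFactors = FALSE
  )
  calls <- structure(
    list(call = call_matrix,
         p = matrix(0.5, nrow(call_matrix), ncol(call_matrix),
                    dimnames = dimnames(call_matrix))),
    class = "detection_call_table"
  )
  list(calls = calls, annotations = ann)
}

test_that("the replicate detection predicate reads patterns order-free", {
  # the stated pattern set shares exactly the >=2-Present property
  expect_true(sample_detected(c("P", "P", "P")))
  expect_true(sample_detected(c("P", "P", "M")))
  expect_true(sample_detected(c("P", "P", "A")))
  expect_true(sample_detected(c("A", "P", "P")))  # order-free
  expect_false(sample_detected(c("A", "A", "A")))
  expect_false(sample_detected(c("P", "M", "M")))
  expect_false(sample_detected(c("P", "A", "A")))
  expect_error(sample_detected(c("P", "P")), "expected 3")
  expect_error(sample_detected(c("P", "P", "X")), "P, M or A")
})

test_that("mask counts match exhaustive hand enumeration on a toy panel", {
  ids <- sprintf("PS%02d", 1:10)
  set.seed(21)
  cm <- matrix(sample(c("P", "M", "A"), 10 * 15, replace = TRUE,
                      prob = c(0.4, 0.2, 0.4)),
               10, 15,
               dimnames = list(ids, sprintf("m%02d", 1:15)))
  fix <- make_panel_calls(cm)
  mask <- build_crosshyb_table(fix$calls, fix$annotations)

  # brute-force oracle: loop every probe set and biological sample
  for (i in seq_len(10)) {
    n_det <- 0
    for (b in 1:5) {
      reps <- cm[i, (b - 1) * 3 + 1:3]
      if (sum(reps == "P") >= 2) n_det <- n_det + 1
    }
    expect_equal(unname(mask[ids[i]]), n_det)
  }

  # no probe set detected anywhere -> empty mask at every stringency
  none <- cm
  none[] <- "A"
  empty <- build_crosshyb_table(make_panel_calls(none)$calls,
                                fix$annotations)
  for (s in 1:5) expect_length(mask_at_stringency(empty, s), 0)

  # a human sample in the panel is an error
  bad_ann <- fix$annotations
  bad_ann$rna_species[4] <- "human"
  expect_error(build_crosshyb_table(fix$calls, bad_ann), "non-mouse")
})

test_that("stringency views are nested and order-invariant", {
  set.seed(22)
  for (rep in 1:10) {
    cm <- matrix(sample(c("P", "M", "A"), 8 * 15, replace = TRUE),
                 8, 15,
                 dimnames = list(sprintf("PS%d", 1:8),
                                 sprintf("m%02d", 1:15)))
    fix <- make_panel_calls(cm)
    mask <- build_crosshyb_table(fix$calls, fix$annotations)
    for (s in 1:4) {
      expect_true(all(mask_at_stringency(mask, s + 1) %in%
                        mask_at_stringency(mask, s)))
    }
    # permuting panel columns (samples and replicates) changes nothing
    perm <- c(4:6, 1:3, 13:15, 7:9, 12, 10, 11)
    fix2 <- make_panel_calls(cm[, perm])
    mask2 <- build_crosshyb_table(fix2$calls, fix2$annotations)
    expect_equal(as.integer(mask[names(mask2)]), as.integer(mask2))
  }
  fix <- make_panel_calls(matrix("A", 2, 15,
                                 dimnames = list(c("a", "b"),
                                                 sprintf("m%d", 1:15))))
  mask <- build_crosshyb_table(fix$calls, fix$annotations)
  expect_error(mask_at_stringency(mask, 0), "stringency")
  expect_error(mask_at_stringency(mask, 6), "stringency")
})

test_that("generator truth propagates into the mask", {
  cfg <- cohort_config(n_probe_sets = 80, probe_pairs_per_set = 11,
                       crosshyb_fraction = 0.15,
                       crosshyb_affinity_range = c(0.8, 1),
                       mouse_expressed_fraction = 1,
                       noise_sd = 0.1, background_mean = 20, seed = 23)
  lay <- generate_chip_layout(80, 11, 0, seed = 23)
  panel <- simulate_mouse_panel(cfg, lay)
  calls <- detection_calls(panel$tables, lay)
  mask <- build_crosshyb_table(calls, panel$annotations)
  # every transcript is expressed in every mouse sample, so the truly
  # cross-hybridizing sets must be detected in all 5 samples
  xhyb <- panel$truth$crosshyb_ids
  expect_true(all(mask[xhyb] == 5))
  expect_true(all(mask[setdiff(names(mask), xhyb)] == 0))
})

test_that("apply_mask partitions a ranked list order-preservingly", {
  tbl <- data.frame(probe_set_id = c("a", "b", "c", "d", "e"),
                    fold_change = c(9, 7, 5, 3, 1),
                    stringsAsFactors = FALSE)
  res <- apply_mask(tbl, c("b", "d"))
  expect_equal(res$retained$probe_set_id, c("a", "c", "e"))
  expect_equal(res$retained$rank, 1:3)
  expect_equal(res$removed$probe_set_id, c("b", "d"))

  # empty mask: unchanged; idempotence on the retained list
  expect_equal(apply_mask(tbl, character())$retained$probe_set_id,
               tbl$probe_set_id)
  again <- apply_mask(res$retained, c("b", "d"))
  expect_equal(again$retained$probe_set_id, res$retained$probe_set_id)
})

test_that("masks serialize without zero rows and load with a universe", {
  counts <- structure(c(a = 5L, b = 4L, c = 1L, d = 0L),
                      class = "crosshyb_mask", n_samples = 5L)
  expect_setequal(mask_at_stringency(counts, 4), c("a", "b"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_crosshyb_mask(counts, path)
  body <- read.delim(path, comment.char = "#")
  expect_false("d" %in% body$probe_set_id)  # zeros omitted from the file
  back <- read_crosshyb_mask(path, universe = c("a", "b", "c", "d"))
  expect_equal(unname(back[c("a", "b", "c", "d")]), c(5L, 4L, 1L, 0L))
})
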