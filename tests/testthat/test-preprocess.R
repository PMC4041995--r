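test_that("median scaling hits the target exactly and errors on zero signal", {
  lay <- tiny_layout(2, 5)
  # median 250 doubled to 500
  tab <- probe_intensity_table("S", rep(250, 10), rep(100, 10), lay)
  out <- scale_to_median(tab, 500)
  expect_equal(out$pm, rep(500, 10))
  expect_equal(out$mm, rep(200, 10))

  # already at target: unchanged
  lay11 <- chip_layout(rep("PS1", 11))
  tab2 <- probe_intensity_table("S", c(rep(500, 6), 1:5), rep(1, 11), lay11)
  expect_equal(scale_to_median(tab2, 500)$pm, tab2$pm)

  # arbitrary table: postcondition to 1e-9 relative
  set.seed(1)
  tab3 <- probe_intensity_table("S", rexp(10, 1 / 300), rexp(10, 1 / 90), lay)
  expect_equal(median(scale_to_median(tab3, 500)$pm), 500,
               tolerance = 1e-9)

  zero <- probe_intensity_table("S", rep(0, 10), rep(0, 10), lay)
  expect_error(scale_to_median(zero), "median PM")
})

test_that("quantile normalization equalizes column distributions", {
  # hand-computed mean order statistics
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  out <- quantile_normalize(m)
  expect_equal(unname(out[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, "b"]), c(2.5, 3.5, 4.5))

  # single column and identical columns are fixed points
  one <- matrix(c(3, 1, 2), dimnames = list(NULL, "x"))
  expect_equal(quantile_normalize(one), one)
  two <- cbind(x = c(3, 1, 2), y = c(3, 1, 2))
  expect_equal(quantile_normalize(two), two)

  # multiset identity, rank preservation, idempotence
  set.seed(42)
  r <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("s", 1:4)))
  qn <- quantile_normalize(r)
  for (j in 2:4) expect_equal(sort(qn[, j]), sort(qn[, 1]))
  expect_equal(apply(qn, 2, rank), apply(r, 2, rank))
  expect_equal(quantile_normalize(qn), qn)
  expect_error(quantile_normalize(matrix(c(1, NA), 1, 2)), "missing")
})

test_that("quantile normalization agrees with the limma reference", {
  skip_if_not_installed("limma")
  set.seed(7)
  r <- matrix(rlnorm(600), 100, 6)
  expect_equal(unname(quantile_normalize(r)),
               unname(limma::normalizeQuantiles(r)), tolerance = 1e-12)
})

test_that("median polish recovers an exactly additive model", {
  lay <- chip_layout(rep("PS1", 4))
  a <- c(0.5, -1, 2, 0)        # sample effects
  b <- c(1, -2, 0.5, 0.2)      # probe effects
  x <- outer(b, a, `+`) + 7
  colnames(x) <- paste0("s", 1:4)
  expr <- median_polish_summarize(lay, x)
  # recovered sample-level expression equals mu + a up to the additive
  # split between overall and effects
  expect_equal(unname(expr["PS1", ] - mean(expr["PS1", ])),
               a - mean(a), tolerance = 1e-10)

  # a single-probe set passes through unchanged
  lay1 <- chip_layout("PS1")
  row <- matrix(c(5, 6, 7), 1, dimnames = list(NULL, paste0("s", 1:3)))
  expect_equal(unname(median_polish_summarize(lay1, row)["PS1", ]),
               c(5, 6, 7))
})

test_that("median polish matches the stats::medpolish oracle on random blocks", {
  lay <- chip_layout(rep("PS1", 5))
  set.seed(101)
  for (i in 1:200) {
    x <- matrix(rnorm(20, 8, 1), 5, 4,
                dimnames = list(NULL, paste0("s", 1:4)))
    # one gross outlier cell
    x[sample(5, 1), sample(4, 1)] <- x[1, 1] + sample(c(-1, 1), 1) * 50
    expr <- median_polish_summarize(lay, x, tol = 1e-9, max_iter = 100)
    oracle <- suppressWarnings(
      stats::medpolish(x, eps = 1e-9, maxiter = 100, trace.iter = FALSE))
    expect_equal(unname(expr["PS1", ]),
                 unname(oracle$overall + oracle$col), tolerance = 1e-6)
  }
})

test_that("rma duplicates columns for duplicated samples and is order-equivariant", {
  lay <- tiny_layout(5, 4)
  t1 <- tiny_table(lay, "A", seed = 1)
  t2 <- tiny_table(lay, "B", seed = 1)  # identical values, new id
  e <- rma(list(t1, t2), lay)
  expect_equal(unname(e[, "A"]), unname(e[, "B"]))

  set.seed(2)
  tabs <- lapply(c("A", "B", "C"), function(s) {
    probe_intensity_table(s, rlnorm(lay$n_probe_pairs, 5, 1),
                          rlnorm(lay$n_probe_pairs, 4, 1), lay)
  })
  e1 <- rma(tabs, lay)
  e2 <- rma(rev(tabs), lay)
  expect_equal(e1[, colnames(e2)], e2, ignore_attr = TRUE)
})

test_that("rma expression is monotone in true abundance without noise", {
  cfg <- cohort_config(n_probe_sets = 30, probe_pairs_per_set = 4,
                       n_controls = 0, noise_sd = 0, mm_leak = 0,
                       background_mean = 0, mouse_fraction = 0, seed = 8)
  lay <- generate_chip_layout(30, 4, 0, seed = 8)
  co <- simulate_cohort(cfg, lay)
  e <- rma(co$tables, lay)
  truth_order <- order(co$truth$abundance[rownames(e)])
  expect_equal(order(e[, 1]), truth_order)
})

test_that("detection p-values come from the exact signed-rank distribution", {
  params <- detection_params()

  # null signal: all pairs PM = MM, R = 0 below tau -> Absent
  lay <- chip_layout(rep("PS1", 11))
  null_tab <- probe_intensity_table("S", rep(100, 11), rep(100, 11), lay)
  res <- mas5_detection_calls(null_tab, lay, params)
  expect_equal(as.character(res$call), "A")
  expect_gte(res$detection_p, params$alpha2)

  # saturated signal: R ~ 1 for 11 pairs -> minimal attainable p = 2^-11
  sat <- probe_intensity_table("S", rep(4000, 11), rep(1, 11), lay)
  res <- mas5_detection_calls(sat, lay, params)
  expect_equal(res$detection_p, 1 / 2048)
  expect_equal(as.character(res$call), "P")

  # mixed fixed vector: exact-enumeration oracle over 2^11 assignments
  set.seed(31)
  r_scores <- runif(11, -0.4, 0.9)
  expect_equal(signed_rank_p(r_scores, mu = params$tau),
               brute_force_signed_rank_p(r_scores, mu = params$tau),
               tolerance = 1e-12)

  # tie-free inputs also match the exact wilcox.test reference
  for (seed in 1:20) {
    set.seed(seed)
    x <- rnorm(sample(5:12, 1))
    expect_equal(signed_rank_p(x, mu = 0.015),
                 suppressWarnings(stats::wilcox.test(
                   x, mu = 0.015, alternative = "greater",
                   exact = TRUE)$p.value),
                 tolerance = 1e-12)
  }
})

test_that("detection p-values are invariant to joint PM/MM rescaling", {
  lay <- chip_layout(rep(c("PS1", "PS2"), each = 6))
  set.seed(4)
  pm <- rlnorm(12, 6, 1)
  mm <- rlnorm(12, 5, 1)
  a <- mas5_detection_calls(probe_intensity_table("S", pm, mm, lay), lay)
  b <- mas5_detection_calls(
    probe_intensity_table("S", pm * 37.5, mm * 37.5, lay), lay)
  expect_equal(a$detection_p, b$detection_p, tolerance = 1e-12)
})

test_that("probe sets with no usable pairs are Absent with p = 1", {
  lay <- chip_layout(rep("PS1", 3))
  tab <- probe_intensity_table("S", rep(0, 3), rep(0, 3), lay)
  res <- mas5_detection_calls(tab, lay)
  expect_equal(res$detection_p, 1)
  expect_equal(as.character(res$call), "A")
})

test_that("the percentile filter implements the at-least-one-sample rule", {
  ids <- sprintf("PS%02d", 1:10)
  one_col <- matrix(1:10, 10, 1, dimnames = list(ids, "s1"))
  # 20th percentile of 1..10 (linear interpolation) = 2.8: bottom 2 removed
  expect_setequal(percentile_filter(one_col, 20), ids[3:10])
  expect_setequal(percentile_filter(one_col, 0), ids)
  expect_error(percentile_filter(one_col, 100), "pct")

  # above threshold in exactly one of 5 samples -> retained
  m <- matrix(1, 10, 5, dimnames = list(ids, paste0("s", 1:5)))
  m[2:10, ] <- matrix(seq(2, 10), 9, 5)
  m[1, 3] <- 100  # low everywhere except one sample
  expect_true("PS01" %in% percentile_filter(m, 20))
})
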