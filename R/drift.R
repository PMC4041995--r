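## Passage-to-passage differential expression, the per-model stability
## metric (count of transcripts changed >3-fold, p < 0.05, between P1
## and P4 / P1 and P10), and trajectory / ranking views.

## Vectorized two-group comparison over the rows of a log2 expression
## matrix. "anova" is one-way fixed-effects ANOVA, identical to the
## pooled-variance t-test for two groups; "welch_t" relaxes the equal-
## variance assumption.
.row_two_group_p <- function(mat, a_cols, b_cols,
                             test = c("anova", "welch_t")) {
  test <- match.arg(test)
  na <- length(a_cols)
  nb <- length(b_cols)
  ma <- rowMeans(mat[, a_cols, drop = FALSE])
  mb <- rowMeans(mat[, b_cols, drop = FALSE])
  va <- rowSums((mat[, a_cols, drop = FALSE] - ma)^2) / (na - 1)
  vb <- rowSums((mat[, b_cols, drop = FALSE] - mb)^2) / (nb - 1)
  if (test == "anova") {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (mb - ma) / se
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  p[se == 0 & mb == ma] <- 1
  list(mean_a = ma, mean_b = mb, p = p)
}

#' Pairwise differential expression between two sample groups
#'
#' Per retained probe set (after the percentile noise filter), computes
#' the unadjusted p-value of the configured test and the linear fold
#' change `FC = 2^|mean_B - mean_A|` with its direction, and returns the
#' records passing both cutoffs (or the full table).
#'
#' @param mat log2 expression matrix (probe sets x samples).
#' @param group_a,group_b disjoint character vectors of sample ids, each
#'   of size >= 2.
#' @param fc_cutoff linear fold-change cutoff, strict (default 2).
#' @param p_cutoff unadjusted p cutoff (default 0.05).
#' @param test `"anova"` (one-way, = pooled t for two groups) or
#'   `"welch_t"`.
#' @param pct percentile filter applied before testing (default 20; set
#'   0 to disable).
#' @param full return the full per-probe-set table instead of only the
#'   passing records.
#' @return data.frame with `probe_set_id`, `mean_a`, `mean_b`,
#'   `fold_change`, `direction`, `p_value` (and `passes` when
#'   `full = TRUE`).
#' @export
pairwise_de <- function(mat, group_a, group_b, fc_cutoff = 2,
                        p_cutoff = 0.05, test = c("anova", "welch_t"),
                        pct = 20, full = FALSE) {
  test <- match.arg(test)
  if (length(intersect(group_a, group_b)) > 0L) {
    stop("groups overlap: ",
         paste(intersect(group_a, group_b), collapse = ", "))
  }
  if (length(group_a) < 2L) stop("group_a has fewer than 2 samples")
  if (length(group_b) < 2L) stop("group_b has fewer than 2 samples")
  missing <- setdiff(c(group_a, group_b), colnames(mat))
  if (length(missing) > 0L) {
    stop("samples not in matrix: ", paste(missing, collapse = ", "))
  }
  sub <- mat[, c(group_a, group_b), drop = FALSE]
  keep <- percentile_filter(sub, pct)
  sub <- sub[keep, , drop = FALSE]
  res <- .row_two_group_p(sub, seq_along(group_a),
                          length(group_a) + seq_along(group_b), test)
  diff <- res$mean_b - res$mean_a
  out <- data.frame(
    probe_set_id = keep,
    mean_a = unname(res$mean_a),
    mean_b = unname(res$mean_b),
    fold_change = 2^abs(diff),
    direction = ifelse(diff >= 0, "up", "down"),
    p_value = unname(res$p),
    stringsAsFactors = FALSE
  )
  out$passes <- out$fold_change > fc_cutoff & out$p_value < p_cutoff
  if (full) {
    out
  } else {
    res <- out[out$passes, setdiff(names(out), "passes"), drop = FALSE]
    rownames(res) <- NULL
    res
  }
}

#' Per-model passage-stability metric
#'
#' Counts the probe sets changed more than `fc_cutoff`-fold in either
#' direction (p < `p_cutoff`) between P1 and P4, and between P1 and P10.
#' A low P1->P10 count marks a transcriptionally stable model.
#'
#' @param mat log2 expression matrix.
#' @param annotations sample-sheet data.frame.
#' @param model model name to evaluate.
#' @param fc_cutoff linear fold-change cutoff, strict (default 3).
#' @param p_cutoff unadjusted p cutoff (default 0.05).
#' @param test see [pairwise_de()].
#' @param pct percentile filter (default 20; 0 disables).
#' @return one-row data.frame of class `stability_report`:
#'   `model_name`, `n_changed_P1_P4`, `n_changed_P1_P10`.
#' @export
stability_metric <- function(mat, annotations, model, fc_cutoff = 3,
                             p_cutoff = 0.05,
                             test = c("anova", "welch_t"), pct = 20) {
  test <- match.arg(test)
  ann <- annotations[annotations$model_name == model, ]
  if (nrow(ann) == 0L) stop("unknown model: ", model)
  have <- unique(ann$passage)
  need <- c("P1", "P4", "P10")
  if (!all(need %in% have)) {
    stop(sprintf("model %s lacks passage(s) %s (available: %s)",
                 model, paste(setdiff(need, have), collapse = ", "),
                 paste(have, collapse = ", ")))
  }
  ids <- function(p) ann$sample_id[ann$passage == p]
  n14 <- nrow(pairwise_de(mat, ids("P1"), ids("P4"), fc_cutoff,
                          p_cutoff, test, pct))
  n110 <- nrow(pairwise_de(mat, ids("P1"), ids("P10"), fc_cutoff,
                           p_cutoff, test, pct))
  structure(
    data.frame(model_name = model, n_changed_P1_P4 = n14,
               n_changed_P1_P10 = n110, stringsAsFactors = FALSE),
    class = c("stability_report", "data.frame")
  )
}

#' Rank models by transcriptional stability
#'
#' Ascending by the P1->P10 count (most stable first); ties broken by
#' the P1->P4 count, then model name.
#'
#' @param reports list of [stability_metric()] rows, or a single
#'   data.frame of them.
#' @return data.frame with a `rank` column, most stable model first.
#' @export
rank_models_by_stability <- function(reports) {
  df <- if (is.data.frame(reports)) reports else do.call(rbind, reports)
  if (anyDuplicated(df$model_name)) {
    stop("duplicate model names: ",
         paste(unique(df$model_name[duplicated(df$model_name)]),
               collapse = ", "))
  }
  df <- df[order(df$n_changed_P1_P10, df$n_changed_P1_P4,
                 df$model_name), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Per-model, per-passage expression trajectory of one probe set
#'
#' @param probe_set_id probe-set identifier (one row of `mat`).
#' @param mat log2 expression matrix.
#' @param annotations sample-sheet data.frame.
#' @return data.frame with one row per model: mean log2 expression at
#'   each passage present plus `delta_P1_P10` (NA when either passage is
#'   missing, never silently 0).
#' @export
transcript_trajectory <- function(probe_set_id, mat, annotations) {
  if (!probe_set_id %in% rownames(mat)) {
    stop("unknown probe set: ", probe_set_id)
  }
  x <- mat[probe_set_id, ]
  ann <- annotations[match(colnames(mat), annotations$sample_id), ]
  models <- unique(ann$model_name)
  passages <- intersect(c("P0", "P1", "P4", "P10"), unique(ann$passage))
  out <- data.frame(model_name = models, stringsAsFactors = FALSE)
  for (p in passages) {
    out[[paste0("mean_", p)]] <- vapply(models, function(m) {
      cols <- ann$model_name == m & ann$passage == p
      if (!any(cols)) return(NA_real_)
      mean(x[cols])
    }, numeric(1))
  }
  m1 <- if ("mean_P1" %in% names(out)) out$mean_P1 else NA_real_
  m10 <- if ("mean_P10" %in% names(out)) out$mean_P10 else NA_real_
  out$delta_P1_P10 <- m10 - m1
  rownames(out) <- NULL
  out
}

#' Rank models by mean expression of a probe set at one passage
#'
#' Descending by mean log2 expression; ties broken alphabetically by
#' model name.
#'
#' @inheritParams transcript_trajectory
#' @param passage passage label to rank at (e.g. `"P1"`).
#' @return data.frame `model_name`, `mean_log2`, `rank`.
#' @export
rank_models_by_expression <- function(probe_set_id, mat, annotations,
                                      passage = "P1") {
  if (!probe_set_id %in% rownames(mat)) {
    stop("unknown probe set: ", probe_set_id)
  }
  ann <- annotations[match(colnames(mat), annotations$sample_id), ]
  sel <- ann$passage == passage
  if (!any(sel)) stop("no samples at passage ", passage)
  x <- mat[probe_set_id, sel]
  models <- ann$model_name[sel]
  means <- tapply(x, models, mean)
  df <- data.frame(model_name = names(means),
                   mean_log2 = as.numeric(means),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$mean_log2, df$model_name), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}
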