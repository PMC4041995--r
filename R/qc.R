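## Cohort quality control: control-probe profiles, PCA outlier flagging,
## hierarchical co-clustering of models, and an in-silico
## species-composition score standing in for the wet-lab species PCR.

#' Control-probe profile QC
#'
#' Extracts per-sample expression profiles over the control (`AFFX-`)
#' probe sets and flags samples whose Pearson correlation with the
#' cohort-median control profile falls below `corr_threshold` — the
#' implementable analog of visually spotting a chip with control-probe
#' errors.
#'
#' @param mat expression matrix (probe sets x samples) containing the
#'   control probe sets among its rows.
#' @param layout the [chip_layout()] naming the control sets.
#' @param corr_threshold flag threshold on the Pearson correlation
#'   (default 0.9).
#' @return list with `profile` (controls x samples), `correlation`,
#'   `flagged` (named logical) and `evaluable`.
#' @export
control_probe_profile <- function(mat, layout, corr_threshold = 0.9) {
  ctrl <- intersect(layout$control_ids, rownames(mat))
  if (length(ctrl) == 0L) {
    stop("no control probe sets (AFFX- prefix) found in layout/matrix")
  }
  prof <- mat[ctrl, , drop = FALSE]
  if (ncol(prof) < 2L || length(ctrl) < 2L) {
    return(list(profile = prof, correlation = NULL,
                flagged = stats::setNames(logical(ncol(prof)),
                                          colnames(prof)),
                evaluable = FALSE))
  }
  med <- apply(prof, 1L, stats::median)
  corr <- apply(prof, 2L, function(col) {
    if (stats::sd(col) == 0 || stats::sd(med) == 0) return(1)
    stats::cor(col, med)
  })
  list(profile = prof, correlation = corr,
       flagged = corr < corr_threshold, evaluable = TRUE)
}

#' PCA outlier flagging
#'
#' PCA on mean-centered probe-set expression with samples as
#' observations; a sample is flagged when the robust z-score
#' (median/MAD) of its distance from the cohort centroid in the first
#' `k` components exceeds `z_threshold`.
#'
#' @param mat expression matrix (probe sets x samples).
#' @param k number of leading components (default 3).
#' @param z_threshold robust z-score flag threshold (default 4).
#' @return list with `coordinates` (samples x k), `distance`, `z`,
#'   `flagged`, `evaluable`.
#' @export
pca_outliers <- function(mat, k = 3, z_threshold = 4) {
  if (ncol(mat) < 3L) {
    return(list(coordinates = NULL, distance = NULL, z = NULL,
                flagged = stats::setNames(logical(ncol(mat)),
                                          colnames(mat)),
                evaluable = FALSE))
  }
  x <- t(mat)
  x <- sweep(x, 2L, colMeans(x))
  if (all(abs(x) < 1e-12)) {
    # zero variance: no structure, no outliers
    return(list(coordinates = matrix(0, nrow(x), k,
                                     dimnames = list(rownames(x), NULL)),
                distance = stats::setNames(numeric(nrow(x)), rownames(x)),
                z = stats::setNames(numeric(nrow(x)), rownames(x)),
                flagged = stats::setNames(logical(nrow(x)), rownames(x)),
                evaluable = TRUE))
  }
  k <- min(k, ncol(x), nrow(x) - 1L)
  pc <- stats::prcomp(x, center = FALSE, rank. = k)
  coords <- pc$x[, seq_len(k), drop = FALSE]
  d <- sqrt(rowSums(coords^2))
  md <- stats::median(d)
  s <- stats::mad(d)
  z <- if (s > 0) {
    (d - md) / s
  } else {
    ifelse(d > md + 1e-9 * max(md, 1), Inf, 0)
  }
  list(coordinates = coords, distance = d, z = z,
       flagged = z > z_threshold, evaluable = TRUE)
}

## Vectorized one-way fixed-effects ANOVA p-values across the rows of a
## log2 expression matrix. Groups with a single replicate contribute to
## the between-group sum of squares only.
.row_anova_p <- function(mat, groups) {
  groups <- droplevels(as.factor(groups))
  k <- nlevels(groups)
  n <- ncol(mat)
  if (k < 2L || n - k < 1L) {
    return(stats::setNames(rep(NA_real_, nrow(mat)), rownames(mat)))
  }
  grand <- rowMeans(mat)
  ss_between <- 0
  ss_within <- 0
  for (g in levels(groups)) {
    cols <- which(groups == g)
    gm <- rowMeans(mat[, cols, drop = FALSE])
    ss_between <- ss_between + length(cols) * (gm - grand)^2
    ss_within <- ss_within +
      rowSums((mat[, cols, drop = FALSE] - gm)^2)
  }
  f <- (ss_between / (k - 1)) / (ss_within / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  p[ss_within == 0 & ss_between == 0] <- 1
  stats::setNames(p, rownames(mat))
}

## Smallest merge-tree cluster containing each leaf with >= target
## members, via the hclust merge matrix.
.leaf_cluster <- function(hc, leaf, target_size) {
  members <- lapply(seq_len(nrow(hc$merge)), function(i) integer(0))
  current <- -leaf
  repeat {
    step <- which(hc$merge[, 1L] == current | hc$merge[, 2L] == current)
    if (length(step) == 0L) return(NULL)
    current <- step
    leaves <- .merge_members(hc$merge, step)
    if (length(leaves) >= target_size) return(leaves)
  }
}

.merge_members <- function(merge, node) {
  out <- integer(0)
  stack <- node
  while (length(stack) > 0L) {
    i <- stack[[1L]]
    stack <- stack[-1L]
    for (child in merge[i, ]) {
      if (child < 0) out <- c(out, -child) else stack <- c(stack, child)
    }
  }
  out
}

#' Hierarchical co-clustering of cohort samples
#'
#' Filters probe sets (percentile filter, one-way ANOVA across
#' model-passage conditions, fold-range cutoff across condition means),
#' then clusters samples with distance `1 - |Pearson r|` and centroid
#' linkage. Per-model purity is the fraction of the model's samples
#' whose smallest enclosing subtree of at least the model's sample count
#' is exactly that size and model-pure; a single-sample model has purity
#' 1.
#'
#' @param mat expression matrix (probe sets x samples).
#' @param annotations sample-sheet data.frame covering the columns.
#' @param fold_cutoff linear fold range across condition means a probe
#'   set must reach (default 100).
#' @param anova_p unadjusted ANOVA p cutoff (default 0.05).
#' @param pct percentile filter cutoff (default 20).
#' @return list with `hclust`, `purity` (named per model),
#'   `n_probe_sets_used`.
#' @export
hierarchical_cocluster <- function(mat, annotations, fold_cutoff = 100,
                                   anova_p = 0.05, pct = 20) {
  ann <- annotations[match(colnames(mat), annotations$sample_id), ]
  if (anyNA(ann$sample_id)) stop("annotations do not cover all samples")
  cond <- interaction(ann$model_name, ann$passage, drop = TRUE)
  keep <- percentile_filter(mat, pct)
  sub <- mat[keep, , drop = FALSE]
  p <- .row_anova_p(sub, cond)
  cond_means <- vapply(levels(cond), function(g) {
    rowMeans(sub[, cond == g, drop = FALSE])
  }, numeric(nrow(sub)))
  fold_range <- apply(cond_means, 1L, function(v) max(v) - min(v))
  sel <- !is.na(p) & p < anova_p & fold_range >= log2(fold_cutoff)
  if (sum(sel) < 2L) {
    stop("fewer than 2 probe sets pass the clustering filter; ",
         "lower fold_cutoff or relax anova_p")
  }
  sub <- sub[sel, , drop = FALSE]
  d <- stats::as.dist(1 - abs(stats::cor(sub)))
  hc <- stats::hclust(d, method = "centroid")
  purity <- vapply(unique(ann$model_name), function(m) {
    idx <- which(ann$model_name == m)
    if (length(idx) == 1L) return(1)
    pure <- vapply(idx, function(i) {
      leaves <- .leaf_cluster(hc, i, length(idx))
      !is.null(leaves) && length(leaves) == length(idx) &&
        all(ann$model_name[leaves] == m)
    }, logical(1))
    mean(pure)
  }, numeric(1))
  names(purity) <- unique(ann$model_name)
  list(hclust = hc, purity = purity, n_probe_sets_used = sum(sel))
}

#' In-silico species-composition score
#'
#' Rank-based analog of a species-specific PCR check: per sample, the
#' mean within-sample expression rank of the cross-hybridization-masked
#' probe sets is compared with the mean rank of the unmasked sets;
#' `score = mean_rank_masked / (mean_rank_masked + mean_rank_unmasked)`
#' lies in [0, 1] and grows as mouse-derived signal dominates.
#'
#' @param mat expression matrix (probe sets x samples).
#' @param mask_set character vector of masked (cross-hybridizing)
#'   probe-set ids.
#' @param flag_cutoff samples with score above this are flagged
#'   (default 0.6).
#' @return data.frame with `sample_id`, `score`, `flagged`; or a list
#'   with `evaluable = FALSE` when the mask is empty or covers all rows.
#' @export
species_composition_score <- function(mat, mask_set, flag_cutoff = 0.6) {
  masked <- intersect(rownames(mat), mask_set)
  unmasked <- setdiff(rownames(mat), mask_set)
  if (length(masked) == 0L || length(unmasked) == 0L) {
    return(list(evaluable = FALSE,
                reason = "mask empty or covering every probe set"))
  }
  score <- apply(mat, 2L, function(col) {
    r <- rank(col)
    mr <- mean(r[rownames(mat) %in% masked])
    ur <- mean(r[rownames(mat) %in% unmasked])
    mr / (mr + ur)
  })
  data.frame(sample_id = colnames(mat), score = unname(score),
             flagged = unname(score > flag_cutoff),
             stringsAsFactors = FALSE)
}

#' Assemble a cohort QC report
#'
#' Convenience wrapper running [control_probe_profile()],
#' [pca_outliers()] and (if a mask is given)
#' [species_composition_score()]; every flagged sample carries at least
#' one named reason.
#'
#' @inheritParams control_probe_profile
#' @inheritParams pca_outliers
#' @param mask_set optional masked probe-set ids for the species score.
#' @return list with the component results plus `flags`, a data.frame of
#'   `sample_id` and `reason`.
#' @export
qc_report <- function(mat, layout, corr_threshold = 0.9, k = 3,
                      z_threshold = 4, mask_set = NULL) {
  ctrl <- control_probe_profile(mat, layout, corr_threshold)
  pca <- pca_outliers(mat, k, z_threshold)
  flags <- data.frame(sample_id = character(), reason = character(),
                      stringsAsFactors = FALSE)
  if (isTRUE(ctrl$evaluable) && any(ctrl$flagged)) {
    flags <- rbind(flags, data.frame(
      sample_id = names(which(ctrl$flagged)),
      reason = "control-probe profile correlation below threshold"))
  }
  if (isTRUE(pca$evaluable) && any(pca$flagged)) {
    flags <- rbind(flags, data.frame(
      sample_id = names(which(pca$flagged)),
      reason = "PCA robust-distance outlier"))
  }
  species <- NULL
  if (!is.null(mask_set)) {
    species <- species_composition_score(mat, mask_set)
    if (is.data.frame(species) && any(species$flagged)) {
      flags <- rbind(flags, data.frame(
        sample_id = species$sample_id[species$flagged],
        reason = "high mouse-likeness species-composition score"))
    }
  }
  list(control = ctrl, pca = pca, species = species, flags = flags)
}
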