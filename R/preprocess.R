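## Probe-level -> probe-set-level processing: median-intensity scaling,
## quantile normalization, median-polish summarization (the RMA-style
## path), and Present/Marginal/Absent detection calls from an exact
## Wilcoxon signed-rank test on probe-pair discrimination scores.

#' Detection-call parameters
#'
#' Thresholds of the Present/Marginal/Absent classifier: `tau` is the
#' discrimination threshold the probe-pair scores are tested against;
#' p < `alpha1` gives Present, `alpha1 <= p < alpha2` Marginal, else
#' Absent. Defaults are the platform's published standard constants.
#'
#' @param tau discrimination threshold (default 0.015).
#' @param alpha1 Present p-value cutoff (default 0.04).
#' @param alpha2 Marginal p-value cutoff (default 0.06).
#' @export
detection_params <- function(tau = 0.015, alpha1 = 0.04, alpha2 = 0.06) {
  if (!(alpha1 > 0 && alpha1 < alpha2 && alpha2 < 1)) {
    stop("need 0 < alpha1 < alpha2 < 1")
  }
  if (tau < 0) stop("tau must be >= 0")
  structure(list(tau = tau, alpha1 = alpha1, alpha2 = alpha2),
            class = "detection_params")
}

#' Normalization configuration
#'
#' @param median_scaling_target target median PM intensity (default 500
#'   intensity units, the study-wide chip scaling setting).
#' @param use_quantile apply quantile normalization (default TRUE).
#' @param background_method `"none"` or `"minimum-shift"` (shift
#'   intensities so the per-sample minimum maps to 1 before log).
#' @export
normalization_config <- function(median_scaling_target = 500,
                                 use_quantile = TRUE,
                                 background_method = c("none",
                                                       "minimum-shift")) {
  if (median_scaling_target <= 0) {
    stop("median_scaling_target must be > 0")
  }
  structure(
    list(median_scaling_target = median_scaling_target,
         use_quantile = isTRUE(use_quantile),
         background_method = match.arg(background_method),
         log_base = 2),
    class = "normalization_config"
  )
}

#' Scale a probe intensity table to a target median
#'
#' Multiplies PM and MM by `target / median(PM)` so the median PM of the
#' output equals `target` exactly (up to float rounding).
#'
#' @param table a [probe_intensity_table()].
#' @param target target median intensity (default 500).
#' @param layout the table's [chip_layout()] (carried for re-wrapping).
#' @export
scale_to_median <- function(table, target = 500, layout = NULL) {
  stopifnot(inherits(table, "probe_intensity_table"))
  if (target <= 0) stop("target must be > 0")
  med <- stats::median(table$pm)
  if (!is.finite(med) || med <= 0) {
    stop("median PM is not positive; cannot scale sample ", table$sample_id)
  }
  k <- target / med
  out <- table
  out$pm <- table$pm * k
  out$mm <- table$mm * k
  out
}

#' Quantile normalization
#'
#' Forces every column (sample) to share one empirical distribution: the
#' vector of row means of the column-wise order statistics. Within-column
#' ranks are preserved; ties receive the mean of the reference values they
#' span. Idempotent.
#'
#' @param mat numeric matrix, probes (or probe sets) x samples, no missing
#'   values.
#' @return matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(mat) {
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  if (anyNA(mat)) stop("quantile_normalize: missing values not allowed")
  if (ncol(mat) < 1L) stop("need at least one column")
  if (ncol(mat) == 1L) return(mat)
  ref <- rowMeans(apply(mat, 2L, sort, method = "radix"))
  out <- apply(mat, 2L, function(col) {
    r <- rank(col, ties.method = "average")
    (ref[floor(r)] + ref[ceiling(r)]) / 2
  })
  dimnames(out) <- dimnames(mat)
  out
}

## Tukey median polish of one probe-set block: fits
## x_{ij} = overall + probe_i + sample_j + resid by alternating median
## sweeps (rows first), re-centering the accumulated effects each pass.
.median_polish <- function(x, tol = 0.01, max_iter = 10L) {
  nr <- nrow(x)
  nc <- ncol(x)
  overall <- 0
  probe_eff <- numeric(nr)
  sample_eff <- numeric(nc)
  r <- x
  oldsum <- 0
  for (iter in seq_len(max_iter)) {
    rd <- apply(r, 1L, stats::median)
    r <- r - rd
    probe_eff <- probe_eff + rd
    d <- stats::median(sample_eff)
    sample_eff <- sample_eff - d
    overall <- overall + d
    cd <- apply(r, 2L, stats::median)
    r <- r - rep(cd, each = nr)
    sample_eff <- sample_eff + cd
    d <- stats::median(probe_eff)
    probe_eff <- probe_eff - d
    overall <- overall + d
    newsum <- sum(abs(r))
    if (newsum == 0 || abs(newsum - oldsum) < tol * newsum) break
    oldsum <- newsum
  }
  list(overall = overall, probe = probe_eff, sample = sample_eff,
       residuals = r)
}

#' Median-polish summarization of normalized log2 PM values
#'
#' Per probe set, fits the additive model
#' `log2(PM_ij) = mu + probe_i + sample_j + eps` by iterative median
#' sweeps and reports probe-set expression `mu + sample_j`.
#'
#' @param layout a [chip_layout()]; every row of `mat` is a probe-pair
#'   index of this layout.
#' @param mat numeric matrix of log2 PM values, probe pairs x samples.
#' @param tol convergence tolerance on the residual L1 norm change
#'   (default 0.01).
#' @param max_iter maximum sweep iterations (default 10, common practice).
#' @return expression matrix, probe sets x samples, with class
#'   `matrix`; row order follows `layout$probe_set_ids`.
#' @export
median_polish_summarize <- function(layout, mat, tol = 0.01,
                                    max_iter = 10L) {
  stopifnot(inherits(layout, "chip_layout"))
  if (nrow(mat) != layout$n_probe_pairs) {
    stop(sprintf("matrix has %d probe rows, layout expects %d",
                 nrow(mat), layout$n_probe_pairs))
  }
  out <- matrix(NA_real_, length(layout$probe_set_ids), ncol(mat),
                dimnames = list(layout$probe_set_ids, colnames(mat)))
  for (ps in layout$probe_set_ids) {
    idx <- layout$probe_pairs[[ps]]
    if (length(idx) == 0L) stop("probe set with zero probes: ", ps)
    block <- mat[idx, , drop = FALSE]
    if (length(idx) == 1L) {
      out[ps, ] <- block[1L, ]
    } else {
      fit <- .median_polish(block, tol = tol, max_iter = max_iter)
      out[ps, ] <- fit$overall + fit$sample
    }
  }
  out
}

#' RMA-style expression measure
#'
#' Composition: optional median scaling and background handling, log2 of
#' PM, quantile normalization across samples, median-polish summarization
#' per probe set. Provenance (normalization method, scaling target) is
#' attached to the result.
#'
#' @param tables list of [probe_intensity_table()] sharing `layout`.
#' @param layout the [chip_layout()].
#' @param config a [normalization_config()].
#' @return probe-set x sample matrix of log2 expression with a
#'   `provenance` attribute.
#' @export
rma <- function(tables, layout, config = normalization_config()) {
  stopifnot(inherits(layout, "chip_layout"))
  if (length(tables) == 0L) stop("no intensity tables supplied")
  ids <- vapply(tables, function(t) t$sample_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate sample ids in tables")
  pm <- vapply(tables, function(t) {
    if (length(t$pm) != layout$n_probe_pairs) {
      stop("sample ", t$sample_id, " not aligned to layout")
    }
    t$pm
  }, numeric(layout$n_probe_pairs))
  colnames(pm) <- ids
  if (!is.null(config$median_scaling_target)) {
    med <- apply(pm, 2L, stats::median)
    if (any(med <= 0)) stop("sample with non-positive median PM")
    pm <- sweep(pm, 2L, config$median_scaling_target / med, `*`)
  }
  if (config$background_method == "minimum-shift") {
    pm <- sweep(pm, 2L, apply(pm, 2L, min) - 1, `-`)
  }
  lpm <- log2(pmax(pm, 2^-20))
  if (config$use_quantile && ncol(lpm) > 1L) {
    lpm <- quantile_normalize(lpm)
  }
  expr <- median_polish_summarize(layout, lpm)
  attr(expr, "provenance") <- list(
    normalization_method = if (config$use_quantile) {
      "median-scale + quantile + median-polish (RMA-style)"
    } else {
      "median-scale + median-polish"
    },
    median_scaling_target = config$median_scaling_target
  )
  expr
}

## --------------------------------------------------------------------------
## Exact one-sided Wilcoxon signed-rank p-value for H0: median(x) = mu
## against median(x) > mu. Zeros dropped, ties midranked. Exact null
## distribution by generating-function convolution over the doubled
## midranks (integers) for n <= exact_limit; normal approximation with tie
## correction and continuity correction above.

#' One-sided Wilcoxon signed-rank p-value (exact for small n)
#'
#' @param x numeric vector of scores.
#' @param mu null median.
#' @param exact_limit largest n for which the exact null distribution is
#'   enumerated (default 12; the platform norm of 11 probe pairs stays on
#'   the exact path).
#' @return p-value for the alternative `median(x) > mu`.
#' @export
signed_rank_p <- function(x, mu = 0, exact_limit = 12L) {
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_limit) {
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1L)
    f[1L] <- 1
    for (v in r2) {
      f[(v + 1L):(total + 1L)] <- f[(v + 1L):(total + 1L)] +
        f[1L:(total + 1L - v)]
    }
    w2 <- as.integer(round(2 * w))
    sum(f[(w2 + 1L):(total + 1L)]) / 2^n
  } else {
    mu_w <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    stats::pnorm((w - mu_w - 0.5) / sqrt(sigma2), lower.tail = FALSE)
  }
}

#' Present/Marginal/Absent detection calls for one sample
#'
#' Per probe pair the discrimination score `R = (PM - MM) / (PM + MM)` is
#' computed; pairs with `PM + MM = 0` are dropped (a probe set with all
#' pairs dropped is Absent with p = 1). A one-sided Wilcoxon signed-rank
#' test of `H0: median(R) = tau` against `> tau` yields the detection
#' p-value, classified by the `alpha1`/`alpha2` thresholds.
#'
#' @param table a [probe_intensity_table()].
#' @param layout its [chip_layout()].
#' @param params a [detection_params()].
#' @return data.frame with `probe_set_id`, `call` (factor P/M/A) and
#'   `detection_p`.
#' @export
mas5_detection_calls <- function(table, layout,
                                 params = detection_params()) {
  stopifnot(inherits(table, "probe_intensity_table"),
            inherits(layout, "chip_layout"),
            inherits(params, "detection_params"))
  ids <- layout$probe_set_ids
  p <- vapply(ids, function(ps) {
    idx <- layout$probe_pairs[[ps]]
    pm <- table$pm[idx]
    mm <- table$mm[idx]
    keep <- (pm + mm) > 0
    if (!any(keep)) return(1)
    r <- (pm[keep] - mm[keep]) / (pm[keep] + mm[keep])
    signed_rank_p(r, mu = params$tau)
  }, numeric(1))
  call <- ifelse(p < params$alpha1, "P",
                 ifelse(p < params$alpha2, "M", "A"))
  data.frame(
    probe_set_id = ids,
    call = factor(call, levels = c("P", "M", "A")),
    detection_p = unname(p),
    stringsAsFactors = FALSE
  )
}

#' Detection calls for a set of samples
#'
#' Detection is a within-sample test, so calls are computed on each
#' median-scaled (not quantile-normalized) intensity table.
#'
#' @param tables list of [probe_intensity_table()].
#' @param layout the shared [chip_layout()].
#' @param params a [detection_params()].
#' @param median_target median scaling target applied before testing; the
#'   discrimination score is scale-free so this does not change p-values,
#'   but it mirrors platform practice. `NULL` to skip.
#' @return list of class `detection_call_table` with matrices `call`
#'   (character) and `p`, probe sets x samples.
#' @export
detection_calls <- function(tables, layout, params = detection_params(),
                            median_target = 500) {
  ids <- vapply(tables, function(t) t$sample_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate sample ids")
  call_m <- matrix(NA_character_, length(layout$probe_set_ids),
                   length(tables),
                   dimnames = list(layout$probe_set_ids, ids))
  p_m <- matrix(NA_real_, length(layout$probe_set_ids), length(tables),
                dimnames = list(layout$probe_set_ids, ids))
  for (i in seq_along(tables)) {
    t <- tables[[i]]
    if (!is.null(median_target)) {
      t <- scale_to_median(t, median_target)
    }
    res <- mas5_detection_calls(t, layout, params)
    call_m[, i] <- as.character(res$call)
    p_m[, i] <- res$detection_p
  }
  structure(list(call = call_m, p = p_m), class = "detection_call_table")
}

#' Percentile noise filter
#'
#' A probe set is retained iff its expression exceeds the `pct`-th
#' percentile of the per-sample expression distribution in at least one
#' sample — the usual reading that the bottom fifth of intensities on a
#' genome-wide array represent noise.
#'
#' @param mat expression matrix (probe sets x samples).
#' @param pct percentile cutoff in `[0, 100)` (default 20).
#' @return character vector of retained probe-set ids.
#' @export
percentile_filter <- function(mat, pct = 20) {
  if (pct < 0 || pct >= 100) stop("pct must lie in [0, 100)")
  if (pct == 0) return(rownames(mat))
  thr <- apply(mat, 2L, stats::quantile, probs = pct / 100, names = FALSE)
  keep <- rowSums(mat > rep(thr, each = nrow(mat))) > 0
  rownames(mat)[keep]
}
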