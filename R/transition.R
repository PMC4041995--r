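## In vitro -> in vivo (P0 -> P1) transition analysis: per-model and
## per-class average fold changes, top-N up-regulated ranking, and the
## two-block (pre-mask / post-mask) report.

#' Per-probe-set P0 -> P1 fold change for one model
#'
#' `FC = 2^(mean log2 P1 - mean log2 P0)` as a signed linear ratio:
#' values > 1 are up-regulated in vivo, < 1 down-regulated; `ratio`
#' carries the direction-free magnitude.
#'
#' @param mat log2 expression matrix.
#' @param annotations sample-sheet data.frame.
#' @param model model name; needs >= 2 samples at each of P0 and P1.
#' @return data.frame `probe_set_id`, `fold_change` (signed linear,
#'   2^diff), `ratio` (>= 1), `direction`.
#' @export
average_fold_change <- function(mat, annotations, model) {
  ann <- annotations[annotations$model_name == model, ]
  if (nrow(ann) == 0L) stop("unknown model: ", model)
  p0 <- ann$sample_id[ann$passage == "P0"]
  p1 <- ann$sample_id[ann$passage == "P1"]
  if (length(p0) < 2L || length(p1) < 2L) {
    stop(sprintf("model %s needs >= 2 samples at P0 and P1 (has %d, %d)",
                 model, length(p0), length(p1)))
  }
  diff <- rowMeans(mat[, p1, drop = FALSE]) -
    rowMeans(mat[, p0, drop = FALSE])
  data.frame(
    probe_set_id = rownames(mat),
    fold_change = 2^diff,
    ratio = 2^abs(diff),
    direction = ifelse(diff >= 0, "up", "down"),
    stringsAsFactors = FALSE
  )
}

#' Class-level average fold change
#'
#' Per probe set, the arithmetic mean of the member models' linear fold
#' changes (each model is paired with its own P1 xenografts first;
#' averaging happens on the per-model linear FC values). Reduces to the
#' identity for a singleton class and is invariant to member order.
#'
#' @param fc_tables named list of [average_fold_change()] outputs, one
#'   per member model.
#' @return data.frame `probe_set_id`, `fold_change`, `direction`,
#'   sorted descending by fold change.
#' @export
class_fold_change <- function(fc_tables) {
  if (length(fc_tables) == 0L) stop("empty model class")
  ids <- fc_tables[[1L]]$probe_set_id
  for (t in fc_tables) {
    if (!identical(sort(t$probe_set_id), sort(ids))) {
      stop("member fold-change tables cover different probe sets")
    }
  }
  fc <- rowMeans(vapply(fc_tables, function(t) {
    t$fold_change[match(ids, t$probe_set_id)]
  }, numeric(length(ids))))
  out <- data.frame(
    probe_set_id = ids,
    fold_change = fc,
    direction = ifelse(fc >= 1, "up", "down"),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$fold_change, out$probe_set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top-N up-regulated probe sets
#'
#' Descending by fold change; ties broken lexicographically by probe-set
#' id; exactly `min(n, nrow)` entries, re-ranked 1..n.
#'
#' @param transition_table data.frame with `probe_set_id` and
#'   `fold_change`.
#' @param n list length (default 50).
#' @param direction `"up"` (default) sorts descending; `"down"` returns
#'   the most down-regulated entries (smallest signed FC first).
#' @export
top_upregulated <- function(transition_table, n = 50,
                            direction = c("up", "down")) {
  direction <- match.arg(direction)
  ord <- if (direction == "up") {
    order(-transition_table$fold_change, transition_table$probe_set_id)
  } else {
    order(transition_table$fold_change, transition_table$probe_set_id)
  }
  out <- transition_table[ord, , drop = FALSE]
  out <- utils::head(out, n)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Two-block transition report (pre-mask and post-mask top N)
#'
#' The pre-mask block is the top N of the full ranked table annotated
#' with each entry's mouse-sample count; the post-mask block is the top
#' N of the masked full table, so entries ranked below N pre-mask can
#' enter once cross-hybridizing probe sets are removed.
#'
#' @param transition_table full ranked table (`probe_set_id`,
#'   `fold_change`, optional `gene_symbol`).
#' @param mask a `crosshyb_mask` (counts) or a character vector of
#'   masked probe-set ids.
#' @param n block size (default 50).
#' @param stringency stringency used when `mask` carries counts
#'   (default 1, matching a worked example that excludes probe sets
#'   flagged in as few as one mouse sample).
#' @param direction passed to [top_upregulated()].
#' @return list with `pre_mask` (top N, `n_mouse_samples` column) and
#'   `post_mask` (top N after removal, re-ranked).
#' @export
transition_report <- function(transition_table, mask, n = 50,
                              stringency = 1,
                              direction = c("up", "down")) {
  direction <- match.arg(direction)
  mask_set <- if (inherits(mask, "crosshyb_mask")) {
    mask_at_stringency(mask, stringency)
  } else {
    as.character(mask)
  }
  counts <- if (inherits(mask, "crosshyb_mask")) {
    stats::setNames(as.integer(mask), names(mask))
  } else if ("n_mouse_samples" %in% names(transition_table)) {
    stats::setNames(transition_table$n_mouse_samples,
                    transition_table$probe_set_id)
  } else {
    NULL
  }
  pre <- top_upregulated(transition_table, n, direction)
  pre$n_mouse_samples <- if (is.null(counts)) {
    as.integer(pre$probe_set_id %in% mask_set)
  } else {
    cnt <- counts[pre$probe_set_id]
    cnt[is.na(cnt)] <- 0L
    as.integer(cnt)
  }
  post <- top_upregulated(apply_mask(transition_table,
                                     mask_set)$retained, n, direction)
  list(pre_mask = pre, post_mask = post)
}
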