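## Mouse cross-hybridization mask: built from detection calls on
## mouse-RNA-on-human-array samples, applied to ranked fold-change lists.
##
## A probe set is "detected" in one mouse biological sample when at least
## 2 of its 3 replicate calls are Present (the unordered reading of the
## PPP/PPM/PPA replicate-call patterns; replicate order is arbitrary).
## The mask records, per probe set, in how many of the biological samples
## (out of 5) it was detected; stringency s keeps probe sets with count
## >= s.

#' Replicate-level detection predicate for one mouse sample
#'
#' @param calls character vector of replicate calls in {P, M, A}.
#' @param n_replicates expected replicate count (default 3).
#' @param min_present minimum Present calls for detection (default 2,
#'   the property shared by the PPP/PPM/PPA patterns).
#' @return logical scalar.
#' @export
sample_detected <- function(calls, n_replicates = 3L, min_present = 2L) {
  calls <- as.character(calls)
  if (length(calls) != n_replicates) {
    stop(sprintf("expected %d replicate calls, got %d",
                 n_replicates, length(calls)))
  }
  if (!all(calls %in% c("P", "M", "A"))) {
    stop("calls must be P, M or A")
  }
  sum(calls == "P") >= min_present
}

#' Build the cross-hybridization mask from a mouse-panel call table
#'
#' Groups the panel's replicate columns by biological sample
#' (`model_name` in the annotations), applies [sample_detected()] per
#' probe set and sample, and counts the biological samples in which each
#' probe set is detected.
#'
#' @param calls a `detection_call_table` (from [detection_calls()]) over
#'   the mouse panel columns.
#' @param annotations sample-sheet rows for the panel; all must have
#'   `rna_species == "mouse"`.
#' @param min_present see [sample_detected()].
#' @return object of class `crosshyb_mask`: a named integer vector of
#'   per-probe-set detected-sample counts (zeros included) with
#'   attributes `n_samples` and `sample_ids`.
#' @export
build_crosshyb_table <- function(calls, annotations, min_present = 2L) {
  stopifnot(inherits(calls, "detection_call_table"))
  ann <- annotations[match(colnames(calls$call), annotations$sample_id), ]
  if (anyNA(ann$sample_id)) {
    stop("annotations do not cover all panel columns")
  }
  if (!all(ann$rna_species == "mouse")) {
    stop("non-mouse sample in cross-hybridization panel: ",
         paste(ann$sample_id[ann$rna_species != "mouse"], collapse = ", "))
  }
  bio <- unique(ann$model_name)
  counts <- stats::setNames(integer(nrow(calls$call)),
                            rownames(calls$call))
  for (b in bio) {
    cols <- which(ann$model_name == b)
    det <- apply(calls$call[, cols, drop = FALSE], 1L, sample_detected,
                 n_replicates = length(cols), min_present = min_present)
    counts <- counts + as.integer(det)
  }
  structure(counts, class = "crosshyb_mask",
            n_samples = length(bio), sample_ids = bio)
}

#' @export
print.crosshyb_mask <- function(x, ...) {
  cat(sprintf(
    "crosshyb_mask: %d probe sets, %d flagged in >=1 of %d mouse samples\n",
    length(x), sum(x >= 1L), attr(x, "n_samples")
  ))
  invisible(x)
}

#' Stringency view of a cross-hybridization mask
#'
#' @param mask a `crosshyb_mask` (or bare named integer vector of
#'   counts).
#' @param s stringency: minimum number of mouse samples (1..n_samples,
#'   study design 1..5) a probe set must be detected in.
#' @return character vector of masked probe-set ids; nested downward in
#'   `s` (mask(s+1) is a subset of mask(s)).
#' @export
mask_at_stringency <- function(mask, s) {
  n <- attr(mask, "n_samples")
  if (is.null(n)) n <- max(5L, max(mask))
  if (length(s) != 1L || is.na(s) || s < 1L || s > n) {
    stop(sprintf("stringency must lie in 1..%d", n))
  }
  names(mask)[mask >= s]
}

#' Apply a mask to a ranked fold-change list
#'
#' Order-preserving partition of a ranked table into retained and
#' removed entries; retained entries are re-ranked 1..n. Idempotent, and
#' an empty mask is valid (nothing removed).
#'
#' @param ranked data.frame with at least `probe_set_id`; row order is
#'   the ranking.
#' @param mask_set character vector of masked probe-set ids.
#' @return list with `retained` (re-ranked) and `removed`.
#' @export
apply_mask <- function(ranked, mask_set) {
  stopifnot(is.data.frame(ranked), "probe_set_id" %in% names(ranked))
  hit <- ranked$probe_set_id %in% mask_set
  retained <- ranked[!hit, , drop = FALSE]
  removed <- ranked[hit, , drop = FALSE]
  if (nrow(retained) > 0L) retained$rank <- seq_len(nrow(retained))
  rownames(retained) <- NULL
  rownames(removed) <- NULL
  list(retained = retained, removed = removed)
}

#' Serialize / load a cross-hybridization mask (TSV)
#'
#' Format: `probe_set_id<TAB>n_mouse_samples`; probe sets with count 0
#' are omitted from the file but defined as 0 on load when a universe is
#' supplied.
#'
#' @param mask a `crosshyb_mask`.
#' @param path file path.
#' @export
write_crosshyb_mask <- function(mask, path) {
  df <- data.frame(probe_set_id = names(mask),
                   n_mouse_samples = as.integer(mask))
  df <- df[df$n_mouse_samples > 0L, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_samples: %d", attr(mask, "n_samples")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_crosshyb_mask
#' @param universe optional character vector of all probe-set ids; ids
#'   absent from the file get count 0.
#' @export
read_crosshyb_mask <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- .read_comment_header(path)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  if (!all(c("probe_set_id", "n_mouse_samples") %in% names(df))) {
    stop(path, ": mask file needs columns probe_set_id, n_mouse_samples")
  }
  n_samples <- if (!is.null(header[["n_samples"]])) {
    as.integer(header[["n_samples"]])
  } else {
    max(5L, max(df$n_mouse_samples))
  }
  ids <- if (is.null(universe)) df$probe_set_id else
    union(universe, df$probe_set_id)
  counts <- stats::setNames(integer(length(ids)), ids)
  counts[df$probe_set_id] <- as.integer(df$n_mouse_samples)
  structure(counts, class = "crosshyb_mask", n_samples = n_samples,
            sample_ids = NULL)
}

#' Load the worked-example transition table fixture
#'
#' Fixture format: TSV with columns `rank`, `probe_set_id`,
#' `gene_symbol`, `fold_change`, and (for the pre-mask block)
#' `n_mouse_samples`.
#'
#' @param path TSV path.
#' @return data.frame ordered by `rank`.
#' @export
read_transition_fixture <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          na.strings = c("NA", ""))
  required <- c("rank", "probe_set_id", "fold_change")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(path, ": missing column(s): ", paste(missing, collapse = ", "))
  }
  df$gene_symbol[is.na(df$gene_symbol)] <- ""
  df[order(df$rank), , drop = FALSE]
}
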