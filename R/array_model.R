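#' @keywords internal
"_PACKAGE"

## Controlled vocabulary for the passage factor. P0 is the in vitro culture
## used for implantation; P1/P4/P10 are serial in vivo transplant
## generations; MOUSE_PANEL marks mouse-RNA-on-human-array samples used to
## build the cross-hybridization mask.
PASSAGE_LEVELS <- c("P0", "P1", "P4", "P10", "MOUSE_PANEL")

RNA_SPECIES_LEVELS <- c("human", "mouse")

#' Chip layout: probe-pair to probe-set structure of an array
#'
#' A `chip_layout` maps every probe-pair index on the array to exactly one
#' probe set, and flags control probe sets by the `AFFX-` identifier prefix
#' convention. Probe-pair indices run 1..n in chip order.
#'
#' @param probe_set_of character vector, one entry per probe-pair index,
#'   giving the probe-set identifier that pair belongs to.
#' @return An object of class `chip_layout` with elements `probe_set_ids`
#'   (unique set identifiers, first-appearance order), `probe_set_of`,
#'   `probe_pairs` (named list mapping set id to its probe-pair indices),
#'   `control_ids` and `n_probe_pairs`.
#' @export
chip_layout <- function(probe_set_of) {
  probe_set_of <- trimws(as.character(probe_set_of))
  if (length(probe_set_of) == 0L) {
    stop("chip layout must contain at least one probe pair")
  }
  if (anyNA(probe_set_of) || any(probe_set_of == "")) {
    stop("chip layout contains missing probe-set identifiers")
  }
  ids <- unique(probe_set_of)
  pairs <- split(seq_along(probe_set_of), factor(probe_set_of, levels = ids))
  structure(
    list(
      probe_set_ids = ids,
      probe_set_of = probe_set_of,
      probe_pairs = pairs,
      control_ids = ids[startsWith(ids, "AFFX-")],
      n_probe_pairs = length(probe_set_of)
    ),
    class = "chip_layout"
  )
}

#' @export
print.chip_layout <- function(x, ...) {
  cat(sprintf(
    "chip_layout: %d probe sets, %d probe pairs, %d controls\n",
    length(x$probe_set_ids), x$n_probe_pairs, length(x$control_ids)
  ))
  invisible(x)
}

#' Per-sample probe-level intensity table
#'
#' Raw-array stand-in: perfect-match (PM) and mismatch (MM) fluorescence
#' intensities over the probe-pair indices of a [chip_layout()].
#'
#' @param sample_id sample identifier.
#' @param pm,mm numeric vectors of nonnegative finite intensities, aligned
#'   to the layout's probe-pair order.
#' @param layout the `chip_layout` the intensities are aligned to.
#' @export
probe_intensity_table <- function(sample_id, pm, mm, layout) {
  stopifnot(inherits(layout, "chip_layout"))
  sample_id <- trimws(as.character(sample_id))
  pm <- as.numeric(pm)
  mm <- as.numeric(mm)
  if (length(pm) != length(mm)) {
    stop("pm and mm must have the same length")
  }
  if (length(pm) != layout$n_probe_pairs) {
    stop(sprintf(
      "intensity table has %d probe pairs but layout expects %d",
      length(pm), layout$n_probe_pairs
    ))
  }
  if (!all(is.finite(pm)) || !all(is.finite(mm))) {
    stop("intensities must be finite")
  }
  if (any(pm < 0) || any(mm < 0)) {
    stop(sprintf(
      "negative intensity at probe index %d",
      which(pm < 0 | mm < 0)[1L]
    ))
  }
  structure(
    list(sample_id = sample_id, pm = pm, mm = mm),
    class = "probe_intensity_table"
  )
}

## ---------------------------------------------------------------------------
## Plain-text formats. All are tab- or comma-separated with '#' header
## comment lines carrying identity/provenance, so that fixtures remain
## diffable and round-trip bit-identically on the chosen decimal
## representation.

.read_comment_header <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  out <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || !startsWith(line, "#")) break
    out <- c(out, line)
  }
  kv <- list()
  for (line in out) {
    m <- regmatches(line, regexec("^#\\s*([^:]+):\\s*(.*)$", line))[[1L]]
    if (length(m) == 3L) kv[[trimws(m[2L])]] <- trimws(m[3L])
  }
  kv
}

#' Write / read a probe intensity table (TSV dialect)
#'
#' Format: `#`-prefixed header comments carrying `sample_id` and `layout`,
#' then a header line `probe_index<TAB>pm<TAB>mm` and one row per probe
#' pair. Intensities are serialized with full precision (`format(...,
#' digits = 17)`) so a write-then-read round trip is bit-identical.
#'
#' @param table a [probe_intensity_table()].
#' @param path file path.
#' @param layout the [chip_layout()] the file must conform to.
#' @param layout_name optional layout label recorded in the header.
#' @export
write_probe_intensity_table <- function(table, path, layout_name = "layout") {
  stopifnot(inherits(table, "probe_intensity_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# sample_id: ", table$sample_id),
    paste0("# layout: ", layout_name),
    "probe_index\tpm\tmm"
  ), con)
  writeLines(sprintf(
    "%d\t%s\t%s",
    seq_along(table$pm),
    format(table$pm, digits = 17, trim = TRUE, scientific = FALSE),
    format(table$mm, digits = 17, trim = TRUE, scientific = FALSE)
  ), con)
  invisible(path)
}

#' @rdname write_probe_intensity_table
#' @export
read_probe_intensity_table <- function(path, layout) {
  stopifnot(inherits(layout, "chip_layout"))
  if (!file.exists(path)) stop("file not found: ", path)
  header <- .read_comment_header(path)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  required <- c("probe_index", "pm", "mm")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")))
  }
  if (nrow(df) != layout$n_probe_pairs) {
    stop(sprintf(
      "%s: %d probe rows but layout expects %d", path,
      nrow(df), layout$n_probe_pairs
    ))
  }
  bad <- which(!is.finite(df$pm) | !is.finite(df$mm) | df$pm < 0 | df$mm < 0)
  if (length(bad) > 0L) {
    stop(sprintf("%s: negative or non-finite intensity at data row %d",
                 path, bad[1L]))
  }
  df <- df[order(df$probe_index), , drop = FALSE]
  sample_id <- header[["sample_id"]]
  if (is.null(sample_id)) sample_id <- basename(path)
  probe_intensity_table(sample_id, df$pm, df$mm, layout)
}

#' Write / read a chip layout (TSV: probe_set_id, probe_index)
#' @param layout a [chip_layout()].
#' @param path file path.
#' @export
write_chip_layout <- function(layout, path) {
  stopifnot(inherits(layout, "chip_layout"))
  df <- data.frame(
    probe_set_id = layout$probe_set_of,
    probe_index = seq_len(layout$n_probe_pairs)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chip_layout
#' @export
read_chip_layout <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  if (!all(c("probe_set_id", "probe_index") %in% names(df))) {
    stop(path, ": layout file needs columns probe_set_id, probe_index")
  }
  df <- df[order(df$probe_index), , drop = FALSE]
  if (!identical(as.integer(df$probe_index), seq_len(nrow(df)))) {
    stop(path, ": probe_index must be a permutation of 1..n")
  }
  chip_layout(df$probe_set_id)
}

#' Read / write a sample sheet (CSV)
#'
#' Columns: `sample_id,model_name,passage,replicate_index,rna_species,
#' tumor_class`. Passage labels are validated against the controlled
#' vocabulary P0/P1/P4/P10/MOUSE_PANEL; duplicate sample ids are rejected.
#'
#' @param path CSV file path.
#' @return data.frame of sample annotations.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        colClasses = "character")
  required <- c("sample_id", "model_name", "passage", "replicate_index",
                "rna_species", "tumor_class")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")))
  }
  for (col in required) df[[col]] <- trimws(df[[col]])
  df$replicate_index <- as.integer(df$replicate_index)
  validate_annotations(df)
  df
}

#' @rdname read_sample_sheet
#' @param annotations annotation data.frame as returned by `read_sample_sheet`.
#' @export
write_sample_sheet <- function(annotations, path) {
  validate_annotations(annotations)
  utils::write.csv(annotations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a sample annotation data.frame
#' @param annotations data.frame with the sample-sheet columns.
#' @return the annotations, invisibly, on success.
#' @export
validate_annotations <- function(annotations) {
  bad <- setdiff(unique(annotations$passage), PASSAGE_LEVELS)
  if (length(bad) > 0L) {
    stop(sprintf(
      "unknown passage label(s): %s (allowed: %s)",
      paste(bad, collapse = ", "), paste(PASSAGE_LEVELS, collapse = ", ")
    ))
  }
  dup <- annotations$sample_id[duplicated(annotations$sample_id)]
  if (length(dup) > 0L) {
    stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "))
  }
  bad <- setdiff(unique(annotations$rna_species), RNA_SPECIES_LEVELS)
  if (length(bad) > 0L) {
    stop("unknown rna_species: ", paste(bad, collapse = ", "))
  }
  if (any(!is.finite(annotations$replicate_index) |
            annotations$replicate_index < 1)) {
    stop("replicate_index must be a positive integer")
  }
  invisible(annotations)
}

#' Write / read a probe-set expression matrix (TSV)
#'
#' First column `probe_set_id`, one column per sample; `#` header comments
#' carry provenance (`normalization_method`, `median_scaling_target`).
#' Values are log2 normalized expression and must be finite.
#'
#' @param matrix numeric matrix, rownames = probe-set ids, colnames =
#'   sample ids.
#' @param path file path.
#' @export
write_expression_matrix <- function(matrix, path) {
  stopifnot(is.matrix(matrix))
  if (any(!is.finite(matrix))) {
    stop("expression matrix contains non-finite values; refusing to write")
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop("expression matrix must have row and column names")
  }
  prov <- attr(matrix, "provenance")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(prov)) {
    for (key in names(prov)) {
      writeLines(sprintf("# %s: %s", key, prov[[key]]), con)
    }
  }
  writeLines(paste(c("probe_set_id", colnames(matrix)), collapse = "\t"), con)
  body <- apply(format(matrix, digits = 17, trim = TRUE,
                       scientific = FALSE), 1L, paste, collapse = "\t")
  writeLines(paste(rownames(matrix), body, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- .read_comment_header(path)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop(path, ": no expression data found (header-only or empty file)")
  }
  if (names(df)[1L] != "probe_set_id") {
    stop(path, ": first column must be probe_set_id")
  }
  if (anyDuplicated(df$probe_set_id)) {
    stop(path, ": duplicated probe_set_id rows")
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$probe_set_id
  if (any(!is.finite(m))) stop(path, ": non-finite expression values")
  if (length(header) > 0L) attr(m, "provenance") <- header
  m
}

#' Cross-check a cohort of intensity tables against its sample sheet
#'
#' Verifies the tables and annotations are in bijection and reports
#' replicate counts per model and passage. Deviations from the design of
#' five tumors per in vivo passage, or in vitro (P0) replicate counts
#' outside 2..5, are reported as warnings in the returned report (the count
#' expectations mirror the published cohort design, where e.g. a model may
#' contribute only 4 samples at P1).
#'
#' @param tables list of [probe_intensity_table()].
#' @param annotations sample-sheet data.frame.
#' @param layout the shared [chip_layout()].
#' @return list with `counts` (model x passage replicate counts) and
#'   `warnings` (character vector, possibly empty).
#' @export
validate_cohort <- function(tables, annotations, layout) {
  validate_annotations(annotations)
  table_ids <- vapply(tables, function(t) t$sample_id, character(1))
  if (anyDuplicated(table_ids)) {
    stop("duplicate sample_id among intensity tables")
  }
  orphan_tables <- setdiff(table_ids, annotations$sample_id)
  if (length(orphan_tables) > 0L) {
    stop("intensity table without annotation: ",
         paste(orphan_tables, collapse = ", "))
  }
  orphan_ann <- setdiff(annotations$sample_id, table_ids)
  if (length(orphan_ann) > 0L) {
    stop("annotation without intensity table: ",
         paste(orphan_ann, collapse = ", "))
  }
  for (t in tables) {
    if (length(t$pm) != layout$n_probe_pairs) {
      stop(sprintf("sample %s: %d probe pairs, layout expects %d",
                   t$sample_id, length(t$pm), layout$n_probe_pairs))
    }
  }
  counts <- table(annotations$model_name,
                  factor(annotations$passage, levels = PASSAGE_LEVELS))
  warnings <- character()
  for (model in rownames(counts)) {
    for (p in c("P1", "P4", "P10")) {
      n <- counts[model, p]
      if (n > 0L && n != 5L) {
        warnings <- c(warnings,
                      sprintf("%d samples %s for %s (expected 5)", n, p, model))
      }
    }
    n0 <- counts[model, "P0"]
    if (n0 > 0L && (n0 < 2L || n0 > 5L)) {
      warnings <- c(warnings,
                    sprintf("%d samples P0 for %s (expected 2-5)", n0, model))
    }
  }
  list(counts = counts, warnings = warnings)
}
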