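## Gene-set over-representation statistics with the column semantics of
## a DAVID-style report: modified Fisher (EASE) p-value, fold
## enrichment, Benjamini-Hochberg adjusted p, and FDR percent.

#' Hypergeometric upper-tail (Fisher) p-value
#'
#' `P[X >= k]` for X hypergeometric: drawing `n` genes from a background
#' of `N` containing `K` term members.
#'
#' @param k overlap size.
#' @param n gene-list size.
#' @param K term size.
#' @param N background size.
#' @export
fisher_p <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || k > min(n, K) || K > N || n > N) {
    stop(sprintf("inconsistent counts: k=%d n=%d K=%d N=%d", k, n, K, N))
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' EASE score (jackknifed Fisher p-value)
#'
#' The conservative DAVID convention: one gene is removed from the
#' overlap before the upper-tail test, so `ease_p(k, ...) =
#' fisher_p(k - 1, ...)` and an overlap of one is never significant
#' (p = 1).
#'
#' @inheritParams fisher_p
#' @export
ease_p <- function(k, n, K, N) {
  if (k <= 1) {
    # validate before the early exit
    if (any(c(k, n, K, N) < 0) || k > min(n, K) || K > N || n > N) {
      stop(sprintf("inconsistent counts: k=%d n=%d K=%d N=%d", k, n, K, N))
    }
    return(1)
  }
  fisher_p(k - 1, n, K, N)
}

#' Fold enrichment
#'
#' `(k/n) / (K/N)`: overlap rate in the list relative to the background
#' rate of the term.
#'
#' @inheritParams fisher_p
#' @export
fold_enrichment <- function(k, n, K, N) {
  if (any(c(n, K, N) <= 0)) stop("n, K, N must be positive")
  (k / n) / (K / N)
}

#' Read gene sets in GMT format
#'
#' One term per line: `term_id<TAB>term_name<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file path.
#' @return named list of character vectors; names are term ids, the
#'   `term_name` attribute carries descriptions.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 3L)
  if (length(bad) > 0L) {
    stop(sprintf("%s: line %d has fewer than 3 fields", path, bad[1L]))
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  attr(sets, "term_name") <- stats::setNames(
    vapply(parts, `[[`, character(1), 2L), names(sets))
  sets
}

#' Gene-set over-representation analysis of a gene list
#'
#' One record per term with overlap `k >= min_overlap`; the p-value is
#' the EASE score by default (plain Fisher optional), `benjamini` is the
#' Benjamini-Hochberg adjustment over the tested terms and
#' `fdr_percent = benjamini * 100`. Output sorted ascending by p, ties
#' by term id. Genes absent from the background are dropped with a
#' warning and the test runs on the mapped subset.
#'
#' @param genes character vector (the gene list).
#' @param collection named list of term gene vectors (e.g. from
#'   [read_gmt()]).
#' @param background character vector, the gene universe. Defaults to
#'   the union of all term members.
#' @param min_overlap minimum overlap to report a term (default 2).
#' @param stat `"ease"` (default) or `"fisher"`.
#' @return data.frame `term_id`, `term_name`, `gene_count`, `p_value`,
#'   `fold_enrichment`, `benjamini`, `fdr_percent`.
#' @export
enrich_list <- function(genes, collection, background = NULL,
                        min_overlap = 2L, stat = c("ease", "fisher")) {
  stat <- match.arg(stat)
  if (is.null(background)) background <- unique(unlist(collection))
  background <- unique(background)
  genes <- unique(genes)
  unmapped <- setdiff(genes, background)
  if (length(unmapped) > 0L) {
    warning(sprintf("%d gene(s) not in background, dropped: %s",
                    length(unmapped),
                    paste(utils::head(unmapped, 10), collapse = ", ")))
    genes <- intersect(genes, background)
  }
  n <- length(genes)
  N <- length(background)
  term_names <- attr(collection, "term_name")
  rows <- lapply(names(collection), function(tid) {
    members <- intersect(collection[[tid]], background)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(genes, members))
    if (k < min_overlap) return(NULL)
    p <- if (stat == "ease") ease_p(k, n, K, N) else fisher_p(k, n, K, N)
    data.frame(
      term_id = tid,
      term_name = if (!is.null(term_names)) term_names[[tid]] else tid,
      gene_count = k,
      p_value = p,
      fold_enrichment = fold_enrichment(k, n, K, N),
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(term_id = character(), term_name = character(),
                      gene_count = integer(), p_value = numeric(),
                      fold_enrichment = numeric(), benjamini = numeric(),
                      fdr_percent = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$benjamini <- stats::p.adjust(out$p_value, method = "BH")
  out$fdr_percent <- out$benjamini * 100
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
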