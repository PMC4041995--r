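## In vivo efficacy arithmetic: caliper-to-weight conversion, percent
## treated-over-control (%T/C), the activity call, and per-day group
## comparison.

#' Caliper measurement to tumor weight
#'
#' `weight (mg) = length (mm) x width^2 (mm) / 2`; at 10 x 10 mm a tumor
#' weighs approximately 500 mg.
#'
#' @param length_mm,width_mm caliper measurements; length is the longer
#'   axis.
#' @return weight in mg (vectorized).
#' @export
caliper_to_weight <- function(length_mm, width_mm) {
  if (any(length_mm < 0) || any(width_mm < 0)) {
    stop("caliper measurements must be >= 0")
  }
  length_mm * width_mm^2 / 2
}

#' Read a caliper measurement CSV
#'
#' Columns: `animal_id,group,day,length_mm,width_mm` with group in
#' {vehicle, treated}. Rows where width exceeds length are swapped with
#' a warning (length is defined as the longer axis).
#'
#' @param path CSV path.
#' @return data.frame with an added `weight_mg` column.
#' @export
read_caliper_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  required <- c("animal_id", "group", "day", "length_mm", "width_mm")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(path, ": missing column(s): ", paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(df$group), c("vehicle", "treated"))
  if (length(bad) > 0L) {
    stop("group must be vehicle or treated; found: ",
         paste(bad, collapse = ", "))
  }
  swap <- df$width_mm > df$length_mm
  if (any(swap)) {
    warning(sum(swap), " row(s) had width > length; axes swapped")
    tmp <- df$length_mm[swap]
    df$length_mm[swap] <- df$width_mm[swap]
    df$width_mm[swap] <- tmp
  }
  df$weight_mg <- caliper_to_weight(df$length_mm, df$width_mm)
  df
}

#' Two-sample comparison of tumor weights at one day
#'
#' Student's (pooled-variance) two-sided t-test; not evaluable (NA) when
#' either group has fewer than 2 animals.
#'
#' @param treated,control numeric weight vectors.
#' @return p-value, or NA when not evaluable.
#' @export
group_compare <- function(treated, control) {
  if (length(treated) < 2L || length(control) < 2L) return(NA_real_)
  if (stats::sd(treated) == 0 && stats::sd(control) == 0) {
    return(if (mean(treated) == mean(control)) 1 else 0)
  }
  stats::t.test(treated, control, var.equal = TRUE)$p.value
}

#' Percent treated-over-control (%T/C) and the optimal value
#'
#' Per day with both groups measured,
#' `%T/C = 100 x summary(treated) / summary(control)` where the group
#' summary is the median tumor weight; the optimal %T/C is the minimum
#' over days. %T/C is inversely related to tumor sensitivity, and a
#' value of 40% or lower indicates antitumor activity.
#'
#' @param measurements data.frame as from [read_caliper_csv()] (needs
#'   `group`, `day`, `weight_mg`).
#' @param summary `"median"` (default) or `"mean"` group summary.
#' @return list of class `efficacy_result`: `per_day` (data.frame with
#'   `day`, `percent_tc`, `p_value`), `optimal_percent_tc`, `active`.
#' @export
percent_tc <- function(measurements, summary = c("median", "mean")) {
  summary <- match.arg(summary)
  fn <- if (summary == "median") stats::median else mean
  stopifnot(all(c("group", "day", "weight_mg") %in% names(measurements)))
  days <- sort(unique(measurements$day))
  rows <- lapply(days, function(d) {
    t <- measurements$weight_mg[measurements$day == d &
                                  measurements$group == "treated"]
    c <- measurements$weight_mg[measurements$day == d &
                                  measurements$group == "vehicle"]
    if (length(t) == 0L || length(c) == 0L) {
      warning("day ", d, " lacks one group; skipped")
      return(NULL)
    }
    if (fn(c) <= 0) {
      warning("day ", d, " has non-positive control summary; skipped")
      return(NULL)
    }
    data.frame(day = d, percent_tc = 100 * fn(t) / fn(c),
               p_value = group_compare(t, c))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("no day with both groups measured")
  per_day <- do.call(rbind, rows)
  rownames(per_day) <- NULL
  optimal <- min(per_day$percent_tc)
  structure(
    list(per_day = per_day, optimal_percent_tc = optimal,
         active = activity_call(optimal) == "active"),
    class = "efficacy_result"
  )
}

#' Antitumor activity call from the optimal %T/C
#'
#' Active iff the optimal %T/C is 40% or lower (boundary inclusive).
#'
#' @param optimal_tc optimal percent T/C.
#' @return `"active"` or `"inactive"`.
#' @export
activity_call <- function(optimal_tc) {
  if (optimal_tc < 0) stop("%T/C must be >= 0")
  if (optimal_tc <= 40) "active" else "inactive"
}

#' @export
print.efficacy_result <- function(x, ...) {
  cat(sprintf("efficacy_result: optimal %%T/C = %.1f (%s)\n",
              x$optimal_percent_tc,
              if (x$active) "active" else "inactive"))
  print(x$per_day)
  invisible(x)
}
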