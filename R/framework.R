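# Indicator-framework membership accounting: which indicators appear in
# established reference frameworks (CRI, PEOPLES, Sendai) and which are
# novel. The packaged membership fixture lives under
# inst/extdata/indicator_membership.csv. Prose overlap claims that
# disagree with the cell-level table are surfaced, never reconciled.

#' Load an indicator-framework membership table
#'
#' CSV with columns `no`, `indicator`, `dimension`, one column per
#' reference framework, and `novel`. Cells may use 1/0, TRUE/FALSE, or the
#' checkmark/dash convention (any of `✓`, `x` is NOT accepted); an
#' unknown symbol is an error naming the row.
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @param framework_cols names of the framework flag columns.
#' @return `membership_table`: data.frame with logical flag columns.
#' @export
load_membership <- function(path = system.file("extdata",
                                               "indicator_membership.csv",
                                               package = "resilmine"),
                            framework_cols = c("cri", "peoples", "sendai")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("indicator", framework_cols, "novel")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("membership CSV missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$indicator))
    stop("duplicate indicator names in membership table")
  to_flag <- function(col, colname) {
    v <- trimws(as.character(col))
    out <- rep(NA, length(v))
    out[v %in% c("1", "TRUE", "true", "✓")] <- TRUE
    out[v %in% c("0", "FALSE", "false", "-", "–", "")] <- FALSE
    bad <- which(is.na(out))
    if (length(bad))
      stop("unknown symbol '", v[bad[1]], "' in column ", colname,
           ", row ", bad[1], " (", df$indicator[bad[1]], ")")
    out
  }
  for (cc in c(framework_cols, "novel")) df[[cc]] <- to_flag(df[[cc]], cc)
  attr(df, "framework_cols") <- framework_cols
  class(df) <- c("membership_table", "data.frame")
  df
}

#' Write a membership table as CSV (0/1 flags)
#'
#' @param t a `membership_table`.
#' @param path output path.
#' @export
write_membership <- function(t, path) {
  df <- as.data.frame(t)
  for (cc in c(attr(t, "framework_cols"), "novel"))
    df[[cc]] <- as.integer(df[[cc]])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Framework overlap and novelty statistics
#'
#' Per-framework presence counts (column sums) and fractions of the total
#' indicator count, plus the novel count/fraction. Novelty and framework
#' presence are reported per row without assuming exclusivity (a row may
#' be both present in a framework and marked novel).
#'
#' @param t a `membership_table`.
#' @return list with `n`, `frameworks` (data.frame framework, count,
#'   fraction), `novel_count`, `novel_fraction`, and `both` (rows marked
#'   novel yet present in at least one framework).
#' @export
overlap_stats <- function(t) {
  if (!nrow(t)) stop("membership table is empty")
  fcols <- attr(t, "framework_cols") %||% c("cri", "peoples", "sendai")
  counts <- vapply(fcols, function(cc) sum(t[[cc]]), integer(1))
  present_any <- Reduce(`|`, lapply(fcols, function(cc) t[[cc]]))
  list(n = nrow(t),
       frameworks = data.frame(framework = fcols,
                               count = as.integer(counts),
                               fraction = as.numeric(counts) / nrow(t)),
       novel_count = sum(t$novel),
       novel_fraction = sum(t$novel) / nrow(t),
       both = t$indicator[t$novel & present_any])
}
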