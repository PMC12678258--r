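# Expert-validation statistics: Cohen's kappa (pairwise and panel mean),
# Likert retention, reviewer consensus gating, and flagging of indicators
# whose group means diverge across NPI-stringency strata.

#' Read a rating table from CSV
#'
#' Expects an `item` column plus one column per rater; an optional
#' `group:` prefix row is not used — rater groups go in a `groups`
#' attribute supplied here.
#'
#' @param path CSV path (columns: item, then raters).
#' @param groups optional character vector, one group label per rater.
#' @return an items x raters matrix of class `"rating_table"`.
#' @export
read_rating_table <- function(path, groups = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"item" %in% names(df)) stop("rating CSV needs an 'item' column")
  m <- as.matrix(df[setdiff(names(df), "item")])
  rownames(m) <- df$item
  if (!is.null(groups)) {
    stopifnot(length(groups) == ncol(m))
    attr(m, "groups") <- as.character(groups)
  }
  class(m) <- c("rating_table", class(m))
  m
}

#' Write a rating table as CSV
#'
#' @param table items x raters matrix.
#' @param path output path.
#' @export
write_rating_table <- function(table, path) {
  m <- unclass(table)
  attr(m, "groups") <- NULL
  df <- data.frame(item = rownames(m) %||% seq_len(nrow(m)), m,
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Cohen's kappa between two raters
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and
#' chance agreement `p_e` from the raters' marginal category frequencies.
#' When both raters are constant and equal (`p_e = 1`), agreement is
#' perfect and kappa is defined as 1 by convention (with a message).
#'
#' @param r1,r2 equal-length rating vectors (>= 2 items); any ordinal or
#'   categorical coding.
#' @return scalar <= 1.
#' @export
cohen_kappa <- function(r1, r2) {
  if (length(r1) != length(r2)) stop("rating vectors differ in length")
  if (length(r1) < 2) stop("kappa needs at least 2 items")
  cats <- sort(unique(c(r1, r2)))
  p_o <- mean(r1 == r2)
  m1 <- table(factor(r1, levels = cats)) / length(r1)
  m2 <- table(factor(r2, levels = cats)) / length(r2)
  p_e <- sum(as.numeric(m1) * as.numeric(m2))
  if (p_e >= 1) {
    message("both raters constant and identical; kappa = 1 by convention")
    return(1)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Panel kappa: mean of all pairwise Cohen's kappas
#'
#' Invariant to rater order; reduces to [cohen_kappa()] for two raters.
#'
#' @param table items x raters matrix (>= 2 raters).
#' @return scalar <= 1.
#' @export
panel_kappa <- function(table) {
  m <- as.matrix(table)
  if (ncol(m) < 2) stop("panel kappa needs at least 2 raters")
  pairs <- utils::combn(ncol(m), 2)
  mean(apply(pairs, 2, function(ij) cohen_kappa(m[, ij[1]], m[, ij[2]])))
}

#' Likert retention rule
#'
#' An item is retained iff at least `min_approvals` raters score it at or
#' above `approval_score` AND its mean score is at least `mean_floor`
#' (both sub-rules individually toggleable). Raising any score never
#' removes a retained item.
#'
#' @param table items x raters matrix of 1-5 scores.
#' @param min_approvals required count of approving raters (default 4).
#' @param approval_score score counting as approval (default 4).
#' @param mean_floor required item mean (default 4.0).
#' @param use_approvals,use_mean toggles for the two sub-rules.
#' @return logical vector of retained items (named by rownames).
#' @export
likert_retention <- function(table, min_approvals = 4L, approval_score = 4,
                             mean_floor = 4.0, use_approvals = TRUE,
                             use_mean = TRUE) {
  m <- as.matrix(table)
  ok_appr <- rowSums(m >= approval_score) >= min_approvals
  ok_mean <- rowMeans(m) >= mean_floor
  out <- rep(TRUE, nrow(m))
  if (use_approvals) out <- out & ok_appr
  if (use_mean) out <- out & ok_mean
  stats::setNames(out, rownames(m))
  }

#' Reviewer consensus gate
#'
#' Pass iff the approval fraction is at least the threshold (default 2/3,
#' i.e. the "at least two of three reviewers" rule; exactly 2/3 passes,
#' anything below it fails).
#'
#' @param fractions numeric approval fractions in [0, 1].
#' @param threshold consensus threshold (default `2/3`).
#' @return logical vector.
#' @export
consensus_gate <- function(fractions, threshold = 2 / 3) {
  stopifnot(all(fractions >= 0 & fractions <= 1))
  fractions >= threshold
}

#' Flag indicators with divergent scores across NPI groups
#'
#' An item is flagged when the relative range of its group means,
#' `(max - min) / overall mean`, exceeds the threshold (default 0.20).
#' Flagged items remain retained; the flag marks them for contextual
#' interpretation only. Set `method = "cv"` to use the coefficient of
#' variation of the group means instead.
#'
#' @param group_means items x groups matrix of mean scores (>= 2 groups).
#' @param threshold flagging threshold (default 0.20).
#' @param method `"relative_range"` (default) or `"cv"`.
#' @return logical vector of flags (named by rownames).
#' @export
npi_variance_flag <- function(group_means, threshold = 0.20,
                              method = c("relative_range", "cv")) {
  method <- match.arg(method)
  m <- as.matrix(group_means)
  if (ncol(m) < 2) stop("need at least 2 groups")
  overall <- rowMeans(m)
  if (any(overall == 0)) stop("zero overall mean for item(s): ",
                              paste(which(overall == 0), collapse = ", "))
  stat <- if (method == "relative_range")
    (apply(m, 1, max) - apply(m, 1, min)) / overall
  else
    apply(m, 1, stats::sd) / overall
  stats::setNames(stat > threshold, rownames(m))
}
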