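# First-pass screen scoring: the weighted mean of SE-reporter, CMV-reporter
# and viability inhibition, and hit identification.
#
# Scale convention: L, C and X are INHIBITION percentages,
# 100 - percent-of-control, so that "weighted average above 60" identifies
# compounds that suppress the SE reporter. The convention is recorded in the
# `scale` attribute of every score table.

#' Weighted screen score
#'
#' The primary-screen score `W = (4L + 2C + X) / 7`, the weighted mean of
#' SE-reporter (`L`), CMV-reporter (`C`) and viability (`X`) inhibition
#' percentages, weighting the SE channel 4:2:1 over CMV and viability.
#' No clamping is applied.
#'
#' @param L,C,X inhibition percentages (vectorised; 100 - percent-of-control).
#' @return weighted scores, same length as the inputs.
#' @export
weighted_score <- function(L, C, X) {
  if (!all(is.finite(L), is.finite(C), is.finite(X)))
    abort_op("weighted_score", "inputs must be finite")
  (4 * L + 2 * C + X) / 7
}

#' Join normalized channels into a per-compound score table
#'
#' Joins the SE-luciferase, CMV-luciferase and XTT-viability normalized
#' tables on compound id, converts percent-of-control to inhibition
#' (100 - percent), and computes the weighted score. Compounds missing any
#' channel are dropped with a warning and listed in the `missing_channel`
#' attribute.
#'
#' @param se,cmv,xtt normalized measurement tables (one channel each).
#' @return a `data.frame` with columns `compound_id, L, C, X, W`;
#'   attributes `scale` ("inhibition") and `missing_channel`.
#' @export
screen_report <- function(se, cmv, xtt) {
  ids <- unique(c(se$compound_id, cmv$compound_id, xtt$compound_id))
  complete <- ids[ids %in% se$compound_id & ids %in% cmv$compound_id &
                    ids %in% xtt$compound_id]
  incomplete <- setdiff(ids, complete)
  if (length(incomplete) > 0L)
    warning(length(incomplete), " compound(s) missing a channel were excluded")
  L <- 100 - se$percent_of_control[match(complete, se$compound_id)]
  C <- 100 - cmv$percent_of_control[match(complete, cmv$compound_id)]
  X <- 100 - xtt$percent_of_control[match(complete, xtt$compound_id)]
  out <- data.frame(compound_id = complete, L = L, C = C, X = X,
                    W = weighted_score(L, C, X), stringsAsFactors = FALSE)
  attr(out, "scale") <- "inhibition"
  attr(out, "missing_channel") <- incomplete
  out
}

#' Call screen hits from weighted scores
#'
#' Flags compounds with `W` strictly above the threshold (default 60) as
#' hits, and reports the Tukey boxplot fences of the `W` distribution
#' (Q1 - 1.5 IQR, Q3 + 1.5 IQR) as a concordance check on the fixed cut:
#' the fences are informational, the threshold is the decision rule.
#'
#' @param scores a score table from [screen_report()] (columns
#'   `compound_id`, `W`), or any data.frame with those columns.
#' @param threshold hit threshold on `W` (default 60; strict `>`).
#' @return `scores` with an `is_hit` column; attributes `threshold` and
#'   `boxplot_fences` (named lower/upper).
#' @export
call_hits <- function(scores, threshold = 60) {
  if (is.null(scores) || nrow(scores) == 0L)
    abort_op("call_hits", "empty score table")
  if (!all(is.finite(scores$W))) abort_op("call_hits", "non-finite W")
  q <- stats::quantile(scores$W, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  out <- scores
  out$is_hit <- scores$W > threshold
  attr(out, "threshold") <- threshold
  attr(out, "scale") <- attr(scores, "scale") %||% "inhibition"
  attr(out, "boxplot_fences") <- c(lower = q[1] - 1.5 * iqr,
                                   upper = q[2] + 1.5 * iqr)
  out
}
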