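# Plate data model, CSV I/O, normalization to negative controls, and assay QC.
#
# A plate table is a data.frame with columns
#   plate_id, row, col, compound_id, role, channel, dose_M, time_h, signal
# where row/col are 0-based well coordinates, role is one of
# "negative_DMSO", "positive_ActD", "sample", channel is one of
# "SE_luc", "CMV_luc", "XTT", "confluence", "fluorescence", doses are molar,
# times in hours, and signal is a non-negative reading (RLU / OD / % / AFU).

PLATE_COLUMNS <- c("plate_id", "row", "col", "compound_id", "role",
                   "channel", "dose_M", "time_h", "signal")
PLATE_ROLES <- c("negative_DMSO", "positive_ActD", "sample")
PLATE_CHANNELS <- c("SE_luc", "CMV_luc", "XTT", "confluence", "fluorescence")

#' Read a plate-reader CSV
#'
#' Expects a UTF-8, comma-separated file with a header row and the columns
#' `plate_id,row,col,compound_id,role,channel,dose_M,time_h,signal`
#' (doses molar, times hours, dot decimal). Malformed rows are reported with
#' their line numbers.
#'
#' @param path path to the CSV file.
#' @return a plate `data.frame` (see module docs for the column contract).
#' @export
read_plate_csv <- function(path) {
  if (!file.exists(path)) abort_op("read_plate_csv", paste("no such file:", path))
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    warning("empty plate file: ", path)
    return(empty_plate_table())
  }
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(PLATE_COLUMNS, names(tbl))
  if (length(missing) > 0L)
    abort_op("read_plate_csv",
             paste("missing required column(s):", paste(missing, collapse = ", ")))
  tbl <- tbl[PLATE_COLUMNS]
  if (nrow(tbl) == 0L) {
    warning("plate file has a header but no rows: ", path)
    return(tbl)
  }
  bad <- which(!is.finite(tbl$signal))
  if (length(bad) > 0L)
    abort_op("read_plate_csv",
             paste("non-numeric signal at line(s):",
                   paste(bad + 1L, collapse = ", ")))
  neg <- which(tbl$signal < 0)
  if (length(neg) > 0L)
    abort_op("read_plate_csv",
             paste("negative signal at line(s):", paste(neg + 1L, collapse = ", ")))
  bad_role <- which(!tbl$role %in% PLATE_ROLES)
  if (length(bad_role) > 0L)
    abort_op("read_plate_csv",
             paste("unknown role at line(s):", paste(bad_role + 1L, collapse = ", ")))
  tbl
}

#' Write a plate table to CSV
#'
#' @param table a plate `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(table, path) {
  validate_plate(table, "write_plate_csv")
  utils::write.csv(table[PLATE_COLUMNS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

empty_plate_table <- function() {
  data.frame(plate_id = character(), row = integer(), col = integer(),
             compound_id = character(), role = character(), channel = character(),
             dose_M = numeric(), time_h = numeric(), signal = numeric(),
             stringsAsFactors = FALSE)
}

validate_plate <- function(tbl, op) {
  missing <- setdiff(PLATE_COLUMNS, names(tbl))
  if (length(missing) > 0L)
    abort_op(op, paste("missing plate column(s):", paste(missing, collapse = ", ")))
  if (nrow(tbl) > 0L && any(tbl$signal < 0, na.rm = TRUE))
    abort_op(op, "negative signal values are not allowed")
  invisible(tbl)
}

#' Normalize well signals to same-plate negative controls
#'
#' Converts raw signals to percent-of-control: each sample well's signal is
#' divided by the mean of the negative (DMSO) control wells of the same plate
#' and channel, times 100, so 100 means "no effect". Control wells are
#' excluded from the output. Replicate wells of the same compound, channel
#' and dose (across plates) are summarised by mean, SD and n.
#'
#' @param plate a plate `data.frame` (possibly several plates).
#' @return a `data.frame` with columns `compound_id, channel, dose_M,
#'   percent_of_control, sd, n`.
#' @export
normalize_to_negative <- function(plate) {
  validate_plate(plate, "normalize_to_negative")
  if (nrow(plate) == 0L) abort_op("normalize_to_negative", "empty plate table")
  key <- interaction(plate$plate_id, plate$channel, drop = TRUE)
  out <- vector("list", nlevels(key))
  for (i in seq_len(nlevels(key))) {
    sub <- plate[key == levels(key)[i], , drop = FALSE]
    negs <- sub$signal[sub$role == "negative_DMSO"]
    if (length(negs) < 2L)
      abort_op("normalize_to_negative",
               sprintf("plate '%s' channel '%s' has %d negative-control wells (need >= 2)",
                       sub$plate_id[1], sub$channel[1], length(negs)))
    mu <- mean(negs)
    if (mu == 0)
      abort_op("normalize_to_negative",
               sprintf("negative-control mean is 0 on plate '%s' channel '%s'",
                       sub$plate_id[1], sub$channel[1]))
    smp <- sub[sub$role == "sample", , drop = FALSE]
    if (nrow(smp) == 0L) next
    out[[i]] <- data.frame(compound_id = smp$compound_id,
                           channel = smp$channel,
                           dose_M = smp$dose_M,
                           percent = 100 * smp$signal / mu,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(compound_id = character(), channel = character(),
                      dose_M = numeric(), percent_of_control = numeric(),
                      sd = numeric(), n = integer(), stringsAsFactors = FALSE))
  grp <- interaction(res$compound_id, res$channel, res$dose_M, drop = TRUE)
  agg <- data.frame(
    compound_id = tapply(res$compound_id, grp, `[`, 1L),
    channel = tapply(res$channel, grp, `[`, 1L),
    dose_M = as.numeric(tapply(res$dose_M, grp, `[`, 1L)),
    percent_of_control = as.numeric(tapply(res$percent, grp, mean)),
    sd = as.numeric(tapply(res$percent, grp, function(v)
      if (length(v) > 1L) stats::sd(v) else 0)),
    n = as.integer(tapply(res$percent, grp, length)),
    stringsAsFactors = FALSE)
  rownames(agg) <- NULL
  agg[order(agg$compound_id, agg$channel, -agg$dose_M), , drop = FALSE]
}

#' Z-factor assay quality control for one plate
#'
#' Computes Zhang's Z' statistic
#' \deqn{Z' = 1 - 3 (\sigma_p + \sigma_n) / |\mu_p - \mu_n|}
#' from the positive and negative control wells of one plate and channel,
#' using sample SDs (n - 1 denominator). A plate passes when Z' meets the
#' configured threshold (default 0.7, the routinely achieved plate
#' performance for this assay).
#'
#' @param plate a plate `data.frame` containing exactly one `plate_id`.
#' @param channel channel to assess.
#' @param threshold pass threshold on Z' (default 0.7).
#' @return a one-row `data.frame`: `plate_id, channel, mu_n, sd_n, mu_p,
#'   sd_p, z_factor, pass`.
#' @export
z_factor <- function(plate, channel, threshold = 0.7) {
  validate_plate(plate, "z_factor")
  sub <- plate[plate$channel == channel, , drop = FALSE]
  if (nrow(sub) == 0L) abort_op("z_factor", paste("no wells for channel", channel))
  if (length(unique(sub$plate_id)) != 1L)
    abort_op("z_factor", "z_factor expects a single plate")
  negs <- sub$signal[sub$role == "negative_DMSO"]
  poss <- sub$signal[sub$role == "positive_ActD"]
  if (length(negs) < 2L || length(poss) < 2L)
    abort_op("z_factor", "need >= 2 wells in each control role")
  mu_n <- mean(negs); sd_n <- stats::sd(negs)
  mu_p <- mean(poss); sd_p <- stats::sd(poss)
  z <- if (mu_p == mu_n) -Inf else 1 - 3 * (sd_p + sd_n) / abs(mu_p - mu_n)
  data.frame(plate_id = sub$plate_id[1], channel = channel,
             mu_n = mu_n, sd_n = sd_n, mu_p = mu_p, sd_p = sd_p,
             z_factor = z, pass = is.finite(z) && z >= threshold,
             stringsAsFactors = FALSE)
}

#' Squared Pearson correlation between two replicate runs
#'
#' Matches compounds by id and returns the squared Pearson correlation of
#' their percent-of-control values — the assay-reproducibility statistic.
#' Returns `NA` when fewer than 3 compounds are shared.
#'
#' @param rep_a,rep_b normalized measurement tables
#'   (from [normalize_to_negative()]), one channel each.
#' @return squared Pearson correlation (unitless), or `NA_real_`.
#' @export
replicate_r2 <- function(rep_a, rep_b) {
  shared <- intersect(rep_a$compound_id, rep_b$compound_id)
  if (length(shared) < 3L) return(NA_real_)
  a <- rep_a$percent_of_control[match(shared, rep_a$compound_id)]
  b <- rep_b$percent_of_control[match(shared, rep_b$compound_id)]
  stats::cor(a, b)^2
}
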