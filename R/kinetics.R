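# Time-resolved growth IC50 trajectories and progress-curve HDAC isoform
# inhibition panels.

#' Growth response at one timepoint
#'
#' Dose response from confluence curves: the drug well's confluence gain
#' over the shared starting confluence, as a percent of the DMSO gain,
#' clamped at 0. Using the gain rather than raw confluence cancels seeding
#' density.
#'
#' @param curves growth `data.frame` for one compound
#'   (`dose_M, time_h, confluence`; dose 0 rows, if present, are ignored).
#' @param t timepoint (hours, must be on the measured grid).
#' @param dmso_curves DMSO growth rows (`time_h, confluence`).
#' @return a `data.frame`: `dose_M, response_pct`; attribute `usable`
#'   (FALSE when DMSO shows no growth at `t`).
#' @export
growth_response_at <- function(curves, t, dmso_curves) {
  d0 <- dmso_curves[dmso_curves$time_h == t, , drop = FALSE]
  if (nrow(d0) == 0L) abort_op("growth_response_at", "t not on the DMSO grid")
  c0 <- mean(dmso_curves$confluence[dmso_curves$time_h == min(dmso_curves$time_h)])
  dmso_gain <- mean(d0$confluence) - c0
  sub <- curves[curves$time_h == t & curves$dose_M > 0, , drop = FALSE]
  doses <- sort(unique(sub$dose_M), decreasing = TRUE)
  gain <- vapply(doses, function(d)
    mean(sub$confluence[sub$dose_M == d]) - c0, 0)
  out <- data.frame(dose_M = doses,
                    response_pct = if (dmso_gain > 0)
                      pmax(0, 100 * gain / dmso_gain) else NA_real_)
  attr(out, "usable") <- dmso_gain > 0
  out
}

#' IC50 trajectory over a growth time course
#'
#' Fits a 4PL dose-response at every usable timepoint (DMSO grown above its
#' starting confluence, and still below the saturation cap of 95%
#' confluence — the monitored window) and tracks the fitted IC50 over time.
#' `stabilization_time` is the first timepoint from which the IC50 stays
#' within `stab_fold` of its final value: early for an immediate-acting
#' compound, late for a slow-onset one.
#'
#' @param curves growth `data.frame` for one compound (dose > 0 rows).
#' @param dmso_curves DMSO growth rows.
#' @param stab_fold stabilization fold tolerance (default 1.5).
#' @param dmso_cap drop timepoints after DMSO exceeds this confluence
#'   (default 95%).
#' @return a list of class `ic50_trajectory`: `table` (data.frame
#'   `time_h, ic50, converged, crosses_50`), `stabilization_time` (hours),
#'   `stab_fold`.
#' @export
ic50_trajectory <- function(curves, dmso_curves, stab_fold = 1.5,
                            dmso_cap = 95) {
  times <- sort(unique(dmso_curves$time_h))
  c0 <- mean(dmso_curves$confluence[dmso_curves$time_h == times[1]])
  rows <- list()
  for (t in times) {
    dm <- mean(dmso_curves$confluence[dmso_curves$time_h == t])
    if (dm - c0 <= 0 || dm > dmso_cap) next
    resp <- growth_response_at(curves, t, dmso_curves)
    if (!isTRUE(attr(resp, "usable")) || nrow(resp) < 4L) next
    fit <- fit_4pl(resp$dose_M, resp$response_pct)
    rows[[length(rows) + 1L]] <- data.frame(
      time_h = t,
      ic50 = if (fit$converged && fit$crosses_50) fit$ic50 else NA_real_,
      converged = fit$converged, crosses_50 = fit$crosses_50)
  }
  tab <- do.call(rbind, rows) %||%
    data.frame(time_h = numeric(), ic50 = numeric(),
               converged = logical(), crosses_50 = logical())
  stab <- NA_real_
  usable <- which(!is.na(tab$ic50))
  if (length(usable) > 0L) {
    final <- tab$ic50[usable[length(usable)]]
    within <- tab$ic50[usable] >= final / stab_fold &
      tab$ic50[usable] <= final * stab_fold
    # first usable timepoint from which every later IC50 stays in band
    ok_from <- rev(cumprod(rev(within))) == 1
    if (any(ok_from)) stab <- tab$time_h[usable[which(ok_from)[1]]]
  }
  structure(list(table = tab, stabilization_time = stab,
                 stab_fold = stab_fold),
            class = "ic50_trajectory")
}

#' Detect the linear range of a progress curve
#'
#' Sliding-window search over contiguous timepoints: among windows of at
#' least `min_points` whose ordinary least-squares fit achieves R-squared
#' at or above `r2_min`, returns the longest, ties broken toward the
#' earliest window — the enzymatic linear phase precedes substrate
#' depletion, so the earliest qualifying window is the assay's linear
#' range (the reported rate is its mid-range first derivative, i.e. the
#' window slope). If no window meets the bound, the best-R-squared window
#' of `min_points` is returned, flagged.
#'
#' Two rates are reported: `rate`, the least-squares slope across the
#' window (the plain linear-range rate), and `rate_initial`, the tangent
#' of a quadratic fit at the window start — a depletion-corrected estimate
#' of the enzymatic rate entering the window, which stays unbiased even
#' when mild substrate-depletion curvature survives inside the accepted
#' window.
#'
#' @param time,signal the trace (>= 6 points, ascending time).
#' @param r2_min R-squared bound (default 0.99).
#' @param min_points minimum window length (default 5).
#' @return a list: `t_start`, `t_end`, `rate` (signal units per time unit),
#'   `rate_initial`, `r2`, `met_criterion`.
#' @export
detect_linear_range <- function(time, signal, r2_min = 0.99, min_points = 5L) {
  n <- length(time)
  if (n < 6L || length(signal) != n)
    abort_op("detect_linear_range", "need >= 6 timepoints")
  if (is.unsorted(time, strictly = TRUE))
    abort_op("detect_linear_range", "time must be strictly ascending")
  win_stats <- function(i, j) {
    x <- time[i:j]; y <- signal[i:j]
    sxx <- sum((x - mean(x))^2)
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    syy <- sum((y - mean(y))^2)
    slope <- sxy / sxx
    sse <- syy - sxy^2 / sxx
    r2 <- if (syy <= 1e-12) 1 else 1 - sse / syy  # constant trace: perfect fit
    list(slope = slope, r2 = max(0, min(1, r2)))
  }
  # tangent of a quadratic fit at the window start (depletion-corrected
  # rate entering the window); falls back to the linear slope if the
  # quadratic is degenerate
  rate_init <- function(i, j, slope) {
    x <- time[i:j] - time[i]; y <- signal[i:j]
    fit <- tryCatch(stats::lm.fit(cbind(1, x, x^2), y)$coefficients[2],
                    error = function(e) NA_real_)
    if (is.finite(fit)) unname(fit) else slope
  }
  wrap <- function(i, w, s, met) {
    list(t_start = time[i], t_end = time[i + w - 1L], rate = s$slope,
         rate_initial = rate_init(i, i + w - 1L, s$slope),
         r2 = s$r2, met_criterion = met)
  }
  for (w in seq(n, min_points)) {
    for (i in seq_len(n - w + 1L)) {
      s <- win_stats(i, i + w - 1L)
      if (s$r2 >= r2_min) return(wrap(i, w, s, TRUE))
    }
  }
  # fallback: no window met the bound (noisy trace) — take the best-R2
  # window over all lengths >= min_points, preferring longer windows
  best <- NULL
  for (w in seq(n, min_points)) {
    for (i in seq_len(n - w + 1L)) {
      s <- win_stats(i, i + w - 1L)
      if (is.null(best) || s$r2 > best$r2 + 1e-9) best <- c(s, i = i, w = w)
    }
  }
  wrap(best$i, best$w, best, FALSE)
}

# Initial rate of one progress-curve trace: least-squares fit of the
# substrate-depletion model b0 + (v/k)(1 - exp(-k t)); falls back to the
# plain linear slope when the exponential is unidentifiable (near-linear
# or flat trace, where the slope is the rate anyway).
.progress_rate <- function(time, signal) {
  n <- length(time)
  early <- seq_len(min(8L, n))
  sl <- stats::coef(stats::lm(signal[early] ~ time[early]))[2]
  v <- tryCatch({
    fit <- minpack.lm::nlsLM(
      signal ~ b0 + (v / k) * (1 - exp(-k * time)),
      start = list(b0 = signal[1], v = max(sl, 1e-6), k = 1 / max(time)),
      lower = c(-Inf, 0, 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 100))
    unname(stats::coef(fit)["v"])
  }, error = function(e) NA_real_)
  if (!is.finite(v)) unname(stats::coef(stats::lm(signal ~ time))[2]) else v
}

#' HDAC isoform IC50 panel from progress curves
#'
#' For each isoform: every trace's enzymatic rate is the initial rate `v`
#' of the substrate-depletion model
#' `F(t) = b0 + (v/k) (1 - exp(-k t))` fitted to the trace — the rate of
#' the linear phase, estimated without the window-selection noise of a
#' sliding linear fit (which [detect_linear_range()] still provides for
#' QC); relative activity is the rate as a percent of the
#' mean DMSO (conc 0) rate; a 4PL fit of activity vs concentration yields
#' the isoform IC50. Isoforms whose activity never drops below 50% within
#' the tested concentrations are censored. Rate-ratio normalization makes
#' the panel invariant to detector gain. `fold_selectivity` is relative to
#' the most sensitive (lowest-IC50) isoform.
#'
#' @param curves progress-curve `data.frame`
#'   (`isoform, conc_M, time_min, signal`; conc 0 rows are the DMSO
#'   traces).
#' @param r2_min,min_points linear-range criterion, see
#'   [detect_linear_range()].
#' @return a `data.frame` of class `isoform_profile`: `isoform, ic50,
#'   censored, fold_selectivity, top, bottom, hill, min_activity`.
#' @export
isoform_ic50_panel <- function(curves, r2_min = 0.99, min_points = 5L) {
  isoforms <- unique(curves$isoform)
  rows <- list()
  for (iso in isoforms) {
    sub <- curves[curves$isoform == iso, , drop = FALSE]
    concs <- sort(unique(sub$conc_M))
    if (!0 %in% concs) {
      warning("isoform ", iso, " has no DMSO trace; skipped")
      next
    }
    # mean initial rate over replicate wells of one concentration
    rate_at <- function(cc) {
      tr <- sub[sub$conc_M == cc, , drop = FALSE]
      wells <- if ("well" %in% names(tr)) unique(tr$well) else 1L
      mean(vapply(wells, function(w) {
        one <- if ("well" %in% names(tr)) tr[tr$well == w, , drop = FALSE] else tr
        one <- one[order(one$time_min), , drop = FALSE]
        .progress_rate(one$time_min, one$signal)
      }, 0))
    }
    dmso_rate <- rate_at(0)
    test_concs <- concs[concs > 0]
    if (length(test_concs) < 4L)
      abort_op("isoform_ic50_panel", "need >= 4 inhibitor concentrations")
    activity <- vapply(test_concs, rate_at, 0) / dmso_rate * 100
    censored <- min(activity) > 50
    ic50 <- NA_real_; top <- NA_real_; bottom <- NA_real_; hill <- NA_real_
    if (!censored) {
      fit <- fit_4pl(test_concs, activity)
      ic50 <- fit$ic50; top <- fit$top; bottom <- fit$bottom; hill <- fit$hill
      if (!fit$converged || !fit$crosses_50) { censored <- TRUE; ic50 <- NA_real_ }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      isoform = iso, ic50 = ic50, censored = censored,
      top = top, bottom = bottom, hill = hill,
      min_activity = min(activity), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) abort_op("isoform_ic50_panel", "no usable isoforms")
  best <- suppressWarnings(min(out$ic50, na.rm = TRUE))
  out$fold_selectivity <- out$ic50 / best
  class(out) <- c("isoform_profile", class(out))
  out
}
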