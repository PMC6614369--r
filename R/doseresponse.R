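# Four-parameter logistic fitting, IC50 extraction, SE-selectivity
# classification, and SE-vs-viability differentials.

#' Construct a geometric dose-dilution series
#'
#' Serial-dilution design: `n` doses starting at `top` and dividing by
#' `factor` at each step (the confirmation assays use 12 concentrations from
#' 30 uM divided by 3, bottoming out at 0.17 nM).
#'
#' @param top top dose (molar, > 0).
#' @param n number of concentrations (>= 2).
#' @param factor dilution factor (> 1).
#' @return a list of class `dose_series`: `doses` (strictly decreasing,
#'   molar), `n_points`, `dilution_factor`.
#' @export
make_dose_series <- function(top, n, factor) {
  if (!is.finite(top) || top <= 0) abort_op("make_dose_series", "top must be > 0")
  if (n < 2) abort_op("make_dose_series", "need n >= 2 doses")
  if (!is.finite(factor) || factor <= 1) abort_op("make_dose_series", "factor must be > 1")
  structure(list(doses = top / factor^(seq_len(n) - 1),
                 n_points = as.integer(n), dilution_factor = factor),
            class = "dose_series")
}

# Internal: residual function for the 4PL in log-dose space.
# theta = (top, bottom, hill, log_ic50); hill kept positive by construction
# of the starts (a rising curve is fitted with bottom > top, not hill < 0).
.fourpl_resid <- function(theta, logx, y) {
  y - (theta[2] + (theta[1] - theta[2]) /
         (1 + exp(theta[3] * (logx - theta[4]))))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `y = bottom + (top - bottom) / (1 + (x/ic50)^hill)` with unconstrained
#' top and bottom, performed in log-dose space with multi-start
#' Levenberg-Marquardt (starts: data-range asymptotes crossed with
#' hill in {0.5, 1, 2} and ic50 at the dose-grid quartiles). The reported
#' IC50 is the curve's inflection dose (relative IC50). `crosses_50` is
#' TRUE iff the fitted curve attains 50% within the tested dose range;
#' otherwise `censored` says on which side the fit ran off.
#'
#' @param series a `dose_series` (or a numeric vector of doses, molar).
#' @param responses percent-of-control responses, one per dose.
#' @return a list of class `fourpl_fit`: `top`, `bottom`, `hill`, `ic50`,
#'   `r2`, `sse`, `converged`, `crosses_50`,
#'   `censored` ("none"/"above_top_dose"/"below_bottom_dose").
#' @export
fit_4pl <- function(series, responses) {
  doses <- if (inherits(series, "dose_series")) series$doses else as.numeric(series)
  if (length(doses) != length(responses))
    abort_op("fit_4pl", "doses and responses must have equal length")
  ok <- is.finite(doses) & is.finite(responses) & doses > 0
  doses <- doses[ok]; responses <- responses[ok]
  if (length(unique(doses)) < 4L)
    abort_op("fit_4pl", "need >= 4 distinct positive doses with finite responses")
  logx <- log(doses)
  y <- responses

  lo <- min(y); hi <- max(y)
  qs <- stats::quantile(logx, c(0.25, 0.5, 0.75), names = FALSE)
  starts <- expand.grid(top = hi, bottom = lo, hill = c(0.5, 1, 2),
                        lic = qs, KEEP.OUT.ATTRS = FALSE)
  # A rising curve has its high asymptote at high dose: add swapped starts.
  starts <- rbind(starts,
                  expand.grid(top = lo, bottom = hi, hill = c(0.5, 1, 2),
                              lic = qs, KEEP.OUT.ATTRS = FALSE))

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = as.numeric(starts[i, ]),
        fn = .fourpl_resid, logx = logx, y = y,
        control = minpack.lm::nls.lm.control(
          maxiter = 200, ftol = 1e-14, ptol = 1e-14, gtol = 0)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse - 1e-12) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) {
    return(structure(list(top = NA_real_, bottom = NA_real_, hill = NA_real_,
                          ic50 = NA_real_, r2 = NA_real_, sse = NA_real_,
                          converged = FALSE, crosses_50 = FALSE,
                          censored = "above_top_dose"),
                     class = "fourpl_fit"))
  }
  th <- best$fit$par
  # Canonical orientation: hill > 0, top = zero-dose asymptote.
  if (th[3] < 0) th <- c(th[2], th[1], -th[3], th[4])
  top <- th[1]; bottom <- th[2]; hill <- th[3]; ic50 <- exp(th[4])
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - best$sse / sst else if (best$sse < 1e-8) 1 else NA_real_
  yhat_lo <- four_pl(min(doses), top, bottom, hill, ic50)
  yhat_hi <- four_pl(max(doses), top, bottom, hill, ic50)
  crosses <- (yhat_lo - 50) * (yhat_hi - 50) <= 0 &&
    is.finite(yhat_lo) && is.finite(yhat_hi)
  censored <- if (crosses) "none"
    else if (min(yhat_lo, yhat_hi) > 50) "above_top_dose"
    else "below_bottom_dose"
  structure(list(top = top, bottom = bottom, hill = hill, ic50 = ic50,
                 r2 = r2, sse = best$sse,
                 converged = isTRUE(best$fit$info %in% 1:4),
                 crosses_50 = crosses, censored = censored),
            class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf("4PL fit: top=%.3g bottom=%.3g hill=%.3g ic50=%.3g M (r2=%.4f, %s)\n",
              x$top, x$bottom, x$hill, x$ic50, x$r2,
              if (x$crosses_50) "crosses 50%" else paste("censored:", x$censored)))
  invisible(x)
}

#' Default SE-selectivity classification thresholds
#'
#' A response is inactive while more than `inactive_se_floor` percent of SE
#' luciferase remains (60); active responses are general transcriptional
#' inhibition when SE and CMV differ by at most `general_diff_cap` points
#' (30), SE-down-CMV-up when CMV exceeds `cmv_up_threshold` percent (170),
#' and SE-selective otherwise.
#'
#' @param inactive_se_floor,general_diff_cap,cmv_up_threshold thresholds in
#'   percent / percentage points.
#' @return a named list of class `classification_rules`.
#' @export
classification_rules <- function(inactive_se_floor = 60, general_diff_cap = 30,
                                 cmv_up_threshold = 170) {
  stopifnot(inactive_se_floor > 0, general_diff_cap > 0, cmv_up_threshold > 0)
  structure(list(inactive_se_floor = inactive_se_floor,
                 general_diff_cap = general_diff_cap,
                 cmv_up_threshold = cmv_up_threshold),
            class = "classification_rules")
}

# Vectorised per-dose category. Ordered rule: SE above the floor -> inactive;
# else CMV above the up-threshold -> se_down_cmv_up; else a difference within
# the cap -> general_inhibition; else se_selective. The ordering resolves the
# overlap between the "CMV <= 170" and "<= 30 points difference" definitions.
.category_at <- function(se, cmv, rules) {
  out <- rep("se_selective", length(se))
  out[(cmv - se) <= rules$general_diff_cap] <- "general_inhibition"
  out[cmv > rules$cmv_up_threshold] <- "se_down_cmv_up"
  out[se > rules$inactive_se_floor] <- "inactive"
  out
}

#' Classify a compound's SE-vs-CMV dose response
#'
#' Applies the four-category rule per dose, then reduces to a compound-level
#' call at the evaluation dose: the lowest dose at which SE response has
#' dropped to the inactive floor (<= 60%), i.e. the most sensitive
#' informative dose. A compound whose SE response never reaches the floor is
#' inactive.
#'
#' @param se_pct,cmv_pct percent-of-control responses on a shared dose grid.
#' @param doses the shared dose grid (molar).
#' @param rules a `classification_rules` object.
#' @return a list of class `selectivity_call`: `category`,
#'   `evaluation_dose` (molar, NA if inactive), `per_dose` (data.frame of
#'   dose, se, cmv, category), `max_se_selectivity` (points).
#' @export
classify_selectivity <- function(se_pct, cmv_pct, doses,
                                 rules = classification_rules()) {
  if (length(se_pct) != length(cmv_pct) || length(se_pct) != length(doses))
    abort_op("classify_selectivity", "SE, CMV and dose grids must match")
  per_dose <- data.frame(dose_M = doses, se = se_pct, cmv = cmv_pct,
                         category = .category_at(se_pct, cmv_pct, rules),
                         stringsAsFactors = FALSE)
  active <- which(se_pct <= rules$inactive_se_floor)
  if (length(active) == 0L) {
    category <- "inactive"; eval_dose <- NA_real_
  } else {
    i <- active[which.min(doses[active])]
    category <- per_dose$category[i]; eval_dose <- doses[i]
  }
  structure(list(category = category, evaluation_dose = eval_dose,
                 per_dose = per_dose,
                 max_se_selectivity = max(cmv_pct - se_pct)),
            class = "selectivity_call")
}

#' Classify a whole library of dose-response curves at once
#'
#' Matrix form of [classify_selectivity()] for screening-scale inputs: one
#' row per compound, one column per dose.
#'
#' @param se_mat,cmv_mat matrices (compounds x doses) of percent-of-control.
#' @param doses shared dose grid (molar), length `ncol(se_mat)`.
#' @param rules a `classification_rules` object.
#' @return a `data.frame`: `compound_id` (rownames or index), `category`,
#'   `evaluation_dose`, `max_se_selectivity`.
#' @export
classify_library <- function(se_mat, cmv_mat, doses,
                             rules = classification_rules()) {
  if (!all(dim(se_mat) == dim(cmv_mat)) || ncol(se_mat) != length(doses))
    abort_op("classify_library", "SE and CMV matrices and dose grid must match")
  n <- nrow(se_mat)
  active <- se_mat <= rules$inactive_se_floor
  # evaluation dose: lowest dose with SE at/below the floor
  eval_col <- apply(active, 1L, function(a) {
    idx <- which(a)
    if (length(idx) == 0L) NA_integer_ else idx[which.min(doses[idx])]
  })
  category <- rep("inactive", n)
  has <- !is.na(eval_col)
  ij <- cbind(which(has), eval_col[has])
  category[has] <- .category_at(se_mat[ij], cmv_mat[ij], rules)
  data.frame(compound_id = rownames(se_mat) %||% as.character(seq_len(n)),
             category = category,
             evaluation_dose = ifelse(has, doses[eval_col], NA_real_),
             max_se_selectivity = apply(cmv_mat - se_mat, 1L, max),
             stringsAsFactors = FALSE)
}

#' Maximum SE selectivity of a compound
#'
#' The largest CMV-minus-SE gap over the dose grid, in percentage points:
#' the per-compound statistic used to rank-order probes by how much more
#' they suppress SE-driven than promoter-driven transcription.
#'
#' @param se_pct,cmv_pct percent-of-control responses on a shared grid.
#' @return maximum of `cmv_pct - se_pct` (percentage points).
#' @export
max_se_selectivity <- function(se_pct, cmv_pct) {
  if (length(se_pct) != length(cmv_pct))
    abort_op("max_se_selectivity", "curves must share a dose grid")
  max(cmv_pct - se_pct)
}

#' SE-transcription vs viability differential
#'
#' Per-dose difference `viability% - SE%`. Positive values flag doses where
#' SE output is lost before the cells die (the signature of an SE-selective
#' compound such as Vorinostat); a transcriptionally unselective compound
#' shows a flat, near-zero band.
#'
#' @param se_pct,viability_pct percent-of-control responses on a shared grid.
#' @param doses the shared dose grid (molar).
#' @return a `data.frame`: `dose_M`, `differential` (points).
#' @export
se_viability_differential <- function(se_pct, viability_pct, doses) {
  if (length(se_pct) != length(viability_pct) || length(se_pct) != length(doses))
    abort_op("se_viability_differential", "curves must share a dose grid")
  data.frame(dose_M = doses, differential = viability_pct - se_pct)
}
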