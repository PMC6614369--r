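# Synthetic-data generators with planted ground truth for every pipeline
# stage: compound libraries read out on SE-reporter / CMV-reporter /
# viability channels, dose-response plates, confluence growth curves,
# deacetylase progress curves, and a toy epigenome with planted
# super-enhancers and a drug-responsive expression matrix.
#
# Conventions: doses molar, times hours (growth) or minutes (enzyme),
# responses percent-of-control. Noise is multiplicative lognormal with unit
# mean (plate readers are scale-noise dominated); control wells have their
# own planted mean/SD. Every generator is deterministic for a fixed seed.

MECHANISM_CLASSES <- c("inactive", "general_inhibitor", "se_selective",
                       "se_down_cmv_up", "viability_only")

#' Specify a synthetic compound library
#'
#' @param n_compounds library size (>= 1).
#' @param class_proportions named simplex weights over the mechanism classes
#'   `inactive, general_inhibitor, se_selective, se_down_cmv_up,
#'   viability_only` (must sum to 1).
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   well noise (default 0.1).
#' @param seed RNG seed.
#' @param plate_layout list: `rows`, `cols`, `n_neg`, `n_pos` control wells
#'   per plate (default 384-well, 16 negatives + 16 positives on the edge
#'   columns).
#' @param controls list of planted control-well parameters: `neg_mean`,
#'   `neg_sd`, `pos_mean`, `pos_sd` (raw signal units; negative mean 100 so
#'   raw signals read directly as percent).
#' @return a list of class `library_spec`.
#' @export
library_spec <- function(n_compounds,
                         class_proportions = c(inactive = 0.92,
                                               general_inhibitor = 0.03,
                                               se_selective = 0.02,
                                               se_down_cmv_up = 0.01,
                                               viability_only = 0.02),
                         noise_cv = 0.1, seed = 1,
                         plate_layout = list(rows = 16L, cols = 24L,
                                             n_neg = 16L, n_pos = 16L),
                         controls = list(neg_mean = 100, neg_sd = 4,
                                         pos_mean = 5, pos_sd = 2)) {
  if (n_compounds < 1) abort_op("library_spec", "n_compounds must be >= 1")
  if (is.null(names(class_proportions)) ||
      !all(names(class_proportions) %in% MECHANISM_CLASSES))
    abort_op("library_spec", paste("class_proportions must be named from:",
                                   paste(MECHANISM_CLASSES, collapse = ", ")))
  if (any(class_proportions < 0) || abs(sum(class_proportions) - 1) > 1e-9)
    abort_op("library_spec", "class_proportions must be non-negative and sum to 1")
  if (noise_cv < 0) abort_op("library_spec", "noise_cv must be >= 0")
  structure(list(n_compounds = as.integer(n_compounds),
                 class_proportions = class_proportions,
                 noise_cv = noise_cv, seed = as.integer(seed),
                 plate_layout = plate_layout, controls = controls),
            class = "library_spec")
}

#' Simulate a compound library with planted mechanism classes
#'
#' Draws a mechanism class per compound and class-consistent 4PL parameters
#' for the three readout channels (SE reporter, CMV reporter, XTT
#' viability). Column naming: `<ch>_top` is the zero-dose asymptote,
#' `<ch>_bottom` the high-dose asymptote (above `top` for the rising CMV
#' channel of `se_down_cmv_up` compounds). A minority of active compounds
#' are slow-acting (benzamide-like), with `onset_h = 96`; the rest act
#' immediately (`onset_h = 0`).
#'
#' @param spec a `library_spec`.
#' @return a `data.frame` of compound truth, one row per compound.
#' @export
simulate_library <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  set.seed(spec$seed)
  n <- spec$n_compounds
  cls <- sample(names(spec$class_proportions), n, replace = TRUE,
                prob = spec$class_proportions)
  tr <- data.frame(compound_id = sprintf("cmpd%06d", seq_len(n)),
                   mechanism_class = cls, stringsAsFactors = FALSE)
  flat <- function(ch) {
    tr[[paste0(ch, "_top")]] <<- rep(100, n)
    tr[[paste0(ch, "_bottom")]] <<- rep(100, n)
    tr[[paste0(ch, "_hill")]] <<- rep(1, n)
    tr[[paste0(ch, "_ic50")]] <<- rep(1e-3, n)
  }
  flat("se"); flat("cmv"); flat("via")
  tr$onset_h <- rep(0, n)

  gi <- cls == "general_inhibitor"
  if (any(gi)) {
    m <- sum(gi)
    ic <- 10^stats::runif(m, -6.7, -5.7)
    hill <- stats::runif(m, 1.5, 2.5)
    seb <- stats::runif(m, 0, 12)
    tr$se_bottom[gi] <- seb; tr$se_hill[gi] <- hill; tr$se_ic50[gi] <- ic
    tr$cmv_bottom[gi] <- pmax(0, seb + stats::runif(m, -8, 8))
    tr$cmv_hill[gi] <- hill; tr$cmv_ic50[gi] <- ic
    tr$via_bottom[gi] <- stats::runif(m, 0, 20)
    tr$via_hill[gi] <- stats::runif(m, 2, 3); tr$via_ic50[gi] <- ic
  }
  ses <- cls == "se_selective"
  if (any(ses)) {
    m <- sum(ses)
    ic <- 10^stats::runif(m, -7.5, -6)
    tr$se_bottom[ses] <- stats::runif(m, 0, 20)
    tr$se_hill[ses] <- stats::runif(m, 1.5, 2.5); tr$se_ic50[ses] <- ic
    tr$cmv_bottom[ses] <- stats::runif(m, 85, 110)
    tr$cmv_hill[ses] <- rep(1, m); tr$cmv_ic50[ses] <- ic
    tr$via_bottom[ses] <- stats::runif(m, 0, 25)
    tr$via_hill[ses] <- stats::runif(m, 2, 3)
    tr$via_ic50[ses] <- ic * 10^stats::runif(m, 0.7, 1.2)
  }
  sdu <- cls == "se_down_cmv_up"
  if (any(sdu)) {
    m <- sum(sdu)
    ic <- 10^stats::runif(m, -7.5, -6)
    tr$se_bottom[sdu] <- stats::runif(m, 0, 20)
    tr$se_hill[sdu] <- stats::runif(m, 1.5, 2.5); tr$se_ic50[sdu] <- ic
    tr$cmv_bottom[sdu] <- stats::runif(m, 220, 300)
    tr$cmv_hill[sdu] <- stats::runif(m, 1.5, 2.5); tr$cmv_ic50[sdu] <- ic / 3
    tr$via_bottom[sdu] <- stats::runif(m, 0, 25)
    tr$via_hill[sdu] <- stats::runif(m, 2, 3)
    tr$via_ic50[sdu] <- ic * 10^stats::runif(m, 0.7, 1.2)
  }
  vo <- cls == "viability_only"
  if (any(vo)) {
    m <- sum(vo)
    tr$via_bottom[vo] <- stats::runif(m, 0, 20)
    tr$via_hill[vo] <- stats::runif(m, 2, 3)
    tr$via_ic50[vo] <- 10^stats::runif(m, -6.5, -5.5)
  }
  slow <- cls %in% c("general_inhibitor", "se_selective", "se_down_cmv_up") &
    stats::runif(n) < 0.15
  tr$onset_h[slow] <- 96
  tr
}

#' Evaluate a compound's planted response at a dose
#'
#' @param truth compound-truth `data.frame` (one or more rows).
#' @param dose dose in molar (scalar).
#' @param channel one of `"SE_luc"`, `"CMV_luc"`, `"XTT"`.
#' @return planted percent-of-control response, one value per truth row.
#' @export
compound_response <- function(truth, dose, channel) {
  pre <- switch(channel, SE_luc = "se", CMV_luc = "cmv", XTT = "via",
                abort_op("compound_response", paste("unknown channel:", channel)))
  four_pl(dose, truth[[paste0(pre, "_top")]], truth[[paste0(pre, "_bottom")]],
          truth[[paste0(pre, "_hill")]], truth[[paste0(pre, "_ic50")]])
}

# Control wells for one plate: planted Normal means/SDs, truncated at zero
# (signals are non-negative).
.control_signals <- function(n, mean, sd) pmax(0, stats::rnorm(n, mean, sd))

# Lay out one plate: n_neg negatives down the first column, n_pos positives
# down the last column, samples filling the interior columns row-major.
.plate_wells <- function(layout) {
  rows <- layout$rows; cols <- layout$cols
  neg <- data.frame(row = seq_len(layout$n_neg) - 1L, col = 0L,
                    role = "negative_DMSO")
  pos <- data.frame(row = seq_len(layout$n_pos) - 1L, col = cols - 1L,
                    role = "positive_ActD")
  cap <- rows * (cols - 2L)
  smp <- expand.grid(row = seq_len(rows) - 1L, col = seq_len(cols - 2L),
                     KEEP.OUT.ATTRS = FALSE)
  smp$role <- "sample"
  list(neg = neg, pos = pos, sample = smp, capacity = cap)
}

#' Simulate a single control-only QC plate
#'
#' One plate holding only the negative (DMSO) and positive (actinomycin
#' D-like) control wells, drawn from their planted Normal means/SDs
#' (defaults: negatives mean 100, SD 4; positives mean 5, SD 2; 16 wells
#' each) — the input for Z-factor assay QC.
#'
#' @param n_neg,n_pos control well counts.
#' @param neg_mean,neg_sd,pos_mean,pos_sd planted control parameters.
#' @param channel channel label (default `"SE_luc"`).
#' @param plate_id plate label.
#' @return a plate `data.frame`.
#' @export
simulate_control_plate <- function(n_neg = 16, n_pos = 16,
                                   neg_mean = 100, neg_sd = 4,
                                   pos_mean = 5, pos_sd = 2,
                                   channel = "SE_luc", plate_id = "qc_plate") {
  data.frame(plate_id = plate_id,
             row = c(seq_len(n_neg), seq_len(n_pos)) - 1L,
             col = rep(c(0L, 23L), c(n_neg, n_pos)),
             compound_id = "",
             role = rep(c("negative_DMSO", "positive_ActD"), c(n_neg, n_pos)),
             channel = channel, dose_M = 0, time_h = 24,
             signal = c(.control_signals(n_neg, neg_mean, neg_sd),
                        .control_signals(n_pos, pos_mean, pos_sd)),
             stringsAsFactors = FALSE)
}

#' Simulate the single-dose primary screen
#'
#' Reads out every library compound at one dose (default 10 uM, the screen
#' concentration) on the SE-reporter, CMV-reporter and XTT channels, in
#' replicate, at 24 h. Signals are the compound's planted 4PL value times
#' unit-mean lognormal noise (CV = `spec$noise_cv`), scaled so the
#' negative-control mean is the planted `neg_mean`; control wells are drawn
#' from their own planted means/SDs. Each channel x replicate is a separate
#' run of 384-well plates.
#'
#' @param truth compound-truth table from [simulate_library()].
#' @param spec the `library_spec` used to generate it.
#' @param dose screen dose (molar, default `10e-6`).
#' @param replicates number of replicate runs (>= 1, default 2).
#' @param channels channels to read out.
#' @return a plate `data.frame` covering all plates.
#' @export
simulate_primary_screen <- function(truth, spec, dose = 10e-6, replicates = 2,
                                    channels = c("SE_luc", "CMV_luc", "XTT")) {
  stopifnot(inherits(spec, "library_spec"))
  if (replicates < 1) abort_op("simulate_primary_screen", "replicates must be >= 1")
  set.seed(spec$seed + 1L)
  wells <- .plate_wells(spec$plate_layout)
  ctl <- spec$controls
  if (spec$noise_cv == 0) ctl$neg_sd <- ctl$pos_sd <- 0  # zero-noise identity
  n <- nrow(truth)
  n_plates <- ceiling(n / wells$capacity)
  out <- vector("list", length(channels) * replicates * n_plates)
  k <- 0L
  for (ch in channels) {
    pct <- compound_response(truth, dose, ch)
    for (r in seq_len(replicates)) {
      for (p in seq_len(n_plates)) {
        idx <- ((p - 1L) * wells$capacity + 1L):min(p * wells$capacity, n)
        m <- length(idx)
        pid <- sprintf("%s_r%d_p%03d", ch, r, p)
        smp <- wells$sample[seq_len(m), , drop = FALSE]
        plate <- data.frame(
          plate_id = pid,
          row = c(wells$neg$row, wells$pos$row, smp$row),
          col = c(wells$neg$col, wells$pos$col, smp$col),
          compound_id = c(rep("", nrow(wells$neg) + nrow(wells$pos)),
                          truth$compound_id[idx]),
          role = c(wells$neg$role, wells$pos$role, smp$role),
          channel = ch, dose_M = dose, time_h = 24,
          signal = c(.control_signals(nrow(wells$neg), ctl$neg_mean, ctl$neg_sd),
                     .control_signals(nrow(wells$pos), ctl$pos_mean, ctl$pos_sd),
                     pct[idx] / 100 * ctl$neg_mean * lognormal_factor(m, spec$noise_cv)),
          stringsAsFactors = FALSE)
        k <- k + 1L
        out[[k]] <- plate
      }
    }
  }
  do.call(rbind, out)
}

#' Simulate a dose-response plate set for one compound
#'
#' One plate per channel: the dose series in `replicates` wells per dose
#' (quadruplicate by default, matching the confirmation assays) plus
#' control wells. Per-well signal is the planted 4PL value at that dose
#' times lognormal noise.
#'
#' @param truth_row one row of compound truth.
#' @param series a `dose_series` (strictly decreasing doses).
#' @param channels channels to read out.
#' @param replicates wells per dose (default 4).
#' @param noise_cv noise CV (default 0).
#' @param seed RNG seed.
#' @param controls control-well parameters as in [library_spec()].
#' @return a plate `data.frame`.
#' @export
simulate_dose_response <- function(truth_row, series,
                                   channels = c("SE_luc", "CMV_luc"),
                                   replicates = 4, noise_cv = 0, seed = 1,
                                   controls = list(neg_mean = 100, neg_sd = 4,
                                                   pos_mean = 5, pos_sd = 2)) {
  stopifnot(inherits(series, "dose_series"))
  if (any(diff(series$doses) >= 0))
    abort_op("simulate_dose_response", "dose series must be strictly decreasing")
  bad <- setdiff(channels, c("SE_luc", "CMV_luc", "XTT"))
  if (length(bad) > 0L)
    abort_op("simulate_dose_response", paste("unknown channel:", bad[1]))
  if (noise_cv == 0) controls$neg_sd <- controls$pos_sd <- 0  # zero-noise identity
  set.seed(seed)
  out <- vector("list", length(channels))
  for (i in seq_along(channels)) {
    ch <- channels[i]
    doses <- rep(series$doses, each = replicates)
    pct <- vapply(doses, function(d) compound_response(truth_row, d, ch), 0)
    m <- length(doses)
    n_neg <- 16L; n_pos <- 16L
    out[[i]] <- data.frame(
      plate_id = sprintf("%s_%s_dr", truth_row$compound_id, ch),
      row = c(seq_len(n_neg), seq_len(n_pos), seq_len(m) %% 16L) - c(1L, 1L, 0L)[
        rep(1:3, c(n_neg, n_pos, m))],
      col = c(rep(0L, n_neg), rep(23L, n_pos), 1L + (seq_len(m) - 1L) %/% 16L),
      compound_id = c(rep("", n_neg + n_pos), rep(truth_row$compound_id, m)),
      role = rep(c("negative_DMSO", "positive_ActD", "sample"),
                 c(n_neg, n_pos, m)),
      channel = ch,
      dose_M = c(rep(0, n_neg + n_pos), doses),
      time_h = 24,
      signal = c(.control_signals(n_neg, controls$neg_mean, controls$neg_sd),
                 .control_signals(n_pos, controls$pos_mean, controls$pos_sd),
                 pct / 100 * controls$neg_mean * lognormal_factor(m, noise_cv)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate library-scale dose-response matrices
#'
#' Replicate-mean percent-of-control responses for every compound on a
#' shared dose grid: the screening-scale input for the SE-selectivity
#' classifier. Equivalent to averaging `replicates` noisy wells per
#' compound x dose.
#'
#' @param truth compound-truth table.
#' @param series a `dose_series`.
#' @param channel channel to read out.
#' @param replicates wells per dose (default 4).
#' @param noise_cv noise CV.
#' @param seed RNG seed.
#' @return a matrix (compounds x doses) with compound ids as rownames.
#' @export
simulate_response_matrix <- function(truth, series, channel, replicates = 4,
                                     noise_cv = 0.1, seed = 1) {
  stopifnot(inherits(series, "dose_series"))
  set.seed(seed)
  n <- nrow(truth); d <- length(series$doses)
  base <- vapply(series$doses,
                 function(x) compound_response(truth, x, channel),
                 numeric(n))
  base <- matrix(base, nrow = n, ncol = d)
  if (noise_cv > 0) {
    acc <- matrix(0, n, d)
    for (r in seq_len(replicates))
      acc <- acc + base * matrix(lognormal_factor(n * d, noise_cv), n, d)
    base <- acc / replicates
  }
  rownames(base) <- truth$compound_id
  colnames(base) <- signif(series$doses, 4)
  base
}

# Integrated logistic growth exponent for one dose:
#   R(t) = r0 * integral_0^t (1 - I(dose * ramp(s))) ds,
# where ramp(s) = min(1, s/onset) scales the EFFECTIVE DOSE (slow-acting
# compounds develop potency over time, so their apparent IC50 declines
# smoothly) and I(x) is the fractional viability inhibition from the 4PL.
# onset = 0 means full potency immediately (closed form). Trapezoidal
# integration on a 1 h grid otherwise.
.growth_exponent <- function(t, r0, dose, inhib_fun, onset) {
  if (onset <= 0 || dose == 0) return(r0 * (1 - inhib_fun(dose)) * t)
  grid <- seq(0, max(t), by = 1)
  eff <- 1 - inhib_fun(dose * pmin(1, grid / onset))
  cum <- c(0, cumsum((eff[-1] + eff[-length(eff)]) / 2))
  r0 * stats::approx(grid, cum, xout = t)$y
}

#' Simulate confluence-vs-time growth curves under drug
#'
#' Logistic growth of percent confluence toward 100%, with the drug scaling
#' the growth rate by `1 - I(dose)` where `I` is the planted fractional
#' viability inhibition (from the compound's viability 4PL). Slow-acting
#' compounds develop potency over time: the effective dose ramps linearly
#' from 0 to the nominal dose across `onset_h` hours, so the apparent IC50
#' starts high and declines smoothly as the compound takes hold.
#' DMSO wells (dose 0) grow at the full rate. Defaults emulate an
#' Incucyte-style multi-day experiment: 15% seeding confluence, images
#' every 4 h, DMSO crossing 95% confluence near the end of a 7-day window
#' (so slow-onset effects have time to develop before monitoring stops).
#'
#' @param truth_row one row of compound truth (uses `via_*` and `onset_h`).
#' @param series a `dose_series`, or numeric vector of doses (molar).
#' @param timepoints hours, ascending from 0 (default `seq(0, 168, 4)`).
#' @param c0 starting confluence (%).
#' @param r0 unconstrained logistic growth rate (per hour).
#' @param noise_cv multiplicative noise CV on confluence (default 0).
#' @param seed RNG seed.
#' @return a `data.frame`: `compound_id, dose_M, time_h, confluence`
#'   (dose 0 rows are the DMSO controls, compound_id `"DMSO"`).
#' @export
simulate_growth <- function(truth_row, series, timepoints = seq(0, 168, 4),
                            c0 = 15, r0 = 0.033, noise_cv = 0, seed = 1) {
  doses <- if (inherits(series, "dose_series")) series$doses else as.numeric(series)
  if (is.unsorted(timepoints) || any(timepoints < 0))
    abort_op("simulate_growth", "timepoints must be ascending and >= 0")
  set.seed(seed)
  all_doses <- c(0, doses)
  inhib_fun <- function(x) {
    x <- pmax(x, 0)
    via <- four_pl(x, truth_row$via_top, truth_row$via_bottom,
                   truth_row$via_hill, truth_row$via_ic50)
    pmin(1, pmax(0, 1 - via / 100))
  }
  onset <- truth_row$onset_h
  expo_by_dose <- lapply(all_doses, function(d)
    .growth_exponent(timepoints, r0, d, inhib_fun, onset))
  grid <- expand.grid(time_h = timepoints, dose_M = all_doses,
                      KEEP.OUT.ATTRS = FALSE)
  expo <- unlist(expo_by_dose)
  conf <- 100 / (1 + (100 / c0 - 1) * exp(-expo))
  if (noise_cv > 0)
    conf <- pmin(100, conf * lognormal_factor(length(conf), noise_cv))
  data.frame(compound_id = ifelse(grid$dose_M == 0, "DMSO",
                                  truth_row$compound_id),
             dose_M = grid$dose_M, time_h = grid$time_h, confluence = conf,
             stringsAsFactors = FALSE)
}

#' Simulate fluorogenic deacetylase progress curves
#'
#' Coupled-assay traces per HDAC isoform and inhibitor concentration:
#' fluorescence released at initial rate `v0 / (1 + [I]/Ki)` (fractional
#' occupancy of a competitive inhibitor) with an exponential
#' substrate-depletion plateau,
#' `F(t) = baseline + S * (1 - exp(-(v/S) t))`, so early times are linear
#' at rate `v` and late times saturate at `baseline + S`. DMSO traces
#' (conc 0) run at the full rate.
#'
#' Noise has two multiplicative lognormal components reflecting how these
#' assays actually vary: a per-well amplitude factor (`noise_cv`, enzyme
#' load and pipetting — the dominant term, shared by all reads of one
#' trace) and a small independent per-read detector factor
#' (`read_noise_cv`).
#'
#' @param ki named numeric vector: planted Ki (molar) per isoform; `Inf`
#'   means no inhibition.
#' @param inhibitor_concs concentrations (molar, >= 0; 0 rows are DMSO).
#' @param timepoints_min minutes (default every 5 min to 240, the assay read interval).
#' @param v0 uninhibited rate (AFU/min), `baseline` (AFU), `s_tot` total
#'   releasable fluorescence (AFU).
#' @param noise_cv per-well amplitude CV.
#' @param read_noise_cv per-read detector CV (default 0.02 whenever
#'   `noise_cv > 0`, else 0).
#' @param replicates wells per isoform x concentration (default 2, the
#'   assay's duplicate design).
#' @param seed RNG seed.
#' @return a `data.frame`: `isoform, conc_M, well, time_min, signal`.
#' @export
simulate_progress_curves <- function(ki, inhibitor_concs,
                                     timepoints_min = seq(0, 240, 5),
                                     v0 = 50, baseline = 100, s_tot = 9000,
                                     noise_cv = 0,
                                     read_noise_cv = if (noise_cv > 0) 0.02 else 0,
                                     replicates = 2, seed = 1) {
  if (any(ki <= 0)) abort_op("simulate_progress_curves", "Ki must be > 0")
  if (any(inhibitor_concs < 0))
    abort_op("simulate_progress_curves", "concentrations must be >= 0")
  if (replicates < 1) abort_op("simulate_progress_curves", "replicates must be >= 1")
  set.seed(seed)
  grid <- expand.grid(time_min = timepoints_min, well = seq_len(replicates),
                      conc_M = inhibitor_concs, isoform = names(ki),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  kival <- ki[grid$isoform]
  v <- v0 / (1 + grid$conc_M / kival)
  accum <- s_tot * (1 - exp(-(v / s_tot) * grid$time_min))
  n_traces <- replicates * length(inhibitor_concs) * length(ki)
  if (noise_cv > 0) {
    amp <- rep(lognormal_factor(n_traces, noise_cv),
               each = length(timepoints_min))
    accum <- accum * amp
  }
  if (read_noise_cv > 0)
    accum <- accum * lognormal_factor(length(accum), read_noise_cv)
  data.frame(isoform = grid$isoform, conc_M = grid$conc_M,
             well = grid$well, time_min = grid$time_min,
             signal = baseline + accum, stringsAsFactors = FALSE)
}

#' Simulate a toy epigenome with planted super-enhancers
#'
#' Builds TSS coordinates on a jittered grid (guaranteeing inter-gene
#' spacing), plants `n_se` super-enhancer loci 20-40 kb downstream of their
#' host gene's TSS, places a cluster of high-signal peaks for every factor
#' (the anchor HDAC plus the core-regulatory TFs) inside each SE locus, and
#' scatters low-signal background peaks per factor (a fraction of which
#' fail the high-confidence q-value filter). The companion expression
#' matrix carries a planted negative log2 fold-change for SE-associated
#' genes under each drug, near-zero elsewhere. Planted SE signal dominates
#' any stitched background region, producing the hockey-stick rank-signal
#' curve.
#'
#' @param params list overriding any of: `chrom_sizes` (named), `n_genes`,
#'   `n_se`, `peaks_per_se`, `n_background`, `factors`, `se_log2fc`,
#'   `drugs`, `bg_q_fail_frac`.
#' @param seed RNG seed.
#' @return a list of class `synthetic_epigenome`: `chrom_sizes`, `tss`
#'   (data.frame `chrom,pos,strand,gene_id`), `peaks` (named list of BED-like
#'   data.frames `chrom,start,end,name,signal,q_value`), `se_loci`
#'   (data.frame with `gene_id`), `expression` (genes x conditions FPKM
#'   matrix, first column DMSO), `truth` (list: `se_genes`, `cr_tf_set`,
#'   `anchor`).
#' @export
simulate_epigenome <- function(params = list(), seed = 1) {
  p <- utils::modifyList(list(
    chrom_sizes = c(chr1 = 5e7, chr2 = 4e7),
    n_genes = 300L, n_se = 15L, peaks_per_se = 4L, n_background = 300L,
    factors = c("HDAC2", "PAX3FOXO1", "MYOD1", "MYOG", "MYCN", "SOX8"),
    se_log2fc = -2, drugs = c("HDACi_A", "HDACi_B", "HDACi_C"),
    bg_q_fail_frac = 0.3), params)
  if (any(p$chrom_sizes <= 0)) abort_op("simulate_epigenome", "invalid chrom sizes")
  set.seed(seed)

  # TSS on a jittered grid per chromosome: spacing guarantees that a SE
  # planted 20-40 kb downstream of its host TSS has that TSS as nearest.
  sizes <- p$chrom_sizes
  n_per <- pmax(1L, round(p$n_genes * sizes / sum(sizes)))
  tss <- do.call(rbind, lapply(seq_along(sizes), function(i) {
    k <- n_per[i]
    step <- sizes[i] / (k + 1)
    pos <- round(step * seq_len(k) + stats::runif(k, -0.2, 0.2) * step)
    data.frame(chrom = names(sizes)[i], pos = pos,
               strand = sample(c("+", "-"), k, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  tss$gene_id <- sprintf("gene%04d", seq_len(nrow(tss)))
  rownames(tss) <- NULL

  se_genes_idx <- sort(sample(nrow(tss), p$n_se))
  se_width <- round(stats::runif(p$n_se, 15000, 30000))
  se_start <- tss$pos[se_genes_idx] + 20000L
  se_loci <- data.frame(chrom = tss$chrom[se_genes_idx],
                        start = se_start, end = se_start + se_width,
                        name = sprintf("SE%03d", seq_len(p$n_se)),
                        gene_id = tss$gene_id[se_genes_idx],
                        stringsAsFactors = FALSE)

  # Shared SE peak template: CR TFs and the anchor HDAC co-bind the same
  # sites, so the peak coordinates inside each SE locus are drawn once and
  # reused by every factor (signals and q-values are factor-specific).
  # Peaks are spread evenly across the locus (jittered strata) so intra-
  # locus gaps stay below the stitch distance and each planted locus
  # stitches into exactly one region.
  se_template <- do.call(rbind, lapply(seq_len(p$n_se), function(i) {
    k <- p$peaks_per_se
    w <- round(stats::runif(k, 400, 800))
    width_i <- se_loci$end[i] - se_loci$start[i]
    centers <- se_loci$start[i] +
      ((seq_len(k) - 0.5) / k + stats::runif(k, -0.05, 0.05)) * width_i
    s <- round(centers - w / 2)
    data.frame(chrom = se_loci$chrom[i], start = s, end = s + w,
               stringsAsFactors = FALSE)
  }))

  peaks <- stats::setNames(vector("list", length(p$factors)), p$factors)
  for (f in p$factors) {
    kk <- nrow(se_template)
    se_pk <- data.frame(se_template,
                        signal = stats::runif(kk, 40, 80),
                        q_value = 10^-stats::runif(kk, 15, 40),
                        stringsAsFactors = FALSE)
    # dispersed background: one peak per sampled 100 kb cell, jittered
    # within the cell's first 80 kb, so background peaks never stitch
    # together (inter-peak gap always > 12.5 kb)
    m <- p$n_background
    cell <- 1e5
    n_cells <- floor(sizes / cell)
    m_per <- pmax(1L, round(m * n_cells / sum(n_cells)))
    ch <- rep(names(sizes), m_per)
    cells <- unlist(lapply(seq_along(sizes), function(i)
      sample.int(n_cells[i], m_per[i])))
    pos <- round((cells - 1) * cell + stats::runif(length(ch), 0, 8e4))
    bg <- data.frame(chrom = ch, start = pos,
                     end = pos + round(stats::runif(length(ch), 300, 700)),
                     signal = stats::runif(length(ch), 1, 8),
                     q_value = ifelse(stats::runif(length(ch)) < p$bg_q_fail_frac,
                                      10^-stats::runif(length(ch), 3, 8),
                                      10^-stats::runif(length(ch), 10, 15)),
                     stringsAsFactors = FALSE)
    # keep background clear of the planted loci so SE membership is unambiguous
    near_se <- vapply(seq_len(nrow(bg)), function(j) {
      any(bg$chrom[j] == se_loci$chrom &
            bg$end[j] > se_loci$start - 20000 &
            bg$start[j] < se_loci$end + 20000)
    }, TRUE)
    bg <- bg[!near_se, , drop = FALSE]
    pk <- rbind(se_pk, bg)
    pk <- pk[order(pk$chrom, pk$start), , drop = FALSE]
    pk$name <- sprintf("%s_pk%05d", f, seq_len(nrow(pk)))
    rownames(pk) <- NULL
    peaks[[f]] <- pk[, c("chrom", "start", "end", "name", "signal", "q_value")]
  }

  genes <- tss$gene_id
  base <- stats::rlnorm(length(genes), meanlog = log(20), sdlog = 1)
  names(base) <- genes
  expr <- matrix(0, nrow = length(genes), ncol = 1 + length(p$drugs),
                 dimnames = list(genes, c("DMSO", p$drugs)))
  expr[, "DMSO"] <- base
  is_se_gene <- genes %in% se_loci$gene_id
  for (d in p$drugs) {
    lfc <- ifelse(is_se_gene,
                  p$se_log2fc + stats::rnorm(length(genes), 0, 0.2),
                  stats::rnorm(length(genes), 0, 0.3))
    expr[, d] <- base * 2^lfc
  }

  structure(list(chrom_sizes = sizes, tss = tss, peaks = peaks,
                 se_loci = se_loci, expression = expr,
                 truth = list(se_genes = se_loci$gene_id,
                              cr_tf_set = se_loci$gene_id,
                              anchor = p$factors[1])),
            class = "synthetic_epigenome")
}

#' Write a synthetic epigenome to plain-text files
#'
#' Emits per-factor peak BED files, a TSS BED, the expression TSV, a GMT
#' with the planted core-regulatory TF set, and a JSON truth sidecar.
#'
#' @param epi a `synthetic_epigenome`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_epigenome <- function(epi, dir) {
  stopifnot(inherits(epi, "synthetic_epigenome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (f in names(epi$peaks))
    write_bed(epi$peaks[[f]], file.path(dir, paste0(f, "_peaks.bed")))
  tss_bed <- data.frame(chrom = epi$tss$chrom, start = epi$tss$pos,
                        end = epi$tss$pos + 1L, name = epi$tss$gene_id,
                        signal = 0, q_value = 0, stringsAsFactors = FALSE)
  write_bed(tss_bed, file.path(dir, "tss.bed"))
  ex <- data.frame(gene_id = rownames(epi$expression), epi$expression,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(ex, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(list(CR_TF = epi$truth$cr_tf_set), file.path(dir, "gene_sets.gmt"))
  jsonlite::write_json(epi$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
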