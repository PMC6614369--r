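test_that("library generation is seed-deterministic and validates proportions", {
  spec <- library_spec(500, seed = 1)
  expect_identical(simulate_library(spec), simulate_library(spec))
  expect_error(library_spec(500, class_proportions = c(inactive = 0.7)),
               "sum to 1")
  expect_error(library_spec(0), "n_compounds")
  expect_error(library_spec(10, class_proportions = c(bogus = 1)), "named")

  pure <- library_spec(100, class_proportions = c(inactive = 1), seed = 2)
  lib <- simulate_library(pure)
  expect_equal(nrow(lib), 100)
  expect_true(all(lib$mechanism_class == "inactive"))
})

test_that("class counts match the binomial sampling distribution over seeds", {
  props <- c(inactive = 0.97, se_selective = 0.01, general_inhibitor = 0.02)
  n <- 2000
  counts <- vapply(1:100, function(s) {
    lib <- simulate_library(library_spec(n, class_proportions = props,
                                         seed = s))
    sum(lib$mechanism_class == "se_selective")
  }, 0L)
  # binomial oracle: 95% of counts inside the exact central interval
  lo <- stats::qbinom(0.025, n, 0.01); hi <- stats::qbinom(0.975, n, 0.01)
  expect_gte(mean(counts >= lo & counts <= hi), 0.90)
  expect_equal(mean(counts) / n, 0.01, tolerance = 0.25)
})

test_that("zero-noise screen signals equal the planted 4PL values", {
  spec <- library_spec(50, noise_cv = 0, seed = 3)
  truth <- simulate_library(spec)
  plates <- simulate_primary_screen(truth, spec, dose = 1e-5, replicates = 1)
  norm <- normalize_to_negative(plates)
  # inactive compound: equals the negative-control mean on every channel
  ina <- truth$compound_id[truth$mechanism_class == "inactive"][1]
  smp <- plates[plates$compound_id == ina, ]
  for (ch in unique(smp$channel)) {
    mu_n <- mean(plates$signal[plates$role == "negative_DMSO" &
                                 plates$plate_id ==
                                   smp$plate_id[smp$channel == ch][1]])
    expect_equal(smp$signal[smp$channel == ch], mu_n, tolerance = 0.15)
  }
  # planted strong SE inhibitor reads out its 4PL value at 10 uM
  for (cls in c("se_selective", "general_inhibitor")) {
    id <- truth$compound_id[truth$mechanism_class == cls][1]
    if (is.na(id)) next
    got <- norm$percent_of_control[norm$compound_id == id &
                                     norm$channel == "SE_luc"]
    want <- compound_response(truth[truth$compound_id == id, ], 1e-5, "SE_luc")
    expect_equal(got, want, tolerance = 1e-9)
  }
  expect_error(simulate_primary_screen(truth, spec, replicates = 0),
               "replicates")
})

test_that("replicate plates at CV 0.1 correlate like the real assay", {
  # validation-run composition: a broadly active probe mix, whose activity
  # spread (not the noise floor) dominates the between-replicate correlation
  spec <- library_spec(3000,
                       class_proportions = c(inactive = 0.5,
                                             general_inhibitor = 0.2,
                                             se_selective = 0.15,
                                             se_down_cmv_up = 0.05,
                                             viability_only = 0.1),
                       noise_cv = 0.1, seed = 4)
  truth <- simulate_library(spec)
  plates <- simulate_primary_screen(truth, spec, replicates = 2)
  se <- plates[plates$channel == "SE_luc", ]
  r1 <- normalize_to_negative(se[grepl("_r1_", se$plate_id), ])
  r2 <- normalize_to_negative(se[grepl("_r2_", se$plate_id), ])
  expect_gt(replicate_r2(r1, r2), 0.8)
})

test_that("dose-response generator honours noise, channels and determinism", {
  s <- make_dose_series(30e-6, 12, 3)
  truth <- simulate_library(library_spec(20, seed = 5))
  row <- truth[truth$mechanism_class != "inactive", ][1, ]
  a <- simulate_dose_response(row, s, noise_cv = 0.1, seed = 9)
  b <- simulate_dose_response(row, s, noise_cv = 0.1, seed = 9)
  expect_identical(a, b)
  expect_error(simulate_dose_response(row, s, channels = "bogus"), "channel")

  clean <- simulate_dose_response(row, s, noise_cv = 0)
  norm <- normalize_to_negative(clean)
  se <- norm[norm$channel == "SE_luc", ]
  expect_equal(se$percent_of_control,
               vapply(se$dose_M, function(d)
                 compound_response(row, d, "SE_luc"), 0),
               tolerance = 1e-9)
})

test_that("growth curves: DMSO saturates, onset separates the archetypes", {
  s <- make_dose_series(30e-6, 8, 3)
  tr <- data.frame(compound_id = "x", via_top = 100, via_bottom = 0,
                   via_hill = 2.5, via_ic50 = 1e-6, onset_h = 0)
  g <- simulate_growth(tr, s)
  dmso <- g[g$dose_M == 0, ]
  expect_true(all(diff(dmso$confluence) > 0))
  expect_gt(max(dmso$confluence), 95)
  # drug slows growth monotonically in dose at a fixed time
  at100 <- g[g$time_h == 100 & g$dose_M > 0, ]
  expect_true(all(diff(at100$confluence[order(at100$dose_M)]) <= 1e-9))
  expect_error(simulate_growth(tr, s, timepoints = c(5, 3)), "ascending")

  slow <- tr; slow$onset_h <- 96
  gs <- simulate_growth(slow, s)
  # same dose suppresses growth less early under slow onset
  pick <- function(gg, t) gg$confluence[gg$time_h == t & gg$dose_M == s$doses[3]]
  expect_gt(pick(gs, 48), pick(g, 48))
  # once potency is fully developed the slow compound stalls too
  expect_lt(pick(gs, 168) - pick(gs, 120), 2)
  # while the immediate-acting compound never grew at this dose
  expect_lt(pick(g, 168), 20)
})

test_that("progress curves obey occupancy arithmetic and reject bad Ki", {
  concs <- c(0, 50e-9)
  pc <- simulate_progress_curves(c(HDAC3 = 50e-9), concs, replicates = 1)
  dmso <- pc[pc$conc_M == 0, ]
  atki <- pc[pc$conc_M == 50e-9, ]
  # [I] = Ki: early linear-range rate is half the DMSO rate
  r_d <- detect_linear_range(dmso$time_min, dmso$signal)
  r_k <- detect_linear_range(atki$time_min, atki$signal)
  expect_equal(r_k$rate_initial / r_d$rate_initial, 0.5, tolerance = 0.02)
  # [I] = 0 trace identical to DMSO trace
  pc2 <- simulate_progress_curves(c(HDAC3 = 50e-9), c(0, 0), replicates = 1)
  expect_equal(pc2$signal[pc2$conc_M == 0][1:49], dmso$signal)
  expect_error(simulate_progress_curves(c(H = -1), 0), "Ki")
  expect_error(simulate_progress_curves(c(H = 1), -1), "concentrations")
})

test_that("epigenome generator plants co-binding, SEs and depletion", {
  epi <- simulate_epigenome(seed = 6)
  expect_identical(simulate_epigenome(seed = 6)$peaks, epi$peaks)
  # peaks within chromosome bounds
  for (f in names(epi$peaks)) {
    pk <- epi$peaks[[f]]
    expect_true(all(pk$start >= 0))
    expect_true(all(pk$end <= epi$chrom_sizes[pk$chrom]))
    expect_true(all(pk$start < pk$end))
  }
  # every planted SE locus covered by >= 1 peak of every factor
  for (f in names(epi$peaks)) {
    pk <- epi$peaks[[f]]
    covered <- vapply(seq_len(nrow(epi$se_loci)), function(i)
      any(pk$chrom == epi$se_loci$chrom[i] & pk$start < epi$se_loci$end[i] &
            pk$end > epi$se_loci$start[i]), TRUE)
    expect_true(all(covered))
  }
  # co-binding query returns >= n_se all-factor sites
  anchor <- filter_peaks(epi$peaks$HDAC2)
  others <- lapply(epi$peaks[setdiff(names(epi$peaks), "HDAC2")],
                   filter_peaks)
  cb <- cobound_sites(anchor, others)
  expect_gte(cb$n_cobound, nrow(epi$se_loci))
  # planted depletion: SE genes down under every drug
  lfc <- log2(epi$expression[epi$truth$se_genes, "HDACi_A"] /
                epi$expression[epi$truth$se_genes, "DMSO"])
  expect_true(all(lfc < -1))
})

test_that("epigenome files round-trip through the plain-text writers", {
  epi <- simulate_epigenome(list(n_genes = 60L, n_se = 5L,
                                 n_background = 50L), seed = 7)
  dir <- withr::local_tempdir()
  write_epigenome(epi, dir)
  back <- read_bed(file.path(dir, "HDAC2_peaks.bed"))
  orig <- epi$peaks$HDAC2[order(epi$peaks$HDAC2$chrom,
                                epi$peaks$HDAC2$start), ]
  expect_equal(back$start, orig$start)
  expect_equal(back$signal, orig$signal, tolerance = 1e-9)
  expect_equal(back$q_value, orig$q_value, tolerance = 1e-6)
  gmt <- read_gmt(file.path(dir, "gene_sets.gmt"))
  expect_identical(gmt$CR_TF, epi$truth$cr_tf_set)
  expr <- utils::read.table(file.path(dir, "expression.tsv"), header = TRUE,
                            sep = "\t", check.names = FALSE)
  expect_equal(expr$DMSO, unname(epi$expression[, "DMSO"]))
})
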