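# Fixture builders and independent brute-force oracles used across tests.

# A minimal one-plate table: controls plus explicit sample signals.
make_test_plate <- function(samples = c(a = 50, b = 100, c = 0),
                            negs = c(90, 110), poss = c(5, 5),
                            channel = "SE_luc", plate_id = "p1") {
  n <- length(samples); nn <- length(negs); np <- length(poss)
  data.frame(
    plate_id = plate_id,
    row = seq_len(n + nn + np) - 1L, col = 0L,
    compound_id = c(names(samples), rep("", nn + np)),
    role = rep(c("sample", "negative_DMSO", "positive_ActD"), c(n, nn, np)),
    channel = channel, dose_M = 1e-5, time_h = 24,
    signal = c(unname(samples), negs, poss),
    stringsAsFactors = FALSE)
}

random_peaks <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e6,
                         width_range = c(100, 5000)) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(max_pos, n, replace = TRUE)
  w <- sample(seq(width_range[1], width_range[2]), n, replace = TRUE)
  df <- data.frame(chrom = chrom, start = start, end = start + w,
                   name = sprintf("pk%04d", seq_len(n)),
                   signal = round(stats::runif(n, 0.5, 20), 3),
                   q_value = 10^-stats::runif(n, 2, 20),
                   stringsAsFactors = FALSE)
  df[order(df$chrom, df$start), ]
}

random_tss <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e6) {
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             pos = sample.int(max_pos, n, replace = TRUE),
             gene_id = sprintf("g%04d", seq_len(n)),
             stringsAsFactors = FALSE)
}

# O(n^2) pairwise-merge stitching oracle
bf_stitch <- function(peaks, distance) {
  out <- list()
  for (ch in unique(peaks$chrom)) {
    sub <- peaks[peaks$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    groups <- list(1L)
    for (i in seq_len(nrow(sub))[-1]) {
      cur <- groups[[length(groups)]]
      gap <- sub$start[i] - max(sub$end[cur])
      if (gap <= distance) groups[[length(groups)]] <- c(cur, i)
      else groups[[length(groups) + 1L]] <- i
    }
    for (g in groups)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = min(sub$start[g]), end = max(sub$end[g]),
        signal = sum(sub$signal[g]), n_peaks = length(g),
        stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

bf_overlaps_any <- function(a_row, peaks) {
  any(peaks$chrom == a_row$chrom &
        peaks$start < a_row$end & peaks$end > a_row$start)
}

bf_occupancy <- function(container, peaks) {
  hit <- vapply(seq_len(nrow(container)), function(i)
    bf_overlaps_any(container[i, ], peaks), TRUE)
  100 * mean(hit)
}

bf_nearest_tss <- function(peaks, tss) {
  vapply(seq_len(nrow(peaks)), function(i) {
    mid <- (peaks$start[i] + peaks$end[i]) / 2
    cand <- tss[tss$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(cand) == 0L) return(NA_character_)
    d <- abs(mid - cand$pos)
    cand <- cand[d == min(d), , drop = FALSE]
    cand <- cand[order(cand$pos, cand$gene_id), , drop = FALSE]
    cand$gene_id[1]
  }, "")
}

bf_min_tss_dist <- function(peaks, tss) {
  vapply(seq_len(nrow(peaks)), function(i) {
    mid <- (peaks$start[i] + peaks$end[i]) / 2
    cand <- tss[tss$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(cand) == 0L) return(Inf)
    min(abs(mid - cand$pos))
  }, 0)
}

bf_cobound <- function(anchor, sets) {
  vapply(seq_len(nrow(anchor)), function(i)
    all(vapply(sets, function(s) bf_overlaps_any(anchor[i, ], s), TRUE)),
    TRUE)
}

# exhaustive running-sum walk for the enrichment score
bf_gsea_es <- function(scores, is_hit, p = 1) {
  nr <- sum(abs(scores[is_hit])^p)
  run <- 0; best <- 0
  for (i in seq_along(scores)) {
    run <- run + if (is_hit[i]) abs(scores[i])^p / nr else -1 / sum(!is_hit)
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# the standard planted isoform Ki table (molar): HDAC3-selective compound
planted_ki <- function() {
  c(HDAC1 = 1600e-9, HDAC2 = 1600e-9, HDAC3 = 50e-9,
    HDAC4 = 1, HDAC5 = 1, HDAC6 = 1, HDAC7 = 1, HDAC8 = 1, HDAC9 = 1)
}

expected_category <- function(mechanism_class) {
  ifelse(mechanism_class == "general_inhibitor", "general_inhibition",
         ifelse(mechanism_class == "viability_only", "inactive",
                mechanism_class))
}
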