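test_that("BED round-trips, sorts, and rejects invalid intervals", {
  set.seed(1)
  pk <- random_peaks(25)
  shuffled <- pk[sample.int(nrow(pk)), ]
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(shuffled, path)
  back <- read_bed(path)
  expect_equal(back$start, pk$start)
  expect_equal(back$chrom, pk$chrom)
  expect_equal(back$signal, pk$signal, tolerance = 1e-9)
  expect_equal(back$q_value, pk$q_value, tolerance = 1e-6)

  bad <- pk; bad$end[3] <- bad$start[3]
  expect_error(write_bed(bad, path), "invalid interval")
  writeLines("chr1\t100\t50\tx\t1\t.\t0.1", path)
  expect_error(read_bed(path), "start >= end at line")
})

test_that("peak filter is strict at the q-value boundary", {
  pk <- random_peaks(10)
  pk$q_value <- c(1, 1e-9, 1e-10, rep(0.5, 7))
  kept <- filter_peaks(pk, genomics_config())
  expect_identical(kept$name, pk$name[3])  # exactly 1e-9 excluded
  expect_equal(nrow(filter_peaks(transform(pk, q_value = 1))), 0)
  pk$q_value <- NULL
  expect_error(filter_peaks(pk), "q_value")
  # count agrees with a brute-force filter on a random instance
  set.seed(2)
  rp <- random_peaks(200)
  expect_equal(nrow(filter_peaks(rp)), sum(rp$q_value < 1e-9))
})

test_that("stitching merges gaps up to the distance and matches brute force", {
  pk <- data.frame(chrom = "chr1",
                   start = c(0L, 10300L, 40000L),
                   end = c(500L, 11000L, 41000L),
                   name = c("a", "b", "c"), signal = c(1, 2, 4),
                   q_value = 1e-12)
  st <- stitch(pk, 12500)  # gap a-b = 9800 <= 12500 merged; b-c = 29000 not
  expect_equal(nrow(st), 2)
  expect_equal(st$signal, c(3, 4))
  expect_equal(st$n_peaks, c(2L, 1L))

  just_over <- pk; just_over$start[2] <- 500L + 12501L; just_over$end[2] <- 14000L
  expect_equal(nrow(stitch(just_over, 12500)), 3)
  just_at <- pk; just_at$start[2] <- 500L + 12500L; just_at$end[2] <- 14000L
  expect_equal(nrow(stitch(just_at, 12500)), 2)

  set.seed(3)
  for (i in 1:5) {
    rp <- random_peaks(200, max_pos = 3e5)
    got <- stitch(rp, 12500)
    want <- bf_stitch(rp, 12500)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$signal, want$signal)
    expect_equal(got$n_peaks, want$n_peaks)
  }
})

test_that("stitch is idempotent", {
  set.seed(4)
  rp <- random_peaks(150, max_pos = 4e5)
  once <- stitch(rp, 12500)
  twice <- stitch(once, 12500)
  # regions and summed signal unchanged (constituent counts reset by design:
  # re-stitching sees regions, not the original peaks)
  keep <- c("chrom", "start", "end", "signal")
  expect_equal(twice[keep], once[keep])
})

test_that("super-enhancer calling finds the hockey-stick elbow", {
  st <- data.frame(chrom = "chr1", start = (0:4) * 100000L,
                   end = (0:4) * 100000L + 1000L,
                   name = paste0("r", 1:5),
                   signal = c(1, 1, 1, 1, 100), n_peaks = 1L)
  se <- call_superenhancers(st)
  expect_identical(se$is_SE, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(attr(se, "cutoff_signal"), 1)
  expect_false(attr(se, "degenerate"))
  expect_equal(se$rank[5], 1L)

  # relabeling region names never changes calls
  relabeled <- st; relabeled$name <- paste0("zz", 5:1)
  expect_identical(call_superenhancers(relabeled)$is_SE, se$is_SE)

  flat <- st; flat$signal <- 7
  se0 <- call_superenhancers(flat)
  expect_true(attr(se0, "degenerate"))
  expect_false(any(se0$is_SE))
  expect_error(call_superenhancers(st[1:2, ]), "3 stitched")
})

test_that("SE caller recovers exactly the planted loci from the epigenome", {
  for (seed in c(2, 9)) {
    epi <- simulate_epigenome(seed = seed)
    se <- call_superenhancers(stitch(filter_peaks(epi$peaks$HDAC2), 12500))
    called <- se[se$is_SE, ]
    expect_equal(nrow(called), nrow(epi$se_loci))
    hit <- vapply(seq_len(nrow(epi$se_loci)), function(i)
      any(called$chrom == epi$se_loci$chrom[i] &
            called$start < epi$se_loci$end[i] &
            called$end > epi$se_loci$start[i]), TRUE)
    expect_true(all(hit))
  }
})

test_that("occupancy and distal fractions match brute-force oracles", {
  set.seed(5)
  container <- random_peaks(40, width_range = c(5000, 20000))
  peaks <- random_peaks(60)
  expect_equal(occupancy_fraction(container, peaks),
               bf_occupancy(container, peaks))
  expect_equal(occupancy_fraction(container, container), 100)
  far <- container; far$chrom <- "chrX"
  expect_equal(occupancy_fraction(container, far), 0)
  expect_true(is.na(occupancy_fraction(container[0, ], peaks)))

  tss <- random_tss(30)
  df <- distal_fraction(peaks, tss)
  expect_equal(df$fraction_distal,
               100 * mean(bf_min_tss_dist(peaks, tss) > 5000))
  # midpoint at a TSS: proximal; 5001 bp away from the only TSS: distal
  one_tss <- data.frame(chrom = "chr1", pos = 50000L, gene_id = "g1")
  at <- data.frame(chrom = "chr1", start = 49950L, end = 50050L,
                   name = "p", signal = 1, q_value = 0)
  away <- data.frame(chrom = "chr1", start = 55001L - 50L, end = 55001L + 50L,
                     name = "p", signal = 1, q_value = 0)
  expect_false(distal_fraction(at, one_tss)$annotation$distal)
  expect_true(distal_fraction(away, one_tss)$annotation$distal)
})

test_that("occupancy is invariant to relabeling and permutation", {
  set.seed(6)
  container <- random_peaks(30, width_range = c(2000, 10000))
  peaks <- random_peaks(50)
  base <- occupancy_fraction(container, peaks)
  perm <- occupancy_fraction(container[sample.int(30), ],
                             peaks[sample.int(50), ])
  expect_equal(perm, base)
  relab <- function(df) { df$chrom <- paste0("X", df$chrom); df }
  expect_equal(occupancy_fraction(relab(container), relab(peaks)), base)
})

test_that("co-binding matches brute-force membership enumeration", {
  set.seed(7)
  anchor <- random_peaks(50)
  sets <- list(A = random_peaks(40), B = random_peaks(40),
               C = random_peaks(40))
  cb <- cobound_sites(anchor, sets)
  want <- bf_cobound(anchor, sets)
  expect_equal(cb$n_cobound, sum(want))
  expect_equal(cb$cobound$name, anchor$name[want])
  # Venn region counts vs brute-force patterns
  pats <- vapply(seq_len(nrow(anchor)), function(i)
    paste(as.integer(vapply(sets, function(s)
      bf_overlaps_any(anchor[i, ], s), TRUE)), collapse = ""), "")
  expect_equal(unname(cb$venn["111"]), sum(pats == "111"))
  expect_equal(unname(cb$venn["000"]), sum(pats == "000"))
  expect_equal(sum(cb$venn), nrow(anchor))

  # k = 1 with the anchor itself: everything co-bound; disjoint set: zero
  expect_equal(cobound_sites(anchor, list(self = anchor))$n_cobound,
               nrow(anchor))
  off <- anchor; off$chrom <- "chrZ"
  expect_equal(cobound_sites(anchor, list(off = off))$n_cobound, 0)
})

test_that("nearest-gene association matches brute force with deterministic ties", {
  set.seed(8)
  peaks <- random_peaks(80)
  tss <- random_tss(25)
  got <- associate_genes(peaks, tss)
  expect_identical(got$gene_id, bf_nearest_tss(peaks, tss))
  # single gene: everything assigned to it
  one <- data.frame(chrom = c("chr1", "chr2"), pos = c(1L, 1L),
                    gene_id = c("only1", "only2"))
  expect_true(all(associate_genes(peaks, one)$gene_id ==
                    ifelse(peaks$chrom == "chr1", "only1", "only2")))
  # equidistant pair: lower coordinate wins
  pair <- data.frame(chrom = "chr1", pos = c(900L, 1100L),
                     gene_id = c("hi", "lo"))
  pk <- data.frame(chrom = "chr1", start = 950L, end = 1050L, name = "p",
                   signal = 1, q_value = 0)
  expect_identical(associate_genes(pk, pair)$gene_id, "hi")
})

test_that("expression ranking computes log2FC and delta-FPKM scores", {
  ct <- c(g1 = 1, g2 = 10, g3 = 100)
  tr <- c(g1 = 3, g2 = 10, g3 = 20)
  rk <- log2fc_rank(tr, ct)
  expect_equal(rk$score[rk$gene_id == "g1"], 1)       # log2(4/2)
  expect_equal(rk$score[rk$gene_id == "g2"], 0)
  expect_true(all(diff(rk$score) <= 0))
  expect_error(log2fc_rank(c(g1 = -1), c(g1 = 1)), "negative")
  # identical expression: all zeros; input order irrelevant
  same <- log2fc_rank(ct, ct[c(3, 1, 2)])
  expect_true(all(same$score == 0))
  expect_identical(same$gene_id, sort(names(ct)))     # tie-break by id

  mat <- cbind(d1 = c(g1 = 5, g2 = 1), d2 = c(g1 = 7, g2 = 3))
  dk <- delta_fpkm_rank(mat, c(g1 = 1, g2 = 2))
  expect_equal(dk$score[dk$gene_id == "g1"], mean(c(4, 6)))
  expect_equal(dk$score[dk$gene_id == "g2"], 0)
})

test_that("Welch test agrees with the closed-form arithmetic", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  w <- welch_test(a, b)
  # hand formulas: se^2 = 1/3 + 1/3, t = -1/sqrt(2/3), Satterthwaite df = 4
  se2 <- stats::var(a) / 3 + stats::var(b) / 3
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((stats::var(a) / 3)^2 / 2 + (stats::var(b) / 3)^2 / 2)
  expect_equal(w$t, t_hand)
  expect_equal(w$df, df_hand)
  expect_equal(w$p, 2 * stats::pt(t_hand, df_hand))

  # identical groups: t = 0, p = 1; swapping flips the sign only
  wi <- welch_test(a, a)
  expect_equal(wi$t, 0); expect_equal(wi$p, 1)
  ws <- welch_test(b, a)
  expect_equal(ws$t, -w$t); expect_equal(ws$p, w$p)

  # degenerate variance in both groups
  expect_equal(welch_test(c(1, 1), c(1, 1))$p, 1)
  expect_equal(welch_test(c(1, 1), c(2, 2))$p, 0)
  expect_error(welch_test(1, c(1, 2)), "n >= 2")
})

test_that("enrichment score matches the exhaustive running-sum walk", {
  set.seed(9)
  N <- 200
  ranked <- data.frame(gene_id = sprintf("g%03d", 1:N),
                       score = sort(stats::rnorm(N), decreasing = TRUE))
  # top-k set with equal weights: ES = 1 (all increments before any miss)
  eq <- ranked; eq$score <- rep(2, N)
  k <- 15
  es_top <- gsea(eq, eq$gene_id[1:k], n_permutations = 10)$es
  expect_equal(es_top, bf_gsea_es(eq$score, seq_len(N) <= k))
  expect_equal(es_top, 1)

  # random sets vs the brute-force walk
  for (i in 1:10) {
    gs <- sample(ranked$gene_id, 20)
    expect_equal(gsea(ranked, gs, n_permutations = 5)$es,
                 bf_gsea_es(ranked$score, ranked$gene_id %in% gs))
  }

  # whole-universe set: undefined sentinel
  whole <- gsea(ranked, ranked$gene_id, n_permutations = 5)
  expect_true(is.na(whole$es))
})

test_that("ES is bounded and flips sign under score negation", {
  set.seed(10)
  N <- 300
  ranked <- data.frame(gene_id = sprintf("g%03d", 1:N),
                       score = sort(stats::rnorm(N), decreasing = TRUE))
  for (i in 1:10) {
    gs <- sample(ranked$gene_id, sample(5:40, 1))
    r <- gsea(ranked, gs, n_permutations = 5)
    expect_lte(abs(r$es), 1)
    neg <- data.frame(gene_id = ranked$gene_id, score = -ranked$score)
    neg <- neg[order(-neg$score, neg$gene_id), ]
    rn <- gsea(neg, gs, n_permutations = 5)
    expect_equal(rn$es, -r$es, tolerance = 1e-12)
  }
})

test_that("enrichment agrees with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(11)
  N <- 500
  scores <- sort(stats::rnorm(N), decreasing = TRUE)
  ranked <- data.frame(gene_id = sprintf("g%03d", 1:N), score = scores)
  gs <- sample(ranked$gene_id, 30)
  ours <- gsea(ranked, gs, n_permutations = 100)$es
  stats_vec <- stats::setNames(ranked$score, ranked$gene_id)
  theirs <- suppressWarnings(
    fgsea::fgsea(list(set = gs), stats_vec, nPermSimple = 100))$ES
  expect_equal(ours, theirs, tolerance = 1e-6)
})

test_that("three-set overlap counts match a brute-force membership table", {
  sets <- list(A = c("x", "y", "z"), B = c("y", "z", "w"), C = c("z", "q"))
  ov <- set_overlap(sets)
  expect_equal(unname(ov["A_B_C"]), 1L)   # z
  expect_equal(unname(ov["A_B"]), 1L)     # y
  expect_equal(unname(ov["A_only"]), 1L)  # x
  expect_equal(unname(ov["C_only"]), 1L)  # q
  expect_equal(sum(ov), 5L)

  same <- set_overlap(list(A = c("a", "b"), B = c("a", "b"), C = c("a", "b")))
  expect_equal(unname(same["A_B_C"]), 2L)
  expect_equal(sum(same), 2L)
  disj <- set_overlap(list(A = "a", B = "b", C = "c"))
  expect_equal(unname(disj["A_B_C"]), 0L)
  expect_equal(sum(disj == 1L), 3L)

  set.seed(12)
  u <- sprintf("m%03d", 1:100)
  rs <- list(A = sample(u, 40), B = sample(u, 40), C = sample(u, 40))
  ov <- set_overlap(rs)
  mem <- cbind(A = u %in% rs$A, B = u %in% rs$B, C = u %in% rs$C)
  expect_equal(unname(ov["A_B_C"]), sum(rowSums(mem) == 3))
  expect_equal(unname(ov["A_only"]), sum(mem[, 1] & !mem[, 2] & !mem[, 3]))
})
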