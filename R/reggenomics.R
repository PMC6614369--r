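# Interval-level regulatory genomics: peak filtering, enhancer stitching and
# super-enhancer calling, occupancy / co-binding / distal statistics, gene
# association, expression ranking, Welch test, and GSEA-style enrichment.
#
# Intervals follow the BED convention everywhere: 0-based, half-open
# [start, end). A peak table is a data.frame with columns
# chrom, start, end, name, signal, q_value. Distances are between interval
# midpoints; strand is ignored (TSS positions are already strand-resolved).

#' Default regulatory-genomics thresholds
#'
#' `peak_q_max` (1e-9): the high-confidence peak filter, strict.
#' `distal_min_distance` (5,000 bp): a peak is distal when its midpoint is
#' farther than this from every TSS. `stitch_distance` (12,500 bp): peaks
#' closer than this are merged into one enhancer region.
#'
#' @param peak_q_max,distal_min_distance,stitch_distance thresholds.
#' @return a named list of class `genomics_config`.
#' @export
genomics_config <- function(peak_q_max = 1e-9, distal_min_distance = 5000,
                            stitch_distance = 12500) {
  stopifnot(peak_q_max > 0, distal_min_distance > 0, stitch_distance > 0)
  structure(list(peak_q_max = peak_q_max,
                 distal_min_distance = distal_min_distance,
                 stitch_distance = stitch_distance),
            class = "genomics_config")
}

.as_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

.validate_intervals <- function(df, op) {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df)))
    abort_op(op, "interval table needs chrom, start, end columns")
  bad <- which(df$start >= df$end | df$start < 0)
  if (length(bad) > 0L)
    abort_op(op, paste("invalid interval (start >= end or start < 0) at row(s):",
                       paste(bad, collapse = ", ")))
  invisible(df)
}

#' Read a BED file of peaks
#'
#' BED3+ dialect with signal in column 5 and q-value in column 7
#' (`chrom start end name signal strand q_value`), tab-separated, 0-based
#' half-open. Missing trailing columns default to `name = bed_<i>`,
#' `signal = 0`, `q_value = NA`. Output is sorted by (chrom, start).
#'
#' @param path path to the BED file.
#' @return a peak `data.frame`: `chrom, start, end, name, signal, q_value`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort_op("read_bed", paste("no such file:", path))
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = paste0("V", 1:7), fill = TRUE)
  df <- data.frame(chrom = raw$V1, start = as.integer(raw$V2),
                   end = as.integer(raw$V3),
                   name = if (all(is.na(raw$V4)) || all(raw$V4 == ""))
                     sprintf("bed_%d", seq_len(nrow(raw))) else raw$V4,
                   signal = ifelse(is.na(suppressWarnings(as.numeric(raw$V5))),
                                   0, suppressWarnings(as.numeric(raw$V5))),
                   q_value = suppressWarnings(as.numeric(raw$V7)),
                   stringsAsFactors = FALSE)
  bad <- which(df$start >= df$end | df$start < 0)
  if (length(bad) > 0L)
    abort_op("read_bed", paste("start >= end at line(s):",
                               paste(bad, collapse = ", ")))
  df[order(df$chrom, df$start), , drop = FALSE]
}

#' Write peaks as BED
#'
#' Inverse of [read_bed()]: columns
#' `chrom start end name signal strand q_value` (strand written as `.`),
#' sorted by (chrom, start).
#'
#' @param peaks a peak `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  .validate_intervals(peaks, "write_bed")
  df <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
  out <- data.frame(df$chrom, df$start, df$end,
                    df$name %||% sprintf("bed_%d", seq_len(nrow(df))),
                    df$signal %||% 0, ".",
                    df$q_value %||% NA_real_)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from GMT
#'
#' @param path path to a GMT file (name, description, then member genes,
#'   tab-separated).
#' @return a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[`, "", 1L))
}

#' Filter peaks to high confidence
#'
#' Keeps peaks with `q_value` strictly below `config$peak_q_max`
#' (default 1e-9); a peak at exactly the bound is excluded.
#'
#' @param peaks a peak `data.frame` with a `q_value` column.
#' @param config a `genomics_config`.
#' @return the filtered peak `data.frame`.
#' @export
filter_peaks <- function(peaks, config = genomics_config()) {
  if (!"q_value" %in% names(peaks) || anyNA(peaks$q_value))
    abort_op("filter_peaks", "peaks must carry q_value")
  peaks[peaks$q_value < config$peak_q_max, , drop = FALSE]
}

#' Stitch peaks into enhancer regions
#'
#' Merges same-chromosome peaks whose inter-peak gap is at most `distance`
#' bp (default 12,500) into disjoint regions, carrying the summed signal
#' and constituent peak count.
#'
#' @param peaks a peak `data.frame`.
#' @param distance stitching distance in bp.
#' @return a `data.frame`: `chrom, start, end, name, signal, n_peaks`,
#'   sorted by (chrom, start).
#' @export
stitch <- function(peaks, distance = 12500) {
  .validate_intervals(peaks, "stitch")
  if (nrow(peaks) == 0L)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), signal = numeric(),
                      n_peaks = integer(), stringsAsFactors = FALSE))
  gr <- .as_gr(peaks)
  red <- GenomicRanges::reduce(gr, min.gapwidth = distance + 1L)
  hits <- GenomicRanges::findOverlaps(gr, red)
  sig <- peaks$signal %||% rep(0, nrow(peaks))
  sums <- tapply(sig[S4Vectors::queryHits(hits)],
                 S4Vectors::subjectHits(hits), sum)
  counts <- tapply(S4Vectors::queryHits(hits),
                   S4Vectors::subjectHits(hits), length)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                    start = GenomicRanges::start(red) - 1L,
                    end = GenomicRanges::end(red),
                    signal = as.numeric(sums[as.character(seq_along(red))]),
                    n_peaks = as.integer(counts[as.character(seq_along(red))]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$name <- sprintf("region_%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "name", "signal", "n_peaks")]
}

#' Call super-enhancers from stitched regions
#'
#' Ranks stitched regions by summed signal ascending, scales both rank and
#' signal to [0, 1], and finds the point where the rank-signal curve's
#' tangent has slope 1 (equivalently, the point farthest below the y = x
#' diagonal). Regions with signal strictly above the cutoff signal are
#' super-enhancers — the upper tail of the hockey stick. With all-equal
#' signals the geometry is degenerate: zero SEs, flagged.
#'
#' @param stitched a stitched-region `data.frame` (from [stitch()]).
#' @return the input with `rank` (descending by signal, 1 = strongest) and
#'   `is_SE` columns; attributes `cutoff_signal` and `degenerate`.
#' @export
call_superenhancers <- function(stitched) {
  n <- nrow(stitched)
  if (n < 3L) abort_op("call_superenhancers", "need >= 3 stitched regions")
  sig <- stitched$signal
  out <- stitched
  out$rank <- as.integer(rank(-sig, ties.method = "first"))
  if (max(sig) == min(sig)) {
    out$is_SE <- FALSE
    attr(out, "cutoff_signal") <- NA_real_
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  ord <- order(sig)  # ascending
  y <- (sig[ord] - min(sig)) / (max(sig) - min(sig))
  x <- (seq_len(n) - 1) / (n - 1)
  cut_idx <- which.max(x - y)
  cutoff <- sig[ord][cut_idx]
  out$is_SE <- sig > cutoff
  attr(out, "cutoff_signal") <- cutoff
  attr(out, "degenerate") <- FALSE
  out
}

#' Fraction of container regions bound by any peak
#'
#' Percent of `container` intervals overlapping at least 1 bp of any
#' interval in `peaks` — e.g. the share of super-enhancers occupied by a
#' factor's high-confidence peaks.
#'
#' @param container,peaks interval `data.frame`s.
#' @return percent (0-100), or `NA` if `container` is empty.
#' @export
occupancy_fraction <- function(container, peaks) {
  .validate_intervals(container, "occupancy_fraction")
  if (nrow(container) == 0L) return(NA_real_)
  if (nrow(peaks) == 0L) return(0)
  .validate_intervals(peaks, "occupancy_fraction")
  # no shared chromosomes simply means zero overlap, not a warning
  n_hit <- sum(suppressWarnings(
    GenomicRanges::countOverlaps(.as_gr(container), .as_gr(peaks))) > 0)
  100 * n_hit / nrow(container)
}

.midpoint <- function(df) (df$start + df$end) / 2

# distance from each peak midpoint to the nearest TSS position
.nearest_tss_dist <- function(peaks, tss) {
  mids <- .midpoint(peaks)
  dist <- rep(Inf, nrow(peaks))
  idx <- rep(NA_integer_, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    ti <- which(tss$chrom == ch)
    if (length(ti) == 0L) next
    d <- abs(outer(mids[pi], tss$pos[ti], "-"))
    j <- apply(d, 1L, function(r) {
      cand <- which(r == min(r))
      if (length(cand) > 1L) {  # tie-break: lower coordinate, then gene id
        ordc <- cand[order(tss$pos[ti][cand], tss$gene_id[ti][cand])]
        ordc[1]
      } else cand
    })
    dist[pi] <- d[cbind(seq_along(pi), j)]
    idx[pi] <- ti[j]
  }
  list(dist = dist, tss_idx = idx)
}

#' Fraction of peaks distal to all TSSs
#'
#' A peak is distal when its midpoint is more than
#' `config$distal_min_distance` bp (default 5,000) from every TSS.
#'
#' @param peaks a peak `data.frame`.
#' @param tss a TSS `data.frame`: `chrom, pos, gene_id`.
#' @param config a `genomics_config`.
#' @return a list: `fraction_distal` (percent), `annotation` (data.frame
#'   `name, distance, distal`).
#' @export
distal_fraction <- function(peaks, tss, config = genomics_config()) {
  if (nrow(tss) == 0L) abort_op("distal_fraction", "TSS list is empty")
  nt <- .nearest_tss_dist(peaks, tss)
  distal <- nt$dist > config$distal_min_distance
  list(fraction_distal = 100 * mean(distal),
       annotation = data.frame(name = peaks$name %||%
                                 sprintf("peak_%d", seq_len(nrow(peaks))),
                               distance = nt$dist, distal = distal,
                               stringsAsFactors = FALSE))
}

#' Anchor sites co-bound by every factor
#'
#' Returns the anchor peaks overlapping at least one peak from each of the
#' `k` factor peak sets, and — for `k <= 3` — the full Venn region counts
#' of anchor membership across factors.
#'
#' @param anchor_peaks anchor peak `data.frame`.
#' @param factor_peak_sets named list of peak `data.frame`s.
#' @return a list: `cobound` (the co-bound anchor rows), `n_cobound`,
#'   `membership` (logical matrix anchors x factors), `venn` (named counts,
#'   `k <= 3` only).
#' @export
cobound_sites <- function(anchor_peaks, factor_peak_sets) {
  k <- length(factor_peak_sets)
  if (k < 1L) abort_op("cobound_sites", "need >= 1 factor set")
  .validate_intervals(anchor_peaks, "cobound_sites")
  agr <- .as_gr(anchor_peaks)
  membership <- vapply(factor_peak_sets, function(fp) {
    if (nrow(fp) == 0L) return(rep(FALSE, nrow(anchor_peaks)))
    suppressWarnings(GenomicRanges::countOverlaps(agr, .as_gr(fp))) > 0
  }, logical(nrow(anchor_peaks)))
  membership <- matrix(membership, nrow = nrow(anchor_peaks),
                       dimnames = list(NULL, names(factor_peak_sets)))
  all_bound <- rowSums(membership) == k
  venn <- NULL
  if (k <= 3L) {
    pat <- apply(membership, 1L, function(r) paste(ifelse(r, "1", "0"),
                                                   collapse = ""))
    combos <- do.call(expand.grid, rep(list(c("0", "1")), k))
    labels <- apply(combos, 1L, paste, collapse = "")
    venn <- stats::setNames(vapply(labels, function(l) sum(pat == l), 0L),
                            labels)
  }
  list(cobound = anchor_peaks[all_bound, , drop = FALSE],
       n_cobound = sum(all_bound), membership = membership, venn = venn)
}

#' Associate peaks with their nearest gene
#'
#' Assigns every peak to the TSS nearest its midpoint; ties are broken by
#' lower TSS coordinate, then lexicographic gene id.
#'
#' @param peaks a peak `data.frame`.
#' @param tss a TSS `data.frame`: `chrom, pos, gene_id`.
#' @return `peaks` with `gene_id` and `tss_distance` columns.
#' @export
associate_genes <- function(peaks, tss) {
  if (nrow(tss) == 0L) abort_op("associate_genes", "TSS list is empty")
  nt <- .nearest_tss_dist(peaks, tss)
  out <- peaks
  out$gene_id <- tss$gene_id[nt$tss_idx]
  out$tss_distance <- nt$dist
  out
}

#' Rank genes by log2 fold-change
#'
#' Score per gene: `log2((treated + pc) / (control + pc))` with pseudocount
#' `pc = 1` FPKM, ordered descending; ties broken by gene id ascending.
#'
#' @param treated,control named FPKM vectors over a shared gene universe.
#' @param pseudocount added to both (default 1).
#' @return a `data.frame`: `gene_id, score`, descending.
#' @export
log2fc_rank <- function(treated, control, pseudocount = 1) {
  genes <- intersect(names(treated), names(control))
  if (length(genes) == 0L) abort_op("log2fc_rank", "no shared genes")
  tr <- treated[genes]; ct <- control[genes]
  if (any(tr < 0) || any(ct < 0)) abort_op("log2fc_rank", "negative FPKM")
  score <- log2((tr + pseudocount) / (ct + pseudocount))
  out <- data.frame(gene_id = genes, score = as.numeric(score),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank genes by average delta-FPKM over a drug panel
#'
#' Score per gene: mean over drugs of (treated - control) FPKM, ordered
#' descending.
#'
#' @param treated_mat genes x drugs FPKM matrix.
#' @param control named control FPKM vector.
#' @return a `data.frame`: `gene_id, score`, descending.
#' @export
delta_fpkm_rank <- function(treated_mat, control) {
  genes <- intersect(rownames(treated_mat), names(control))
  if (length(genes) == 0L) abort_op("delta_fpkm_rank", "no shared genes")
  if (any(treated_mat[genes, ] < 0) || any(control[genes] < 0))
    abort_op("delta_fpkm_rank", "negative FPKM")
  score <- rowMeans(treated_mat[genes, , drop = FALSE] - control[genes])
  out <- data.frame(gene_id = genes, score = as.numeric(score),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Welch's unpaired two-sample t test
#'
#' Two-sided Welch test (unequal variances, Satterthwaite degrees of
#' freedom), used to compare log2 fold-changes of SE-associated vs other
#' genes. Degenerate inputs (zero variance in both groups) return p = 1
#' when the means are equal and p = 0 otherwise, flagged.
#'
#' @param group_a,group_b numeric score vectors (each n >= 2).
#' @return a list of class `welch_result`: `mean_a, mean_b, sd_a, sd_b,
#'   n_a, n_b, t, df, p, degenerate`.
#' @export
welch_test <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    abort_op("welch_test", "each group needs n >= 2")
  va <- stats::var(group_a); vb <- stats::var(group_b)
  base <- list(mean_a = mean(group_a), mean_b = mean(group_b),
               sd_a = sqrt(va), sd_b = sqrt(vb),
               n_a = length(group_a), n_b = length(group_b))
  if (va == 0 && vb == 0) {
    eq <- isTRUE(all.equal(mean(group_a), mean(group_b)))
    return(structure(c(base, list(t = if (eq) 0 else Inf, df = NA_real_,
                                  p = if (eq) 1 else 0, degenerate = TRUE)),
                     class = "welch_result"))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  structure(c(base, list(t = unname(ht$statistic), df = unname(ht$parameter),
                         p = ht$p.value, degenerate = FALSE)),
            class = "welch_result")
}

# Core running-sum enrichment score. ranked: data.frame(gene_id, score)
# descending. Returns the signed extreme deviation and the hit indicator.
.gsea_es <- function(scores, is_hit, weight_exponent = 1) {
  nr <- sum(abs(scores[is_hit])^weight_exponent)
  n_miss <- sum(!is_hit)
  if (nr == 0 || n_miss == 0) return(0)
  steps <- ifelse(is_hit, abs(scores)^weight_exponent / nr, -1 / n_miss)
  run <- cumsum(steps)
  run[which.max(abs(run))]
}

#' Ranked-list gene-set enrichment (GSEA-style)
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment: walking down the
#' ranked list, the sum gains `|score|^p / NR` at set members and loses
#' `1/(N - Nh)` elsewhere; ES is the extreme deviation. Nominal p and NES
#' come from gene-set permutation (random sets of the same size), the
#' nominal p being the same-sign tail fraction and NES the ES divided by
#' the mean same-sign permuted |ES|.
#'
#' @param ranked a `data.frame` `gene_id, score` in descending score order
#'   (from [log2fc_rank()] or [delta_fpkm_rank()]).
#' @param gene_set character vector of member genes (intersection with the
#'   ranked universe must have >= 2 genes, else NA sentinel result).
#' @param weight_exponent the weight p (default 1).
#' @param n_permutations gene-set permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @return a list of class `enrichment_result`: `es, nes, p, n_genes,
#'   leading_edge, n_permutations`.
#' @export
gsea <- function(ranked, gene_set, weight_exponent = 1,
                 n_permutations = 1000, seed = 1) {
  scores <- ranked$score
  is_hit <- ranked$gene_id %in% gene_set
  nh <- sum(is_hit)
  if (nh < 2L || nh == nrow(ranked)) {
    return(structure(list(es = NA_real_, nes = NA_real_, p = NA_real_,
                          n_genes = nh, leading_edge = character(),
                          n_permutations = 0L),
                     class = "enrichment_result"))
  }
  es <- .gsea_es(scores, is_hit, weight_exponent)

  # leading edge: members at or before the extreme of the running sum
  nr <- sum(abs(scores[is_hit])^weight_exponent)
  steps <- ifelse(is_hit, abs(scores)^weight_exponent / nr, -1 / sum(!is_hit))
  run <- cumsum(steps)
  peak <- which.max(abs(run))
  leading <- if (es >= 0) ranked$gene_id[seq_len(peak)][is_hit[seq_len(peak)]]
    else ranked$gene_id[peak:length(run)][is_hit[peak:length(run)]]

  set.seed(seed)
  n <- nrow(ranked)
  perm <- vapply(seq_len(n_permutations), function(i) {
    h <- logical(n); h[sample.int(n, nh)] <- TRUE
    .gsea_es(scores, h, weight_exponent)
  }, 0)
  same_sign <- if (es >= 0) perm[perm >= 0] else perm[perm < 0]
  # nominal p against the same-sign permutation tail (standard convention)
  p <- (1 + sum(if (es >= 0) same_sign >= es else same_sign <= es)) /
    (1 + length(same_sign))
  nes <- if (length(same_sign) > 0 && mean(abs(same_sign)) > 0)
    es / mean(abs(same_sign)) else NA_real_
  structure(list(es = es, nes = nes, p = p, n_genes = nh,
                 leading_edge = leading,
                 n_permutations = as.integer(n_permutations)),
            class = "enrichment_result")
}

#' Three-set overlap (Venn) counts
#'
#' All intersection-region cardinalities for three gene sets, e.g. the
#' up/down gene sets of three drugs.
#'
#' @param sets named list of exactly 3 character vectors.
#' @return named integer vector over the 7 Venn regions (names like
#'   `"A_only"`, `"A_B"`, `"A_B_C"` using the set names).
#' @export
set_overlap <- function(sets) {
  if (length(sets) != 3L) abort_op("set_overlap", "need exactly 3 sets")
  nm <- names(sets)
  u <- unique(unlist(sets))
  mem <- vapply(sets, function(s) u %in% s, logical(length(u)))
  if (length(u) == 1L) mem <- matrix(mem, nrow = 1L, dimnames = list(NULL, nm))
  pat <- apply(mem, 1L, function(r) paste(nm[r], collapse = "_"))
  pat <- ifelse(pat %in% nm, paste0(pat, "_only"), pat)  # singletons
  regions <- c(paste0(nm, "_only"),
               paste(nm[1], nm[2], sep = "_"), paste(nm[1], nm[3], sep = "_"),
               paste(nm[2], nm[3], sep = "_"),
               paste(nm[1], nm[2], nm[3], sep = "_"))
  counts <- stats::setNames(integer(length(regions)), regions)
  tab <- table(pat)
  hit <- intersect(names(tab), names(counts))
  counts[hit] <- as.integer(tab[hit])
  counts
}
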