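# End-to-end orchestration: declarative config, deterministic runs, tables +
# JSON summary with stage provenance. The analysis/ scripts are thin drivers
# over these two functions and the module functions they chain.

#' Assemble a run configuration
#'
#' Single declarative configuration for the pipelines. Every tunable
#' defaults to the value used throughout the assay: hit threshold 60,
#' channel weights 4:2:1, classification thresholds 60 / 30 / 170,
#' stitch distance 12,500 bp, peak q-value bound 1e-9.
#'
#' @param seed master seed.
#' @param out_dir output directory.
#' @param library_spec a [library_spec()] (screen pipeline).
#' @param screen_dose screen dose, molar.
#' @param hit_threshold hit cut on the weighted score.
#' @param rules a [classification_rules()].
#' @param genomics a [genomics_config()].
#' @param epigenome_params parameter overrides for [simulate_epigenome()].
#' @param n_permutations GSEA permutations.
#' @return a list of class `run_config`.
#' @export
run_config <- function(seed = 1, out_dir = tempfile("crscreen_run_"),
                       library_spec = NULL, screen_dose = 10e-6,
                       hit_threshold = 60,
                       rules = classification_rules(),
                       genomics = genomics_config(),
                       epigenome_params = list(),
                       n_permutations = 1000) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 library_spec = library_spec, screen_dose = screen_dose,
                 hit_threshold = hit_threshold, rules = rules,
                 genomics = genomics, epigenome_params = epigenome_params,
                 n_permutations = n_permutations),
            class = "run_config")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.provenance <- function(stage, params) {
  list(stage = stage, params = params,
       package = as.character(utils::packageVersion("crscreen")))
}

#' Run the screening pipeline end to end
#'
#' Chains simulate -> normalize -> QC -> score -> hit call on the
#' configured synthetic library, writing the normalized tables, per-plate
#' QC, the hit table and a JSON summary (with the parameters used at every
#' stage) under `config$out_dir`. Deterministic given the config seeds.
#'
#' @param config a `run_config` with a non-NULL `library_spec`.
#' @return a list: `truth`, `qc`, `scores`, `hits`, `summary` (also
#'   written to disk), invisibly.
#' @export
run_screen_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$library_spec))
    abort_op("run_screen_pipeline", "config$library_spec is required")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  truth <- simulate_library(config$library_spec)
  plates <- simulate_primary_screen(truth, config$library_spec,
                                    dose = config$screen_dose)

  qc <- do.call(rbind, lapply(split(plates, plates$plate_id), function(p)
    z_factor(p, p$channel[1])))
  rownames(qc) <- NULL

  norm <- normalize_to_negative(plates)
  by_ch <- split(norm, norm$channel)
  for (ch in c("SE_luc", "CMV_luc", "XTT"))
    if (is.null(by_ch[[ch]]))
      abort_op("run_screen_pipeline", paste("missing channel:", ch))
  scores <- screen_report(by_ch$SE_luc, by_ch$CMV_luc, by_ch$XTT)
  hits <- call_hits(scores, threshold = config$hit_threshold)

  .write_tsv(qc, file.path(config$out_dir, "plate_qc.tsv"))
  .write_tsv(hits, file.path(config$out_dir, "hit_scores.tsv"))
  summary <- list(
    provenance = .provenance("screen", list(
      seed = config$library_spec$seed, n_compounds = nrow(truth),
      dose_M = config$screen_dose, hit_threshold = config$hit_threshold,
      weights = "4:2:1", scale = "inhibition",
      noise_cv = config$library_spec$noise_cv)),
    n_plates = nrow(qc), min_z_factor = min(qc$z_factor),
    n_hits = sum(hits$is_hit),
    boxplot_fences = as.list(attr(hits, "boxplot_fences")))
  jsonlite::write_json(summary, file.path(config$out_dir, "screen_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(truth = truth, qc = qc, scores = scores, hits = hits,
                 summary = summary))
}

#' Run the regulatory-genomics pipeline end to end
#'
#' Chains simulate epigenome -> q-value filter -> stitch -> SE call ->
#' occupancy / co-binding -> gene association -> expression ranking ->
#' Welch comparison of SE-associated vs other genes -> GSEA of the planted
#' core-regulatory TF set, writing tables and a JSON summary with
#' parameters under `config$out_dir`. Deterministic given the config seed.
#'
#' @param config a `run_config`.
#' @return a list: `epigenome`, `superenhancers`, `occupancy_pct`,
#'   `cobinding`, `welch`, `enrichment`, `summary`, invisibly.
#' @export
run_genomics_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  gcfg <- config$genomics

  epi <- simulate_epigenome(config$epigenome_params, seed = config$seed)
  anchor <- epi$truth$anchor
  anchor_peaks <- filter_peaks(epi$peaks[[anchor]], gcfg)
  stitched <- stitch(anchor_peaks, gcfg$stitch_distance)
  se <- call_superenhancers(stitched)
  se_regions <- se[se$is_SE, , drop = FALSE]

  occ <- occupancy_fraction(se_regions, anchor_peaks)
  factors <- setdiff(names(epi$peaks), anchor)
  cb <- cobound_sites(anchor_peaks,
                      lapply(epi$peaks[factors], filter_peaks, config = gcfg))

  assoc <- associate_genes(anchor_peaks, epi$tss)
  in_se <- suppressWarnings(
    GenomicRanges::countOverlaps(.as_gr(assoc), .as_gr(se_regions))) > 0
  se_genes <- unique(assoc$gene_id[in_se])

  control <- epi$expression[, 1]
  drug <- epi$expression[, 2]
  ranked <- log2fc_rank(drug, control)
  wt <- welch_test(ranked$score[ranked$gene_id %in% se_genes],
                   ranked$score[!ranked$gene_id %in% se_genes])
  enr <- gsea(ranked, epi$truth$cr_tf_set,
              n_permutations = config$n_permutations, seed = config$seed)

  .write_tsv(se, file.path(config$out_dir, "superenhancers.tsv"))
  .write_tsv(ranked, file.path(config$out_dir, "ranked_genes.tsv"))
  summary <- list(
    provenance = .provenance("genomics", list(
      seed = config$seed, peak_q_max = gcfg$peak_q_max,
      stitch_distance = gcfg$stitch_distance,
      distal_min_distance = gcfg$distal_min_distance,
      n_permutations = config$n_permutations)),
    n_superenhancers = sum(se$is_SE), occupancy_pct = occ,
    n_cobound = cb$n_cobound,
    welch = list(t = wt$t, df = wt$df, p = wt$p,
                 mean_se = wt$mean_a, mean_other = wt$mean_b),
    enrichment = list(es = enr$es, nes = enr$nes, p = enr$p))
  jsonlite::write_json(summary,
                       file.path(config$out_dir, "genomics_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(epigenome = epi, superenhancers = se, occupancy_pct = occ,
                 cobinding = cb, welch = wt, enrichment = enr,
                 summary = summary))
}
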