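#!/usr/bin/env Rscript
# Stage 2 — QC, normalization, and hit calling.
#
# Reads the stage-1 plates, computes per-plate Z-factors (pass bound 0.7),
# normalizes each plate to its negative controls, assembles the per-compound
# (L, C, X) inhibition triple, scores W = (4L + 2C + X)/7, and calls hits at
# the strict W > 60 cut. Reports recall against the planted truth.

suppressPackageStartupMessages(library(crscreen))

plates <- read_plate_csv("results/01_primary_screen_plates.csv")
truth <- utils::read.table("results/01_library_truth.tsv", sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)

qc <- do.call(rbind, lapply(split(plates, plates$plate_id), function(p)
  z_factor(p, p$channel[1])))
cat(sprintf("plate QC: %d plates, Z' range %.3f-%.3f, all pass: %s\n",
            nrow(qc), min(qc$z_factor), max(qc$z_factor), all(qc$pass)))

norm <- normalize_to_negative(plates)
by_ch <- split(norm, norm$channel)
scores <- screen_report(by_ch$SE_luc, by_ch$CMV_luc, by_ch$XTT)
hits <- call_hits(scores, threshold = 60)

utils::write.table(qc, "results/02_plate_qc.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(hits, "results/02_hit_scores.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

n_hits <- sum(hits$is_hit)
cat(sprintf("hits: %d of %d compounds (%.2f%%), boxplot upper fence %.1f\n",
            n_hits, nrow(hits), 100 * n_hits / nrow(hits),
            attr(hits, "boxplot_fences")["upper"]))

# recall of compounds whose planted weighted score clears 70
w_true <- weighted_score(100 - compound_response(truth, 1e-5, "SE_luc"),
                         100 - compound_response(truth, 1e-5, "CMV_luc"),
                         100 - compound_response(truth, 1e-5, "XTT"))
strong <- truth$compound_id[w_true > 70]
recall <- mean(strong %in% hits$compound_id[hits$is_hit])
cat(sprintf("recall of planted strong inhibitors (true W > 70): %.3f (n = %d)\n",
            recall, length(strong)))
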