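#!/usr/bin/env Rscript
# Stage 1 — simulate the primary screen.
#
# Builds a 20,000-compound synthetic library (a scaled stand-in for a
# 63,000-compound collection) with planted mechanism classes, reads every
# compound out at 10 uM on the SE-reporter, CMV-reporter and XTT-viability
# channels in duplicate 384-well plates, and writes the raw plate table
# plus the ground-truth sidecar.

suppressPackageStartupMessages(library(crscreen))
dir.create("results", showWarnings = FALSE)

spec <- library_spec(20000, noise_cv = 0.1, seed = 20260925)
truth <- simulate_library(spec)
plates <- simulate_primary_screen(truth, spec, dose = 10e-6, replicates = 2)

write_plate_csv(plates, "results/01_primary_screen_plates.csv")
utils::write.table(truth, "results/01_library_truth.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("library:", nrow(truth), "compounds\n")
print(table(truth$mechanism_class))
cat("plates written:", length(unique(plates$plate_id)),
    "(", nrow(plates), "wells )\n")
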