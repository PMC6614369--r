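#!/usr/bin/env Rscript
# Stage 4 — time-resolved growth IC50 trajectories.
#
# Contrasts an immediate-acting compound with a slow-onset benzamide-like
# compound (potency developing over ~4 days) in an Incucyte-style
# confluence time course: dose response at every 4 h imaging timepoint,
# 4PL fit per timepoint, and the IC50 trajectory with its stabilization
# time.

suppressPackageStartupMessages(library(crscreen))

series <- make_dose_series(30e-6, 12, 3)
archetypes <- data.frame(
  compound_id = c("immediate_hydroxamate", "slow_benzamide"),
  via_top = 100, via_bottom = 0, via_hill = 2.5, via_ic50 = 1e-6,
  onset_h = c(0, 96), stringsAsFactors = FALSE)

trajs <- lapply(seq_len(nrow(archetypes)), function(i) {
  g <- simulate_growth(archetypes[i, ], series, seed = 400 + i)
  tr <- ic50_trajectory(g[g$dose_M > 0, ], g[g$dose_M == 0, ])
  tab <- tr$table
  tab$compound_id <- archetypes$compound_id[i]
  list(table = tab, stab = tr$stabilization_time)
})

all_tab <- do.call(rbind, lapply(trajs, `[[`, "table"))
utils::write.table(all_tab, "results/04_ic50_trajectories.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

for (i in seq_along(trajs)) {
  v <- trajs[[i]]$table$ic50
  v <- v[!is.na(v)]
  cat(sprintf("%s: IC50 %.3g -> %.3g M over the window, stabilizes at %g h\n",
              archetypes$compound_id[i], v[1], v[length(v)],
              trajs[[i]]$stab))
}
cat("slow-onset compound stabilizes",
    trajs[[2]]$stab - trajs[[1]]$stab, "h later than the immediate one\n")
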