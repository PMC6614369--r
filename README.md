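# crscreen

Analysis pipeline for dual-reporter chemical screens that probe
**super-enhancer (SE)-driven versus promoter-driven transcription**, plus
the regulatory-genomics stages used to interpret the hits.

Fusion-positive rhabdomyosarcoma cells depend on a handful of core
regulatory (CR) transcription factors whose genes are driven by super
enhancers. A cell line carrying two chromatin-integrated luciferase
reporters — one under a CR-TF-bound intronic SE, one under a constitutive
CMV promoter — lets a compound library be ranked by how selectively each
molecule collapses SE-driven transcription. This package implements the
analysis for every stage of that campaign, for screening scientists and
computational biologists who want the chain reusable and testable:

* **Plate QC and normalization** — percent-of-control against same-plate
  DMSO wells; Zhang's Z' = 1 − 3(σ_p + σ_n)/|μ_p − μ_n| with a 0.7 pass
  bound; replicate R².
* **Hit scoring** — the weighted mean W = (4L + 2C + X)/7 of SE-reporter
  (L), CMV-reporter (C) and viability (X) inhibition, hits at strict
  W > 60, Tukey fences reported alongside.
* **Dose response** — unconstrained 4PL
  y = bottom + (top − bottom)/(1 + (x/IC50)^h) fitted by multi-start
  Levenberg–Marquardt in log dose; four-category SE-selectivity
  classification (inactive / general inhibition / SE selective /
  SE-down-CMV-up at the 60% / 30-point / 170% thresholds); maximum SE
  selectivity ranking; SE-vs-viability differentials.
* **Kinetics** — per-timepoint growth IC50 trajectories with
  stabilization times (immediate vs slow-onset compounds), and HDAC1–9
  progress-curve panels: linear-range rates normalized to DMSO, isoform
  IC50s with censoring.
* **Regulatory genomics** — q < 1e-9 peak filtering, 12,500 bp enhancer
  stitching, hockey-stick SE calling, occupancy / co-binding / distal
  statistics, nearest-TSS gene association, log2FC and delta-FPKM
  ranking, Welch tests, and weighted-KS gene-set enrichment with
  permutation p/NES.
* **Synthetic data** — generators with planted ground truth for every
  input (libraries, plates, growth curves, progress curves, a toy
  epigenome), so the whole chain is exercised end to end without
  external data.

## Worked example

The `analysis/` directory is a numbered workflow over the package. Stage
1 simulates a 20,000-compound screen (10 µM, duplicate 384-well plates,
three channels); stages 2–6 analyze it:

```sh
Rscript analysis/01_simulate_screen.R
Rscript analysis/02_screen_qc_hits.R
```

```
plate QC: 342 plates, Z' range 0.707-0.885, all pass: TRUE
hits: 893 of 20000 compounds (4.46%), boxplot upper fence 14.6
recall of planted strong inhibitors (true W > 70): 1.000 (n = 623)
```

Every plate clears the 0.7 Z' bound; 893 compounds score W > 60, and all
planted compounds whose true weighted score exceeds 70 are recovered.
Stage 3 confirms the hits in 12-point dose response and classifies them:

```
category counts among confirmed hits:
general_inhibition       se_selective
               587                306
most SE-selective: cmpd018914 (118 points, SE IC50 9.61e-08 M)
planted class recovered for 99.8% of confirmed hits
```

Stage 5 recovers an HDAC3-selective inhibitor's isoform profile from
noisy duplicate progress curves (planted: HDAC3 50 nM, HDAC1/2 1600 nM,
six isoforms inactive):

```
  HDAC1  IC50  2151.1 nM (61.1-fold vs most sensitive)
  HDAC2  IC50  1741.2 nM (49.5-fold vs most sensitive)
  HDAC3  IC50    35.2 nM (1.0-fold vs most sensitive)
  HDAC4  censored (activity floor 95%)
  ...
most sensitive isoform: HDAC3
```

Stage 6 runs the genomics chain on the planted epigenome: 15/15 SEs
called, 100% SE occupancy by the anchor HDAC's high-confidence peaks, 60
five-factor co-bound sites, Welch p = 3.1e-13 for SE-associated vs other
genes, and CR-TF enrichment ES = −1.0.

The methods vignette (`vignettes/crscreen-methods.Rmd`) documents the
models, parameter defaults, noise structure, and the generator's scope.

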