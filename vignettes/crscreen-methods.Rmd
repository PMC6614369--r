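---
title: "Methods: dual-reporter chemical screening of super-enhancer-driven transcription"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-reporter chemical screening of super-enhancer-driven transcription}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crscreen)
```

# The assay and what the package computes

Fusion-positive rhabdomyosarcoma cells depend on a small circuit of core
regulatory (CR) transcription factors whose genes are driven by super
enhancers (SEs). A cell line carrying two chromatin-integrated luciferase
reporters — one driven by a CR-TF-bound intronic SE, one by a constitutive
CMV promoter — turns that dependency into a screenable phenotype: a
compound that selectively collapses SE-driven transcription dims the SE
reporter while leaving the CMV reporter (and, at first, viability) intact.

`crscreen` implements the full analysis chain around that assay:

1. **plates** — plate data model, normalization to same-plate DMSO
   controls, Z-factor QC, replicate correlation;
2. **hitcalling** — the weighted screen score and hit identification;
3. **doseresponse** — four-parameter logistic (4PL) fitting and the
   four-category SE-selectivity classification;
4. **kinetics** — time-resolved growth IC50 trajectories and enzymatic
   progress-curve isoform panels;
5. **reggenomics** — peak filtering, enhancer stitching, hockey-stick SE
   calling, occupancy/co-binding statistics, expression ranking, Welch
   comparison, and GSEA-style enrichment;
6. **simdata** — generators for every input above, with planted ground
   truth, so the whole chain is testable without external data.

# Models and procedures

## Normalization and assay QC

Each well's signal is expressed as percent-of-control: $100 \times
s / \bar{s}_{\mathrm{DMSO}}$, where $\bar{s}_{\mathrm{DMSO}}$ is the mean
of the negative-control wells **of the same plate and channel** (never
pooled across plates). Plate quality is Zhang's
$Z' = 1 - 3(\sigma_p + \sigma_n)/|\mu_p - \mu_n|$ over the positive
(actinomycin-D-like) and negative control wells, with sample SDs — the
cited formula does not fix the estimator, and the $n-1$ denominator is the
conservative choice at 16 wells per role. The pass bound defaults to 0.7,
the plate performance this assay routinely achieves; 0.5 is the
conventional "excellent assay" floor.

## Hit scoring

The primary screen reads three channels at 10 µM: SE-reporter
luminescence ($L$), CMV-reporter luminescence ($C$) and XTT viability
($X$). Scores are combined as the weighted mean

$$W = \frac{4L + 2C + X}{7},$$

with $L, C, X$ on the **inhibition** scale ($100 -$ percent-of-control).
The scale convention matters: a fixed "above 60" hit cut is only coherent
if larger numbers mean stronger suppression, so the package states the
scale in every score table's metadata. The cut is strict ($W > 60$), and
the Tukey boxplot fences of the $W$ distribution are reported alongside as
a QC concordance check — the fixed threshold, not the fences, is the
decision rule, since the boxplot-vs-cutoff sequencing in the assay
description is ambiguous.

## Dose response and selectivity classification

Confirmation uses a 12-concentration, 3-fold dilution series from 30 µM
(bottom 0.17 nM) in quadruplicate. Curves follow the 4PL

$$y(x) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
{1 + (x/\mathrm{IC}_{50})^{h}},$$

with *top* the zero-dose asymptote. Top and bottom are unconstrained —
necessary because HDAC inhibitors *increase* CMV-promoter output (bottom
above top on that channel). Fitting is least squares in log-dose with
multi-start Levenberg–Marquardt (starts: data-range asymptotes ×
hill ∈ {0.5, 1, 2} × IC50 at the log-dose quartiles; SSE tolerance
1e-14); the reported IC50 is the inflection (relative) IC50.
Non-convergent fits return a flagged object, never an exception, and a
curve that never attains 50% within the tested range is censored on the
appropriate side.

Per-dose classification applies an ordered rule to the (SE%, CMV%) pair:

| order | condition | category |
|---|---|---|
| 1 | SE > 60% remains | inactive |
| 2 | CMV > 170% | SE-down-CMV-up |
| 3 | CMV − SE ≤ 30 points | general inhibition |
| 4 | otherwise | SE selective |

The ordering resolves the overlap between the "CMV ≤ 170%" and
"≤ 30-point difference" definitions: the CMV-up branch is taken first, so
the difference test only ever sees compounds with a quiet CMV channel.
The compound-level call is read at the **evaluation dose** — the lowest
dose at which SE output has dropped to the 60% floor, i.e. the most
sensitive informative dose; a compound that never reaches the floor is
inactive. Maximum SE selectivity is $\max_x (\mathrm{CMV}\% -
\mathrm{SE}\%)$ over the grid, and the SE-vs-viability differential is the
per-dose $(\mathrm{viability}\% - \mathrm{SE}\%)$ map, positive where SE
output is lost before the cells die.

## Growth kinetics

Confluence grows logistically toward 100% from a 15% seed at rate
$r_0 = 0.033\,\mathrm{h}^{-1}$ (DMSO crosses 95% near the end of a 7-day
window, matching a multi-day imaging experiment), with the drug scaling
the rate by $1 - I(x_\mathrm{eff})$, where $I$ is the fractional
viability inhibition from the compound's 4PL. Slow-acting compounds
develop **potency** over time: the effective dose ramps linearly from 0
to nominal across `onset_h` hours. A ramp on potency, rather than on
effect magnitude, is what makes the apparent IC50 measurable-but-high at
early timepoints and smoothly declining afterwards — the observed
slow-benzamide phenotype; an effect-magnitude ramp would instead censor
all early timepoints.

The dose response at time $t$ is the confluence **gain** ratio
$100(c_\mathrm{drug}(t) - c_0)/(c_\mathrm{DMSO}(t) - c_0)$, clamped at 0;
using gain over baseline cancels seeding density. Timepoints where DMSO
has not yet grown, or has passed 95% confluence, are excluded (the
monitored window). The IC50 trajectory refits the 4PL per timepoint, and
`stabilization_time` is the first time from which the IC50 stays within
1.5-fold of its final value — a tolerance chosen to separate the planted
immediate/slow archetypes cleanly: even an immediate-acting compound's
apparent IC50 drifts ~1.3-fold across the window, because logistic
saturation compresses late-time dose discrimination, so a tighter band
would flag drift that is a property of confluence assays, not of the
compound.

## Enzyme progress curves

Deacetylase activity is read as fluorogenic product release. Traces are
generated as $F(t) = b_0 + S(1 - e^{-(v/S)t})$: linear at early times at
rate $v = v_0/(1 + [I]/K_i)$ (fractional occupancy of a competitive
inhibitor), saturating as substrate depletes ($v_0 = 50$ AFU/min,
$S = 9000$ AFU, reads every 5 min to 240 min, duplicate wells).
`detect_linear_range()` implements the linear-range criterion — the
longest window of ≥ 5 points with linear-fit $R^2 \ge 0.99$, ties broken
toward the earliest window (the enzymatic linear phase precedes
depletion) — and reports both the window slope and a depletion-corrected
initial rate. The isoform panel, however, estimates each well's rate by
fitting the depletion model itself and taking $v$: selecting windows by
"looks linear" under read noise conditions on noise realizations that
straighten curvature, which biases slopes of fast (curved) traces low and
distorts the shape of the activity-vs-concentration curve; fitting the
generating model removes that selection effect. Activities are rates as
percent of the mean DMSO rate (making the panel invariant to detector
gain), the IC50 per isoform comes from an unconstrained 4PL in
concentration, and isoforms whose activity never drops below 50% within
the tested range are censored.

## Regulatory genomics

All intervals are BED-convention (0-based, half-open); distances are
between midpoints; strand is ignored (TSS positions are already
strand-resolved). Peaks are filtered to high confidence at
$q < 10^{-9}$ (strict). Peaks with inter-peak gaps ≤ 12,500 bp are
stitched into enhancer regions carrying summed signal. SE calling ranks
stitched regions by signal, scales rank and signal to $[0,1]$, and cuts
where the curve's tangent reaches slope 1 — implemented as the point
farthest below the $y = x$ diagonal, the classic hockey-stick elbow;
regions strictly above the cutoff signal are SEs. All-equal signals are a
degenerate geometry: zero SEs, flagged. The TSS-exclusion refinement some
SE callers offer is deliberately omitted.

Downstream statistics: occupancy (percent of SEs overlapping ≥ 1 bp of a
peak set), distal fraction (midpoint > 5 kb from every TSS), co-binding
(anchor sites overlapped by every factor set, with Venn counts for
≤ 3 sets), nearest-TSS gene association (ties: lower coordinate, then
lexicographic gene id), log2 fold-change ranking with a pseudocount of
1 FPKM (score $\log_2\frac{t+1}{c+1}$; ties broken by gene id for a
deterministic ranking), delta-FPKM averaged over a drug panel, Welch's
unequal-variance $t$ test (via `stats::t.test`, with explicit handling of
zero-variance degeneracies), and a weighted Kolmogorov–Smirnov running-sum
enrichment score: walking the ranked list, hits add
$|s|^p/N_R$ and misses subtract $1/(N - N_h)$; ES is the extreme
deviation, the nominal p is the same-sign gene-set-permutation tail
fraction, and NES divides ES by the mean same-sign permuted |ES|.
Gene-set permutation (not phenotype permutation) is used because
per-replicate expression matrices may not be available.

# The synthetic-data generator

The generator defines the study conditions; its defaults are fixed, not
tuning knobs. It emulates:

* **Compound libraries** with five planted mechanism classes (inactive,
  general inhibitor, SE selective, SE-down-CMV-up, viability-only) and
  class-consistent 4PL parameters per channel. SE-selective compounds get
  sub-micromolar SE IC50s with viability effects ~5–16× weaker (SE output
  collapses before cells die); CMV-up compounds plant a rising CMV
  channel reaching 220–300%; 15% of active compounds are slow-acting
  (onset 96 h). Well noise is multiplicative lognormal with unit mean
  (plate readers are scale-noise dominated), CV 0.1 by default; control
  wells draw from their own planted means/SDs (negatives 100 ± 4,
  positives 5 ± 2, 16 + 16 per 384-well plate on the edge columns — the
  assay description does not state a layout, so this explicit default is
  the package's choice). Setting the noise CV to zero silences control
  noise too, so zero-noise generation inverts exactly through downstream
  fitting.
* **Progress-curve noise** decomposes into a per-well amplitude factor
  (pipetting/enzyme load, the dominant term) and a 2% per-read detector
  factor; independent 10% noise on a *cumulative* signal would be
  unphysical.
* **A toy epigenome**: TSSs on a jittered grid (guaranteed spacing), SE
  loci 20–40 kb downstream of their host gene, a shared peak template per
  locus (CR TFs co-bind the same sites) with high signal, and dispersed
  background peaks — one per sampled 100-kb cell, so background never
  stitches and the rank-signal curve has a clean hockey-stick gap — with
  a 30% fraction failing the q-value filter. The expression matrix plants
  log2FC ≈ −2 on SE genes under each of three drugs, ≈ 0 elsewhere.

What it does **not** emulate: spatial plate effects (edge/B-score
artifacts), compound carry-over, sequence-level reads, peak-caller noise,
correlated gene-gene expression structure, or images (confluence is
generated as numbers). Passing tests therefore demonstrate correctness of
the analysis chain under the stated error model, not robustness to every
artifact of real screens.

# Problem sizes and numerical choices

The test suite and acceptance script run at desk scale, chosen to keep
sampling error well below the tolerances they check: 5,000-compound
libraries over 20 seeds for classification recovery, 200 noisy fits for
IC50 recovery, 50 seeds for the isoform panel, 200 random instances for
the interval-operation oracles, and 500 trials at 99 permutations for the
enrichment null calibration. Brute-force oracles (pairwise merging,
all-pairs distances, exhaustive running sums) are written independently
in the test helpers and never share code with the implementation.

Tie-breaks and degenerate inputs are deterministic throughout: stable
sort orders are documented per operation, equal control means yield a
−∞ Z-factor sentinel, flat dose-response data censor rather than error,
and zero-variance Welch comparisons return flagged p ∈ {0, 1}.

# Known limitations

* The 4PL IC50 is the relative (inflection) IC50; absolute-IC50 and
  growth-rate-corrected metrics are out of scope.
* The enzyme model collapses the two-enzyme (deacetylase + protease)
  coupling into a single effective rate and does not model slow-binding
  kinetics; `onset_h` in the growth model is phenomenological.
* SE calling reimplements the rank-signal tangent cutoff; it does not
  reproduce any particular external caller's region bookkeeping
  (TSS exclusion, signal binning) beyond the stitch distance and cutoff
  geometry.
* Real-data headline figures from the original screens (hit counts,
  occupancy percentages, overlap gene counts) depend on proprietary
  compound collections and raw sequencing data; the package's claims are
  about recovering *planted* truth under the stated error model, and the
  module accepts externally produced peak/expression files for users who
  wish to go further.
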