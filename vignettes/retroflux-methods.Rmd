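---
title: "Models and methods behind retroflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind retroflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`retroflux` quantifies single-cell time-lapse movies of MS2-labeled
retroviral genomic RNA (gRNA) and, because suitable public movie data do
not exist, ships a mechanistic simulator plus a synthetic-microscopy
renderer so that every estimator in the measurement chain can be verified
by parameter recovery. Two nuclear-export programs are modeled:

* **Rev/RRE/CRM1** — nuclear retention until Rev accumulates, then either a
  gradual redistribution of the MS2-YFP signal to the cytoplasm or a
  threshold-triggered *burst* in which the nuclear signal is evacuated en
  masse in well under an hour;
* **CTE/NXF1/NXT1** — constitutive export followed, in phenotype-positive
  cells, by microtubule (MT)-directed transport and clustering at the
  centrosome/MTOC; depolymerizing MTs (nocodazole) arrests transcripts in
  a band at the nuclear envelope instead.

# The cell and transcription model

Each simulated cell is an adherent, HeLa-like object: a star-convex
boundary (base radius 16–19 µm with low-order harmonic shape variation),
an elliptical nucleus (semi-axes 6–7.5 × 4.5–6 µm) strictly inside it, a
juxtanuclear centrosome 0.8–2.2 µm outside the nuclear envelope, and 24
MT tracks radiating from the centrosome to the cell boundary.

Transcription of the labeled reporter starts `tx_onset` = 4 h
post-transfection (imaging in this field typically starts around 6 h, when
nuclear punctae first become visible) and produces transcripts as a
Poisson process at `k_tx` = 8 per hour. Both values are free defaults
chosen so that punctae are individually countable during the first imaging
hours and the burst trigger (below) arms in the middle of a 36-h movie.

# MS2-YFP pool bookkeeping

The nuclear MS2-YFP pool (`ms2_pool` arbitrary units) binds transcripts
carrying 24 binding loops with up to 48 coat proteins each. The package
uses an equilibrium-redistribution ledger: nuclear transcripts share the
bound pool up to their capacity, coats travel with a transcript when it is
exported, and exported coats never return to the nucleus. Consequently the
total nuclear YFP equals `pool − U`, where `U` is the cumulative exported
unit total — the single state variable that drives the measured
cytoplasmic-to-nuclear (C:N) ratio.

The per-transcript capacity is `pool / ms2_saturation`. For the Rev
program `ms2_saturation` = 30: the pool is sequestered by a few dozen
fully loaded transcripts, long before the burst trigger count is reached,
which is the saturation interpretation of the en-masse signal transfer.
For the CTE program `ms2_saturation` = 150: loading is distributive across
many transcripts, each carrying a smaller coat load. Besides the
biological reading, the distributive choice keeps the cytoplasmic display
of CTE cells fine-grained enough that the MTOC enrichment score of a
*non*-clustered cell is not dominated by a handful of bright spots.

A burst transfers the entire remaining nuclear content — bound and free —
to the cytoplasm at once; most of it is rendered as a diffuse cytoplasmic
haze (the display split is 8% spot-bound / 92% diffuse for the Rev
program, 100% spot-bound for the CTE program, whose coats stay
transcript-associated and must cluster with their transcripts).

# Export programs

* **none** — transcripts stay nuclear; punctae accumulate.
* **burst** (probability `burst_penetrance` per cell) — the burst arms
  when `burst_threshold` = 100 nuclear transcripts have accumulated (and
  Rev is present); after a 0.25-h arming delay (export-complex assembly,
  during which the nuclear count sits at the threshold) all nuclear
  content leaves within `burst_duration` = 0.25 h. Transcripts born afterwards are exported
  within minutes but carry no label (the pool is gone), so the nucleus
  stays dark — as observed after real evacuation events.
* **gradual** (penetrant cells that do not burst) — a per-cell transition
  window `W` is drawn from Normal(9.0, 3.4) h truncated at 0.25 h, and a
  per-cell plateau ratio from Normal(3.2, 0.5) truncated at 2.6. Export is
  scheduled by a controller that drives the *measured-space* C:N ratio
  (including autofluorescence, computed from the same signal model the
  renderer uses) linearly from zero to the plateau over `W`, then holds
  it. The design goal of the gradual realization is that the
  downstream 10–90% duration estimator should recover the drawn window
  without bias; a linear exported *fraction* does not achieve that —
  C:N is a convex function of the exported fraction, which biases the
  estimator low by 15–20% — so the package schedules linearity in the
  quantity the estimator actually consumes. The underlying per-particle
  export is correspondingly front-loaded; this is a deliberate design
  choice, stated here because the two formulations are not equivalent.
* **cte_mtoc** — transcripts export constitutively (exponential nuclear
  residence, rate `k_exp_max` = 2/h). In penetrant cells (probability
  `penetrance`) exported transcripts cycle through
  cytoplasm → MT-bound → MTOC → cytoplasm; under nocodazole they are
  arrested within 2 µm of the nuclear envelope and the MTOC is never
  occupied.

# Two integration regimes

Physics is integrated at `min(10 s, frame_interval / 2)`. At long-mode
cadences (30–60 min) free diffusion fully equilibrates between frames
(4·D·Δt ≈ 3600 µm² for `D_cyt` = 0.5 µm²/s, far exceeding the squared
cell size), so positions at each recorded frame are drawn from the exact
equilibrium — uniform within the compartment — rather than substepped.
This is exact sampling, not an approximation. Compartment states advance
once per recorded frame through the legal edge set
nuclear → cytoplasmic ↔ MT-bound → MTOC → cytoplasmic; the chain's
stationary law puts `mtoc_occupancy` = 0.75 of a penetrant cell's
exported transcripts at the MTOC.

In fast mode (700 ms frames) diffusion, MT run-and-reverse transport
(speed `mt_speed` = 0.6 µm/s, exponential run lengths of mean
`mt_run_length` = 3 µm, direction reversal probability 0.3 per run end,
first run minus-end-directed), MTOC capture within
`mtoc_capture_radius` = 1 µm and exponential dwell
(`mtoc_dwell_mean` = 240 s) are integrated explicitly.

# Rendering model

Movies are 16-bit, 256 × 256 px at 0.325 µm/px (one cell per field), PSF
an isotropic Gaussian of σ = 0.4 µm, Poisson shot noise over a
100-count background plus Gaussian read noise (σ = 3). A flat cell-body
autofluorescence (80 photons/px) makes the cell outline segmentable in
every channel and frame. The 256-px field was chosen over a larger one
because a single HeLa-sized cell fits with margin and the acceptance
cohorts stay desk-scale.

The YFP channel conserves photons per compartment: the nuclear haze and
at most 8 discrete punctae share exactly `pool − U` units (a punctum's
photons are borrowed from the haze), and the cytoplasm carries exactly
`U`. Each rendered punctum is calibrated *in measured space*: its
amplitude is set so that the spot-disk MFI over the surrounding
nucleoplasm equals the scenario's `punctae_enrichment` (2.8 by default),
using a brute-force disk-gain oracle averaged over subpixel emitter
positions. Rendering only the first eight punctae reflects the sparse,
countable regime in which fold-enrichment is measured; a crowded 2-D
projection of dozens of 3-D punctae merges into the haze. This is the
main place where the 2-D renderer cannot honor 3-D physics: a real
punctum carries ≤48 fluorophores against a pool of millions and is only
visible because optical sectioning suppresses the out-of-focus pool, so
2-D amplitudes are a calibrated measurement-space construct, not a
photon-count ground truth.

CFP renders cytoplasmic Gag (a diffuse fill proportional to accumulated
translation), bright membrane assembly-site spots, and an MTOC
accumulation term in the CTE program. mCherry renders the Rev level
weighted 60/40 nucleus/cytoplasm — the partition is not quantified
anywhere, so the weighting is an arbitrary documented constant. DNA fills
the nucleus; PCNT is a pericentrin-like centrosome marker spot.

# Measurement chain — numerical choices

* **Segmentation** replaces hand-drawn regions: Otsu after σ = 2 px
  smoothing for the nucleus (hole-filled largest component, ≥200 px),
  triangle threshold (on intensities clipped at the 99.5th percentile, so
  a dense bright cluster cannot push the threshold above the dim cell
  body) plus closing for the cell, then an erosion matched to
  the smoothing radius — the triangle threshold catches the far tail of
  the blurred edge and would otherwise dilate the mask by ~10%, diluting
  cytoplasmic MFI. Because the cells are stationary, cohort pipelines
  segment once per cell (as regions of interest are drawn once in
  practice) via the `masks` argument of `measure_movie()`.
* **Background** is the median over a 10-px annulus outside the cell.
* **Punctae detection** is Laplacian-of-Gaussian at the PSF scale with a
  5·MAD threshold on the in-mask LoG response (response-space MAD, same
  spirit as an intensity MAD but consistent units), local maxima only in
  the eroded mask core (the mask boundary itself generates LoG maxima),
  subpixel centroid refinement in a disk of radius 2σ. Two spots closer
  than the PSF scale merge.
* **Fold-enrichment** excludes all spot disks from the nucleoplasm
  reference to avoid self-contamination. The measured grand mean sits a
  few percent below the configured value because autofluorescence and
  neighbor-spot tails inflate the reference; this attenuation is a
  property of the measurement, not the calibration.
* **Transition duration** is `(t_last_cross(0.9) − t_first_cross(0.1)) / 0.8`
  on the min-max-normalized C:N trace, linearly interpolated — unbiased
  for the generator's linear ramps and robust to endpoint noise. The
  10/90 convention is this package's operational definition of
  "minimum-to-maximum" duration.
* **Export classes**: `none` if the final raw C:N < 1.5, `burst` if the
  duration is under 1.0 h, else `gradual`. The 1-h cutoff follows the
  observed en-masse evacuations; the 1.5 gate and the 1.5 / (1/1.5)
  distribution-class boundaries are declared conventions in place of
  blind visual scoring.
* **Onsets** (Rev, VLP) use sustained-2-frame rules against 3·SD of the
  baseline-centred series (Rev; the clamped MFI floor from cell
  autofluorescence is subtracted first) or a count of ≥3 assembly sites (VLP) for single-frame
  shot-noise robustness. The registry VLP onset distributions are quoted
  in measured space — moments of the observable (≥5 h) distribution — so
  the generator moment-matches the underlying normal before truncating,
  and several assembly sites nucleate together at onset so the count rule
  reads the drawn time without a rate-dependent lag.
* **MTOC score**: fold = MFI in a 3-µm disk around the centrosome over
  the matched perinuclear band (cytoplasm at the same distance-to-nucleus
  range, disk excluded); targeted at fold ≥ 3. The band reference is the
  numeric analog of visual scoring and is what distinguishes a centrosome
  cluster from nocodazole-arrested transcripts ringing the whole
  envelope; a remaining-cytoplasm reference (available via
  `reference = "cytoplasm"`) cannot make that distinction, because the
  juxtanuclear disk always samples the bright ring.
* **Tracking** links detections by distance-ordered greedy mutual-nearest
  assignment (deterministic, tie-broken by track then spot index) within
  1.5 µm/frame and one-frame gap closing. Speeds average per-step
  displacements above a noise floor of twice the localization σ. Motion
  classes use the MSD exponent over lags 1…n/4 (directed ≥ 1.3,
  confined ≤ 0.7). The cohort-level MT speed pools *directed tracks of at
  least 25 points*: short tracks give unstable exponents, and freely
  diffusing transcripts rarely remain linkable that long because their
  larger steps break the linking radius, so track length itself separates
  motor transport from diffusion.

# What the generator does and does not emulate

It emulates: nuclear punctae with calibrated fold-enrichment; pool
saturation and en-masse evacuation; gradual transitions with realistic
per-cell duration spread; constitutive CTE export with MT transport,
MTOC clustering, bidirectional runs and nocodazole arrest; Rev and Gag
reporter kinetics with membrane assembly sites; penetrance mixtures at
the published fractions; and both acquisition regimes (30-min and 700-ms
cadence).

It does not emulate: mitosis and spindle-pole partitioning, 3-D optics or
deconvolution, photobleaching, stage drift, cell crowding or motility,
transcript degradation (rate 0 by default — turnover is never
quantified for these reporters), or pore-level export kinetics. Passing
tests therefore demonstrate that the estimators recover known parameters
under this generative model — not that they are robust to every artifact
of real microscopy.

# Problem sizes

The shipped verification runs use cohorts of 25–300 cells per condition
(matching the scale of the scored populations they model: roughly 300
cells over three independent transfections for phenotype fractions, 30
cells for kinetic traces, 50 cells per pathway for assembly onset, ≥50
tracks for transport speed), movies of 36 h at 30-min cadence or ~50 s at
700-ms cadence, and one 256² cell per movie.

# Known limitations

* The C:N plateau of an exporting cell is held constant by the export
  controller; real traces often decline after the peak (pool turnover,
  bleaching), which this model omits.
* Burst cells whose 0.25-h evacuation straddles two 30-min frames can
  measure a duration of ~1 h and fall on the gradual side of the 1-h
  rule; a few percent of true bursts are misclassified, so measured burst
  fractions sit slightly below the configured penetrance.
* Punctae counts are only rendered faithfully in the sparse regime (≤8
  per nucleus); the pre-burst punctae build-up is represented in the
  ground truth but not in the rendered image.
* The MS2 pool display in 2-D is measurement-space calibrated; absolute
  photon counts do not correspond to fluorophore numbers.
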