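---
title: "Methods: virtual multiplexed IHC and spatial immune contexture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual multiplexed IHC and spatial immune contexture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The assay this package models

Chromogenic immunohistochemistry stains one protein per slide: a brown
chromogen (AEC or DAB) marks antibody binding and blue hematoxylin
counterstains every nucleus. Sequential ("next-generation") IHC gets
around the one-marker limit by staining, scanning and destaining the same
physical section repeatedly — here six times, for a panel of four T-cell
lineage markers (CD3, CD4, CD8, Foxp3), the proliferation marker Ki67 and
cytokeratin (CK) for tumour epithelium. Because the section never moves
between chemistry and scanner by more than a rigid placement error, the
six scans can be fused computationally into one *virtual multiplexed
image* carrying all markers on a common pixel grid.

`ngiplex` implements that fusion and everything downstream of it:

1. **Optical density and unmixing.** Transmitted intensity follows
   Beer–Lambert, so `OD_c = -log10((I_c + 1)/(bg_c + 1))` per RGB channel
   makes stain contributions additive. Each pixel's OD 3-vector is
   decomposed by least squares onto two unit colour vectors (published
   Ruifrok–Johnston vectors for hematoxylin and DAB/AEC); negative
   coefficients are clipped and the off-plane residual discarded. A basis
   angle below 10 degrees is rejected as unmixable.
2. **Registration.** The counterstain repeats in every round, so
   hematoxylin OD maps drive registration. The model is a similarity
   transform (translation, rotation, scale gated to [0.9, 1.1]): serial
   scans of one slide have no local deformation, so nothing non-rigid is
   estimated. Coarse search: phase correlation over a rotation grid on a
   mean-pooled pyramid; refinement: Nelder–Mead on the normalised
   cross-correlation at quarter resolution (a second half/full-resolution
   pass is available but the default already recovers synthetic warps to
   well under 0.1 px). A registration whose best NCC stays below a floor
   (default 0.2) raises a typed failure condition carrying the score
   rather than silently fusing garbage.
3. **Cell detection and phenotyping.** Nuclei are detected on the fused
   hematoxylin map by smoothing, thresholding and watershed on the
   distance transform; components are filtered by equivalent diameter
   (4–14 µm) and circularity (≥ 0.6). Marker positivity is the mean
   chromogen OD over a compartment matched to the marker's biology —
   nuclear disk for Ki67/Foxp3, a 1.5 µm membrane ring for CD3/CD4/CD8,
   the nucleus dilated 2 µm for cytoplasmic CK — against a fixed
   per-marker threshold (default 0.15 OD, closed boundary: equality is
   positive). Exclusive phenotypes follow the standard gate: CD3⁺ cells
   are CD8 T (CD8⁺CD4⁻), CD4 T (CD4⁺Foxp3⁻), Treg (CD4⁺Foxp3⁺) or
   CD3-only; CD3⁻CK⁺ cells are tumour; the rest are "other". CD4⁺CD8⁺
   double positives are resolved toward the higher mean OD (ties to CD8)
   and counted as conflicts; Ki67 is a modifier flag, never a phenotype.
4. **Spatial zoning.** The CK OD map thresholded inside the ROI, closed
   (2 µm), small objects removed and holes filled, gives the tumour mask
   A. Zone B is the peritumoural stroma within 30 µm of A by the *exact
   Euclidean distance transform* — not iterated structuring-element
   dilation, which carries an octagonal metric bias — with a closed
   boundary (exactly 30 µm is B). Zone C is the remaining ROI. The
   partition property (A, B, C disjoint, union = ROI) is asserted on
   every call, and the test suite holds the EDT implementation to
   bit-equality with a brute-force per-pixel minimum-distance oracle.
5. **Contexture metrics.** Densities (cells/mm²) per marker and zone use
   *marker-level* (overlapping) positivity, because CD3/CD4/CD8/Foxp3
   densities are reported side by side and a Treg contributes to three of
   them; subset proportions use the exclusive phenotypes and sum to one.
   Ki67⁺ fractions, the proliferating Foxp3⁺/CD8⁺ ratio and the
   proliferating-immune fraction (immune Ki67⁺ over immune-plus-tumour
   Ki67⁺, "other" cells excluded) complete the per-sample readout.
   Fractions with empty denominators are missing (`NA`), never zero, and
   propagate as missing. Samples with a total ROI under 100,000 µm² fail
   QC; the bound is read as an area (the only reading consistent with a
   region-of-interest filter) and the boundary is closed.
6. **Statistics.** Spearman correlation, Mann–Whitney/Kruskal–Wallis,
   paired Wilcoxon, t-based paired-difference intervals and univariate
   logistic odds ratios (reported per 10 sTIL points or per 1000
   cells/mm²), all two-sided. Small samples get exact enumeration
   p-values (full permutation enumeration for Spearman at n ≤ 8 without
   ties; sign-flip enumeration for Wilcoxon at n ≤ 12; labelling
   enumeration for Mann–Whitney at n₁+n₂ ≤ 12); large samples the
   standard approximations. The two-group normal approximation carries
   the tie correction but no continuity correction, making it
   algebraically identical to the two-group Kruskal–Wallis chi-square —
   a property the tests check to 1e-6. Zero paired differences are
   dropped (the common convention; the choice is documented, not
   universal).
7. **Expression and SAM.** Counts are log2(x+1) transformed and each
   sample shifted so its five-housekeeping-gene mean (ACTB, MRPL19,
   PSMC4, RPLP0, SF3A1) equals the grand mean. Gene–sTIL association
   uses quantitative-response SAM: d = slope/(se + s0) from the
   regression of expression on sTILs, s0 chosen over percentiles of the
   standard errors to minimise the coefficient of variation of
   window-wise MADs of d, a permutation null of the sTIL vector, and
   q-values from median false-call counts, monotone in |d|. The
   regression-slope form of the statistic is this package's normative
   choice; the method family is standard but the original tooling does
   not pin down the statistic for a continuous response.

## The synthetic slide generator

No per-cell raw data or images accompany the study design this package
targets, so validation runs against a seeded forward model that renders
what the scanner would have seen.

A ground-truth cell map is built first: tumour cells on a jittered 8 µm
grid filling the configured nests (cytoplasmic CK blobs of 6 µm radius,
so the union is a connected epithelial mask); immune cells with an
exclusive phenotype mix that defaults to 160/100/40/45
CD8-T/CD4-T/Treg/CD3-only — mirroring the reported ~47/30/11/13 split of
CD3⁺ subsets in HER2⁺ breast tumours — plus 60 CD3⁻ stromal cells, on a
0.26 mm² field at 0.5 µm/px. Ki67 is Bernoulli per cell with zone-specific
rates (A/B/C = 0.25/0.15/0.08 for immune cells, mirroring the reported
decrease of proliferating T cells away from tumour; 0.45 for tumour
cells, the dominant proliferative compartment). Each round renders
nuclear hematoxylin for every cell plus the round's chromogen in its
compartment, warps the ideal OD fields by that round's configured
misalignment (a global similarity transform — rigid by design, matching
the registration contract), adds Gaussian OD noise (default 0.02), and
quantises through the Beer–Lambert model to 8-bit RGB.

Three placement rules make the phantom's ground truth *checkable* rather
than merely plausible, and are deliberate design choices:

- **Spacing.** All cells keep ≥ 8.5 µm centre distance (9 µm between
  immune and tumour cells). Nuclei (7 µm) never overlap, and the
  measurement compartment of one cell can never pick up enough of a
  neighbour's same-marker stain to cross threshold — single-neighbour
  ring crosstalk peaks near 0.08 OD against a 0.15 threshold.
- **Intratumoural cells sit deep.** A configured fraction (default 0.15)
  of immune cells is placed ≥ 18 µm inside nest boundaries with ≥ 20 µm
  mutual spacing. Their stromal micro-pockets are isolated holes fully
  enclosed by tumour, so hole-filling labels them zone A identically in
  the ground truth and the analysis; scattered single intratumoural
  lymphocytes are also the biologically typical picture.
- **Stromal cells avoid the knife edge.** Stromal cells keep 2 µm clear
  of the 30 µm B/C contour, so sub-pixel differences between the true and
  recovered tumour mask cannot flip zone labels.

The ground-truth tumour mask is produced by the analyzer's own
`build_tumor_mask` applied to the noise-free ideal CK field (threshold at
half the chromogen amplitude, which localises a soft-edged boundary
without bias), and ground-truth zones by the shared `partition_zones`.
Truth and analysis therefore share one mask and zone semantics; what the
pipeline is tested on is everything the acquisition adds — misalignment,
registration error, unmixing, noise, quantisation, detection and
thresholding.

What the generator does **not** emulate: tissue texture and
autofluorescence, staining-chemistry artefacts (incomplete stripping,
tissue loss between rounds), non-rigid deformation, irregular nuclear
shapes, and cell-density regimes where compartments genuinely overlap.
Passing the recovery tests therefore demonstrates correctness of the
measurement pipeline under its stated geometric model, not robustness to
every pathology of real slides.

## The synthetic cohort generator

Cohort tables emulate a neoadjuvant anti-HER2 trial structure: three
timepoints (baseline, day 15, surgery) per patient; hormone-receptor
status and a PAM50-style label per patient (HER2-enriched dominant, as in
HER2⁺ disease); per-stratum pCR probabilities (defaults 0.45 HR−, 0.20
HR+, ≈ 30% overall). sTILs come from a latent patient inflammation level
(beta-distributed, HR− above HR+) plus *iid measurement noise at every
timepoint*, a mean day-15 shift per HR stratum (defaults +12.5 points
HR−, +2.1 HR+, the reported cohort dynamics) and a surgery shift
conditional on pCR (−21.5 vs −0.9). Scores are then clipped to [0, 100]
and rounded to pathologist granularity: steps of 5 below 10%, steps of 10
above. The latent-plus-noise construction matters: with the noise on the
day-15 arm only, clipping at zero inflates the null rejection rate of the
paired test; with exchangeable timepoints the null is honest, which the
Monte-Carlo tests verify.

The expression module writes raw counts for a panel (default 200 genes)
containing the five housekeeping genes at stable high levels, ten
TIL-linked immune genes (MS4A1, PD1, CD8A, CD19, IKBKE, IDO1, TAP1, TYMP,
CD3G, LAG3) constructed at a target log-scale correlation with sTILs
(default 0.5, the middle of the reported 0.34–0.52 per-gene range), and
null genes.

## Numerical choices and degenerate inputs

- OD ceiling 3.0 everywhere; +1 pseudo-intensity before the log and +1
  pseudo-count before log2 keep black pixels and zero counts finite.
- Background (white) intensity: per-channel 99th percentile unless
  supplied — a robust white estimate needing no calibration target.
- Bilinear interpolation for OD maps, nearest-neighbour for masks;
  pixels not covered by all warped rounds form the valid-pixel mask and
  are excluded from analysis; a compartment wholly outside it yields an
  indeterminate call, excluded downstream and counted in QC.
- Coordinates: origin top-left, x = column, y = row, half-open pixel
  boxes; a centroid at micron coordinate x lies in pixel column
  `floor(x / pixel_size) + 1`.
- Closed boundaries throughout: mean OD equal to threshold is positive,
  exactly 30 µm is zone B, exactly 100,000 µm² passes QC, and equal sTIL
  scores are "stable" dynamics (no tolerance band).
- Degenerate statistics are flagged, not faked: constant vectors give a
  missing rho, all-zero paired differences a missing p, separated
  logistic fits a `converged = FALSE` result; SAM refuses fewer than 50
  permutations.

## Problem sizes used by the test and acceptance suites

Unit tests run on a 512×512 px (256 µm) slide with ~470 cells; the
recovery acceptance check uses the full default 1024×1024 px slide
(~1100 cells); registration recovery uses ten random warps up to ±20 px
and ±3°; SAM operating characteristics use 500 genes × 60 samples × 20
replicates at 200 permutations; cohort recovery uses 100 replicates of 60
patients. These sizes give every per-zone, per-marker cell of the
comparison enough events to make its tolerance meaningful while keeping a
full run on one CPU comfortable.

## Known limitations

- Two-stain unmixing only; a third chromogen would need a different
  basis and is out of scope.
- The registration search covers rotations to ±3.5° by default; grossly
  rotated scans need a wider grid (`max_rotation_deg`).
- Per-marker thresholds are fixed constants by default. The Otsu
  alternative is provided but not the default, to keep runs
  deterministic; neither is a substitute for calibrating against a
  pathologist on real material.
- The phantom validates the pipeline under its own geometric model (see
  above); accuracy figures from synthetic slides should not be quoted as
  expected performance on clinical scans.
- Whole-slide tile pyramids (NDPI/SVS) are not read; the readers expect
  pre-extracted 8-bit RGB regions.
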