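---
title: "Methods: quantifying gene–enhancer proximity by 3D FISH and 5C"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying gene-enhancer proximity by 3D FISH and 5C}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`chromprox` implements the two quantitative readouts by which one decides
whether a gene and a distal enhancer colocalise in nuclei: per-allele 3D
FISH inter-probe distances with 200-nm distance-class statistics, and 5C
contact-matrix processing (normalisation, window binning, virtual 4C,
insulation boundaries). Both arms are driven by synthetic-data generators
with known ground truth, so every stage of the analysis can be tested
without any external data. This vignette explains the models, the
parameters that matter, and the choices made where the design was open.

## The distance model

An allele's true 3D separation between the gene probe and the enhancer
probe is modelled as a two-component mixture: with probability `p_coloc` a
half-normal "looped" component with scale `short_scale_nm`, otherwise a
normal "open" component (`tail_mean_nm`, `tail_sd_nm`) truncated at zero.
The published evidence is binned histograms, not a parametric law, so this
form is a modelling decision; it was chosen because both components have
closed-form CDFs (`distance_cdf()`), which gives every downstream test an
analytic oracle. `distance_model_for_fraction()` solves for `p_coloc` so
that the analytic `P(d < 200 nm)` equals a requested colocalised fraction;
group presets anchor to reported levels (about 0.79 for expressing
distal-posterior limb tissue seen at super-resolution, 0.35 for the same
tissue by conventional widefield, 0.25 for distal anterior tissue, 0.10
for flank, under 0.05 for a control locus outside the regulatory domain).
The per-tissue component shapes are illustrative, not fitted.

Distance classes are half-open: colocalised is `d < 200`, adjacent
`200 <= d < 400`, separate `d >= 400` (a distance of exactly 200 nm is
adjacent, because colocalisation is defined strictly below 200).

## The imaging model

Each nucleus is a per-nucleus crop (default 36 x 36 x 18 voxels of
100 x 100 x 120 nm; the z step matches the 0.120 um stacks used in
practice) containing two alleles at least 1.2 um apart, each rendered as
one anisotropic-Gaussian spot per colour channel. PSF sigmas are set so
that FWHM matches the nominal resolutions: conventional widefield 250 nm
lateral / 200 nm axial, structured illumination (SIM) half of both. Probe
orientation is uniform on the sphere; spot placement resamples (bounded
retries) rather than clipping at stack edges.

Noise has three parts:

* Poisson photon noise on spot plus background,
* Gaussian camera read noise (`read_noise_sd`, default 2 counts),
* a **structured nuclear background**: the mean background
  (`background_level`, default 20 counts) is modulated by a smooth random
  field with relative sd `background_sd_frac` (default 0.5) and
  correlation length `background_corr_nm` (default 400 nm), drawn
  independently per channel.

The structured term is essential, not cosmetic. With a flat background,
any photon budget bright enough to detect yields centroids accurate to a
few nm in **both** modalities, and conventional and super-resolution
imaging would measure identical colocalisation — contradicting the
central observation that conventional widefield under-reports
colocalisation relative to SIM (reported medians 241 vs 136 nm in
expressing tissue). Real tissue sections carry strong non-uniform
background (autofluorescence, off-target probe binding); an
intensity-weighted centroid integrates that structure over a window that
scales with the PSF, so the wide conventional PSF is degraded far more
than the narrow SIM PSF. The default photon budget (500 photons per spot)
was calibrated once so that imaging the ~0.79-truth preset under both
modalities reproduces the direction and rough magnitude of that published
contrast, and was not revisited afterwards. `photons_for_snr()` converts
between photon budget and peak SNR for scenarios specified in SNR terms.

What the generator does **not** emulate: probe physical extent (a fosmid
decorates tens of kb of chromatin), deconvolution and SIM-reconstruction
artifacts, chromatic aberration (a rigid registration offset can be
supplied at pairing, never estimated), nuclear segmentation, and optical
effects beyond a Gaussian PSF. Passing tests therefore show that the
quantification recovers truth under this stylised imaging model, not that
it would on any particular microscope.

## Spot quantification

Detection band-passes the stack with a difference of Gaussians at the
expected spot scale (surround ratio 1.6 — kept tight deliberately: a wide
surround widens the passband toward the low frequencies where the
structured background lives), normalises to robust SNR units
(median/MAD), keeps 26-neighbourhood local maxima above `min_snr`
(default 6), applies non-maximum suppression within `min_separation_nm`
(default 400 nm), and refines survivors with a background-subtracted
intensity-weighted centroid over an ellipsoidal neighbourhood
(`refine_radius_nm`, default 2.5 lateral sigmas). Two exclusion rules
mirror what an analyst does: spots below a fraction
(`min_rel_intensity`, default 0.25) of the brightest spot in the stack
are discarded (the published analyses likewise excluded alleles with weak
probe signals), and pipelines cap detections per channel at the expected
allele count. Channels are paired by mutual nearest neighbour under a
2000 nm gate — far above all reported inter-probe medians (~140–350 nm),
so the gate only prevents pairing across alleles. Losing pairs to
detection is normal and expected at realistic budgets; the published SIM
data likewise measured both alleles in fewer than half of the cells.

## Distance statistics

All statistics run on a flat per-allele table (tissue, stage, modality,
section, nucleus, allele, `d_nm`):

* binned distributions in 200-nm half-open bins, proportions pooled over
  alleles;
* the error bar convention follows the published figures: s.e.m. is the
  sd of per-**section** proportions divided by the square root of the
  number of sections (undefined, reported `NA`, for a single section),
  while pooled point estimates weight alleles;
* per-cell categories (`both` / `one` / `none` colocalised alleles) over
  nuclei with exactly two measured alleles, others excluded and counted;
* boxplot summaries with whiskers at the 2.5/97.5 percentiles ("95%
  range", not 1.5 IQR) and type-7 linear-interpolation quantiles;
* Fisher's exact test on pooled colocalised/not allele counts
  (two-sided by the minimum-likelihood rule, the common convention —
  documented because the doubling rule differs; a zero-margin table is
  defined as p = 1) and the Mann–Whitney U test on raw distances (exact
  by enumeration when the pooled sample is at most 20 without ties,
  otherwise normal approximation with tie and continuity corrections).
  Whether the published Fisher tests pooled alleles across sections is
  not stated; pooled-allele counts are used here.
* No multiple-testing correction is applied anywhere: the readouts are
  raw pairwise p-values, as in the source figures.

## The 5C model

Restriction digestion (`digest_sequence()`, HindIII `A^AGCTT` by default)
tiles a region into fragments; `assign_primers()` marks fragments of
100 bp–20 kb eligible (repeat masking is an input, never recomputed) and
assigns alternating forward/reverse orientations starting with reverse,
so the counts split at worst one apart — the published 365-primer design
splits 182/183. Only forward x reverse pairs carry counts; F x F and
R x R are structurally absent, as the alternating 5C chemistry implies.

The count generator places expected intensity
`lambda(i,j) ∝ |mid_i − mid_j|^(−decay_exponent)` (default exponent 1),
multiplied by `inter_domain_factor` (default 0.3) for **each** domain
boundary a pair straddles and by the enrichment fold over declared peak
pairs, then draws one multinomial of `total_reads` (default 10^6) over
all F x R pairs, so counts conserve the total exactly. The default region
mirrors the studied landscape: ~1.7 Mb with two boundaries partitioning
it into three domains, the middle one containing a gene–enhancer peak
pair at fold 3 ("somewhat enriched").

Processing follows the published description exactly: normalised
frequency is raw count / total reads x 10^3; binning tiles the region
with non-overlapping 28-kb windows anchored at the region start (the
terminal window may be partial; window overlap is not specified in the
source, so non-overlapping windows are used and documented); a window
pair's value is the arithmetic mean over contributing fragment pairs, and
empty window pairs are `NA` — missing is never silently zero, in memory
or in any file format. "Total reads" is taken as the grand sum of used
reads when not supplied. Virtual 4C extracts the binned row(s) of a
viewpoint with the self-window masked.

Insulation scores average the window-pair square crossing each window
(`flank_windows` = 3 on each side). A boundary call requires a strict
local minimum below `mean − 1 sd` of scores **and** below 0.7 x the
median score. The depth requirement is this package's addition: on a
homogeneous decay-only matrix sampled at finite reads, scores fluctuate a
few percent and the mean−1 sd rule alone would flag noise minima; a 30%
depth is far outside that fluctuation but far shallower than a real
domain boundary at the default attenuation. All three parameters are
configurable.

## Reproducibility and numerics

Every stochastic entry point takes one integer seed and reseeds R's RNG
on entry, so identical configuration gives bit-identical truth tables,
stacks, counts and output files; numeric columns are serialised with 17
significant digits so TSV round-trips are exact. Quantile convention,
tie-breaks (pairing ties broken by distance then channel-1 index;
detection ties by filtered intensity then voxel order) and degenerate
inputs (empty datasets, zero margins, uniform images, zero totals) are
all pinned by tests. Scales in the test-suite experiments (120 alleles
per group, 50-seed properties, 10^5-read matrices) match the published
problem sizes where those are stated, and otherwise were chosen as
representative desk-scale sizes.

## Known limitations

* The distance mixture is a stand-in for unpublished per-tissue
  distributions; only its 200-nm mass is anchored.
* The imaging arm is a stylised widefield/SIM contrast; absolute measured
  medians depend on the calibrated photon budget.
* Insulation boundary detection is a deliberately simple operationalisation
  of domains that were identified visually in the source; it is not a
  general TAD caller and is not compared against external Hi-C calls.
* The nucleus/section hierarchy is respected only through the
  across-section s.e.m.; no mixed-effects modelling.
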