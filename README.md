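# chromprox

Quantitative machinery for deciding whether a gene and a distal enhancer
colocalise in nuclei — the question at the heart of long-range
transcriptional regulation, where an enhancer hundreds of kb to ~1 Mb away
(like a limb enhancer acting on its developmental gene across a gene
desert) must find its promoter in 3D nuclear space.

The package implements the two complementary readouts used for that
question, each driven by a ground-truthed synthetic-data generator so
every stage is testable offline:

**3D FISH quantification.** Two-colour probe pairs mark the gene and the
enhancer in nuclei. `chromprox` simulates per-nucleus image stacks
(anisotropic Gaussian PSFs for conventional widefield and
structured-illumination modalities; Poisson photon noise, read noise and
structured nuclear background), detects spots by band-pass filtering and
robust SNR thresholding, localises centroids at sub-voxel precision,
pairs channels by mutual nearest neighbour, and computes inter-probe
distances *d* in nm. Statistics follow the field's conventions:

* distance classes — colocalised (*d* < 200 nm), adjacent
  (200 ≤ *d* < 400 nm), separate (*d* ≥ 400 nm);
* 200-nm binned frequency distributions and colocalisation frequencies
  with s.e.m. across tissue sections;
* per-cell allele categories (both / one / none colocalised);
* boxplot summaries (median, IQR, whiskers at the 2.5/97.5 percentiles);
* two-sided Fisher's exact tests on colocalised counts and Mann–Whitney
  *U* tests on distances.

**5C contact-map processing.** Chromosome conformation capture carbon
copy measures ligation frequencies between forward- and reverse-primed
restriction fragments. `chromprox` digests sequence (HindIII, `A^AGCTT`),
assigns alternating F/R primers to fragments of 100 bp–20 kb, simulates
multinomial contact counts with power-law distance decay
λ(i,j) ∝ |mid_i − mid_j|^(−α), interaction-domain attenuation and
enriched peak pairs, then normalises (raw/total × 10³), bins over 28-kb
windows (mean per window pair; missing is `NA`, never zero), extracts
virtual-4C viewpoint tracks, and calls insulation-score domain
boundaries.

## Worked example

Simulate an expressing-tissue group (true colocalised fraction 0.79) and
a non-expressing group (0.25), image them, and run the statistics:

```r
library(chromprox)

cfg <- default_run_config(seed = 1)
cfg$fish$groups <- list(
  zpa             = list(coloc_fraction = 0.79, n_nuclei = 30, n_sections = 2),
  distal_anterior = list(coloc_fraction = 0.25, n_nuclei = 30, n_sections = 2))
res <- run_fish_pipeline(cfg, out_dir = "fish_out")
res$frequencies
#>             group proportion        sem n_alleles n_sections
#> 1             zpa  0.5277778 0.08125000        36          2
#> 2 distal_anterior  0.2187500 0.01012146        32          2
res$comparisons[res$comparisons$test == "fisher_exact", ]
#>   group1          group2         test statistic         p
#> 1    zpa distal_anterior fisher_exact        NA 0.0124492
```

The measured proportions sit below the true fractions (0.79 / 0.25)
because conventional-widefield imaging is lossy and noisy — that is the
point of simulating it; the group contrast and its Fisher p-value are
what the analysis reads out, and some alleles are lost to the detection
filters (36 + 32 measured of 60 + 60 simulated). The 5C arm:

```r
c5 <- run_5c_pipeline(cfg, out_dir = "c5_out")
c5$boundaries
#>   window    start      end       score
#> 1     13 28653086 28681086 0.008940865
#> 2     57 29885086 29913086 0.009361772
head(c5$tracks$gene, 3)   # virtual 4C from the gene viewpoint
#>   chrom    start      end       value
#> 1  chr5 28317086 28345086 0.002233333
#> 2  chr5 28345086 28373086 0.002028571
#> 3  chr5 28373086 28401086 0.002342857
```

The two insulation minima flank the middle interaction domain: the
simulated boundaries at 28.65 and 29.90 Mb fall in windows 12–13 and 57
of the 28-kb grid.

All outputs are plain text (TSV / BED / BEDPE / bedGraph / multi-page
TIFF), written deterministically: the same config and seed give
byte-identical files.

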