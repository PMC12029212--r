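# nuclocale

Nuclear genome organization is usually summarized along a single radial
axis or as a binary active/inactive division. `nuclocale` implements
the analysis toolkit for a richer view: mapping and classifying the
genome *relative to three nuclear locales* — nuclear speckles (SON
TSA-seq), the nuclear lamina (LMNB1 TSA-seq and DamID), and nucleoli
(MKI67IP TSA-seq) — and relating changes in locale proximity to gene
expression and DNA replication timing. It is written for computational
genomicists working with binned TSA-seq/DamID/Repli-seq tracks and for
imaging groups working with segmented nuclei and chromatin-tracing
probe tables.

The package provides, as tested and reusable components:

* **Speckle TSA-seq peak calling** — LOESS smoothing (span), a local
  maximum filter (window half-width *w*), retention of apexes showing a
  strict reduction in value off the apex, replicate-agreement grid
  search over (span, *w*), and Type I/II classification by Hi-C
  subcompartment overlap (A1 → I, A2/B1 → II).
* **LAD segmentation and the three-class facultative scheme** — a
  2-state Gaussian HMM on lamina DamID (positive state = LAD), a
  cross-cell-type consensus (union of LADs in ≥ 1 cell type), and
  per-cell-type classification of facultative iLADs into
  peak-within-valley (p-w-v) versus valley (v) fiLADs by local
  enrichment relative to the 5th percentile of the LAD enrichment
  distribution; plus the cLAD score (bins counted by the number of
  cell lines, up to 7, calling them LAD).
* **Scatter-space classifiers** — the H1 off-diagonal ROI lines
  (`LMNB1 < -1.5*SON - 1.3`, C2 below `-1.5*SON - 2.2`), C1–C4 LAD
  quadrants centered at (−3.0, 0.25), equatorial vs non-equatorial LAD
  clusters (LMNB1 > 0.75 / SON < 0.98), and count-thresholded 2D
  overlay histograms (pixels shown at ≥ 10 genomic bins).
* **Replication timing** — E/L log-ratios, 16-fraction Trep/Twidth by
  cumulative interpolation, initiation-zone calling on the earliness
  track, and quartile IZ timing classes.
* **Function linkage** — per-gene z-normalized TSA-seq deltas with
  `log2((FPKM+1)/(FPKM+1))` expression changes, rank-checked OLS with
  classical CIs, speckle association fractions (< 250 nm), and
  Hartigan's dip test with seeded Monte-Carlo p-values.
* **3D geometry** — locale mask morphology (V, SA by marching
  tetrahedra, SA/V, 26-connected components), asymmetric
  surface-to-surface locale distances, tyramide-diffusion simulation
  (kernel `B·exp(-R·d)`, B = 5.86, R = 3 µm⁻¹), PCA-based nucleus
  normalization into a 4×2×1 cuboid, equatorial-polarity metrics, and
  centromere distances from cytoband annotations.
* **Synthetic data with planted truth** for every stage: DamID tracks
  with planted domain classes and AR(1) noise, replicated TSA-seq
  tracks with planted peaks, Repli-seq profiles with known Trep/Twidth,
  and voxelized nuclei (round ellipsoids or flat adherent discs) with
  locale masks and polarity-biased probe clouds.

## Worked example

Plant 20 speckle peaks (amplitude/noise = 3) on a 100 Mb chromosome,
optimize the caller on two synthetic replicates, and score recovery:

```r
library(nuclocale)

spec <- genome_spec(c(chr1 = 1e8), bin_size = 25000, seed = 42)
apex_bins <- seq(100, 3900, length.out = 20)
pk <- planted_peaks("chr1", (apex_bins - 0.5) * 25000,
                    amplitude = 3, width_bp = 1.5e5)
reps <- make_tsa_replicates(spec, pk, rep_noise_sd = 1, n_reps = 2)

opt <- optimize_parameters(reps[[1]], reps[[2]],
                           span_grid = c(0.003, 0.006),
                           w_grid = c(15, 40, 100))
#> selected span: 0.006  w: 100  agreement: 0.739

peaks <- call_peaks(reps[[1]], opt$span, opt$w)
head(peaks[, c("chrom", "apex_bin", "apex_bp", "score")], 4)
#>   chrom apex_bin  apex_bp    score
#> 1  chr1      100  2487500 2.962779
#> 2  chr1      300  7487500 2.799359
#> 3  chr1      500 12487500 2.195052
#> 4  chr1      702 17537500 2.298412
```

All 20 calls land within ±2 bins of a planted apex (sensitivity 1,
precision 1): the agreement search selects the widest window because
noise maxima do not reproduce between replicates. The smoothed apex
scores (~2.2–3.0) sit below the planted amplitude 3 by the smoothing
attenuation.

The LAD/fiLAD pipeline runs the same way from planted truth:

```r
g <- make_class_genome(genome_spec(c(chr1 = 5e7, chr2 = 5e7), seed = 42))
lads <- lapply(g$tracks, call_lads_hmm)
cls <- classify_consensus(build_consensus(lads), g$tracks)
table(cls$A$label)
#>       LAD pwv_fiLAD   v_fiLAD
#>        73         5        12
evaluate_class_recovery(g$truth, cls)$accuracy
#> [1] 0.967033
```

and the replication-timing round trip is exact to interpolation error:

```r
trep_twidth(make_repli_profiles(c(0.2, 0.5, 0.8), c(0.1, 0.1, 0.1)))
#>    trep twidth
#> 1 0.201 0.1035
#> 2 0.500 0.1040
#> 3 0.799 0.1035
```

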