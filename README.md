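# octavasc

Quantification of the retinal microvasculature on en-face optical
coherence tomography angiography (OCTA), with the cohort-level statistics
used to relate those measurements to clinical outcomes in diabetic
retinopathy (DR).

OCTA images blood flow in the superficial capillary plexus without dye. As
retinopathy progresses, capillaries drop out; `octavasc` turns an en-face
flow image into numbers that track that loss, and provides the analysis
layer a reading-centre or research group needs around them. It is aimed at
ophthalmic imaging researchers who have en-face angiograms plus per-eye
clinical tables, and at methodologists who want a fully synthetic,
ground-truthed test bed for OCTA vessel metrics.

## What it computes

**Per image** (`segment_vessels()`, `quantify_image()`): a Frangi-type
multiscale Hessian vesselness filter, Otsu/fixed binarization (hybrid of
enhanced and raw masks by default), separation of large vessels (morphological
opening + constrained reconstruction), topology-preserving Guo–Hall
skeletonization, and a 4-connectivity perimeter map. Within an annulus ROI
(disc: outer 1.375 mm / inner 0.5 mm; macula: inner 0.75 mm) and its
quadrants or sectors, six parameters per region *R* with vessel/skeleton/
perimeter pixel counts V, S, P:

    VAD = V/|R|        vessel area density
    VSD = S/|R|        vessel skeleton density
    VDI = V/S          vessel diameter index (mean calibre, px)
    VPI = P/|R|        vessel perimeter index
    VCI = P^2/(4*pi*V) vessel complexity index
    flux = mean flow intensity over vessel pixels in R

Images are admitted only when the device signal-strength index exceeds 7.

**Per cohort** (`run_analysis()`): Snellen→LogMAR conversion
(`-log10(num/den)`), two-line visual-acuity stability classification,
control-standardized blood-panel z-scores, and OCT×OCTA Spearman
correlation matrices with per-panel Bonferroni correction and
weak/moderate/high strength labels ([0,0.3), [0.3,0.7), [0.7,1] by |rho|).
Group comparisons: exact/approximate Mann-Whitney U, Kruskal-Wallis H,
Pearson chi-square, Welch's t from summary statistics.

**Synthetic data** (`generate_phantom()`, `generate_cohort()`): procedural
vessel-network phantoms with exact ground-truth masks, grade-series
phantoms with monotone capillary dropout, and per-eye cohorts with
published grade-conditional lab/OCT marginals, a configurable latent
coupling between RNFL thickness and disc OCTA metrics, and Snellen-chart
acuity transitions.

## Worked example

```r
library(octavasc)

ph <- generate_phantom(phantom_spec(seed = 1))   # 512 px, 3 mm field
quantify_image(ph$image)
#>   region roi_px   vad    vsd  vdi    vpi   vci  flux
#> 1  whole  37508 0.210 0.0504 4.17 0.0995 140.5 0.667
#> 2      S   9377 0.215 0.0505 4.24 0.1024  36.5 0.667
#> 3      N   9377 0.207 0.0502 4.12 0.1004  36.3 0.666
#> 4      I   9377 0.179 0.0435 4.11 0.0809  27.3 0.672
#> 5      T   9377 0.241 0.0573 4.20 0.1143  40.5 0.663
```

One row for the whole peripapillary annulus plus one per quadrant
(superior, nasal, inferior, temporal). About 21% of the annulus is
capillary (`vad`), mean capillary calibre is ~4.2 px (`vdi`), and the
complexity index is high, as expected for a dense branching network; `flux`
is the mean normalized flow signal inside vessels. Large vessels are
removed before all six metrics.

```r
cfg <- run_config(synthetic = TRUE, output_dir = "reports", seed = 1)
res <- run_analysis(cfg)
res$summary$pct_dm_stable            # 93.58  (% diabetic eyes VA-stable)
res$summary$pct_ctrl_best_va_baseline # 90.53 (% controls at 20/20-20/30)
res$summary$n_significant_disc       # 75 disc cells significant after
res$summary$n_significant_macula     # 1  Bonferroni; macula ~ none
```

The synthetic cohort reproduces the qualitative clinical picture: most
diabetic eyes hold their acuity over follow-up, and RNFL thickness
correlates with disc OCTA metrics (through the configured latent coupling)
but not with macular metrics. `reports/` receives the CSV tables, heat-map
PNGs and a JSON summary.

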