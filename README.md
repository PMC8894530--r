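# zirconomics

Noise robustness of radiomic features from low-count immuno-PET.

## The problem

89Zr-labelled monoclonal-antibody PET (89Zr-immuno-PET) is acquired at very
low photon counts: 89Zr emits positrons in only ~23% of decays, and its
78-hour half-life forces injected activities around 37 MBq, decayed to
roughly 8–20 MBq by the time of scanning several days post-injection. The
resulting images are noisy, and radiomic features — the hundreds of
intensity, histogram and texture descriptors used to quantify tumour
heterogeneity — inherit that noise as **variability** (imprecision between
statistically identical acquisitions) and **bias** (systematic drift away
from full-count values). Before any feature can serve as a biomarker in
this regime, one needs to know which features are robust to counting noise.

`zirconomics` implements the complete count-splitting analysis for this
question, usable by imaging scientists without access to raw list-mode
data:

* a **phantom module** simulating multi-patient scans with Poisson-limited
  counts and *count-split replicates*: binomial thinning of the voxelwise
  counts produces two independent images at 50% counts (S50p), and thinning
  again produces four at 25% (S25p) — the image-domain statistical
  equivalent of separating alternate list-mode events;
* an **IBSI-style radiomics engine**: SUV conversion, isotropic 2 mm
  resampling, fixed-bin-width discretisation at 0.25 SUV, and 458 features
  in ten families (local intensity, intensity statistics, intensity
  histogram, intensity-volume histogram, GLCM, GLRLM, GLSZM, GLDZM, NGTDM,
  NGLDM across their 2-D/2.5-D/3-D aggregations);
* a **robustness module**: per feature and noise level, precision as the
  two-way absolute-agreement single-measurement intraclass correlation
  coefficient,

  `ICC = (MSR − MSE) / (MSR + (k−1) MSE + (k/n)(MSC − MSE))`,

  and accuracy as the similarity distance metric across the m replicates,

  `SDM = (1/m) Σ_j σ_f² / ((1/n) Σ_i (f_i − r_ij)² + σ_f²)`,

  both computed under lesion subsampling (100 iterations, ≤ 3 lesions per
  patient, percentile 95% CIs), categorised as poor / moderate / good /
  excellent at cut-offs 0.5 / 0.75 / 0.9, with Fisher's exact test
  comparing the category distributions between S50p and S25p at α = 0.01.

## Worked example

Simulate one patient with a single textured 6.9 ml lesion, build the
count-split replicates, and extract features:

```r
library(zirconomics)

sp <- phantomSpec(lesions = list(
  lesionSpec(centre = c(0, 0, 0), radii = c(12, 11, 13), contrast = 6)))
ds <- buildDataset(list(sp), seed = 7)
ds
#> PhantomDataset: 1 patients, 7 images, master seed 7

p  <- patients(ds)[[1]]
fv <- extractAllFeatures(p$scans$full, p$masks[[1]], p$meta)
round(fv[c("stat.mean", "loc.peak_local", "ih.entropy",
           "glcm.contrast.3d_mrg", "glszm.zone_percentage.3d")], 3)
#>                stat.mean           loc.peak_local               ih.entropy
#>                    4.279                    5.327                    3.706
#>     glcm.contrast.3d_mrg glszm.zone_percentage.3d
#>                    5.725                    0.139
```

The lesion was generated at contrast 6 on a SUV-1 background; after the
7 mm PSF the mean lesion SUV is 4.28 with a local intensity peak of 5.33.
`ih.entropy` of 3.7 bits and a GLCM contrast of 5.7 reflect the correlated
uptake texture plus Poisson noise. The same feature on the two half-count
replicates shows the noise-induced wobble the robustness analysis
quantifies:

```r
sapply(c("s50p_1", "s50p_2"), function(r)
  extractAllFeatures(p$scans[[r]], p$masks[[1]], p$meta)["glcm.contrast.3d_mrg"])
#> s50p_1.glcm.contrast.3d_mrg s50p_2.glcm.contrast.3d_mrg
#>                       6.808                       6.506
```

The full study — several patients, robustness tables, per-family category
percentages, Fisher comparisons, a markdown report — runs from a config:

```r
out <- runPipeline(defaultRunConfig(), outDir = "run1")
```

or from the shell via the thin CLI shipped in `inst/cli/`:

```sh
Rscript inst/cli/zirconomics run-all --out run1 --seed 1
```

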