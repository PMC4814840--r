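# specell

Label-free, quantitative cell phenotyping from multispectral
autofluorescence microscopy.

Endogenous fluorophores (NAD(P)H, flavins, retinoids, porphyrins)
make every cell intrinsically fluorescent. A simple multispectral
upgrade of a wide-field microscope — excitation stepped through
10 nm bands between ~334 and 495 nm, emission collected at
450–700 nm — records a spectrum at every pixel, and that is enough to
distinguish cell groups, track differentiation, and find hidden
subpopulations without any stain or label. `specell` is an R package
for the whole analysis chain behind that idea, aimed at microscopists
and computational biologists working with hyperspectral
autofluorescence stacks.

## What it does

Each cell is represented by a feature vector in a space *V* spanned
by mathematically defined features: mean channel intensities,
excitation band ratios (e.g. the 360 nm/460 nm redox surrogate for
the NADH/flavin balance), statistics of per-pixel PCA scores, channel
correlations, spectral-angle variation, co-occurrence texture and
morphology. Cell populations are clusters of vectors in *V*, analysed
with data-dependent linear operators:

* **PCA** — the unitary rotation onto covariance eigenvectors
  ("canonical variables"); top-3 scores also drive false-colour RGB
  renderings of stacks.
* **LDA** — canonical discriminant variables from the
  `Sw⁻¹Sb` eigenproblem: `n − 1` axes for `n` groups, fitted after
  standardisation and PCA decorrelation with shrinkage `Sw ← (1−λ)Sw +
  λ diag(Sw)`.
* **TPP** — targeted projection pursuit: an orthonormal basis whose
  projection matches a user-supplied target configuration up to
  per-axis scale (orthogonal Procrustes + Stiefel refinement).
* **Hypothesis testing** — two groups are projected onto the single
  optimised discriminant direction and compared with the two-sample
  Kolmogorov–Smirnov test (significance at p < 0.05; split-sample
  mode for a calibrated test).
* **Classification** — linear / quadratic / naive-Bayes Gaussian
  discriminants with leave-one-out cross-validated ROC/AUROC, and the
  three-dataset scheme (select features on dataset 1, train on 2,
  test on 3).
* **Unmixing** — nonnegative matrix factorisation of pixel spectra
  into endmember spectra and abundance maps, plus spectral similarity
  and co-localisation measures.
* **Subpopulations** — silhouette-selected k-means with a
  Gaussian-null calibration, then LDA projection of the discovered
  clusters.
* **Synthetic scenes** — a generator with full ground truth (cells,
  abundances, noiseless expectation) so every stage is testable
  without microscope data.

Stacks travel as multi-page TIFF + YAML channel sidecar; feature
tables are tibbles; fitted objects have `tidy()`/`glance()`/
`autoplot()` methods. A thin CLI (`inst/cli/specell`) exposes the
stages as subcommands (`simulate`, `denoise`, `segment`, `features`,
`test-groups`, `classify`, `run`, ...).

## Worked example

Simulate a two-group field (24 cells whose dominant endmembers are
swapped between groups), run the pipeline, and test the groups:

```r
library(specell)
library(dplyr)

scene <- synth_scene(
  seed = 42, image_size = c(128, 128), n_cells = 24,
  cell_radius_px = c(4.5, 6.5),
  group_abundance_profiles = list(
    control = list(mean = c(1, 0.4, 0.2), sd = 0.05),
    treated = list(mean = c(0.2, 0.4, 1), sd = 0.05)))
truth <- render_scene(scene)

stack <- truth$stack |> subtract_background() |> denoise_stack()
seg   <- segment_cells(stack)
seg
#> <segmentation> 24 cells (min area 50 px), 0 border-touching

feats <- extract_features(stack, seg)          # default18 registry
gt <- truth$labels[cbind(round(seg$cells$centroid_row),
                         round(seg$cells$centroid_col))]
feats$group <- truth$cells$group[gt[match(feats$cell_id,
                                          seg$cells$cell_id)]]

feats |> group_by(group) |>
  summarise(ratio_360_460 = mean(ratio_360_460),
            pc1_variance = mean(pc1_variance))
#> # A tibble: 2 × 3
#>   group   ratio_360_460 pc1_variance
#>   <chr>           <dbl>        <dbl>
#> 1 control         2.08         619.
#> 2 treated         0.179         16.8

res <- discriminate_1d(select(feats, -cell_id, -group), feats$group,
                       split = seq_len(nrow(feats)) %% 2 == 0)
c(KS = res$ks_statistic, p = res$p_value)
#>          KS           p
#> 1.000000000 0.002525646
```

The 360/460 band ratio drops ten-fold when the short-wavelength
endmember is swapped out — the treated cells look "flavin-shifted" —
and the held-out 1-D discriminant projection separates the groups
completely (KS D = 1, exact p = 0.0025 at 12 cells per group). A
cross-validated classifier on the same table reaches
`glance(loocv_roc(...))$auroc = 1`.

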