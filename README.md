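# ki67pi

Ki-67 proliferation-index (PI) scoring for H-DAB immunohistochemistry
ROIs, with the reader-concordance statistics used to evaluate automated
scoring against visual assessment, and a synthetic-data generator that
makes the whole pipeline testable without any slide data.

## Who this is for

Pathology image-analysis developers and researchers who need (a) a
transparent, classical (non-learned) Ki-67 quantification pipeline whose
every threshold is inspectable and configurable, and (b) the standard
agreement analytics — pairwise RMSE matrices, Bland–Altman limits of
agreement, agreement rates, error-bracket histograms — for two-round
(unassisted vs AI-assisted) reader studies.

## The method

For an RGB brightfield ROI with resolution `mpp` microns/pixel:

1. **Stain separation.** Per channel, `OD = −log10(I/255)`; the OD vector
   of each pixel is decomposed onto unit haematoxylin and DAB reference
   directions (Ruifrok–Johnston colour deconvolution; configurable),
   negative concentrations clamped to 0.
2. **Nuclear segmentation** on the haematoxylin channel: Otsu (or fixed)
   threshold with strict `>`; exact Euclidean distance transform,
   normalised per image; seeds = local maxima of the distance map (height
   ≥ `min_height`, greedy non-maximum suppression at `min_distance_px`,
   deterministic plateau tie-breaks); marker-controlled watershed by
   priority flooding of the negated distance map; physical size gates
   (default 10–400 µm²) against debris and clumps.
3. **Positivity.** A nucleus is Ki-67 positive iff its mean DAB OD ≥
   `dab_threshold` (default 0.15; 0 reproduces the "any intensity is
   positive" convention).
4. **PI.** Nuclei belong to an ROI by the centroid rule;
   `PI = 100 · n_pos / (n_pos + n_neg)`, undefined (flagged) for an empty
   ROI. Review overlays draw positive contours red, negative blue, the
   ROI outline black.

For a reader study with scores `s_r(i)` over ROIs `i`, discordance between
readers is `RMSE(a,b) = sqrt(mean((s_a − s_b)²))`; a round's discordance
is the mean over reader pairs; the assistance effect is
`100·(pre − post)/pre`; and agreement between two score vectors is
summarised by the Bland–Altman mean difference and limits of agreement
`mean ± 1.96·SD` of the paired differences.

## Worked example

```r
library(ki67pi)

# a synthetic 288x288 H-DAB field: 80 nuclei, 25% truly positive
sim <- simulate_roi_image(simulation_config(n_nuclei = 80,
                                            positive_fraction = 0.25,
                                            seed = 11))
res <- score_image(sim$image)
res$scores[["full-frame"]]
#> <roi_score> 'full-frame': PI 25.0% (20 positive / 80 nuclei, 75.0% negative)

head(res$nuclei[c("label_id", "area_um2", "mean_dab_od", "call")], 4)
#>   label_id area_um2 mean_dab_od     call
#> 1        1    48.00 0.800492551 positive
#> 2        2    49.50 0.006437562 negative
#> 3        3    49.25 0.007099533 negative
#> 4        4    49.25 0.006387879 negative
```

The segmentation found all 80 simulated nuclei and called exactly the 20
rendered with DAB positive: the reported PI equals the generator's ground
truth. A simulated two-round reader study over 88 slides × 5 ROIs:

```r
st  <- simulate_study(88, 5, seed = 20)
tab <- simulate_reader_scores(st$manifest$true_pi, study_reader_models(),
                              ai_scores = st$manifest$true_pi, seed = 21)
rep <- concordance_report(tab, c("P1", "P2", "P3"),
                          c("P1-AI", "P2-AI", "P3-AI"))
rep$rmse_matrix
#>          P1    P2    P3 P1-AI P2-AI P3-AI
#> P1     0.00 13.23 12.51 10.36 10.43 10.35
#> P2    13.23  0.00 11.04  8.01  7.85  8.09
#> P3    12.51 11.04  0.00  8.64  8.91  8.78
#> P1-AI 10.36  8.01  8.64  0.00  2.39  2.52
#> P2-AI 10.43  7.85  8.91  2.39  0.00  2.41
#> P3-AI 10.35  8.09  8.78  2.52  2.41  0.00
rep$reduction_percent
#> 80.1  (mean pairwise discordance 12.26 -> 2.44)
```

Unassisted readers (noise 10 pp plus systematic biases) disagree by
11–13 pp RMSE; once all three anchor on the same AI output (noise
1.8 pp), pairwise discordance collapses to ~2.5 pp — an ~80% reduction.

A command-line surface wraps the same functions
(`system.file("cli/ki67pi.R", package = "ki67pi")`), with `score`,
`stats`, `simulate` and `overlay` subcommands reading PNG/TIFF images,
GeoJSON ROI polygons, CSV score tables and a YAML config.

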