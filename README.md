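# olivemorph

Olive cultivar discrimination from the three-dimensional morphology of the
fruit, its stone and the stone's internal cavity.

X-ray micro-computed tomography resolves, in a single scan, the whole drupe
(prefix `D`), the lignified endocarp or stone (`E`) and the internal stone
cavity (`C`). From segmented volumes one can measure continuous morphometric
traits — volume, surface area, Wadell sphericity, elongation L/W, bilateral
asymmetry, position of the maximum transverse area (MTA), groove count,
lenticel density, rugosity — and derive the discrete UPOV "states of
expression" that variety-distinctness protocols use. `olivemorph` implements
the full analysis chain for this kind of study, parameterized on five
autochthonous Campania cultivars (Ravece, Ortice, Frantoio, Rotondella,
Minucciola), for plant phenotyping researchers and anyone evaluating
morphology-based cultivar authentication:

* **Synthetic data** — per-cultivar trait/note generators built from the
  published group summaries, and seeded voxel *phantoms* (ovoid fruit,
  grooved stone, internal cavity, lenticel surface marks, three Otsu-separable
  gray-level populations) with exact ground truth, so every downstream stage
  is testable without the original scans.
* **Imaging** — hierarchical two-pass Otsu segmentation of
  mesocarp/stone/cavity, 3-D connected components and hole filling (compiled),
  principal-axis alignment with an explicit apex convention, TIFF-stack and
  NRRD volume I/O.
* **Morphometry** — the trait extractors above; surface areas come from a
  marching-tetrahedra triangulated isosurface of the smoothed mask indicator.
* **Statistics** — Tukey–Kramer significant-pair counts (raw data *or*
  printed mean/SE/n summaries), Pearson correlation with p-values, a
  Mahalanobis outlier screen, canonical LDA with leave-one-out
  cross-validation, potency-index predictor ranking, Bhattacharyya varietal
  overlap, and a batch-stratified 70/30 linear-SVM prediction stage.

The two statistics at the core:

* **Bhattacharyya distance / coefficient** between cultivars *v1, v2* in the
  4-D discriminant space (mean vectors μ₁, μ₂; covariances Σ₁, Σ₂;
  Σ = (Σ₁+Σ₂)/2):

  D_B = ⅛ (μ₁−μ₂)ᵀ Σ⁻¹ (μ₁−μ₂) + ½ ln[ det Σ / √(det Σ₁ · det Σ₂) ],
  BhC = exp(−D_B)

  BhC = 1 means identical distributions; small BhC means distinct cultivars.
* **Potency index** of predictor *i*: Σⱼ r²ᵢⱼ λⱼ, the squared structure
  loading of the predictor on each discriminant function weighted by the
  function's eigenvalue — a composite importance score.

All user-facing functions take a data frame first and return tibbles, so
analyses chain with the pipe; fitted objects have `tidy()`, `glance()` and
`autoplot()` methods.

## Worked example

```r
library(olivemorph)

run <- run_pipeline(run_config(seed = 1))
print(run)
#> <olive_run> seed 1, 121 olives
#>   LDA overall: D+E+C 86.0, D+E 88.4, D 72.7, E 78.5, C 71.9%
#>   SVM train 100.0% / validation 62.2%

head(run$tukey, 4)
#>   trait          n_significant
#> 1 D_Volume                   6
#> 2 D_Surface_area             6
#> 3 D_Sphericity               5
#> 4 D_L_W                      6

glance(run$lda[["D+E+C"]]$overlap)
#>   average_BhC max_pair      max_BhC min_pair              min_BhC
#> 1       0.104 Ravece-Ortice   0.500 Ortice-Minucciola 0.000000887

head(run$potency, 3)
#>   predictor potency  rank
#> 1 D_Volume     1.59     1
#> 2 D_Weight     1.54     2
#> 3 C_Sphericity 1.52     3
```

One seeded run of the full synthetic pipeline: 121 olives are drawn from the
five cultivar profiles, UPOV notes are derived and merged with simulated
visual notes, the univariate battery reproduces per-trait significant-pair
counts (e.g. 6 of the 10 cultivar pairs differ in whole-fruit volume),
canonical LDA classifies 86% of olives with all compartments (and degrades to
72–79% on single compartments, cavity weakest), Ravece–Ortice shows the
largest pairwise overlap (BhC 0.50) exactly as the most-confusable pair, and
the held-out SVM predicts 62% of the validation olives. `autoplot()` on the
LDA fit, the overlap matrix or the potency ranking draws the standard
figures.

The imaging path works the same way on volumes:

```r
ph    <- generate_drupe_phantom(phantom_spec(groove_count = 4, lenticel_count = 50))
masks <- segment_drupe(ph$volume)
traits <- measure_olive(ph$volume, masks, apex = "+z")  # one tidy row
```

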