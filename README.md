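# footprintr

Quantitative analysis of human and fossil hominin footprints: surface
orientation and landmark depth morphometrics, ensemble-tree body-mass
estimation, gait classification, a subject-level resampling Mahalanobis test
of trackway similarity, and mean-method sex attribution — with a synthetic
footprint generator providing known ground truth for calibration and power
studies.

## The problem

Trace fossils are one of the few direct records of locomotion and group
behaviour in extinct hominins, but extracting biology from a footprint
requires a chain of quantitative steps. Given 3-D models of fossil tracks
and a reference sample of experimentally produced prints from habitually
barefoot modern humans, an ichnologist wants to know:

* **How heavy was the track-maker?** Print size scales with body mass, but a
  single length measurement is a weak predictor.
* **Is the track's shape within the human range?** Depth topography encodes
  foot function — medial weight transfer, toe-off, the longitudinal arch —
  and a trackway whose topography no human sample ever produces implies a
  different gait.
* **What was the composition of the group?** With many trackways on one
  surface, mass predictions support sex attribution and group-structure
  inference.

`footprintr` packages this workflow for biological anthropologists and
ichnologists, together with a generator of synthetic footprint populations
so every statistical property of the pipeline can be demonstrated on data
with known truth.

## Methods at the core

* **Depth morphometrics.** Each print surface is oriented so that the
  least-squares plane *z = ax + by + c* through the undisturbed margin
  becomes the X-Y plane; depths are then measured (positive downward,
  bilinear interpolation) at 14 functionally relevant landmarks: medial and
  lateral heel, medial and lateral midfoot, metatarsal heads 1–5, toes 1–5.
  The forefoot depth gradient — the slope of depth against medial-to-lateral
  position across mt1..mt5 and toe1..toe5 — summarises human-like medial
  weight transfer (negative slope = medial deeper).
* **Body mass.** A bagged ensemble of 500 regression trees predicts mass
  from five dimensions (heel-to-hallux and heel-to-2nd-toe lengths, forefoot
  and heel breadths, mean depth), with per-tree bootstrap bookkeeping
  (in-bag ∪ out-of-bag = training set; for n = 343 the expected unique
  in-bag count n(1−(1−1/n)^n) ≈ 217) and an OOB error estimate. A
  length-only ordinary least-squares regression is the benchmark; trackways
  are predicted from their average print dimensions.
* **Trackway similarity.** For a k-print fossil trackway, the null
  distribution is built by repeatedly (default 10,000×) sampling one human
  subject, drawing k of their prints, averaging the topography and computing
  its Mahalanobis distance √(dᵀS⁻¹d) from the mean of the *remaining*
  subjects' prints. The trackway's own distance from the (gait-matched) pool
  mean is referred to this null: p = (1 + #{null ≥ d}) / (1 + N).
* **Sex attribution.** The mean method: trackways above the mean of the
  non-excluded predicted masses are called male, below female, with
  child-outlier exclusion and per-site composition counts.

See the methods vignette (`vignettes/footprint-analysis.Rmd`) for the model
assumptions, tunable parameters, numerical choices and limitations.

## Worked example

```r
library(footprintr)

# A synthetic reference population: 41 subjects, ~490 prints
cfg <- population_config(seed = 42)
reference <- generate_footprints(generate_population(cfg), cfg)

# Mass model vs length-only benchmark
parts <- split_train_test(reference, seed = 1)
model <- fit_mass_model(parts$train, seed = 2)
evaluate_mass_models(model, fit_length_regression(parts$train), parts$test)
#> Body-mass model evaluation
#>   n train / test: 354 / 148
#>   ensemble test RMSE:     3.21 kg (OOB 2.37 kg)
#>   length-only test RMSE:  6.47 kg

# A 4-trackway fossil site with known (hidden) composition
scenario <- generate_fossil_scenario(n_trackways = 4, prints_per_trackway = 5,
                                     config = cfg, seed = 3)
masses <- sapply(scenario$truth$trackway_id, function(id)
  predict_trackway_mass(model,
    scenario$trackways[scenario$trackways$subject_id == id, ]))
round(masses, 1)
#>  T01  T02  T03  T04
#> 49.4 55.3 50.6 40.7

# Is trackway T01 morphologically within the human range?
clf <- fit_gait_classifier(reference, seed = 4)
tw <- scenario$trackways[scenario$trackways$subject_id == "T01", ]
compare_trackway(tw, reference, gait = predict_gait(clf, tw),
                 n_iterations = 10000, seed = 5)
#> Trackway resampling comparison
#>   gait-matched pool: 248 prints from 41 subjects (walking)
#>   trackway prints: 5   iterations: 10000
#>   Mahalanobis distance: 2.193   null 95th pctile: 2.885
#>   P(null >= distance): 0.3

# Sex attribution by the mean method
att <- attribute_sex(masses)
site_composition(att)
#>   site_id males females excluded trackways
#> 1    site     3       1        0         4
```

The ensemble beats the length-only regression by roughly a factor of two in
test RMSE because two further dimensions (breadths, depth) carry mass
information beyond length. Trackway T01 sits at Mahalanobis distance 2.19
from the average walking footprint — inside the null distribution (p = 0.3),
i.e. indistinguishable from a five-print human trackway. Of the four
trackways, three fall above the assemblage mass mean and are attributed
male; the generating truth for this seed is two males and two females, with
the heaviest female (49.6 kg, predicted 50.6 kg) narrowly above the mean —
the kind of error the mean method is expected to make near the threshold.

`run_pipeline()` chains all stages and writes report tables plus a JSON run
manifest; `inst/cli/footprintr` exposes the same steps as shell subcommands
(`simulate`, `estimate-mass`, `classify-gait`, `compare`, `attribute-sex`,
`pipeline`).

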