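# cmquant

Quantification of cardiomyocyte maturation readouts from imaging and
functional assays, with seeded synthetic-data generators for every input
modality.

## The scientific problem

Pluripotent stem cell-derived cardiomyocytes (PSC-CMs) start out immature,
and assessing how far a culture condition pushes them toward the adult
phenotype requires a panel of quantitative readouts rather than any single
number: sarcomere length and the organization of striations, percent
sarcomere shortening under electrical pacing, calcium-transient kinetics,
mitochondrial respiration, the fraction of binucleated cells, and the
fraction of cells past a maturation-reporter fluorescence gate. `cmquant`
implements one tested estimator per readout:

| Readout | Function(s) | Core idea |
|---|---|---|
| Sarcomere alignment index | `orientation_histogram()`, `alignment_index()` | structure-tensor orientations; mass near ±90° vs the analytic uniform reference (uniform → 1.0, perfect → 4.5) |
| Sarcomere length | `extract_line_profile()`, `estimate_sarcomere_length()` | dominant spectral peak of the line scan, parabolic refinement, explicit `undetermined` below a confidence threshold |
| Percent shortening | `framewise_sarcomere_length()`, `shortening_metrics()` | per-frame spectral length; diastolic = 95th percentile, systolic = mean per-beat minimum |
| Calcium kinetics | `compute_dff()`, `transient_metrics()` | ΔF/F₀; fitted stimulus phase; per-beat offset-exponential decay fit |
| OCR partition | `partition_ocr()`, `group_summary()` | basal / ATP-linked / proton-leak / maximal from four injection phases |
| Morphometry, binucleation | `measure_cells()`, `classify_nuclearity()`, `nuclearity_table()` | corrected chain-code perimeter, moment ellipse axes, majority-overlap nucleus assignment, chi-square |
| Fluorescence gating | `gate_positive()` | rank-based 99.9 % control-quantile gate |

Each estimator has a matching generator (`gen_striated_image()`,
`gen_contraction_movie()`, `gen_calcium_trace()`, `gen_ocr_series()`,
`gen_cell_population()`, `gen_cytometry_sample()`) that emulates the raw
data with known ground truth, so every claim in the test suite is a
parameter-recovery experiment.

## Worked example

A noise-free 5 s movie paced at 1 Hz, contracting from a diastolic
sarcomere length of 2.03 µm to a systolic 1.89 µm:

```r
library(cmquant)

movie <- gen_contraction_movie(2.03, 1.89,
                               trace_spec(duration = 5, dt = 0.02, seed = 1L),
                               pixel_size = 0.1)
trace <- framewise_sarcomere_length(movie$stack, movie$times,
                                    pacing_hz = 1, pixel_size = 0.1)
sm <- shortening_metrics(trace)
sprintf("resting %.3f um, systolic %.3f um, shortening %.2f%% over %d beats",
        sm$resting_length, sm$min_length, sm$percent_shortening, sm$n_beats)
#> "resting 2.030 um, systolic 1.890 um, shortening 6.90% over 5 beats"
```

Sarcomere organization on synthetic striated images, well-organized versus
heavily dispersed:

```r
org <- gen_striated_image(striated_image_spec(spacing = 2,
                                              dispersion_deg = 0, seed = 7L))
alignment_index(orientation_histogram(org$image))$index
#> 4.258826   # 95% of orientation mass within 20 degrees of +/-90

dis <- gen_striated_image(striated_image_spec(spacing = 2,
                                              dispersion_deg = 40, seed = 7L))
alignment_index(orientation_histogram(dis$image))$index
#> 0.8688763  # indistinguishable from random (1.0) or worse
```

Calcium kinetics on one noisy paced trace (truth: time to peak 0.1 s,
amplitude 1.5, decay time 0.15 s × ln 10 = 0.345 s; signal-to-noise 10):

```r
ca <- gen_calcium_trace(trace_spec(noise_sd = 15, seed = 3L))
tm <- transient_metrics(compute_dff(ca$trace, pacing_hz = 1))
tm$summary
#>           metric  mean     sd n_beats
#> 1   time_to_peak 0.106 0.0000      10
#> 2 peak_amplitude 1.600 0.1382      10
#> 3     decay_time 0.360 0.0696      10
```

Single traces carry single-trace noise; across 100 such traces the median
relative error of all three metrics is about 3 % (see
`results/calcium_recovery_medians.csv`).

## Repository layout

* `R/` — the package: estimators, generators, file I/O, and a validated
  stage runner (`run_stage()`) that writes atomic outputs plus a manifest
  of seeds and checksums.
* `analysis/01_simulate.R` … `07_cytometry.R` — numbered drivers that
  generate the synthetic study and write every derived table under
  `results/`.
* `scripts/acceptance.R` — one-shot summary of the headline quantities as
  JSON: `Rscript scripts/acceptance.R --seed 1 --out acceptance.json`.
* `vignettes/cardiomyocyte-maturation-metrics.Rmd` — methods, defaults,
  and the reasoning behind the estimator design choices.
* `tests/testthat/` — unit, property, and end-to-end acceptance tests.

## Requirements

R ≥ 4.1 with `EBImage` (Bioconductor) and `tiff`. Tests additionally use
`testthat`; the acceptance script uses `jsonlite`.
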