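# pepscreen

Robust detection of reactive peptides from peptide microarray scans.

Peptide microarrays screen an antibody repertoire against thousands of
printed peptides at once. The per-peptide question is binary — did the
sample react? — but raw spot intensities are dominated by nuisance
structure: print-needle and subarray offsets, spatial incubation
gradients along slide rows and columns, spot-level artifacts, and
peptides that bind the dye-coupled secondary antibody regardless of the
sample. `pepscreen` removes each of these in turn:

1. **GPR I/O** — reads and writes GenePix Result (ATF 1.0) files
   bit-exactly, joins incubation and label-free scatterlight scans
   (`read_gpr`, `write_gpr`, `join_scans`).
2. **Normalization** — binary-log transform, then a linear effects
   model `log2(intensity) = peptide + subarray + needle + row + column`
   fitted on dedicated control peptides only and subtracted from every
   spot (`normalize_slide`, `fit_effects_model`, `correct_effects`).
3. **Spot quality control** (optional) — a random forest trained on
   replicate-regression prediction-band labels flags unreliable spots
   from quantification and scatterlight features (`band_label`,
   `train_reliability_classifier`); replicates are aggregated with
   reliability weights (`aggregate_replicates`).
4. **Secondary-binder exclusion** — a two-component Gaussian mixture
   fitted on a sample-free (empty) slide identifies peptides that react
   with the detection antibody alone; they are excluded per print batch
   (`detect_secondary_binders`, `em_fit`).
5. **Signal calling** — on sample slides, a peptide is called reactive
   when the probability that the fitted noise component produces its
   intensity is below α = 0.05 (`call_signals`, `exceedance_prob`).
6. **Evaluation** — sensitivity/specificity/accuracy against a truth
   assignment with bootstrap confidence intervals (`evaluate_calls`,
   `bootstrap_ci`), plus a fully ground-truthed synthetic slide
   generator (`generate_experiment`).

The model and defaults are described in `vignettes/methods.Rmd`.

## Worked example

Generate a synthetic six-slide study (two print batches, each with one
empty, one low- and one high-concentration spike-in slide) and analyze
it end to end:

```r
library(pepscreen)

ex_dir <- file.path(tempdir(), "pepscreen-demo")
generate_experiment(generator_params(seed = 1), dir = ex_dir)

truth <- read.delim(file.path(ex_dir, "truth_peptides.tsv"))
truth <- truth[!is.na(truth$truth), c("peptide_id", "truth")]

bundle <- run_pipeline(list(
  manifest   = file.path(ex_dir, "manifest.csv"),
  annotation = file.path(ex_dir, "control_annotation.csv"),
  truth      = truth,
  bootstrap  = list(B = 500, seed = 1),
  out_dir    = file.path(ex_dir, "results")))
#> reading slide array1 (empty)
#> ...
#> batch 1: 342 peptide(s) excluded as secondary binders
#> batch 2: 349 peptide(s) excluded as secondary binders
#> slide array2: 266 reactive peptide(s) called
#> slide array3: 441 reactive peptide(s) called
#> ...

head(bundle$calls[["array3"]], 3)
#>    peptide_id    class normalized_intensity secondary_binder        p_hat reactive excluded_reason
#> 1 CTRL_NEG_01 negative             9.841539            FALSE 1.663906e-01    FALSE            <NA>
#> 2 CTRL_NEG_02 negative             9.311900            FALSE 5.094453e-01    FALSE            <NA>
#> 3 CTRL_POS_01 positive            13.514873            FALSE 2.080123e-15     TRUE            <NA>

bundle$evaluations[["array3"]]$metrics   # high-concentration slide
#> tp=199 fp=3 tn=159 fn=0 | sensitivity=1.000 specificity=0.981 accuracy=0.992

m <- bundle$evaluations[["array2"]]$metrics  # low-concentration slide
ci <- bundle$evaluations[["array2"]]$ci$sensitivity
sprintf("low-spike sensitivity %.3f [%.3f, %.3f], specificity %.3f",
        m$sensitivity, ci$lower, ci$upper, m$specificity)
#> "low-spike sensitivity 0.729 [0.666, 0.794], specificity 1.000"

variance_reduction(bundle$slides[["array1"]]$model)
#> 0.8446933   # fraction of control variance explained by position effects
```

`out_dir` receives one ANOVA TSV per slide, one call table per sample
slide, mixture-fit and evaluation JSON, and the run log. The same
workflow is available from the command line:

```sh
exec/pepscreen simulate --seed 1 --out demo/
exec/pepscreen run --config config.yaml   # see ?run_pipeline for the format
```

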