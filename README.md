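# phosphoDIA

In silico spectral libraries and error control for DIA
phosphoproteomics, in R.

Peptide-centric analysis of data-independent acquisition (DIA)
phosphoproteome data needs a spectral library — per precursor, a set of
annotated fragment m/z–intensity pairs plus an indexed retention time
(iRT). Building that library experimentally from fractionated DDA runs
costs weeks of instrument time and sample. phosphoDIA predicts it
instead: it provides, for proteomics researchers and
computational-MS developers,

* a **fragment-intensity model** — embedding → bidirectional LSTM →
  Transformer encoder → per-position linear regressor — that maps a
  modified phosphopeptide `[x0, x1..xn, +q]` to an L×8 intensity matrix
  over the channels {b, y} × {+1, +2} × {no loss, −H3PO4}, with
  impossible channels (fragment absent, or neutral loss without a
  phosphosite in the fragment) held at the sentinel −1, excluded from
  the masked-MSE loss and filtered from predictions;
* an **iRT model** — the same trunk with an ensemble of encoder depths
  4–8 and softmax-weighted position pooling — trained with RMSE on
  RT normalized by a fixed (−100, 200) window, evaluated by
  Δt95% = 2·|z−ẑ|₍₉₅%₎;
* the **library engineering** around them: tryptic in silico digestion
  with phosphosite-driven peptide enumeration, predicted / hybrid /
  focused / reverse-decoy / two-species entrapment libraries,
  parameter-grid screening, iRT calibration, and Spectronaut-style TSV
  I/O;
* the **error-control calculators**: reverse-decoy FDR
  `2·H_rev/(H_orig+H_rev)`, entrapment FDR with library-size and
  1/(1−0.01) normalization, synthetic-peptide FLR, and two-proteome
  quantification statistics (measured ratios, FQR curves, replicate
  %CV);
* a **seeded synthetic-data module** generating every input the stack
  consumes (peptides, learnable ground-truth spectra and retention
  times, identification tables, two-proteome dilution matrices), so
  everything is testable offline.

The models are trained by a small reverse-mode autodiff engine written
in base R for this package (verified against finite differences in the
test suite); no deep-learning runtime is required.

## Worked example

Simulate a 64-precursor cohort, train the reduced models, and build a
predicted library with its reverse-decoy companion:

```r
library(phosphoDIA)

cfg <- synth_config(seed = 7, n_peptides = 64, length_range = c(7, 15),
                    spectrum_noise_sd = 0)
precursors <- gen_peptides(cfg)
spectra    <- gen_ground_truth_spectra(precursors, cfg, L = 15)
rts        <- gen_ground_truth_rt(precursors$modified_peptide, cfg)

ion <- build_ion_model(reduced_ion_config(max_len = 15), seed = 1)
ion <- train_ion_model(
  ion,
  list(peptides = precursors$modified_peptide,
       charges  = precursors$charge,
       targets  = spectra),
  train_config(max_epochs = 100, batch_size = 32,
               learning_rate = 1e-3, eval_every = 25, seed = 1))
ion$val_metric
#> [1] 0.9828978

rt <- build_rt_ensemble(reduced_rt_config(max_len = 15), seed = 1)
rt <- train_rt_ensemble(
  rt, list(peptides = precursors$modified_peptide, rt = rts),
  train_config(max_epochs = 30, batch_size = 32,
               learning_rate = 1e-3, eval_every = 10, seed = 1))

lib <- generate_predicted_library(precursors, ion, rt, library_filters())
lib
#> <SpectralLibrary> 64 precursors, 1466 fragments (predicted)

build_decoy_appended_library(lib, ion, rt, library_filters())
#> <SpectralLibrary> 128 precursors, 2936 fragments (target+decoy)

write_library_tsv(lib, "predicted_library.tsv")
```

`ion$val_metric` is the median per-peptide Pearson correlation between
predicted and ground-truth spectra (best checkpoint on the validation
set — here the training set itself, an overfitting check). The library
print shows precursor and fragment counts by source; the TSV has one
row per fragment (`PrecursorMz`, `ModifiedPeptide` in
`_AS[Phospho (STY)]DK_` notation, `iRT`, `FragmentMz`,
`RelativeIntensity`, `FragmentType/Number/Charge`, `FragmentLossType`,
…) ready for import into a DIA search engine.

The error-control arithmetic operates on search hit counts:

```r
fdr_reverse(hits_original = 990, hits_reverse = 10)
#> [1] 0.02
fdr_entrapment(hits_true = 20000, hits_false = 10,
               libsize_main = 200000, libsize_entrapment = 100000)$fdr
#> [1] 0.001009082
```

A thin command-line front end with `simulate`, `digest`, `build-lib`,
`evaluate` and `fdr` subcommands is installed under
`system.file("cli", "phosphodia", package = "phosphoDIA")`.

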