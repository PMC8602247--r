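---
title: "Models and methods behind phosphoDIA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phosphoDIA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphoDIA)
```

## The problem

Peptide-centric analysis of data-independent acquisition (DIA)
phosphoproteomics needs a spectral library: for every phosphopeptide
precursor, a set of annotated fragment m/z-intensity pairs plus an
indexed retention time (iRT). Building such a library experimentally
(fractionated DDA runs) costs weeks of instrument time. phosphoDIA
instead predicts libraries in silico: two sequence models regress
fragment-ion intensities and iRT directly from the modified peptide
sequence, and a set of library-engineering operations turns those
predictions into search-ready TSV libraries with built-in error
control (reverse-decoy FDR, two-species entrapment FDR, site-level
FLR, and quantification-level FQR).

## Peptide representation

A phosphopeptide is a residue string over the 20 standard amino acids
with three modification types: phospho (S/T/Y), methionine oxidation,
and N-terminal acetylation. The compact text dialect writes one token
per residue, with digits replacing modified residues (`1` = oxidized
M, `2`/`3`/`4` = phospho-S/T/Y) and a leading `*` (acetylated) or `@`
(free N-terminus). The leading marker is defined here to encode
exactly the N-terminal acetyl flag — the alternative reading (any
modification present) would make the marker redundant with the digit
tokens, so we fix the narrower meaning and document it.

The model vocabulary assigns token ids in a fixed, documented order
(alphabetical amino acids, digits `1`-`4`, `*`, `@`, charge tokens
`+1`..`+6`, padding), so checkpoints remain portable across sessions.
The ion model input appends a precursor-charge token; the RT model
input does not. Peptide length is validated to 7–50 by default (a
typical tryptic range); both bounds are arguments.

## The fragment-ion channel space

The ion model's output for a peptide of length $n$ is an $L \times 8$
matrix: row $i$ holds the intensities of fragments $b_i$ and $y_i$ at
charge $+1$ and $+2$, each with and without loss of phosphoric acid
(H3PO4, 97.9769 Da), in the fixed column order b+1/b+2 no-loss,
b+1/b+2 loss, then the same four for y ions. Two structural rules
define which cells can exist:

* rows beyond $n-1$ are impossible (a peptide of length $n$ has
  $n-1$ backbone cleavages), and
* a neutral-loss channel is possible only if the fragment actually
  contains a phosphorylated residue ($b_i$ spans residues $1..i$,
  $y_i$ spans $n-i+1..n$).

Impossible cells carry the sentinel $-1$; possible cells are
normalized to $[0,1]$ against the base peak. The sentinel convention
does double duty: it masks the training loss (no gradient flows into
impossible cells) and it filters predictions (impossible cells are
forced back to $-1$ after the forward pass). Two deliberate
simplifications: a fragment with several phosphosites still loses a
single H3PO4 (the channel space has no multi-loss columns, so
multi-loss is unrepresentable rather than approximated), and $+2$
fragment channels are not additionally masked by precursor charge or
fragment length — only the two rules above are structural; anything
else is left for the model to learn. Both are configurable judgments,
not chemistry claims.

Fragment and precursor m/z use standard monoisotopic b/y arithmetic
with cysteine treated as carbamidomethylated (fixed +57.02146,
toggleable), phospho +79.96633, oxidation +15.99491, and N-terminal
acetyl +42.01057 (contributing to b ions and the precursor). Written
outputs round m/z to 4 decimals; full precision is kept internally.

## Model architecture

Both regressors share a trunk: token embedding, a bidirectional LSTM,
a linear projection, sinusoidal position encoding, and a stack of
post-norm Transformer encoder layers (multi-head self-attention with
key-padding masks, then a two-layer feed-forward block, residual
connections and layer normalization around each).

* **Ion model.** 192-dim amino-acid embedding concatenated with a
  64-dim charge embedding broadcast to every position (the
  architecture leaves the concatenation point open; per-position
  concatenation is the natural choice for a per-position regressor);
  two biLSTM layers of hidden size 512 per direction; the 1024-wide
  bidirectional output is linearly projected to the Transformer width
  `d_model` (default 512 — the reconciliation between the biLSTM
  width and the encoder width is a genuine design gap, and an explicit
  projection is the cleanest fix); eight encoder layers with eight
  heads; a final per-position linear layer maps `d_model` to the 8
  ion channels.
* **RT model.** 256-dim embedding, same trunk, and an *ensemble* of
  encoder stacks of depths 4–8. Each member computes a per-position
  scalar weight, softmax-normalized over non-pad positions
  (normalization of the "instance-specific weight" is unspecified;
  softmax makes the pooled feature a proper convex combination),
  pools the position features by that weight, and maps the pooled
  vector to one scalar. The ensemble prediction is the arithmetic
  mean of member outputs. Because the RT rescaling is affine,
  averaging on the normalized or the rescaled scale is equivalent; we
  average on the normalized scale.

Position encoding is added after the projection (so the encoder sees
it at its own width). Padded positions participate in the recurrences
but are masked out of attention keys, pooling, and the loss; the pad
token has its own learned embedding.

The models are trained by a small reverse-mode automatic
differentiation engine written for this package (dense-matrix tape
with explicit backward rules for each primitive, verified against
finite differences in the test suite) and Adam. No external deep
learning runtime is required.

## Training

* **Losses.** Masked mean squared error over target-valid cells for
  the ion task; root mean squared error on normalized RT for the RT
  task.
* **Normalization.** RT targets map to $z = (RT - rt_{min}) /
  (rt_{max} - rt_{min})$ with a deliberately wide fixed window
  $(-100, 200)$ in iRT units, so one scale serves any dataset.
* **Schedule.** Adam at learning rate 1e-3 for a first large
  pretraining corpus and 1e-4 otherwise, decayed by 0.1 at milestone
  epochs (default: 2/3 and 5/6 of the epoch budget — the milestones
  are tunable and only their existence, not their placement, is
  prescribed).
* **Splitting.** Train/validation/test at 8:1:1 (9:1 for
  pretraining), grouped by modified sequence so all charge states of
  one peptide land in one split — otherwise charge-state twins leak
  across the boundary and inflate validation metrics.
* **Selection.** The checkpoint with the best validation metric
  (median per-peptide Pearson correlation for the ion task, maximized;
  delta-t95 for RT, minimized) is returned, not the last epoch.
* **Transfer.** Fine-tuning starts from a pretrained checkpoint's
  weights and never touches the pretraining data.

## Evaluation metrics

Per spectrum pair, over the cells valid in the *target's* mask: the
Pearson correlation coefficient, and the normalized spectral angle
$SA = 1 - 2\,\cos^{-1}(\hat{y} \cdot y)/\pi$ with both valid-cell
vectors scaled to unit L2 norm (dot product clamped to $[-1,1]$
against float error; with nonnegative intensities SA cannot be
negative). Cohort summaries are medians over peptides; pairs with
zero variance or zero norm are reported missing and excluded. The
comparison support is all valid cells, including zeros — restricting
to nonzero target cells would reward predictions only where the
instrument happened to record signal, and the choice is centralized
so its sensitivity can be probed.

For RT: the median absolute error (a median, not a mean), the
coefficient of determination of the observed-on-predicted OLS line,
and delta-t95 — twice the 95th-percentile absolute deviation, i.e.
the narrowest window containing 95% of prediction errors. The
percentile is fixed to nearest-rank on the sorted deviations so
reported numbers are bit-stable across platforms; interpolating
definitions would differ in the third digit.

## Digestion and database-driven libraries

Tryptic in silico digestion cleaves C-terminal to K/R. The default
rule suppresses cleavage before proline ("trypsin"); "trypsin/P" is
available because site databases are digested both ways in practice.
Peptides of length 7–30 with no missed cleavage are kept (all
configurable). Registered phosphosites falling inside a peptide are
enumerated as phosphoforms — one site per form by default, all
combinations up to the cap otherwise; unmodified forms are not
emitted, and peptides containing additional unregistered S/T/Y keep
them unmodified. Duplicate sequences from paralogous proteins are
deduplicated by modified sequence with provenance concatenated, and
each unique phosphopeptide is emitted at charges 2/3/4. Initiator
methionine is not specially removed. N-terminal acetylation is not
enumerated by the digestion stack (site tables record phosphosites
only).

## Library engineering

A spectral library is keyed by (modified sequence, charge). The
operations preserve value semantics (inputs are never mutated) and
key uniqueness:

* **Predicted libraries** run both models over a precursor list,
  keep the best `top_n` fragments (default 25) above an intensity
  floor (default 0.05 relative; the floor for predicted libraries is
  a package default, set so that near-zero regression noise does not
  inflate libraries, and can be set to 0) inside a fragment m/z
  window (default 200–2000).
* **Hybrid merge**: union by key; on collision the experimental
  entry wins entirely (spectrum and iRT).
* **Focused libraries** for iterative searching subset
  predicted-source entries to the identified keys; experimental
  entries are kept whole under the hybrid rule (optionally filtered).
* **Reverse decoys** reverse residues 1..n-1 keeping the C-terminal
  residue and charge; modifications travel with their residues; the
  decoy spectrum and iRT are model predictions. Palindromic decoys
  colliding with target keys are dropped and counted rather than
  mutated.
* **Entrapment libraries** concatenate a main-species and a
  foreign-species library, drop cross-species sequence overlaps from
  the entrapment side, and record per-species unique-peptide counts
  for the entrapment FDR.
* **iRT calibration** fits observed RT on predicted iRT by OLS over
  shared peptides and applies the line to the whole library.

TSV serialization writes one row per fragment with
Spectronaut-import-style columns; reading validates the column set
and rejects H3PO4 annotations on fragments that contain no
phosphosite. Identification-table readers exclude entries with
phosphosite localization probability not strictly above 0.75 (class I
sites; the boundary itself is excluded), drop fragment annotations
outside the 8-channel space while keeping the entry, and renormalize
intensities per entry. The MaxQuant/Spectronaut dialects are
best-effort column-subset adapters, not full parsers.

## Error control

* **Reverse-decoy FDR** $= 2\,H_{rev} / (H_{orig} + H_{rev})$.
* **Entrapment FDR**: foreign-species hits are scaled by the
  main-to-entrapment library-size ratio and by $1/(1-0.01)$ to offset
  the search engine's own 1% tolerance; the FDR is the normalized
  false count over (true + normalized false).
* **FLR** on a synthetic-peptide set: false identified sites over all
  identified sites, with the true-site recovery rate reported
  alongside.
* **Quantification**: intensities are de-normalized by their
  normalization factors; measured ratios divide per-condition
  replicate means by control means (a precursor contributes only
  where observed in both); the FQR at threshold $t$ is the fraction
  of (precursor, condition) measurements whose relative error
  $|measured/expected - 1|$ exceeds $t$ — measurement-level counting,
  chosen over peptide-level because it is the finer-grained and
  monotone notion (a log-scale error is available behind a flag);
  replicate CV is $100 \cdot sd/mean$. Missing replicates are
  excluded pairwise, never imputed.

## The synthetic-data generator

Every input the package consumes can be generated with a seed, so the
full stack is testable offline. The generator emulates the
*structure* of phosphoproteome data, not instrument physics:

* peptides of length 7–30 with a mono-phosphosite majority
  (1/2/3 sites with probability 0.70/0.25/0.05), charges mostly 2–3,
  occasional methionine oxidation and N-terminal acetylation;
* a smooth deterministic fragmentation rule (a series- and
  charge-dependent Gaussian bump over relative fragment position,
  neutral-loss channels at a fixed 0.4 fraction of their no-loss
  partner) — intentionally simple so reduced models can learn it on a
  CPU; it is a test harness, not a fragmentation theory;
* an additive retention model (fixed per-residue coefficients plus
  modification offsets, published via `rt_coefficients()`) with
  Gaussian noise — exactly the structure additive iRT regression
  assumes;
* multiplicative lognormal intensity noise (sdlog 0.1 by default,
  about 10% CV — the replicate-reproducibility regime of typical DIA
  data);
* a two-proteome dilution design: a fixed background species and a
  spiked species at expected ratios 0.25/0.5/1.5/2 across four
  conditions against a control, six replicates each.

Consequently, passing the learning checks shows that the models can
fit sequence-determined, smoothly varying targets end to end through
the masking machinery — it does not show that real fragmentation or
chromatography is captured; that requires transfer learning on real
identification tables, for which the same training entry points are
used.

## Problem sizes and numerical choices in the checks

The bundled checks run on one CPU with reduced models (32/16-dim
embeddings, hidden 64, one biLSTM layer, two encoder layers, two
heads — the LSTM depth of the reduced configuration is this package's
choice): overfitting 64 noiseless synthetic precursors of length 7–15
for up to 150 epochs per seed (median training PCC across three
seeds), and RT recovery on 500 peptides (90/10 split, 50 epochs)
against a 10%-of-span delta-t95 bar. Degenerate inputs are defined,
not patched around: zero-variance spectra yield missing correlations,
zero-norm vectors yield missing spectral angles, empty masks are
errors, and peak ties break deterministically by channel order then
fragment number.

## Known limitations

Only b/y ions at +1/+2 with single H3PO4 loss are represented (no
a/c/x/z ions, immonium ions, isotope envelopes, or HPO3 loss); PTMs
beyond phospho/oxidation/N-terminal acetyl are out of scope; I/L are
indistinguishable; the engine is CPU-oriented and unsuitable for
full-scale pretraining; and DIA search engines themselves (XIC
extraction, peptide-centric scoring) are outside the package — the
library TSVs and the error-control calculators are the interface to
them.
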