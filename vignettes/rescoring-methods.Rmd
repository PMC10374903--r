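---
title: "Methods: deep-learning-derived features for PSM rescoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deep-learning-derived features for PSM rescoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msrescore)
```

## The problem

Database search engines score peptide-spectrum matches (PSMs) using only the
presence of fragment ions, not their intensities, and ignore how plausibly a
peptide elutes (retention time, RT) or drifts (ion mobility, IM, as inverse
reduced mobility 1/K0). Deep-learning models predict all three properties per
peptidoform — fragment intensities, one RT on an arbitrary predicted scale
such as iRT, and one 1/K0 value — and comparing prediction with observation
yields features that a semi-supervised rescorer (Percolator) can exploit to
recover identifications near the FDR boundary. This package computes those
features and writes them into extended Percolator pin files; it does not run
the search, the prediction network, or Percolator itself.

## Spectral entropy similarity

For a PSM, each predicted fragment is matched to the highest-intensity
experimental peak within an m/z tolerance (default 20 ppm, the usual search
tolerance; an absolute-Da mode is available). Predicted and experimental
intensities therefore form two vectors of identical length `F` (the number of
predicted fragments), with zeros where no peak fell inside the tolerance.
Both vectors are normalised to unit sum — the entropy functional needs
probability vectors — and with Shannon entropy $S(x) = -\sum_i x_i \ln x_i$
the similarity is

$$ 1 - \frac{2\,S\!\left(\tfrac{P+Q}{2}\right) - S(P) - S(Q)}{\ln 4} \in [0, 1]. $$

It equals 1 exactly when the normalised spectra coincide and 0 when they are
disjoint. Ties between equal-intensity candidate peaks break to the peak
closest in m/z, then to the lower m/z, so matching is deterministic and
independent of peak order. Within a single PSM one experimental peak may
serve several predicted fragments; exclusivity is enforced only *across*
ranks (below). An all-zero experimental vector scores 0 rather than NaN so
that every PSM receives a numeric feature — Percolator cannot ingest
missing values. An optional "correlated features" set (cosine, normalised
dot product, Pearson/Spearman, Bray–Curtis complement, matched count and
fraction) is available but off by default; correlations on constant vectors
are defined as 0.

Only b- and y-ions at fragment charges 1–2 are modelled, the content of the
prediction-library dialects supported (at most 12 fragments per entry in the
default dialect). Neutral losses and other ion series are out of scope.

## Multi-rank DIA processing

DIA scans contain fragments of several co-fragmented peptides, so pin files
may report multiple PSMs per scan (ranks 1..k, with k = 3 for narrow-window
and 5 for conventional DIA). PSMs of one scan are processed in ascending
rank; after each PSM's features are computed, the single selected
experimental peak of every predicted fragment is deleted before the next
rank is matched. Re-using the same peaks across co-fragmented PSMs invites
spurious hits. Two fragments selecting one peak cause exactly one deletion.
An alternative reading — deleting *every* in-tolerance peak rather than the
selected one — would be more aggressive; we remove only the selected peak,
which is the minimal interpretation consistent with "highest-intensity peak
within tolerance". In DDA mode no consumption occurs.

## RT and IM calibration

Experimental RT (minutes) and predicted RT live on different scales, so a
monotone mapping is fitted per spectral file from confident PSMs: rank-1
targets with e-value below `10^-3.5` (a threshold at which decoy matches are
essentially absent), capped at the 5000 lowest e-values. The pipeline does
not assume pin files expose a raw e-value column; the column name and a
transform (`identity`, `pow10_of_negated`, `exp_of_negated`) are
configurable, defaulting to a `log10_evalue`-style column.

The fit is LOESS (degree 1, tricube weights) of predicted on experimental
values at span 0.05 for RT and 0.1 for IM, followed by isotonic regression
(pool-adjacent-violators) of the fitted values at the training abscissae to
enforce monotonicity, then piecewise-linear interpolation between abscissae.
Queries outside the training domain clamp to the boundary values. With fewer
than 50 qualifying PSMs an ordinary least-squares line replaces the LOESS
step. Numerical choices: the effective span is floored at `min(1, 30/n)` so
each local window contains enough points for a degree-1 fit at small n;
duplicate abscissae collapse to the mean isotonic value; the exact-surface
LOESS evaluation is used so results do not depend on interpolation cells.
IM models are fitted per precursor charge, since 1/K0 at fixed m/z shifts
systematically with charge; charges with fewer than 50 confident PSMs fall
back to a model pooled over all charges. Calibration is per spectral file —
chromatography drifts between runs, and fitting globally would blur exactly
the deviations the features measure.

The features are `delta_rt_loess = |mapping(rt_exp) − rt_pred|` (predicted-
scale units) and a normalised variant dividing by the interquartile range of
absolute training residuals. The normaliser is this package's choice of a
robust spread estimate: it makes deltas comparable across runs whose
calibrations differ in quality, which matters most for small inputs (e.g.
few-cell samples) where the raw delta distribution is wide. A zero IQR
(perfect training fit) falls back to the raw delta with a warning. Missing
inputs (scan without RT, entry without prediction) yield a sentinel — a
large constant (default 100) for deltas, 0 for similarities — never NaN.

## KDE probability with a uniform prior

The delta features presume a monotone relationship. A complementary,
shape-free feature asks: *given* the experimental RT, how probable is the
predicted RT? The experimental axis is cut into bins (1 min for RT,
0.01 1/K0 for IM). Each confident PSM adds its predicted value to its bin
with integer multiplicity `w = clamp(floor(−log10 e), 1, 10)` — the idea is
that better-scoring PSMs should weigh more, but there is no canonical
mapping from e-value to multiplicity, so this rule is the package's own
choice and is exposed in the configuration. Each bin receives a Gaussian
KDE with Silverman's rule-of-thumb bandwidth `1.06·σ̂·m^(−1/5)` over the
weight-expanded sample; zero-variance bins get a floor bandwidth of
`0.1 × bin width` to avoid degenerate kernels.

Sparse bins would otherwise hand out inflated densities — a single-PSM bin
evaluates its own kernel at its own mode — so the empirical density
$P_E$ is blended with a uniform prior. Sorting bins ascending by weighted
count, $U$ is the count of the bin at the 10th percentile (nearest-rank,
ties toward the smaller bin), and $P_U = 1/(\text{hi} - \text{lo})$ over the
observed predicted range padded by 1%. The feature for a PSM in a bin with
weighted count $E$ is

$$ \frac{P_U \cdot U}{U + E} + \frac{P_E \cdot E}{U + E}, $$

which returns exactly $P_U$ for an empty bin and converges to $P_E$ as the
bin fills. IM bin sets are built per charge, mirroring the calibration.
Decoy PSMs never contribute to bins (the bins use the same confident target
set as the calibration), though the feature is computed for every PSM.

## Modifications the prediction model cannot see

Peptidoforms are keyed by (sequence, modification set, charge); peptides
differing only in a PTM or charge are distinct entries. When a PSM carries a
modification outside the model's supported set (defaults: carbamidomethyl-C
+57.02146, oxidised M +15.9949, N-terminal acetyl +42.0106), the library is
queried for the peptide without it, and each predicted fragment whose
residue span covers the modified position is shifted by the covered mass
delta divided by the fragment charge. Intensities, predicted RT and
predicted IM are reused unchanged — a deliberate approximation: the
intensity pattern of, say, a phosphopeptide differs from its unmodified
counterpart, and the shift only fixes the m/z axis. Conflicting deltas
reported at one position are summed. Monoisotopic masses are used
throughout (proton 1.00727646688 Da, water 18.0105646863 Da).

## What the synthetic generator emulates — and what it does not

`simulate_rescoring_data()` produces a library (msp or TSV), spectra (MGF or
mzML), a pin file and a truth table from one seeded stream. Targets pair a
scan with its own peptide's prediction: fragment intensities perturbed by
multiplicative log-normal noise (default σ = 0.3, a realistic
prediction-spectrum mismatch), 10% fragment dropout, 10 uniform background
peaks; the peptide's predicted RT is a monotone warp (default: logistic
squash of a 120-min gradient onto a 0–100 predicted scale) of the scan's RT
plus Gaussian noise (σ = 1 predicted unit); IM follows distinct per-charge
linear maps (σ = 0.01). Decoys pair a scan with an unrelated peptide: the
spectrum is generated from a shadow peptide absent from the pin file, and
the decoy's predicted RT/IM follow the warp of a random, unrelated
coordinate. E-values overlap (−log10 e uniform on 3–9 for targets, 0.2–3.2
for decoys), mimicking the score blur near the identification boundary. The
generator also plants the supported variable modifications and exercises the
m/z-shift path.

Passing tests on this generator show that the feature definitions,
calibration and probability machinery behave as specified under controlled
noise; they do not show instrument-specific behaviour (Orbitrap vs timsTOF
noise structure, interference in wide DIA windows, charge-dependent
fragmentation efficiency), nor how much the features improve identification
counts after Percolator — that depends on the rescorer and real data. The
generator's near-coincident predicted fragments (within ~25 ppm inside one
peptide) are pruned so the highest-intensity matching rule is unambiguous in
the noise-free limit.

## Problem sizes and determinism

The shipped tests and the acceptance script use simulations of 40–1000 PSMs,
20-seed medians for stochastic comparisons, 1000-point calibration fits and
10,000-point monotonicity grids — sizes at which every stochastic assertion
is stable under seed changes while the whole suite stays quick. The feature
path contains no randomness: two runs on identical inputs produce
byte-identical extended pin files (feature values are serialised with
`%.6g`). Randomness exists only in the generator and is fully governed by
its `seed` argument.

## Known limitations

* Only b/y ions, charges 1–2, no neutral losses; prediction dialects with
  other ion series are not parsed.
* The e-value→multiplicity rule and the residual-IQR normaliser are this
  package's design choices where the underlying method descriptions are
  silent; both are configurable.
* Calibration is per file; cross-run alignment is out of scope.
* mzML reading requires the Bioconductor mzR package; MGF and all TSV
  formats are parsed natively.
* No FDR estimation, protein inference, or rescoring itself — the output is
  the extended pin file.

## A minimal run

```{r example, eval = FALSE}
dir <- tempfile()
sim <- simulate_rescoring_data(dir, n_psms = 200, seed = 42)
cfg <- rescore_config(features = c("unweighted_spectral_entropy",
                                   "delta_rt_loess",
                                   "rt_probability_uniform_prior"))
res <- run_rescoring(sim$pin, sim$spectra, sim$library,
                     file.path(dir, "out"), cfg)
feats <- compute_features(read_pin(sim$pin), read_spectra(sim$spectra),
                          read_prediction_library(sim$library), cfg)
plot_feature_separation(feats, "unweighted_spectral_entropy")
```
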