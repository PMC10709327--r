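---
title: "Capped-peptide discovery: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capped-peptide discovery: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cappedpep)
```

This vignette is the package's own account of the science it implements:
the prediction model and its assumptions, the mass-spectrometric chemistry,
the targeted-detection rules, the downstream statistics, and the design
choices made where the design was genuinely open. It states no empirical
result that the test suite does not itself compute.

## The prediction model

Capped peptides are fragments of classically secreted proteins bearing an
N-terminal pyroglutamate and a C-terminal amide. Both modifications are
encoded in the precursor sequence: amidation requires a glycine donor
immediately followed by a dibasic proprotein-convertase site, recognised
here as the tripeptide `G[K/R]R`; pyroglutamate forms by cyclisation of an
N-terminal glutamine. The model therefore enumerates, for every `G[K/R]R`
motif at position $m$, every glutamine at position $q$ with

$$2 \le m - q \le 20,$$

and emits the inclusive span $[q, m-1]$ as a candidate. The model's
assumptions, and their consequences:

- **Every in-window glutamine seeds a candidate**, not only the nearest.
  Nested candidates (a Q inside another candidate's span) are real output;
  this is what lets one protein yield several peptides, and the shortest
  cores coexist with longer extensions of themselves.
- **The length ceiling (20 residues, counting the pyroGlu)** is a
  practical synthesis limit for authentic standards, not a biological
  statement. It is a tunable (`max_length`).
- **The floor of 2** excludes a bare pGlu-NH2, which is chemically
  degenerate. Tunable (`min_length`).
- **No proteolysis model.** The upstream cleavage that liberates the
  glutamine is deliberately not modelled — known capped peptides arise via
  heterogeneous routes (convertase plus exopeptidase trimming, signal
  peptidase, other proteases), so any upstream-site filter would remove
  real peptides. Consequently candidates overlapping the signal peptide
  are kept by default; `exclude_signal_overlap = TRUE` opts into the
  filter.
- **Ambiguity handling.** Sequences may contain B, Z, X, U, O; these never
  match the motif, and candidates whose core contains one are dropped
  rather than guessed at.
- **Duplicates.** Identical cores at distinct coordinates within one
  protein are retained (coordinates differ) and flagged
  (`duplicated_core`); nothing is deduplicated across proteins. Totals
  reported per proteome are therefore candidate counts, with distinct
  precursor counts available via the accession column.

## Mass-spectrometric chemistry

Neutral monoisotopic mass is $\sum_i m_{res}(a_i) + m_{H_2O} + \sum \Delta$,
with standard monoisotopic residue masses hard-coded in one constants block
(`mass_constants()`); average masses are out of scope. The modification
deltas are pyroGlu-from-Gln $-17.0265491$ Da (loss of ammonia), C-terminal
amide $-0.9840156$ Da ($-$OH $\to$ $-$NH$_2$), and carbamidomethyl-Cys
$+57.0214637$ Da. The first two sum to exactly $-m_{H_2O}$, so a doubly
capped peptide's neutral mass equals its bare residue sum — a cancellation
identity the tests exploit as an invariant. Carbamidomethyl is applied as a
fixed modification by default because the workflow this package targets
alkylates samples with iodoacetamide; it is toggleable.

Fragmentation covers the b/y series only, charges 1–2 — what a triple
quadrupole monitors in practice; a/x/c/z series are omitted. The N-terminal
delta lands on b ions; the amide replaces the y-series water with ammonia,
preserving the complementarity identity
$b_i + y_{n-i} = M + 2 m_{proton}$. Transition design takes, per candidate,
the most intense theoretical match in a reference MS/MS spectrum when one
is supplied (mimicking design from synthetic-standard spectra), otherwise
the highest-m/z fragment above a 200 Da floor (low-mass product ions are
dominated by chemical noise on QQQ instruments); candidates whose fragments
all fall below the floor are flagged instead of silently receiving a bad
transition.

One printed-value subtlety: extracted-ion chromatograms quote the observed
parent ion of the pGlu-FFGLM-NH2 standard as m/z 724.341, while the
theoretical [M+H]+ computes to 724.3487. The theoretical value is treated
as canonical and agreement is asserted at the extraction tolerance of
20 ppm (the two differ by ~11 ppm), never at face precision.

## Targeted detection

Detection is tiered, and each tier is recorded independently:

1. **MS1**: a feature matches at $|\Delta m/z| \le 20$ ppm and
   $|\Delta rt| \le 1$ min of the authentic standard; ties break by smaller
   ppm error, then larger area. Both tolerances are parameters; the
   defaults are the workflow's printed windows.
2. **MRM**: evaluated only when a standard retention time exists
   (without a standard the tier is marked *not evaluated*, not failed).
   S/N is (peak − baseline median) / (1.4826 × MAD of a disjoint noise
   window); the threshold is > 2.5 and the apex must co-elute within
   ±0.2 min. Vendor acquisition software rarely documents its S/N formula,
   so the robust MAD estimator was chosen; the contract is
   threshold behaviour, not absolute S/N values. The apex and height are
   read from a lightly smoothed trace (5-point boxcar) — standard
   chromatographic practice that keeps single noise samples from defining
   the peak. The ±0.2 min co-elution default is a choice; the source only
   says "same retention time".
3. **MS/MS**: at least one theoretical b/y ion matched within 0.5 Da.

Quantification inverts an OLS external standard curve,
$c = (A - b)/s$; non-positive slopes are an error (unusable curve), and
negative back-calculations are clipped to zero with a flag rather than
reported as negative concentrations. Peak areas, where computed from
traces, use baseline-subtracted trapezoidal integration over the RT
window.

## Downstream statistics

- **Composition**: each peptide contributes its own frequency vector over
  the 20 canonical residues (vectors sum to 1); per residue, a two-sided
  two-sample Student's t-test. Raw p-values by default (matching how such
  panels are usually reported); Benjamini–Hochberg via `p_adjust = "BH"`.
  When both groups have zero variance the t-statistic is undefined; the
  implementation reports p = 1 for equal means and ~0 otherwise and flags
  the row, rather than erroring mid-panel.
- **Flanking profiles**: residue frequencies at offsets $-k..-1, +1..+k$
  around the capped residue. At the C terminus the downstream convention
  is genuinely ambiguous because the motif abuts the amidated residue;
  both conventions are implemented (`into_motif`, where +1 is the donor
  glycine by construction, and `past_motif`, which skips the tripeptide)
  and neither is asserted as the published one.
- **Fold changes**: ratio of condition means with Student's t-test; a zero
  control mean yields a flagged infinite ratio, and log2 fold changes are
  reported alongside.
- **Expression heatmaps**: replicates averaged per tissue, each gene row
  normalised to sum 1, log10, then row z-scores using the sample-sd
  convention (a three-tissue row `1, 10, 100` maps to exactly
  $-1, 0, +1$); rows with non-positive values or zero variance are flagged
  and excluded rather than propagating NaN. Rows and columns are ordered
  by complete-linkage hierarchical clustering on Euclidean distance.
- **Cross-species**: exact conservation is literal core-sequence equality.
  The similarity tree uses pairwise Needleman–Wunsch global alignment
  (match +1, mismatch 0, gap −1; distance = 1 − identity over alignment
  length) and average linkage, with lexicographic input ordering for
  determinism. This is a deliberate, documented stand-in for a progressive
  multiple alignment's guide tree: leaf sets and close-pair structure are
  comparable, cluster-level reproduction of a reference phylotree is
  not asserted.

## Curve fits

The 4PL dose-response
$y = bottom + (top - bottom) / (1 + (EC_{50}/d)^{h})$ is fitted by
Levenberg–Marquardt least squares, parameterised internally on
$\log_{10}$ dose and $\log_{10} EC_{50}$ for conditioning, with a
deterministic multi-start grid over hill slopes (0.5, 1, 2, −1) and EC50
quartiles of the dose range; the best-RSS fit wins, and the result is
canonicalised to $top \ge bottom$ (the model is invariant under swapping
the asymptotes with $h \to -h$). Inputs must span at least 5 dose levels
and 2 log-units — below that an EC50 is not identifiable. Decay fits
$A e^{-kt}$ on the raw scale so that zero and near-zero late points carry
honest weight (a log-scale fit would have to discard them), initialised
from a log-linear regression on the positive levels;
$t_{1/2} = \ln 2 / k$.

## The synthetic-data generators

The generators exist so every stage can be tested against known truth
without any external download. What they emulate, and what they do not:

- `make_proteome()` draws uniform-composition background sequences,
  rejection-sampled until candidate-free, then inserts one compliant
  context per planted protein (re-drawing until the predictor's closure
  over the record is exactly the plant) and three decoy classes: a
  glutamine at distance 21 (one beyond the window), a `GKK` motif (second
  basic must be R), and a core with an internal X. Planted cores carry no
  internal Q/G/R/K so each plant is exactly one candidate and counts are
  exact. Uniform residue frequencies are a simplification — real
  secretomes are biased and the planted-core alphabet restriction biases
  composition further — so composition-level results on synthetic
  proteomes say nothing about real ones; closure and count tests do.
- `make_ms1_and_traces()` plants features at theoretical m/z with 3 ppm
  Gaussian jitter (a 20 ppm window is then a 6.7σ bound, so planted
  features always match) and decoys at a fixed +25 ppm; traces are
  Gaussian elution peaks (σ = 0.1 min) whose height is S/N × the
  MAD-calibrated baseline scale. No chromatographic tailing, isotope
  envelopes or matrix effects.
- `make_quant_experiment()` uses mean-preserving log-normal noise, so
  cv = 0 reproduces planted means exactly and fold-change recovery is
  unbiased by construction.
- `make_pharm_data()` defaults mirror the assay designs the package
  targets: decay sampled at 0/20/40/60 min, dose-response at 8 log-spaced
  levels spanning ±3 logs around the EC50, duplicate measurements.

All generators are deterministic per seed.

## Problem sizes and numerical tolerances

The test suite runs everything at desk scale: predictor-vs-oracle
equivalence on 1,000 random sequences up to length 500; mass and
complementarity identities on 100–1,000 random peptides at $10^{-6}$ and
$10^{-4}$ Da; 100-replicate noise simulations for EC50 (5% noise, median
within 25%), half-life (10% noise, median within 15%) and standard-curve
quantification (S/N ≥ 10, median within 5%); and a 1,000-replicate null
simulation of the composition test at n = 50/group (empirical size
0.05 ± 0.02). These sizes were chosen as the smallest that make the
statistical assertions stable across seeds.

## Known limitations

- Prediction counts on the curated mouse/human secretome lists depend on
  those exact Uniprot exports, which are not redistributed with the
  package; the corresponding acceptance check runs only when the user
  supplies the FASTA files under `inst/extdata/`.
- No vendor raw-file parsing; feature, trace and curve inputs are open
  delimited text. An mzML adapter is a possible extension, not a current
  feature.
- No retention-time prediction or alignment across runs: matching assumes
  the standard and the sample were run under the same chromatography.
- The cross-species tree is a guide tree, not a phylogeny; no substitution
  matrices, no bootstrap.
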