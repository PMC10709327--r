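# cappedpep

Discovery and targeted detection of **capped peptides** — secreted-protein
fragments carrying two chemical "caps": an N-terminal pyroglutamate (pGlu)
and a C-terminal amide. Co-incident capping marks classical signaling
peptides such as TRH (pGlu-HP-NH2) and GnRH (pGlu-HWSYGLRPG-NH2), and the
same motif logic predicts many more candidate peptides hidden in secreted
preproproteins. `cappedpep` is for peptidomics and metabolomics groups who
want to enumerate these candidates from a curated secretome, design targeted
LC-MS assays for them, and run the downstream statistics on the resulting
quantification tables.

## What it computes

**Prediction.** A C-terminal amidation site is a glycine–dibasic tripeptide
`G[K/R]R` (the glycine is the amide donor; the dibasic pair marks
proprotein-convertase cleavage). For every motif at position *m* in a
secreted protein, every glutamine at position *q* with
2 ≤ *m* − *q* ≤ 20 seeds a candidate: the inclusive span
`sequence[q .. m−1]`, rendered `pGlu-<core minus Q>-NH2`. All qualifying
glutamines are enumerated, so motifs can yield nested candidates and one
protein several peptides.

**Chemistry.** Neutral monoisotopic mass is the residue-mass sum plus water
plus modification deltas: pyroGlu-from-Gln −17.0265491 Da, C-amide
−0.9840156 Da, carbamidomethyl-Cys +57.0214637 Da (iodoacetamide-alkylated
samples). The two caps cancel the water term exactly, so a doubly capped
peptide's mass equals its bare residue sum. Ions follow
*m/z* = (M + *z*·1.00727646)/*z*; b/y fragment series and one default MRM
transition per candidate (most intense reference-spectrum match, else the
highest-m/z fragment above 200 Da) are derived from the same constants.

**Detection.** The two-step targeted rules: an MS1 feature matches when it
is within 20 ppm of the theoretical m/z *and* within 1 min of the authentic
standard's retention time; an MRM trace validates when S/N > 2.5, with
S/N = (peak − baseline median) / (1.4826 × MAD of an off-peak window), and
the apex co-elutes within ±0.2 min; full MS/MS detection requires at least
one matched daughter ion (±0.5 Da). Concentrations come from an external
standard curve (OLS of area on concentration, inverted).

**Downstream.** Per-residue composition t-tests against a reference hormone
set, flanking-residue frequency profiles around either cap, per-peptide
fold-change tables with Student's t-tests, tissue-expression z-score
heatmaps (relative → log10 → row z-score, complete-linkage clustering),
4-parameter logistic EC50 fits, exponential-decay half-lives
(t½ = ln 2 / k), exact cross-species conservation and an average-linkage
similarity tree over pairwise global alignments. Synthetic-data generators
plant known candidates, features, fold changes and curve parameters so every
stage is testable against ground truth.

## Worked example

```r
library(cappedpep)

prot <- tibble::tibble(accession = "TAC1", gene = "Tac1",
                       sequence = "RRPKPQQFFGLMGKR")
predict_capped_peptides(prot)
#> # A tibble: 2 x 10
#>   accession start   end core_sequence capped_notation length motif
#> 1 TAC1          6    12 QQFFGLM       pGlu-QFFGLM-NH2      7 GKR
#> 2 TAC1          7    12 QFFGLM        pGlu-FFGLM-NH2       6 GKR
```

Both glutamines upstream of the `GKR` motif seed candidates; the second is
the tachykinin-like peptide pGlu-FFGLM-NH2. Its ion chemistry:

```r
ion_mz(peptide_mass("QFFGLM"), 1)
#> [1] 724.3487                # [M+H]+, within 20 ppm of the observed 724.341
fragment_ions("QFFGLM") |> dplyr::filter(annotation == "b4+")
#>   series index charge    mz annotation
#> 1 b          4      1  463.2 b4+      # the MRM product ion, 724.3 -> 463.2
```

A plasma-stability half-life from a decay series:

```r
t <- c(0, 20, 40, 60)
fit <- fit_decay(tibble::tibble(time_min = t, level = 100 * 2^(-t / 17.1)))
fit
#> Exponential decay fit: t1/2 = 17.1 min (k = 0.04053 /min, A = 100)
generics::glance(fit)
#> # A tibble: 1 x 4
#>   t_half      k      rss     n
#> 1   17.1 0.0405 6.63e-29     4
```

End-to-end runs go through `pipeline_config()` + `run_discovery()`, or the
thin CLI at `inst/scripts/cappedpep`
(`cappedpep predict --fasta F --out preds.tsv`, `cappedpep run --config
cfg.yaml --out dir/`). Generators (`make_proteome()`,
`make_ms1_and_traces()`, `make_quant_experiment()`, `make_pharm_data()`)
produce every input format with recorded truth.

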