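# apoScreen

High-content microRNA inhibitor screen analysis for apoptosis phenotypes
in drug-responsive and endocrine-resistant breast cancer.

## The problem

Screens that transfect a library of miR inhibitors (954 antisense
oligonucleotides in the design this package targets) into a parental
breast cancer line (MCF7) and endocrine-resistant derivatives (TamR,
LTED) read out apoptosis by imaging: a Hoechst nuclear stain counts
cells, a caspase-3/7 reporter marks dying ones. The analysis question is
which inhibitors kill which lines — and in particular which preferentially
kill the resistant lines, since those are candidate therapeutics for
endocrine-refractory disease.

`apoScreen` is for analysts running or re-analysing such screens. It
covers the whole chain:

1. **Image quantification** — nuclear segmentation of the Hoechst channel
   (Gaussian smoothing → Otsu → area filter → optional watershed), caspase
   measured *inside nuclei only*, and the **apoptotic score**: the
   fraction (0–1) of caspase-positive nuclei per field, averaged over a
   well's fields.
2. **Hit calling** — per inhibitor *i*, the log fold change
   `LFC_i = log2((X̄_resistant + c) / (X_MCF7 + c))` (replicate means,
   pseudocount `c = 0.001`), standardised over the library by the robust
   Z-score `RZ_i = 0.6745 (x_i − median) / MAD` with
   `MAD = median|x_i − median|`; significance at `|RZ| ≥ 2.5`
   (one-sided normal tail `1 − Φ(2.5) = 0.00621`), plus a three-way
   phenotype classification: `responsive_only` (score ≥ 0.10 in MCF7
   only), `resistant_only` (≥ 0.20 in both resistant lines only), `pan`
   (≥ 0.50 in all three).
3. **Direct-target nomination** — intersect a differential-expression
   table (`p < 0.05`, strict) with the union of predicted and validated
   miR target databases, with per-gene provenance.
4. **HSA synergy** — surplus of a two-drug combination grid over the
   highest-single-agent reference `max(e_i0, e_0j)`.
5. **Assay formulas** — ΔΔCt fold change (`2^(−ΔΔCt)`, multi-reference),
   tumour volume (`w² × l / 2`), the 3-point IHC rubric, SRB relative
   growth.

A seeded synthetic-data module (`genFieldImage`, `genScreenTable`,
`genTargetsAndDegs`, `genDoseResponse`) generates every input with
recorded ground truth, so the full pipeline is testable without any
external data.

## Worked example

```r
library(apoScreen)

# a full simulated screen: 954 inhibitors x 3 lines x 3 replicates,
# 26 planted hits, replicate noise SD 0.02
tbl  <- genScreenTable(screenScenario(noiseSd = 0.02), seed = 1)
hits <- callHits(tbl$scores)
table(hits$category)
#>            none             pan  resistant_only responsive_only
#>             928              13               9               4

head(hits, 3)
#> DataFrame with 3 rows and 9 columns
#>   inhibitor_id      MCF7      TamR      LTED resistant_mean       lfc  rz_score
#> 1     miR-0268 0.0267569  0.282138  0.298854       0.290496   3.39256   7.83679
#> 2     miR-0306 0.0270214  0.272513  0.296919       0.284716   3.34998   7.72289
#> 3     miR-0344 0.0335629  0.286662  0.280348       0.283505   3.04116   6.89683
#>   significant       category
#> 1        TRUE resistant_only
#> 2        TRUE resistant_only
#> 3        TRUE resistant_only
```

All 26 planted hits are recovered with their exact category labels; the
top of the table is the resistant-only class because the
resistant-vs-parental LFC is what the robust Z standardises.
`S4Vectors::metadata(hits)` holds the library LFC median (0.463 here) and
MAD (0.252) behind the scores.

The imaging side, end to end on one synthetic field:

```r
f  <- genFieldImage(nNuclei = 120, apoptoticFraction = 0.25, seed = 9)
scoreField(callApoptotic(segmentNuclei(f$image)))
#>   nCells nApoptotic apoptoticScore
#> 1    120         30           0.25
```

Segmentation recovered all 120 nuclei and the apoptotic score matches the
generated truth exactly.

## Documentation

The methods vignette (`vignettes/apoScreen-methods.Rmd`) describes the
model and its assumptions, every tunable parameter with its default and
rationale, what the synthetic data does and does not emulate, numerical
edge-case policy, and known limitations.
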