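# msclong

Predicting the remaining replicative lifespan and osteogenic capacity of
cultured bone-marrow multipotential stromal cells (MSCs).

Culture-expanded MSCs drift towards replicative senescence and lose
bone-forming potency on the way, at a rate that depends strongly on donor
age. Passage number and accrued population doublings (PD) are therefore
poor quality-control read-outs; what matters is the culture's *remaining*
lifespan — population doublings before senescence (**PD-BS**). `msclong`
is for cell-therapy and stromal-biology labs that want a quantitative,
donor-age-independent estimate of that reserve from two molecular
measurements.

The core model couples the two markers with the widest and tightest
dynamic ranges across expansion:

```
score = SPARC x 1 / PRAMEF2
```

where SPARC is osteonectin mRNA as a 2^(−ΔCt) relative expression
(HPRT reference) and PRAMEF2 is a CpG-island methylation percent. SPARC
rises steeply as senescence approaches; PRAMEF2 methylation falls tightly
with accrued PD. The score is calibrated against PD-BS and against CFU-O
(colony-forming unit-osteoblast per 500 MSCs) by least squares with
t-based 95% bands, and a score at or below 5 indicates a guaranteed
proliferative reserve at 95% confidence.

The package implements the full pipeline around that model:

| stage | functions |
|---|---|
| culture accounting (p0 PD, accrued PD, senescence, PD-BS) | `p0_population_doublings`, `accrue`, `detect_senescence`, `pd_before_senescence`, `annotate_culture` |
| qPCR quantification (2^(−ΔCt), 2^(−ΔΔCt)) | `relative_expression`, `fold_induction`, `panel_quantify` |
| telomere assay (T/S ratio, bp, paired shift) | `ts_ratio`, `ts_to_bp`, `paired_shift` |
| six-CpG methylation clock | `clock_model`, `fit_clock`, `predicted_passage_number`, `island_report` |
| marker screening | `screen_markers`, `presenescence_fold`, `classify_induction`, `induction_table` |
| composite-score model | `composite_score`, `calibrate_longevity` (+ `print`/`summary`/`coef`/`predict`/`plot` methods), `predict_remaining`, `threshold_classify`, `score_all_islands` |
| small-sample statistics | `spearman_cor`, `wilcoxon_signed_rank`, `mann_whitney`, `ols_line` |
| synthetic cohort & pipeline | `default_config`, `generate_cohort`, `write_cohort`, `validate_inputs`, `run_pipeline` |

No donor data are distributed; a calibrated synthetic-cohort generator
(`generate_cohort`) emulates a seven-donor, age 2–72 study so the whole
pipeline is testable end to end. See the vignette
(`vignettes/msc-longevity.Rmd`) for the generative model and every
convention (senescence rule, detection cutoff, band types, exact
small-sample test nulls).

## Worked example

Simulate the default cohort and run every stage:

```r
library(msclong)
res <- run_pipeline()
print(res)
```

```
MSC longevity pipeline run (seed 42 )

Top screened candidates:
               gene   rho_pdbs   gradient candidate strong
SPARC         SPARC -0.7600284 -16.446819      TRUE   TRUE
TNFRSF11B TNFRSF11B -0.9210664  -1.157600      TRUE   TRUE
FZD4           FZD4 -0.9166736  -0.105499      TRUE   TRUE

Island correlations (PRAMEF2):
         island     rho_pd         p_pd  rho_pdbs       p_pdbs  n
PRAMEF2 PRAMEF2 -0.9704348 4.534094e-15 0.7975111 3.062072e-06 24

Composite-score longevity calibration (n = 24 points)
  PD-BS = 19.7160 + -1.3771 x score   (residual SD 3.098 PD)
  CFU-O = 113.6540 + -7.6023 x score   (residual SD 19.138)
  Spearman rho(score, PD-BS) = -0.906 (p = 1.09e-09)
  Spearman rho(score, PD)    = 0.907 (p = 1.01e-09)
  Spearman rho(score, CFU-O) = -0.807 (p = 1.9e-06)
  Band: confidence at level 0.95 

At score = 5: 12.8 PD-BS (lower bound 10.9)
Telomere shift on differentiation: median 94 bp (p = 2.38e-07)
```

Reading the output: SPARC heads the marker screen (it associates with
all four functional measures and has by far the steepest expression
gradient per PD of remaining lifespan, −16.4 relative-expression units
per PD). PRAMEF2 methylation correlates at −0.97 with accrued PD and
+0.80 with PD-BS over the 24 methylation samples. Combining the two, the
composite score correlates at −0.91 with PD-BS — better than either
marker alone — and a culture scoring 5 is predicted to retain 12.8 PD
(at least 10.9 PD at the 95% lower bound) and a matching CFU-O reserve.
Osteogenic differentiation shortens telomeres by a median 94 bp across
the 23 assay pairs.

For real data, point `run_pipeline()` at the five input CSVs (culture
log, expression Cts, methylation, telomere Cts, clonal assays):

```r
res <- run_pipeline(inputs = list(
  culture = "culture.csv", expression = "expression_ct.csv",
  methylation = "methylation.csv", telomere = "telomere_ct.csv",
  clonal = "clonal.csv"), out_dir = "report")
```

`validate_inputs()` checks the schemas first and reports problems with
file, row and column; `write_cohort()` writes a synthetic data set in
exactly this layout if you want a template.

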