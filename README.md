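# survSigSearch

Discovery and evaluation of small prognostic gene-expression signatures in
survival cohorts.

Given a genes-by-samples expression matrix (log2(x+1)-normalized RNA-seq
abundances) and per-sample survival records, the package finds the best
small Cox signature by brute force and evaluates it the way clinical
biomarker studies do:

1. **Prevalence filter** — keep genes nonzero in at least half the samples.
2. **Univariate Cox screen** — keep genes whose single-gene Cox fit has a
   Wald P below 0.001.
3. **Exhaustive search** — evaluate *every* combination of 1–3 screened
   genes as a multivariate Cox model; the risk score of sample *i* is the
   linear predictor

   *score(i) = Σ<sub>g</sub> β̂<sub>g</sub> E<sub>gi</sub>*

   and each combination is scored by the ROC-AUC of this score against
   end-of-follow-up vital status on the training cohort. The maximum-AUC
   model wins (ties break toward fewer genes).
4. **Evaluation** — median-split risk stratification, Kaplan–Meier curves,
   the log-rank test, Harrell's C-index and ROC-AUC with 95% CIs, on
   training, validation, cross-platform (missing-marker) and clinical
   subgroup cohorts; plus a Pearson coexpression screen (r > 0.6,
   P < 0.01) and a 1000× random-50%-subsampling harness that compares
   competing signatures by t-tests on their AUC distributions.

The survival statistics (Efron-tie Cox Newton–Raphson, product-limit
estimator, log-rank, Harrell's C, Mann–Whitney AUC with DeLong variance)
are implemented from first principles in this package and cross-checked in
the test suite against independent oracles (`survival`, `pROC`, hand
computations, brute-force likelihood grids). A synthetic-cohort generator
with planted proportional-hazards signatures makes the whole pipeline
testable without external data; see the methods vignette
(`vignettes/signature-search-methods.Rmd`) for the model, the generator's
assumptions, and all numerical conventions.

## Worked example

```r
library(survSigSearch)

coh <- simulateCohort(nSamples = 300, nGenes = 200, plantedGenes = 1:3,
                      plantedBetas = c(1, 0.9, -0.8), censorRate = 0.4,
                      zeroInflation = 0.1, seed = 42)
coh   <- filterLowExpression(coh)
parts <- splitCohort(coh, 0.5, seed = 42)

sc <- univariateScreen(parts$train, 0.001)
sc
#> ScreenResult: 3 of 200 genes retained at Wald P < 0.001

res <- exhaustiveSearch(parts$train, sc, maxSize = 3)
res
#> SearchResult over 7 combinations ( 0 skipped )
#> best model:
#> SignatureModel 'best': risk score = +0.8848*SYNG000001 +1.1020*SYNG000002 -0.8638*SYNG000003
#>   training AUC: 0.7858

evaluateModel(res@best, parts$validation)
#> Signature evaluation over 150 samples
#>   mean survival: low-risk 1463 vs high-risk 228 days
#> Log-rank test: chi-square = 128.1248 on 1 df, P = 1.054e-29
#>   group 1: observed 24 vs expected 68.19 deaths
#> AUC = 0.865 (95% CI 0.808-0.923), P = 7.02e-36 (92 positives, 58 negatives)
#> C-index = 0.868 (95% CI 0.861-0.875), P = 0 over 8134 pairs
```

The screen recovers exactly the three planted genes, the search fits their
multivariate Cox coefficients (close to the generating values 1, 0.9,
−0.8), and on the held-out half the signature separates the risk groups
decisively: the low-risk group outlives the high-risk group (1463 vs 228
days mean follow-up), with validation AUC 0.865 and C-index 0.868.

Real data enter through `readExpression()` / `readClinical()` /
`assembleCohort()` (TSV formats documented on those help pages), and a
thin command-line wrapper with `simulate | screen | search | evaluate |
compare | pipeline` subcommands lives at `inst/scripts/survsig.R` —
including deterministic `--chunk i/w` partitioning of the search for
resumable full-scale runs (415 candidates at k = 3 is ~1.2 × 10⁷ Cox
fits).

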