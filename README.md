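# ectoMark

Discovery and validation of prognostic cancer biomarkers based on
**ectopic gene activation**: the expression, in a tumour, of genes that
are normally silent in all adult non-germline somatic tissues (typically
testis- or placenta-restricted genes). Because such genes have near-zero
somatic background, their activation is an almost binary signal with a
robust threshold — which makes it transferable from transcriptomics to an
immunohistochemistry (IHC) test usable in a pathology lab.

The package is aimed at computational biologists building or auditing
threshold-based prognostic classifiers for head-and-neck / oral squamous
cell carcinoma style cohorts (genes × patients expression plus overall
survival), and implements the whole procedure as tested, seeded, reusable
stages.

## The method

For a candidate gene with expression $x_p$ in patient $p$ and overall
survival $(t_p, \delta_p)$, the screen keeps the gene iff all three hold:

1. **Cox association** — univariate Cox PH fit on z-scored expression:
   $p < 0.05$ and $\hat\beta > 0$ (overexpression ⇒ shorter survival);
2. **Threshold stratification** — some percentile threshold $q$ splits
   patients (high $x > x_{(q)}$ vs low) with two-group log-rank
   $p < 0.05$ and the high group faring worse;
3. **Threshold stability** — the longest contiguous run of significant
   percentiles on the 10–90 grid spans **> 50 percentile points**.

Selected genes are binarised into activation calls
($x >$ 2 × somatic background ceiling, or a cohort-internal percentile),
and a small panel (three genes in the published application: *AREG*,
*CCNA1*, *DDX20*) is summed per patient: **0–1 activations = good
prognosis, 2–3 = poor**. The grouping is evaluated by Kaplan–Meier /
log-rank / Cox (HR per additional activation), within clinical subgroups
(TNM early/late, HPV, tonsil–base-of-tongue site) and in multivariate
models. The same 0–3 count is reproduced at the protein level by
composite IHC scoring (intensity 0–3 × proportion category, marker
specific cutoffs). Finally, classifier-positive vs negative tumours are
compared genome-wide (Welch t on log2(x+1), |FC| > 2, p < 0.01) and
scored against gene sets with a weighted running-sum GSEA engine.

Synthetic-data generators (normal-tissue panel, tumour cohort with
survival driven by planted activations under an exponential
proportional-hazards model, coupled IHC tables) carry full ground-truth
records, so every stage is validated by parameter recovery.

## A worked example

```r
library(ectoMark)
cfg <- simConfig(n_genes = 250, n_tissue_specific = 40,
    n_ectopic_candidates = 40, n_true_prognostic = 3,
    n_patients = 150, seed = 11)
res <- runPipeline(cfg, outDir = NULL, gseaPermutations = 100)
res
#> ectoMark pipeline run (seed 11 , version 0.2.0 )
#>  - simulate: 250 genes, 150 patients, 136 events
#>  - catalog: 40 candidates
#>  - screen: 1 genes pass all 3 criteria
#>  - screen: fewer than 3 selected; topping up by Cox rank
#>  - activate: panel gene_0002,gene_0003,gene_0001; mean count 1.29
#>  - ihc: 150 patients scored
#>  - signature: 3 up / 0 down genes

res$stratification
#> Stratification of 150 patients ( 136 events )
#>   by activation count: 0=30, 1=60, 2=47, 3=13
#>   risk groups: good=90, poor=60
#>   two-group log-rank p = 1.61e-12
#>   Cox HR per activation = 2.434 ( p = 2.019e-14 )
```

Reading the output: the catalog found the 40 planted tissue-predominant
silent genes; at this small cohort size only one gene clears the strict
>50-percentile stability criterion, but the three planted prognostic
genes head the Cox ranking (cox_p 6.7e-08, 4.9e-04, 2.3e-03) and the
assembled 3-gene panel separates good from poor prognosis sharply — the
recovered hazard ratio per activation, 2.43, is close to the generating
value of 2.5. At the validation scale used in the test suite (n = 400,
20 seeds) the screen selects all three planted genes in ≥ 80% of seeds.

Each stage is also callable on its own (`selectTissuePredominantGenes()`,
`runScreen()`, `callActivations()`, `scorePanel()`,
`stratifiedSurvival()`, `scoreIHCMarker()`, `differentialExpression()`,
`gseaEnrichment()`, …) on matrices/tables read with the TSV/GMT loaders.

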