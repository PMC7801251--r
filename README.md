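# dctnet — dynamic cross-tissue network analysis

`dctnet` integrates **paired case/control transcriptomes measured over the
same tissues and genes** (e.g., one crop variety grown in two environments
with very different phenotypes, profiled across a developmental tissue
series) and finds the genes and the tissue driving the phenotype difference
at the **co-expression network level** rather than the expression level.
Genes whose expression barely moves but whose network neighborhood rewires —
invisible to fold-change screens — are exactly what it targets.

## Who it is for

Systems biologists with FPKM-like expression tables for two conditions over
m matched tissues, a transcription-factor list, and a short list of genes
already known to affect the phenotype ("anchor" genes), who want a ranked
list of new candidate genes and the key tissue of the phenotype.

## The method

1. **Feature genes.** DEGs (max fold change across tissues ≥ 1.2, with a
   pseudocount), plus TFs and anchors regardless of expression change,
   deduplicated, form the columns of the matrices `X₁` (case), `X₂`
   (control).
2. **Joint-correlation NMF (jcNMF).** Both matrices are factorized as
   `Xᵢ ≈ WᵢHᵢ` (`W`: tissues × modules, `H`: modules × genes) under the
   *soft* constraint that the tissue Gram matrices agree with the conserved
   tissue correlation matrix `R`:

   `min Σᵢ ‖Xᵢ − WᵢHᵢ‖²F + λ Σᵢ ‖WᵢWᵢᵀ − R‖²F ,  W, H ≥ 0`

   solved by multiplicative updates (compiled core). The classical hard
   constraint `W₁ = W₂` and independent NMFs are available as comparison
   modes.
3. **Differential networks.** Each tissue maps to its strongest module; the
   module row of `H` yields the tissue's gene set; pairwise Pearson
   correlations between `H` columns with a two-sided t-test (`P < 0.05`)
   give the co-expression networks `C(H₁)`, `C(H₂)`; their set differences
   `Diff₁`/`Diff₂` are the condition-specific networks.
4. **Candidate ranking.** `R(u) = mean PCC(H[,u], H[,v in anchors])`; the
   per-tissue top 30 genes, present in ≥ 4 tissues, are consensus
   candidates, orderable by the product rank of `R(u)`, fold change and
   network degree.
5. **Key tissue.** Matched-pair t-test on the paired `Diff₁`/`Diff₂` degree
   vectors, `t = Σd / √((nΣd² − (Σd)²)/(n−1))`; smallest p wins.

## Worked example (synthetic data with known truth)

```r
library(dctnet)

ds  <- generate_paired_dataset(synthetic_spec(seed = 1))  # 7 tissues x 500 genes
cfg <- dct_config(ds$case, ds$control,
                  anchor_ids = ds$truth$anchor_ids,
                  fc_cutoff = 1,   # synthetic X is already the feature-gene matrix
                  seed = 1)
run <- run_pipeline(cfg)
run
#> dct_run: 500 feature genes, key tissue 'T3', 10 consensus candidates
run$fit
#> jcnmf_fit (mode soft, k = 7, lambda = 1): objective 4.73263 after 5000
#> iterations; constraint residual 0.4043
head(run$consensus$candidates, 3)
#>   gene_id tissue_count    mean_R
#> 1   g0493            7 0.9212571
#> 2   g0495            7 0.9135633
#> 3   g0492            7 0.9047868
run$significance
#>   tissue_id n_genes         t            p
#> 1        T1      86  1.256953 2.122136e-01
#> 2        T2      85  5.343449 7.680733e-07
#> 3        T3      85 13.608737 5.945597e-23
#> ...
```

Reading the output: all 10 planted anchor-correlated genes (`g0491`–`g0500`)
are recovered as consensus candidates with mean anchor relatedness ≈ 0.9
(the generator's planted correlation), and tissue `T3` — the tissue whose
module was rewired in the case condition — shows by far the strongest
paired degree change (t = 13.6, p ≈ 6e-23), so it is reported as the key
tissue.

With real data, replace the matrices by TSV paths (genes as rows, tissue
columns) and supply TF/anchor gene-ID lists:

```r
cfg <- dct_config("case.tsv", "control.tsv",
                  anchor_ids = "anchors.txt", tf_ids = "tfs.txt",
                  outdir = "results/")
run <- run_pipeline(cfg)
```

All stage outputs (feature catalog, factors, gene sets, edge lists,
rankings, significance table, JSON report) are written under `outdir`. A
command-line front end with `simulate` and `run` subcommands is installed at
`inst/scripts/dct-pipeline.R`.

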