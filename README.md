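# ertargets

Discovery of estrogen-receptor (ER) target genes whose binding persists in
endocrine-resistant breast cancer cells, and screening of those genes for
association with patient survival.

## Who this is for

ER drives most breast cancers, and endocrine therapy works by starving or
blocking it. In resistant cells ER keeps binding chromatin without hormone.
Given ChIP-seq peak calls from a resistant and a responsive condition, a
cell-line differential-expression table, and a patient cohort with
expression, receptor status and follow-up, `ertargets` runs the complete
discovery funnel:

1. **Peak FDR filter** (≤ 0.5%) on both conditions, then depth
   normalization of intensities.
2. **Overlap analysis** — sites sharing ≥ 1 bp are *common*, the rest
   *unique*; resistant-associated sites are common sites with an intensity
   change ratio (resistant / responsive) ≥ 0.9, plus resistant-only sites.
3. **TSS annotation** — genes with a TSS within ±20 kb of the peak summit.
4. **Expression filter** — fold change ≥ 1.2 with BH-adjusted p < 0.05.
5. **Survival screening** — univariate Cox score per gene,

       s = U / √I   (partial-likelihood score statistic at β = 0,
                     Breslow ties, per-SD standardized expression),

   keep |s| ≥ 2.39, then Kaplan–Meier / log-rank comparisons of
   median-split (single gene) or 2-means (panel) risk groups, within
   ER/HER2 receptor subgroups.

A synthetic-data generator (`simulate_study()`) plants candidate genes,
single-filter-failing decoys, and prognostic hazard coefficients, so every
stage is testable with known ground truth and no external downloads. A
minimal ERE consensus scanner (`scan_ere()`) is included for checking
binding sites for the estrogen response element.

## Worked example

```r
library(ertargets)

sim <- simulate_study(sim_config(seed = 1))     # planted ground truth
cfg <- run_config(peaks_a = sim$peaks_a, peaks_b = sim$peaks_b,
                  genes = sim$genes, expression = sim$expr,
                  groups = sim$groups)
disc <- run_discovery(cfg)
disc$report
```

```
RunReport (discovery), ertargets 0.1.0, 2.01s
stages:
              stage n_in n_out seconds
1        fdr_filter  855   770   0.009
2           overlap  406   307   1.973
3      change_ratio  406   300   0.001
4          annotate  300   186   0.020
5 expression_filter  186    10   0.005
counts:
  peaks_a_raw        450
  ...
  resistant_sites    300
  genes_annotated    186
  candidates         10
```

The funnel narrows 855 raw peaks to 300 resistant-associated sites, 186
annotated genes, and exactly the 10 planted candidates. Screening those
candidates in the simulated 400-patient cohort:

```r
sel <- select_genes_by_cox(sim$cohort, disc$candidates$gene_id)
sel
#>   gene_id     score
#> 1   G0184 -7.532867
#> 2   G0309  7.177528
#> 3   G0010  5.994789
#> 4   G0429  5.807898
#> 5   G0334 -4.664365

single_gene_km(sim$cohort, "G0184")
#> Survival comparison: G0184, median split, endpoint OS
#>   groups: low n=200, high n=200
#>   log-rank chi-square = 33.14 (1 df), p = 8.588e-09
```

All five genes planted with nonzero hazard coefficients pass the 2.39
cutoff with the planted signs (negative = protective: high expression,
better survival); the median-split log-rank comparison of the top gene is
decisive. `plot(single_gene_km(...))` draws the two Kaplan–Meier curves.

There is also a command line:

```sh
Rscript inst/cli/ertargets.R all --out run1 --seed 1
Rscript inst/cli/ertargets.R discover --peaks-a a.xls --peaks-b b.xls \
    --genes genes.tsv --de de.tsv --min-ratio 0.9 --out run2
```

Subcommands: `simulate`, `discover`, `survive`, `all`. Threshold overrides
(`--fdr-pct`, `--min-ratio`, `--window`, `--min-fc`, `--max-q`,
`--cox-cutoff`) are validated up front and recorded in `report.json`.

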