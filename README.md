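# pamparray

Analysis toolkit for immune transcriptomics of fish macrophages stimulated
with pathogen-associated molecular patterns (PAMPs: bacterial LPS and PGN).
It is aimed at analysts working with two classic data types that still back
much of the non-model-organism immunogenomics literature:

* **PAMP-primed EST libraries.** ESTs from a bacterial-primed and a
  viral-primed cDNA library are length filtered (> 100 nt), clustered into
  contigs by single-linkage local alignment (≥ 95% identity over ≥ 40 nt),
  and each contig's library composition is tested with a frequency rule: a
  contig whose members come at **strictly more than 75%** from one library
  (minimum 4 members) is called enriched for that library's stimulus.
* **Single-channel oligonucleotide microarrays.** Probe-level scans are
  scored per spot with the quality ratio `R = (SI − SB)/(SDI + SDB)`,
  background corrected and log2 transformed, percentile-shift normalized
  (each array minus its own median), filtered on per-probe SD percentiles,
  QC'd via probe-pair Pearson correlation bins, and summarized to gene
  level (mean within a probe set, median across probe sets). Each treatment
  is tested against control with a two-group one-way ANOVA; calls combine
  `p < 0.001` with a signed linear fold change `|FC| > 2`
  (`FC = 2^Δ` if ≥ 1, else `−2^{−Δ}`), and the two treatments' significant
  sets are partitioned into exclusive and common transcripts (Venn). GO
  terms are tested for over-representation with the hypergeometric upper
  tail (≥ 4 DE genes per term; Bonferroni and BH reported). Array fold
  changes are cross-validated against RT-qPCR quantified by the Pfaffl
  method, `ratio = E_t^{ΔCq_t} / E_r^{ΔCq_r}` with 18S as reference, using
  Spearman rank correlation per treatment.

A synthetic-data module (`synth_config()`, `generate_est_libraries()`,
`generate_array_experiment()`, `generate_qpcr()`) plants known enrichment,
differential expression and fold changes, so the whole pipeline can be
scored end-to-end against ground truth — including an exactly recoverable
zero-noise configuration.

## Worked example

```r
library(pamparray)

cfg <- synth_config(n_targets = 400, n_transcripts = 10,
                    n_est_per_library = 80, seed = 42)
res <- run_pipeline(cfg, out_dir = "run1")
#> [pamparray] est: generating and clustering EST libraries
#> [pamparray] array: generating scans, QC and normalization
#> [pamparray] de: per-treatment testing and Venn partition
#> [pamparray] enrich: GO term over-representation
#> [pamparray] qpcr: Pfaffl quantification and cross-platform correlation

res$summary$n_significant
#> LPS PGN
#>  21  20
res$summary$venn
#>   n_a n_b n_exclusive_a n_common n_exclusive_b
#> 1  21  20            11       10            10
res$qpcr$correlation
#>   condition      rho  n
#> 1       LPS 0.965035 12
#> 2       PGN 1.000000 12
```

With 400 targets and 5% planted differential expression per treatment
(half shared between treatments), the run calls 21 and 20 significant
transcripts for LPS and PGN with 10 in common — matching the planted
structure — and the twelve genes carried into the synthetic qPCR panel
rank almost identically on both platforms (Spearman ρ ≈ 0.97 and 1.00).
`run1/` contains per-stage TSVs (contig report, normalized matrix, DE
tables, enrichment tables, Cq table) plus `summary.json`.

The packaged reference comparison of twelve immune genes measured on both
platforms reproduces the published cross-platform agreement:

```r
cross_platform_correlation(crossplatform_reference())
#>   condition       rho  n
#> 1       LPS 0.7915949 12
#> 2       PGN 0.7740817 12
```

## Documentation

The methods vignette (`vignettes/pamparray-methods.Rmd`) describes the
models, parameter choices, numerical conventions and the generator's known
limitations.
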