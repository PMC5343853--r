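---
title: "Methods: EST library enrichment, array QC and cross-platform validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EST library enrichment, array QC and cross-platform validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamparray)
```

# Overview

`pamparray` implements an immunotranscriptomics workflow built around two
complementary measurements of the macrophage response to pathogen-associated
molecular patterns (PAMPs, here bacterial LPS and PGN):

1. **EST library comparison.** Two cDNA libraries — one primed with bacterial
   stimuli, one with viral stimuli — are sequenced as expressed sequence tags
   (ESTs). After a length filter, ESTs are clustered into contigs, and each
   contig's library composition is tested with a frequency rule: a contig is
   called enriched for a stimulus when strictly more than 75% of its member
   ESTs come from that library.
2. **Single-channel oligonucleotide array analysis.** Probe-level scans are
   quality scored, background corrected, log2 transformed, percentile-shift
   normalized, filtered on per-probe variability, summarized to gene level,
   and tested per treatment against control. Significant sets are partitioned
   into treatment-exclusive and common transcripts; GO terms are tested for
   over-representation; and fold changes are cross-validated against
   efficiency-corrected RT-qPCR (Pfaffl quantification) by Spearman rank
   correlation.

A synthetic-data module generates all three data types with known planted
truth, which is how the package demonstrates that each stage recovers what
it claims to recover.

# The EST stage

## Clustering

A full assembler builds consensus sequences; the downstream statistic here
needs only *membership*, so the package uses greedy single-linkage
clustering: two ESTs are linked when their best local alignment reaches 95%
identity over at least 40 nt (`Biostrings::pairwiseAlignment`, match 2,
mismatch −3, gap open 5, gap extend 2), and contigs are the connected
components of the link relation. A shared exact 16-mer is required before a
pair is aligned; at ≤2% per-EST divergence sibling ESTs share many 16-mers
while unrelated random sequences essentially never do, so the prefilter
changes nothing but runtime. The test suite checks the clusterer against a
brute-force all-pairs oracle that aligns every pair and finds components by
breadth-first search. Precomputed assignments (e.g. from CAP3) can be
supplied instead of the built-in clusterer. Ties are resolved by input
order, making the output deterministic.

## The enrichment rule

For a contig with $n_b$ bacterial-library and $n_v$ viral-library members,
the call is *bacterial-enriched* iff $n_b + n_v \ge m$ and
$n_b/(n_b+n_v) > 0.75$ (strictly), symmetrically for viral. Two readings
were genuinely open:

* **"longer than 100 nt"** is read strictly (`length > 100`); the
  threshold is a parameter.
* **Minimum contig size** $m$: the frequency rule alone lets a singleton
  "pass" at 100%; the package defaults to $m = 4$ (exposed as `min_total`).
  The boundary case 3:1 is exactly 75% and is deliberately *not* called.

The chance of a null contig passing the rule is a two-sided binomial tail
(≈0.125 at size 4, ≈0.04 at size 12, ≈0.01 at size 30), so with a few dozen
null transcripts per library pair roughly one false call per run is
expected. Recovery rates are therefore measured pooled over replicate
generated library pairs (`evaluate_est_recovery()`, 8 replicates by
default), which keeps the Monte-Carlo error on the reported sensitivity and
precision small.

# The array stage

## Spot quality and preprocessing

Each spot carries foreground and background intensities and their pixel
SDs; the quality ratio $R = (SI - SB)/(SDI + SDB)$ is scale invariant and
negative when background exceeds signal. Values enter the analysis as
$\log_2\max(SI - SB, 1)$: the floor of one linear unit keeps
background-dominated spots finite and is configurable.

Percentile-shift normalization subtracts each array's own percentile
(default the median, linear-interpolation quantile) from all its values, so
every column's median becomes exactly zero; the operation is idempotent.
One property worth knowing: the median is only location-invariant when most
genes are unchanged. When differential expression is asymmetric, the
treated arrays' medians move slightly, which shows up in the zero-noise
closed loop as a small constant offset on all null genes (≈0.02 log2 at
the default planted fraction). The offset is far below the fold-change
filter, but it is why the exact-recovery test evaluates the joint
p-and-fold-change call rather than the p-value alone.

## Variability filtering and probe-pair QC

Per-probe SDs across arrays are computed and probes outside a percentile
band of the SD distribution are removed (bounds inclusive). The band is a
free parameter: `sd_filter()` itself defaults to [5, 95], matching the
idea of trimming both dead and hyper-variable probes, but the assembled
pipeline defaults to [1, 100]. The reason is scientific, not numerical:
when true differential expression is present, the most variable probes
*are* the biology, and an aggressive upper cut removes exactly the
true positives. On data where high variance is known to mean artefacts,
tighten the band.

Annotated targets carry three probes; two of the three are chosen
pseudo-randomly (seeded, reproducible) and their Pearson correlation across
arrays is binned: strong $r > 0.7$, moderate $0.5 < r \le 0.7$, weak
positive $0 \le r \le 0.5$, negative $r < 0$ — the four bins partition
$[-1, 1]$. Note that in the synthetic data probe-pair correlations are high
only for differentially expressed targets: the generator gives probes
independent per-spot noise around a target mean that is constant across
replicate arrays, so null targets have nothing shared to correlate. Real
replicate arrays carry biological variation shared by all probes of a
target, which is why published platforms report predominantly strong bins.
The bin table is descriptive output, not a validated quantity.

Gene-level summarization takes the mean of retained probes within a probe
set per array and the median across probe sets of a gene; genes losing all
probes are dropped and reported.

## Differential expression

Each treatment is contrasted separately against control with a two-group
one-way fixed-effects ANOVA (an F test with 1 and $n-2$ df, equal to the
squared pooled-variance t statistic — asserted numerically in the tests);
Kruskal–Wallis is available as the non-parametric alternative. With zero
residual variance the call is decided by separation: p = 1 for equal
means, p = 0 otherwise.

Fold changes use the signed linear convention: $2^{\Delta}$ reported as is
when ≥ 1 and as $-2^{-\Delta}$ otherwise, so $|FC| \ge 1$ always and
down-regulation is negative. The default call is raw $p < 0.001$ combined
with $|FC| > 2$; Benjamini–Hochberg q-values are reported alongside but
never silently substituted. Printed percentages use the significant set of
the same condition as denominator and are formatted to two significant
figures (so 17/1201 prints as 1.4% and 1112/3353 as 33%).

The two treatments' significant sets are partitioned into
exclusive-to-LPS, exclusive-to-PGN and common transcripts by exact set
algebra, with both marginal identities
($|A| = |A_{\mathrm{excl}}| + |\mathrm{common}|$, same for B) checked.

## GO enrichment

Per term, over-representation of the DE set against the background is the
hypergeometric upper tail $P(X \ge k)$ (one-sided, the DAVID convention).
The background is the set of genes that survived QC and summarization —
only genes that could have been called DE belong in the universe. Terms
with fewer than 4 DE genes are excluded *before* correction; Bonferroni
(over the tested terms) and BH q-values are both reported because both
corrections are in common use and the choice is left to the analyst.
Annotations are used as given: no ontology-graph propagation.

# qPCR cross-validation

Pfaffl quantification corrects for amplification efficiency per primer
set:
$$\mathrm{ratio} = \frac{E_t^{\Delta Cq_t}}{E_r^{\Delta Cq_r}},$$
with $\Delta Cq$ oriented control − treated so induction gives a ratio
above 1, and 18S as the default flat reference. Efficiencies default to 2
(perfect doubling) when the input omits them; replicate wells are averaged
on the Cq scale before $\Delta Cq$. Ratios are converted to the same
signed convention as the array fold changes and the two platforms are
compared per treatment by Spearman rank correlation (average ranks on
ties; equal to Pearson on ranks, asserted in the tests). On the packaged
12-gene reference comparison both treatments exceed 0.7 (≈0.79 LPS,
≈0.77 PGN). Whether to pool treatments or correlate per treatment was an
open choice; the package computes per treatment and reports both.

# The synthetic-data generators

The generator defaults describe the study conditions once; they are not
tuned per analysis.

* **ESTs**: 30 transcripts, 300 ESTs per library, 40% of transcripts
  planted as library-enriched (split between libraries). Each transcript
  has a random 600-nt ancestor; an EST is a 3′ suffix of 250–600 nt
  (5% shortened to 60–100 nt so the length filter has work to do) with a
  per-EST substitution rate drawn below 2%, keeping sibling identity above
  the 95% clustering threshold. A planted transcript draws each EST from
  its home library with probability 0.9 — above the 75% rule in
  expectation; other transcripts draw evenly. Per-library totals are exact
  by construction.
* **Arrays**: 2000 targets, conditions control/LPS/PGN with 4 arrays each,
  3 probes per annotated target (25% of targets single-probe), 10
  spike-ins at fixed levels. Baseline log2 expression ~ N(10, 1); per-spot
  noise N(0, 0.3) on the log2 scale; additive background ~ N(20, 5) on the
  linear scale, with the same draw reported as the spot's background
  estimate, so background subtraction is exact and the zero-noise
  configuration is exactly recoverable. 5% of targets per treatment are
  planted DE, half common to both treatments; magnitudes are log-uniform
  on [2, 16], induced with probability 0.7.
* **qPCR**: up to 12 planted genes plus the flat 18S reference at Cq 15;
  a planted log2 fold change $f$ shifts the gene's Cq by $-f/\log_2 E$
  cycles; Cq noise shares `noise_sd`.

What the generators do **not** emulate: shared biological replicate
variation (see the probe-pair note above), scanner spatial artefacts, dye
chemistry, sequence-dependent probe affinity, pooling correlation between
cultures contributing to one RNA pool, and assembler consensus errors.
Passing the closed-loop tests therefore demonstrates the correctness of
the statistics and plumbing, not robustness to every failure mode of real
scans.

# Problem sizes and determinism

All randomness flows from named seeds in the configuration; fixed seeds
give byte-identical outputs (asserted on FASTA bytes and pipeline TSVs).
The test suite and the acceptance script run the default study conditions:
one 2000-target array experiment per scoring run and eight replicate EST
library pairs pooled for the enrichment rates (a few minutes of
alignment); smaller configurations are used where a property does not need
the full size.

# A worked end-to-end run

```{r pipeline, eval = FALSE}
cfg <- synth_config(n_targets = 400, n_transcripts = 10,
                    n_est_per_library = 80, seed = 42)
res <- run_pipeline(cfg, out_dir = "run1")
res$summary$n_significant
res$summary$venn
res$qpcr$correlation
```

The summary reports, for each treatment, the significant count, the
FC-filtered count and its percentage (denominator: that treatment's
significant set), the Venn partition, the probe-removal percentage, the
probe-pair correlation bins, and the per-treatment array-vs-qPCR Spearman
coefficients; every percentage recomputes from the summary's own counts.

# Known limitations

* The clusterer is a membership stand-in, not an assembler; overlapping
  ESTs that a consensus caller would split by haplotype stay together.
* Median normalization assumes a mostly unchanged transcriptome; strongly
  asymmetric regulation shifts treated arrays' locations slightly (see
  above).
* The enrichment rule's false-call rate at small contig sizes is a
  property of the rule itself; report precision only from pooled
  replicates or larger libraries.
* GO enrichment treats annotations as flat labels.
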