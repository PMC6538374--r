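# peakladder

Linking differential chromatin accessibility to differential gene
expression is hard to do peak by peak: a single ATAC-seq peak rarely maps
cleanly onto a single transcriptional change. `peakladder` implements the
population-level alternative used in regulatory-genomics studies of
chromatin remodelling (e.g. SWI/SNF-subunit knockdowns in human embryonic
stem cells): expand the differential peaks over a *ladder* of genomic
distances, count how many transcription start sites (TSS) each expansion
encompasses, and at every distance test whether differentially expressed
genes (DEGs) are over-represented among the encompassed TSS. The resulting
significance curve is read against an empirical null built from random
peak sets matched to the differential set in number and width.

The package is aimed at computational biologists analysing ATAC-seq /
RNA-seq pairs who need the statistical layer downstream of peak calling
and differential testing: peak post-processing, enrichment statistics,
signal normalization, and a synthetic-data generator to validate the whole
pipeline without sequencing data.

## The statistics

At each ladder distance *d*, peaks are expanded by *d* on both sides
(clipped to chromosome bounds), expanded ranges are unioned, and distinct
genes with TSS inside the union are counted. With

- *m* = genes carrying the target label (e.g. upregulated),
- *n* = remaining genes,
- *k* = encompassed TSS,
- *q* = encompassed TSS with the label,

the enrichment p-value is the upper tail of the hypergeometric
distribution, `P(X >= q)` (the literal `phyper(q, m, n, k, lower.tail =
FALSE)` convention `P(X > q)` is available via `tail = "exclusive"`). The
same quadruple drives region-overlap tests (differential peaks vs.
enhancer, super-enhancer or TF binding-site catalogues, with the merged
"considered regions" as universe) and TSS±window tests against ChIP-seq
peak sets.

The null model draws, typically 1000 times, a random subset of the
observed peak universe with the differential set's size and decile-binned
width profile, repeats the ladder on each draw, and summarizes the random
curves as the 5% / median / 95% quantiles of `-log10 p` per distance.

Supporting modules implement the standard peak post-processing (removal of
the top 0.1% of exceptionally high-depth regions, cross-condition merging
into considered regions, max-group-mean filtering, q-value/fold-change
thresholding into higher/lower-accessibility sets) and median-equalization
normalization: per-condition scale factors that equalize median read
counts over the above-median-signal considered regions, feeding metaplots
and per-region normalized read counts.

## Worked example

Everything below runs from a seeded synthetic bundle, so the numbers are
reproducible:

```r
library(peakladder)

cfg    <- simulation_config(seed = 42)   # 40 Mb genome, 1000 genes,
bundle <- simulate_tables(cfg)           # 5000 peaks, planted D = 50 kb
ha     <- bundle$peaks[bundle$peaks$role == "HA", ]

res <- ladder_with_null(ha, bundle$peaks, bundle$genes, label = "up",
                        distances = c(1e4, 2.5e4, 5e4, 1e5, 5e5),
                        sizes = bundle$sizes, n_random = 100, seed = 42)
res[, c("d_bp", "encompassed_tss", "deg_hits", "p_value",
        "neg_log10_p", "null_median", "null_q95")]
#>     d_bp encompassed_tss deg_hits  p_value neg_log10_p null_median null_q95
#> 1  10000             117       32 1.38e-10        9.86       0.322    1.255
#> 2  25000             199       60 2.10e-25       24.68       0.229    1.213
#> 3  50000             338       84 7.86e-38       37.10       0.232    1.232
#> 4 100000             551       86 2.03e-21       20.69       0.310    1.231
#> 5 500000             951       88 9.74e-03        2.01       0.200    0.974
```

The observed `-log10 p` rises far above the matched-random envelope
(`null_q95` ~ 1.2) out to the planted 50 kb linkage distance and decays
back toward the null as the expansions swallow most of the genome — the
signature the ladder is designed to detect. A single hypergeometric call
reproduces a desk-scale calculation directly; for a universe of 17,462
genes with 1,785 upregulated, 955 encompassed TSS of which 132 are
upregulated:

```r
hypergeom_upper_tail(132, 1785, 15677, 955)
#> [1] 0.0001735158
```

Overlap of the same HA peaks with the synthetic super-enhancer catalogue,
against the full peak universe:

```r
region_overlap_enrichment(ha, bundle$features$superenhancers, bundle$peaks)
#> Region-overlap enrichment (query_centric, inclusive tail)
#>   q = 3  m = 162  n = 4838  k = 150
#>   p = 0.8712
```

Here only 3 of 150 HA peaks fall in super-enhancers, about what the 162
super-enhancer-overlapping peaks among 5000 predict — no enrichment, and
the test says so (the generator plants no peak/super-enhancer association).

A command-line front end over the same functions ships in
`inst/cli/peakladder.R` with subcommands `simulate`, `filter-peaks`,
`merge`, `diff-call`, `ladder`, `overlap`, `tss-window`, `composition`,
`normalize`, `counts` and `metaplot`.

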