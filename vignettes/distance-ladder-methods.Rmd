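---
title: "Methods: distance-ladder enrichment, matched-random nulls, and signal normalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distance-ladder enrichment, matched-random nulls, and signal normalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakladder)
```

# The model

`peakladder` asks a population-level question: do differentially
accessible peaks sit closer to differentially expressed genes than chance
predicts, and over what genomic range? The unit of counting is the gene,
represented by its strand-aware transcription start site (TSS: the 5'
base of the gene body, `start` for `+` genes and `end - 1` for `-` genes
in 0-based half-open coordinates). For a peak set $P$, a gene table $G$
and a distance $d$:

1. every peak is expanded by $d$ bp on both sides, clipped to chromosome
   bounds;
2. expanded ranges are unioned, so a gene covered by many nearby peaks is
   counted once — the hypergeometric model below samples *distinct* genes
   without replacement and would be invalid otherwise;
3. $k$ = distinct genes with TSS inside the union, $q$ = those carrying
   the target differential label, $m$ = all labelled genes, $n = |G| - m$;
4. the enrichment p-value is $P(X \ge q)$ for
   $X \sim \mathrm{Hypergeom}(m, n, k)$.

Repeating this over an increasing ladder of distances traces how far the
peak-gene association extends. The assumptions are those of the
hypergeometric model: genes are exchangeable under the null, and the
labelled set is fixed in advance by the RNA-seq analysis. Both are
violated in subtle ways by real genomes (gene clustering, co-regulation,
domain structure), which is exactly why the package never interprets the
observed curve against its nominal p-value alone but against an empirical
null (below).

## Tail convention

The default is the inclusive upper tail $P(X \ge q)$, the standard
enrichment convention. The literal `phyper(q, m, n, k, lower.tail =
FALSE)` call computes the exclusive tail $P(X > q)$; it is exposed as
`tail = "exclusive"` so published analyses that used the raw call can be
reproduced exactly. For well-populated tails the two differ by less than
the uncertainty in any of the counts; for small $q$ they can differ
materially, which is why both are first-class rather than one being an
approximation of the other. `P(X >= q)` is evaluated through
`phyper(q - 1, ..., log.p = TRUE)`, so extreme significance does not
underflow before the final exponentiation; for plotting, p-values are
floored at `1e-300` before taking $-\log_{10}$.

## Range semantics

"A range of $d$ around a peak" is interpreted as a **radius**: the
expanded interval is `[start - d, end + d)`. This matches reading the
ladder axis as "genes within $d$ of a peak". Because the alternative
reading (total expanded width $d$, i.e. $\pm d/2$) cannot be excluded for
every published figure, `range_mode = "total_width"` implements it; the
default stays `"radius"`.

# The matched-random null

`sample_matched_peak_sets()` draws random subsets of the observed peak
universe with the differential set's exact size and a matching width
profile. Width matching uses decile bins whose edges are the target's own
width quantiles (type 7); each random set reproduces the target's per-bin
counts, drawing without replacement within a set. Decile binning is
scale-free: it adapts to any width distribution without a bandwidth
parameter. If a bin runs short of universe peaks the deficit is borrowed
from the nearest adjacent bins and the total borrow count is attached to
the result — borrowing slightly softens the match rather than failing,
because a hard failure would bias which universes can be analysed.

The per-distance p-values of the random sets are summarized as the 5%,
50% and 95% quantiles of $-\log_{10} p$ (type-7, the linear-interpolation
definition, matching the quantile convention of the plotting layer). An
observed curve exceeding the 95% line marks distances at which the
differential peaks are more gene-associated than matched random peaks —
the operative significance statement, robust to the exchangeability
violations noted above. The published workflow uses 1000 random sets;
`n_random` is a parameter, and the validation suite uses 100, which
stabilizes the 95% quantile to well within the width of the Monte Carlo
bands it is tested against.

# Overlap and composition tests

`region_overlap_enrichment()` applies the same hypergeometric machinery
at the peak level: universe = the merged considered regions, marked =
universe peaks overlapping a feature catalogue, drawn = the differential
set, hits = differential peaks overlapping the catalogue. Overlap means
at least one shared base, strand-blind, in half-open coordinates —
bookended intervals do not overlap. The differential set must be a
coordinate subset of the universe; a mismatch is an error because a
silently mismatched universe is the easiest way to fabricate enrichment.
`feature_centric` mode additionally reports how many catalogue regions
are hit, for "present in X/Y regions" statements.

`tss_window_enrichment()` is the gene-centric variant: a gene is marked
if its TSS ± `window` (default 2500 bp, i.e. a 5 kb promoter window)
intersects the feature set.

`geneset_composition()` tallies promoter chromatin classes (bivalent,
H3K4me3-only, H3K27me3-only, neither) over a gene list; classes are never
dropped when empty, fractions sum to 1, and unclassified genes are
reported as their own category rather than being discarded.
`closest_gene_composition()` maps peaks to nearest genes first
(edge-to-TSS distance, 0 inside the peak), deduplicates, then tallies.
Nearest-gene ties break to the lexicographically smallest `gene_id`:
arbitrary but deterministic, which matters for reproducible pipelines.

# Peak post-processing

- `exclude_high_depth()` removes exactly `floor(fraction * n)` peaks of
  highest depth per peak file, before merging. The floor rule never
  removes anything from sets smaller than `1/fraction` peaks —
  conservative, and deterministic under depth ties (ties break by
  chromosome then start, later-sorted removed first).
- `merge_considered_regions()` unions per-condition calls into the
  considered regions used as the statistical universe. Only strictly
  overlapping intervals coalesce by default (`merge_gap = 0`); bookended
  intervals stay separate.
- `mgm_filter()` keeps peaks whose maximum per-condition group mean
  strictly exceeds `mgm_min` — a depth floor that removes regions whose
  differential statistics would be noise-driven.
- `call_differential()` labels peaks HA / LA / unchanged from a q-value
  ceiling and a signed linear fold-change floor. Two presets encode the
  two published analysis regimes: `steady_state` (q < 0.05, FC > 1.5,
  mgm > 8) and `neural` (q < 0.01, FC > 2, mgm > 32). The source
  analyses state the stricter regime both as linear FC > 2 and as
  log2 FC > 2 in different places; rather than silently picking one, the
  threshold is an explicit knob and the presets use the linear reading.
  Fold changes in `(-1, 1)` are rejected loudly, since they indicate the
  ratio (rather than signed) convention.

# Signal normalization

`median_equalization_factors()` computes per-condition multiplicative
factors that equalize median read counts over high-signal regions:

1. per-region cross-condition mean;
2. retain regions whose mean **strictly** exceeds the median of those
   means (a literal reading of "above the median"; ties at the median are
   excluded) — this is the filter that keeps noise-level regions from
   dominating the medians. The filter statistic is the cross-condition
   mean because it is symmetric in the conditions; filtering on any
   single condition would bias its own factor;
3. the reference is the geometric mean of per-condition medians over the
   retained regions, making the result invariant to condition order and
   to relabelling of the reference condition;
4. `factor_c = reference / median_c`.

After application, all per-condition medians over the retained set equal
the reference to within floating-point error (tested at 1e-9 relative
tolerance). A condition with zero median over retained regions has no
meaningful factor and is an error.

One property worth stating because it bounds what any median-based
normalization can do: the factor estimate inherits the sampling error of
a sample median. With negative-binomial counts at dispersion
$\alpha$, the per-count coefficient of variation is at least
$\sqrt{\alpha}$ no matter how deep the sequencing, so with $R$ retained
regions the relative error of each recovered factor scales like
$\sqrt{\alpha} / \sqrt{R}$ (times an order-statistics constant, plus an
integer-discreteness term at shallow depth). At the generator's default
conditions (dispersion 0.2, ~2500 retained regions) this floor sits at
the one-to-few-percent level; exact recovery is only expected of
noiseless data, and the test suite probes both regimes.

`region_read_counts()` sums `value x covered bases` over a bedGraph
track (missing coverage contributes 0; a region on a chromosome absent
from the track is a warning, not an error, because empty coverage is
legitimate data). `metaplot()` splits each region into `n_bins` equal
sub-intervals — remainder bases go to the leftmost bins so profiles are
bit-reproducible — averages per-base signal per bin, reverses
minus-strand regions, and takes the unweighted mean across regions.
Scaled-region binning (rather than fixed-width anchors around centers)
was chosen because the region sets of interest (super-enhancers) vary
10-fold in width and the question is about their internal profile.

# The synthetic-data generator

`simulate_tables()` / `simulate()` produce every input the pipeline
reads, with planted truth recorded in a manifest. The generator defines
the package's study conditions; its defaults are fixed, not tuning
parameters:

- **Genome**: two 20 Mb chromosomes. Small enough that full
  1000-set resampling runs finish in minutes, large enough that a 2 Mb
  ladder does not saturate immediately; all sizes scale upward.
- **Genes**: 1000, uniform with a 5 kb minimum TSS spacing, random
  strands.
- **Peaks**: 5000; widths log-normal (median 400 bp, log-sd 0.5, the
  shape of typical ATAC peak-width distributions); 40% of peaks cluster
  within ~1 kb of a TSS, the rest are uniform background.
- **Differential structure**: 300 differential peaks, split HA/LA, with
  q and fold-change drawn to pass both threshold presets; each plants,
  with probability $\pi = 0.6$, a concordant label (HA→up, LA→down) on
  one gene within $D$ = 50 kb; background genes are labelled
  differential at rate $\rho = 0.02$. Concordance is planted because the
  ladder analysis pairs HA with upregulation and LA with downregulation.
- **Counts**: negative binomial, mean = width x 0.1 reads/bp x
  per-condition scale $s_c$ (defaults 1.0 / 1.3 / 0.7), dispersion 0.2
  (fixed: this is a generator, not a fitter). Tens of reads per
  median-width peak is a realistic bulk-ATAC depth.
- **Artifacts**: 3 regions at 100x depth — by construction the depth
  outliers the high-depth filter should remove.
- **Chromatin classes**: 18% bivalent baseline, enriched to 35% among
  planted differential genes, so composition analyses have signal to
  find.
- **Features**: 500 enhancers (1 kb), 30 super-enhancers (10-50 kb,
  anchored on gene neighbourhoods), 2000 TF sites (200 bp).

All randomness derives from the config seed; identical configs give
byte-identical bundles. `truth_check()` verifies manifest/file
consistency.

What the generator does **not** emulate: linkage disequilibrium of gene
regulation (each planted link is one peak to one gene), distance-decaying
contact structure, GC or mappability bias, replicate structure behind the
group means, and signal autocorrelation along the genome. Passing the
calibration and recovery tests therefore demonstrates that the
statistical machinery is correct and well-calibrated under the stated
model — not that real chromatin obeys that model. In particular the
matched-random null only matches number and width; on real data,
GC- or signal-matched nulls may be stricter.

# Validation design

The test suite validates every operation against independent oracles:
exhaustive enumeration of hypergeometric draws (complete sweep of all
universes up to 14 items), a log-factorial closed form on larger random
cases, per-base occupancy scans for every union/overlap operation, and
step-by-step recomputation for the normalization. Two system-level
properties are checked on the full pipeline:

- **Calibration**: with $\pi = 0$ (no planted linkage) the observed
  ladder statistic should exceed the 95% envelope at a fixed 50 kb
  distance in about 5% of replicates (200 seeded bundles, 100 random
  sets each; the acceptance band 5% ± 4% reflects binomial Monte Carlo
  error). The exceedance rate runs slightly below nominal because the
  hypergeometric statistic is discrete and ties with the envelope count
  as non-exceedances.
- **Recovery**: at the default planted linkage ($\pi = 0.6$, $D$ =
  50 kb) the observed curve should clear the 95% envelope at every
  distance from 10 kb to 50 kb in at least 90% of 50 seeds, with
  encompassed-TSS counts non-decreasing in distance in every run.

Problem sizes (40 Mb genome, 100-set nulls, 200/50 replicates) were
chosen so the whole suite validates the statistics at meaningful Monte
Carlo resolution while remaining a routine desk-scale run.

# Known limitations

- Strand is ignored in all overlap computations (appropriate for
  ATAC/ChIP peaks); there is no strand-aware overlap mode.
- No minimum-overlap-fraction option: one shared base counts.
- No multiple-testing correction across ladder distances or feature
  catalogues; raw p-values are reported, as is conventional for these
  envelope-calibrated curves, and `stats::p.adjust` composes trivially
  when needed.
- The differential statistics (q, fold change) are inputs, not outputs:
  the package thresholds an existing moderated-statistics table and
  deliberately does not re-implement one.
- Whether a gene table's TSS column is 0- or 1-based cannot be guessed
  from the data; the `coordinate_system` column externalizes the choice
  and defaults to the BED-native 0-based reading.
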