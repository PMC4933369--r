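---
title: "Methods: peak-set construction, gene-peak association and enrichment analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peak-set construction, gene-peak association and enrichment analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmpchip)
```

## The problem

BMP (Dpp) signalling in the early Drosophila embryo drives a
transcriptional network read out by the signal-activated Smad (pMad) and
the competing repressor Brinker (Brk). Identifying which genes that
network regulates requires integrating two very different data types:
ChIP-seq binding regions for the two factors (at two time points, called
at two p-value stringencies, in two replicates each) and an RNA-seq
derived list of differentially expressed (DE) genes. `bmpchip`
implements the interval algebra, combination rules and statistics of
that integration, together with downstream overlap analyses against
external factor tracks (insulators, pioneer factors, DamID) and
summit-centred motif enrichment.

All coordinates are BED-convention: 0-based starts, half-open ends.
Workbook-style supplementary tables are treated as 1-based inclusive and
converted on read (configurable via `one_based`). Chromosome-name
prefixes can be harmonized with `normalize_chrom()`, since mismatched
`chr` prefixes are the most common silent failure in interval work.

## Peak-set construction

A peak enters the final set only if present in both replicates
(`reproducible_peaks()`, at least 1 bp of overlap; replicate-1
coordinates are retained by default because no published rule selects a
replicate — `coords = "intersection"` gives the conservative
alternative). Where a region was called at both the 1e-4 and 1e-5
cutoffs, `stringency_refine()` swaps in the higher-resolution strict
coordinates; a loose region containing several strict calls is replaced
by all of them.

Time points are combined with late-coordinate precedence
(`combine_timepoints()`), and the four factor/time-point sets merge into
the combined BMP list with precedence pMad 3–3.5 h > Brk 3–3.5 h >
pMad 2–2.5 h > Brk 2–2.5 h (`combine_bmp()`). Beyond "late pMad
coordinates are retained", the relative order of the remaining three
sets is a design choice here: it extends the two stated rules (late over
early, pMad over Brk) transitively. Chains of overlapping peaks collapse
onto the highest-precedence member, which is the transitive application
of the same rule; no coordinates are ever invented, a property the test
suite checks on random inputs. Multiple source experiments for one
external factor are concatenated and merged (`merge_factor_datasets()`)
so a factor cannot be double-counted.

Browser read tracks are scaled by `normalization_factors()`: the mean of
all per-sample median read values divided by each sample's median, which
equalizes medians exactly.

Peaks without an explicit summit column use the interval midpoint
`floor((start + end) / 2)` as the anchor. This is a documented
assumption: published peak tables do not always carry summit columns,
and the midpoint is the only anchor computable from the interval alone.

## Gene-peak association

`gene_to_peak()` lists all (peak, gene) pairs with `|TSS − summit| ≤ d`
on the same chromosome, with d defaulting to the window ladder 5, 10,
20, 40 kb; `peak_to_gene()` is the same pairing restricted to DE genes
(or a caller-supplied subset, e.g. targets confirmed by expression
data). The TSS anchors both directions — gene-body edges are the
plausible alternative, but the TSS keeps the two directions symmetric
(their unordered pair sets coincide when the gene subset is "all
genes", a tested invariant). The window boundary is inclusive.

`association_test()` builds the 2×2 table of DE/non-DE × near/not-near
(a gene is "near" if ≥ 1 summit lies within d of its TSS; genes on
chromosomes absent from the peak set count as not near rather than
being dropped) and reports:

* Pearson's chi-square, df = 1, no continuity correction (two-sided by
  construction);
* a one-sided upper-tail binomial p: the probability of observing at
  least the DE near-count in `tot_de` trials at the non-DE near-rate —
  one-sided because the scientific question is directional ("are DE
  genes *more* likely to be near a peak"). When the non-DE near-count
  is 0 the null is degenerate; the result carries a
  `degenerate_null` flag and p is reported as 0 (or 1 when the DE
  near-count is also 0);
* the fraction of peaks with ≥ 1 DE gene in the window.

`proximity_fractions()` tabulates the two percentages over the distance
ladder; both are non-decreasing in d by construction and by test.

## Overlap analysis and phantom peaks

`percentage_overlap()` is record-based on the query side (one peak
overlapping three target records counts once): 100 × |overlapping query
records| / |query|. Before comparing an external enhancer set's
insulator overlap with the BMP peaks', regions of the external set that
themselves overlap the BMP peaks are removed (`exclusive_prep()`), so
the comparison is between disjoint region classes. `at_least_one()`
reports the fraction of peaks overlapping the union of a panel of
tracks (the union via concatenate-and-merge); whether GAF-type factors
join the panel is simply the caller's choice of list elements.

`phantom_classify()` implements the DamID rescue: candidates are the
dual-bound peaks intersecting a published phantom-peak list; candidates
present in the antibody-free DamID profile are reassigned real, the
rest stay potential phantoms. The two classes partition the candidates
exactly (tested). The reported percentage uses the dual-bound peak
count as denominator, matching the phrasing "of the dual bound peaks";
the candidate count is also returned so the alternative normalization
is one division away.

## Motif enrichment

`extract_summit_windows()` cuts 250 bp windows (125 bp either side of
the summit, half-open); windows running off a chromosome end are
skipped with a warning rather than truncated, because a shorter window
would bias per-window occurrence probabilities. `scan_motif()` matches
an IUPAC consensus on both strands — strandedness is not biologically
meaningful for the enhancer-scale factors involved — and `N` bases in
the sequence match nothing. Occurrence is binary per window (≥ 1
match), which is what a "percentage of peaks containing the motif"
means; match counts are deliberately not used.

`enrichment()` compares test windows against control windows (in
application: housekeeping-enhancer regions), reporting the two
percentages, their ratio (1 = no enrichment; infinite ratios are
flagged when the control percentage is 0) and a two-tailed Fisher's
exact p on the with/without × test/control table. The suite verifies
`fisher.test`'s two-tailed summation against an exhaustive
hypergeometric enumeration for every table with total ≤ 30.

## The synthetic-data generator

The generator exists so that every stage is testable without any
external download, with planted parameters the analysis should
recover. Defaults (chosen once, as realistic study-scale conditions):

| parameter | default | rationale |
|---|---|---|
| genome | 2 × 5 Mb | two chromosomes exercise cross-chromosome logic while keeping the suite fast |
| `n_genes`, `de_fraction` | 2000, 0.15 | ≈ 300 DE genes, the scale of an embryonic DE list |
| `n_peaks`, `peak_width` | 300, 400 bp | typical high-stringency embryo ChIP set |
| `proximity_effect`, `d0` | 3, 5 kb | a three-fold DE enrichment near summits, detectable but not trivial |
| `replicate_jitter_sd`, `replicate_dropout` | 30 bp, 0.05 | replicate peak calls agree to tens of bp and drop a few percent of calls |
| `motif_rate_test` / `motif_rate_control` | 0.4 / 0.1 | a planted four-fold occurrence ratio |
| `track_overlap_fraction` | 0.6 | the upper range of insulator co-binding |
| `gc_content` | 0.43 | Drosophila euchromatin |

DE labels are assigned *before* placement: each DE gene falls inside
the merged summit ± d0 windows with probability
`min(1, proximity_effect × base_rate)` and otherwise uniformly in
their complement, where `base_rate` is the exact covered fraction of
the genome. At `proximity_effect = 1` DE and non-DE geometry are
therefore statistically indistinguishable (the null-calibration
condition), and the DE/non-DE near-rate ratio estimates the planted
effect. Tracks overlap each reference record independently with the
planted probability, with decoy intervals placed so they cannot touch
the reference — the measured record-level overlap is exactly
binomial. All generators set the RNG seed from the config and are
byte-deterministic.

What the generator does **not** emulate: real genomes are not i.i.d.
sequence (no repeats, no local GC structure), gene TSSs are not uniform
(clustering, promoter-proximal bias), peak widths and summit offsets
are not homogeneous, and DE calling noise is absent (labels are exact).
Passing tests therefore demonstrate the correctness and calibration of
the algebra and statistics under the stated model, not robustness to
every artefact of real embryo data.

## Numerical and edge-case choices

* Half-open arithmetic throughout; book-ended intervals (gap 0) merge,
  but do not intersect (no shared base).
* `intersect_u`/`subtract_u` partition the query exactly; merging a
  target never changes query-side overlap counts (both tested).
* Degenerate association nulls are flagged rather than silently
  returning NaN.
* Empty query sets are an error where a percentage would be 0/0
  (`percentage_overlap`, `phantom_classify`), and identity cases
  (empty strict set, empty late set, empty BMP subtractor) return the
  input unchanged.
* Problem sizes in the test suite (200 random oracle instances, 200
  null permutations, 100 power and 100 enrichment replicates, full
  Fisher enumeration to n = 30) were chosen so the whole suite
  completes in about a minute and a half while keeping Monte-Carlo
  acceptance bands narrow (exact binomial 95% intervals).

## Reproducing published summary tables

`reproduce_supplementary()` recomputes, from coordinates alone,
per-sheet peak counts, pairwise pMad/Brk overlap counts per time point,
time-point retention fractions, the combined BMP list size and (given a
gene table) DE-gene counts and proximity fractions, and displays them
against expected values. It accepts either in-memory collections or
XLSX workbooks via `read_supplementary_xlsx()`, which converts 1-based
browser coordinates and coerces yes/no annotation columns to logical.
The test suite exercises this path against a fixture workbook built
from the generator's own ground truth.

## Known limitations

* The exact binomial null of the original integration software is not
  published; the construction used here (upper tail at the non-DE
  near-rate) is stated, not asserted identical.
* Which replicate's coordinates survive reproducibility filtering, and
  the precedence order below late-pMad in `combine_bmp()`, are
  documented conventions, configurable where a convention exists.
* No peak calling, read alignment, DE modelling, liftover or de-novo
  motif discovery: inputs begin at peak/gene tables, and motifs are
  supplied consensus strings.
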