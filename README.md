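# bmpchip

Tools for deciphering a BMP-responsive transcriptional network from
ChIP-seq and RNA-seq data in the early Drosophila embryo. The package is
aimed at regulatory genomicists who have (i) peak sets for the
signal-activated Smad (pMad) and the repressor Brinker (Brk) at two
developmental time points and two calling stringencies, (ii) a list of
genes differentially expressed (DE) in response to ectopic BMP/Dpp
signalling, and (iii) external interval tracks (insulator proteins,
Zelda, DamID, phantom-peak lists) — and who need the integration
statistics connecting them.

## What it computes

**Peak-set construction.** Replicate-reproducible peaks (≥ 1 bp overlap
in both replicates), coordinate refinement by stringency (strict 1e-5
calls replace the loose 1e-4 coordinates where both exist), time-point
combination with late-coordinate precedence, the combined BMP list with
precedence pMad 3–3.5 h > Brk 3–3.5 h > pMad 2–2.5 h > Brk 2–2.5 h, and
read-track normalization factors (mean of per-sample medians divided by
each sample's median).

**Gene-peak association.** With peak summit *s* and gene TSS *t*, the
pairing at window half-width *d* is all same-chromosome pairs with
|t − s| ≤ d (d ∈ {5, 10, 20, 40} kb by default). Writing the 2×2 table
of DE/non-DE × near/not-near genes, significance is assessed by
Pearson's chi-square (df = 1, no continuity correction) and a one-sided
binomial tail

&nbsp;&nbsp;&nbsp;&nbsp;P(X ≥ near_de), X ~ Binomial(tot_de, near_nonde / tot_nonde),

plus the fraction of peaks with a DE gene in the window.

**Overlap and phantom peaks.** Record-based percentage overlaps against
factor tracks (merged across source experiments), remove-before-compare
preparation of external enhancer sets, at-least-one-insulator
aggregation, and DamID-based reassignment of candidate phantom peaks
(candidates = dual-bound ∩ phantom list; those in DamID are real, the
rest stay phantom — an exact partition).

**Motif enrichment.** 250 bp summit-centred windows, IUPAC consensus
scanning on both strands (N matches nothing), and enrichment of the
per-window occurrence percentage over a control set (e.g. housekeeping
enhancers): ratio plus two-tailed Fisher's exact p.

**Synthetic data.** A seeded generator produces genomes, gene tables
with a DE subset planted near peak summits at a configurable effect
size, jittered/dropped replicate peak sets, overlap tracks with a
planted overlap fraction, and motif windows with planted occurrence
rates — so the whole pipeline is testable end to end and recovers its
planted parameters.

## Worked example

```r
library(bmpchip)

cfg  <- sim_config(seed = 42)                     # 2 x 5 Mb, 2000 genes, 300 peaks
sim  <- simulate_genes_and_peaks(cfg)
peaks <- reproducible_peaks(sim$peaks_rep1, sim$peaks_rep2)
nrow(peaks)
#> [1] 286

association_test(peaks, sim$genes, 10000)
#> Peak-gene association at d = 10000 bp
#>        near not_near
#> de      251       49
#> non_de  750      950
#> chi-square = 159.541 (p = 1.43e-36), one-sided binomial p = 1.9e-45
#> 66.4% of peaks have a DE gene within 10000 bp

proximity_fractions(peaks, sim$genes)
#>   distance pct_peaks_with_gene pct_genes_with_peak
#> 1     5000            60.48951            76.33333
#> 2    10000            66.43357            83.66667
#> 3    20000            78.67133            92.33333
#> 4    40000            89.16084            97.66667

mw <- simulate_motif_windows(cfg, "CAGGTAG")      # plant rates 0.4 vs 0.1
enrichment(mw$test, mw$control, motif_consensus("Zld", "CAGGTAG"))
#> motif Zld: 43.5% of 200 test vs 12.0% of 200 control windows (ratio 3.62), Fisher p = 1.49e-12
```

Reading the output: 286 of 300 simulated peaks are replicate-reproducible
(5% dropout was planted); DE genes are strongly enriched near summits
(the generator planted a three-fold proximity effect at 5 kb, and the
near-rate ratio (251/300)/(750/1700) ≈ 1.9 at the wider 10 kb window
reflects that signal diluted by chance proximity); both proximity
percentages rise monotonically with distance; and the Zld-site plant
(4-fold) is recovered as a 3.6-fold occurrence ratio — chance 7-mer hits
in background sequence pull the ratio below the planted value, which is
expected behaviour, not a defect.

For published supplementary workbooks, `read_supplementary_xlsx()` +
`reproduce_supplementary()` recompute per-sheet peak counts, pairwise
pMad/Brk overlaps, time-point retention, combined-list size and
proximity fractions directly from the coordinates, side by side with
expected values.

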