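# TEreg — regulatory signatures of transposable-element families

`TEreg` is an R/Bioconductor-style package for asking whether families of
transposable elements (TEs) — typically the long terminal repeats of
endogenous retroviruses — behave like gene-regulatory elements in a cell
type of interest, such as trophoblast. It is aimed at computational
(epi)genomicists who have peak sets (ChIP-seq / CUT&Tag / CUT&RUN /
DNase), a RepeatMasker-style repeat annotation, gene models and expression
matrices, and want family-level statistics rather than per-locus calls.

## The statistic at its core

For each repeat family *f* with copies *E<sub>f</sub>* and a peak set *P*,
the observed count is

> k<sub>f</sub> = #{ p ∈ P : p overlaps (≥1 bp) some e ∈ E<sub>f</sub> }

compared against N random controls in which every peak is re-placed
uniformly at random on its own chromosome, with its length preserved,
entirely inside mappable sequence (the complement of an exclusion mask).
With null counts k<sub>f</sub><sup>(1)</sup> … k<sub>f</sub><sup>(N)</sup>:

> p<sub>f</sub> = (1 + #{ i : k<sub>f</sub><sup>(i)</sup> ≥ k<sub>f</sub> }) / (N + 1),
> fold<sub>f</sub> = k<sub>f</sub> / max( mean(k<sub>f</sub><sup>(·)</sup>), 1/N )

A family is *significant* at p < 0.05 and fold > 2 with ≥ 10 copies
overlapped by peaks (BH q-values are reported alongside). Downstream
stages select candidate families (concordance between two cell contexts,
then open-chromatin tissue specificity), profile chromatin-state
combinations per copy (H3K27ac/H3K4me1/H3K4me3/H3K9me3/H3K27me3),
associate marked elements with expression changes by distance bins
(ANOVA + Tukey against the >100-kb reference group, or rank-sum tests),
detect TE-derived promoters (multi-exonic transcripts with a TSS inside
an element), and stratify cross-species expression ratios by whether
nearby elements have reciprocal-liftover orthologs. A seeded
synthetic-data module generates genomes, annotations, masks, peaks,
expression and two-species fixtures with planted structure, so the whole
pipeline is testable against ground truth.

## Worked example

Simulate a genome in which 40% of 300 peaks are planted into family
`F01`, then run the enrichment test:

```r
library(TEreg)
library(GenomicRanges)

cfg <- simulationConfig(
  seed = 42,
  chromosomes = data.frame(name = c("chr1", "chr2"), length = c(5e6, 5e6)),
  families = data.frame(name = sprintf("F%02d", 1:10), copy_number = 30L,
                        length_mean = 800, length_sd = 150),
  maskFraction = 0.1,
  peaks = list(count = 300L, length_mean = 300, length_sd = 50,
               planted = c(F01 = 0.4)))
genome <- simulateGenome(cfg)
peaks  <- simulatePeaks(cfg, genome)
enr <- familyEnrichment(peaks$peaks, genome$annotation, genome$space,
                        nPerm = 199, seed = 1)
head(enr[order(enr$p_emp, -enr$fold), ], 3)
#>  family n_copies n_obs_peaks n_elements_hit null_mean null_sd    fold p_emp  q_bh significant
#>     F01       30         121             29      1.08   1.061 111.995 0.005  0.05        TRUE
#>     F05       30           1              1      1.08   1.056   0.926 0.680  1.00       FALSE
#>     F03       30           1              1      1.11   0.961   0.905 0.695  1.00       FALSE
```

`F01` is recovered: 121 of 300 peaks overlap its copies where ~1.1 would
be expected by chance (fold ≈ 112), 29 of its 30 copies are hit, and the
empirical p-value is at its minimum attainable value 1/200 = 0.005 for
199 permutations. No other family comes close.

Planting a +1 log2 expression effect for genes within 50 kb of `F01`
copies and stratifying genes by distance:

```r
marked <- granges(familyElements(genome$annotation, "F01"))
sim <- simulateExpression(cfg, genome, marked)
fc  <- computeLog2FC(sim$expr, "A", "B")
st  <- stratifyByDistance(fc, genome$genes, marked)
st$summary
#>         bin    n   mean median
#>     overlap  128 0.9386 0.9420
#>      <=10kb   88 0.9826 0.9468
#>   10kb-50kb  378 0.9985 1.0296
#>  50kb-100kb  327 0.0368 0.0294
#>      >100kb 1079 0.0017 0.0034
st$anova_p
#> ~0 (below double precision)
```

The bins inside the planted 50-kb window recover the +1 effect; the
50–100-kb and >100-kb bins sit at zero, and the ANOVA + Tukey contrasts
against the >100-kb reference group flag exactly the near bins.

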